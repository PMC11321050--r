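---
title: "Methods: karyotype inference and aneuploidy statistics with aneukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype inference and aneuploidy statistics with aneukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aneukit quantifies whole-chromosome aneuploidy from three kinds of evidence:
single-cell RNA-seq count matrices, metaphase-spread chromosome counts, and
centromere-marker fluorescence images. This vignette explains the models and
procedures, the parameters that matter, what the synthetic-data generators do
and do not emulate, and the numerical choices made where the design was open.

```{r setup, message = FALSE}
library(aneukit)
library(dplyr)
```

## Karyotype inference from single-cell expression

The dosage model is multiplicative: when a cell carries $c$ copies of a
chromosome, the expected transcript output of every gene on it scales by
$c/2$, so a trisomy raises the chromosome's aggregate expression toward
1.5x and a monosomy lowers it toward 0.5x.

After quality filtering (default: keep cells with at least 5000 detected
genes and at most 20% mitochondrial counts), counts are normalized so every
cell has the same total (the median raw library size). For cell $c$ and
chromosome $k$ the chromosome score is the sum of normalized counts over
genes on $k$,
$$s_{c,k} = \sum_{g \in k} x^{\mathrm{norm}}_{g,c},$$
and the deviation is the ratio to the across-cell median,
$$r_{c,k} = \frac{s_{c,k}}{\operatorname{median}_{c'} s_{c',k}}.$$
A ratio rather than a difference is used because dosage is multiplicative
and ratios are scale-free; with an even number of cells the median is the
mean of the two central order statistics. Note that equal-total
normalization attenuates the dosage signal: a trisomy of a chromosome that
holds a fraction $f_k$ of the library in disomic cells yields
$r = 1.5 / (1 + 0.5 f_k)$, not 1.5, because the extra output of the
trisomic chromosome is renormalized away across the whole cell. The caller's
effect-size gates account for this.

Significance comes from a permutation null over the gene-to-chromosome
assignment: each of $B$ permutations shuffles the gene labels globally
(preserving every chromosome's gene-set size, and leaving each cell's
expression profile intact), recomputes all scores and deviations, and the
two-sided p-value with add-one smoothing is
$$p_{c,k} = \frac{1 + \#\{b : |\log r^{(b)}_{c,k}| \ge |\log r_{c,k}|\}}{1 + B}.$$
The statistic $|\log r|$ makes gains and losses symmetric on the
multiplicative scale. $B \ge 100$ is enforced; the default is $B = 999$,
giving a p-value floor of $10^{-3}$.

Calls combine significance and effect size: gain if the Benjamini–Hochberg
q-value (over all cell-chromosome pairs) is at most $\alpha = 0.05$ *and*
$r \ge 1.25$; loss if $q \le \alpha$ and $r \le 0.75$. The gates sit midway
between disomy and the expected 1.5x/0.5x dosage so that statistically
significant but biologically tiny deviations are not called. Cells are
classified by their number of gained-or-lost chromosomes: 0 euploid, 1–3
simple aneuploid, 4 or more complex aneuploid. Chromosome Y is excluded
from the default genome (near-zero expression makes its score unstable);
chromosomes with fewer than 25 genes are still called but flagged
low-confidence.

Power is limited by the p-value floor: with $B = 999$ and BH correction
over ~4600 pairs, a planted event is typically recovered only when its
observed deviation beats all 999 permutations. On the standard recovery
simulation (200 cells x 2000 genes, NB dispersion 0.1, 20% simple + 5%
complex aneuploid) precision is ~0.98–1.00 and recall ~0.90–0.97 across
seeds; misses concentrate on the smallest chromosomes (23–34 simulated
genes), whose score noise is largest.

## The count simulator

`simulate_counts()` generates the ground-truth-labelled matrices used
throughout. Per-gene baseline means are log-normal (meanlog 3, sdlog 1:
median ~20 counts, realistic several-fold spread between genes); per-cell
library-size factors are log-normal (sdlog 0.2); counts are negative
binomial with variance $\mu + \alpha\mu^2$ ($\alpha = 0$ degrades to
Poisson; default $\alpha = 0.1$, a typical single-cell dispersion).
Gains are trisomies and losses monosomies, chosen uniformly; simple cells
change 1–3 chromosomes, complex cells 4–10. Genes are spread over 22
autosomes plus X proportionally to approximate GRCh38 protein-coding gene
counts, so chromosome sizes are realistically asymmetric. Default fractions
are 20% simple and 5% complex aneuploid cells.

The simulator emulates dosage scaling, gene-level mean heterogeneity,
library-size variation and overdispersion. It does **not** emulate
segmental CNVs, doublets, ambient RNA, cell-cycle structure, dropout beyond
NB sampling, or batch effects — so passing recovery tests here demonstrates
the statistical machinery under the dosage model, not robustness to every
artefact of real single-cell data.

All generators are pure functions of their parameters and one seed; a
global seed fans out to fixed per-stage child seeds (counts, spreads, foci,
permutation, module scoring), so stages are individually reproducible.

## Spread statistics and the missegregation test

For a spread with $n_i$ chromosomes, the deviation is
$d_i = |n_i - e_i| / p_i$ with $e_i$ the nearest of 46/92/184 and $p_i$
the matching ploidy 2/4/8; karyotype complexity is the mean of the $d_i$
and karyotype heterogeneity their sample standard deviation (the $n-1$
denominator — the convention when "SD" is unqualified). Counts exactly
midway between euploid numbers (e.g. 69) go to the lower one; this is
configurable. Spread classes use $|n_i - e_i|$ with the same 0 / 1–3 / ≥4
partition. Because the class is based on the absolute difference, balanced
gain-plus-loss karyotypes (e.g. 46 chromosomes after one gain and one
loss) are invisible — a stated limitation of spread counting itself.

The missegregation test asks, per chromosome, whether its observed number
of gain-or-loss events across $n$ cells is consistent with
$\mathrm{Binomial}(n, P)$, where $P$ is the overall per-(cell, chromosome)
aneuploidy probability. $P$ is treated as user input (the reference
analysis used $n = 116$, $P = 0.21826$, an expectation of $nP = 25.3$
events per chromosome); `estimate_missegregation_p()` offers the moment
estimator total events / (cells x chromosomes). The two-sided p-value is
exact, by minimum likelihood: the sum of $\mathrm{Binomial}(n, P)$
probabilities of all outcomes whose point mass does not exceed that of the
observed count (a relative tolerance of $10^{-7}$ absorbs floating-point
ties). Tiers are marked at 0.05 / 0.01 / 0.001. Spearman correlation
against embedded GRCh38 chromosome lengths quantifies the tendency of
larger chromosomes to missegregate more often.

## Module scoring

`module_score()` scores a gene program per cell as the mean expression of
the program genes minus the mean of expression-matched controls: genes are
ranked by average expression and cut into `n_bins = 24` equal-frequency
bins; each program gene draws `n_ctrl = 100` controls from its bin
(without replacement; with replacement plus a warning when the bin is too
small). Controls exclude the entire program set, which gives the score a
clean location property: adding a constant to the program genes in one
cell moves that cell's score by exactly that constant. Scoring operates on
`log1p` of the equal-total-normalized matrix — module scores are
conventionally computed on log-normalized expression, and on that scale a
multiplicative fold-change in raw expression appears as an approximately
additive shift. The default program is the seven-gene p53 pathway set
(CDKN1A, GADD45A, PLK2, MDM2, RPS27L, TRIAP1, FAS).

`score_vs_aneuploidy()` fits ordinary least squares of score on the number
of aneuploid chromosomes and reports the Pearson correlation;
`group_scores()` compares classes with one-way ANOVA and Tukey HSD via the
standard `stats` routines.

## Centromere-foci counting

Nuclei are segmented by Otsu's threshold on the nucleus-marker channel
(8-connected components of at least 200 px). Within each nucleus the
centromere channel is thresholded again by Otsu — computed from the pixels
inside that nucleus only — and the suprathreshold pixels form the
chromosome clusters. Cluster intensity is a background-subtracted sum: the
median of the sub-threshold pixels in the nucleus is taken as local
background and removed before summation, because without it the intensity
*ratio* rule below would be offset-sensitive.

Counting assumes most centromeres are spatially separated, so the median
cluster intensity $\tilde I$ approximates one centromere's intensity. Each
cluster's base count is $\mathrm{round}(I_i / \tilde I)$ and the nucleus
total is the sum. Unusually bright or dim clusters make the ratio
unreliable, so a mitigation replaces the base count by the number of local
intensity maxima (at least 1) for the three brightest clusters of each
nucleus and for every cluster dimmer than the mean cluster intensity.
Ties in the top three are broken by cluster label order. A nucleus with a
single cluster is counted by local maxima alone and flagged. The count is
invariant under positive rescaling of the centromere channel.

Peak detection runs on a lightly smoothed image (Gaussian $\sigma$ = 0.5 px)
and a peak must be the maximum of its 3x3 neighbourhood
(`min_peak_sep = 1`). These defaults were chosen deliberately small
relative to the simulated PSF ($\sigma$ = 1.5 px): smoothing at or above
the PSF scale widens the effective spot so much that two spots merged into
one component almost never retain two local maxima, which defeats the
mitigation and produces a systematic undercount. With the light smoothing,
counting is exact on clean nuclei for any true count in 30–92, and at 20%
spot clustering with 20% intensity CV and additive noise the median
absolute count error over 50 nuclei is ~1–2.

Classification uses the foci-specific boundaries: 47 or fewer chromosomes
euploid (small deviations cannot be reliably resolved by foci counting),
48–49 simple, 50 or more complex. Mean immunostain intensity (e.g. p53) is
the arithmetic mean of that channel over the nucleus mask.

### The image simulator

`simulate_foci_image()` renders 2D three-channel images: uniform nucleus
disks on a jittered grid (never overlapping), Gaussian centromere spots,
and a uniform nuclear immunostain at a per-nucleus level, plus optional
Gaussian pixel noise. Confocal z-stacks are represented by their
max-intensity-projection equivalent; the counting algorithm is
dimensionality-agnostic and 2D keeps fixtures small. Non-clustered spots
keep at least $5\sigma$ separation so each is its own component. A
`cluster_fraction` of spots is placed within one PSF width of an anchor
spot, with the PSF width taken as the $1/e^2$ spot diameter ($4\sigma$)
and separations drawn uniformly between half a width and one width: this
spans the regime where two spots merge into one thresholded component yet
usually remain distinguishable as local maxima. Exactly coincident spots
are not simulated — they are indistinguishable in principle from a single
bright centromere, and the generator keeps clusters as well-defined pairs
(a clustered spot may touch only its own anchor, never chain across
anchors). Nucleus radii are sized automatically so the requested spot
count fits at the required separation. The simulator does not model 3D
PSFs, uneven illumination, or nucleus shape irregularity.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → infer → score → (optionally foci) →
summarize, driven by a flat YAML-serializable configuration whose unknown
keys are rejected. Outputs are plain CSV/MTX/TIFF plus a JSON run report
listing every file written; reruns with the same configuration are
byte-identical because all randomness flows from the single seed. The
default demo configuration (200 cells x 2000 genes, 999 permutations, 50
spreads, 9 nuclei) runs in well under ten minutes on one CPU; these sizes
were chosen so the full chain stays interactive while keeping per-module
statistical checks meaningful.

## Worked example

```{r example, message = FALSE, warning = FALSE}
sim <- simulate_counts(n_cells = 60, n_genes = 800, dispersion = 0.05,
                       seed = 42)
calls <- infer_karyotypes(sim$counts, sim$genes, min_genes = 5,
                          n_perm = 999, seed = 42)
glance(calls)

ch <- complexity_heterogeneity(c(45, 47, 46), min_spreads = 1)
ch$stats[, c("complexity", "heterogeneity")]

binomial_expected_events(116, 0.21826)
```

## Known limitations

- Only whole-chromosome events are called; segmental changes are out of
  scope by design.
- Recall of the permutation caller is bounded by the p-value floor
  $1/(1+B)$ after multiplicity correction; small chromosomes are hardest.
- The binomial missegregation test treats cells and chromosomes as
  exchangeable; chromosome-specific missegregation propensities violate
  its null in the direction the size-correlation test is designed to
  detect.
- Foci counting degrades when many centromeres overlap (high
  `cluster_fraction`) or when spot intensity variation approaches the
  single/double intensity gap.
- The generators emulate the study conditions, not the full messiness of
  real data; see the per-module notes above.
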