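#' Human chromosome reference table
#'
#' Approximate GRCh38 assembly lengths and Ensembl protein-coding gene
#' counts for the 24 human chromosomes. These constants shape the default
#' simulated genome (realistic size asymmetry between chromosomes) and
#' supply the length covariate for [size_missegregation_correlation()].
#' They are deliberately embedded so no annotation download is required;
#' gene counts are approximate and should not be used as an annotation
#' source.
#'
#' @param include_y Keep chromosome Y (default `FALSE`: its near-zero
#'   expression makes chromosome-level scores unstable).
#' @return A tibble with columns `chromosome`, `length_bp`,
#'   `n_protein_coding`.
#' @export
#' @examples
#' hsa_chromosomes()
hsa_chromosomes <- function(include_y = FALSE) {
  tab <- tibble::tibble(
    chromosome = c(paste0("chr", 1:22), "chrX", "chrY"),
    length_bp = c(
      248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
      159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
      114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
      58617616, 64444167, 46709983, 50818468, 156040895, 57227415
    ),
    n_protein_coding = c(
      2058, 1309, 1078, 752, 876, 1048, 989, 677, 786, 733, 1298, 1034,
      327, 830, 613, 873, 1197, 270, 1472, 544, 234, 488, 842, 71
    )
  )
  if (!include_y) tab <- dplyr::filter(tab, .data$chromosome != "chrY")
  tab
}

#' Default p53 pathway gene set
#'
#' The seven-gene p53 transcriptional program used for per-cell module
#' scoring: CDKN1A, GADD45A, PLK2, MDM2, RPS27L, TRIAP1, FAS.
#'
#' @return Character vector of gene symbols.
#' @export
p53_gene_set <- function() {
  c("CDKN1A", "GADD45A", "PLK2", "MDM2", "RPS27L", "TRIAP1", "FAS")
}

# Deterministic fan-out of one global seed into per-stage child seeds.
# Stage names are fixed; the scheme keeps children strictly below 2^31.
stage_seeds <- c(
  counts = 1L, spreads = 2L, foci = 3L, permutation = 4L,
  module_score = 5L, pipeline = 6L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(stage_seeds))
  (as.integer(seed) %% 1000000L) * 2011L + stage_seeds[[stage]] * 104729L
}

# Classify a per-cell count of aneuploid chromosomes: 0 euploid,
# 1-3 simple, >=4 complex.
aneuploidy_class <- function(n_aneuploid) {
  stopifnot(all(n_aneuploid >= 0))
  factor(
    dplyr::case_when(
      n_aneuploid == 0 ~ "euploid",
      n_aneuploid <= 3 ~ "simple",
      TRUE ~ "complex"
    ),
    levels = c("euploid", "simple", "complex")
  )
}
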