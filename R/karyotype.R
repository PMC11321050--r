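#' Quality-filter a count matrix
#'
#' Drops cells with too few detected genes or too high a mitochondrial read
#' fraction (defaults: fewer than 5000 genes detected, or more than 20%
#' mitochondrial counts). Mitochondrial genes are identified by id prefix or
#' an explicit list.
#'
#' @param counts Gene x cell matrix of nonnegative integer counts with
#'   dimnames.
#' @param min_genes_detected Minimum number of genes with count > 0.
#' @param max_mito_fraction Maximum fraction of counts from mitochondrial
#'   genes.
#' @param mito_gene_prefix Prefix identifying mitochondrial genes (default
#'   `"MT-"`).
#' @param mito_genes Optional explicit character vector of mitochondrial gene
#'   ids, overriding the prefix.
#' @return List with `counts` (filtered matrix) and `excluded` (tibble
#'   `cell_id`, `n_genes_detected`, `mito_fraction`, `reason`).
#' @export
qc_filter <- function(counts,
                      min_genes_detected = 5000,
                      max_mito_fraction = 0.20,
                      mito_gene_prefix = "MT-",
                      mito_genes = NULL) {
  check_count_matrix(counts)
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    abort("max_mito_fraction must lie in [0,1]")
  }
  mito <- if (is.null(mito_genes)) {
    startsWith(rownames(counts), mito_gene_prefix)
  } else {
    rownames(counts) %in% mito_genes
  }
  n_detected <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)

  low_genes <- n_detected < min_genes_detected
  high_mito <- mito_frac > max_mito_fraction
  drop <- low_genes | high_mito
  if (all(drop)) {
    abort(sprintf(
      "all cells excluded by QC (min_genes_detected = %d, max_mito_fraction = %.2f)",
      min_genes_detected, max_mito_fraction
    ))
  }
  excluded <- tibble::tibble(
    cell_id = colnames(counts)[drop],
    n_genes_detected = as.integer(n_detected[drop]),
    mito_fraction = as.numeric(mito_frac[drop]),
    reason = dplyr::case_when(
      low_genes[drop] & high_mito[drop] ~ "low_genes;high_mito",
      low_genes[drop] ~ "low_genes",
      TRUE ~ "high_mito"
    )
  )
  list(counts = counts[, !drop, drop = FALSE], excluded = excluded)
}

#' Equal-total library-size normalization
#'
#' Scales each cell's counts so every cell has the same total, the median raw
#' library size (so ratios between cells become comparable while the overall
#' count scale is preserved).
#'
#' @param counts Gene x cell matrix; every cell must have total count > 0.
#' @param target Total to scale to; default the median raw library size.
#' @return Dense numeric matrix of normalized counts, same dimnames.
#' @export
normalize_counts <- function(counts, target = NULL) {
  check_count_matrix(counts, allow_real = TRUE)
  tot <- Matrix::colSums(counts)
  if (any(tot <= 0)) {
    abort(sprintf("%d cell(s) have zero total count; remove before normalizing",
                  sum(tot <= 0)))
  }
  target <- target %||% median(tot)
  out <- as.matrix(counts) %*% diag(target / tot, length(tot))
  dimnames(out) <- dimnames(counts)
  out
}

#' Per-cell chromosome expression scores and median-deviation ratios
#'
#' Sums normalized counts across all genes on each chromosome to give a
#' chromosome score \eqn{s_{c,k}} per cell, then divides by the across-cell
#' median to give the deviation ratio
#' \eqn{r_{c,k} = s_{c,k} / \mathrm{median}_c(s_{c,k})}. Under the dosage
#' model a trisomy pushes \eqn{r} toward 1.5 and a monosomy toward 0.5
#' (attenuated by equal-total renormalization).
#'
#' @param norm Normalized gene x cell matrix (see [normalize_counts()]).
#' @param gene_chromosome Named character vector or tibble (`gene_id`,
#'   `chromosome`) mapping every gene to one chromosome.
#' @param min_genes Chromosomes with fewer genes are flagged low-confidence
#'   (default 25).
#' @return Object of class `chrom_scores`: list with `score` and `deviation`
#'   (cell x chromosome matrices), `flagged` (low-confidence chromosomes),
#'   `n_genes` (genes per chromosome).
#' @export
chromosome_scores <- function(norm, gene_chromosome, min_genes = 25) {
  map <- as_gene_map(gene_chromosome)
  missing <- setdiff(rownames(norm), names(map))
  if (length(missing) > 0) {
    abort(sprintf("%d gene(s) lack a chromosome assignment (e.g. %s)",
                  length(missing), missing[1]))
  }
  chrom <- map[rownames(norm)]
  sizes <- table(chrom)
  if (any(sizes == 0)) warn("chromosomes with 0 genes excluded")

  score <- score_by_chromosome(norm, chrom)
  deviation <- deviation_from_median(score)
  flagged <- names(sizes)[sizes < min_genes]
  if (length(flagged) > 0) {
    inform(sprintf("low-confidence chromosomes (< %d genes): %s",
                   min_genes, paste(flagged, collapse = ", ")))
  }
  structure(
    list(score = score, deviation = deviation, flagged = flagged,
         n_genes = as.integer(sizes), chromosomes = names(sizes)),
    class = "chrom_scores"
  )
}

#' @export
print.chrom_scores <- function(x, ...) {
  cat(sprintf("Chromosome scores: %d cells x %d chromosomes\n",
              nrow(x$score), ncol(x$score)))
  if (length(x$flagged)) {
    cat("flagged low-confidence:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn chromosome_scores Long tibble (`cell_id`, `chromosome`,
#'   `score`, `deviation`).
#' @param x A `chrom_scores` object.
#' @param ... Unused.
#' @export
#' @method tidy chrom_scores
tidy.chrom_scores <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame.table(x$score, stringsAsFactors = FALSE))
  names(long) <- c("cell_id", "chromosome", "score")
  long$deviation <- as.vector(x$deviation)
  long
}

# cell x chromosome sums of a gene x cell matrix under a gene->chromosome
# labelling; rowsum() groups genes, result transposed to cells in rows.
score_by_chromosome <- function(norm, chrom) {
  s <- t(rowsum(norm, group = chrom))
  rownames(s) <- colnames(norm)
  s
}

deviation_from_median <- function(score) {
  med <- apply(score, 2, median)
  if (any(med <= 0)) {
    abort("per-chromosome median score <= 0; check input matrix")
  }
  sweep(score, 2, med, "/")
}

#' Permutation null for chromosome-score deviations
#'
#' Builds a significance reference for each (cell, chromosome) deviation by
#' shuffling the gene-to-chromosome assignment: each permutation reassigns
#' gene labels globally (preserving the multiset of chromosome gene-set
#' sizes), recomputes all chromosome scores and deviations, and records how
#' extreme the permuted deviations are. The two-sided p-value with add-one
#' smoothing is
#' \deqn{p = (1 + \#\{|\log r^{perm}| \ge |\log r^{obs}|\}) / (1 + B).}
#'
#' @inheritParams chromosome_scores
#' @param n_perm Number of permutations (at least 100; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Cell x chromosome matrix of p-values in (0, 1].
#' @export
permutation_null <- function(norm, gene_chromosome, n_perm = 999, seed = 1) {
  if (n_perm < 100) {
    abort("n_perm must be >= 100: fewer permutations give too coarse a p-value resolution")
  }
  map <- as_gene_map(gene_chromosome)
  chrom <- map[rownames(norm)]
  obs <- deviation_from_median(score_by_chromosome(norm, chrom))
  obs_stat <- abs(log(obs))

  exceed <- matrix(0L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  withr_seed(child_seed(seed, "permutation"), {
    for (b in seq_len(n_perm)) {
      perm_chrom <- sample(chrom)
      r <- deviation_from_median(score_by_chromosome(norm, perm_chrom))
      exceed <- exceed + (abs(log(r)) >= obs_stat)
    }
  })
  (1 + exceed) / (1 + n_perm)
}

#' Call per-cell whole-chromosome gains and losses
#'
#' Combines deviation ratios with permutation p-values: a chromosome is
#' called gained in a cell when its BH-adjusted q-value is at most `alpha`
#' and its deviation ratio is at least `gain_min`; lost when q <= `alpha`
#' and the ratio is at most `loss_max`; otherwise neutral. The effect-size
#' gates sit midway between disomy and the expected 1.5x / 0.5x dosage so
#' that significant but tiny deviations are not called. Cells are then
#' classified euploid (0 events), simple (1-3) or complex (>= 4), counting
#' each gained or lost chromosome as one aneuploid chromosome.
#'
#' @param scores A `chrom_scores` object.
#' @param pvals Matrix of p-values from [permutation_null()] (same shape).
#' @param alpha FDR level for Benjamini-Hochberg adjustment over all
#'   (cell, chromosome) pairs (default 0.05).
#' @param gain_min,loss_max Deviation-ratio gates (defaults 1.25 and 0.75);
#'   requires `gain_min > 1 > loss_max > 0`.
#' @return Object of class `karyotype_calls`: `calls` (tibble `cell_id`,
#'   `chromosome`, `deviation`, `p_value`, `q_value`, `call`) and `cells`
#'   (tibble `cell_id`, `n_aneuploid`, `class`), plus `params`.
#' @export
#' @examples
#' sim <- simulate_counts(n_cells = 30, n_genes = 400, dispersion = 0, seed = 2)
#' norm <- normalize_counts(sim$counts)
#' sc <- chromosome_scores(norm, sim$genes, min_genes = 1)
#' p <- permutation_null(norm, sim$genes, n_perm = 199, seed = 2)
#' calls <- call_karyotypes(sc, p)
#' glance(calls)
call_karyotypes <- function(scores, pvals, alpha = 0.05,
                            gain_min = 1.25, loss_max = 0.75) {
  stopifnot(inherits(scores, "chrom_scores"))
  if (!(gain_min > 1 && 1 > loss_max && loss_max > 0)) {
    abort("need gain_min > 1 > loss_max > 0")
  }
  r <- scores$deviation
  if (!identical(dim(pvals), dim(r))) {
    abort("pvals must match the deviation matrix in shape")
  }
  q <- matrix(p.adjust(pvals, method = "BH"), nrow(pvals), ncol(pvals),
              dimnames = dimnames(pvals))
  call <- matrix("neutral", nrow(r), ncol(r), dimnames = dimnames(r))
  call[q <= alpha & r >= gain_min] <- "gain"
  call[q <= alpha & r <= loss_max] <- "loss"

  calls <- tibble::tibble(
    cell_id = rep(rownames(r), times = ncol(r)),
    chromosome = rep(colnames(r), each = nrow(r)),
    deviation = as.vector(r),
    p_value = as.vector(pvals),
    q_value = as.vector(q),
    call = factor(as.vector(call), levels = c("loss", "neutral", "gain"))
  )
  cells <- calls |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_aneuploid = sum(.data$call != "neutral")) |>
    dplyr::mutate(class = aneuploidy_class(.data$n_aneuploid)) |>
    dplyr::arrange(match(.data$cell_id, rownames(r)))

  structure(
    list(calls = calls, cells = cells,
         params = list(alpha = alpha, gain_min = gain_min, loss_max = loss_max)),
    class = "karyotype_calls"
  )
}

#' @export
print.karyotype_calls <- function(x, ...) {
  cat(sprintf("Karyotype calls: %d cells x %d chromosomes\n",
              nrow(x$cells), length(unique(x$calls$chromosome))))
  print(dplyr::count(x$cells, .data$class, .drop = FALSE))
  invisible(x)
}

#' @describeIn call_karyotypes Per-(cell, chromosome) calls as a tibble.
#' @param x A `karyotype_calls` object.
#' @param ... Unused.
#' @export
#' @method tidy karyotype_calls
tidy.karyotype_calls <- function(x, ...) x$calls

#' @describeIn call_karyotypes One-row summary: cells, aneuploid fraction,
#'   class counts, thresholds used.
#' @export
#' @method glance karyotype_calls
glance.karyotype_calls <- function(x, ...) {
  cls <- table(x$cells$class)
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_euploid = as.integer(cls[["euploid"]]),
    n_simple = as.integer(cls[["simple"]]),
    n_complex = as.integer(cls[["complex"]]),
    aneuploid_fraction = mean(x$cells$n_aneuploid > 0),
    alpha = x$params$alpha,
    gain_min = x$params$gain_min,
    loss_max = x$params$loss_max
  )
}

#' Heatmap of deviation ratios with calls
#'
#' @param object A `karyotype_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot karyotype_calls
autoplot.karyotype_calls <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$chromosome, y = .data$cell_id,
                               fill = log2(.data$deviation))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 deviation") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-chromosome gain and loss tallies
#'
#' Counts how often each chromosome was called gained or lost across a set
#' of cells (all cells by default).
#'
#' @param calls A `karyotype_calls` object.
#' @param cells Optional character vector of cell ids to restrict to.
#' @return Tibble `chromosome`, `n_gain`, `n_loss`, `n_events`.
#' @export
per_chromosome_event_counts <- function(calls, cells = NULL) {
  stopifnot(inherits(calls, "karyotype_calls"))
  d <- calls$calls
  if (!is.null(cells)) {
    d <- dplyr::filter(d, .data$cell_id %in% cells)
    if (nrow(d) == 0) abort("cell subset is empty")
  }
  d |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      n_gain = sum(.data$call == "gain"),
      n_loss = sum(.data$call == "loss")
    ) |>
    dplyr::mutate(n_events = .data$n_gain + .data$n_loss)
}

#' Run the full karyotype-inference chain
#'
#' Convenience wrapper: QC filter, equal-total normalization, chromosome
#' scores, permutation null, calls.
#'
#' @inheritParams qc_filter
#' @inheritParams chromosome_scores
#' @inheritParams permutation_null
#' @inheritParams call_karyotypes
#' @param qc Apply QC filtering first (default FALSE: simulated matrices are
#'   already clean).
#' @return A `karyotype_calls` object (with `excluded` attached when `qc`).
#' @export
infer_karyotypes <- function(counts, gene_chromosome, qc = FALSE,
                             min_genes_detected = 5000,
                             max_mito_fraction = 0.20,
                             min_genes = 25, n_perm = 999, alpha = 0.05,
                             gain_min = 1.25, loss_max = 0.75, seed = 1) {
  excluded <- NULL
  if (qc) {
    f <- qc_filter(counts, min_genes_detected, max_mito_fraction)
    counts <- f$counts
    excluded <- f$excluded
  }
  norm <- normalize_counts(counts)
  sc <- chromosome_scores(norm, gene_chromosome, min_genes = min_genes)
  p <- permutation_null(norm, gene_chromosome, n_perm = n_perm, seed = seed)
  out <- call_karyotypes(sc, p, alpha = alpha,
                         gain_min = gain_min, loss_max = loss_max)
  out$excluded <- excluded
  out$scores <- sc
  out
}

as_gene_map <- function(gene_chromosome) {
  if (is.data.frame(gene_chromosome)) {
    if (!all(c("gene_id", "chromosome") %in% names(gene_chromosome))) {
      abort("gene_chromosome data frame needs columns gene_id and chromosome")
    }
    map <- setNames(as.character(gene_chromosome$chromosome),
                    gene_chromosome$gene_id)
  } else {
    if (is.null(names(gene_chromosome))) {
      abort("gene_chromosome vector must be named by gene id")
    }
    map <- setNames(as.character(gene_chromosome), names(gene_chromosome))
  }
  if (anyDuplicated(names(map))) abort("duplicate gene ids in gene_chromosome")
  map
}

check_count_matrix <- function(counts, allow_real = FALSE) {
  if (is.null(dim(counts))) abort("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry gene and cell dimnames")
  }
  if (min(counts) < 0) abort("counts must be nonnegative")
  invisible(TRUE)
}
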