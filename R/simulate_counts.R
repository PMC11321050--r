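#' Simulate a single-cell count matrix with planted whole-chromosome aneuploidy
#'
#' Generates a gene-by-cell matrix of negative-binomial counts in which genes
#' on a chromosome with copy number \eqn{c} have expected counts scaled by
#' \eqn{c/2}, emulating the dosage effect by which transcript abundance across
#' a chromosome tracks its copy number. A configurable fraction of cells carry
#' simple (1-3 chromosomes changed) or complex (4 or more) aneuploidy; gains
#' are trisomies (1.5x dosage) and losses monosomies (0.5x dosage).
#'
#' Per-gene baseline means are log-normal; per-cell library-size factors are
#' log-normal; counts are negative binomial with variance
#' \eqn{\mu + \alpha \mu^2}, so `dispersion = 0` degrades to Poisson.
#' Everything is a pure function of the parameters and `seed`.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param genes_per_chromosome Named integer vector mapping chromosome to gene
#'   count, summing to `n_genes`. Default: proportional to GRCh38
#'   protein-coding gene counts over 22 autosomes plus X ([hsa_chromosomes()]).
#' @param baseline_mean_logmean,baseline_mean_logsd Log-normal parameters of
#'   per-gene baseline expected counts (defaults 3 and 1: median 20 counts).
#' @param dispersion Negative-binomial dispersion \eqn{\alpha \ge 0}.
#' @param libsize_logsd Log-normal sd of per-cell library-size factors.
#' @param aneuploid_fraction_simple,aneuploid_fraction_complex Fractions of
#'   cells planted as simple / complex aneuploid (sum at most 1).
#' @param max_aneuploid Upper bound on chromosomes changed in a complex cell.
#' @param seed Integer seed.
#' @return A list of class `aneu_sim_counts`:
#'   `counts` (integer gene x cell matrix), `genes` (tibble `gene_id`,
#'   `chromosome`), `truth` (tibble `cell_id`, `n_aneuploid`, `class`),
#'   `copies` (tibble `cell_id`, `chromosome`, `copies` for all entries
#'   differing from the diploid baseline of 2), and `params`.
#' @export
#' @examples
#' sim <- simulate_counts(n_cells = 20, n_genes = 300, seed = 1)
#' dim(sim$counts)
#' dplyr::count(sim$truth, class)
simulate_counts <- function(n_cells = 200,
                            n_genes = 2000,
                            genes_per_chromosome = NULL,
                            baseline_mean_logmean = 3,
                            baseline_mean_logsd = 1,
                            dispersion = 0.1,
                            libsize_logsd = 0.2,
                            aneuploid_fraction_simple = 0.2,
                            aneuploid_fraction_complex = 0.05,
                            max_aneuploid = 10,
                            seed = 1) {
  if (n_genes < 1 || n_cells < 1) abort("n_genes and n_cells must be positive")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (libsize_logsd < 0 || baseline_mean_logsd < 0) abort("log-sd parameters must be >= 0")
  fracs <- c(aneuploid_fraction_simple, aneuploid_fraction_complex)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1) {
    abort("aneuploid fractions must lie in [0,1] and sum to at most 1")
  }

  if (is.null(genes_per_chromosome)) {
    genes_per_chromosome <- default_genes_per_chromosome(n_genes)
  }
  if (is.null(names(genes_per_chromosome))) {
    abort("genes_per_chromosome must be a named vector")
  }
  if (sum(genes_per_chromosome) != n_genes) {
    abort("genes_per_chromosome must sum to n_genes")
  }
  chroms <- names(genes_per_chromosome)

  withr_seed(child_seed(seed, "counts"), {
    gene_chrom <- rep(chroms, times = genes_per_chromosome)
    genes <- tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chromosome = gene_chrom
    )
    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))

    base_mean <- rlnorm(n_genes, baseline_mean_logmean, baseline_mean_logsd)
    lib_factor <- rlnorm(n_cells, 0, libsize_logsd)

    # plant karyotypes: first assign class counts deterministically, then
    # shuffle cell order so class is independent of cell index
    n_simple <- round(aneuploid_fraction_simple * n_cells)
    n_complex <- round(aneuploid_fraction_complex * n_cells)
    class_vec <- sample(c(
      rep("simple", n_simple), rep("complex", n_complex),
      rep("euploid", n_cells - n_simple - n_complex)
    ))

    copy_mat <- matrix(2L, nrow = length(chroms), ncol = n_cells,
                       dimnames = list(chroms, cell_ids))
    for (j in seq_len(n_cells)) {
      n_ev <- switch(class_vec[j],
        euploid = 0L,
        simple = sample(1:3, 1),
        complex = sample(4:max_aneuploid, 1)
      )
      n_ev <- min(n_ev, length(chroms))
      if (n_ev > 0) {
        hit <- sample(chroms, n_ev)
        copy_mat[hit, j] <- ifelse(runif(n_ev) < 0.5, 1L, 3L)
      }
    }

    mu <- outer(base_mean, lib_factor) * (copy_mat[gene_chrom, , drop = FALSE] / 2)
    counts <- draw_nb(mu, dispersion)
    dimnames(counts) <- list(genes$gene_id, cell_ids)

    n_aneu <- colSums(copy_mat != 2L)
    truth <- tibble::tibble(
      cell_id = cell_ids,
      n_aneuploid = as.integer(n_aneu),
      class = aneuploidy_class(n_aneu)
    )
    copies <- tibble::as_tibble(as.data.frame.table(copy_mat,
                                                    stringsAsFactors = FALSE))
    names(copies) <- c("chromosome", "cell_id", "copies")
    copies <- dplyr::filter(copies[, c("cell_id", "chromosome", "copies")],
                            .data$copies != 2L)

    structure(
      list(
        counts = counts, genes = genes, truth = truth, copies = copies,
        params = list(
          n_cells = n_cells, n_genes = n_genes,
          genes_per_chromosome = genes_per_chromosome,
          baseline_mean_logmean = baseline_mean_logmean,
          baseline_mean_logsd = baseline_mean_logsd,
          dispersion = dispersion, libsize_logsd = libsize_logsd,
          aneuploid_fraction_simple = aneuploid_fraction_simple,
          aneuploid_fraction_complex = aneuploid_fraction_complex,
          max_aneuploid = max_aneuploid, seed = seed
        )
      ),
      class = "aneu_sim_counts"
    )
  })
}

#' @export
print.aneu_sim_counts <- function(x, ...) {
  cat(sprintf(
    "Simulated count matrix: %d genes x %d cells (%d chromosomes)\n",
    nrow(x$counts), ncol(x$counts), length(x$params$genes_per_chromosome)
  ))
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}

# Split n_genes across the default genome proportionally to protein-coding
# gene content, largest-remainder rounding so the split sums exactly.
default_genes_per_chromosome <- function(n_genes) {
  tab <- hsa_chromosomes(include_y = FALSE)
  raw <- n_genes * tab$n_protein_coding / sum(tab$n_protein_coding)
  base <- floor(raw)
  rem <- n_genes - sum(base)
  if (rem > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  if (any(base == 0)) base[base == 0] <- 1  # tiny n_genes: keep every chromosome
  # re-balance if the zero-fix overshot
  while (sum(base) > n_genes) {
    i <- which.max(base)
    base[i] <- base[i] - 1
  }
  setNames(as.integer(base), tab$chromosome)
}

draw_nb <- function(mu, dispersion) {
  n <- length(mu)
  x <- if (dispersion == 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
  matrix(as.integer(x), nrow = nrow(mu), ncol = ncol(mu))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
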