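# Independent brute-force oracles and small deterministic fixtures used
# across the suite. Everything here is loop-based and deliberately naive so
# it shares no code path with the package implementation.

# Deterministic dosage matrix: per-gene baseline means replicated across
# cells, with chromosome copy numbers scaling gene means by copies/2.
# No sampling noise at all (counts are expected values, possibly fractional).
make_dosage_matrix <- function(base_mean, gene_chrom, copy_mat) {
  n_genes <- length(base_mean)
  n_cells <- ncol(copy_mat)
  m <- matrix(0, n_genes, n_cells)
  for (j in seq_len(n_cells)) {
    m[, j] <- base_mean * copy_mat[gene_chrom, j] / 2
  }
  rownames(m) <- names(base_mean) %||% sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("c%03d", seq_len(n_cells))
  m
}

# Loop-based recomputation of chromosome scores and median-deviation ratios.
oracle_deviations <- function(norm, chrom) {
  chroms <- sort(unique(chrom))
  s <- matrix(0, ncol(norm), length(chroms),
              dimnames = list(colnames(norm), chroms))
  for (c in seq_len(ncol(norm))) {
    for (k in seq_along(chroms)) {
      s[c, k] <- sum(norm[chrom == chroms[k], c])
    }
  }
  r <- s
  for (k in seq_along(chroms)) {
    r[, k] <- s[, k] / median(s[, k])
  }
  list(score = s, deviation = r)
}

# Loop-based permutation p-values replaying the same permutation stream the
# package uses (child seed of stage "permutation").
oracle_perm_p <- function(norm, chrom, n_perm, seed) {
  obs <- oracle_deviations(norm, chrom)$deviation
  stat <- abs(log(obs))
  exceed <- matrix(0, nrow(stat), ncol(stat))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed((as.integer(seed) %% 1000000L) * 2011L + 4L * 104729L)
  for (b in seq_len(n_perm)) {
    perm <- sample(chrom)
    r <- oracle_deviations(norm, perm)$deviation
    exceed <- exceed + (abs(log(r)) >= stat)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  (1 + exceed) / (1 + n_perm)
}

# Per-spread complexity deviation recomputed arithmetically.
oracle_spread_deviation <- function(n) {
  eu <- c(46, 92, 184)
  pl <- c(2, 4, 8)
  d <- abs(n - eu)
  i <- which(d == min(d))[1]  # tie to the lower euploid number
  abs(n - eu[i]) / pl[i]
}

# Exact two-sided binomial p by explicit minimum-likelihood summation with
# log-scale pmf computed from lchoose (independent of dbinom).
oracle_binom_p <- function(k, n, P) {
  logpmf <- vapply(0:n, function(x) {
    lchoose(n, x) + x * log(P) + (n - x) * log1p(-P)
  }, numeric(1))
  pk <- logpmf[k + 1]
  min(1, sum(exp(logpmf[logpmf <= pk + log1p(1e-7)])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
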