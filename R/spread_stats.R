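#' Karyotype complexity and heterogeneity from metaphase-spread counts
#'
#' For each spread with chromosome count \eqn{n_i}, the deviation is
#' \eqn{d_i = |n_i - e_i| / p_i} where \eqn{e_i} is the nearest euploid
#' number among 46, 92, 184 and \eqn{p_i} the corresponding ploidy (2, 4, 8).
#' Karyotype complexity is the mean of the \eqn{d_i} and karyotype
#' heterogeneity their sample standard deviation. Each spread is also
#' classified from \eqn{|n_i - e_i|}: 0 euploid, 1-3 simple, >= 4 complex.
#'
#' Counts exactly midway between two euploid numbers (e.g. 69) are assigned
#' to the lower one; override with `tie = "upper"`.
#'
#' @param spreads Tibble/data frame with columns `condition` and `count`
#'   (positive integer chromosome counts), or a bare numeric vector of
#'   counts treated as one condition.
#' @param euploid_numbers,ploidies Paired reference vectors (defaults
#'   46/92/184 and 2/4/8).
#' @param tie `"lower"` (default) or `"upper"`: which euploid number claims
#'   an equidistant count.
#' @param min_spreads Conditions with fewer spreads are flagged (default 30,
#'   the conventional minimum for manual counting).
#' @return Object of class `spread_stats`: `per_spread` tibble (`condition`,
#'   `count`, `nearest_euploid`, `ploidy`, `deviation`, `class`) and `stats`
#'   tibble (`condition`, `n`, `complexity`, `heterogeneity`,
#'   `frac_euploid`, `frac_simple`, `frac_complex`, `flagged_low_n`).
#' @export
#' @examples
#' ch <- complexity_heterogeneity(c(45, 47, 46))
#' ch$stats
complexity_heterogeneity <- function(spreads,
                                     euploid_numbers = c(46, 92, 184),
                                     ploidies = c(2, 4, 8),
                                     tie = c("lower", "upper"),
                                     min_spreads = 30) {
  tie <- match.arg(tie)
  if (is.numeric(spreads)) {
    spreads <- tibble::tibble(condition = "all", count = spreads)
  }
  if (!all(c("condition", "count") %in% names(spreads))) {
    abort("spreads needs columns condition and count")
  }
  if (nrow(spreads) == 0) abort("no spread counts supplied")
  if (any(spreads$count < 1)) abort("chromosome counts must be >= 1")
  stopifnot(length(euploid_numbers) == length(ploidies))

  idx <- nearest_euploid_index(spreads$count, euploid_numbers, tie)
  per_spread <- spreads |>
    dplyr::mutate(
      nearest_euploid = euploid_numbers[idx],
      ploidy = ploidies[idx],
      deviation = abs(.data$count - .data$nearest_euploid) / .data$ploidy,
      class = aneuploidy_class(abs(.data$count - .data$nearest_euploid))
    )
  stats <- per_spread |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      complexity = mean(.data$deviation),
      heterogeneity = if (dplyr::n() > 1) sd(.data$deviation) else 0,
      frac_euploid = mean(.data$class == "euploid"),
      frac_simple = mean(.data$class == "simple"),
      frac_complex = mean(.data$class == "complex")
    ) |>
    dplyr::mutate(flagged_low_n = .data$n < min_spreads)
  if (any(stats$flagged_low_n)) {
    inform(sprintf("condition(s) with fewer than %d spreads: %s",
                   min_spreads,
                   paste(stats$condition[stats$flagged_low_n], collapse = ", ")))
  }
  structure(list(per_spread = per_spread, stats = stats),
            class = "spread_stats")
}

nearest_euploid_index <- function(count, euploid_numbers, tie = "lower") {
  ord <- order(euploid_numbers)
  eu <- euploid_numbers[ord]
  vapply(count, function(n) {
    d <- abs(n - eu)
    cand <- which(d == min(d))
    i <- if (tie == "lower") cand[1] else cand[length(cand)]
    ord[i]
  }, integer(1))
}

#' @export
print.spread_stats <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' @describeIn complexity_heterogeneity Per-spread tibble.
#' @param x A `spread_stats` object.
#' @param ... Unused.
#' @export
#' @method tidy spread_stats
tidy.spread_stats <- function(x, ...) x$per_spread

#' @describeIn complexity_heterogeneity Per-condition summary tibble.
#' @export
#' @method glance spread_stats
glance.spread_stats <- function(x, ...) x$stats

#' Karyotype histogram of spread counts by condition
#'
#' @param object A `spread_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot spread_stats
autoplot.spread_stats <- function(object, ...) {
  ggplot2::ggplot(object$per_spread,
                  ggplot2::aes(x = .data$count, fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "chromosomes per spread", y = "spreads") +
    ggplot2::theme_minimal()
}

#' Expected aneuploid events per chromosome under a binomial model
#'
#' With `n` cells and per-(cell, chromosome) aneuploidy probability `P`, the
#' expected number of gain-or-loss events per chromosome is \eqn{nP}.
#'
#' @param n Number of cells.
#' @param P Per-(cell, chromosome) aneuploidy probability.
#' @return Tibble with `expected` (\eqn{nP}) and `expected_rounded` (its
#'   nearest-integer display value).
#' @export
#' @examples
#' binomial_expected_events(116, 0.21826)
binomial_expected_events <- function(n, P) {
  if (P < 0 || P > 1) abort("P must lie in [0,1]")
  if (n < 0) abort("n must be nonnegative")
  tibble::tibble(n = n, P = P, expected = n * P,
                 expected_rounded = round(n * P))
}

#' Exact two-sided binomial test of per-chromosome missegregation counts
#'
#' Tests each chromosome's observed aneuploid-event count against
#' \eqn{\mathrm{Binomial}(n, P)}. The two-sided p-value uses the
#' minimum-likelihood method: the sum of probabilities of all outcomes whose
#' point mass does not exceed that of the observed count (within a relative
#' tolerance of 1e-7 to absorb floating-point ties). Significance tiers are
#' marked at 0.05 (*), 0.01 (**) and 0.001 (***).
#'
#' @param observed Named numeric vector or tibble (`chromosome`, `events`)
#'   of gain+loss event counts per chromosome.
#' @param n Number of cells (each chromosome can be gained or lost at most
#'   once per cell, so counts cannot exceed `n`).
#' @param P Per-(cell, chromosome) aneuploidy probability.
#' @return Tibble `chromosome`, `events`, `expected`, `p_value`, `signif`
#'   (one of "", "*", "**", "***").
#' @export
#' @examples
#' binomial_missegregation_test(c(chr1 = 40, chr2 = 20), n = 116, P = 0.21826)
binomial_missegregation_test <- function(observed, n, P) {
  if (is.data.frame(observed)) {
    obs <- setNames(observed$events, observed$chromosome)
  } else {
    obs <- observed
  }
  if (is.null(names(obs))) abort("observed must be named by chromosome")
  if (any(obs < 0) || any(obs != round(obs))) abort("event counts must be nonnegative integers")
  if (any(obs > n)) abort("an event count exceeds n: a chromosome can change at most once per cell")
  if (P < 0 || P > 1) abort("P must lie in [0,1]")

  p <- unname(vapply(obs, function(k) binom_two_sided(k, n, P), numeric(1)))
  tibble::tibble(
    chromosome = names(obs),
    events = as.integer(obs),
    expected = n * P,
    p_value = p,
    signif = dplyr::case_when(
      p < 0.001 ~ "***",
      p < 0.01 ~ "**",
      p < 0.05 ~ "*",
      TRUE ~ ""
    )
  )
}

# Minimum-likelihood two-sided exact binomial p-value: sum the pmf over all
# outcomes no more likely than the observed one. The (1 + 1e-7) factor
# guards against spurious strict inequalities from floating point.
binom_two_sided <- function(k, n, P) {
  if (P == 0) return(as.numeric(k == 0))
  if (P == 1) return(as.numeric(k == n))
  pmf <- dbinom(0:n, n, P)
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

#' Estimate the per-(cell, chromosome) aneuploidy probability
#'
#' Simple moment estimator: total events divided by cells times chromosomes.
#'
#' @param total_events Total gain+loss events across all chromosomes.
#' @param n_cells,n_chromosomes Study dimensions.
#' @return Estimated probability.
#' @export
estimate_missegregation_p <- function(total_events, n_cells, n_chromosomes) {
  if (n_cells < 1 || n_chromosomes < 1) abort("dimensions must be positive")
  total_events / (n_cells * n_chromosomes)
}

#' Rank correlation between chromosome size and missegregation frequency
#'
#' Spearman correlation of per-chromosome event counts against chromosome
#' length (GRCh38 lengths from [hsa_chromosomes()] by default), asking
#' whether larger chromosomes are missegregated more often.
#'
#' @param observed Named numeric vector or tibble (`chromosome`, `events`).
#' @param chrom_lengths Optional named vector of lengths; default the
#'   embedded GRCh38 table.
#' @return Tibble `rho`, `p_value`, `n_chromosomes`.
#' @export
size_missegregation_correlation <- function(observed, chrom_lengths = NULL) {
  if (is.data.frame(observed)) {
    obs <- setNames(observed$events, observed$chromosome)
  } else {
    obs <- observed
  }
  if (length(obs) < 5) abort("need at least 5 chromosomes")
  if (is.null(chrom_lengths)) {
    tab <- hsa_chromosomes(include_y = TRUE)
    chrom_lengths <- setNames(tab$length_bp, tab$chromosome)
  }
  missing <- setdiff(names(obs), names(chrom_lengths))
  if (length(missing) > 0) {
    abort(sprintf("no length for chromosome(s): %s", paste(missing, collapse = ", ")))
  }
  len <- chrom_lengths[names(obs)]
  if (sd(obs) == 0 || sd(len) == 0) {
    abort("correlation undefined: constant input vector")
  }
  ct <- suppressWarnings(cor.test(len, obs, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_chromosomes = length(obs))
}
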