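#' Simulate metaphase-spread chromosome counts
#'
#' Draws integer chromosome counts clustered at a near-diploid base with
#' discrete deviations, emulating manually counted metaphase spreads. Each
#' spread's count is `base_count` plus a deviation sampled from
#' `deviation_distribution`.
#'
#' @param n Number of spreads.
#' @param base_count Euploid chromosome number the distribution is centred on
#'   (default 46).
#' @param deviation_distribution Named numeric vector mapping signed integer
#'   deviations (names) to probabilities summing to 1. The default puts
#'   46% of mass at 0 with symmetric deviations out to +/-4.
#' @param condition Label recorded on every spread.
#' @param seed Integer seed.
#' @return A list of class `aneu_sim_spreads`: `spreads` (tibble `condition`,
#'   `count`) and `truth` (tibble `condition`, `count`, `deviation`).
#' @export
#' @examples
#' simulate_spreads(10, seed = 1)$spreads
simulate_spreads <- function(n,
                             base_count = 46,
                             deviation_distribution = c(
                               "-4" = 0.02, "-3" = 0.03, "-2" = 0.07,
                               "-1" = 0.15, "0" = 0.46, "1" = 0.15,
                               "2" = 0.07, "3" = 0.03, "4" = 0.02
                             ),
                             condition = "simulated",
                             seed = 1) {
  if (n < 1) abort("n must be positive")
  if (is.null(names(deviation_distribution))) {
    abort("deviation_distribution must be named by signed integer deviations")
  }
  devs <- as.integer(names(deviation_distribution))
  probs <- as.numeric(deviation_distribution)
  if (any(is.na(devs))) abort("deviation names must parse as integers")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("deviation probabilities must be nonnegative and sum to 1")
  }
  if (any(base_count + devs <= 0)) {
    abort("configuration allows chromosome counts <= 0; rejected")
  }

  withr_seed(child_seed(seed, "spreads"), {
    d <- sample(devs, n, replace = TRUE, prob = probs)
    truth <- tibble::tibble(
      condition = condition,
      count = as.integer(base_count + d),
      deviation = as.integer(d)
    )
    structure(
      list(
        spreads = truth[, c("condition", "count")],
        truth = truth,
        params = list(n = n, base_count = base_count,
                      deviation_distribution = deviation_distribution,
                      condition = condition, seed = seed)
      ),
      class = "aneu_sim_spreads"
    )
  })
}
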