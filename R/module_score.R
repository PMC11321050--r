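#' Per-cell gene-set module score with expression-matched controls
#'
#' Scores a gene program (such as the p53 pathway set) in every cell as the
#' mean expression of the program genes minus the mean expression of control
#' genes matched on average expression: all genes are ranked by their mean
#' across cells and cut into `n_bins` equal-size bins; for each program gene,
#' `n_ctrl` control genes are sampled without replacement from its bin
#' (excluding the program genes themselves). This
#' removes the component of the score driven purely by expression level.
#'
#' Expression should be log-normalized: by convention `log1p` of the
#' equal-total normalized matrix (see [normalize_counts()]); use
#' `log_transform = TRUE` to apply it here.
#'
#' @param norm Gene x cell normalized expression matrix.
#' @param genes Character vector of program gene ids (default the p53
#'   pathway set, [p53_gene_set()]).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes per program gene (default 100). When a bin
#'   holds fewer candidates the controls are sampled with replacement, with
#'   a warning.
#' @param seed Integer seed for control sampling.
#' @param log_transform Apply `log1p` before scoring (default TRUE).
#' @return Object of class `module_scores`: `scores` tibble (`cell_id`,
#'   `score`), `missing_genes` (program genes absent from the matrix),
#'   `params`.
#' @export
#' @examples
#' sim <- simulate_counts(n_cells = 30, n_genes = 500, seed = 3)
#' norm <- normalize_counts(sim$counts)
#' ms <- module_score(norm, genes = rownames(norm)[1:7], n_ctrl = 10, seed = 1)
#' head(ms$scores)
module_score <- function(norm, genes = p53_gene_set(), n_bins = 24,
                         n_ctrl = 100, seed = 1, log_transform = TRUE) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (n_ctrl < 1) abort("n_ctrl must be >= 1")
  if (length(genes) == 0) abort("empty gene set")
  present <- intersect(genes, rownames(norm))
  missing_genes <- setdiff(genes, rownames(norm))
  if (length(missing_genes) > 0) {
    warn(sprintf("%d program gene(s) absent from the matrix: %s",
                 length(missing_genes), paste(missing_genes, collapse = ", ")))
  }
  if (length(present) == 0) abort("no program genes present in the matrix")

  expr <- if (log_transform) log1p(norm) else norm
  avg <- rowMeans(expr)
  # equal-frequency bins on average expression; ties broken by rank order
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  names(bin) <- rownames(expr)

  withr_seed(child_seed(seed, "module_score"), {
    ctrl_genes <- unlist(lapply(present, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], present)
      if (length(pool) < n_ctrl) {
        warn(sprintf("bin of gene %s has only %d candidate controls; sampling with replacement",
                     g, length(pool)))
        sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl)
      }
    }))
  })

  prog_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl_genes, , drop = FALSE])
  structure(
    list(
      scores = tibble::tibble(cell_id = colnames(expr),
                              score = unname(prog_mean - ctrl_mean)),
      missing_genes = missing_genes,
      control_genes = ctrl_genes,
      params = list(genes = genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed, log_transform = log_transform)
    ),
    class = "module_scores"
  )
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("Module scores for %d cells (%d program genes, %d bins, %d controls/gene)\n",
              nrow(x$scores), length(x$params$genes) - length(x$missing_genes),
              x$params$n_bins, x$params$n_ctrl))
  print(summary(x$scores$score))
  invisible(x)
}

#' @describeIn module_score Per-cell scores as a tibble.
#' @param x A `module_scores` object.
#' @param ... Unused.
#' @export
#' @method tidy module_scores
tidy.module_scores <- function(x, ...) x$scores

#' Relate module scores to the number of aneuploid chromosomes
#'
#' Ordinary least-squares regression of per-cell module score on the number
#' of aneuploid chromosomes called per cell, with the Pearson correlation.
#'
#' @param scores A `module_scores` object (or tibble `cell_id`, `score`).
#' @param calls A `karyotype_calls` object (or tibble `cell_id`,
#'   `n_aneuploid`).
#' @return Object of class `score_aneuploidy_fit`: `fit` (the `lm`), `data`
#'   (joined tibble), `slope`, `intercept`, `pearson_r`.
#' @export
score_vs_aneuploidy <- function(scores, calls) {
  s <- if (inherits(scores, "module_scores")) scores$scores else scores
  k <- if (inherits(calls, "karyotype_calls")) calls$cells else calls
  d <- dplyr::inner_join(s, k, by = "cell_id")
  if (nrow(d) < 3) abort("need at least 3 shared cells")
  fit <- lm(score ~ n_aneuploid, data = d)
  structure(
    list(
      fit = fit, data = d,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      pearson_r = if (sd(d$score) == 0 || sd(d$n_aneuploid) == 0) NA_real_
                  else cor(d$n_aneuploid, d$score)
    ),
    class = "score_aneuploidy_fit"
  )
}

#' @export
print.score_aneuploidy_fit <- function(x, ...) {
  cat(sprintf("score ~ n_aneuploid: slope %.4g, intercept %.4g, r = %.3f (n = %d)\n",
              x$slope, x$intercept, x$pearson_r, nrow(x$data)))
  invisible(x)
}

#' @describeIn score_vs_aneuploidy Coefficient table of the underlying fit.
#' @param x A `score_aneuploidy_fit` object.
#' @param ... Unused.
#' @export
#' @method tidy score_aneuploidy_fit
tidy.score_aneuploidy_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
}

#' @describeIn score_vs_aneuploidy One-row model summary.
#' @export
#' @method glance score_aneuploidy_fit
glance.score_aneuploidy_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, pearson_r = x$pearson_r,
    r_squared = s$r.squared, sigma = s$sigma, n = nrow(x$data)
  )
}

#' Scatter of module score against aneuploid chromosome number
#'
#' @param object A `score_aneuploidy_fit` object.
#' @param ... Unused.
#' @return A ggplot with the regression line.
#' @export
#' @method autoplot score_aneuploidy_fit
autoplot.score_aneuploidy_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$n_aneuploid, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b") +
    ggplot2::labs(x = "aneuploid chromosomes per cell", y = "module score") +
    ggplot2::theme_minimal()
}

#' Compare module scores across ploidy classes
#'
#' Per-class summaries (mean, SD, n) for euploid / simple / complex cells,
#' with one-way ANOVA and Tukey honest significant differences delegated to
#' [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param scores A `module_scores` object or tibble (`cell_id`, `score`).
#' @param classes A `karyotype_calls` object or tibble (`cell_id`, `class`).
#' @return List of class `group_scores`: `summary` tibble (`class`, `n`,
#'   `mean`, `sd`), `anova` (tidy one-row tibble with F and p), `tukey`
#'   (tibble of pairwise contrasts).
#' @export
group_scores <- function(scores, classes) {
  s <- if (inherits(scores, "module_scores")) scores$scores else scores
  k <- if (inherits(classes, "karyotype_calls")) classes$cells else classes
  d <- dplyr::inner_join(s, k[, c("cell_id", "class")], by = "cell_id")
  d$class <- factor(as.character(d$class),
                    levels = c("euploid", "simple", "complex"))
  present <- levels(droplevels(d$class))
  if (length(present) < 2) {
    abort("need at least 2 ploidy classes present to compare")
  }
  if (length(present) < 3) {
    warn(sprintf("class(es) with no cells dropped: %s",
                 paste(setdiff(levels(d$class), present), collapse = ", ")))
  }
  d$class <- droplevels(d$class)
  summary_tbl <- d |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score))
  fit <- aov(score ~ class, data = d)
  av <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$class
  structure(
    list(
      summary = summary_tbl,
      anova = tibble::tibble(f_statistic = av["class", "F value"],
                             p_value = av["class", "Pr(>F)"],
                             df = av["class", "Df"]),
      tukey = tibble::tibble(
        contrast = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    ),
    class = "group_scores"
  )
}

#' @export
print.group_scores <- function(x, ...) {
  print(x$summary)
  cat(sprintf("ANOVA: F = %.3f, p = %.3g\n", x$anova$f_statistic, x$anova$p_value))
  invisible(x)
}
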