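make_block_matrix <- function(n_blocks = 6, block_size = 30, n_cells = 20,
                              seed = 4) {
  # genes come in expression blocks so average-expression bins are exact
  set.seed(seed)
  means <- rep(2^(seq_len(n_blocks)), each = block_size)
  m <- matrix(rep(means, n_cells), ncol = n_cells)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_blocks * block_size)),
                      sprintf("c%02d", seq_len(n_cells)))
  m
}

test_that("program genes identical to their bin score exactly zero", {
  m <- make_block_matrix()
  # with as many bins as blocks, each block is one bin; controls drawn from
  # the same bin have identical expression, so the score vanishes
  ms <- module_score(m, genes = rownames(m)[1:5], n_bins = 6, n_ctrl = 10,
                     seed = 1, log_transform = FALSE)
  expect_true(all(abs(ms$scores$score) < 1e-12))
})

test_that("a planted shift in half the cells is recovered within resampling error", {
  set.seed(12)
  n_cells <- 60
  m <- matrix(rlnorm(500 * n_cells, 3, 0.3), 500, n_cells,
              dimnames = list(sprintf("g%03d", 1:500),
                              sprintf("c%02d", seq_len(n_cells))))
  delta <- 0.8
  prog <- rownames(m)[sample(500, 7)]
  shifted <- seq_len(n_cells / 2)
  m2 <- m
  m2[prog, shifted] <- m2[prog, shifted] * exp(delta)  # +delta on log scale
  ms <- module_score(m2, genes = prog, n_bins = 10, n_ctrl = 25, seed = 2,
                     log_transform = TRUE)
  gap <- mean(ms$scores$score[shifted]) - mean(ms$scores$score[-shifted])
  # multiplicative exp(delta) on log1p scale is slightly below delta for
  # finite expression; allow 3 SE plus that bias margin
  se <- sd(ms$scores$score) / sqrt(n_cells / 2)
  expect_lt(abs(gap - delta), 3 * se + 0.08)
})

test_that("module scores are deterministic in the seed and report missing genes", {
  m <- make_block_matrix()
  a <- module_score(m, genes = rownames(m)[1:7], n_bins = 4, n_ctrl = 12, seed = 7)
  b <- module_score(m, genes = rownames(m)[1:7], n_bins = 4, n_ctrl = 12, seed = 7)
  expect_identical(a$scores, b$scores)
  c <- module_score(m, genes = rownames(m)[1:7], n_bins = 4, n_ctrl = 12, seed = 8)
  expect_false(identical(a$scores, c$scores))

  expect_warning(
    ms <- module_score(m, genes = c(rownames(m)[1:3], "NOPE1"), n_bins = 4,
                       n_ctrl = 5, seed = 1),
    "absent"
  )
  expect_equal(ms$missing_genes, "NOPE1")
  expect_error(suppressWarnings(module_score(m, genes = "NOPE1")), "no program genes")
  expect_error(module_score(m, genes = rownames(m)[1], n_bins = 1), "n_bins")
  # bin smaller than n_ctrl falls back to replacement with a warning
  expect_warning(module_score(m, genes = rownames(m)[1], n_bins = 6,
                              n_ctrl = 1000, seed = 1), "replacement")
})

test_that("adding a constant to program genes in one cell shifts only that score", {
  m <- make_block_matrix()
  prog <- rownames(m)[1:5]
  ms1 <- module_score(m, genes = prog, n_bins = 6, n_ctrl = 10, seed = 3,
                      log_transform = FALSE)
  m2 <- m
  m2[prog, 4] <- m2[prog, 4] + 2.5
  ms2 <- module_score(m2, genes = prog, n_bins = 6, n_ctrl = 10, seed = 3,
                      log_transform = FALSE)
  # same control draw (same seed, same bins since one cell barely moves the
  # block averages): cell 4 shifts by +2.5, others unchanged
  expect_equal(ms2$scores$score[4] - ms1$scores$score[4], 2.5)
  expect_equal(ms2$scores$score[-4], ms1$scores$score[-4])
})

test_that("null random gene sets score zero on average", {
  set.seed(31)
  m <- matrix(rlnorm(400 * 40, 2, 0.4), 400, 40,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("c%02d", 1:40)))
  means <- vapply(1:60, function(i) {
    ms <- module_score(m, genes = sample(rownames(m), 7), n_bins = 10,
                       n_ctrl = 20, seed = i)
    mean(ms$scores$score)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("score-aneuploidy regression recovers exact and noisy linear relations", {
  scores <- tibble::tibble(cell_id = sprintf("c%03d", 1:100),
                           score = NA_real_)
  calls <- tibble::tibble(cell_id = scores$cell_id,
                          n_aneuploid = rep(0:9, each = 10))
  # exactly linear: slope recovered exactly
  scores$score <- 0.3 * calls$n_aneuploid + 1
  fit <- score_vs_aneuploidy(scores, calls)
  expect_equal(fit$slope, 0.3)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$pearson_r, 1)
  # constant scores: slope 0
  scores$score <- 2
  fit0 <- score_vs_aneuploidy(scores, calls)
  expect_equal(fit0$slope, 0)
  # noisy: slope within its own CI of the truth
  set.seed(6)
  scores$score <- 0.1 * calls$n_aneuploid + rnorm(100, 0, 0.05)
  fitn <- score_vs_aneuploidy(scores, calls)
  ci <- stats::confint(fitn$fit)["n_aneuploid", ]
  expect_gt(0.1, ci[1]); expect_lt(0.1, ci[2])
  expect_s3_class(glance(fitn), "tbl_df")
  expect_s3_class(autoplot(fitn), "ggplot")
  expect_error(score_vs_aneuploidy(scores[1:2, ], calls), "at least 3")
})

test_that("group comparisons order planted class shifts and need two classes", {
  set.seed(9)
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:90),
    class = rep(c("euploid", "simple", "complex"), each = 30)
  )
  shift <- c(euploid = 0, simple = 0.4, complex = 1)
  scores <- tibble::tibble(
    cell_id = cells$cell_id,
    score = rnorm(90, shift[cells$class], 0.2)
  )
  gs <- group_scores(scores, cells)
  mu <- setNames(gs$summary$mean, as.character(gs$summary$class))
  expect_true(mu[["euploid"]] < mu[["simple"]] &&
                mu[["simple"]] < mu[["complex"]])
  expect_lt(gs$anova$p_value, 1e-6)
  expect_equal(nrow(gs$tukey), 3)
  expect_error(group_scores(scores, dplyr::mutate(cells, class = "euploid")),
               "at least 2")
  # identical distributions: class means statistically indistinguishable
  scores0 <- dplyr::mutate(scores, score = rep(c(1, 2, 3), 30))
  gs0 <- suppressWarnings(group_scores(scores0, cells))
  expect_gt(gs0$anova$p_value, 0.05)
})
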