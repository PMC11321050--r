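make_qc_matrix <- function() {
  # 6 cells x 6000 genes incl. mitochondrial block; three cells planted to
  # fail QC: c2 (low genes), c4 (high mito), c6 (both)
  set.seed(1)
  n_genes <- 6000
  genes <- c(sprintf("MT-G%02d", 1:10), sprintf("G%04d", seq_len(n_genes - 10)))
  m <- matrix(1L, n_genes, 6, dimnames = list(genes, paste0("c", 1:6)))
  m[, 2] <- 0L; m[seq_len(4999), 2] <- 1L           # 4999 genes detected
  m[1:10, 4] <- 500L                                 # mito fraction >> 0.2
  m[, 6] <- 0L; m[seq_len(100), 6] <- 1L; m[1:10, 6] <- 300L
  m
}

test_that("QC filter excludes exactly the planted failing cells with reasons", {
  m <- make_qc_matrix()
  res <- qc_filter(m)
  expect_setequal(res$excluded$cell_id, c("c2", "c4", "c6"))
  expect_equal(colnames(res$counts), c("c1", "c3", "c5"))
  ex <- res$excluded[order(res$excluded$cell_id), ]
  expect_equal(ex$reason[ex$cell_id == "c2"], "low_genes")
  expect_equal(ex$reason[ex$cell_id == "c4"], "high_mito")
  expect_equal(ex$reason[ex$cell_id == "c6"], "low_genes;high_mito")
  # a cell with exactly 4999 genes detected is excluded (strict < 5000)
  expect_true("c2" %in% res$excluded$cell_id)
  expect_equal(ex$n_genes_detected[ex$cell_id == "c2"], 4999L)
  # zero mito and enough genes is retained
  expect_false("c1" %in% res$excluded$cell_id)
  expect_error(qc_filter(m, min_genes_detected = 1e7), "all cells excluded")
})

test_that("equal-total normalization is scale-invariant and preserves targets", {
  m <- matrix(c(1, 2, 3, 2, 4, 6, 5, 1, 0), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  norm <- normalize_counts(m)
  # proportional cells become identical
  expect_equal(norm[, 1], norm[, 2])
  # all totals equal the median raw library size
  expect_equal(unname(colSums(norm)), rep(median(colSums(m)), 3))
  # single cell: unchanged
  single <- m[, 1, drop = FALSE]
  expect_equal(normalize_counts(single), single)
  m0 <- m; m0[, 2] <- 0
  expect_error(normalize_counts(m0), "zero total")
})

test_that("chromosome scores and deviations match the loop-based oracle", {
  set.seed(7)
  n_genes <- 30
  chrom <- rep(c("chr1", "chr2", "chr3"), each = 10)
  m <- matrix(rpois(n_genes * 5, 20), n_genes, 5,
              dimnames = list(sprintf("g%02d", 1:n_genes), sprintf("c%d", 1:5)))
  norm <- normalize_counts(m)
  sc <- suppressMessages(
    chromosome_scores(norm, setNames(chrom, rownames(m)), min_genes = 1)
  )
  orc <- oracle_deviations(norm, chrom)
  expect_equal(sc$score, orc$score)
  expect_equal(sc$deviation, orc$deviation)
  # permutation p-values match oracle exactly with the stream fixed
  p <- permutation_null(norm, setNames(chrom, rownames(m)),
                        n_perm = 120, seed = 31)
  orc_p <- oracle_perm_p(norm, chrom, n_perm = 120, seed = 31)
  expect_equal(unname(p), unname(orc_p))
})

test_that("identical cells give deviation 1 everywhere; cell order only permutes rows", {
  m <- matrix(rep(c(5, 9, 13), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  sc <- suppressMessages(chromosome_scores(
    m, setNames(c("chr1", "chr1", "chr2"), rownames(m)), min_genes = 1
  ))
  expect_true(all(sc$deviation == 1))

  set.seed(2)
  m2 <- matrix(rpois(40, 15), 10, 4,
               dimnames = list(sprintf("g%02d", 1:10), paste0("c", 1:4)))
  map <- setNames(rep(c("chrA", "chrB"), each = 5), rownames(m2))
  r1 <- suppressMessages(chromosome_scores(m2, map, min_genes = 1))$deviation
  perm <- c(3, 1, 4, 2)
  r2 <- suppressMessages(
    chromosome_scores(m2[, perm], map, min_genes = 1)
  )$deviation
  expect_equal(r2, r1[perm, ])
})

test_that("noise-free trisomy deviation follows the dosage-renormalization closed form", {
  # genes on 4 chromosomes; one trisomic cell for chr2 among 11 cells
  set.seed(11)
  base <- rlnorm(400, 3, 0.5)
  names(base) <- sprintf("g%03d", 1:400)
  chrom <- rep(paste0("chr", 1:4), each = 100)
  copies <- matrix(2, 4, 11, dimnames = list(paste0("chr", 1:4), NULL))
  copies["chr2", 1] <- 3
  m <- make_dosage_matrix(base, chrom, copies)
  norm <- normalize_counts(m)
  sc <- suppressMessages(
    chromosome_scores(norm, setNames(chrom, rownames(m)), min_genes = 1)
  )
  f_k <- sum(base[chrom == "chr2"]) / sum(base)
  expected <- 1.5 / (1 + 0.5 * f_k)
  expect_lt(abs(sc$deviation[1, "chr2"] / expected - 1), 0.02)
  # monotonicity: higher copy number strictly increases the deviation ratio
  r_by_copies <- vapply(c(2, 3, 4, 5), function(cp) {
    cpy <- copies; cpy["chr2", 1] <- cp
    mm <- make_dosage_matrix(base, chrom, cpy)
    scm <- suppressMessages(chromosome_scores(
      normalize_counts(mm), setNames(chrom, rownames(mm)), min_genes = 1
    ))
    scm$deviation[1, "chr2"]
  }, numeric(1))
  expect_true(all(diff(r_by_copies) > 0))
})

test_that("permutation p-values respect smoothing bounds and flag planted trisomy", {
  set.seed(21)
  base <- rlnorm(300, 3, 0.4)
  chrom <- rep(paste0("chr", 1:3), each = 100)
  copies <- matrix(2, 3, 50, dimnames = list(paste0("chr", 1:3), NULL))
  copies["chr3", 7] <- 3
  mu <- make_dosage_matrix(base, chrom, copies)
  # Poisson counts around the dosage means: null cells get genuine sampling
  # noise so their permutation p-values are roughly uniform
  m <- matrix(rpois(length(mu), mu), nrow(mu), dimnames = dimnames(mu))
  norm <- normalize_counts(m)
  map <- setNames(chrom, rownames(m))
  p <- permutation_null(norm, map, n_perm = 999, seed = 3)
  expect_true(all(p > 0 & p <= 1))
  # the planted pair attains the smoothing minimum 1/(1 + n_perm)
  expect_equal(unname(p[7, "chr3"]), 1 / 1000)
  expect_error(permutation_null(norm, map, n_perm = 50), "n_perm")
  # null pairs (drop the trisomic cell) are not wildly non-uniform
  p0 <- p[-7, c("chr1", "chr2")]
  ks <- suppressWarnings(stats::ks.test(as.vector(p0), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("calls combine FDR and effect-size gates; classes follow event counts", {
  # all-deviation-1 input: everything neutral
  m <- matrix(rep(c(5, 9, 13, 2), 5), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  sc <- suppressMessages(chromosome_scores(
    m, setNames(c("chr1", "chr1", "chr2", "chr2"), rownames(m)), min_genes = 1
  ))
  pv <- matrix(1 / 1000, 5, 2, dimnames = dimnames(sc$deviation))
  calls <- call_karyotypes(sc, pv)
  expect_true(all(calls$calls$call == "neutral"))
  expect_true(all(calls$cells$class == "euploid"))
  expect_error(call_karyotypes(sc, pv, gain_min = 0.9), "gain_min")

  # synthetic deviations: 2 events -> simple, 5 -> complex
  dev <- matrix(1, 2, 6, dimnames = list(c("a", "b"), paste0("chr", 1:6)))
  dev["a", 1:2] <- 1.5
  dev["b", 1:4] <- 1.5; dev["b", 5] <- 0.5
  sc2 <- structure(list(score = dev, deviation = dev, flagged = character(),
                        n_genes = rep(100L, 6),
                        chromosomes = colnames(dev)),
                   class = "chrom_scores")
  pv2 <- matrix(1, 2, 6, dimnames = dimnames(dev))
  pv2[dev != 1] <- 1 / 1000
  calls2 <- call_karyotypes(sc2, pv2)
  cls <- setNames(as.character(calls2$cells$class), calls2$cells$cell_id)
  expect_equal(cls[["a"]], "simple")
  expect_equal(cls[["b"]], "complex")
  expect_true(all(calls2$calls$q_value >= calls2$calls$p_value))

  ev <- per_chromosome_event_counts(calls2)
  expect_equal(sum(ev$n_gain), 6L)
  expect_equal(sum(ev$n_loss), 1L)
  expect_equal(ev$n_gain[ev$chromosome == "chr1"], 2L)
  expect_error(per_chromosome_event_counts(calls2, cells = "nope"), "empty")
})

test_that("tidy/glance accessors expose calls and summaries", {
  sim <- simulate_counts(n_cells = 24, n_genes = 200, dispersion = 0, seed = 2)
  calls <- suppressMessages(
    infer_karyotypes(sim$counts, sim$genes, min_genes = 1,
                     n_perm = 150, seed = 2)
  )
  td <- tidy(calls)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 24 * 23)
  gl <- glance(calls)
  expect_equal(gl$n_cells, 24)
  expect_equal(gl$n_euploid + gl$n_simple + gl$n_complex, 24L)
  expect_s3_class(autoplot(calls), "ggplot")
})
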