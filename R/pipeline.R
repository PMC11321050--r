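#' Default pipeline configuration
#'
#' Flat, typed key-value configuration covering every stage. Serializable to
#' YAML with [write_config()]; unknown keys are rejected on read so typos
#' cannot silently fall back to defaults.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "infer", "score", "summarize"),
    seed = 1L,
    # simulate
    n_cells = 200L, n_genes = 2000L, dispersion = 0.1, libsize_logsd = 0.2,
    aneuploid_fraction_simple = 0.2, aneuploid_fraction_complex = 0.05,
    n_spreads = 50L,
    # foci stage
    n_nuclei = 9L, foci_cluster_fraction = 0.2, foci_intensity_cv = 0.2,
    foci_noise_sd = 0.02,
    # infer
    min_genes_detected = 5000L, max_mito_fraction = 0.2, qc = FALSE,
    min_genes = 25L, n_perm = 999L, alpha = 0.05,
    gain_min = 1.25, loss_max = 0.75,
    # score
    score_genes = "p53", n_bins = 24L, n_ctrl = 100L
  )
}

#' Read and write pipeline configuration files
#'
#' YAML files holding the flat key-value configuration of
#' [default_config()]. `read_config()` starts from the defaults, overlays
#' the file, and rejects unknown keys.
#'
#' @param path YAML file path.
#' @param config Named list (subset of [default_config()] keys).
#' @return `read_config` returns the merged configuration list;
#'   `write_config` the path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  merge_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(overrides) {
  cfg <- default_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order — `simulate` (counts,
#' spreads, foci image with ground truth), `infer` (karyotype calls),
#' `score` (module scores and their relation to aneuploidy), `foci`
#' (chromosome counting on the simulated image), `summarize` (per-class cell
#' counts and truth comparison) — writing CSV/MTX/TIFF outputs plus a
#' machine-readable JSON run report. All randomness flows from the single
#' `seed` through fixed per-stage child seeds, so an identical configuration
#' reruns to byte-identical outputs.
#'
#' @param config Named list (see [default_config()]), or a YAML path.
#' @param out_dir Output directory.
#' @return A `run_report` list: `config`, `outputs` (named file paths),
#'   `stages`, `warnings`, `version`. Written as `run_report.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  warnings <- character()
  stages <- cfg$stages

  needs <- function(stage, files) {
    miss <- files[!file.exists(unlist(files))]
    if (length(miss) > 0) {
      abort(sprintf("stage '%s' needs missing upstream output: %s",
                    stage, paste(unlist(miss), collapse = ", ")))
    }
  }
  timer <- function(stage, expr) {
    t0 <- Sys.time()
    r <- expr
    message(sprintf("[aneukit] stage %-10s %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  if ("simulate" %in% stages) {
    timer("simulate", {
      sim <- simulate_counts(
        n_cells = cfg$n_cells, n_genes = cfg$n_genes,
        dispersion = cfg$dispersion, libsize_logsd = cfg$libsize_logsd,
        aneuploid_fraction_simple = cfg$aneuploid_fraction_simple,
        aneuploid_fraction_complex = cfg$aneuploid_fraction_complex,
        seed = cfg$seed
      )
      write_count_matrix(sim, file.path(out_dir, "counts"))
      outputs$counts_dir <- file.path(out_dir, "counts")
      sp <- simulate_spreads(cfg$n_spreads, seed = cfg$seed)
      outputs$spreads <- write_spreads(sp, file.path(out_dir, "spreads.csv"))
      fo <- simulate_foci_image(
        cfg$n_nuclei, foci_counts = rep(46L, cfg$n_nuclei),
        cluster_fraction = cfg$foci_cluster_fraction,
        spot_intensity_cv = cfg$foci_intensity_cv,
        noise_sd = cfg$foci_noise_sd, seed = cfg$seed
      )
      outputs$foci_tiff <- write_foci_tiff(fo, file.path(out_dir, "foci.tif"))
      readr::write_csv(fo$truth, file.path(out_dir, "foci_truth.csv"))
      outputs$foci_truth <- file.path(out_dir, "foci_truth.csv")
    })
  }

  if ("infer" %in% stages) {
    needs("infer", file.path(out_dir, "counts", "matrix.mtx"))
    timer("infer", {
      cm <- read_count_matrix(file.path(out_dir, "counts"))
      calls <- infer_karyotypes(
        cm$counts, cm$genes, qc = isTRUE(cfg$qc),
        min_genes_detected = cfg$min_genes_detected,
        max_mito_fraction = cfg$max_mito_fraction,
        min_genes = cfg$min_genes, n_perm = cfg$n_perm, alpha = cfg$alpha,
        gain_min = cfg$gain_min, loss_max = cfg$loss_max, seed = cfg$seed
      )
      readr::write_csv(calls$calls, file.path(out_dir, "calls.csv"))
      readr::write_csv(calls$cells, file.path(out_dir, "cell_classes.csv"))
      outputs$calls <- file.path(out_dir, "calls.csv")
      outputs$cell_classes <- file.path(out_dir, "cell_classes.csv")
    })
  }

  if ("score" %in% stages) {
    needs("score", file.path(out_dir, "counts", "matrix.mtx"))
    timer("score", {
      cm <- read_count_matrix(file.path(out_dir, "counts"))
      norm <- normalize_counts(cm$counts)
      genes <- if (identical(cfg$score_genes, "p53")) {
        # simulated gene ids: use the first 7 genes as a stand-in program
        if (all(p53_gene_set() %in% rownames(norm))) p53_gene_set()
        else rownames(norm)[seq_len(7)]
      } else {
        cfg$score_genes
      }
      ms <- module_score(norm, genes = genes, n_bins = cfg$n_bins,
                         n_ctrl = min(cfg$n_ctrl, nrow(norm) %/% cfg$n_bins - 1),
                         seed = cfg$seed)
      readr::write_csv(ms$scores, file.path(out_dir, "scores.csv"))
      outputs$scores <- file.path(out_dir, "scores.csv")
    })
  }

  if ("foci" %in% stages) {
    needs("foci", file.path(out_dir, "foci.tif"))
    timer("foci", {
      arr <- read_foci_tiff(file.path(out_dir, "foci.tif"))
      res <- count_chromosomes(arr)
      readr::write_csv(res, file.path(out_dir, "foci_counts.csv"))
      outputs$foci_counts <- file.path(out_dir, "foci_counts.csv")
    })
  }

  if ("summarize" %in% stages) {
    needs("summarize", file.path(out_dir, "cell_classes.csv"))
    timer("summarize", {
      cells <- readr::read_csv(file.path(out_dir, "cell_classes.csv"),
                               show_col_types = FALSE)
      truth_path <- file.path(out_dir, "counts", "truth_cells.csv")
      truth <- if (file.exists(truth_path)) {
        readr::read_csv(truth_path, show_col_types = FALSE)
      }
      summ <- summarize_calls(cells, truth)
      readr::write_csv(summ$class_counts, file.path(out_dir, "summary.csv"))
      outputs$summary <- file.path(out_dir, "summary.csv")
      if (!is.null(summ$confusion)) {
        readr::write_csv(summ$confusion, file.path(out_dir, "confusion.csv"))
        outputs$confusion <- file.path(out_dir, "confusion.csv")
      }
    })
  }

  report <- list(
    config = cfg,
    stages = stages,
    outputs = outputs,
    warnings = warnings,
    version = as.character(utils::packageVersion("aneukit"))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "run_report"
  invisible(report)
}

#' Summarize karyotype calls, optionally against ground truth
#'
#' Tallies cells per ploidy class; when a truth table is supplied, adds the
#' class confusion matrix and per-class precision/recall plus overall
#' accuracy.
#'
#' @param cells Tibble (`cell_id`, `class`) of called cells, or a
#'   `karyotype_calls` object.
#' @param truth Optional tibble (`cell_id`, `class`) of true classes.
#' @return List with `class_counts`, and when truth is given `confusion`
#'   (long tibble `true_class`, `called_class`, `n`) and `metrics`
#'   (`accuracy` plus per-class precision/recall).
#' @export
summarize_calls <- function(cells, truth = NULL) {
  if (inherits(cells, "karyotype_calls")) cells <- cells$cells
  lv <- c("euploid", "simple", "complex")
  cells$class <- factor(as.character(cells$class), levels = lv)
  out <- list(class_counts = dplyr::count(cells, .data$class, .drop = FALSE,
                                          name = "n_cells"))
  if (!is.null(truth)) {
    truth$class <- factor(as.character(truth$class), levels = lv)
    j <- dplyr::inner_join(cells, truth, by = "cell_id",
                           suffix = c("_called", "_true"))
    tab <- table(true_class = j$class_true, called_class = j$class_called)
    conf <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
    names(conf) <- c("true_class", "called_class", "n")
    per_class <- purrr::map_dfr(lv, function(cl) {
      tp <- sum(j$class_true == cl & j$class_called == cl)
      tibble::tibble(
        class = cl,
        precision = tp / max(1, sum(j$class_called == cl)),
        recall = tp / max(1, sum(j$class_true == cl))
      )
    })
    out$confusion <- conf
    out$metrics <- list(
      accuracy = mean(j$class_true == j$class_called),
      per_class = per_class
    )
  }
  out
}
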