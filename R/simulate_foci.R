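#' Simulate a centromere-foci fluorescence image with ground truth
#'
#' Renders a three-channel 2D image emulating a max-intensity projection of
#' fixed G1 nuclei: a nucleus-marker channel (uniform disks, Cdt1-like), a
#' centromere channel (diffraction-limited Gaussian spots, CENPA-like), and an
#' immunostain channel (uniform nuclear signal at a per-nucleus level,
#' p53-like). Nuclei are laid out on a jittered grid so they never overlap.
#'
#' A fraction `cluster_fraction` of spots is placed within one PSF width of
#' an already placed spot, where the PSF width is taken as the \eqn{1/e^2}
#' spot diameter (\eqn{4 \sigma}); separations are drawn uniformly between
#' half a width and one width, spanning the regime in which two spots merge
#' into one connected component after thresholding yet usually remain
#' distinguishable as separate local intensity maxima. (Fully coincident
#' spots are indistinguishable from a single bright centromere by any
#' intensity-free criterion, so they are not simulated.) The remaining spots
#' are kept at least \eqn{5 \sigma} apart so each is its own component.
#'
#' @param n_nuclei Number of nuclei.
#' @param foci_counts Integer vector, length `n_nuclei`: true spots (one per
#'   chromosome) in each nucleus.
#' @param cluster_fraction Proportion of spots placed into clusters.
#' @param psf_sigma_px Gaussian spot sigma in pixels.
#' @param spot_intensity_cv Coefficient of variation of per-spot amplitude.
#' @param background_level Additive background in all channels.
#' @param noise_sd Gaussian pixel noise sd.
#' @param p53_levels Per-nucleus immunostain level (scalar recycled).
#' @param nucleus_radius_px Nucleus disk radius; default `NULL` sizes nuclei
#'   automatically so the largest requested spot count fits at the required
#'   separation (packing fraction kept below 0.4 so rejection sampling
#'   converges).
#' @param seed Integer seed.
#' @return A list of class `aneu_sim_foci`: `image` (height x width x 3
#'   array, channels nucleus / centromere / immunostain), `truth` (tibble
#'   `nucleus_id`, `true_foci_count`, `n_clusters_truth`, `p53_level`,
#'   `center_x`, `center_y`), `spots` (tibble `nucleus_id`, `x`, `y`,
#'   `amplitude`, `cluster`), and `params`.
#' @export
#' @examples
#' sim <- simulate_foci_image(2, foci_counts = c(46, 50), seed = 1)
#' sim$truth
simulate_foci_image <- function(n_nuclei,
                                foci_counts = rep(46L, n_nuclei),
                                cluster_fraction = 0,
                                psf_sigma_px = 1.5,
                                spot_intensity_cv = 0,
                                background_level = 0.02,
                                noise_sd = 0,
                                p53_levels = 0.3,
                                nucleus_radius_px = NULL,
                                seed = 1) {
  if (length(foci_counts) != n_nuclei) {
    abort("foci_counts must have length n_nuclei")
  }
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    abort("cluster_fraction must lie in [0,1]")
  }
  if (any(foci_counts < 1)) abort("foci_counts must be >= 1")
  p53_levels <- rep_len(p53_levels, n_nuclei)

  if (is.null(nucleus_radius_px)) {
    min_sep <- 5 * psf_sigma_px
    nucleus_radius_px <- ceiling(
      (min_sep / 2) * sqrt(max(foci_counts) / 0.4) + 4 * psf_sigma_px
    )
  }

  ncol_grid <- ceiling(sqrt(n_nuclei))
  nrow_grid <- ceiling(n_nuclei / ncol_grid)
  pitch <- ceiling(2 * nucleus_radius_px + 12)
  width <- ncol_grid * pitch
  height <- nrow_grid * pitch

  withr_seed(child_seed(seed, "foci"), {
    centers <- tibble::tibble(
      nucleus_id = seq_len(n_nuclei),
      center_x = ((seq_len(n_nuclei) - 1) %% ncol_grid) * pitch + pitch / 2 +
        runif(n_nuclei, -3, 3),
      center_y = ((seq_len(n_nuclei) - 1) %/% ncol_grid) * pitch + pitch / 2 +
        runif(n_nuclei, -3, 3)
    )

    spots <- purrr::map_dfr(seq_len(n_nuclei), function(i) {
      place_spots(
        n = foci_counts[i], cx = centers$center_x[i], cy = centers$center_y[i],
        radius = nucleus_radius_px - 4 * psf_sigma_px,
        cluster_fraction = cluster_fraction, sigma = psf_sigma_px,
        nucleus_id = i
      )
    })
    spots$amplitude <- 0.6 * pmax(0.05, 1 + spot_intensity_cv * rnorm(nrow(spots)))

    nuc_ch <- matrix(background_level, height, width)
    imm_ch <- matrix(background_level, height, width)
    for (i in seq_len(n_nuclei)) {
      win <- disk_window(centers$center_x[i], centers$center_y[i],
                         nucleus_radius_px + 1, height, width)
      inside <- (win$xs - centers$center_x[i])^2 +
        (win$ys - centers$center_y[i])^2 <= nucleus_radius_px^2
      patch <- nuc_ch[win$rows, win$cols]
      patch[inside] <- 0.6
      nuc_ch[win$rows, win$cols] <- patch
      patch <- imm_ch[win$rows, win$cols]
      patch[inside] <- patch[inside] + p53_levels[i]
      imm_ch[win$rows, win$cols] <- patch
    }

    cen_ch <- matrix(background_level, height, width)
    spot_reach <- ceiling(5 * psf_sigma_px)
    for (k in seq_len(nrow(spots))) {
      win <- disk_window(spots$x[k], spots$y[k], spot_reach, height, width)
      cen_ch[win$rows, win$cols] <- cen_ch[win$rows, win$cols] +
        gaussian_spot(win$xs, win$ys, spots$x[k], spots$y[k],
                      spots$amplitude[k], psf_sigma_px)
    }

    if (noise_sd > 0) {
      nuc_ch <- nuc_ch + rnorm(length(nuc_ch), 0, noise_sd)
      cen_ch <- cen_ch + rnorm(length(cen_ch), 0, noise_sd)
      imm_ch <- imm_ch + rnorm(length(imm_ch), 0, noise_sd)
    }

    img <- array(0, dim = c(height, width, 3),
                 dimnames = list(NULL, NULL,
                                 c("nucleus", "centromere", "immunostain")))
    img[, , 1] <- pmax(nuc_ch, 0)
    img[, , 2] <- pmax(cen_ch, 0)
    img[, , 3] <- pmax(imm_ch, 0)

    n_clusters_truth <- spots |>
      dplyr::group_by(.data$nucleus_id) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$cluster)) |>
      dplyr::pull(.data$n)

    truth <- dplyr::mutate(
      centers,
      true_foci_count = as.integer(foci_counts),
      n_clusters_truth = as.integer(n_clusters_truth),
      p53_level = p53_levels,
      .after = "nucleus_id"
    )

    structure(
      list(
        image = img, truth = truth, spots = spots,
        params = list(
          n_nuclei = n_nuclei, foci_counts = foci_counts,
          cluster_fraction = cluster_fraction, psf_sigma_px = psf_sigma_px,
          spot_intensity_cv = spot_intensity_cv,
          background_level = background_level, noise_sd = noise_sd,
          p53_levels = p53_levels, nucleus_radius_px = nucleus_radius_px,
          seed = seed
        )
      ),
      class = "aneu_sim_foci"
    )
  })
}

# Place n spot centres inside a disk. Non-clustered spots keep >= 5 sigma
# separation (distinct components after thresholding); clustered spots sit
# within one FWHM (2.355 sigma) of an anchor spot.
place_spots <- function(n, cx, cy, radius, cluster_fraction, sigma, nucleus_id) {
  if (radius <= 2 * sigma) {
    abort("nucleus too small to place spots; increase nucleus_radius_px")
  }
  n_clustered <- round(cluster_fraction * n)
  n_anchor <- n - n_clustered
  if (n_anchor < 1) {
    abort("cluster_fraction too high: no anchor spots left")
  }
  min_sep <- 5 * sigma
  pts <- matrix(NA_real_, n_anchor, 2)
  tries <- 0
  placed <- 0
  while (placed < n_anchor) {
    tries <- tries + 1
    if (tries > 20000) {
      abort("could not place spots without overlap at requested density")
    }
    r <- radius * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- c(cx + r * cos(th), cy + r * sin(th))
    if (placed == 0 ||
        min((pts[seq_len(placed), 1] - p[1])^2 +
            (pts[seq_len(placed), 2] - p[2])^2) >= min_sep^2) {
      placed <- placed + 1
      pts[placed, ] <- p
    }
  }
  out <- tibble::tibble(
    nucleus_id = nucleus_id,
    x = pts[, 1], y = pts[, 2],
    cluster = seq_len(n_anchor)
  )
  if (n_clustered > 0) {
    anchors <- sample(seq_len(n_anchor), n_clustered, replace = n_clustered > n_anchor)
    psf_width <- 4 * sigma
    partners <- matrix(NA_real_, n_clustered, 2)
    for (j in seq_len(n_clustered)) {
      a <- anchors[j]
      for (try in seq_len(500)) {
        d <- runif(1, 0.5 * psf_width, psf_width)
        th <- runif(1, 0, 2 * pi)
        p <- c(out$x[a] + d * cos(th), out$y[a] + d * sin(th))
        # partner may touch only its own anchor: keep clear of all other
        # spots so clusters stay well-defined pairs, never chains
        others <- rbind(pts[-a, , drop = FALSE],
                        partners[seq_len(j - 1), , drop = FALSE])
        others <- others[stats::complete.cases(others), , drop = FALSE]
        if (nrow(others) == 0 ||
            min((others[, 1] - p[1])^2 + (others[, 2] - p[2])^2) >= (4 * sigma)^2) {
          partners[j, ] <- p
          break
        }
      }
      if (is.na(partners[j, 1])) {
        abort("could not place clustered spots without chaining; reduce density")
      }
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      nucleus_id = nucleus_id,
      x = partners[, 1], y = partners[, 2],
      cluster = anchors
    ))
  }
  out
}

gaussian_spot <- function(xs, ys, x0, y0, amplitude, sigma) {
  amplitude * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
}

# Coordinate grids for the clamped square window around (cx, cy).
disk_window <- function(cx, cy, reach, height, width) {
  rows <- max(1, floor(cy - reach)):min(height, ceiling(cy + reach))
  cols <- max(1, floor(cx - reach)):min(width, ceiling(cx + reach))
  list(
    rows = rows, cols = cols,
    xs = matrix(rep(cols, each = length(rows)), nrow = length(rows)),
    ys = matrix(rep(rows, times = length(cols)), nrow = length(rows))
  )
}
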