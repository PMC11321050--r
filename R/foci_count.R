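#' Otsu threshold of a pixel sample
#'
#' Between-class-variance-maximizing threshold over a 256-level histogram of
#' the supplied pixel values. Unlike whole-image implementations this
#' operates on an arbitrary pixel sample, so it can threshold the pixels
#' inside one nucleus mask only.
#'
#' @param values Numeric vector of pixel intensities.
#' @param levels Histogram resolution (default 256).
#' @return Threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("no finite pixel values")
  rng <- range(values)
  if (rng[1] == rng[2]) abort("constant pixel values: threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- as.numeric(tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                           nbins = levels))
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  w1 <- w[levels] - w
  mu_tot <- mu[levels]
  # between-class variance for thresholds after each bin
  bcv <- ifelse(w > 0 & w1 > 0, (mu_tot * w / w[levels] - mu)^2 *
                  w[levels]^2 / (w * w1), NA_real_)
  # equivalently w0*w1*(m0-m1)^2 up to a constant factor; argmax is what matters
  k <- which.max(bcv)
  breaks[k + 1]
}

# 8-connected component labelling of a binary matrix: 4-connected labelling
# via EBImage::bwlabel, then diagonal neighbours merged with union-find.
label_components8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (dd[2] == 1) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (dd[2] == 1) 2:w else seq_len(w - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Segment nuclei from the nucleus-marker channel
#'
#' Otsu-thresholds the nucleus channel and keeps 8-connected components of
#' at least `min_area_px` pixels.
#'
#' @param img `aneu_sim_foci` object, 3D array (height x width x channels),
#'   or 2D matrix of the nucleus channel.
#' @param min_area_px Minimum component area (default 200).
#' @param channel Channel index of the nucleus marker when `img` is 3D.
#' @return Integer label matrix (0 = background) with attribute `centroids`
#'   (tibble `nucleus_id`, `center_x`, `center_y`, `area_px`).
#' @export
segment_nuclei <- function(img, min_area_px = 200, channel = 1) {
  ch <- get_channel(img, channel)
  th <- otsu_threshold(as.vector(ch))
  lab <- label_components8(ch > th)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) {
    warn("no nuclei of sufficient area found")
    lab[] <- 0
    return(structure(lab, centroids = tibble::tibble(
      nucleus_id = integer(), center_x = numeric(), center_y = numeric(),
      area_px = integer()
    )))
  }
  relabel <- rep(0L, length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  cent <- purrr::map_dfr(seq_along(keep), function(i) {
    px <- which(out == i, arr.ind = TRUE)
    tibble::tibble(nucleus_id = i, center_x = mean(px[, 2]),
                   center_y = mean(px[, 1]), area_px = nrow(px))
  })
  structure(out, centroids = cent)
}

#' Segment centromere clusters within each nucleus
#'
#' Applies a per-nucleus Otsu threshold to the centromere channel inside
#' each nucleus mask and labels the suprathreshold pixels into 8-connected
#' clusters. Cluster intensities are background-subtracted sums: the
#' per-nucleus median of sub-threshold pixels is taken as the local
#' background and removed from every pixel before summation.
#'
#' @param img `aneu_sim_foci` object or 3D array.
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param channel Centromere channel index (default 2).
#' @return Object of class `cluster_set`: `clusters` tibble (`nucleus_id`,
#'   `cluster_id`, `intensity`, `area_px`), `label_matrix` (cluster labels,
#'   unique across nuclei), `background` (per-nucleus background tibble).
#' @export
segment_clusters <- function(img, nucleus_labels, channel = 2) {
  ch <- get_channel(img, channel)
  n_nuc <- max(nucleus_labels)
  if (n_nuc == 0) abort("no nuclei in label matrix")
  all_lab <- matrix(0L, nrow(ch), ncol(ch))
  clusters <- list()
  bg_tbl <- list()
  next_id <- 0L
  for (i in seq_len(n_nuc)) {
    in_mask <- nucleus_labels == i
    v <- ch[in_mask]
    th <- tryCatch(otsu_threshold(v), error = function(e) NA_real_)
    if (is.na(th) || !any(v > th)) {
      warn(sprintf("nucleus %d has no suprathreshold centromere pixels", i))
      bg_tbl[[i]] <- tibble::tibble(nucleus_id = i, background = NA_real_,
                                    threshold = th)
      next
    }
    background <- median(v[v <= th])
    binary <- matrix(FALSE, nrow(ch), ncol(ch))
    binary[in_mask] <- ch[in_mask] > th
    lab <- label_components8(binary)
    k <- max(lab)
    fg <- lab > 0
    lab_v <- lab[fg]
    val_v <- pmax(ch[fg] - background, 0)
    vals <- tibble::tibble(
      nucleus_id = i,
      cluster_id = next_id + seq_len(k),
      intensity = as.vector(rowsum(val_v, lab_v)),
      area_px = tabulate(lab_v, nbins = k)
    )
    all_lab[fg] <- next_id + lab_v
    next_id <- next_id + k
    clusters[[i]] <- vals
    bg_tbl[[i]] <- tibble::tibble(nucleus_id = i, background = background,
                                  threshold = th)
  }
  structure(
    list(clusters = dplyr::bind_rows(clusters),
         label_matrix = all_lab,
         background = dplyr::bind_rows(bg_tbl)),
    class = "cluster_set"
  )
}

#' Count chromosomes per nucleus from centromere clusters
#'
#' Implements intensity-ratio counting with local-maxima mitigation. Within
#' each nucleus the median cluster intensity approximates the intensity of a
#' single centromere (assuming most are separated), so each cluster's base
#' count is its intensity divided by the median, rounded to the nearest
#' integer. Because unusually bright or dim clusters make that ratio
#' unreliable, the three highest-intensity clusters and every cluster dimmer
#' than the mean cluster intensity are instead counted by their number of
#' local intensity maxima (at least 1). The nucleus total N is the sum of
#' per-cluster counts.
#'
#' @param cs A `cluster_set` from [segment_clusters()].
#' @param img The image (for local-maxima detection on the centromere
#'   channel).
#' @param channel Centromere channel index (default 2).
#' @param smooth_sigma Gaussian sigma (pixels) applied before peak detection
#'   (default 0.5; kept well below the PSF sigma so that two spots that are
#'   merged as a component but distinct as intensity maxima are not blurred
#'   into one peak).
#' @param min_peak_sep Minimum peak separation in pixels (default 1): a peak
#'   must be the maximum of its (2 sep + 1)^2 neighbourhood.
#' @return Tibble `nucleus_id`, `n_clusters`, `foci_count`, `class`,
#'   `flagged` (TRUE when a nucleus had a single cluster and was counted by
#'   local maxima alone).
#' @export
count_foci <- function(cs, img, channel = 2, smooth_sigma = 0.5,
                       min_peak_sep = 1) {
  stopifnot(inherits(cs, "cluster_set"))
  if (nrow(cs$clusters) == 0) abort("no clusters to count")
  ch <- get_channel(img, channel)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(ch),
                                          sigma = smooth_sigma))
  peak_ok <- local_max_mask(sm, min_peak_sep)
  # plateaus of tied maxima collapse to one peak each; tally peaks per cluster
  peak_comp <- label_components8(peak_ok & cs$label_matrix > 0)
  peaks_per_cluster <- rep(0L, max(cs$clusters$cluster_id))
  if (max(peak_comp) > 0) {
    first_px <- match(seq_len(max(peak_comp)), peak_comp)
    tal <- tabulate(cs$label_matrix[first_px],
                    nbins = max(cs$clusters$cluster_id))
    peaks_per_cluster <- tal
  }

  cs$clusters |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::group_modify(function(d, key) {
      i_median <- median(d$intensity)
      i_mean <- mean(d$intensity)
      base <- round(d$intensity / i_median)
      top3 <- utils::head(order(d$intensity, decreasing = TRUE), 3)
      use_peaks <- seq_len(nrow(d)) %in% top3 | d$intensity < i_mean
      single <- nrow(d) == 1
      if (single) use_peaks <- TRUE
      counts <- base
      counts[use_peaks] <- pmax(1L, peaks_per_cluster[d$cluster_id[use_peaks]])
      tibble::tibble(
        n_clusters = nrow(d),
        foci_count = as.integer(sum(counts)),
        flagged = single
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(class = classify_ploidy(.data$foci_count),
                  .after = "foci_count")
}

# Pixels that are the maximum of their (2*sep+1)^2 neighbourhood.
local_max_mask <- function(sm, sep) {
  mx <- sm
  for (dy in -sep:sep) {
    for (dx in -sep:sep) {
      if (dy == 0 && dx == 0) next
      mx <- pmax(mx, shift_matrix(sm, dy, dx))
    }
  }
  sm >= mx
}

shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h
  ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Classify a chromosome count into ploidy classes
#'
#' Foci-based boundaries: 47 or fewer chromosomes is euploid (small gains
#' or losses cannot be reliably resolved by foci counting), 48-49 simple
#' aneuploid, 50 or more complex aneuploid.
#'
#' @param n Integer chromosome count(s).
#' @return Factor with levels euploid / simple / complex.
#' @export
#' @examples
#' classify_ploidy(c(46, 47, 48, 49, 50, 55))
classify_ploidy <- function(n) {
  if (any(n < 0)) abort("chromosome counts must be >= 0")
  factor(
    dplyr::case_when(n <= 47 ~ "euploid", n <= 49 ~ "simple", TRUE ~ "complex"),
    levels = c("euploid", "simple", "complex")
  )
}

#' Mean immunostain intensity per nucleus
#'
#' Arithmetic mean of the immunostain channel over each nucleus mask.
#'
#' @param img `aneu_sim_foci` object or 3D array.
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param channel Immunostain channel index (default 3).
#' @return Tibble `nucleus_id`, `mean_immunostain`.
#' @export
mean_nuclear_intensity <- function(img, nucleus_labels, channel = 3) {
  ch <- get_channel(img, channel)
  n_nuc <- max(nucleus_labels)
  if (n_nuc == 0) abort("empty nucleus mask")
  purrr::map_dfr(seq_len(n_nuc), function(i) {
    px <- nucleus_labels == i
    if (!any(px)) abort(sprintf("nucleus %d has an empty mask", i))
    tibble::tibble(nucleus_id = i, mean_immunostain = mean(ch[px]))
  })
}

#' Count chromosomes in a centromere-foci image end to end
#'
#' Segments nuclei, segments centromere clusters, counts foci per nucleus,
#' classifies ploidy, and (when an immunostain channel is present) measures
#' mean nuclear immunostain intensity.
#'
#' @param img `aneu_sim_foci` object or 3D array (height x width x
#'   channels).
#' @param channels Named integer vector giving channel indices (defaults
#'   `c(nucleus = 1, centromere = 2, immunostain = 3)`); set
#'   `immunostain = NA` to skip intensity measurement.
#' @param min_area_px Minimum nucleus area.
#' @inheritParams count_foci
#' @return Tibble `nucleus_id`, `center_x`, `center_y`, `n_clusters`,
#'   `foci_count`, `class`, `mean_immunostain`.
#' @export
#' @examples
#' sim <- simulate_foci_image(2, foci_counts = c(46, 52), seed = 1)
#' count_chromosomes(sim)
count_chromosomes <- function(img,
                              channels = c(nucleus = 1, centromere = 2,
                                           immunostain = 3),
                              min_area_px = 200, smooth_sigma = 0.5,
                              min_peak_sep = 1) {
  labs <- segment_nuclei(img, min_area_px = min_area_px,
                         channel = channels[["nucleus"]])
  cs <- segment_clusters(img, labs, channel = channels[["centromere"]])
  res <- count_foci(cs, img, channel = channels[["centromere"]],
                    smooth_sigma = smooth_sigma, min_peak_sep = min_peak_sep)
  out <- dplyr::left_join(attr(labs, "centroids"), res, by = "nucleus_id")
  if (!is.na(channels[["immunostain"]])) {
    out <- dplyr::left_join(
      out, mean_nuclear_intensity(img, labs,
                                  channel = channels[["immunostain"]]),
      by = "nucleus_id"
    )
  }
  out
}

get_channel <- function(img, channel) {
  if (inherits(img, "aneu_sim_foci")) img <- img$image
  if (length(dim(img)) == 3) {
    img[, , channel]
  } else if (length(dim(img)) == 2) {
    img
  } else {
    abort("img must be a 2D matrix or 3D array")
  }
}
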