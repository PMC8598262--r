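#' Background-correct and contrast-stretch a channel
#'
#' Estimates the large-scale background as a linear plane (offset plus
#' gradient) fitted by least squares to the dim pixels of the field — those
#' at or below the `bg_quantile` intensity quantile, which are background
#' wherever the bright microtissue does not dominate the whole frame —
#' subtracts it, clamps negatives to zero, then linearly rescales between
#' robust low/high percentiles to `[0, 1]`. The subtraction makes masks
#' invariant to global additive offsets; the percentile stretch makes the
#' downstream automatic threshold invariant to global multiplicative gain.
#' A plane fit is used rather than heavy smoothing because microtissues can
#' occupy most of the field of view, leaving no smoothing scale that is both
#' larger than the droplet and smaller than the image. Intensity
#' quantification must be done on the raw channel, not on this
#' display-oriented output.
#'
#' @param channel 2D numeric matrix.
#' @param bg_quantile Intensity quantile selecting the dim pixels used for
#'   the background fit.
#' @param low_q,high_q Percentiles used for the linear stretch.
#' @return Matrix in `[0, 1]` with attribute `preprocess_params` recording
#'   the settings, the fitted plane coefficients, and the stretch anchors.
#' @export
preprocess <- function(channel, bg_quantile = 0.5, low_q = 0.01,
                       high_q = 0.999) {
  if (!is.matrix(channel) || length(channel) == 0) {
    stop("channel must be a non-empty 2D array", call. = FALSE)
  }
  beta <- background_plane_fit(channel, bg_quantile)
  n <- nrow(channel); m <- ncol(channel)
  bg <- beta[1] + outer(beta[2] * seq_len(n), beta[3] * seq_len(m), "+")
  corrected <- pmax(channel - bg, 0)
  lo <- stats::quantile(corrected, low_q, names = FALSE)
  hi <- stats::quantile(corrected, high_q, names = FALSE)
  if (hi <= lo) {
    warning("no contrast to stretch; returning background-subtracted image",
            call. = FALSE)
    out <- corrected
  } else {
    out <- pmin(pmax((corrected - lo) / (hi - lo), 0), 1)
  }
  attr(out, "preprocess_params") <- list(bg_quantile = bg_quantile,
                                         plane = beta, low_q = low_q,
                                         high_q = high_q, stretch_lo = lo,
                                         stretch_hi = hi)
  out
}

# Least-squares plane (intercept, row slope, col slope) through the dim
# pixels of the field. Deterministically thinned to at most 20k points.
background_plane_fit <- function(channel, bg_quantile) {
  n <- nrow(channel)
  thr <- stats::quantile(channel, bg_quantile, names = FALSE)
  sel <- which(channel <= thr)
  if (length(sel) > 20000) {
    sel <- sel[unique(round(seq(1, length(sel), length.out = 20000)))]
  }
  rows <- ((sel - 1) %% n) + 1
  cols <- ((sel - 1) %/% n) + 1
  x <- cbind(1, rows, cols)
  beta <- qr.coef(qr(x), channel[sel])
  beta[is.na(beta)] <- 0
  unname(beta)
}

# Perimeter from the count of 4-connected mask/background pixel edges.
# The staircase edge count overestimates a smooth contour's length by 4/pi,
# so scaling by pi/4 makes a digital disk's circularity come out ~1.
mask_perimeter <- function(mask) {
  m <- mask * 1
  pad <- function(x, dr, dc) {
    n <- nrow(x); p <- ncol(x)
    out <- matrix(0, n, p)
    rs <- seq_len(n) + dr; cs <- seq_len(p) + dc
    ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  edges <- sum(m & !pad(m, 1, 0)) + sum(m & !pad(m, -1, 0)) +
    sum(m & !pad(m, 0, 1)) + sum(m & !pad(m, 0, -1))
  edges * pi / 4
}

#' Segment microtissue droplets from a preprocessed channel
#'
#' Gaussian smoothing, global thresholding, hole filling,
#' connected-component labeling, then removal of small components and (by
#' default) components touching the image border, whose projected area is
#' censored. Shape descriptors are computed per surviving component.
#'
#' The automatic threshold is Otsu's bimodal split computed on
#' log-transformed intensity: fluorescence histograms are heavily
#' right-skewed (dim background, moderate diffuse tissue signal, bright
#' per-cell puncta), and on the raw scale Otsu can lock onto the
#' puncta-versus-tissue split instead of the tissue-versus-background one.
#' The log compresses the bright tail so the background/tissue gap
#' dominates. A second pass then re-thresholds at the midpoint between the
#' background level and the lower-quartile tissue level, which centers the
#' boundary on the 50% crossing of the smoothed edge profile and removes
#' the mask-dilation bias a low threshold would introduce. A fixed
#' threshold (on the `[0, 1]` preprocessed scale) can be supplied instead.
#'
#' @param image Preprocessed 2D matrix in `[0, 1]` (see [preprocess()]).
#' @param pixel_size Physical pixel size, um/px.
#' @param smooth_sigma Gaussian smoothing before thresholding, px.
#' @param threshold Fixed threshold in `[0, 1]`, or `NULL` for automatic
#'   Otsu thresholding.
#' @param min_area_px Minimum component area in px^2; smaller components are
#'   treated as debris.
#' @param exclude_border Drop components touching the border (they remain
#'   flagged in the attributes).
#' @return List of `droplet_mask` objects (possibly empty, with a warning),
#'   each holding `label`, logical `pixels`, `area_px`, `area_um2`,
#'   `equiv_diameter_um`, `circularity`, `centroid`, `touches_border`.
#'   Attribute `qc` records how many components each filter removed.
#' @export
segment_droplets <- function(image, pixel_size, smooth_sigma = 2,
                             threshold = NULL, min_area_px = 1000,
                             exclude_border = TRUE) {
  stopifnot(is.matrix(image), pixel_size > 0)
  sm <- EBImage::gblur(image, sigma = smooth_sigma, boundary = "replicate")
  if (is.null(threshold)) {
    # Otsu on log intensity; report the threshold back on the linear scale
    eps <- 0.01
    lg <- log10(pmax(sm, 0) + eps)
    rg <- range(lg)
    t_log <- EBImage::otsu(EBImage::Image((lg - rg[1]) / diff(rg)),
                           range = c(0, 1))
    threshold <- 10^(t_log * diff(rg) + rg[1]) - eps
    coarse <- sm > threshold
    if (any(coarse) && !all(coarse)) {
      bg_level <- mean(sm[!coarse])
      # The tissue level is sampled on a thin ring just inside the smoothed
      # edge ramp: it avoids both the ramp itself (which dominates the
      # histogram of a small droplet) and bright per-cell puncta deeper in
      # the tissue interior.
      er <- function(k) {
        EBImage::imageData(EBImage::erode(
          EBImage::Image(coarse * 1),
          EBImage::makeBrush(2L * k + 1L, "disc"))) > 0
      }
      k1 <- as.integer(ceiling(3 * smooth_sigma))
      inner <- er(k1)
      ring <- inner & !er(k1 + 3L)
      ref <- if (any(ring)) ring else if (any(inner)) inner else coarse
      tissue_lo <- stats::median(sm[ref])
      if (tissue_lo > bg_level) {
        # Edge localization: among candidate levels between background and
        # the near-edge tissue level, keep the one whose mask contour sits
        # on the steepest intensity gradient — for a smoothed step edge the
        # gradient peaks at the 50% crossing, independent of how bright the
        # tissue is further in.
        nr <- nrow(sm); nc <- ncol(sm)
        gx <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2
        gy <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2
        grad <- sqrt(gx^2 + gy^2)
        cand <- bg_level + seq(0.3, 0.7, by = 0.05) * (tissue_lo - bg_level)
        score <- vapply(cand, function(t) {
          b <- sm > t
          nb <- rbind(b[-1, ], FALSE) | rbind(FALSE, b[-nr, ]) |
            cbind(b[, -1], FALSE) | cbind(FALSE, b[, -nc])
          all_nb <- rbind(b[-1, ], FALSE) & rbind(FALSE, b[-nr, ]) &
            cbind(b[, -1], FALSE) & cbind(FALSE, b[, -nc])
          # symmetric band: pixels just inside plus just outside the contour
          edge <- (b & !all_nb) | (!b & nb)
          if (!any(edge)) return(-Inf)
          mean(grad[edge])
        }, numeric(1))
        threshold <- cand[which.max(score)]
      }
    }
  }
  binary <- sm > threshold
  lab <- EBImage::bwlabel(binary)
  lab <- EBImage::fillHull(lab)
  lab <- EBImage::imageData(lab)
  n_lab <- max(lab)
  masks <- list()
  n_small <- 0L; n_border <- 0L
  for (l in seq_len(n_lab)) {
    pix <- lab == l
    area_px <- sum(pix)
    if (area_px < min_area_px) {
      n_small <- n_small + 1L
      next
    }
    idx <- which(pix, arr.ind = TRUE)
    touches <- any(idx == 1L) || any(idx[, 1] == nrow(pix)) ||
      any(idx[, 2] == ncol(pix))
    if (touches && exclude_border) {
      n_border <- n_border + 1L
      next
    }
    area_um2 <- area_px * pixel_size^2
    perim <- mask_perimeter(pix)
    masks[[length(masks) + 1L]] <- structure(list(
      label = l, pixels = pix, area_px = area_px, area_um2 = area_um2,
      equiv_diameter_um = 2 * sqrt(area_um2 / pi),
      circularity = 4 * pi * area_px / perim^2,
      centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
      touches_border = touches
    ), class = "droplet_mask")
  }
  if (length(masks) == 0) {
    warning("no droplets survived segmentation filters", call. = FALSE)
  }
  attr(masks, "qc") <- list(threshold = threshold, n_components = n_lab,
                            removed_small = n_small,
                            removed_border = n_border)
  masks
}

# 1D Otsu on a numeric sample: threshold maximizing between-class variance
# over the sorted unique midpoints. Used to split per-cell live-stain means.
otsu_split <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(NA_real_)
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  bcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) / length(x)^2 * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

#' Count nuclei inside a droplet mask
#'
#' Blob detection restricted to the mask: Gaussian smoothing at the expected
#' nucleus scale, local maxima (grayscale dilation equality) above a
#' prominence threshold relative to the in-mask background, then greedy
#' minimum-separation suppression ordered by intensity (ties broken by
#' (row, col) lexicographic order for determinism). Two blobs closer than
#' `min_sep` are merged and counted once.
#'
#' @param nuclei_channel Raw 2D matrix of the nuclear stain.
#' @param mask A `droplet_mask` (or logical matrix).
#' @param sigma Expected nucleus blob width, px.
#' @param min_sep Minimum center separation, px. The default `3 * sigma`
#'   sits just below the `4 * sigma` packing floor of the synthetic
#'   generator so that nuclei placed at the minimum allowed distance are
#'   still resolved after their detected peaks shift by up to a pixel on
#'   the grid.
#' @param prominence Fraction of the in-mask dynamic range (peak minus
#'   background) a maximum must exceed above background to count.
#' @return List with `count` (integer) and `centroids` (n x 2 matrix of
#'   (row, col) positions inside the mask).
#' @export
count_nuclei <- function(nuclei_channel, mask, sigma = 2, min_sep = 3 * sigma,
                         prominence = 0.3) {
  pix <- if (inherits(mask, "droplet_mask")) mask$pixels else mask
  if (!any(pix)) stop("mask is empty; no region to count in", call. = FALSE)
  sm <- EBImage::gblur(nuclei_channel, sigma = sigma, boundary = "replicate")
  inmask <- sm[pix]
  bg <- stats::quantile(inmask, 0.1, names = FALSE)
  peak <- max(inmask)
  thr <- bg + prominence * (peak - bg)
  brush_size <- 2L * as.integer(ceiling(min_sep / 2)) + 1L
  dil <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(sm), EBImage::makeBrush(brush_size, "disc"))
  )
  is_max <- pix & (sm >= dil) & (sm > thr)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(count = 0L, centroids = matrix(numeric(0), 0, 2)))
  }
  vals <- sm[is_max]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (nrow(keep) == 0 ||
        min((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) >= min_sep^2) {
      keep <- rbind(keep, p)
    }
  }
  dimnames(keep) <- list(NULL, c("row", "col"))
  list(count = nrow(keep), centroids = keep)
}

#' Classify live/dead cells from a viability stain
#'
#' Each cell's live-stain level is the mean intensity in a fixed-radius disk
#' around its centroid. Cells are split live/dead by an automatic bimodal
#' (Otsu) threshold on the per-cell means. When the per-cell means are not
#' bimodal — a droplet where every cell is alive, or every cell dead — the
#' Otsu split would cut a unimodal population in half, so a separation guard
#' is applied: if the dimmer Otsu class is more than half as bright as the
#' brighter class, all cells are assigned to one side by comparison with
#' `fixed_threshold`. All-equal per-cell means fall back to
#' `fixed_threshold` with a warning.
#'
#' @param live_channel Raw 2D matrix of the live stain.
#' @param centroids n x 2 matrix of (row, col) cell positions (n >= 1).
#' @param radius Sampling disk radius, px.
#' @param fixed_threshold Fallback absolute threshold (camera units) used
#'   when no bimodal split exists.
#' @return List with `live` (integer), `total` (integer), `fraction` in
#'   `[0, 1]`, and the per-cell means.
#' @export
classify_viability <- function(live_channel, centroids, radius = 3,
                               fixed_threshold = 100) {
  if (is.null(nrow(centroids)) || nrow(centroids) == 0) {
    stop("at least one cell centroid is required", call. = FALSE)
  }
  n <- nrow(live_channel); m <- ncol(live_channel)
  means <- vapply(seq_len(nrow(centroids)), function(k) {
    r0 <- centroids[k, 1]; c0 <- centroids[k, 2]
    rs <- max(1, floor(r0 - radius)):min(n, ceiling(r0 + radius))
    cs <- max(1, floor(c0 - radius)):min(m, ceiling(c0 + radius))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    mean(live_channel[rs, cs][d2 <= radius^2])
  }, numeric(1))

  if (diff(range(means)) < .Machine$double.eps^0.5) {
    warning("per-cell live means are all equal; using fixed threshold",
            call. = FALSE)
    live <- means > fixed_threshold
  } else {
    t_auto <- otsu_split(means)
    lo <- means[means <= t_auto]; hi <- means[means > t_auto]
    if (mean(lo) > 0.5 * mean(hi)) {
      # unimodal population: decide the whole droplet by the fixed threshold
      live <- rep(mean(means) > fixed_threshold, length(means))
    } else {
      live <- means > t_auto
    }
  }
  list(live = sum(live), total = length(means),
       fraction = sum(live) / length(means), per_cell_means = means)
}
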