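#' Construct an image frame
#'
#' Lightweight container for one grayscale time-lapse frame: an intensity
#' matrix (rows = y, columns = x), the pixel size and the acquisition
#' time.
#'
#' @param pixels numeric matrix of non-negative intensities
#' @param pixel_size um per pixel
#' @param t acquisition time (h)
#' @return a `cda_frame`
#' @export
cda_frame <- function(pixels, pixel_size = 1.3, t = 0) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(list(pixels = pixels, pixel_size = pixel_size, t = t),
            class = "cda_frame")
}

as_pixels <- function(x) if (inherits(x, "cda_frame")) x$pixels else x

rewrap <- function(frame, pixels) {
  if (inherits(frame, "cda_frame")) { frame$pixels <- pixels; frame }
  else pixels
}

# flat disk kernel, odd size, normalized to sum 1
disk_kernel <- function(radius_px) {
  r <- ceiling(radius_px)
  g <- seq(-r, r)
  d <- outer(g, g, function(i, j) sqrt(i^2 + j^2)) <= radius_px
  k <- d / sum(d)
  k
}

# convolution with reflective (mirror) boundary handling via padding
convolve_reflect <- function(px, kernel) {
  r <- (nrow(kernel) - 1) / 2
  nr <- nrow(px); nc <- ncol(px)
  ri <- c(pmin(r:1, nr), seq_len(nr), nr - pmin(seq_len(r), nr - 1) + 0)
  top <- px[pmin(r:1, nr), , drop = FALSE]
  bot <- px[nr - (seq_len(r) - 1), , drop = FALSE]
  pad <- rbind(top, px, bot)
  lef <- pad[, pmin(r:1, nc), drop = FALSE]
  rig <- pad[, nc - (seq_len(r) - 1), drop = FALSE]
  pad <- cbind(lef, pad, rig)
  out <- EBImage::filter2(pad, kernel, boundary = "circular")
  out[r + seq_len(nr), r + seq_len(nc)]
}

#' Correct non-uniform illumination
#'
#' Convolves the raw frame with a flat disk kernel to estimate the smooth
#' illumination background, then divides the original image by it. A pure
#' shading field maps to a frame of ones; objects much smaller than the
#' kernel keep their contrast against the local background.
#'
#' @param frame a `cda_frame` or intensity matrix
#' @param kernel_radius_px disk radius in pixels (at least 5)
#' @return corrected frame, same type as the input
#' @export
correct_illumination <- function(frame, kernel_radius_px = 25) {
  if (kernel_radius_px < 5) stop("kernel_radius_px must be >= 5")
  px <- as_pixels(frame)
  bg <- convolve_reflect(px, disk_kernel(kernel_radius_px))
  bg <- pmax(bg, 1e-12)
  rewrap(frame, px / bg)
}

#' Hyperbolic-tangent contrast equalization
#'
#' Centers intensities on the frame mean and passes them through tanh,
#' compressing out-of-focus intensity differences while preserving pixel
#' ordering; output lies in (-1, 1) with the background near 0.
#'
#' @param frame a `cda_frame` or intensity matrix
#' @param gain slope of the tanh at the mean intensity
#' @return contrast-equalized frame, same type as the input
#' @export
tanh_contrast <- function(frame, gain = 10) {
  if (gain <= 0) stop("gain must be positive")
  px <- as_pixels(frame)
  rewrap(frame, tanh(gain * (px - mean(px))))
}

# 8-connected labeling of a logical matrix via union-find on the pixel
# adjacency graph (EBImage's labeller is 4-connected).
label_components8 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  idx <- which(binary)
  labels <- matrix(0L, nr, nc)
  if (!length(idx)) return(labels)
  inb <- matrix(FALSE, nr, nc); inb[idx] <- TRUE
  edges <- integer(0)
  # directed offsets covering all 8 neighbours once: E, S, SE, SW
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- (c2[ok] - 1) * nr + r2[ok]
    keep <- inb[j]
    if (any(keep)) edges <- c(edges, rbind(idx[ok][keep], j[keep]))
  }
  vmap <- match(seq_len(nr * nc), idx)  # pixel index -> vertex id
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, vmap[edges])
  comp <- igraph::components(g)$membership
  # consecutive labels in order of first appearance (column-major scan)
  labels[idx] <- match(comp, unique(comp))
  labels
}

#' Segment clusters in a preprocessed frame
#'
#' Thresholds the (typically tanh-equalized) frame into a binary mask —
#' clusters image dark in bright-field, so foreground is below the
#' threshold — optionally unions in a high-pass branch (original minus a
#' large-kernel smoothing) that catches single cells too faint for the
#' global threshold, labels 8-connected components and drops those below
#' `min_area_px`.
#'
#' @param frame a `cda_frame` or intensity matrix
#' @param threshold foreground threshold. On a tanh-equalized frame the
#'   background mode sits near 0 and dark objects saturate near -1, so
#'   the default (-0.5 for dark objects, +0.5 for bright) lies halfway
#'   between, far from the background noise peak (threshold 0 would cut
#'   the background noise distribution itself in half)
#' @param min_area_px smallest component kept (px)
#' @param highpass_radius_px radius of the smoothing kernel for the
#'   high-pass single-cell branch, or `NULL` to skip it
#' @param object `"dark"` (bright-field default) or `"bright"`
#' @return a `cda_labelmap`: list with `labels` (integer matrix, 0 =
#'   background) and `records` (data frame `label`, `cx`, `cy` in px
#'   column/row coordinates, `area_px`, `area_um2`)
#' @export
segment_clusters <- function(frame, threshold = NULL, min_area_px = 30,
                             highpass_radius_px = NULL,
                             object = c("dark", "bright")) {
  object <- match.arg(object)
  if (is.null(threshold)) threshold <- if (object == "dark") -0.5 else 0.5
  px <- as_pixels(frame)
  psz <- if (inherits(frame, "cda_frame")) frame$pixel_size else 1
  fg <- if (object == "dark") px < threshold else px > threshold
  if (!is.null(highpass_radius_px)) {
    hp <- px - convolve_reflect(px, disk_kernel(highpass_radius_px))
    cut <- 3 * stats::sd(hp)
    fg <- fg | if (object == "dark") hp < -cut else hp > cut
  }
  labels <- label_components8(fg)
  if (max(labels) == 0L) {
    return(structure(list(labels = labels,
                          records = data.frame(label = integer(0),
                                               cx = numeric(0), cy = numeric(0),
                                               area_px = numeric(0),
                                               area_um2 = numeric(0))),
                     class = "cda_labelmap"))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1) %% nrow(labels)) + 1
  cc <- ((idx - 1) %/% nrow(labels)) + 1
  area <- tabulate(lab)
  keep <- which(area >= min_area_px)
  cx <- tapply(cc, lab, mean)[keep]
  cy <- tapply(rr, lab, mean)[keep]
  # zero out small components and relabel consecutively
  newlab <- integer(max(lab))
  newlab[keep] <- seq_along(keep)
  labels[idx] <- newlab[lab]
  records <- data.frame(label = seq_along(keep),
                        cx = as.numeric(cx), cy = as.numeric(cy),
                        area_px = area[keep],
                        area_um2 = area[keep] * psz^2)
  structure(list(labels = labels, records = records), class = "cda_labelmap")
}

#' @export
print.cda_labelmap <- function(x, ...) {
  cat(sprintf("CDA label map: %d objects, %d x %d px\n",
              nrow(x$records), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Count clusters through a time-lapse stack
#'
#' Runs the preprocessing + segmentation chain on every frame and returns
#' the object count (and density, if a field volume is given) against
#' time.
#'
#' @param stack list of `cda_frame`s, time-ordered
#' @param field_volume imaged volume in mm^3, or `NULL` for raw counts
#' @param preprocess apply illumination correction and tanh contrast
#'   before segmenting
#' @param ... segmentation settings passed to [segment_clusters()]
#' @return data frame (`cda_aggcurve`) with `t_day`, `count` and, if the
#'   volume is known, `density` (mm^-3)
#' @export
aggregation_curve <- function(stack, field_volume = NULL, preprocess = TRUE,
                              ...) {
  if (length(stack) < 3) stop("need at least 3 frames")
  counts <- vapply(stack, function(fr) {
    if (preprocess) fr <- tanh_contrast(correct_illumination(fr))
    nrow(segment_clusters(fr, ...)$records)
  }, numeric(1))
  times <- vapply(stack, function(fr) fr$t, numeric(1)) / 24
  out <- data.frame(t_day = times, count = counts)
  if (!is.null(field_volume)) out$density <- counts / field_volume
  class(out) <- c("cda_aggcurve", "data.frame")
  out
}

#' Fit the lagged exponential aggregation model
#'
#' Cluster counts stay flat for a lag and then decay exponentially:
#' n(t) = n0 * exp(-theta(t - t_lag) * (t - t_lag) / tau_a), with theta
#' the Heaviside step. Fitted by least squares with a multi-start grid
#' over the non-smooth lag parameter followed by Levenberg-Marquardt
#' refinement. The halving time is t_half = t_lag + tau_a * log 2.
#'
#' @param curve data frame with `t_day` and `count` (or `density`)
#' @param use_density fit the density column instead of raw counts
#' @return a `cda_aggfit` list: `n0`, `t_lag`, `tau_a`, `t_half` (all in
#'   days), `residual` (RMS), `fitted`, and `flagged` (`TRUE` with
#'   `tau_a = Inf` when the curve never decreases)
#' @export
fit_aggregation <- function(curve, use_density = FALSE) {
  t <- curve$t_day
  y <- if (use_density && !is.null(curve$density)) curve$density else curve$count
  if (length(t) < 5) stop("need at least 5 points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  dec <- y[length(y)] < y[1]
  if (!dec) {
    out <- list(n0 = y[1], t_lag = 0, tau_a = Inf, t_half = Inf,
                residual = NA_real_, fitted = rep(y[1], length(y)),
                flagged = TRUE)
    class(out) <- "cda_aggfit"
    return(out)
  }
  sse_for <- function(lag) {
    x <- pmax(0, t - lag)
    # conditional linear fit in log space seeds the nonlinear fit
    fit <- stats::lm(log(pmax(y, 1e-9)) ~ x)
    k <- unname(max(-stats::coef(fit)[2], 1e-6))
    n0 <- unname(exp(stats::coef(fit)[1]))
    pred <- n0 * exp(-k * x)
    list(sse = sum((y - pred)^2), n0 = n0, k = k)
  }
  lags <- seq(0, max(t) * 0.75, length.out = 40)
  grid <- lapply(lags, sse_for)
  best <- which.min(vapply(grid, `[[`, numeric(1), "sse"))
  start <- list(n0 = grid[[best]]$n0, t_lag = lags[best],
                k = grid[[best]]$k)
  fit <- try(minpack.lm::nlsLM(
    y ~ n0 * exp(-pmax(0, t - t_lag) * k),
    start = start,
    lower = c(n0 = 0, t_lag = 0, k = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    co <- unlist(start)
  } else co <- stats::coef(fit)
  n0 <- unname(co["n0"]); t_lag <- unname(co["t_lag"]); k <- unname(co["k"])
  pred <- n0 * exp(-pmax(0, t - t_lag) * k)
  out <- list(n0 = n0, t_lag = t_lag, tau_a = 1 / k,
              t_half = t_lag + log(2) / k,
              residual = sqrt(mean((y - pred)^2)), fitted = pred,
              flagged = FALSE)
  class(out) <- "cda_aggfit"
  out
}

#' @export
print.cda_aggfit <- function(x, ...) {
  if (x$flagged) cat("Aggregation fit: no decay (flagged)\n")
  else cat(sprintf(
    "Aggregation fit: n0 = %.2f, t_lag = %.2f d, tau_a = %.2f d, t_half = %.2f d\n",
    x$n0, x$t_lag, x$tau_a, x$t_half))
  invisible(x)
}

#' Particle image velocimetry between two frames
#'
#' For a tile around each tracked object (or grid point) in the first
#' frame, finds the displacement maximizing the normalized
#' cross-correlation with the second frame over a search window, then
#' refines it to sub-pixel precision by 3-point parabolic interpolation
#' along each axis. Featureless tiles are flagged invalid.
#'
#' @param frame_a,frame_b `cda_frame`s or matrices
#' @param centers data frame with `cx`, `cy` (px; e.g. segmentation
#'   records), or `NULL` for a regular grid
#' @param tile_px tile edge (px)
#' @param search_px maximum displacement searched (px)
#' @return data frame `cx`, `cy`, `dx_px`, `dy_px`, `dx_um`, `dy_um`,
#'   `ncc` (peak correlation), `valid`
#' @export
piv_displacement <- function(frame_a, frame_b, centers = NULL,
                             tile_px = 32, search_px = 8) {
  A <- as_pixels(frame_a); B <- as_pixels(frame_b)
  stopifnot(all(dim(A) == dim(B)))
  psz <- if (inherits(frame_a, "cda_frame")) frame_a$pixel_size else 1
  nr <- nrow(A); nc <- ncol(A)
  h <- floor(tile_px / 2)
  margin <- h + search_px + 1
  if (2 * margin >= min(nr, nc)) stop("tile + search window exceed the frame")
  if (is.null(centers)) {
    g <- function(n) seq(margin + 1, n - margin, by = tile_px)
    centers <- expand.grid(cy = g(nr), cx = g(nc))
  }
  res <- lapply(seq_len(nrow(centers)), function(i) {
    cx <- round(centers$cx[i]); cy <- round(centers$cy[i])
    cx <- min(max(cx, margin + 1), nc - margin)
    cy <- min(max(cy, margin + 1), nr - margin)
    tile <- A[(cy - h):(cy + h), (cx - h):(cx + h)]
    if (stats::sd(tile) == 0)
      return(data.frame(cx = cx, cy = cy, dx_px = NA, dy_px = NA,
                        dx_um = NA, dy_um = NA, ncc = NA, valid = FALSE))
    offs <- -search_px:search_px
    ncc <- matrix(-Inf, length(offs), length(offs))
    for (iy in seq_along(offs)) for (ix in seq_along(offs)) {
      sub <- B[(cy + offs[iy] - h):(cy + offs[iy] + h),
               (cx + offs[ix] - h):(cx + offs[ix] + h)]
      s <- stats::sd(sub)
      ncc[iy, ix] <- if (s == 0) -Inf else stats::cor(as.vector(tile), as.vector(sub))
    }
    pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
    dy <- offs[pk[1]]; dx <- offs[pk[2]]
    # parabolic sub-pixel refinement, skipped on the window edge
    refine <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (!is.finite(den) || den >= 0) 0 else 0.5 * (cm - cp) / den
    }
    sy <- if (pk[1] > 1 && pk[1] < length(offs))
      refine(ncc[pk[1] - 1, pk[2]], ncc[pk[1], pk[2]], ncc[pk[1] + 1, pk[2]]) else 0
    sx <- if (pk[2] > 1 && pk[2] < length(offs))
      refine(ncc[pk[1], pk[2] - 1], ncc[pk[1], pk[2]], ncc[pk[1], pk[2] + 1]) else 0
    data.frame(cx = cx, cy = cy, dx_px = dx + sx, dy_px = dy + sy,
               dx_um = (dx + sx) * psz, dy_um = (dy + sy) * psz,
               ncc = max(ncc), valid = TRUE)
  })
  do.call(rbind, res)
}

#' Binned velocity probability density
#'
#' Histogram estimates of the velocity distribution: linear bins over the
#' signed component and log-spaced bins over the magnitude (the natural
#' axes for a heavy-tailed law).
#'
#' @param samples numeric vector of velocity components
#' @param n_bins number of bins for each axis
#' @return list with data frames `component` and `magnitude`, each with
#'   `center`, `width`, `density`
#' @export
velocity_pdf <- function(samples, n_bins = 40) {
  if (length(samples) < 100) stop("need at least 100 samples")
  h <- graphics::hist(samples, breaks = n_bins, plot = FALSE)
  comp <- data.frame(center = h$mids, width = diff(h$breaks),
                     density = h$density)
  mag <- abs(samples[samples != 0])
  if (length(mag)) {
    brk <- exp(seq(log(min(mag)), log(max(mag)), length.out = n_bins + 1))
    brk[1] <- brk[1] * (1 - 1e-9); brk[n_bins + 1] <- brk[n_bins + 1] * (1 + 1e-9)
    cnt <- graphics::hist(mag, breaks = brk, plot = FALSE)$counts
    magd <- data.frame(center = sqrt(brk[-1] * brk[-(n_bins + 1)]),
                       width = diff(brk),
                       density = cnt / (length(mag) * diff(brk)))
  } else magd <- data.frame(center = numeric(0), width = numeric(0),
                            density = numeric(0))
  list(component = comp, magnitude = magd)
}

#' Fit the power-law tail exponent of a velocity distribution
#'
#' Primary estimator: least-squares slope of the log empirical CCDF
#' against log magnitude for samples above `v_min`, reported as the PDF
#' exponent (CCDF slope minus one). Cross-checked by the Hill
#' maximum-likelihood estimator, with a stability scan of the Hill
#' estimate across tail cutoffs from the 90th to the 99th percentile; a
#' drifting scan flags the absence of a stable power law.
#'
#' @param samples velocity components (signed; magnitudes are used)
#' @param v_min tail cutoff; default the 95th percentile of |v|
#' @return a `cda_tailfit` list: `exponent`, `stderr` (CCDF regression),
#'   `hill_exponent`, `hill_stderr`, `v_min`, `n_tail`, `stable`, `scan`
#' @export
fit_tail_exponent <- function(samples, v_min = NULL) {
  x <- sort(abs(samples[is.finite(samples) & samples != 0]), decreasing = TRUE)
  if (is.null(v_min)) v_min <- stats::quantile(x, 0.95)
  tail <- x[x >= v_min]
  if (length(tail) < 200)
    stop("only ", length(tail), " samples above v_min; need >= 200")
  ccdf <- seq_along(x) / length(x)
  sel <- seq_along(tail)
  fit <- stats::lm(log(ccdf[sel]) ~ log(x[sel]))
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  hill <- function(vm) {
    tl <- x[x >= vm]
    a <- 1 / mean(log(tl / vm))
    c(alpha = a, se = a / sqrt(length(tl)))
  }
  h <- hill(v_min)
  scan_q <- seq(0.90, 0.99, by = 0.01)
  scan <- t(vapply(stats::quantile(x, scan_q), hill, numeric(2)))
  scan <- data.frame(quantile = scan_q, vm = stats::quantile(x, scan_q),
                     pdf_exponent = -(scan[, 1] + 1))
  stable <- diff(range(scan$pdf_exponent)) < 0.5
  out <- list(exponent = slope - 1, stderr = se,
              hill_exponent = -(h[["alpha"]] + 1), hill_stderr = h[["se"]],
              v_min = unname(v_min), n_tail = length(tail),
              stable = stable, scan = scan)
  class(out) <- "cda_tailfit"
  out
}

#' @export
print.cda_tailfit <- function(x, ...) {
  cat(sprintf("Tail fit: PDF exponent %.3f +/- %.3f (Hill %.3f), %d tail samples%s\n",
              x$exponent, x$stderr, x$hill_exponent, x$n_tail,
              if (x$stable) "" else " [no stable power law]"))
  invisible(x)
}

#' Quantile-method distribution width
#'
#' Half the central 68.27% inter-quantile range: equals the standard
#' deviation for a Gaussian but stays finite and robust for the
#' heavy-tailed (infinite-variance) velocity laws of this model.
#'
#' @param samples numeric vector
#' @return the width (same units as `samples`)
#' @export
quantile_width <- function(samples) {
  q <- stats::quantile(samples, c(0.158655, 0.841345), names = FALSE)
  (q[2] - q[1]) / 2
}

#' Width-versus-density scaling of velocity distributions
#'
#' Computes the quantile-method width (half the central 68.27%
#' inter-quantile range, robust to the infinite variance of the velocity
#' law) of each density-labelled ensemble and regresses log width on log
#' density; the chemotactic suspension should give a slope of -1/3.
#'
#' @param ensembles named list: names are densities (mm^-3), elements are
#'   vectors of velocity components
#' @return a `cda_widthfit` list: `exponent`, `stderr`, `prefactor`
#'   (width at unit density), `widths` (data frame `density`, `width`)
#' @export
fit_width_scaling <- function(ensembles) {
  if (length(ensembles) < 3) stop("need at least 3 densities")
  dens <- suppressWarnings(as.numeric(names(ensembles)))
  if (anyNA(dens)) stop("ensemble names must be numeric densities")
  w <- vapply(ensembles, quantile_width, numeric(1))
  fit <- stats::lm(log(w) ~ log(dens))
  out <- list(exponent = unname(stats::coef(fit)[2]),
              stderr = summary(fit)$coefficients[2, 2],
              prefactor = exp(unname(stats::coef(fit)[1])),
              widths = data.frame(density = dens, width = unname(w)))
  class(out) <- "cda_widthfit"
  out
}

#' Volumetric growth rate from projected cluster area
#'
#' Total segmented area grows as the 2/3 power of total volume for
#' spherical clusters, so the volumetric rate is 1.5 times the time
#' derivative of log area. The log series is window-averaged before
#' central differencing (one-sided at the ends), which leaves a pure
#' exponential exactly invariant.
#'
#' @param times time points (days), increasing
#' @param areas total segmented area at each time (positive)
#' @param smooth_window odd running-mean window on log area (1 = none)
#' @return growth-rate series (day^-1), one value per time point; the
#'   doubling rate is this divided by log 2
#' @export
volumetric_growth_rate <- function(times, areas, smooth_window = 3) {
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(areas <= 0)) stop("areas must be positive")
  la <- log(areas)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(la, k, sides = 2)
    la <- ifelse(is.na(sm), la, as.numeric(sm))
  }
  n <- length(la)
  d <- numeric(n)
  d[1] <- (la[2] - la[1]) / (times[2] - times[1])
  d[n] <- (la[n] - la[n - 1]) / (times[n] - times[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (la[3:n] - la[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  1.5 * d
}
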