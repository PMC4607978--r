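#' Synthetic acquisition (optics) settings
#'
#' Parameters of the bright-field renderer used to build test movies:
#' pixel size, object contrast, edge blur, smooth illumination shading
#' and additive Gaussian noise. Defaults make preprocessing non-trivial
#' but solvable: a 20 um cell spans ~15 px, shading 30%, noise 3%.
#'
#' @param pixel_size um per pixel
#' @param image_size frame edge in pixels (square frames)
#' @param object_intensity intensity of cluster disks relative to the
#'   unit background (< 1: dark objects, bright-field-like)
#' @param edge_blur_sigma Gaussian blur of object edges (px)
#' @param shading_amplitude relative amplitude of the smooth illumination
#'   field, in [0, 1)
#' @param noise_sigma relative standard deviation of additive noise
#' @param bit_depth 8 or 16 (used when frames are written to TIFF)
#' @return an `cda_optics` list
#' @export
optics_params <- function(pixel_size = 1.3, image_size = 512,
                          object_intensity = 0.35, edge_blur_sigma = 1.5,
                          shading_amplitude = 0.3, noise_sigma = 0.03,
                          bit_depth = 16) {
  stopifnot(noise_sigma >= 0, shading_amplitude >= 0, shading_amplitude < 1,
            edge_blur_sigma >= 0, bit_depth %in% c(8, 16))
  structure(list(pixel_size = pixel_size, image_size = image_size,
                 object_intensity = object_intensity,
                 edge_blur_sigma = edge_blur_sigma,
                 shading_amplitude = shading_amplitude,
                 noise_sigma = noise_sigma, bit_depth = bit_depth),
            class = "cda_optics")
}

#' Random (Poisson) cluster configuration
#'
#' Uniform positions with a Poisson-distributed count — the random
#' suspension assumed by the velocity-statistics theory.
#'
#' @param density number density (mm^-3)
#' @param box_length box edge (um)
#' @param seed RNG seed
#' @return data frame `x`, `y`, `z` (um) with attribute `density`
#' @export
poisson_configuration <- function(density, box_length, seed = 1L) {
  if (density <= 0) stop("density must be positive")
  set.seed(seed)
  n <- stats::rpois(1, density * 1e-9 * box_length^3)
  out <- data.frame(x = stats::runif(n, 0, box_length),
                    y = stats::runif(n, 0, box_length),
                    z = stats::runif(n, 0, box_length))
  attr(out, "density") <- density
  out
}

# smooth multiplicative illumination field: tilted plane plus a long
# wavelength sine, normalized to mean 1 and amplitude `amp`
shading_field <- function(nr, nc, amp, phase = 0) {
  yy <- matrix(seq(0, 1, length.out = nr), nr, nc)
  xx <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  f <- 0.6 * xx + 0.4 * sin(pi * yy + phase)
  f <- f - mean(f)
  1 + amp * f / max(abs(f))
}

#' Render one bright-field-like frame from a cluster state
#'
#' Projects clusters to the xy plane and draws each as a disk of its
#' projected radius, blurs the edges, multiplies by a smooth illumination
#' field and adds Gaussian noise — the artefacts the quantification
#' pipeline is built to undo. The unblemished ground-truth label map is
#' returned alongside; no test needs to reverse-engineer truth from
#' pixels.
#'
#' @param state a `cda_state` (or list with `clusters` data frame having
#'   `x`, `y`, `radius` in um)
#' @param optics an `cda_optics` object
#' @param t time stamp for the frame (h)
#' @param seed RNG seed for the noise
#' @return a `cda_frame` with attributes `truth` (data frame `id`, `cx`,
#'   `cy` in px, `radius_px`, `clipped`) and `truth_labels` (integer
#'   matrix)
#' @export
render_frame <- function(state, optics = optics_params(), t = 0, seed = 1L) {
  set.seed(seed)
  cl <- state$clusters
  npx <- optics$image_size
  psz <- optics$pixel_size
  img <- matrix(1, npx, npx)
  labels <- matrix(0L, npx, npx)
  truth <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      radius_px = numeric(0), clipped = logical(0))
  if (nrow(cl)) {
    for (j in seq_len(nrow(cl))) {
      cx <- cl$x[j] / psz; cy <- cl$y[j] / psz
      r <- cl$radius[j] / psz
      clipped <- cx < -r || cy < -r || cx > npx + r || cy > npx + r
      truth <- rbind(truth, data.frame(id = cl$id[j], cx = cx, cy = cy,
                                       radius_px = r, clipped = clipped))
      if (clipped) next
      rows <- max(1, floor(cy - r)):min(npx, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(npx, ceiling(cx + r))
      if (!length(rows) || !length(cols)) next
      dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
      inside <- dd <= r^2
      img[rows, cols][inside] <- optics$object_intensity
      labels[rows, cols][inside] <- j
    }
  }
  if (optics$edge_blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = optics$edge_blur_sigma))
  img <- img * shading_field(npx, npx, optics$shading_amplitude)
  if (optics$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(npx^2, sd = optics$noise_sigma), npx, npx)
  img <- pmin(pmax(img, 0), 2)
  fr <- cda_frame(img, pixel_size = psz, t = t)
  attr(fr, "truth") <- truth
  attr(fr, "truth_labels") <- labels
  fr
}

#' Render a time-lapse movie from a simulation trajectory
#'
#' One frame per requested time, rendered from the nearest recorded
#' snapshot, with ground-truth counts carried along for validation.
#'
#' @param trajectory a `cda_trajectory` from [run_cda()] (snapshots must
#'   have been recorded at or near `frame_times`)
#' @param optics an `cda_optics` object
#' @param frame_times times (h) within the trajectory span
#' @param seed base RNG seed; frame i uses `seed + i`
#' @return list with `frames` (list of `cda_frame`) and `truth_counts`
#'   (data frame `t_h`, `count`)
#' @export
render_movie <- function(trajectory, optics = optics_params(),
                         frame_times = NULL, seed = 1L) {
  snap_t <- as.numeric(names(trajectory$snapshots))
  if (is.null(frame_times)) frame_times <- snap_t
  if (any(frame_times < min(snap_t) - 1e-9) ||
      any(frame_times > max(trajectory$counts$t_h) + 1e-9))
    stop("frame_times outside the trajectory span")
  frames <- vector("list", length(frame_times))
  counts <- numeric(length(frame_times))
  for (i in seq_along(frame_times)) {
    k <- which.min(abs(snap_t - frame_times[i]))
    st <- list(clusters = trajectory$snapshots[[k]])
    frames[[i]] <- render_frame(st, optics, t = frame_times[i],
                                seed = seed + i)
    counts[i] <- nrow(st$clusters)
  }
  list(frames = frames,
       truth_counts = data.frame(t_h = frame_times, count = counts))
}

#' Reproducible samples from reference laws
#'
#' Fixture generator for the tail- and width-estimator tests: Pareto
#' (power-law), Gaussian, exponential, or the Holtsmark stable law (drawn
#' with the exact sampler [rholtsmark()]).
#'
#' @param law one of `"pareto"`, `"gaussian"`, `"exponential"`,
#'   `"holtsmark"`
#' @param n number of samples
#' @param params named list of law parameters: Pareto `xmin` and
#'   `pdf_exponent` (e.g. -2.5); Gaussian `sd`; exponential `rate`;
#'   Holtsmark `scale`
#' @param seed RNG seed
#' @return numeric vector of length `n`
#' @export
known_law_samples <- function(law, n, params = list(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  switch(law,
    pareto = {
      xmin <- params$xmin %||% 1
      expo <- params$pdf_exponent %||% -2.5
      if (expo >= -1) stop("pdf_exponent must be below -1")
      alpha <- -expo - 1  # CCDF ~ x^-alpha
      xmin * stats::runif(n)^(-1 / alpha)
    },
    gaussian = stats::rnorm(n, sd = params$sd %||% 1),
    exponential = stats::rexp(n, rate = params$rate %||% 1),
    holtsmark = rholtsmark(n, scale = params$scale %||% 1),
    stop("unknown law: ", law))
}

#' Write frames to a multi-page grayscale TIFF
#'
#' Intensities are clipped to [0, 2], scaled to [0, 1] and written at
#' the optics bit depth; a sidecar CSV (`<path>.times.csv`) carries frame
#' times.
#'
#' @param frames list of `cda_frame`s
#' @param path output .tif path
#' @param bit_depth 8 or 16
#' @return `path`, invisibly
#' @export
write_movie_tiff <- function(frames, path, bit_depth = 16) {
  imgs <- lapply(frames, function(fr) pmin(pmax(fr$pixels, 0), 2) / 2)
  tiff::writeTIFF(imgs, path, bits.per.sample = bit_depth)
  times <- vapply(frames, function(fr) fr$t, numeric(1))
  utils::write.csv(data.frame(frame = seq_along(frames), t_h = times),
                   paste0(path, ".times.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a multi-page grayscale TIFF into frames
#'
#' Inverse of [write_movie_tiff()]: reads pages, rescales to the [0, 2]
#' intensity convention, and picks up frame times from the sidecar CSV
#' when present.
#'
#' @param path .tif path
#' @param pixel_size um per pixel to stamp on the frames
#' @return list of `cda_frame`s
#' @export
read_movie_tiff <- function(path, pixel_size = 1.3) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".times.csv")
  times <- if (file.exists(sidecar)) utils::read.csv(sidecar)$t_h
           else seq_along(pages) - 1
  lapply(seq_along(pages), function(i) {
    px <- pages[[i]]
    if (length(dim(px)) == 3) px <- px[, , 1]
    cda_frame(px * 2, pixel_size = pixel_size, t = times[i])
  })
}
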