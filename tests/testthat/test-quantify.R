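# reference flood fill (BFS, 8-neighbour) for labeling tests
flood_labels <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            binary[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

grid_state <- function(params, nx = 6, ny = 6, spacing_um = 110,
                       offset_um = 70, m = 1) {
  n <- nx * ny
  g <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  cl <- data.frame(id = seq_len(n),
                   x = offset_um + g$ix * spacing_um,
                   y = offset_um + g$iy * spacing_um,
                   z = 0, m = m)
  cl$radius <- (params$a / 2) * cl$m^(1 / 3)
  list(clusters = cl, params = params)
}

test_that("8-connected labeling matches a flood-fill reference", {
  # touching only diagonally: one component under 8-connectivity
  b <- matrix(FALSE, 4, 4); b[1, 1] <- TRUE; b[2, 2] <- TRUE
  expect_equal(max(cdakit:::label_components8(b)), 1L)
  for (s in 1:3) {
    set.seed(s)
    b <- matrix(stats::runif(625) < 0.35, 25, 25)
    mine <- cdakit:::label_components8(b)
    ref <- flood_labels(b)
    # same partition: label images must be a relabeling of each other
    expect_equal(max(mine), max(ref))
    expect_true(all(tapply(mine[b], ref[b], function(z) length(unique(z))) == 1))
  }
})

test_that("illumination correction flattens a pure shading field", {
  opt <- optics_params(shading_amplitude = 0.4, noise_sigma = 0,
                       edge_blur_sigma = 0, image_size = 256)
  st <- list(clusters = data.frame(id = integer(0), x = numeric(0),
                                   y = numeric(0), z = numeric(0),
                                   m = numeric(0), radius = numeric(0)))
  fr <- render_frame(st, opt)
  expect_gt(diff(range(fr$pixels)), 0.5)  # strongly shaded input
  corr <- correct_illumination(fr)$pixels
  inner <- corr[30:226, 30:226]
  expect_lt(max(abs(inner - 1)), 0.02)
  expect_error(correct_illumination(fr, kernel_radius_px = 2), ">= 5")
})

test_that("tanh contrast is monotone, centered and bounded", {
  px <- matrix(seq(0, 2, length.out = 100), 10, 10)
  out <- tanh_contrast(px, gain = 5)
  expect_true(all(out > -1 & out < 1))
  expect_true(all(diff(as.numeric(out)) >= 0))
  expect_error(tanh_contrast(px, gain = 0), "positive")
})

test_that("segmentation counts exactly on clean renders", {
  p <- table1_params()
  st <- grid_state(p)
  opt <- optics_params(shading_amplitude = 0, noise_sigma = 0)
  fr <- render_frame(st, opt)
  seg <- segment_clusters(tanh_contrast(correct_illumination(fr)))
  expect_equal(nrow(seg$records), 36)
  # centroids land on the truth grid (within a pixel)
  tr <- attr(fr, "truth")
  ord <- order(round(seg$records$cy / 10), seg$records$cx)
  tord <- order(round(tr$cy / 10), tr$cx)
  expect_lt(max(abs(seg$records$cx[ord] - tr$cx[tord])), 1)
  expect_lt(max(abs(seg$records$cy[ord] - tr$cy[tord])), 1)
  # areas between the drawn disk and the disk plus its blur halo
  expect_gt(median(seg$records$area_px), pi * (10 / 1.3)^2)
  expect_lt(median(seg$records$area_px), pi * (10 / 1.3 + 2.5)^2)
  expect_equal(seg$records$area_um2, seg$records$area_px * 1.3^2)
})

test_that("segmentation stays within 5% under shading and noise", {
  p <- table1_params()
  st <- grid_state(p)
  fr <- render_frame(st, optics_params(), seed = 21)  # defaults: 30% shading, 3% noise
  seg <- segment_clusters(tanh_contrast(correct_illumination(fr)))
  expect_lte(abs(nrow(seg$records) - 36) / 36, 0.05)
  # without illumination correction the shaded frame is miscounted,
  # which is what makes the correction necessary
  raw <- segment_clusters(tanh_contrast(fr))
  expect_gt(abs(nrow(raw$records) - 36) / 36, 0.05)
})

test_that("PIV recovers integer shifts exactly and sub-pixel to 0.2 px", {
  set.seed(3)
  base <- matrix(stats::runif(128 * 128), 128, 128)
  sm <- as.matrix(EBImage::gblur(base, sigma = 2))
  shift_int <- function(m, dy, dx) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(n) - 1 - dx) %% n) + 1]
  }
  b <- shift_int(sm, 3, -2)
  res <- piv_displacement(sm, b, centers = data.frame(cx = 64, cy = 64),
                          tile_px = 32, search_px = 6)
  expect_true(res$valid)
  expect_equal(round(res$dx_px), -2)
  expect_equal(round(res$dy_px), 3)
  expect_lt(abs(res$dx_px - (-2)), 0.05)
  expect_lt(abs(res$dy_px - 3), 0.05)
  # sub-pixel: analytic Gaussian blobs displaced by (0.4, -0.3) px
  blob <- function(cx, cy) {
    outer(seq_len(96), seq_len(96),
          function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * 3^2)))
  }
  a2 <- blob(48, 48) + blob(30, 60) * 0.7
  b2 <- blob(48.4, 47.7) + blob(30.4, 59.7) * 0.7
  r2 <- piv_displacement(a2, b2, centers = data.frame(cx = 48, cy = 48),
                         tile_px = 32, search_px = 5)
  expect_lt(abs(r2$dx_px - 0.4), 0.2)
  expect_lt(abs(r2$dy_px - (-0.3)), 0.2)
  # um conversion uses the pixel size
  fa <- cda_frame(sm, pixel_size = 1.3); fb <- cda_frame(b, pixel_size = 1.3)
  ru <- piv_displacement(fa, fb, centers = data.frame(cx = 64, cy = 64),
                         tile_px = 32, search_px = 6)
  expect_equal(ru$dx_um, ru$dx_px * 1.3)
  # featureless tile is flagged invalid
  flat <- matrix(1, 128, 128)
  rf <- piv_displacement(flat, flat, centers = data.frame(cx = 64, cy = 64))
  expect_false(rf$valid)
})

test_that("aggregation fit recovers the lagged exponential", {
  t <- 0:25
  y <- 40 * exp(-pmax(0, t - 2) / 12.9)
  fit <- fit_aggregation(data.frame(t_day = t, count = y))
  expect_equal(fit$t_lag, 2.0, tolerance = 0.1 / 2.0)
  expect_equal(fit$tau_a, 12.9, tolerance = 0.3 / 12.9)
  expect_equal(fit$t_half, 2 + 12.9 * log(2), tolerance = 0.03)
  expect_lt(fit$residual, 1e-6)
  # 10% multiplicative noise: parameters within 15%
  set.seed(14)
  yn <- y * exp(stats::rnorm(length(y), sd = 0.1))
  fitn <- fit_aggregation(data.frame(t_day = t, count = yn))
  expect_equal(fitn$t_lag, 2.0, tolerance = 0.15 * 2 / 2)
  expect_equal(fitn$tau_a, 12.9, tolerance = 0.15)
  # constant curve is flagged with an infinite decay time
  flat <- fit_aggregation(data.frame(t_day = t, count = rep(7, 26)))
  expect_true(flat$flagged)
  expect_identical(flat$tau_a, Inf)
  expect_error(fit_aggregation(data.frame(t_day = 0:3, count = 4:1)),
               "at least 5")
})

test_that("rescaled curves collapse onto the master exponential", {
  t <- 0:25
  pars <- list(c(30, 1, 8), c(60, 3, 15), c(45, 0.5, 11))
  resid <- vapply(pars, function(p) {
    y <- p[1] * exp(-pmax(0, t - p[2]) / p[3])
    f <- fit_aggregation(data.frame(t_day = t, count = y))
    x <- (t - f$t_lag) / f$tau_a
    max(abs(y / f$n0 - exp(-pmax(0, x))))
  }, numeric(1))
  expect_lt(max(resid), 0.05)
})

test_that("aggregation curve from rendered movies tracks true counts", {
  p <- table1_params(n = 60, t_end = 96, seed = 6L, box_length = 600)
  tr <- run_cda(p, mode = "none", record_times = seq(12, 96, by = 12))
  opt <- optics_params(pixel_size = 1.3, image_size = 512,
                       shading_amplitude = 0.2, noise_sigma = 0.02)
  mov <- render_movie(tr, opt, seed = 40)
  curve <- aggregation_curve(mov$frames)
  expect_s3_class(curve, "cda_aggcurve")
  # projected 2D counts can undercount overlaps; stay within 15% of truth
  expect_lt(mean(abs(curve$count - mov$truth_counts$count) /
                 mov$truth_counts$count), 0.15)
  expect_error(aggregation_curve(mov$frames[1:2]), "at least 3")
})

test_that("volumetric growth rate is exact on exponentials", {
  t <- seq(0, 10, by = 0.5)
  g <- 0.3
  a <- 5 * exp((2 * g / 3) * t)
  expect_equal(volumetric_growth_rate(t, a), rep(g, length(t)),
               tolerance = 1e-10)
  # rate of area doubling relates by log 2
  expect_error(volumetric_growth_rate(t, -a), "positive")
  expect_error(volumetric_growth_rate(t[1:2], a[1:2]), "at least 3")
})

test_that("tail estimator: Pareto recovery and exponential rejection", {
  x <- known_law_samples("pareto", 3e4,
                         list(xmin = 1, pdf_exponent = -2.5), seed = 19)
  tf <- fit_tail_exponent(x)
  expect_lt(abs(tf$exponent - (-2.5)), 0.15)
  expect_lt(abs(tf$hill_exponent - (-2.5)), 0.15)
  expect_true(tf$stable)
  # exponential light tail: the Hill scan drifts, no stable power law
  e <- known_law_samples("exponential", 3e4, list(rate = 1), seed = 20)
  te <- fit_tail_exponent(e)
  expect_false(te$stable)
  expect_error(fit_tail_exponent(x[1:100]), ">= 200")
})

test_that("quantile width and width scaling behave", {
  set.seed(8)
  expect_equal(quantile_width(stats::rnorm(2e5, sd = 2)), 2,
               tolerance = 0.02)
  dens <- c(10, 30, 100, 200)
  ens <- lapply(dens, function(n)
    known_law_samples("holtsmark", 2e4, list(scale = n^(-1 / 3)),
                      seed = 100 + n))
  names(ens) <- dens
  wf <- fit_width_scaling(ens)
  expect_lt(abs(wf$exponent - (-1 / 3)), 0.05)
  expect_error(fit_width_scaling(ens[1:2]), "at least 3")
  names(ens)[1] <- "low"
  expect_error(fit_width_scaling(ens), "numeric")
})
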