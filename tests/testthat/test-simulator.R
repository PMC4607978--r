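two_cluster_state <- function(params, r_init, m = 1) {
  st <- init_state(params, fixed_count = TRUE)
  L <- params$box_length
  st$clusters <- data.frame(id = 1:2,
                            x = L / 2 + c(-r_init / 2, r_init / 2),
                            y = L / 2, z = L / 2, m = m)
  st$clusters$radius <- cdakit:::cluster_radius(st$clusters$m, params)
  st$next_id <- 3L
  st
}

test_that("seeding is reproducible and Poisson/fixed as requested", {
  p <- table1_params(seed = 5L)
  a <- init_state(p)
  b <- init_state(p)
  expect_identical(a$clusters, b$clusters)
  expect_true(all(a$clusters$m == 1))
  expect_true(all(a$clusters$x >= 0 & a$clusters$x < p$box_length))
  f <- init_state(p, fixed_count = TRUE)
  expect_equal(nrow(f$clusters), 30)
  counts <- vapply(1:40, function(s) nrow(init_state(p, seed = s)$clusters),
                   numeric(1))
  expect_gt(stats::var(counts), 0)  # genuinely Poisson, not fixed
})

test_that("advance conserves mass, respects the box and the step cap", {
  p <- table1_params(seed = 2L)
  st <- init_state(p)
  m0 <- sum(st$clusters$m)
  st2 <- advance(st, 0.5)
  expect_equal(sum(st2$clusters$m), m0)
  expect_true(all(st2$clusters$x >= 0 & st2$clusters$x < p$box_length))
  expect_lte(st2$t, 0.5 + 1e-12)
  # displacement never exceeds a quarter cell diameter
  d <- sqrt(rowSums((cdakit:::min_image(
    as.matrix(st2$clusters[, c("x", "y", "z")]) -
      as.matrix(st$clusters[, c("x", "y", "z")]), p$box_length))^2))
  expect_lte(max(d), p$a / 4 + 1e-9)
  expect_error(advance(st, p$dt_max * 2), "dt_max")
})

test_that("two-cluster trajectory is converged in the time step", {
  # sub-collision horizon: halving dt changes 20-day positions by < 1 um
  opts <- list(screened = FALSE, periodic = FALSE, fixed_background = 1.0)
  run20 <- function(dt) {
    p <- table1_params(box_length = 4000, dt_max = dt, t_end = 480)
    st <- two_cluster_state(p, 450)
    while (st$t < p$t_end - 1e-9)
      st <- advance(st, min(dt, p$t_end - st$t), opts)
    as.matrix(st$clusters[, c("x", "y", "z")])
  }
  delta <- run20(0.5) - run20(0.25)
  expect_lt(max(abs(delta)), 1)
})

test_that("coalescence is transitive with min-image centroids and logged", {
  p <- table1_params()
  st <- init_state(p, fixed_count = TRUE)
  # chain 1-2-3: only consecutive pairs touch; all three must merge
  st$clusters <- data.frame(id = 1:3, x = c(500, 518, 536), y = 500, z = 500,
                            m = c(1, 1, 1))
  st$clusters$radius <- cdakit:::cluster_radius(st$clusters$m, p)
  st$next_id <- 4L
  st2 <- coalesce(st)
  expect_equal(nrow(st2$clusters), 1)
  expect_equal(st2$clusters$m, 3)
  expect_equal(st2$clusters$radius, (p$a / 2) * 3^(1 / 3))
  ev <- attr(st2, "merges")
  expect_equal(nrow(ev), 2)  # one event per pair reduction
  expect_equal(ev$m_new, c(2, 3))
  # centroid across the periodic boundary stays near the boundary
  stw <- st
  stw$clusters <- data.frame(id = 1:2, x = c(4, 996), y = 500, z = 500, m = 1)
  stw$clusters$radius <- cdakit:::cluster_radius(1, p)
  stw$next_id <- 3L
  stw2 <- coalesce(stw)
  expect_equal(nrow(stw2$clusters), 1)
  expect_true(stw2$clusters$x > 999 || stw2$clusters$x < 1)
})

test_that("proliferation multiplies mass exactly and supports both modes", {
  p <- table1_params(seed = 3L)
  st <- init_state(p)
  st2 <- proliferate(st, 2, mode = "constant")
  expect_equal(st2$clusters$m, st$clusters$m * exp(p$alpha * 2))
  expect_equal(st2$clusters$radius,
               (p$a / 2) * st2$clusters$m^(1 / 3))
  # concentration-dependent rate peaks at r0 when the felt c equals c0
  stc <- proliferate(st, 1, mode = "concentration_dependent")
  g <- log(stc$clusters$m / st$clusters$m)
  expect_true(all(g > 0 & g <= p$r0_i + 1e-12))
  # stochastic variant conserves integer births and the mean
  set.seed(1)
  sts <- proliferate(st, 1, mode = "constant", stochastic = TRUE)
  expect_true(all(sts$clusters$m >= st$clusters$m))
  expect_true(all(sts$clusters$m %% 1 == 0))
})

test_that("full runs are deterministic, monotone and mass-consistent", {
  p <- table1_params(n = 30, t_end = 48, seed = 8L)
  a <- run_cda(p, mode = "constant")
  b <- run_cda(p, mode = "constant")
  expect_identical(a$counts, b$counts)
  expect_identical(a$final_state$clusters, b$final_state$clusters)
  # count never increases; each decrease is logged as merges
  dc <- diff(a$counts$clusters)
  expect_true(all(dc <= 0))
  expect_equal(sum(-dc), nrow(a$merges))
  # total cells grow exactly at the constant rate between records
  tc <- a$counts$total_cells
  expect_equal(tc[length(tc)],
               tc[1] * exp(p$alpha * a$counts$t_h[length(tc)]),
               tolerance = 1e-8)
})

test_that("velocities of an isolated pair are equal and opposite", {
  p <- table1_params(box_length = 4000)
  st <- two_cluster_state(p, 300)
  v <- compute_velocities(st, list(screened = FALSE, periodic = FALSE,
                                   fixed_background = 1.0))
  expect_equal(v[1, ], -v[2, ], tolerance = 1e-12)
  expect_gt(v[1, 1], 0)  # mutual attraction
  expect_equal(v[1, 2:3], c(0, 0) , tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("halving time picks the first crossing", {
  counts <- data.frame(t_h = c(0, 1, 2, 3), clusters = c(10, 7, 5, 5))
  expect_equal(halving_time(counts), 2)
  expect_true(is.na(halving_time(data.frame(t_h = 0:2,
                                            clusters = c(4, 4, 3)))))
})

test_that("beta does not change motion (Weber-Fechner invariance)", {
  pA <- table1_params(beta = 100, seed = 12L)
  pB <- table1_params(beta = 1000, seed = 12L)
  vA <- compute_velocities(init_state(pA))
  vB <- compute_velocities(init_state(pB))
  expect_equal(vA, vB, tolerance = 1e-12)
})
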