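test_that("screening length closed form and scaling", {
  expect_identical(screening_length(10, 0.1), 600)
  # D = 20 um^2/s, 1/mu ~ 0.58 days -> lambda ~ 1 mm
  expect_equal(screening_length(20, 1 / (0.58 * 24)), 1000, tolerance = 0.01)
  expect_equal(screening_length(40, 0.1), 2 * screening_length(10, 0.1))
  expect_error(screening_length(0, 0.1), "positive")
  expect_error(screening_length(10, -1), "positive")
})

test_that("point source field matches the screened Green function", {
  p <- table1_params()
  q <- 1000 * 3600
  r <- c(600, 0, 0)
  f <- point_source_field(q, r, p)
  expect_equal(f$c, q * exp(-1) / (4 * pi * 36000 * 600))
  # gradient points toward the source and matches finite differences
  expect_lt(f$grad[1], 0)
  expect_equal(f$grad[2:3], c(0, 0))
  h <- 1e-3
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- h
    num <- (point_source_field(q, r + e, p)$c -
            point_source_field(q, r - e, p)$c) / (2 * h)
    expect_equal(f$grad[k], num, tolerance = 1e-6)
  }
  expect_error(point_source_field(q, c(0, 0, 0), p), "singular")
})

test_that("point source field satisfies the steady diffusion equation", {
  # D lap(c) - mu c = 0 away from the source; for a radial profile
  # lap c = (1/r) (r c)'' checked by central differences
  p <- table1_params()
  q <- 3.6e6
  cr <- function(r) point_source_field(q, c(r, 0, 0), p)$c
  for (r in c(100, 300, 900)) {
    h <- 0.05
    lap <- (( (r + h) * cr(r + h) - 2 * r * cr(r) + (r - h) * cr(r - h)) / h^2) / r
    resid <- p$d_c_i * lap - p$mu * cr(r)
    expect_lt(abs(resid), 0.01 * p$mu * cr(r))
  }
})

test_that("mean background level is linear and correct", {
  # 30 cells at beta = 1000/s in 1 mm^3 with mu = 0.1/h -> 1.08 um^-3
  expect_equal(mean_background(1000, 30, 0.1, 1e9), 1.08)
  expect_equal(mean_background(1000, 60, 0.1, 1e9),
               2 * mean_background(1000, 30, 0.1, 1e9))
  expect_error(mean_background(-1, 30, 0.1, 1e9), "positive")
})

test_that("Weber-Fechner velocity: fold-change law, roll-offs, cap", {
  p <- table1_params()
  # no gradient, no drift
  expect_equal(chemotactic_velocity(list(c = 1, grad = c(0, 0, 0)), p),
               c(0, 0, 0))
  # relative gradient 1/lambda -> 3 um/h
  v <- chemotactic_velocity(list(c = 1, grad = c(1 / 600, 0, 0)), p)
  expect_equal(v[1], 3, tolerance = 1e-12)
  # beta-invariance: scaling c and grad together changes nothing
  v2 <- chemotactic_velocity(list(c = 10, grad = c(10 / 600, 0, 0)), p)
  expect_identical(v, v2)
  # below k_on the response fades linearly
  clo <- p$k_on / 4
  vlo <- chemotactic_velocity(list(c = clo, grad = c(clo / 600, 0, 0)), p)
  expect_equal(vlo[1], 3 / 4, tolerance = 1e-12)
  # above k_off it saturates as k_off/c
  chi <- p$k_off * 4
  vhi <- chemotactic_velocity(list(c = chi, grad = c(chi / 600, 0, 0)), p)
  expect_equal(vhi[1], 3 / 4, tolerance = 1e-12)
  # speed cap
  vc <- chemotactic_velocity(list(c = 1, grad = c(1, 0, 0)), p)
  expect_equal(sqrt(sum(vc^2)), p$v_cap)
  expect_error(chemotactic_velocity(list(c = 0, grad = c(1, 0, 0)), p),
               "positive")
})

test_that("superposed field: symmetry and self-exclusion", {
  p <- table1_params(box_length = 2000)
  st <- init_state(p, fixed_count = TRUE)
  # single isolated cluster: no external gradient at its own position
  st1 <- st
  st1$clusters <- data.frame(id = 1L, x = 700, y = 900, z = 1100, m = 1,
                             radius = 10)
  f1 <- superpose_field(st1, c(700, 900, 1100), exclude_id = 1L)
  expect_equal(f1$grad, c(0, 0, 0))
  expect_gt(f1$c, 0)
  # two equal clusters: equal and opposite gradients
  st2 <- st1
  st2$clusters <- data.frame(id = 1:2, x = c(900, 1100), y = 1000, z = 1000,
                             m = 1, radius = 10)
  g1 <- superpose_field(st2, c(900, 1000, 1000), exclude_id = 1L)$grad
  g2 <- superpose_field(st2, c(1100, 1000, 1000), exclude_id = 2L)$grad
  expect_equal(g1, -g2, tolerance = 1e-10)
  expect_gt(g1[1], 0)  # cluster 1 is pulled toward cluster 2
  # evaluating at an included source is singular
  expect_error(superpose_field(st2, c(900, 1000, 1000)), "singular")
})

test_that("superposed field agrees with a deep brute-force image sum", {
  p <- table1_params(box_length = 1000, seed = 4L)
  st <- init_state(p, fixed_count = TRUE)
  set.seed(42)
  n <- 50
  st$clusters <- data.frame(id = seq_len(n),
                            x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                            z = runif(n, 0, 1000), m = runif(n, 1, 5))
  st$clusters$radius <- (p$a / 2) * st$clusters$m^(1 / 3)
  point <- c(333, 587, 101)
  f <- superpose_field(st, point)
  # independent direct sum over all periodic images within 8 lambda
  # (remainder < 0.3% of the background; written without the package's
  # image-shift helper)
  lam <- p$lambda; D <- p$d_c_i
  kr <- -5:5
  sh <- as.matrix(expand.grid(kr, kr, kr)) * 1000
  cc <- 0; gg <- c(0, 0, 0)
  for (j in seq_len(n)) {
    q <- p$beta_i * st$clusters$m[j]
    d <- -sweep(sh, 2, point - c(st$clusters$x[j], st$clusters$y[j],
                                 st$clusters$z[j]), "-")
    r <- sqrt(rowSums(d^2))
    keep <- r <= 8 * lam & r > 0
    rk <- r[keep]
    cc <- cc + sum(q * exp(-rk / lam) / (4 * pi * D * rk))
    dmag <- -q * exp(-rk / lam) * (1 / rk + 1 / lam) / (4 * pi * D * rk^2)
    gg <- gg + colSums(d[keep, , drop = FALSE] * dmag)
  }
  expect_equal(f$c, cc, tolerance = 0.005)
  expect_equal(f$grad, unname(gg), tolerance = 0.005)
})

test_that("compiled field kernel matches the R reference superposition", {
  p <- table1_params(box_length = 1000, seed = 11L)
  st <- init_state(p, seed = 11L)
  ff <- cdakit:::field_at_clusters(st, list(self_conc = TRUE))
  for (i in c(1L, nrow(st$clusters))) {
    ref <- superpose_field(st, as.numeric(st$clusters[i, c("x", "y", "z")]),
                           exclude_id = st$clusters$id[i])
    expect_equal(ff$c[i], ref$c, tolerance = 1e-10)
    expect_equal(as.numeric(ff$grad[i, ]), ref$grad, tolerance = 1e-10)
  }
})
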