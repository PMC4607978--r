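#' @useDynLib cdakit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Dimensionless Holtsmark width prefactor for a Poisson field of
# inverse-square sources: the 3D characteristic function is
# exp(-(4/15)(2 pi)^(3/2) n q^(3/2) |k|^(3/2)), so the one-component scale
# with CF exp(-(s|k|)^(3/2)) is s = C_H * q * n^(2/3) with
# C_H = ((4/15)(2 pi)^(3/2))^(2/3). Verified against the Monte-Carlo
# oracle in the test suite.
holtsmark_prefactor <- ((4 / 15) * (2 * pi)^1.5)^(2 / 3)

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# construction; cached.
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  out <- list(x = nodes[ord], w = weights[ord])
  gl_cache[[key]] <- out
  out
}

#' One-component Holtsmark probability density
#'
#' Marginal density of the isotropic 3D stable law of index 3/2 that
#' governs the velocity of a cluster in a random suspension of
#' inverse-square attractors. Evaluated by numerical inversion of the
#' characteristic function exp(-(scale*|k|)^(3/2)): the oscillatory
#' integral is split at the zeros of the cosine and each panel integrated
#' by Gauss-Legendre quadrature, which is uniformly accurate from the core
#' into the v^(-5/2) tail.
#'
#' @param v velocity component(s) (um/h)
#' @param scale width parameter v_* (um/h), positive
#' @return density values, same length as `v`
#' @export
holtsmark_marginal_pdf <- function(v, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  w <- abs(v) / scale
  gl <- gauss_legendre(12)
  umax <- 30  # exp(-30^1.5) ~ 1e-72
  f <- vapply(w, function(wi) {
    step <- if (wi > 0) min(pi / wi, 0.5) else 0.5
    brk <- seq(0, umax, by = step)
    if (brk[length(brk)] < umax) brk <- c(brk, umax)
    a <- brk[-length(brk)]; b <- brk[-1]
    half <- (b - a) / 2; mid <- (a + b) / 2
    u <- outer(gl$x, half) + rep(mid, each = length(gl$x))
    vals <- cos(u * wi) * exp(-u^1.5)
    sum(colSums(vals * gl$w) * half) / pi
  }, numeric(1))
  f / scale
}

#' Sample the one-component Holtsmark law exactly
#'
#' Chambers-Mallows-Stuck sampler for the symmetric stable law of index
#' 3/2 with characteristic function exp(-(scale*|k|)^(3/2)).
#'
#' @param n number of samples
#' @param scale width parameter v_*
#' @return numeric vector of length `n`
#' @export
rholtsmark <- function(n, scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  alpha <- 1.5
  U <- stats::runif(n, -pi / 2, pi / 2)
  E <- stats::rexp(n)
  Z <- sin(alpha * U) / cos(U)^(1 / alpha) *
    (cos(U - alpha * U) / E)^((1 - alpha) / alpha)
  scale * Z
}

#' Predicted Holtsmark width of the velocity distribution
#'
#' v_* = C_H * (chi0 K_on * mu) / (4 pi D) * n^(-1/3): the Weber-Fechner
#' coupling per unit background concentration supplies the physical
#' prefactor, the fixed dimensionless constant C_H ~ 2.603 comes from the
#' stable-law computation for a Poisson field of inverse-square sources,
#' and the width falls as the -1/3 power of cluster density: denser
#' suspensions move more slowly.
#'
#' @param cluster_density cluster number density (mm^-3)
#' @param params a `cda_params` object
#' @return width v_* in um/h
#' @export
holtsmark_scale <- function(cluster_density, params) {
  if (any(cluster_density <= 0)) stop("density must be positive")
  n_i <- cluster_density * 1e-9
  holtsmark_prefactor * params$chi_ref_i * params$mu /
    (4 * pi * params$d_c_i) * n_i^(-1 / 3)
}

#' Monte-Carlo velocity-field oracle
#'
#' Brute-force reference for the velocity statistics: scatters Poisson
#' configurations of unit sources around a test point and sums their
#' inverse-square chemotactic pulls directly, the same physics as the
#' field superposition plus Weber-Fechner response, with none of the
#' stable-law machinery.
#'
#' In the unscreened point-mass limit (`screened = FALSE`, the regime of
#' the exact Holtsmark law) the direct sum is truncated at `r_max` and the
#' remainder of the infinite Poisson sum, a sum of very many very small
#' independent pulls that is Gaussian to CLT accuracy, is added
#' analytically as noise of per-component variance 4 pi n q^2 / (3 r_max);
#' the background concentration is the uniform mean beta*n/mu. With
#' screening the contributions are Yukawa-damped, the sensed background is
#' the summed concentration of the sampled sources plus the analytic mean
#' of the beyond-`r_max` remainder, and no Gaussian correction is needed
#' beyond 3 lambda.
#'
#' @param density cluster density (mm^-3)
#' @param params a `cda_params` object
#' @param n_samples number of independent configurations
#' @param seed RNG seed
#' @param screened include Yukawa screening and the fluctuating sensed
#'   background (simulation physics) instead of the point-mass limit
#' @param r_max truncation radius (um); defaults to 5 mean spacings
#'   (unscreened) or 3 lambda (screened)
#' @param background screened mode only: `"local"` divides by the
#'   fluctuating concentration actually sensed at the test point (full
#'   fold-change physics; near a dominant source the response saturates,
#'   steepening the extreme tail), `"uniform"` divides by the mean
#'   background beta*n/mu (the stable-law theory's normalization, which
#'   preserves the -5/2 intermediate tail)
#' @param split also return the nearest-source and far-field parts
#' @return matrix (n_samples x 3) of velocity components (um/h), or, if
#'   `split`, a list `full`, `nn`, `far` of such matrices with
#'   `full = nn + far` exactly
#' @export
velocity_field_oracle <- function(density, params, n_samples, seed = 1L,
                                  screened = FALSE, r_max = NULL,
                                  background = c("local", "uniform"),
                                  split = FALSE) {
  stopifnot(n_samples >= 1)
  background <- match.arg(background)
  n_i <- density * 1e-9
  spacing <- n_i^(-1 / 3)
  if (is.null(r_max)) r_max <- if (screened) 3 * params$lambda else 5 * spacing
  set.seed(seed)
  raw <- cpp_oracle_samples(as.integer(n_samples), n_i, r_max,
                            params$lambda, screened)
  pref <- params$beta_i / (4 * pi * params$d_c_i)   # conc per unit (1/r)
  cbar <- params$beta_i * n_i / params$mu           # uniform mean background
  if (screened) {
    lam <- params$lambda
    # analytic mean of the concentration from sources beyond r_max
    c_tail <- pref * n_i * 4 * pi * lam * (r_max + lam) * exp(-r_max / lam)
    denom <- if (background == "uniform") cbar else pref * raw$csum + c_tail
    full <- params$chi_ref_i * pref * raw$g / denom
    nn <- params$chi_ref_i * pref * raw$gnn / denom
  } else {
    A_v <- params$chi_ref_i * pref / cbar  # um^3/h per unit source
    sigma_tail <- A_v * sqrt(4 * pi * n_i / (3 * r_max))
    tail <- matrix(stats::rnorm(3 * n_samples, sd = sigma_tail), ncol = 3)
    full <- A_v * raw$g + tail
    nn <- A_v * raw$gnn
  }
  if (!split) return(full)
  list(full = full, nn = nn, far = full - nn)
}

#' Nearest-neighbour / far-field decomposition of the velocity
#'
#' Splits each oracle configuration's velocity into the pull of the single
#' nearest source and the summed remainder. The nearest source carries the
#' power-law tail; the many weak far sources sum to an approximately
#' Gaussian core, and the two parts add back to the full Holtsmark
#' statistics.
#'
#' @inheritParams velocity_field_oracle
#' @return list with matrices `nn` and `far` (n_samples x 3) and the
#'   `full` sum
#' @export
decompose_nn_far <- function(density, params, n_samples, seed = 1L,
                             screened = FALSE, r_max = NULL) {
  velocity_field_oracle(density, params, n_samples, seed = seed,
                        screened = screened, r_max = r_max, split = TRUE)
}

#' Closed-form coalescence time of an isolated cluster pair
#'
#' In a uniform background c and neglecting screening (separation well
#' below lambda), each cluster of m cells pulls its partner at
#' v(r) = chi0 K_on * beta m / (4 pi D r^2 c), so the gap closes at 2v and
#' r^3 shrinks linearly in time: t_c = (r_init^3 - r_contact^3) / (6 A)
#' with A = chi0 K_on * beta m / (4 pi D c).
#'
#' @param r_init initial center separation (um)
#' @param m_each cells per cluster
#' @param background_c uniform sensed concentration (molecules um^-3)
#' @param params a `cda_params` object
#' @return collision time in hours (0 if already in contact)
#' @export
pair_coalescence_time <- function(r_init, m_each, background_c, params) {
  r_contact <- params$a * m_each^(1 / 3)  # two equal radii (a/2) m^(1/3)
  if (r_init <= r_contact) return(0)
  A <- params$chi_ref_i * params$beta_i * m_each /
    (4 * pi * params$d_c_i * background_c)
  (r_init^3 - r_contact^3) / (6 * A)
}

#' Frozen mean-field aggregation-time calibration constant
#'
#' The coalescence kernel fixes the aggregation e-folding time up to a
#' dimensionless O(1) constant: tau_agg = kappa * D / (chi0 K_on * mu).
#' kappa was calibrated once by exponential-decay fits to agent-based
#' count series at the reference parameter set (the calibration driver is
#' `analysis/03_calibrate_kappa.R`) and is frozen here.
#'
#' @return the dimensionless constant kappa
#' @export
cda_kappa <- function() 0.97

#' Mean-field cluster density under chemotaxis-driven coalescence
#'
#' The pairwise coalescence kernel is proportional to the attractant
#' production of both partners and the chemotactic coefficient and
#' inversely proportional to D; plugged into the coagulation rate equation
#' it yields exponential decay of the cluster count with an e-folding time
#' independent of the initial density: closer packing is exactly offset by
#' the slower Weber-Fechner speeds at the higher background it generates.
#'
#' @param n0 initial cluster density (mm^-3)
#' @param t time(s) (h)
#' @param params a `cda_params` object
#' @param kappa dimensionless calibration constant, see [cda_kappa()]
#' @return list with `density` (mm^-3, same length as `t`), `tau_agg`
#'   (h), and `t_half` (h, = tau_agg * log 2)
#' @export
mean_field_cluster_count <- function(n0, t, params, kappa = cda_kappa()) {
  if (n0 <= 0) stop("n0 must be positive")
  tau <- kappa * params$d_c_i / (params$chi_ref_i * params$mu)
  list(density = n0 * exp(-t / tau), tau_agg = tau, t_half = tau * log(2))
}
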