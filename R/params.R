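#' Model parameters for chemotaxis-driven aggregation
#'
#' Collects every physical and numerical parameter of the CDA model in one
#' validated object, converted once at construction to the internal unit
#' system: micrometres, hours, molecules per cubic micrometre. Published
#' parameter tables for this system quote mixed units (densities per mm^3,
#' production rates per second, proliferation per hour or per day); doing
#' the conversion in a single place removes a whole class of unit bugs.
#'
#' @param n initial cell number density (cells mm^-3)
#' @param a cell diameter (um)
#' @param alpha basal cell proliferation rate (h^-1)
#' @param beta chemoattractant production rate per cell (molecules s^-1)
#' @param chi_ref combined chemotactic response chi0*K_on (um^2 s^-1)
#' @param k_on lower sensing bound (molecules um^-3); below it the
#'   fold-change response fades linearly to zero
#' @param k_off upper sensing bound (molecules um^-3); above it the
#'   response saturates as `k_off/c`
#' @param mu chemoattractant degradation rate (h^-1)
#' @param d_c chemoattractant diffusivity (um^2 s^-1)
#' @param c0 reference concentration for the concentration-dependent
#'   proliferation response (molecules mm^-3)
#' @param r0 peak proliferation rate of the concentration-dependent
#'   variant (day^-1)
#' @param box_length periodic box edge (um)
#' @param dt_max maximum integration step (h)
#' @param t_end simulated duration (h)
#' @param v_cap speed cap regularizing near-contact attraction (um h^-1)
#' @param seed integer RNG seed
#'
#' @return an object of class `cda_params` (a list). Internal-unit fields
#'   carry the suffix `_i`: `n_i` (um^-3), `beta_i` (molecules h^-1),
#'   `chi_ref_i` and `d_c_i` (um^2 h^-1), `c0_i` (molecules um^-3). The
#'   original inputs are kept so that a round trip to table units is exact.
#' @seealso [table1_params()] for the published defaults,
#'   [read_cda_config()] for file-based construction.
#' @export
model_params <- function(n = 30, a = 20, alpha = 0.02, beta = 1000,
                         chi_ref = 0.5, k_on = 1e-4, k_off = 1e2,
                         mu = 0.1, d_c = 10, c0 = 1e9, r0 = 0.48,
                         box_length = 1000, dt_max = 0.5, t_end = 480,
                         v_cap = 50, seed = 1L) {
  num <- list(n = n, a = a, alpha = alpha, beta = beta, chi_ref = chi_ref,
              k_on = k_on, k_off = k_off, mu = mu, d_c = d_c, c0 = c0,
              r0 = r0, box_length = box_length, dt_max = dt_max,
              t_end = t_end, v_cap = v_cap)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  if (k_on >= k_off) stop("k_on must be smaller than k_off")
  p <- c(num, list(seed = as.integer(seed)))
  # internal units: um, h, molecules um^-3
  p$n_i       <- n * 1e-9          # mm^-3 -> um^-3
  p$beta_i    <- beta * 3600       # s^-1 -> h^-1
  p$chi_ref_i <- chi_ref * 3600    # um^2 s^-1 -> um^2 h^-1
  p$d_c_i     <- d_c * 3600        # um^2 s^-1 -> um^2 h^-1
  p$c0_i      <- c0 * 1e-9         # mm^-3 -> um^-3
  p$r0_i      <- r0 / 24           # day^-1 -> h^-1
  p$lambda    <- sqrt(p$d_c_i / p$mu)  # screening length (um)
  class(p) <- "cda_params"
  p
}

#' Published reference parameter set
#'
#' The parameter table used throughout: n in 10-100 mm^-3 (default 30),
#' cell diameter a = 20 um, proliferation alpha = 0.02 h^-1, attractant
#' production beta in 100-1000 s^-1 (default 1000), chemotactic response
#' chi0*K_on = 0.5 um^2/s, degradation mu = 0.1 h^-1 and diffusivity
#' D_c = 10 um^2/s, which together impose an interaction length
#' sqrt(D_c/mu) = 600 um and typical speeds of a few um/h.
#'
#' @param ... overrides passed on to [model_params()] (e.g. `n`, `seed`,
#'   `t_end`).
#' @return a `cda_params` object.
#' @export
table1_params <- function(...) {
  args <- list(...)
  defaults <- list(n = 30, a = 20, alpha = 0.02, beta = 1000,
                   chi_ref = 0.5, mu = 0.1, d_c = 10)
  model_params_args <- utils::modifyList(defaults, args)
  do.call(model_params, model_params_args)
}

#' @export
print.cda_params <- function(x, ...) {
  cat("CDA model parameters\n")
  cat(sprintf("  n = %g mm^-3, a = %g um, alpha = %g h^-1\n",
              x$n, x$a, x$alpha))
  cat(sprintf("  beta = %g s^-1, chi0*Kon = %g um^2/s, mu = %g h^-1, D_c = %g um^2/s\n",
              x$beta, x$chi_ref, x$mu, x$d_c))
  cat(sprintf("  screening length lambda = %g um\n", x$lambda))
  cat(sprintf("  box = %g um, dt_max = %g h, t_end = %g h, v_cap = %g um/h, seed = %d\n",
              x$box_length, x$dt_max, x$t_end, x$v_cap, x$seed))
  invisible(x)
}

#' Convert parameters back to table units
#'
#' Inverse of the construction-time unit conversion; used to verify that
#' conversions are applied exactly once.
#'
#' @param params a `cda_params` object
#' @return named list in table units (mm^-3, um, h^-1, s^-1, um^2/s, day^-1)
#' @export
params_in_table_units <- function(params) {
  stopifnot(inherits(params, "cda_params"))
  list(n = params$n_i * 1e9, a = params$a, alpha = params$alpha,
       beta = params$beta_i / 3600, chi_ref = params$chi_ref_i / 3600,
       mu = params$mu, d_c = params$d_c_i / 3600,
       c0 = params$c0_i * 1e9, r0 = params$r0_i * 24)
}
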