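#' Screening (interaction) length of the attractant field
#'
#' A diffusible factor that is degraded at rate `mu` while diffusing with
#' coefficient `d_c` builds a quasi-steady profile around each source that
#' decays as 1/r out to lambda = sqrt(D/mu) and exponentially beyond;
#' lambda is the distance over which clusters can feel each other.
#'
#' @param d_c diffusivity (um^2 s^-1)
#' @param mu degradation rate (h^-1)
#' @return screening length in um
#' @examples
#' screening_length(10, 0.1)  # 600 um
#' @export
screening_length <- function(d_c, mu) {
  if (!is.numeric(d_c) || !is.numeric(mu) || any(d_c <= 0) || any(mu <= 0))
    stop("d_c and mu must be positive")
  sqrt(d_c * 3600 / mu)
}

#' Steady screened-diffusion field of a point source
#'
#' Solves D lap(c) - mu c + q delta = 0: a Yukawa-screened Coulomb
#' profile. Concentration decays as exp(-r/lambda)/(4 pi D r); the
#' gradient points up-gradient, i.e. toward the source.
#'
#' @param q emission rate of the source (molecules h^-1)
#' @param r_vec displacement from source to evaluation point, 3-vector (um)
#' @param params a `cda_params` object
#' @return a `cda_field` list with `c` (molecules um^-3) and `grad`
#'   (molecules um^-4, 3-vector)
#' @export
point_source_field <- function(q, r_vec, params) {
  stopifnot(inherits(params, "cda_params"), length(r_vec) == 3L)
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("singular evaluation at the source; evaluate at >= cluster radius")
  lam <- params$lambda
  D <- params$d_c_i
  cc <- q * exp(-r / lam) / (4 * pi * D * r)
  dcdr <- -q * exp(-r / lam) * (1 / r + 1 / lam) / (4 * pi * D * r)
  field_sample(cc, dcdr * r_vec / r)
}

field_sample <- function(c, grad) {
  structure(list(c = c, grad = as.numeric(grad)), class = "cda_field")
}

#' Mean background concentration of attractant
#'
#' Within the screening length the 1/r profiles of all sources overlap, so
#' the average level is spatially uniform: production times total cell
#' number over degradation times volume.
#'
#' @param beta per-cell production rate (molecules s^-1)
#' @param total_cells total number of cells in the volume
#' @param mu degradation rate (h^-1)
#' @param volume volume (um^3)
#' @return mean concentration (molecules um^-3)
#' @export
mean_background <- function(beta, total_cells, mu, volume) {
  if (any(c(beta, total_cells, mu, volume) <= 0))
    stop("all inputs must be positive")
  (beta * 3600) * total_cells / (mu * volume)
}

#' Weber-Fechner chemotactic velocity
#'
#' Cells respond to fold changes in attractant: v = chi0*K_on * grad(c)/c
#' inside the sensing range `[k_on, k_off]`, so scaling concentration and
#' gradient together leaves the velocity unchanged. Below `k_on` the
#' response fades linearly with c/k_on; above `k_off` it saturates as
#' k_off/c. The speed is capped at `v_cap` to regularize the near-contact
#' divergence of the inverse-square attraction.
#'
#' @param sample a `cda_field` (or list with `c` and `grad`)
#' @param params a `cda_params` object
#' @return velocity 3-vector (um h^-1)
#' @export
chemotactic_velocity <- function(sample, params) {
  stopifnot(inherits(params, "cda_params"))
  cc <- sample$c
  if (!is.numeric(cc) || cc <= 0) stop("concentration must be positive")
  v <- params$chi_ref_i * sample$grad / cc
  if (cc < params$k_on) v <- v * (cc / params$k_on)
  if (cc > params$k_off) v <- v * (params$k_off / cc)
  spd <- sqrt(sum(v^2))
  if (spd > params$v_cap) v <- v * (params$v_cap / spd)
  v
}

# Periodic image shift vectors (rows) reaching a cutoff from any point of
# the box: all integer multiples of L with |shift| - sqrt(3)/2*L <= cutoff.
image_shifts <- function(box_length, cutoff) {
  kmax <- floor((cutoff + box_length) / box_length)
  g <- seq(-kmax, kmax)
  sh <- as.matrix(expand.grid(x = g, y = g, z = g)) * box_length
  keep <- sqrt(rowSums(sh^2)) <= cutoff + sqrt(3) * box_length
  sh[keep, , drop = FALSE]
}

#' Superposed attractant field of a cluster population
#'
#' Sums the screened point-source fields of every cluster (emission
#' q_j = beta * m_j) over minimum-image displacements plus periodic images
#' out to 3*lambda, and adds the continuum mean of the infinite lattice
#' beyond the cutoff, (beta*M/V/mu)*(1+R/lambda)*exp(-R/lambda), which the
#' truncated sum would otherwise omit (about 20% of the uniform background
#' at R = 3*lambda). The gradient omits the cluster `exclude_id` (a
#' cluster does not chase its own secretion) while the concentration
#' includes every cluster, the excluded one contributing its surface
#' value, i.e. its field evaluated at its own radius.
#'
#' @param state a `cda_state` (see [init_state()])
#' @param point evaluation point, 3-vector (um)
#' @param exclude_id cluster id whose gradient is omitted, or `NULL`
#' @return a `cda_field` list with `c` and `grad`
#' @export
superpose_field <- function(state, point, exclude_id = NULL) {
  params <- state$params
  cl <- state$clusters
  lam <- params$lambda
  D <- params$d_c_i
  cutoff <- 3 * lam
  sh <- image_shifts(params$box_length, cutoff)
  ctot <- 0
  grad <- c(0, 0, 0)
  for (j in seq_len(nrow(cl))) {
    q <- params$beta_i * cl$m[j]
    self <- !is.null(exclude_id) && cl$id[j] == exclude_id
    pj <- c(cl$x[j], cl$y[j], cl$z[j])
    dx <- sweep(sh, 2, point - pj, "+")
    r <- sqrt(rowSums(dx^2))
    if (!self && any(r == 0))
      stop("singular evaluation at the source; evaluate at >= cluster radius")
    keep <- r <= cutoff & r > 0
    if (any(keep)) {
      rk <- r[keep]
      ck <- q * exp(-rk / lam) / (4 * pi * D * rk)
      ctot <- ctot + sum(ck)
      if (!self) {
        dmag <- -q * exp(-rk / lam) * (1 / rk + 1 / lam) / (4 * pi * D * rk^2)
        grad <- grad + colSums(dx[keep, , drop = FALSE] * dmag)
      }
    }
    if (self && any(r == 0)) {
      # own secretion sensed at the cluster surface
      R <- cl$radius[j]
      ctot <- ctot + q * exp(-R / lam) / (4 * pi * D * R)
    }
  }
  n_mass <- sum(cl$m) / params$box_length^3
  ctot <- ctot + (params$beta_i * n_mass / params$mu) *
    (1 + cutoff / lam) * exp(-cutoff / lam)
  field_sample(ctot, grad)
}
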