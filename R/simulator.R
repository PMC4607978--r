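#' Seed an initial simulation state
#'
#' Places single cells (m = 1) uniformly at random in the periodic box.
#' The number of cells is Poisson with mean n*V, matching seeding from a
#' dilute suspension; `fixed_count = TRUE` uses exactly round(n*V) cells
#' instead (useful in tests). Warns if the expected contact overlap
#' fraction exceeds 10%.
#'
#' @param params a `cda_params` object
#' @param seed RNG seed (defaults to `params$seed`)
#' @param fixed_count place exactly `round(n*V)` cells instead of a
#'   Poisson draw
#' @return a `cda_state`: list with time `t` (h), `clusters` data frame
#'   (`id`, `x`, `y`, `z`, `m`, `radius`) and `params`
#' @export
init_state <- function(params, seed = params$seed, fixed_count = FALSE) {
  stopifnot(inherits(params, "cda_params"))
  set.seed(seed)
  L <- params$box_length
  mean_n <- params$n_i * L^3
  n <- if (fixed_count) round(mean_n) else stats::rpois(1, mean_n)
  # expected fraction of cells born inside another's contact sphere
  overlap <- 1 - exp(-params$n_i * 4 / 3 * pi * params$a^3)
  if (overlap > 0.1)
    warning("expected initial overlap fraction ", signif(overlap, 2),
            " exceeds 10%; seeding anyway")
  cl <- data.frame(id = seq_len(n),
                   x = stats::runif(n, 0, L),
                   y = stats::runif(n, 0, L),
                   z = stats::runif(n, 0, L),
                   m = rep(1, n))
  cl$radius <- cluster_radius(cl$m, params)
  state <- list(t = 0, clusters = cl, params = params,
                next_id = n + 1L)
  class(state) <- "cda_state"
  state
}

# volume-conserving sphere of m cells of diameter a
cluster_radius <- function(m, params) (params$a / 2) * m^(1 / 3)

#' @export
print.cda_state <- function(x, ...) {
  cat(sprintf("CDA state: t = %g h, %d clusters, %g cells total\n",
              x$t, nrow(x$clusters), sum(x$clusters$m)))
  invisible(x)
}

# Field (concentration + gradient excluding self) at every cluster center.
# opts: screened (logical), periodic (logical), self_conc (logical: add the
# cluster's own secretion, at its surface, to the concentration — the
# "total felt" concentration; default FALSE = external field only),
# fixed_background (numeric concentration overriding the sensed c, or NULL).
field_at_clusters <- function(state, opts = list()) {
  p <- state$params
  cl <- state$clusters
  screened <- opts$screened %||% TRUE
  periodic <- opts$periodic %||% TRUE
  cutoff <- if (screened) 3 * p$lambda else Inf
  shifts <- if (periodic) {
    if (!is.finite(cutoff))
      stop("periodic boundaries require a finite (screened) cutoff")
    image_shifts(p$box_length, cutoff)
  } else matrix(0, 1, 3)
  pos <- as.matrix(cl[, c("x", "y", "z")])
  f <- cpp_field_at_clusters(pos, cl$m, cl$radius, shifts,
                             p$lambda, p$d_c_i, p$beta_i,
                             if (is.finite(cutoff)) cutoff else 1e30,
                             screened, opts$self_conc %||% FALSE)
  if (screened && periodic) {
    # continuum correction for sources beyond the cutoff: the screened
    # profile integrated over r > R contributes (1 + R/lambda) exp(-R/lambda)
    # of the uniform background beta*n/mu (~20% at R = 3 lambda), which the
    # truncated sum would otherwise systematically omit
    n_mass <- sum(cl$m) / p$box_length^3
    f$c <- f$c + (p$beta_i * n_mass / p$mu) *
      (1 + cutoff / p$lambda) * exp(-cutoff / p$lambda)
  }
  if (!is.null(opts$fixed_background)) f$c <- rep(opts$fixed_background, nrow(cl))
  f
}

#' Chemotactic velocities of all clusters
#'
#' Superposes the attractant field at every cluster center and applies the
#' Weber-Fechner fold-change response with its sensing-range roll-offs and
#' the speed cap. The response is to the external field: both the gradient
#' and the normalizing concentration exclude the cluster's own secretion,
#' which is radially symmetric about the cluster and carries no directional
#' information. (Including it would suppress motility at low density in
#' proportion to the cluster's own surface concentration and break the
#' density independence of the aggregation rate.)
#'
#' @param state a `cda_state`
#' @param opts internal physics switches (`screened`, `periodic`,
#'   `fixed_background`) used by theory cross-checks; leave empty for the
#'   full model
#' @return matrix (clusters x 3) of velocities in um/h, rownames = cluster ids
#' @export
compute_velocities <- function(state, opts = list()) {
  if (nrow(state$clusters) == 0L) stop("empty state")
  p <- state$params
  f <- field_at_clusters(state, opts)
  cc <- f$c
  fac <- p$chi_ref_i / cc
  fac <- fac * ifelse(cc < p$k_on, cc / p$k_on,
                      ifelse(cc > p$k_off, p$k_off / cc, 1))
  v <- f$grad * fac
  spd <- sqrt(rowSums(v^2))
  over <- spd > p$v_cap
  if (any(over)) v[over, ] <- v[over, , drop = FALSE] * (p$v_cap / spd[over])
  rownames(v) <- state$clusters$id
  v
}

#' Advance cluster positions by one Euler step
#'
#' Forward-Euler update with periodic wrapping. The step is internally
#' reduced so that no cluster moves more than a quarter cell diameter,
#' preventing tunneling through contact; the state's clock advances by the
#' step actually taken.
#'
#' @param state a `cda_state`
#' @param dt requested step (h), at most `params$dt_max`
#' @param opts physics switches, see [compute_velocities()]
#' @return updated `cda_state`
#' @export
advance <- function(state, dt, opts = list()) {
  p <- state$params
  if (dt > p$dt_max + 1e-12) stop("dt exceeds dt_max")
  v <- compute_velocities(state, opts)
  vmax <- max(sqrt(rowSums(v^2)))
  dt_eff <- if (vmax > 0) min(dt, p$a / (4 * vmax)) else dt
  cl <- state$clusters
  pos <- as.matrix(cl[, c("x", "y", "z")]) + v * dt_eff
  pos <- pos %% p$box_length
  cl[, c("x", "y", "z")] <- pos
  state$clusters <- cl
  state$t <- state$t + dt_eff
  state
}

# minimum-image displacement b - a (componentwise) in a periodic box
min_image <- function(d, L) d - L * round(d / L)

#' Merge overlapping clusters
#'
#' Any pair whose minimum-image center distance is below the sum of radii
#' coalesces; merging is transitive (connected components by union-find),
#' so chains collapse in one call. A merged cluster carries the summed
#' cell count and the mass-weighted minimum-image centroid, and its radius
#' is recomputed from the volume-conserving sphere rule. One merge event
#' is logged per pair reduction.
#'
#' @param state a `cda_state`
#' @return updated `cda_state`; merge events for this call are in
#'   `attr(, "merges")` (data frame `t`, `id_a`, `id_b`, `id_new`, `m_new`)
#' @export
coalesce <- function(state) {
  cl <- state$clusters
  n <- nrow(cl)
  empty <- data.frame(t = numeric(0), id_a = integer(0), id_b = integer(0),
                      id_new = integer(0), m_new = numeric(0))
  if (n < 2L) { attr(state, "merges") <- empty; return(state) }
  L <- state$params$box_length
  pos <- as.matrix(cl[, c("x", "y", "z")])
  # pairwise minimum-image distances (n is at most a few hundred)
  dx <- min_image(outer(pos[, 1], pos[, 1], "-"), L)
  dy <- min_image(outer(pos[, 2], pos[, 2], "-"), L)
  dz <- min_image(outer(pos[, 3], pos[, 3], "-"), L)
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  rsum <- outer(cl$radius, cl$radius, "+")
  touch <- dist < rsum
  touch[!upper.tri(touch)] <- FALSE
  pairs <- which(touch, arr.ind = TRUE)
  if (nrow(pairs) == 0L) { attr(state, "merges") <- empty; return(state) }

  # union-find for transitive closure
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merges <- empty
  keep <- list()
  next_id <- state$next_id
  for (root in unique(comp)) {
    members <- which(comp == root)
    if (length(members) == 1L) { keep[[length(keep) + 1L]] <- cl[members, ]; next }
    sub <- cl[members, ]
    # mass-weighted centroid via minimum-image displacements from member 1
    ref <- as.numeric(sub[1, c("x", "y", "z")])
    rel <- sweep(as.matrix(sub[, c("x", "y", "z")]), 2, ref, "-")
    rel <- min_image(rel, L)
    cen <- (ref + colSums(rel * sub$m) / sum(sub$m)) %% L
    # log one event per pair reduction, folding members in id order
    ids <- sub$id[order(sub$id)]
    ms <- sub$m[order(sub$id)]
    cur_id <- ids[1]; cur_m <- ms[1]
    for (j in 2:length(ids)) {
      cur_m <- cur_m + ms[j]
      merges <- rbind(merges, data.frame(t = state$t, id_a = cur_id,
                                         id_b = ids[j], id_new = next_id,
                                         m_new = cur_m))
      cur_id <- next_id
      next_id <- next_id + 1L
    }
    newc <- data.frame(id = cur_id, x = cen[1], y = cen[2], z = cen[3],
                       m = sum(sub$m))
    newc$radius <- cluster_radius(newc$m, state$params)
    keep[[length(keep) + 1L]] <- newc
  }
  state$clusters <- do.call(rbind, keep)
  rownames(state$clusters) <- NULL
  state$next_id <- next_id
  attr(state, "merges") <- merges
  state
}

#' Grow clusters by proliferation
#'
#' Constant mode: every cluster grows as m * exp(alpha * dt) (deterministic
#' continuous mass growth). Concentration-dependent mode: each cluster
#' grows at r(c_i) = r0 * 2*(c_i/c0) / (1 + (c_i/c0)^2) — increasing below
#' the reference concentration c0, peaking at r0 exactly at c0, decreasing
#' above — where c_i is the total attractant concentration sensed at the
#' cluster (own secretion included at its surface). `stochastic = TRUE`
#' replaces the deterministic update by Poisson birth events with the same
#' mean (non-default; adds demographic noise).
#'
#' @param state a `cda_state`
#' @param dt time step (h), positive
#' @param mode `"constant"` or `"concentration_dependent"`
#' @param opts physics switches, see [compute_velocities()]
#' @param stochastic draw integer birth counts instead of continuous growth
#' @return updated `cda_state`
#' @export
proliferate <- function(state, dt, mode = c("constant", "concentration_dependent"),
                        opts = list(), stochastic = FALSE) {
  if (dt < 0) stop("dt must be non-negative")
  mode <- match.arg(mode)
  p <- state$params
  rate <- if (mode == "constant") rep(p$alpha, nrow(state$clusters)) else {
    prolif_opts <- opts
    prolif_opts$self_conc <- TRUE  # proliferation senses the total felt c
    cc <- field_at_clusters(state, prolif_opts)$c
    x <- cc / p$c0_i
    p$r0_i * 2 * x / (1 + x^2)
  }
  if (stochastic) {
    births <- stats::rpois(nrow(state$clusters),
                           state$clusters$m * (exp(rate * dt) - 1))
    state$clusters$m <- state$clusters$m + births
  } else {
    state$clusters$m <- state$clusters$m * exp(rate * dt)
  }
  state$clusters$radius <- cluster_radius(state$clusters$m, p)
  state
}

#' Run a full chemotaxis-driven aggregation simulation
#'
#' Repeats move -> merge -> grow until `t_end` (merging before growth keeps
#' radii consistent with the positions that produced contact). Records the
#' cluster-count time series, every merge event, and velocity ensembles at
#' t = 0 plus any requested times. Fully reproducible from the seed.
#'
#' @param params a `cda_params` object
#' @param mode proliferation mode, see [proliferate()]; `"none"` disables
#'   growth
#' @param record_times times (h) at which to record velocity samples and
#'   state snapshots, besides t = 0
#' @param seed RNG seed (defaults to `params$seed`)
#' @param opts physics switches, see [compute_velocities()]
#' @param stop_when_halved stop as soon as the cluster count reaches half
#'   its initial value (the halving time is the usual endpoint)
#' @param fixed_count seed exactly round(n*V) cells, see [init_state()]
#' @return a `cda_trajectory`: list with `counts` (data frame `t_h`,
#'   `clusters`, `total_cells`), `merges`, `velocities` (list of matrices
#'   keyed by time), `snapshots`, `final_state`, `params`
#' @export
run_cda <- function(params, mode = c("constant", "concentration_dependent", "none"),
                    record_times = numeric(0), seed = params$seed,
                    opts = list(), stop_when_halved = FALSE,
                    fixed_count = FALSE) {
  mode <- match.arg(mode)
  state <- init_state(params, seed = seed, fixed_count = fixed_count)
  state <- coalesce(state)  # resolve any overlaps present at seeding
  n0 <- nrow(state$clusters)
  counts <- data.frame(t_h = 0, clusters = n0, total_cells = sum(state$clusters$m))
  merges <- attr(state, "merges")
  velocities <- list()
  snapshots <- list()
  velocities[["0"]] <- compute_velocities(state, opts)
  snapshots[["0"]] <- state$clusters
  pending <- sort(record_times[record_times > 0])
  while (state$t < params$t_end - 1e-9 && nrow(state$clusters) > 1L) {
    dt <- min(params$dt_max, params$t_end - state$t)
    if (length(pending)) dt <- min(dt, pending[1] - state$t)
    state <- advance(state, dt, opts)
    state <- coalesce(state)
    ev <- attr(state, "merges")
    if (nrow(ev)) merges <- rbind(merges, ev)
    if (mode != "none")
      state <- proliferate(state, state$t - counts$t_h[nrow(counts)],
                           mode, opts)
    counts <- rbind(counts, data.frame(t_h = state$t,
                                       clusters = nrow(state$clusters),
                                       total_cells = sum(state$clusters$m)))
    if (length(pending) && state$t >= pending[1] - 1e-9) {
      key <- as.character(pending[1])
      velocities[[key]] <- compute_velocities(state, opts)
      snapshots[[key]] <- state$clusters
      pending <- pending[-1]
    }
    if (stop_when_halved && nrow(state$clusters) <= n0 / 2) break
  }
  out <- list(counts = counts, merges = merges, velocities = velocities,
              snapshots = snapshots, final_state = state, params = params,
              mode = mode, seed = seed)
  class(out) <- "cda_trajectory"
  out
}

#' @export
print.cda_trajectory <- function(x, ...) {
  n0 <- x$counts$clusters[1]
  nT <- x$counts$clusters[nrow(x$counts)]
  cat(sprintf("CDA trajectory: %d -> %d clusters over %.1f h (%d merges, mode %s)\n",
              n0, nT, x$counts$t_h[nrow(x$counts)], nrow(x$merges), x$mode))
  invisible(x)
}

#' Halving time of a cluster-count series
#'
#' First time at which the cluster count reaches half its initial value —
#' the aggregation endpoint reported for both experiments and simulations.
#'
#' @param counts data frame with `t_h` and `clusters` (as in
#'   `run_cda()$counts`), or a `cda_trajectory`
#' @return halving time in hours, or `NA` if the count never halves
#' @export
halving_time <- function(counts) {
  if (inherits(counts, "cda_trajectory")) counts <- counts$counts
  n0 <- counts$clusters[1]
  hit <- which(counts$clusters <= n0 / 2)
  if (!length(hit)) return(NA_real_)
  counts$t_h[hit[1]]
}
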