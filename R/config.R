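#' Read a CDA configuration file
#'
#' Configurations are flat TOML with two tables. `[physical]` mirrors the
#' published parameter names with explicit units in the key
#' (`n_per_mm3`, `a_um`, `alpha_per_h`, `beta_per_s`,
#' `chi_ref_um2_per_s`, `mu_per_h`, `D_um2_per_s`, `c0_per_mm3`,
#' `r0_per_day`); `[numerics]` holds `box_length_um`, `dt_max_h`,
#' `t_end_h`, `seed`, `k_on`, `k_off`, `v_cap`. A single
#' `preset = "table1"` key in `[physical]` expands to the published
#' defaults; explicit keys override the preset. Unknown keys are rejected
#' by name; missing optional keys take the documented defaults.
#'
#' Only the flat key/value TOML subset needed for these two tables is
#' supported (numbers, booleans, quoted strings, `#` comments).
#'
#' @param path path to a TOML file
#' @return a `cda_params` object
#' @export
read_cda_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  toml <- parse_flat_toml(readLines(path, warn = FALSE))
  phys <- toml[["physical"]]  %||% list()
  nums <- toml[["numerics"]]  %||% list()

  phys_map <- c(preset = "preset", n_per_mm3 = "n", a_um = "a",
                alpha_per_h = "alpha", beta_per_s = "beta",
                chi_ref_um2_per_s = "chi_ref", mu_per_h = "mu",
                D_um2_per_s = "d_c", c0_per_mm3 = "c0",
                r0_per_day = "r0")
  nums_map <- c(box_length_um = "box_length", dt_max_h = "dt_max",
                t_end_h = "t_end", seed = "seed", k_on = "k_on",
                k_off = "k_off", v_cap = "v_cap")
  bad <- setdiff(names(phys), names(phys_map))
  if (length(bad)) stop("unknown key in [physical]: ", bad[1])
  bad <- setdiff(names(nums), names(nums_map))
  if (length(bad)) stop("unknown key in [numerics]: ", bad[1])

  args <- list()
  preset <- phys$preset
  phys$preset <- NULL
  if (!is.null(preset)) {
    if (!identical(preset, "table1"))
      stop("unknown preset: ", preset)
  }
  for (k in names(phys)) args[[phys_map[[k]]]] <- phys[[k]]
  for (k in names(nums)) args[[nums_map[[k]]]] <- nums[[k]]

  p <- tryCatch(
    if (is.null(preset)) do.call(model_params, args)
    else do.call(table1_params, args),
    error = function(e) stop("invalid config ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  p
}

#' Write a CDA configuration file
#'
#' Serializes a parameter object to the flat two-table TOML layout read by
#' [read_cda_config()]; parse -> serialize -> parse is the identity.
#'
#' @param params a `cda_params` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cda_config <- function(params, path) {
  stopifnot(inherits(params, "cda_params"))
  u <- params_in_table_units(params)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    "[physical]",
    paste0("n_per_mm3 = ", fmt(u$n)),
    paste0("a_um = ", fmt(u$a)),
    paste0("alpha_per_h = ", fmt(u$alpha)),
    paste0("beta_per_s = ", fmt(u$beta)),
    paste0("chi_ref_um2_per_s = ", fmt(u$chi_ref)),
    paste0("mu_per_h = ", fmt(u$mu)),
    paste0("D_um2_per_s = ", fmt(u$d_c)),
    paste0("c0_per_mm3 = ", fmt(u$c0)),
    paste0("r0_per_day = ", fmt(u$r0)),
    "",
    "[numerics]",
    paste0("box_length_um = ", fmt(params$box_length)),
    paste0("dt_max_h = ", fmt(params$dt_max)),
    paste0("t_end_h = ", fmt(params$t_end)),
    paste0("seed = ", params$seed),
    paste0("k_on = ", fmt(params$k_on)),
    paste0("k_off = ", fmt(params$k_off)),
    paste0("v_cap = ", fmt(params$v_cap)))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal TOML reader for flat [table] / key = value files.
parse_flat_toml <- function(lines) {
  out <- list()
  tab <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      tab <- sub("^\\[\\s*([^]]*?)\\s*\\]$", "\\1", ln)
      if (is.null(out[[tab]])) out[[tab]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed TOML at line ", i, ": ", lines[[i]])
    key <- m[2]; raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      sub('^"(.*)"$', "\\1", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) stop("unparseable TOML value at line ", i, ": ", raw)
      v
    }
    if (is.null(tab)) out[[key]] <- val else out[[tab]][[key]] <- val
  }
  out
}
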