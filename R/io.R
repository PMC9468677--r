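#' Read and write profile curves as CSV
#'
#' Profiles are stored with columns `s`, `x`, `z`, `phi` and a leading
#' comment line recording the length unit.
#'
#' @param profile A `profile_curve`.
#' @param path File path.
#' @param unit Length unit recorded in the metadata comment.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a `profile_curve` tibble (observables
#'   recomputed by quadrature on read).
#' @export
write_profile_csv <- function(profile, path, unit = "um") {
  stopifnot(is.data.frame(profile))
  writeLines(sprintf("# tensiomag profile curve; lengths in %s", unit), path)
  readr::write_csv(as_tibble(profile)[c("s", "x", "z", "phi")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("s", "x", "z", "phi") %in% names(df))) {
    abort_input("profile CSV must have columns s, x, z, phi.")
  }
  structure(as_tibble(df), class = c("profile_curve", class(as_tibble(df))))
}

#' Read aggregate observables from CSV
#'
#' Expects unit-suffixed columns `h_um`, `w_um`, `v_um3` (plus any
#' identifier columns, which are kept).
#'
#' @param path CSV file path.
#' @return A tibble with columns `h`, `w`, `v` (um, um, um^3) and any
#'   identifier columns.
#' @export
read_observables_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("h_um", "w_um", "v_um3")
  if (!all(need %in% names(df))) {
    abort_input(sprintf("observables CSV must have columns %s.",
                        paste(need, collapse = ", ")))
  }
  df %>%
    dplyr::rename(h = "h_um", w = "w_um", v = "v_um3") %>%
    as_tibble()
}

#' @rdname read_observables_csv
#' @param data Tibble with columns `h`, `w`, `v` and identifiers.
#' @export
write_observables_csv <- function(data, path) {
  if (!all(c("h", "w", "v") %in% names(data))) {
    abort_input("`data` must have columns h, w, v.")
  }
  out <- data %>% dplyr::rename(h_um = "h", w_um = "w", v_um3 = "v")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read the magnetic calibration from a YAML config
#'
#' Strict parser: the file must provide `m_v_a_per_m` and
#' `grad_b_t_per_m` (units embedded in the key names), may provide
#' `b_mt`, and any unknown key is rejected.
#'
#' @param path YAML file path.
#' @return A [magnetic_context()].
#' @export
read_magnetic_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  allowed <- c("m_v_a_per_m", "grad_b_t_per_m", "b_mt")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    abort_input(sprintf("unknown config key(s): %s (allowed: %s)",
                        paste(unknown, collapse = ", "),
                        paste(allowed, collapse = ", ")))
  }
  for (k in c("m_v_a_per_m", "grad_b_t_per_m")) {
    if (is.null(cfg[[k]])) {
      abort_input(sprintf("config key `%s` is required.", k))
    }
  }
  magnetic_context(cfg$m_v_a_per_m, cfg$grad_b_t_per_m, cfg$b_mt)
}

#' Write a tension fit as JSON
#'
#' @param fit A `tension_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tension_json <- function(fit, path) {
  stopifnot(inherits(fit, "tension_fit"))
  g <- glance(fit)
  jsonlite::write_json(
    list(
      gamma_mn_per_m = g$gamma_mn_per_m,
      gamma_lower_bound_mn_per_m = g$gamma_lower_bound_mn_per_m,
      b_per_um = g$b_per_um,
      c_per_um2 = g$c_per_um2,
      residual = g$residual,
      converged = g$converged,
      flattened = g$flattened
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Read stacked force curves from CSV
#'
#' Expects columns `time_s`, `height_um`, `force_nn`, `segment` and an
#' optional `curve`/`condition` identifier pair.
#'
#' @param path CSV (or TSV) file path.
#' @return A tibble; single curves are validated with
#'   [as_force_curve()].
#' @export
read_force_curves_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  need <- c("time_s", "height_um", "force_nn", "segment")
  if (!all(need %in% names(df))) {
    abort_input(sprintf("force-curve CSV must have columns %s.",
                        paste(need, collapse = ", ")))
  }
  if (!"curve" %in% names(df)) as_force_curve(df) else as_tibble(df)
}
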