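#' Validate an AFM force-curve table
#'
#' A force curve is a tibble with columns `time_s`, `height_um`,
#' `force_nn` and `segment` (values `approach`, `dwell`, `retract`).
#' Segments must be contiguous and in acquisition order
#' approach -> dwell -> retract, and the retract segment non-empty.
#'
#' @param data A data frame with the columns above.
#' @return The validated tibble with class `force_curve`.
#' @export
as_force_curve <- function(data) {
  need <- c("time_s", "height_um", "force_nn", "segment")
  if (!all(need %in% names(data))) {
    abort_input(sprintf("force curve must have columns %s.",
                        paste(need, collapse = ", ")))
  }
  seg <- as.character(data$segment)
  if (!all(seg %in% c("approach", "dwell", "retract"))) {
    abort_input("`segment` values must be approach, dwell or retract.")
  }
  runs <- rle(seg)$values
  allowed <- c("approach", "dwell", "retract")
  if (anyDuplicated(runs) || !identical(runs, allowed[allowed %in% runs])) {
    abort_input("segments must be contiguous and ordered approach -> dwell -> retract.")
  }
  if (!"retract" %in% seg) abort_input("retract segment is empty.")
  out <- as_tibble(data)
  class(out) <- unique(c("force_curve", class(out)))
  out
}

#' Baseline-correct the retraction segment of a force curve
#'
#' Fits a straight line to the final `window_fraction` of the retract
#' segment -- far from contact, where the cantilever is free -- and
#' subtracts it from the whole retract force trace, removing constant
#' offset and slow drift.  Approach and dwell samples are left
#' untouched.
#'
#' @param curve A [as_force_curve()] table.
#' @param window_fraction Fraction of the retract tail used for the
#'   line fit (default 0.2).
#' @return The curve with the retract `force_nn` corrected; the fitted
#'   baseline coefficients are stored in attribute `baseline`.
#' @export
baseline_correct <- function(curve, window_fraction = 0.2) {
  curve <- as_force_curve(curve)
  idx <- which(curve$segment == "retract")
  if (length(idx) < 20L) {
    abort_input("retract segment too short for baseline correction (need >= 20 samples).")
  }
  n_tail <- max(2L, floor(length(idx) * window_fraction))
  tail_idx <- idx[(length(idx) - n_tail + 1L):length(idx)]
  fit <- lm(force_nn ~ time_s, data = curve[tail_idx, ])
  base <- coef(fit)[[1L]] + coef(fit)[[2L]] * curve$time_s[idx]
  curve$force_nn[idx] <- curve$force_nn[idx] - base
  attr(curve, "baseline") <- coef(fit)
  attr(curve, "baseline_corrected") <- TRUE
  curve
}

# light Savitzky-Golay smoothing of the retract trace so the minimum
# estimate is robust to sampling noise; window scales with the trace
default_sg_window <- function(n) {
  w <- max(5L, round(n / 20))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n %% 2L == 1L) n else n - 1L)
}

#' Detachment force of an AFM retraction curve
#'
#' Magnitude of the lowest point of the baseline-corrected retraction
#' trace, the standard proxy for cell-cell adhesion strength.  A
#' quadratic Savitzky-Golay filter is applied before taking the
#' minimum so the estimate reflects the curve rather than single noise
#' excursions; dips shallower than the noise floor (3x the standard
#' deviation of the corrected, smoothed tail) count as no detachment
#' and return 0.
#'
#' @param curve A [as_force_curve()] table; baseline correction is
#'   applied automatically unless already done.
#' @param window_fraction Tail fraction for baseline/noise estimation.
#' @param sg_window Savitzky-Golay window (odd number of samples);
#'   default scales with the retract length.  `0` disables smoothing.
#' @param noise_floor Override the noise floor (nN).
#' @return Detachment force in nN (positive magnitude, or 0).
#' @export
detachment_force <- function(curve, window_fraction = 0.2,
                             sg_window = NULL, noise_floor = NULL) {
  curve <- as_force_curve(curve)
  if (!isTRUE(attr(curve, "baseline_corrected"))) {
    curve <- baseline_correct(curve, window_fraction)
  }
  f <- curve$force_nn[curve$segment == "retract"]
  n <- length(f)
  # noise floor from the raw corrected tail, before smoothing
  n_tail <- max(2L, floor(n * window_fraction))
  if (is.null(noise_floor)) noise_floor <- 3 * sd(f[(n - n_tail + 1L):n])
  if (is.null(sg_window)) sg_window <- default_sg_window(n)
  if (sg_window >= 5L && n > sg_window) {
    f <- signal::sgolayfilt(f, p = 2, n = sg_window)
  }
  m <- min(f)
  if (m >= -noise_floor) 0 else abs(m)
}

#' Detachment force per curve for a batch of force curves
#'
#' @param data A tibble of stacked force curves with an identifier
#'   column `curve` (plus optional grouping columns such as
#'   `condition`) and the [as_force_curve()] columns.
#' @param ... Passed on to [detachment_force()].
#' @return A tibble with one row per curve: identifier columns and
#'   `detachment_nn`.
#' @export
detachment_force_each <- function(data, ...) {
  if (!"curve" %in% names(data)) {
    abort_input("`data` must have a `curve` identifier column.")
  }
  ids <- setdiff(names(data), c("time_s", "height_um", "force_nn", "segment"))
  data %>%
    group_by(across(dplyr::all_of(ids))) %>%
    dplyr::group_modify(function(d, key) {
      tibble(detachment_nn = detachment_force(d, ...))
    }) %>%
    ungroup()
}

#' Per-condition summary of detachment forces
#'
#' Mean, standard deviation and count of per-curve detachment forces,
#' the form in which adhesion panels are reported.
#'
#' @param data Output of [detachment_force_each()] with a `condition`
#'   column.
#' @return A tibble with `condition`, `mean_nn`, `sd_nn`, `n`.
#' @export
summarize_detachment <- function(data) {
  if (!all(c("condition", "detachment_nn") %in% names(data))) {
    abort_input("`data` must have columns condition and detachment_nn.")
  }
  data %>%
    group_by(.data$condition) %>%
    summarise(mean_nn = mean(.data$detachment_nn),
              sd_nn = sd(.data$detachment_nn), n = dplyr::n(),
              .groups = "drop")
}
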