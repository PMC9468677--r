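#' Wound area from a binary mask
#'
#' @param mask Matrix; nonzero pixels belong to the wound.
#' @param scale_um_per_px Pixel size (um/px); default 1 returns px^2.
#' @return Wound area (um^2, or px^2 at unit scale).
#' @export
wound_area <- function(mask, scale_um_per_px = 1) {
  if (!is.matrix(mask)) abort_input("`mask` must be a matrix.")
  if (scale_um_per_px <= 0) abort_input("`scale_um_per_px` must be > 0.")
  sum(mask != 0) * scale_um_per_px^2
}

#' Wound coverage over time
#'
#' Coverage is the fraction of the original scratched area closed by
#' migration at each timepoint: `coverage(t) = 1 - A(t)/A(0)`, clipped
#' to `[0, 1]`.  Respects existing dplyr grouping (e.g. by scratch or
#' condition); each group must contain its own `t = 0` reference.
#'
#' @param data A data frame with columns `time_h` and `area`
#'   (any consistent unit), optionally grouped.
#' @return The input tibble with a `coverage` column added.
#' @examples
#' wound_coverage(tibble::tibble(time_h = c(0, 24), area = c(100, 25)))
#' @export
wound_coverage <- function(data) {
  if (!all(c("time_h", "area") %in% names(data))) {
    abort_input("`data` must have columns time_h and area.")
  }
  if (any(data$area < 0)) abort_input("wound areas must be >= 0.")
  grouped <- dplyr::is_grouped_df(data)
  res <- data %>%
    dplyr::group_modify(function(d, key) {
      i0 <- which(d$time_h == 0)
      if (length(i0) == 0L) {
        abort_input("missing t = 0 reference timepoint in wound series.")
      }
      a0 <- mean(d$area[i0])
      if (a0 <= 0) abort_input("wound area at t = 0 must be > 0.")
      d$coverage <- pmin(pmax(1 - d$area / a0, 0), 1)
      d
    })
  if (!grouped) res <- ungroup(res)
  res
}

check_counts <- function(x, what) {
  if (length(x) == 0L || any(!is.finite(x)) || any(x < 0) ||
      any(abs(x - round(x)) > 1e-8)) {
    abort_input(sprintf("%s counts must be non-negative integers.", what))
  }
}

#' Transwell invasion index
#'
#' Ratio of the mean per-field invading-cell count of a test condition
#' to that of the control condition.  By definition the index of the
#' control against itself is exactly 1.
#'
#' @param test,control Vectors of per-field invading-cell counts
#'   (non-negative integers, fields pooled across replicates).
#' @return The invasion index (dimensionless).
#' @examples
#' invasion_index(c(65, 65, 65), c(10, 10, 10))  # 6.5
#' @export
invasion_index <- function(test, control) {
  check_counts(test, "test")
  check_counts(control, "control")
  m <- mean(control)
  if (m <= 0) abort_input("control mean count must be > 0.")
  mean(test) / m
}

#' Invasion indices of all conditions against a control
#'
#' Pools fields across replicates for the headline index and also
#' reports per-replicate indices (test replicate vs matching control
#' replicate) with their standard error of the mean, the form used
#' when plotting means +/- SEM over independent biological replicates.
#'
#' @param data A tidy table with columns `condition`, `replicate`,
#'   `field`, `count`.
#' @param control Name of the control condition (present in `data`).
#' @return A tibble with one row per condition: `index` (pooled),
#'   `index_mean` and `index_sem` (across replicates), `n_fields`,
#'   `n_replicates`.
#' @export
summarize_invasion <- function(data, control = "NT") {
  need <- c("condition", "replicate", "field", "count")
  if (!all(need %in% names(data))) {
    abort_input(sprintf("`data` must have columns %s.",
                        paste(need, collapse = ", ")))
  }
  if (!control %in% data$condition) {
    abort_input(sprintf("control condition '%s' not present in the data.", control))
  }
  ctrl <- data %>% filter(.data$condition == control)
  check_counts(ctrl$count, "control")
  ctrl_rep <- ctrl %>%
    group_by(.data$replicate) %>%
    summarise(ctrl_mean = mean(.data$count), .groups = "drop")

  data %>%
    group_by(.data$condition) %>%
    dplyr::group_modify(function(d, key) {
      check_counts(d$count, as.character(key$condition))
      per_rep <- d %>%
        group_by(.data$replicate) %>%
        summarise(test_mean = mean(.data$count), .groups = "drop") %>%
        dplyr::inner_join(ctrl_rep, by = "replicate") %>%
        mutate(index_rep = .data$test_mean / .data$ctrl_mean)
      tibble(
        index = mean(d$count) / mean(ctrl$count),
        index_mean = mean(per_rep$index_rep),
        index_sem = sd(per_rep$index_rep) / sqrt(nrow(per_rep)),
        n_fields = nrow(d),
        n_replicates = nrow(per_rep)
      )
    }) %>%
    ungroup()
}
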