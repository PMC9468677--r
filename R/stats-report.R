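#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Rank-sum comparison in the form used throughout the analysis:
#' the exact two-sided p-value when both samples are small
#' (`n1 + n2 <= 12`) and tie-free, otherwise the normal approximation
#' with tie and continuity corrections.  The returned row also carries
#' the notched-boxplot summary of each group ([notch_summary()]) and
#' the significance-star label ([star_label()]).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param mode `"auto"` (default), `"exact"` (error when ties make the
#'   exact distribution undefined) or `"approx"`.
#' @return A one-row tibble of class `group_comparison`: `u` (the U
#'   statistic for `x`), `p_value`, `n_x`, `n_y`, per-group `median`,
#'   `q1`, `q3`, `notch` (NA when n < 3), `stars`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    abort_input("both samples must be non-empty.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_input("samples must be finite.")
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
    auto = (n1 + n2) <= 12L && !ties,
    exact = if (ties) {
      abort_input("exact p-value undefined with ties; use mode = 'approx'.")
    } else TRUE,
    approx = FALSE
  )
  ranks <- rank(c(x, y))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1  # fully tied: no evidence either way
    method <- "degenerate (all values tied)"
  } else {
    ht <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE)
    )
    p <- ht$p.value
    method <- if (exact) "exact" else "normal approximation (tie + continuity corrected)"
  }
  ns <- function(v) {
    if (length(v) >= 3L) notch_summary(v)
    else tibble(n = length(v), median = median(v),
                q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
                notch = NA_real_)
  }
  sx <- ns(x); sy <- ns(y)
  out <- tibble(
    u = u, p_value = p, n_x = n1, n_y = n2,
    median_x = sx$median, q1_x = sx$q1, q3_x = sx$q3, notch_x = sx$notch,
    median_y = sy$median, q1_y = sy$q1, q3_y = sy$q3, notch_y = sy$notch,
    stars = star_label(p), method = method
  )
  class(out) <- unique(c("group_comparison", class(out)))
  out
}

#' Significance-star label for a p-value
#'
#' `*`, `**`, `***`, `****`, `*****` for p below 0.05, 0.01, 0.001,
#' 0.0001 and 0.00001 respectively; `ns` otherwise.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @return Character vector of labels.
#' @examples
#' star_label(c(0.04, 9e-6, 0.5))
#' @export
star_label <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_input("p-values must lie in (0, 1].")
  }
  cuts <- c(0.05, 0.01, 0.001, 0.0001, 0.00001)
  vapply(p, function(pi) {
    k <- sum(pi < cuts)
    if (k == 0L) "ns" else strrep("*", k)
  }, character(1))
}

#' Notched-boxplot summary of a sample
#'
#' Median and quartiles (linear-interpolation convention, R type 7)
#' plus the McGill notch half-width `1.57 * IQR / sqrt(n)`, the
#' approximate 95% confidence interval on the median used to draw
#' notched boxplots.
#'
#' @param x Numeric sample with at least 3 values.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `notch`.
#' @examples
#' notch_summary(1:9)
#' @export
notch_summary <- function(x) {
  if (length(x) < 3L) abort_input("notch summary needs n >= 3.")
  if (any(!is.finite(x))) abort_input("sample must be finite.")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble(
    n = length(x), median = q[2L], q1 = q[1L], q3 = q[3L],
    notch = 1.57 * (q[3L] - q[1L]) / sqrt(length(x))
  )
}

#' Compare every condition against a control
#'
#' Runs [mann_whitney()] of each non-control condition against the
#' control, mirroring the pairwise-versus-control reporting of assay
#' panels.  No multiple-testing correction is applied, matching that
#' reporting style.
#'
#' @param data A tidy data frame.
#' @param value Name of the numeric value column.
#' @param group Name of the condition column.
#' @param control Control condition label.
#' @param mode Passed to [mann_whitney()].
#' @return A tibble with one row per comparison (`condition` vs the
#'   control) and the [mann_whitney()] columns.
#' @export
compare_groups <- function(data, value, group = "condition",
                           control = "NT", mode = "auto") {
  if (!all(c(value, group) %in% names(data))) {
    abort_input("`value` and `group` must name columns of `data`.")
  }
  groups <- unique(data[[group]])
  if (!control %in% groups) {
    abort_input(sprintf("control condition '%s' not present.", control))
  }
  ctrl <- data[[value]][data[[group]] == control]
  ctrl <- ctrl[is.finite(ctrl)]
  purrr::map_dfr(setdiff(groups, control), function(g) {
    v <- data[[value]][data[[group]] == g]
    v <- v[is.finite(v)]
    cmp <- mann_whitney(v, ctrl, mode = mode)
    dplyr::bind_cols(tibble(condition = g, control = control), cmp)
  })
}
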