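#' Side-view image of an aggregate on the substrate
#'
#' Light container for a grayscale side-view image: a numeric matrix of
#' intensities (row 1 = top of the field of view) plus the pixel scale.
#' Intensities are normalized to `[0, 1]`; 8- or 16-bit integer data
#' are rescaled by their maximum representable value.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param scale_um_per_px Pixel size in micrometres per pixel, > 0.
#' @param orientation Which image side the substrate lies on; only
#'   `"bottom"` is supported (rotate the image upstream otherwise).
#' @return An object of class `side_view_image`.
#' @export
side_view_image <- function(pixels, scale_um_per_px,
                            orientation = "bottom") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_input("`pixels` must be a numeric matrix.")
  }
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0) {
    abort_input("`scale_um_per_px` must be a single finite value > 0.")
  }
  orientation <- match.arg(orientation, "bottom")
  mx <- max(pixels)
  if (mx > 1) {
    denom <- if (mx <= 255) 255 else 65535
    pixels <- pixels / denom
  }
  structure(
    list(pixels = pixels, scale_um_per_px = as.numeric(scale_um_per_px),
         orientation = orientation),
    class = "side_view_image"
  )
}

#' @export
print.side_view_image <- function(x, ...) {
  cat(sprintf("<side_view_image> %d x %d px, %g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px))
  invisible(x)
}

#' Read a side-view image from a TIFF or PNG file
#'
#' @param path Image file path.
#' @param scale_um_per_px Pixel size, um/px.
#' @return A [side_view_image()].
#' @export
read_side_view <- function(path, scale_um_per_px) {
  if (!file.exists(path)) abort_input(sprintf("image file not found: %s", path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1L, 2L), mean)
  # EBImage stores (x, y); transpose to (row, col) with row 1 on top
  side_view_image(t(dat), scale_um_per_px)
}

#' Segment the aggregate from a side-view image
#'
#' Global automatic (Otsu) threshold, polarity auto-detected from the
#' top image border (the background is above the aggregate), followed
#' by largest-connected-component selection and hole filling.
#'
#' @param img A [side_view_image()].
#' @param polarity `"auto"` (default), `"dark"` (object darker than
#'   background) or `"bright"`.
#' @return A logical matrix mask, `TRUE` on the aggregate.
#' @export
segment_aggregate <- function(img, polarity = c("auto", "dark", "bright")) {
  stopifnot(inherits(img, "side_view_image"))
  polarity <- match.arg(polarity)
  px <- img$pixels
  if (diff(range(px)) < 1e-6) {
    abort_input("segmentation failed: image has no contrast (blank image).")
  }
  thr <- EBImage::otsu(EBImage::Image(t(px)))
  if (polarity == "auto") {
    bg <- median(px[1L, ])  # top border row: background above the aggregate
    polarity <- if (bg > thr) "dark" else "bright"
  }
  mask <- if (polarity == "dark") px < thr else px > thr
  if (!any(mask)) {
    abort_input("segmentation failed: no foreground object after thresholding.")
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  mask <- t(EBImage::imageData(EBImage::fillHull(lab == keep))) > 0
  if (any(mask[, 1L]) || any(mask[, ncol(mask)])) {
    abort_input("segmentation failed: object touches the left/right image border.")
  }
  mask
}

#' Extract geometric observables and contour from a side-view image
#'
#' Per-row left/right edges of the segmented aggregate give the
#' contour; the observables follow pixel-count conventions inclusive of
#' both edge pixels: height `h` spans the top row to the substrate row
#' (the lowest populated row; the slide is below), width `w` is the
#' maximal per-row extent, and the volume sums per-row disks,
#' `V = sum pi r^2 * scale^3` with `r` the mean of the left and right
#' half-widths about the symmetry axis (the width-weighted mean of the
#' row midpoints).
#'
#' @param img A [side_view_image()].
#' @param ... Passed on to [segment_aggregate()].
#' @return A list with `observables` (one-row tibble `h`, `w`, `v`, in
#'   um and um^3), `contour` (tibble `row`, `left`, `right`, in px),
#'   `axis_px` (fractional column of the symmetry axis),
#'   `substrate_row`, and `asymmetry` (mean |left half-width - right
#'   half-width| / w, a QC metric).
#' @export
extract_geometry <- function(img, ...) {
  stopifnot(inherits(img, "side_view_image"))
  mask <- segment_aggregate(img, ...)
  sc <- img$scale_um_per_px
  rows <- which(rowSums(mask) > 0)
  contour <- tibble(
    row = rows,
    left = vapply(rows, function(r) min(which(mask[r, ])), integer(1)),
    right = vapply(rows, function(r) max(which(mask[r, ])), integer(1))
  )
  widths <- contour$right - contour$left + 1L
  mid <- (contour$left + contour$right) / 2
  axis <- sum(mid * widths) / sum(widths)
  top_row <- min(rows)
  substrate_row <- max(rows)

  h <- (substrate_row - top_row + 1L) * sc
  w <- max(widths) * sc
  r_px <- widths / 2
  v <- sum(pi * r_px^2) * sc^3
  hw_left <- axis - contour$left + 0.5
  hw_right <- contour$right - axis + 0.5
  asym <- mean(abs(hw_left - hw_right)) / (max(widths))

  list(
    observables = tibble(h = h, w = w, v = v),
    contour = contour,
    axis_px = axis,
    substrate_row = substrate_row,
    asymmetry = asym
  )
}
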