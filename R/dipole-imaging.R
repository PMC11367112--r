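# shift a matrix by (dr, dc) with edge replication
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

# binary dilation with a (2r+1) square structuring element
.dilate <- function(mask, radius) {
  if (radius < 1) return(mask)
  out <- mask
  for (i in seq_len(radius)) {
    out <- out | .shift_mat(out, 1, 0) | .shift_mat(out, -1, 0) |
      .shift_mat(out, 0, 1) | .shift_mat(out, 0, -1) |
      .shift_mat(out, 1, 1) | .shift_mat(out, 1, -1) |
      .shift_mat(out, -1, 1) | .shift_mat(out, -1, -1)
  }
  out
}

# separable 2-D Gaussian blur (sigma in px, reflective edges)
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  hw <- max(3L, ceiling(3 * sigma))
  k <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    pad <- c(rev(x[2:(hw + 1)]), x, rev(x[(n - hw):(n - 1)]))
    as.numeric(stats::filter(pad, k, sides = 2))[(hw + 1):(hw + n)]
  }
  t(apply(t(apply(img, 2, smooth1)), 2, smooth1))
}

#' Sobel gradient magnitude
#'
#' @param img Intensity matrix.
#' @return Matrix of the same shape with the Sobel gradient magnitude.
#' @export
sobel_magnitude <- function(img) {
  gx <- (.shift_mat(img, -1, -1) + 2 * .shift_mat(img, 0, -1) +
           .shift_mat(img, 1, -1)) -
    (.shift_mat(img, -1, 1) + 2 * .shift_mat(img, 0, 1) +
       .shift_mat(img, 1, 1))
  gy <- (.shift_mat(img, -1, -1) + 2 * .shift_mat(img, -1, 0) +
           .shift_mat(img, -1, 1)) -
    (.shift_mat(img, 1, -1) + 2 * .shift_mat(img, 1, 0) +
       .shift_mat(img, 1, 1))
  sqrt(gx^2 + gy^2)
}

#' Seeded watershed segmentation of a cell image
#'
#' Marker-controlled watershed on the Sobel gradient magnitude of the
#' intensity image: regions are flooded from the seed points in order of
#' increasing gradient, so region boundaries settle on the gradient ridges at
#' the bright membrane rings. A membrane ring only a few pixels wide produces
#' two parallel edge ridges with a near-zero gradient channel along its
#' midline; the gradient image is therefore Gaussian-smoothed so the ridges
#' merge and the watershed line settles on the membrane midline instead of
#' hugging one edge. Every cell seed yields one label; pixels reached from
#' background seeds are labeled 0. The flooding order is fully deterministic.
#'
#' @param intensity Intensity matrix (typically the summed two-channel
#'   image).
#' @param seeds Data frame with columns `row`, `col` (1-based) and `kind`
#'   (`"cell"` or `"background"`); at least one of each is required.
#' @param gradient_smooth_sigma SD (px) of the Gaussian applied to the
#'   gradient magnitude; 0 disables smoothing.
#' @return Integer label matrix (0 = background; cell labels numbered in seed
#'   order). Emits a warning on essentially gradient-free images, where the
#'   partition is determined by flooding order alone.
#' @export
segment_cells_watershed <- function(intensity, seeds,
                                    gradient_smooth_sigma = 1.5) {
  stopifnot(is.matrix(intensity),
            all(c("row", "col", "kind") %in% names(seeds)))
  cell <- seeds[seeds$kind == "cell", , drop = FALSE]
  bg <- seeds[seeds$kind == "background", , drop = FALSE]
  if (nrow(cell) < 1 || nrow(bg) < 1)
    stop("need at least one cell seed and one background seed")
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (any(seeds$row < 1 | seeds$row > nr | seeds$col < 1 | seeds$col > nc))
    stop("seed outside image bounds")
  grad <- .gauss_blur(sobel_magnitude(intensity), gradient_smooth_sigma)
  if (max(grad) - min(grad) < 1e-8 * max(1, max(abs(intensity))))
    warning("image has essentially no gradient; segmentation is arbitrary")
  markers <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(cell))) markers[cell$row[i], cell$col[i]] <- i
  bg_label <- nrow(cell) + 1L
  for (i in seq_len(nrow(bg))) markers[bg$row[i], bg$col[i]] <- bg_label
  lab <- seeded_watershed_cpp(grad, markers)
  lab[lab == bg_label] <- 0L
  lab
}

#' Membrane-band mask from a label image
#'
#' Extracts a band of the given total width centered on each label's
#' boundary: the boundary pixels (label pixels adjacent to a different label
#' or to background) dilated by `(band_width_px - 1) %/% 2`, so the band
#' covers both the inner and the outer side of the boundary.
#'
#' @param labels Integer label matrix (0 = background).
#' @param band_width_px Total band width in pixels (>= 1).
#' @return Logical mask matrix.
#' @export
extract_membrane_mask <- function(labels, band_width_px = 3) {
  if (band_width_px < 1) stop("band_width_px must be >= 1")
  if (!any(labels > 0)) stop("label image contains no cells")
  diff_n <- (labels != .shift_mat(labels, 1, 0)) |
    (labels != .shift_mat(labels, -1, 0)) |
    (labels != .shift_mat(labels, 0, 1)) |
    (labels != .shift_mat(labels, 0, -1))
  boundary <- labels > 0 & diff_n
  .dilate(boundary, (band_width_px - 1) %/% 2)
}

#' Background level of one channel
#'
#' Median intensity over background pixels (label 0), excluding a guard band
#' around the cells; the median is robust to residual cell bleed-through.
#'
#' @param channel Intensity matrix.
#' @param labels Integer label matrix.
#' @param guard_px Guard band width around cells (px).
#' @param min_pixels Minimum number of qualifying background pixels.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(channel, labels, guard_px = 2,
                                min_pixels = 100) {
  bg <- labels == 0 & !.dilate(labels > 0, guard_px)
  if (sum(bg) < min_pixels)
    stop("fewer than ", min_pixels, " background pixels available")
  median(channel[bg])
}

#' Segment a two-channel ratio image
#'
#' Convenience wrapper running the full segmentation stage on a
#' `ratio_image_set`: seeded watershed on the summed-channel image, membrane
#' band extraction, and per-channel background estimation.
#'
#' @param image_set A `ratio_image_set` (see [simulate_ratio_images()] or
#'   [read_ratio_image_set()]).
#' @param band_width_px Membrane band width (px).
#' @return List with `labels`, `membrane_mask`, `background_blue`,
#'   `background_red`.
#' @export
segment_ratio_image <- function(image_set, band_width_px = 3) {
  labels <- segment_cells_watershed(
    image_set$channel_blue + image_set$channel_red, image_set$seeds)
  list(labels = labels,
       membrane_mask = extract_membrane_mask(labels, band_width_px),
       background_blue = estimate_background(image_set$channel_blue, labels),
       background_red = estimate_background(image_set$channel_red, labels))
}

#' Membrane excitation ratio of one image
#'
#' Computes the per-pixel background-subtracted excitation ratio
#' `(blue - bg_blue) / (red - bg_red)` over the membrane pixels and its mean.
#' Pixels whose red-channel signal after background subtraction falls below
#' `guard_frac` of the membrane's median red signal are excluded from the
#' ratio (they carry no reliable denominator) and counted.
#'
#' @param image_set A `ratio_image_set`.
#' @param segmentation Result of [segment_ratio_image()].
#' @param guard_frac Denominator guard as a fraction of the membrane median
#'   red signal.
#' @return An object of class `rexc_result` with `ratio_values`,
#'   `mean_ratio`, `n_membrane_pixels` (qualifying pixels), `n_excluded`.
#' @export
compute_excitation_ratio <- function(image_set, segmentation,
                                     guard_frac = 0.05) {
  mask <- segmentation$membrane_mask
  if (!any(mask)) stop("membrane mask is empty")
  blue <- image_set$channel_blue[mask] - segmentation$background_blue
  red <- image_set$channel_red[mask] - segmentation$background_red
  thresh <- guard_frac * median(red)
  ok <- red > pmax(thresh, 0)
  if (!any(ok)) stop("all membrane pixels fail the denominator guard")
  ratio <- blue[ok] / red[ok]
  structure(list(ratio_values = ratio, mean_ratio = mean(ratio),
                 n_membrane_pixels = sum(ok), n_excluded = sum(!ok)),
            class = "rexc_result")
}

#' @export
print.rexc_result <- function(x, ...) {
  cat(sprintf("Excitation ratio: mean %.4f over %d membrane pixels (%d excluded)\n",
              x$mean_ratio, x$n_membrane_pixels, x$n_excluded))
  invisible(x)
}

#' Pixelwise histogram of the excitation ratio
#'
#' @param rexc An `rexc_result`.
#' @param bin_edges Increasing bin edges; bins are left-closed, the last bin
#'   closed on both sides.
#' @return List with `bin_edges`, `counts` and `n_out_of_range` (values
#'   outside the edge range, not counted in any bin).
#' @export
ratio_histogram <- function(rexc, bin_edges) {
  x <- rexc$ratio_values
  if (!length(x)) stop("no membrane pixels to histogram")
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  list(bin_edges = bin_edges, counts = counts,
       n_out_of_range = sum(!inside))
}

#' Full dipole-imaging pipeline for one image pair
#'
#' @param image_set A `ratio_image_set`.
#' @param band_width_px Membrane band width (px).
#' @param guard_frac Denominator guard fraction.
#' @return List with `segmentation` and `rexc`.
#' @export
run_dipole_image <- function(image_set, band_width_px = 3,
                             guard_frac = 0.05) {
  seg <- segment_ratio_image(image_set, band_width_px)
  list(segmentation = seg,
       rexc = compute_excitation_ratio(image_set, seg, guard_frac))
}
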