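#' Simulate a two-channel ratiometric cell image pair
#'
#' Emulates a confocal midplane field of view of membrane-stained cells:
#' circular cells with a bright membrane ring (3 px wide by default) and a
#' dim interior are placed without overlap on a dark background. Both
#' excitation channels share the same geometry; after subtracting the known
#' background, the per-pixel channel-blue / channel-red ratio equals
#' `ratio_true` wherever the dye is present. One interior seed point per cell
#' and a set of background seeds are emitted alongside ground-truth label and
#' membrane masks.
#'
#' @param ratio_true True membrane excitation ratio (blue/red, > 0).
#' @param n_cells Number of cells (>= 1; 0 allowed for degenerate fixtures).
#' @param image_size `c(rows, cols)` of the canvas.
#' @param membrane_width_px Width of the membrane ring (px).
#' @param background_level Additive background in both channels (counts).
#' @param noise_sd Additive Gaussian noise SD in both channels (counts).
#' @param seed Optional integer seed.
#' @param radius_range Cell radius range (px), sampled uniformly.
#' @param membrane_intensity Red-channel membrane intensity above background
#'   (counts); the blue channel is `ratio_true` times this.
#' @param interior_intensity Red-channel interior intensity above background.
#' @param n_background_seeds Number of background seed points.
#' @param max_tries Placement attempts before giving up.
#' @return An object of class `ratio_image_set` with elements `channel_blue`,
#'   `channel_red` (matrices), `seeds` (data frame `row`, `col`, `kind`;
#'    1-based), `labels_true`, `membrane_true`, plus the generating parameters.
#' @export
simulate_ratio_images <- function(ratio_true, n_cells = 35,
                                  image_size = c(512, 512),
                                  membrane_width_px = 3,
                                  background_level = 50, noise_sd = 3,
                                  seed = NULL, radius_range = c(15, 30),
                                  membrane_intensity = 300,
                                  interior_intensity = 10,
                                  n_background_seeds = 4,
                                  max_tries = 20000) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_ratio_images(
    ratio_true, n_cells, image_size, membrane_width_px, background_level,
    noise_sd, NULL, radius_range, membrane_intensity, interior_intensity,
    n_background_seeds, max_tries)))
  stopifnot(ratio_true > 0, n_cells >= 0, membrane_width_px >= 1,
            background_level >= 0, noise_sd >= 0)
  nr <- image_size[1]; nc <- image_size[2]
  rmax <- radius_range[2]
  if (n_cells > 0 && (nr < 2 * rmax + 8 || nc < 2 * rmax + 8))
    stop("image_size too small for the requested cell radii")

  centers <- matrix(numeric(0), ncol = 3)  # row, col, radius
  tries <- 0
  while (nrow(centers) < n_cells) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n_cells, " non-overlapping cells in image_size")
    r <- runif(1, radius_range[1], radius_range[2])
    cy <- runif(1, r + 3, nr - r - 2)
    cx <- runif(1, r + 3, nc - r - 2)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
            centers[, 3] + r + 6))
      centers <- rbind(centers, c(cy, cx, r))
  }

  red <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  membrane <- matrix(FALSE, nr, nc)
  hw <- membrane_width_px / 2
  if (n_cells > 0) for (i in seq_len(n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- centers[i, 3]
    rows <- max(1, floor(cy - r - hw - 1)):min(nr, ceiling(cy + r + hw + 1))
    cols <- max(1, floor(cx - r - hw - 1)):min(nc, ceiling(cx + r + hw + 1))
    d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
    ring <- d >= r - hw & d < r + hw
    inside <- d < r - hw
    red[rows, cols][ring] <- membrane_intensity
    red[rows, cols][inside] <- interior_intensity
    labels[rows, cols][ring | inside] <- i
    membrane[rows, cols][ring] <- TRUE
  }
  blue <- ratio_true * red
  red <- red + background_level
  blue <- blue + background_level
  if (noise_sd > 0) {
    red <- red + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    blue <- blue + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  red[red < 0] <- 0; blue[blue < 0] <- 0

  seeds <- data.frame(row = integer(0), col = integer(0), kind = character(0))
  if (n_cells > 0)
    seeds <- data.frame(row = as.integer(round(centers[, 1])),
                        col = as.integer(round(centers[, 2])),
                        kind = "cell")
  bg <- bg_seed_candidates(nr, nc, centers, n_background_seeds)
  seeds <- rbind(seeds, bg)

  structure(list(channel_blue = blue, channel_red = red, seeds = seeds,
                 labels_true = labels, membrane_true = membrane,
                 ratio_true = ratio_true, background_level = background_level,
                 noise_sd = noise_sd, membrane_width_px = membrane_width_px,
                 centers = centers),
            class = "ratio_image_set")
}

# pick background seed points on a coarse grid, far from every cell
bg_seed_candidates <- function(nr, nc, centers, n_seeds) {
  cand_r <- seq(10, nr - 10, by = 25)
  cand_c <- seq(10, nc - 10, by = 25)
  out <- data.frame(row = integer(0), col = integer(0), kind = character(0))
  for (r in cand_r) {
    for (cc in cand_c) {
      if (nrow(out) >= n_seeds) return(out)
      ok <- nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - r)^2 + (centers[, 2] - cc)^2) >
              centers[, 3] + 8)
      if (ok) out <- rbind(out, data.frame(row = as.integer(r),
                                           col = as.integer(cc),
                                           kind = "background"))
    }
  }
  if (nrow(out) == 0) stop("could not place any background seed")
  out
}

#' @export
print.ratio_image_set <- function(x, ...) {
  cat(sprintf("Ratio image set: %dx%d px, %d cells, true ratio %.3f\n",
              nrow(x$channel_red), ncol(x$channel_red),
              max(x$labels_true), x$ratio_true))
  invisible(x)
}
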