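#' Instrument G-factor
#'
#' `G = Ihv / Ihh`: the detection-system sensitivity ratio for vertically vs
#' horizontally polarized emission, measured under horizontally polarized
#' excitation.
#'
#' @param ihv,ihh Vertical and horizontal emission intensities under
#'   horizontal excitation (a.u.); vectorized.
#' @return G-factor (dimensionless).
#' @export
g_factor <- function(ihv, ihh) {
  if (any(ihh <= 0)) stop("Ihh must be positive")
  ihv / ihh
}

#' Fluorescence anisotropy (L-format)
#'
#' `r = (Ivv - G Ivh) / (Ivv + 2 G Ivh)`. For positive intensities and
#' G > 0 the value lies in (-0.5, 1].
#'
#' @param ivv,ivh Vertical and horizontal emission intensities under vertical
#'   excitation (a.u.); vectorized.
#' @param g Instrument G-factor (> 0).
#' @return Anisotropy (dimensionless).
#' @export
anisotropy <- function(ivv, ivh, g) {
  if (any(g <= 0)) stop("G-factor must be positive")
  denom <- ivv + 2 * g * ivh
  if (any(denom <= 0)) stop("total intensity Ivv + 2 G Ivh must be positive")
  (ivv - g * ivh) / denom
}

#' Generalized polarization
#'
#' `GP = (I_blue - I_red) / (I_blue + I_red)`, in [-1, 1].
#'
#' @param i_blue,i_red Blue-edge and red-edge emission intensities (a.u.);
#'   vectorized.
#' @return Generalized polarization (dimensionless).
#' @export
generalized_polarization <- function(i_blue, i_red) {
  total <- i_blue + i_red
  if (any(total <= 0)) stop("total intensity must be positive")
  (i_blue - i_red) / total
}

#' Anisotropy of a table of polarized quadruples
#'
#' @param quads Data frame with columns `ivv`, `ivh`, `ihv`, `ihh` (one row
#'   per sample).
#' @param g_mode `"per_sample"`: each row uses its own `Ihv/Ihh`;
#'   `"session"`: one G-factor (the mean of `Ihv/Ihh` over the set) is applied
#'   to every sample, treating the quadruple set as one instrument session.
#' @return The input with `g` and `r` columns added.
#' @export
anisotropy_from_quadruples <- function(quads,
                                       g_mode = c("per_sample", "session")) {
  g_mode <- match.arg(g_mode)
  stopifnot(all(c("ivv", "ivh", "ihv", "ihh") %in% names(quads)))
  g <- g_factor(quads$ihv, quads$ihh)
  if (g_mode == "session") g <- rep(mean(g), nrow(quads))
  quads$g <- g
  quads$r <- anisotropy(quads$ivv, quads$ivh, g)
  quads
}

#' Generalized polarization of a table of emission pairs
#'
#' @param pairs Data frame with columns `i_blue`, `i_red`.
#' @return The input with a `gp` column added.
#' @export
gp_from_pairs <- function(pairs) {
  stopifnot(all(c("i_blue", "i_red") %in% names(pairs)))
  pairs$gp <- generalized_polarization(pairs$i_blue, pairs$i_red)
  pairs
}

#' Per-group mean and SEM of probe measurements
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length.
#' @return Data frame with `group`, `n`, `mean`, `sem` (`SD / sqrt(n)`).
#' @export
batch_probe_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  labs <- unique(groups)
  out <- lapply(labs, function(g) {
    x <- values[groups == g]
    if (length(x) < 2) stop("group '", g, "' has fewer than 2 samples")
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = sd(x) / sqrt(length(x)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
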