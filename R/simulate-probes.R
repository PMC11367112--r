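#' Simulate polarized-intensity quadruples
#'
#' Inverts the L-format anisotropy relations analytically: the quadruple
#' (Ivv, Ivh, Ihv, Ihh) is built so that `Ihv / Ihh = g_true` and
#' `Ivv / (g_true * Ivh) = (1 + 2 r) / (1 - r)`, i.e. at zero noise the
#' anisotropy and G-factor computations return `r_true` and `g_true` exactly.
#' Multiplicative Gaussian noise is applied to each intensity independently.
#'
#' @param r_true Target anisotropy, in (-0.5, 1).
#' @param g_true Target instrument G-factor (> 0).
#' @param total_intensity Approximate summed intensity of a quadruple (a.u.).
#' @param noise_sd Multiplicative noise SD (fraction of each intensity).
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Data frame with columns `sample_id`, `ivv`, `ivh`, `ihv`, `ihh`.
#' @export
simulate_polarized_intensities <- function(r_true, g_true = 1.1,
                                           total_intensity = 4e5,
                                           noise_sd = 0.005, n = 9,
                                           seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_polarized_intensities(
    r_true, g_true, total_intensity, noise_sd, n)))
  if (r_true <= -0.5 || r_true >= 1) stop("r_true must lie in (-0.5, 1)")
  stopifnot(g_true > 0, total_intensity > 0, noise_sd >= 0, n >= 1)
  base <- total_intensity / 4
  ivh <- base
  ivv <- g_true * ivh * (1 + 2 * r_true) / (1 - r_true)
  ihh <- base
  ihv <- g_true * ihh
  out <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                    ivv = rep(ivv, n), ivh = rep(ivh, n),
                    ihv = rep(ihv, n), ihh = rep(ihh, n))
  if (noise_sd > 0)
    for (col in c("ivv", "ivh", "ihv", "ihh"))
      out[[col]] <- pmax(out[[col]] * (1 + rnorm(n, 0, noise_sd)),
                         .Machine$double.eps)
  out
}

#' Simulate Laurdan-type emission pairs
#'
#' Analytic inversion of the generalized-polarization formula:
#' `I_blue / I_red = (1 + gp) / (1 - gp)`, so at zero noise the GP computation
#' round-trips to `gp_true` exactly.
#'
#' @param gp_true Target generalized polarization, in (-1, 1).
#' @param total_intensity Summed intensity `I_blue + I_red` (a.u.).
#' @param noise_sd Multiplicative noise SD (fraction of each intensity).
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Data frame with columns `sample_id`, `i_blue`, `i_red`.
#' @export
simulate_gp_intensities <- function(gp_true, total_intensity = 2e5,
                                    noise_sd = 0.01, n = 9, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_gp_intensities(
    gp_true, total_intensity, noise_sd, n)))
  if (abs(gp_true) >= 1) stop("gp_true must lie strictly inside (-1, 1)")
  stopifnot(total_intensity > 0, noise_sd >= 0, n >= 1)
  i_blue <- total_intensity / 2 * (1 + gp_true)
  i_red <- total_intensity / 2 * (1 - gp_true)
  out <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                    i_blue = rep(i_blue, n), i_red = rep(i_red, n))
  if (noise_sd > 0)
    for (col in c("i_blue", "i_red"))
      out[[col]] <- pmax(out[[col]] * (1 + rnorm(n, 0, noise_sd)),
                         .Machine$double.eps)
  out
}
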