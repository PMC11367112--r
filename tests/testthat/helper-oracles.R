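# Independent oracles used to cross-check the package implementations.
# Each is written from the closed forms directly, avoiding the package's
# own code paths.

# GHK-rectification x Boltzmann current, via expm1/plogis (undefined at v = 0)
oracle_ghk <- function(v, gmax, erev, v_half, k) {
  v * gmax * (-expm1(-(v - erev) / 25)) / (-expm1(-v / 25)) *
    stats::plogis((v - v_half) / k)
}

# one-way ANOVA F by explicit sums of squares
oracle_anova_f <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  labs <- unique(groups)
  ss_b <- sum(vapply(labs, function(g) {
    x <- values[groups == g]
    length(x) * (mean(x) - gm)^2
  }, numeric(1)))
  ss_w <- sum(vapply(labs, function(g) {
    x <- values[groups == g]
    sum((x - mean(x))^2)
  }, numeric(1)))
  df_b <- length(labs) - 1
  df_w <- length(values) - length(labs)
  (ss_b / df_b) / (ss_w / df_w)
}

# unadjusted two-sample p from the pooled (all-groups) residual variance,
# the building block Tukey's HSD adjusts
oracle_pooled_t_p <- function(values, groups, g1, g2) {
  groups <- as.character(groups)
  labs <- unique(groups)
  ss_w <- sum(vapply(labs, function(g) {
    x <- values[groups == g]
    sum((x - mean(x))^2)
  }, numeric(1)))
  df_w <- length(values) - length(labs)
  s2 <- ss_w / df_w
  x1 <- values[groups == g1]; x2 <- values[groups == g2]
  tstat <- (mean(x1) - mean(x2)) / sqrt(s2 * (1 / length(x1) + 1 / length(x2)))
  2 * stats::pt(-abs(tstat), df_w)
}

# amplitude of the `freq` component of a periodic trace, via FFT
oracle_sine_amplitude <- function(x, freq, rate) {
  n <- length(x)
  bin <- round(freq * n / rate) + 1
  2 * Mod(stats::fft(x))[bin] / n
}

# flood fill from seeds constrained to pixels below a gradient threshold
# (plain BFS; no priority ordering)
oracle_floodfill <- function(grad, seeds, thresh) {
  nr <- nrow(grad); nc <- ncol(grad)
  lab <- matrix(0L, nr, nc)
  for (s in seq_len(nrow(seeds))) {
    queue <- list(c(seeds$row[s], seeds$col[s]))
    id <- seeds$label[s]
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- p[1]; cc <- p[2]
      if (r < 1 || r > nr || cc < 1 || cc > nc) next
      if (lab[r, cc] != 0L || grad[r, cc] >= thresh) next
      lab[r, cc] <- id
      queue <- c(queue, list(c(r - 1, cc), c(r + 1, cc),
                             c(r, cc - 1), c(r, cc + 1)))
    }
  }
  lab
}

# multi-start nonlinear LS for the GHK x Boltzmann fit: best of `n_starts`
# random bounded starts (independent of the package's grid initialization)
oracle_multistart_iv <- function(v, i, n_starts = 10) {
  best <- NULL; best_sse <- Inf
  for (s in seq_len(n_starts)) {
    st <- list(gmax = stats::runif(1, 0.01, 2),
               erev = stats::runif(1, -110, -50),
               v_half = stats::runif(1, -70, 10),
               k = stats::runif(1, 2, 30))
    fit <- tryCatch(
      minpack.lm::nlsLM(i ~ eval_ghk_boltzmann(v, gmax, erev, v_half, k),
                        data = data.frame(v = v, i = i), start = st,
                        lower = c(1e-9, -120, -100, 1),
                        upper = c(Inf, -40, 50, 60),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- coef(fit) }
  }
  list(coef = best, sse = best_sse)
}

# small fast protocol for tests that do not need the full-length sweeps
short_protocol <- function() {
  voltage_protocol(pulse_duration = 100, pre_pulse_duration = 60,
                   post_pulse_duration = 20, sample_rate = 4000)
}
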