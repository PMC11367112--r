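#' One-way fixed-effects ANOVA
#'
#' Classical between-group F test. The degenerate case of zero variance
#' everywhere with equal group means is reported as `F = 0`, `p = 1`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (>= 2 groups, each with n >= 2).
#' @return List with `f`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) {
    gm <- tapply(values, groups, mean)
    if (max(gm) - min(gm) < 1e-12) { f <- 0; p <- 1 }
    else { f <- Inf; p <- 0 }
  }
  list(f = f, p = p, df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons from the studentized range distribution
#' (Tukey-Kramer adjustment for unequal group sizes), run after a one-way
#' ANOVA. Mirroring the sequential procedure, the pairwise table is always
#' reported but marked `interpreted = FALSE` when the ANOVA is not
#' significant at `alpha`. p values below 1e-12 are floored and labeled
#' `"<1e-12"`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level.
#' @return An object of class `group_comparison`: list with `summary`
#'   (per-group n / mean / SEM), `anova` (see [anova_oneway()]), `pairwise`
#'   (data frame with `pair`, `diff`, `p`, `p_label`, `significant`) and
#'   `interpreted`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  an <- anova_oneway(values, as.character(groups))
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  p <- pmax(tk[, "p adj"], 1e-12)
  pairwise <- data.frame(
    pair = rownames(tk), diff = tk[, "diff"], p = p,
    p_label = ifelse(tk[, "p adj"] < 1e-12, "<1e-12",
                     formatC(p, format = "g", digits = 4)),
    significant = p < alpha, row.names = NULL)
  structure(list(summary = batch_probe_summary(values, as.character(groups)),
                 anova = an, pairwise = pairwise,
                 alpha = alpha, interpreted = an$p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("ANOVA F = %.4g, p = %.3g%s\n", x$anova$f, x$anova$p,
              if (x$interpreted) "" else " (pairwise tests not interpreted)"))
  print(x$summary, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Assemble the study report
#'
#' Builds group comparisons (mean +/- SEM, ANOVA, Tukey HSD) for every
#' parameter table supplied: the gating cohort table (F-V and G-V midpoints
#' and slopes, relative amplitudes), the membrane-probe summaries and the
#' imaging ratios.
#'
#' @param cohort_cells Optional cohort cell table ([analyze_cohort()]
#'   `$cells`, optionally with `relative_amplitude` from
#'   [relative_amplitudes()]).
#' @param probe_values Optional data frame with columns `value`, `group`,
#'   `assay` (e.g. "anisotropy", "gp").
#' @param dipole_values Optional data frame with columns `mean_ratio`,
#'   `group` (one row per image).
#' @param alpha Significance level.
#' @return Named list of `group_comparison` objects.
#' @export
build_report <- function(cohort_cells = NULL, probe_values = NULL,
                         dipole_values = NULL, alpha = 0.05) {
  report <- list()
  compare <- function(vals, grp) {
    if (length(unique(grp)) >= 2) tukey_hsd(vals, grp, alpha)
    else list(summary = batch_probe_summary(vals, grp), anova = NULL,
              pairwise = NULL, interpreted = FALSE)
  }
  if (!is.null(cohort_cells)) {
    for (col in c("v_half_f", "k_f", "v_half_g", "k_g", "relative_amplitude"))
      if (col %in% names(cohort_cells) && !all(is.na(cohort_cells[[col]])))
        report[[col]] <- compare(cohort_cells[[col]], cohort_cells$treatment)
  }
  if (!is.null(probe_values)) {
    stopifnot(all(c("value", "group", "assay") %in% names(probe_values)))
    for (assay in unique(probe_values$assay)) {
      sub <- probe_values[probe_values$assay == assay, ]
      report[[assay]] <- compare(sub$value, sub$group)
    }
  }
  if (!is.null(dipole_values)) {
    stopifnot(all(c("mean_ratio", "group") %in% names(dipole_values)))
    report$rexc <- compare(dipole_values$mean_ratio, dipole_values$group)
  }
  if (!length(report)) stop("no input tables supplied")
  report
}

#' Write a report bundle to disk
#'
#' One tab-delimited summary and one pairwise table per compared parameter,
#' plus a machine-readable JSON bundle.
#'
#' @param report Result of [build_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list()
  for (nm in names(report)) {
    cmp <- report[[nm]]
    write.table(cmp$summary, file.path(dir, paste0(nm, "_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cmp$pairwise))
      write.table(cmp$pairwise, file.path(dir, paste0(nm, "_pairwise.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    js[[nm]] <- list(summary = cmp$summary, anova = cmp$anova,
                     pairwise = cmp$pairwise,
                     interpreted = cmp$interpreted)
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
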