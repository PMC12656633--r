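#' Percent change of a treated group relative to its fresh control
#'
#' `100 * (treated_mean - control_mean) / control_mean`; negative values
#' are reductions. Computed on unrounded inputs; rounding to 2 decimals is
#' a presentation choice (see [reduction_table()]).
#'
#' @param control_mean Mean of the fresh control group (> 0).
#' @param treated_mean Mean of the treated group.
#' @return Percent change (scalar, unrounded).
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("control mean must be positive", call. = FALSE)
  100 * (treated_mean - control_mean) / control_mean
}

#' One-way ANOVA from group summary statistics
#'
#' Recovers the one-factor ANOVA decomposition from group means, standard
#' deviations and sizes alone (no raw replicates needed):
#' `SSB = sum(n_i * (m_i - grand_mean)^2)` with the size-weighted grand
#' mean, `SSW = sum((n_i - 1) * s_i^2)`, `F = (SSB/df_b) / (SSW/df_w)`,
#' and the effect size `eta^2 = SSB / (SSB + SSW)` — identical to the
#' R-squared of the one-factor linear model, the figure SPSS reports for a
#' univariate analysis.
#'
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group standard deviations (>= 0).
#' @param ns Integer vector of group sizes (each >= 2), recycled if scalar.
#' @param labels Optional group labels.
#' @return Object of class `anova_summary`: `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `F`, `p_value`, `eta_squared`.
#' @export
anova_from_summaries <- function(means, sds, ns, labels = NULL) {
  means <- as.numeric(means); sds <- as.numeric(sds)
  g <- length(means)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(sds) != g) stop("means and sds differ in length", call. = FALSE)
  ns <- rep_len(as.integer(ns), g)
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssb < 1e-24 && ssw < 1e-24)
    stop("degenerate input: all means equal and all sds zero", call. = FALSE)
  df_b <- g - 1L
  df_w <- N - g
  Fval <- if (ssw > 0) (ssb / df_b) / (ssw / df_w) else Inf
  pval <- if (is.finite(Fval)) stats::pf(Fval, df_b, df_w,
                                         lower.tail = FALSE) else 0
  structure(list(ss_between = ssb, ss_within = ssw,
                 df_between = df_b, df_within = df_w,
                 F = Fval, p_value = pval,
                 eta_squared = ssb / (ssb + ssw),
                 labels = labels),
            class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf(
    "one-way ANOVA from summaries: F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f\n",
    x$df_between, x$df_within, x$F, x$p_value, x$eta_squared))
  invisible(x)
}

#' Dry-matter to fresh-weight conversion
#'
#' `value_fw = value_dm * (100 - moisture_pct) / 100`. Spectra of wet
#' tissue are paired with analyte values on a fresh basis, so dry-matter
#' lab results must be recalculated using the sample's moisture.
#'
#' @param value_dm Concentration in g/100 g dry matter.
#' @param moisture_pct Moisture percentage of fresh weight, in [0, 100).
#' @return Concentration in g/100 g fresh weight.
#' @export
dm_to_fw <- function(value_dm, moisture_pct) {
  if (any(!is.finite(moisture_pct) | moisture_pct < 0 | moisture_pct >= 100))
    stop("moisture_pct must lie in [0, 100)", call. = FALSE)
  value_dm * (100 - moisture_pct) / 100
}

#' Fresh-weight to dry-matter conversion (inverse of [dm_to_fw()])
#'
#' @param value_fw Concentration in g/100 g fresh weight.
#' @param moisture_pct Moisture percentage of fresh weight, in [0, 100).
#' @return Concentration in g/100 g dry matter.
#' @export
fw_to_dm <- function(value_fw, moisture_pct) {
  if (any(!is.finite(moisture_pct) | moisture_pct < 0 | moisture_pct >= 100))
    stop("moisture_pct must lie in [0, 100)", call. = FALSE)
  value_fw * 100 / (100 - moisture_pct)
}

#' Treatment-effect report from per-group summaries
#'
#' Builds the treatment-comparison table: for every series, mean +/- SD per
#' treatment with the percent change versus the fresh control in
#' parentheses for treated rows (rounded to 2 decimals for display;
#' unrounded values are retained), plus the per-series one-way ANOVA F and
#' eta-squared across treatments.
#'
#' @param summaries data.frame with columns `series`, `treatment`, `mean`,
#'   `sd`, `n`; each series must include a `"fresh"` control row.
#' @return Object of class `reduction_table`: `rows` (data.frame with
#'   `series, treatment, mean, sd, n, pct_change, display`), `anova`
#'   (data.frame with per-series `F`, `p_value`, `eta_squared`).
#' @export
reduction_table <- function(summaries) {
  need <- c("series", "treatment", "mean", "sd", "n")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- NULL
  anova <- NULL
  for (s in unique(summaries$series)) {
    grp <- summaries[summaries$series == s, , drop = FALSE]
    ctrl <- grp[grp$treatment == "fresh", , drop = FALSE]
    if (nrow(ctrl) != 1)
      stop("series ", s, " has no (single) fresh control", call. = FALSE)
    pct <- ifelse(grp$treatment == "fresh", NA_real_,
                  vapply(grp$mean, function(m)
                    percent_reduction(ctrl$mean, m), numeric(1)))
    disp <- sprintf("%.2f ± %.2f", grp$mean, grp$sd)
    disp <- ifelse(is.na(pct), disp,
                   sprintf("%s (%+.2f)", disp, round(pct, 2)))
    rows <- rbind(rows, data.frame(series = s, treatment = grp$treatment,
                                   mean = grp$mean, sd = grp$sd, n = grp$n,
                                   pct_change = pct, display = disp,
                                   stringsAsFactors = FALSE))
    if (nrow(grp) >= 2) {
      a <- anova_from_summaries(grp$mean, grp$sd, grp$n,
                                labels = grp$treatment)
      anova <- rbind(anova, data.frame(series = s, F = a$F,
                                       p_value = a$p_value,
                                       eta_squared = a$eta_squared))
    }
  }
  structure(list(rows = rows, anova = anova), class = "reduction_table")
}

#' @export
print.reduction_table <- function(x, ...) {
  cat("treatment-effect report (mean ± SD, % change vs fresh)\n")
  print(x$rows[c("series", "treatment", "display")], row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("per-series one-way ANOVA:\n")
    print(transform(x$anova, eta_squared = round(eta_squared, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
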