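# Statistical comparison of the two dose-estimation methods and the
# nonparametric location/time batteries: paired t with 95% CI and Pearson
# correlation for the wearable-vs-Standard dose pairs; Shapiro-Wilk,
# Friedman across acquisition points with pairwise Wilcoxon post hocs under
# Bonferroni, Wilcoxon signed-rank for morning-vs-afternoon pairs, and
# Kruskal-Wallis for between-participant respiratory rate.

#' Paired comparison of wearable and Standard-Method doses
#'
#' Computes, for participant-paired dose vectors: means and sample SDs
#' (n - 1 denominator) of both methods, the mean difference (new - std) and
#' its percentage of the Standard-Method mean, the paired t test with the
#' 95% confidence interval on the (std - new) differences (the reporting
#' orientation of the source comparison; the mirrored interval is also
#' returned), and the Pearson correlation of the pairs.
#'
#' @param id_new wearable-system doses, one per participant (ug).
#' @param id_std Standard-Method doses, paired by participant (ug).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `method_comparison`: list with `n`, `mean_new`,
#'   `sd_new`, `mean_std`, `sd_std`, `mean_diff` (new - std), `pct_diff`,
#'   `ci95_low`, `ci95_high` (on std - new), `ci95_low_new_minus_std`,
#'   `ci95_high_new_minus_std`, `t_stat`, `p_value`, `pearson_r`,
#'   `r_p_value`.
#' @export
compare_methods <- function(id_new, id_std, conf_level = 0.95) {
  if (length(id_new) != length(id_std))
    abort_pape("id_new and id_std must be paired (equal length)", "pape_stats_error")
  if (length(id_new) < 3)
    abort_pape("need at least 3 pairs", "pape_stats_error")
  d <- id_std - id_new
  if (stats::sd(d) > 0) {
    tt <- stats::t.test(id_std, id_new, paired = TRUE, conf.level = conf_level)
    ci <- tt$conf.int
    t_stat <- unname(tt$statistic); p_value <- tt$p.value
  } else {
    # constant differences: the interval collapses onto the difference
    ci <- c(mean(d), mean(d))
    t_stat <- if (mean(d) == 0) NaN else sign(mean(d)) * Inf
    p_value <- if (mean(d) == 0) 1 else 0
  }
  r <- if (stats::sd(id_new) == 0 || stats::sd(id_std) == 0) {
    # correlation undefined for a constant margin
    list(estimate = NA_real_, p.value = NA_real_)
  } else {
    stats::cor.test(id_new, id_std)
  }
  mean_new <- mean(id_new); mean_std <- mean(id_std)
  structure(list(
    n = length(id_new),
    mean_new = mean_new, sd_new = stats::sd(id_new),
    mean_std = mean_std, sd_std = stats::sd(id_std),
    mean_diff = mean_new - mean_std,
    pct_diff = 100 * (mean_new - mean_std) / mean_std,
    ci95_low = ci[1], ci95_high = ci[2],
    ci95_low_new_minus_std = -ci[2],
    ci95_high_new_minus_std = -ci[1],
    t_stat = t_stat, p_value = p_value,
    pearson_r = unname(r$estimate), r_p_value = r$p.value
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Paired dose comparison over %d participants\n", x$n))
  cat(sprintf("  Standard Method : mean %.2f (SD %.2f) ug\n", x$mean_std, x$sd_std))
  cat(sprintf("  Wearable system : mean %.2f (SD %.2f) ug\n", x$mean_new, x$sd_new))
  cat(sprintf("  Mean difference (new - std): %.2f ug (%.1f%% of standard mean)\n",
              x$mean_diff, x$pct_diff))
  cat(sprintf("  95%% CI (std - new): %.2f to %.2f  [mirrored: %.2f to %.2f]\n",
              x$ci95_low, x$ci95_high,
              x$ci95_low_new_minus_std, x$ci95_high_new_minus_std))
  cat(sprintf("  Paired t = %.3f, p = %.4f\n", x$t_stat, x$p_value))
  cat(sprintf("  Pearson r = %.3f, p = %.2g\n", x$pearson_r, x$r_p_value))
  invisible(x)
}

# Wilcoxon signed-rank p that tolerates all-zero differences (identical
# paired samples carry no evidence against the null: p = 1).
safe_signed_rank_p <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Nonparametric location/time test battery
#'
#' Runs, on a participants-by-points summary matrix: Shapiro-Wilk normality
#' per point, the Friedman test across points with participants as complete
#' blocks, and — on rejection (or always, if requested) — all pairwise
#' Wilcoxon signed-rank post hocs with Bonferroni adjustment over the
#' `choose(k, 2)` comparisons. Optionally adds a Wilcoxon signed-rank test
#' of paired morning-vs-afternoon summaries and a Kruskal-Wallis test of a
#' per-participant-grouped channel (respiratory rate in the source design).
#'
#' @param point_summaries numeric matrix, participants x points (complete:
#'   no missing cells), columns named by point.
#' @param tod_pairs optional 2-column matrix/data.frame of paired morning
#'   and afternoon summaries.
#' @param grouped_values optional named list: per-participant numeric
#'   vectors for the Kruskal-Wallis between-participant test.
#' @param alpha omnibus level gating the post hocs (default 0.05).
#' @param posthoc `"on_rejection"` (default) or `"always"`.
#' @return object of class `location_test_report`: list with `shapiro_p`
#'   (per point), `friedman` (statistic, df, p_value), `posthoc`
#'   (data.frame point_a, point_b, p_raw, p_adj or NULL), `tod_wilcoxon_p`,
#'   `kruskal` (statistic, df, p_value) — the latter two NULL when their
#'   inputs are absent.
#' @export
location_battery <- function(point_summaries, tod_pairs = NULL,
                             grouped_values = NULL, alpha = 0.05,
                             posthoc = c("on_rejection", "always")) {
  posthoc <- match.arg(posthoc)
  m <- as.matrix(point_summaries)
  if (anyNA(m))
    abort_pape("point_summaries has missing cells; the Friedman test requires complete blocks",
               "pape_stats_error")
  if (ncol(m) < 2 || nrow(m) < 3)
    abort_pape("need >= 2 points and >= 3 participants", "pape_stats_error")
  pts <- colnames(m) %||% as.character(seq_len(ncol(m)))
  colnames(m) <- pts

  shapiro_p <- apply(m, 2, function(v) {
    if (length(unique(v)) < 3) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })

  fr <- stats::friedman.test(m)
  friedman <- list(statistic = unname(fr$statistic),
                   df = unname(fr$parameter), p_value = fr$p.value)

  ph <- NULL
  if (posthoc == "always" || friedman$p_value < alpha) {
    pairs <- utils::combn(ncol(m), 2)
    n_tests <- ncol(pairs)
    p_raw <- apply(pairs, 2, function(ij) safe_signed_rank_p(m[, ij[1]], m[, ij[2]]))
    ph <- data.frame(
      point_a = pts[pairs[1, ]], point_b = pts[pairs[2, ]],
      p_raw = p_raw, p_adj = stats::p.adjust(p_raw, method = "bonferroni"),
      stringsAsFactors = FALSE
    )
  }

  tod_p <- NULL
  if (!is.null(tod_pairs)) {
    tp <- as.matrix(tod_pairs)
    if (ncol(tp) != 2) abort_pape("tod_pairs must have 2 columns", "pape_stats_error")
    tod_p <- safe_signed_rank_p(tp[, 1], tp[, 2])
  }

  kw <- NULL
  if (!is.null(grouped_values)) {
    kt <- stats::kruskal.test(grouped_values)
    kw <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
               p_value = kt$p.value)
  }

  structure(list(shapiro_p = shapiro_p, friedman = friedman, posthoc = ph,
                 tod_wilcoxon_p = tod_p, kruskal = kw),
            class = "location_test_report")
}

#' Packaged per-participant dose table fixture
#'
#' The 20-participant PM2.5 inhaled-dose table shipped with the package:
#' per-participant median (IQR) of the modelled ventilation, the tabulated
#' Standard-Method ventilation, median (IQR) personal and fixed-station
#' daily concentrations, and the two dose estimates.
#'
#' @return data.frame with columns participant, vm_new_med, vm_new_iqr,
#'   vm_std, c_new_med, c_new_iqr, c_std, id_new, id_std.
#' @export
dose_table_fixture <- function() {
  path <- system.file("extdata", "pm25_inhaled_dose_cohort.csv", package = "pape")
  if (!nzchar(path))
    abort_pape("packaged dose table fixture not found", "pape_io_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("participant", "vm_new_med", "vm_new_iqr", "vm_std",
              "c_new_med", "c_new_iqr", "c_std", "id_new", "id_std")
  if (!all(needed %in% names(df)))
    abort_pape("malformed dose table fixture (missing columns)", "pape_io_error")
  if (nrow(df) != 20 || anyNA(df))
    abort_pape("malformed dose table fixture (expected 20 complete rows)", "pape_io_error")
  df
}

#' Reproduce the packaged dose-table comparison
#'
#' Runs [compare_methods()] on the fixture's paired dose columns and
#' recomputes every Standard-Method dose from its printed inputs
#' (`c_std x vm_std / 1000 x 35 min`), reporting the largest absolute
#' deviation from the printed column.
#'
#' @param fixture dose table as returned by [dose_table_fixture()].
#' @param duration_min total static exposure, minutes (7 x 5 by default).
#' @return list with `comparison` (a `method_comparison`),
#'   `id_std_recomputed` (numeric vector), `max_abs_dev` (vs the printed
#'   column, after 2-decimal rounding of the recomputation), and `fixture`.
#' @export
reproduce_dose_table <- function(fixture = dose_table_fixture(), duration_min = 35) {
  comparison <- compare_methods(fixture$id_new, fixture$id_std)
  rec <- mapply(function(c_std, vm_std)
    standard_dose(standard_inputs(c(pm2_5 = c_std), vm_std, duration_min), "pm2_5"),
    fixture$c_std, fixture$vm_std)
  list(comparison = comparison,
       id_std_recomputed = unname(rec),
       max_abs_dev = max(abs(round(rec, 2) - fixture$id_std)),
       fixture = fixture)
}
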