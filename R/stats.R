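#' Relative difference between hemispheres
#'
#' The injury metric `(ipsi - contra) / contra`: the fractional change
#' of a metabolite ratio on the injured side relative to the
#' non-injured mirror ROI. For the in vivo injury-group Bic/Pyr means
#' (0.042 vs 0.072) this evaluates to -0.42 at two decimals.
#'
#' @param ipsi,contra values from the ipsilateral / contralateral ROI
#'   (vectorized)
#' @return `(ipsi - contra) / contra`
#' @examples
#' relative_difference(0.042, 0.072)
#' @export
relative_difference <- function(ipsi, contra) {
  if (any(contra == 0)) stop("contra must be nonzero")
  (ipsi - contra) / contra
}

new_comparison_result <- function(test_name, statistic, p_value,
                                  normality_ok = NA, equal_variance_ok = NA,
                                  n_per_group, mean_se, posthoc = NULL,
                                  warnings = character()) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, normality_ok = normality_ok,
                 equal_variance_ok = equal_variance_ok,
                 n_per_group = n_per_group, mean_se = mean_se,
                 posthoc = posthoc, warnings = warnings),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test_name, ": statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4), "\n",
      sep = "")
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p.value = x$p_value)
}

#' @exportS3Method generics::glance
glance.comparison_result <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p.value = x$p_value,
                 normality_ok = x$normality_ok,
                 equal_variance_ok = x$equal_variance_ok,
                 n = sum(x$n_per_group))
}

#' Paired comparison of ipsilateral vs contralateral values
#'
#' Two-sided paired t-test on matched per-subject values, reporting
#' mean +/- standard error per side. Zero-variance paired differences
#' (all differences identical) are degenerate for the t statistic; by
#' convention identical vectors return t = 0, p = 1 and any constant
#' nonzero difference returns p = 1 with a warning, so degenerate
#' inputs are flagged rather than producing spurious significance.
#'
#' @param ipsi,contra numeric vectors, matched subject order
#' @return a `comparison_result`
#' @export
paired_compare <- function(ipsi, contra) {
  if (length(ipsi) != length(contra))
    stop("ipsi and contra must have equal length (matched subjects)")
  n <- length(ipsi)
  if (n < 2) stop("paired comparison needs at least 2 subjects")
  d <- ipsi - contra
  mean_se <- list(ipsi = c(mean = mean(ipsi), se = stats::sd(ipsi) / sqrt(n)),
                  contra = c(mean = mean(contra), se = stats::sd(contra) / sqrt(n)))
  warns <- character()
  if (stats::sd(d) == 0) {
    warns <- paste("zero within-pair variance; p reported as 1 by",
                   "convention")
    warning(warns, call. = FALSE)
    return(new_comparison_result("paired t-test", statistic = 0,
                                 p_value = 1, n_per_group = c(n, n),
                                 mean_se = mean_se, warnings = warns))
  }
  tt <- stats::t.test(ipsi, contra, paired = TRUE)
  new_comparison_result("paired t-test",
                        statistic = unname(tt$statistic),
                        p_value = tt$p.value, n_per_group = c(n, n),
                        mean_se = mean_se, warnings = warns)
}

# Brown-Forsythe test for equal variances: one-way ANOVA on absolute
# deviations from the group medians.
brown_forsythe <- function(values, groups) {
  z <- abs(values - stats::ave(values, groups, FUN = stats::median))
  if (stats::sd(z) == 0) return(list(statistic = 0, p_value = 1))
  ft <- stats::oneway.test(z ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = ft$p.value)
}

# Dunn's post-hoc rank comparisons (tie-corrected), all pairs,
# two-sided z tests on mean ranks. With two groups this reduces to the
# tie-corrected rank-sum comparison. No multiplicity correction is
# applied, matching the analysis protocol.
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  combos <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    z <- (rbar[[g1]] - rbar[[g2]]) /
      sqrt(s2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p.value = 2 * stats::pnorm(-abs(z)))
  })
}

#' Normality-gated comparison of naive and injured groups
#'
#' Implements the analysis protocol: per-group Shapiro-Wilk and
#' across-group Brown-Forsythe tests at alpha = 0.05 gate the main
#' test. If both assumptions hold, a one-way ANOVA is run; otherwise a
#' Kruskal-Wallis one-way ANOVA on ranks with Dunn's post-hoc test.
#' The result records which path ran. No multiple-comparison
#' correction is applied.
#'
#' @param a,b numeric vectors of per-subject values
#' @param group_names labels for the two groups
#' @param alpha gate level for the assumption tests
#' @return a `comparison_result`; for the rank path `$posthoc` holds
#'   the Dunn comparisons
#' @export
group_compare <- function(a, b, group_names = c("naive", "injury"),
                          alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs n >= 3 for the normality gate")
  values <- c(a, b)
  groups <- factor(rep(group_names, c(length(a), length(b))),
                   levels = group_names)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("all values tied within both groups; no test possible")
  mean_se <- list(
    stats::setNames(c(mean(a), stats::sd(a) / sqrt(length(a))), c("mean", "se")),
    stats::setNames(c(mean(b), stats::sd(b) / sqrt(length(b))), c("mean", "se"))
  )
  names(mean_se) <- group_names

  sw_ok <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  }
  normality_ok <- sw_ok(a) && sw_ok(b)
  bf <- brown_forsythe(values, groups)
  equal_variance_ok <- bf$p_value > alpha

  if (normality_ok && equal_variance_ok) {
    ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    new_comparison_result("one-way ANOVA",
                          statistic = unname(ft$statistic),
                          p_value = ft$p.value,
                          normality_ok = TRUE, equal_variance_ok = TRUE,
                          n_per_group = c(length(a), length(b)),
                          mean_se = mean_se)
  } else {
    kw <- stats::kruskal.test(values, groups)
    new_comparison_result("Kruskal-Wallis ANOVA on ranks",
                          statistic = unname(kw$statistic),
                          p_value = kw$p.value,
                          normality_ok = normality_ok,
                          equal_variance_ok = equal_variance_ok,
                          n_per_group = c(length(a), length(b)),
                          mean_se = mean_se,
                          posthoc = dunn_posthoc(values, groups))
  }
}

#' Group summary tables of hemisphere metrics
#'
#' For each group and ratio metric, reports mean +/- SE per hemisphere
#' and the relative difference between hemispheres. The per-subject
#' convention (compute `(ipsi - contra)/contra` per subject, then
#' average) is the primary summary; the means-ratio variant
#' (`(mean ipsi - mean contra)/mean contra`) is also reported since
#' the two differ whenever subjects' contralateral values differ.
#'
#' @param ratios a [roi_ratio_table()] tibble
#' @param metrics metric column names to summarize
#' @return list with tibbles `hemisphere` (per group x metric x roi)
#'   and `relative_difference` (per group x metric, both conventions)
#' @export
summarize_ratios <- function(ratios,
                             metrics = c("lac_pyr", "bic_pyr",
                                         "bic_lac", "ala_pyr")) {
  metrics <- intersect(metrics, names(ratios))
  long <- ratios |>
    dplyr::select(dplyr::all_of(c("subject", "group", "roi", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  hemi <- long |>
    dplyr::group_by(.data$group, .data$metric, .data$roi) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = dplyr::if_else(.data$n > 1,
                          stats::sd(.data$value[is.finite(.data$value)]) /
                            sqrt(.data$n),
                          NA_real_),
      .groups = "drop"
    )
  paired <- long |>
    tidyr::pivot_wider(names_from = "roi", values_from = "value") |>
    dplyr::filter(is.finite(.data$ipsi), is.finite(.data$contra),
                  .data$contra != 0) |>
    dplyr::mutate(rel_diff = relative_difference(.data$ipsi, .data$contra))
  reldiff <- paired |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rel_diff = mean(.data$rel_diff),
      se_rel_diff = dplyr::if_else(.data$n > 1,
                                   stats::sd(.data$rel_diff) / sqrt(.data$n),
                                   NA_real_),
      rel_diff_of_means = relative_difference(mean(.data$ipsi),
                                              mean(.data$contra)),
      .groups = "drop"
    )
  list(hemisphere = hemi, relative_difference = reldiff)
}
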