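# Cross-contrast comparison of delta-betas: shared-DM selection, Pearson
# correlation, sign-agreement chi-square, and subgroup DM-count asymmetry.

#' Join two contrast results on their common CpG universe
#'
#' Inner join on `cpg_id`, producing one row per shared CpG with both
#' deltas.
#'
#' @param result_a,result_b `contrast_result` data.frames (see
#'   [contrast_stats()]).
#' @return data.frame with columns `cpg_id`, `delta_a`, `delta_b`, `p_a`,
#'   `p_b`.
#' @export
join_contrasts <- function(result_a, result_b) {
  common <- intersect(result_a$cpg_id, result_b$cpg_id)
  if (length(common) == 0)
    stopf("contrast results share no CpG ids")
  ia <- match(common, result_a$cpg_id)
  ib <- match(common, result_b$cpg_id)
  data.frame(cpg_id = common,
             delta_a = result_a$delta[ia], delta_b = result_b$delta[ib],
             p_a = result_a$p[ia], p_b = result_b$p[ib],
             stringsAsFactors = FALSE)
}

#' Select CpGs differentially methylated in both contrasts
#'
#' Keeps rows with `|delta_a| > threshold` and `|delta_b| > threshold`
#' (strict inequalities, both contrasts; no sign constraint, so discordant
#' CpGs are retained for the concordance test).
#'
#' @param joined output of [join_contrasts()].
#' @param threshold absolute delta cutoff in (0, 1]; default 0.15, the
#'   relaxed cutoff used for cross-contrast comparison.
#' @return the selected subset of `joined`.
#' @export
select_shared_dm <- function(joined, threshold = 0.15) {
  if (!(threshold > 0 && threshold <= 1))
    stopf("threshold must be in (0, 1]")
  joined[abs(joined$delta_a) > threshold & abs(joined$delta_b) > threshold, ,
         drop = FALSE]
}

#' Concordance statistics between two contrasts
#'
#' On the selected shared-DM set: Pearson correlation of the two delta
#' vectors; a 2x2 table of `sign(delta_a)` by `sign(delta_b)`; and the
#' df=1 chi-square of that table in closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity correction
#' (optionally with Yates' correction). When a margin of the table is zero
#' the chi-square is undefined and reported as `NA` with a warning.
#'
#' @param subset output of [select_shared_dm()]; needs >= 2 rows and no
#'   zero deltas (impossible after strict selection).
#' @param continuity_correction apply Yates' correction (default `FALSE`;
#'   expected counts are large at typical selection sizes).
#' @return list of class `concordance_result`: `n_selected`, `pearson_r`,
#'   `sign_table` (2x2, rows = contrast A direction, cols = contrast B),
#'   `chi2`, `chi2_p`.
#' @export
concordance_stats <- function(subset, continuity_correction = FALSE) {
  if (nrow(subset) < 2) stopf("need >= 2 selected CpGs")
  if (any(subset$delta_a == 0 | subset$delta_b == 0))
    stopf("zero deltas cannot occur after strict selection")
  r <- if (stats::sd(subset$delta_a) == 0 || stats::sd(subset$delta_b) == 0)
    NA_real_  # degenerate: a constant delta vector has no correlation
  else stats::cor(subset$delta_a, subset$delta_b, method = "pearson")
  sa <- factor(ifelse(subset$delta_a > 0, "hyper", "hypo"),
               levels = c("hyper", "hypo"))
  sb <- factor(ifelse(subset$delta_b > 0, "hyper", "hypo"),
               levels = c("hyper", "hypo"))
  tab <- table(sa, sb)
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  n <- sum(tab)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warnf("a margin of the sign table is zero; chi-square undefined")
    chi2 <- NA_real_
    chi2_p <- NA_real_
  } else {
    num <- abs(a * d - b * c)
    if (continuity_correction) num <- max(0, num - n / 2)
    chi2 <- n * num^2 / prod(margins)
    chi2_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(n_selected = n, threshold = attr(subset, "threshold"),
                 pearson_r = r, sign_table = unclass(tab), chi2 = chi2,
                 chi2_p = chi2_p),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance over %d shared DM CpGs: R = %.3f, chi2(1) = %s, p = %s\n",
              x$n_selected, x$pearson_r,
              format(x$chi2, digits = 4), format(x$chi2_p, digits = 3)))
  print(x$sign_table)
  invisible(x)
}

#' Relative difference between two counts, percent of the first
#'
#' `100 * (n_first - n_second) / n_first`; e.g. 248 vs 189 DM CpGs gives
#' 23.8% (reported as "24% higher").
#'
#' @param n_first,n_second counts; `n_first` is the denominator.
#' @return percent relative difference.
#' @export
relative_difference <- function(n_first, n_second) {
  if (n_first == 0) stopf("first count is zero; relative difference undefined")
  100 * (n_first - n_second) / n_first
}

#' DM counts of a contrast within subgroups of the design
#'
#' Runs the given contrast separately within each level of `subgroup_var`
#' (e.g. the culture contrast within young and within elderly donors),
#' counts the CpGs labelled DM at the thresholds, and reports the relative
#' difference of the first-listed subgroup versus the second.
#'
#' @param beta a [beta_matrix()].
#' @param design a [study_design()].
#' @param spec a [contrast_spec()] (its `subset` is combined with the
#'   subgroup restriction).
#' @param subgroup_var design column to split on (default `"age_group"`).
#' @param subgroup_levels order of levels; first is the reference of the
#'   relative difference. Default: young before elderly.
#' @param delta_threshold,p_threshold passed to [classify_dm()].
#' @return list with `counts` (named DM count per subgroup),
#'   `relative_difference_pct`, and the per-subgroup labelled results.
#' @export
subgroup_dm_counts <- function(beta, design, spec,
                               subgroup_var = "age_group",
                               subgroup_levels = NULL,
                               delta_threshold = 0.20, p_threshold = 0.01) {
  if (!subgroup_var %in% names(design))
    stopf("unknown subgroup variable '%s'", subgroup_var)
  levels_ <- subgroup_levels %||%
    (if (subgroup_var == "age_group") c("young", "elderly")
     else unique(design[[subgroup_var]]))
  results <- list()
  counts <- setNames(integer(length(levels_)), levels_)
  for (lv in levels_) {
    sub_spec <- spec
    sub_spec$subset <- c(spec$subset, setNames(list(lv), subgroup_var))
    res <- classify_dm(contrast_stats(beta, design, sub_spec),
                       delta_threshold, p_threshold)
    counts[lv] <- sum(res$dm_label != "unchanged")
    results[[lv]] <- res
  }
  rel <- if (counts[[1]] == 0) {
    warnf("first subgroup has zero DM CpGs; relative difference undefined")
    NA_real_
  } else {
    relative_difference(counts[[1]], counts[[2]])
  }
  list(counts = counts, relative_difference_pct = rel, results = results)
}
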