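# Per-CpG contrast statistics (delta-beta, Student's t, BH q), DM
# classification at configurable thresholds, and hierarchical clustering
# for heatmap ordering.

#' Define a two-group contrast on the study design
#'
#' @param name contrast label (e.g. `"culture"`, `"aging"`).
#' @param variable grouping column: `"passage_group"` or `"age_group"`.
#' @param level_a reference level (e.g. `"early"` or `"young"`).
#' @param level_b test level; `delta = mean_B - mean_A`.
#' @param paired use the one-sample t test on within-donor differences
#'   (requires complete donor pairs). Default `FALSE`: unpaired
#'   pooled-variance Student's t.
#' @param subset optional named list restricting samples before grouping,
#'   e.g. `list(passage_group = "early")` to test aging at early passage
#'   only, or `list(age_group = "young")` for a donor-age subgroup.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, variable, level_a, level_b, paired = FALSE,
                          subset = NULL) {
  if (!variable %in% c("passage_group", "age_group"))
    stopf("variable must be 'passage_group' or 'age_group'")
  if (identical(level_a, level_b)) stopf("contrast levels must differ")
  structure(list(name = name, variable = variable, level_a = level_a,
                 level_b = level_b, paired = paired, subset = subset),
            class = "contrast_spec")
}

#' The standard long-term-culture contrast (early vs late passage)
#'
#' @param paired paired mode flag.
#' @param subset optional sample restriction (see [contrast_spec()]).
#' @return a `contrast_spec`.
#' @export
culture_contrast <- function(paired = FALSE, subset = NULL) {
  contrast_spec("culture", "passage_group", "early", "late", paired, subset)
}

#' The standard donor-aging contrast (young vs elderly at early passage)
#'
#' Aging is assessed between donors at the second passage, so the contrast
#' restricts to early-passage samples by default.
#'
#' @param subset sample restriction; default early passage only.
#' @return a `contrast_spec`.
#' @export
aging_contrast <- function(subset = list(passage_group = "early")) {
  contrast_spec("aging", "age_group", "young", "elderly", FALSE, subset)
}

apply_subset <- function(design, subset) {
  keep <- rep(TRUE, nrow(design))
  for (nm in names(subset)) {
    if (!nm %in% names(design)) stopf("unknown subset variable '%s'", nm)
    keep <- keep & design[[nm]] %in% subset[[nm]]
  }
  design[keep, , drop = FALSE]
}

#' Per-CpG contrast statistics
#'
#' Computes, for every CpG, the two group means, the delta-beta
#' `delta = mean_B - mean_A`, a two-sided Student's t statistic
#' (pooled-variance unpaired by default; one-sample t on within-donor
#' differences in paired mode), its p-value, and Benjamini-Hochberg
#' adjusted q-values over all tested CpGs.
#'
#' Zero-variance edge cases: when all values are equal in both groups and
#' the delta is zero, `t = 0, p = 1`; a nonzero delta with zero pooled
#' variance yields `p = 0`.
#'
#' @param beta a [beta_matrix()] without missing values in the used samples.
#' @param design a [study_design()] covering the beta columns.
#' @param spec a [contrast_spec()].
#' @return a data.frame of class `contrast_result` with columns `cpg_id`,
#'   `mean_a`, `mean_b`, `delta`, `t`, `p`, `q`, `n_a`, `n_b` and attribute
#'   `spec`.
#' @export
contrast_stats <- function(beta, design, spec) {
  stopifnot(inherits(spec, "contrast_spec"))
  design <- apply_subset(design, spec$subset)
  design <- design[design$sample_id %in% colnames(beta), , drop = FALSE]
  g <- design[[spec$variable]]
  ids_a <- design$sample_id[g == spec$level_a]
  ids_b <- design$sample_id[g == spec$level_b]
  if (length(ids_a) < 2)
    stopf("group '%s' has %d sample(s); need >= 2", spec$level_a,
          length(ids_a))
  if (length(ids_b) < 2)
    stopf("group '%s' has %d sample(s); need >= 2", spec$level_b,
          length(ids_b))
  A <- unclass(beta)[, ids_a, drop = FALSE]
  B <- unclass(beta)[, ids_b, drop = FALSE]
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  delta <- mean_b - mean_a

  if (spec$paired) {
    donors_a <- design$donor_id[match(ids_a, design$sample_id)]
    donors_b <- design$donor_id[match(ids_b, design$sample_id)]
    common <- intersect(donors_a, donors_b)
    if (length(common) < 2)
      stopf("paired mode needs >= 2 complete donor pairs")
    if (length(common) < length(union(donors_a, donors_b)))
      warnf("paired mode drops %d incomplete donor(s)",
            length(union(donors_a, donors_b)) - length(common))
    D <- B[, match(common, donors_b), drop = FALSE] -
      A[, match(common, donors_a), drop = FALSE]
    nd <- length(common)
    dbar <- rowMeans(D)
    sd_d <- sqrt(rowSums((D - dbar)^2) / (nd - 1))
    se <- sd_d / sqrt(nd)
    df <- nd - 1
    tt <- dbar / se
    mean_a <- rowMeans(A[, match(common, donors_a), drop = FALSE])
    mean_b <- rowMeans(B[, match(common, donors_b), drop = FALSE])
    delta <- dbar
    n_a <- n_b <- nd
  } else {
    n_a <- ncol(A)
    n_b <- ncol(B)
    va <- rowSums((A - mean_a)^2) / (n_a - 1)
    vb <- rowSums((B - mean_b)^2) / (n_b - 1)
    sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    tt <- delta / se
  }
  # zero-variance conventions
  tt[se == 0 & delta == 0] <- 0
  tt[se == 0 & delta != 0] <- sign(delta[se == 0 & delta != 0]) * Inf
  p <- 2 * stats::pt(-abs(tt), df)
  p[is.infinite(tt)] <- 0
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(cpg_id = rownames(beta), mean_a = mean_a,
                    mean_b = mean_b, delta = delta, t = tt, p = p, q = q,
                    n_a = n_a, n_b = n_b, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "spec") <- spec
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Label CpGs as hyper-/hypomethylated at the relevance thresholds
#'
#' A CpG is `hyper` when `delta > delta_threshold` (strictly more than the
#' threshold, e.g. "more than 20%"), `hypo` symmetrically, otherwise
#' `unchanged`. When `p_threshold` is non-`NULL`, significance `p <=
#' p_threshold` is additionally required.
#'
#' @param result a `contrast_result` from [contrast_stats()].
#' @param delta_threshold absolute delta-beta relevance cutoff in (0, 1].
#' @param p_threshold optional significance cutoff; default 0.01.
#' @return `result` with an added `dm_label` column.
#' @export
classify_dm <- function(result, delta_threshold = 0.20, p_threshold = 0.01) {
  if (!(delta_threshold > 0 && delta_threshold <= 1))
    stopf("delta_threshold must be in (0, 1]")
  sig <- if (is.null(p_threshold)) TRUE else result$p <= p_threshold
  result$dm_label <- ifelse(result$delta > delta_threshold & sig, "hyper",
                     ifelse(result$delta < -delta_threshold & sig, "hypo",
                            "unchanged"))
  result
}

#' Hierarchical clustering for heatmap ordering
#'
#' Agglomerative clustering with Euclidean distance and average linkage on
#' either axis of the beta matrix. Deterministic given input order.
#'
#' @param beta a [beta_matrix()] (or numeric matrix), no missing values.
#' @param axis cluster `"cpgs"` (rows) or `"samples"` (columns).
#' @return list with `order` (leaf order as indices), `labels` (ids in leaf
#'   order), `merge` and `height` from the merge tree, and the underlying
#'   `hclust` object.
#' @export
hierarchical_cluster <- function(beta, axis = c("cpgs", "samples")) {
  axis <- match.arg(axis)
  x <- unclass(beta)
  if (axis == "samples") x <- t(x)
  if (nrow(x) < 2) stopf("need >= 2 items to cluster on axis '%s'", axis)
  if (anyNA(x)) stopf("missing values not allowed in clustering")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  list(order = hc$order, labels = rownames(x)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}
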