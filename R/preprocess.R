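# Beta computation from channel intensities, detection-p filtering, and
# quantile normalization.

#' Compute beta values from methylated/unmethylated channel intensities
#'
#' `beta = M / (M + U + alpha)`. The offset `alpha` (default 100
#' fluorescence units, the platform convention) regularizes low-intensity
#' assays; `alpha = 0` is supported. Cells with `M + U + alpha == 0` become
#' missing with a warning.
#'
#' @param intensities list with numeric matrices `M` and `U` (same shape,
#'   shared dimnames), both non-negative.
#' @param alpha non-negative offset.
#' @return a [beta_matrix()].
#' @export
compute_beta <- function(intensities, alpha = 100) {
  M <- intensities$M
  U <- intensities$U
  if (!identical(dim(M), dim(U))) stopf("M and U must share shape")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stopf("channel intensities must be non-negative")
  if (alpha < 0) stopf("alpha must be >= 0")
  denom <- M + U + alpha
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warnf("%d assay(s) with zero total intensity set to NA", sum(zero))
    denom[zero] <- NA_real_
  }
  b <- M / denom
  dimnames(b) <- dimnames(M)
  beta_matrix(b)
}

#' Remove CpGs with unreliable detection p-values
#'
#' A CpG is removed when the fraction of samples whose detection p-value
#' exceeds `alpha_det` is greater than `max_fail_fraction`. The defaults
#' (`alpha_det = 0.01`, `max_fail_fraction = 0`: any failing sample removes
#' the CpG) implement a strict rule under which only few sites should fail.
#' Surviving values are never altered.
#'
#' @param beta a [beta_matrix()].
#' @param detection numeric matrix of detection p-values, same shape and
#'   dimnames as `beta`.
#' @param alpha_det detection p-value threshold above which a sample fails.
#' @param max_fail_fraction tolerated fraction of failing samples per CpG.
#' @return list with `beta` (retained rows) and `removed` (data.frame of
#'   `cpg_id` and `fail_fraction` for removed CpGs).
#' @export
filter_by_detection <- function(beta, detection, alpha_det = 0.01,
                                max_fail_fraction = 0) {
  if (!identical(dim(beta), dim(detection)))
    stopf("beta and detection matrices must share shape")
  if (!identical(rownames(beta), rownames(detection)) ||
      !identical(colnames(beta), colnames(detection)))
    stopf("beta and detection matrices must share dimnames")
  fail_frac <- rowMeans(detection > alpha_det)
  drop <- fail_frac > max_fail_fraction
  removed <- data.frame(cpg_id = rownames(beta)[drop],
                        fail_fraction = unname(fail_frac[drop]),
                        stringsAsFactors = FALSE)
  list(beta = beta[!drop, , drop = FALSE], removed = removed)
}

#' Quantile-normalize a beta matrix across samples
#'
#' Forces every column onto the common distribution of across-column means
#' of order statistics, preserving within-column ranks. Tied values receive
#' the mean of the order-statistic means across their tied ranks, so the
#' transform is deterministic and idempotent. CpGs with any missing value
#' are excluded from normalization and reported via the `excluded_cpgs`
#' attribute (unreliable rows are dropped rather than imputed).
#'
#' @param beta a [beta_matrix()] (or numeric matrix with dimnames).
#' @return a normalized [beta_matrix()] of the complete rows, with
#'   attribute `excluded_cpgs` naming any dropped rows.
#' @export
quantile_normalize <- function(beta) {
  x <- unclass(beta)
  incomplete <- rownames(x)[!stats::complete.cases(x)]
  if (length(incomplete) > 0) {
    warnf("%d CpG(s) with missing values excluded from normalization",
          length(incomplete))
    x <- x[stats::complete.cases(x), , drop = FALSE]
  }
  if (nrow(x) == 0) stopf("no complete CpGs to normalize")
  if (nrow(x) == 1) {
    out <- matrix(mean(x), 1, ncol(x), dimnames = dimnames(x))
  } else {
    ref <- rowMeans(apply(x, 2, sort))
    out <- apply(x, 2, function(col) {
      mapped <- numeric(length(col))
      mapped[order(col)] <- ref
      # ties: average the reference values occupying the tied ranks
      stats::ave(mapped, match(col, col), FUN = mean)
    })
    dimnames(out) <- dimnames(x)
  }
  out <- beta_matrix(out)
  if (length(incomplete) > 0) attr(out, "excluded_cpgs") <- incomplete
  out
}
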