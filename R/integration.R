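# Methylation-expression linkage by gene symbol and array-versus-
# pyrosequencing platform comparison.

#' Filter expression probes by present-call fraction
#'
#' A probe set is retained when the fraction of samples in which it is
#' called present (`"P"`) strictly exceeds `min_fraction` ("present in more
#' than 50% of the hybridizations").
#'
#' @param expr an [expression_matrix()].
#' @param min_fraction minimum present fraction (strict); default 0.5.
#' @return character vector of retained probe ids.
#' @export
present_filter <- function(expr, min_fraction = 0.5) {
  frac <- rowMeans(expr$calls == "P")
  rownames(expr$calls)[frac > min_fraction]
}

#' Match CpGs to expression probe sets by gene symbol
#'
#' Many-to-many resolution: a gene's probe sets are aggregated (arithmetic
#' mean of log2 intensities by default, or the maximum-mean probe set), and
#' each CpG is matched independently to its gene's aggregate. Symbols are
#' the canonical uppercased join key. Unmatched CpGs are counted.
#'
#' @param annotation a [cpg_annotation()].
#' @param expr an [expression_matrix()].
#' @param probes optional probe subset (e.g. from [present_filter()]);
#'   default all probes.
#' @param aggregation `"mean"` or `"max"` over a gene's probe sets.
#' @return list with `gene_expression` (gene-by-sample log2 matrix),
#'   `cpg_gene` (data.frame `cpg_id`, `gene_symbol` for matched CpGs),
#'   `probe_ids` (list of probe ids per gene), and counts
#'   `n_cpgs_unmatched`, `n_cpgs_unannotated`.
#' @export
match_by_symbol <- function(annotation, expr, probes = NULL,
                            aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  probes <- probes %||% rownames(expr$intensity)
  probes <- intersect(probes, rownames(expr$intensity))
  sym <- expr$probe_to_symbol[probes]
  keep <- !is.na(sym)
  probes <- probes[keep]
  sym <- sym[keep]
  if (length(probes) == 0) {
    gene_expr <- matrix(numeric(0), 0, ncol(expr$intensity),
                        dimnames = list(NULL, colnames(expr$intensity)))
    probe_ids <- list()
  } else if (aggregation == "mean") {
    gene_expr <- rowsum(expr$intensity[probes, , drop = FALSE], sym)
    gene_expr <- gene_expr / as.vector(table(sym)[rownames(gene_expr)])
    probe_ids <- split(probes, sym)
  } else {
    probe_ids <- split(probes, sym)
    best <- vapply(probe_ids, function(p) {
      p[which.max(rowMeans(expr$intensity[p, , drop = FALSE]))]
    }, "")
    gene_expr <- expr$intensity[best, , drop = FALSE]
    rownames(gene_expr) <- names(best)
  }
  ann_sym <- annotation$gene_symbol
  n_unannot <- sum(is.na(ann_sym))
  matched <- !is.na(ann_sym) & ann_sym %in% rownames(gene_expr)
  list(gene_expression = gene_expr,
       cpg_gene = data.frame(cpg_id = annotation$cpg_id[matched],
                             gene_symbol = ann_sym[matched],
                             stringsAsFactors = FALSE),
       probe_ids = probe_ids,
       n_cpgs_unmatched = sum(!matched) - n_unannot,
       n_cpgs_unannotated = n_unannot)
}

#' Mean expression of genes binned by mean promoter methylation
#'
#' Bins linked genes by their mean beta across samples and summarizes log2
#' intensity per bin: with promoter silencing, nonmethylated bins show
#' higher expression than methylated ones. Default bin edges
#' `c(0, 0.25, 0.75, 1)` define nonmethylated / intermediate / methylated.
#'
#' @param beta a [beta_matrix()].
#' @param mapping output of [match_by_symbol()].
#' @param bin_edges strictly increasing edges over \[0, 1\].
#' @return data.frame per bin: `bin`, `lo`, `hi`, `n_genes`,
#'   `mean_intensity`, `sd_intensity`, `empty` flag.
#' @export
methylation_expression_summary <- function(beta, mapping,
                                           bin_edges = c(0, 0.25, 0.75, 1)) {
  if (any(diff(bin_edges) <= 0)) stopf("bin edges must strictly increase")
  cg <- mapping$cpg_gene
  cg <- cg[cg$cpg_id %in% rownames(beta), , drop = FALSE]
  if (nrow(cg) == 0) stopf("no linked genes")
  gene_beta <- rowsum(unclass(beta)[cg$cpg_id, , drop = FALSE],
                      cg$gene_symbol)
  gene_beta <- rowMeans(gene_beta /
                          as.vector(table(cg$gene_symbol)[rownames(gene_beta)]))
  gene_int <- rowMeans(mapping$gene_expression)[names(gene_beta)]
  bin <- cut(gene_beta, bin_edges, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin),
                    lo = bin_edges[-length(bin_edges)],
                    hi = bin_edges[-1],
                    n_genes = as.vector(table(bin)),
                    mean_intensity = as.vector(tapply(gene_int, bin, mean)),
                    sd_intensity = as.vector(tapply(gene_int, bin, stats::sd)),
                    stringsAsFactors = FALSE)
  out$empty <- out$n_genes == 0
  if (any(out$empty)) warnf("%d empty methylation bin(s)", sum(out$empty))
  if (sum(!out$empty) == 1) warnf("all genes fall in a single bin")
  out
}

#' Differential methylation versus differential expression per gene
#'
#' Pairs each linked gene's delta-beta (most extreme delta among its CpGs)
#' with its log2 expression ratio, reports their Pearson correlation, and,
#' for an optional candidate gene list, the fraction whose directions
#' agree with promoter silencing (hypermethylation with lower expression
#' and vice versa). Genes with a zero delta or zero ratio are excluded
#' from the agreement denominator.
#'
#' @param result a `contrast_result` (see [contrast_stats()]).
#' @param expression_ratio named numeric vector of per-gene log2 expression
#'   ratios for the same biological contrast.
#' @param mapping output of [match_by_symbol()].
#' @param candidates optional character vector of gene symbols.
#' @return list with `pairs` (data.frame `gene_symbol`, `delta`,
#'   `log2_ratio`, `agreement`), `correlation`, and (when candidates are
#'   given) `candidate_agreement` (fraction) and `n_candidates_used`.
#' @export
delta_vs_expression <- function(result, expression_ratio, mapping,
                                candidates = NULL) {
  cg <- mapping$cpg_gene
  if (nrow(cg) == 0) stopf("empty CpG-probe mapping")
  idx <- match(cg$cpg_id, result$cpg_id)
  cg <- cg[!is.na(idx), , drop = FALSE]
  deltas <- result$delta[idx[!is.na(idx)]]
  # per gene: the most extreme CpG delta (sign-preserving)
  gene_delta <- tapply(deltas, cg$gene_symbol,
                       function(d) d[which.max(abs(d))])
  genes <- intersect(names(gene_delta),
                     names(expression_ratio)[!is.na(expression_ratio)])
  if (length(genes) == 0) stopf("no genes shared with expression ratios")
  pairs <- data.frame(gene_symbol = genes,
                      delta = as.numeric(gene_delta[genes]),
                      log2_ratio = as.numeric(expression_ratio[genes]),
                      stringsAsFactors = FALSE)
  pairs$agreement <- ifelse(pairs$delta == 0 | pairs$log2_ratio == 0, NA,
                            sign(pairs$delta) != sign(pairs$log2_ratio))
  correlation <- if (nrow(pairs) >= 2 && stats::sd(pairs$delta) > 0 &&
                     stats::sd(pairs$log2_ratio) > 0) {
    stats::cor(pairs$delta, pairs$log2_ratio)
  } else NA_real_
  out <- list(pairs = pairs, correlation = correlation)
  if (!is.null(candidates)) {
    cand <- pairs[pairs$gene_symbol %in% toupper(candidates), , drop = FALSE]
    usable <- cand$agreement[!is.na(cand$agreement)]
    out$candidate_agreement <- if (length(usable)) mean(usable) else NA_real_
    out$n_candidates_used <- length(usable)
  }
  out
}

#' Compare array betas with pyrosequencing profiles at target CpGs
#'
#' Per target CpG: group-mean array beta and group-mean pyrosequencing
#' fraction (percent / 100), the platform offset (pyro - array, averaged
#' over samples), and the between-group delta on each platform; across
#' targets, the Pearson correlation of the two delta vectors (deltas are
#' invariant to any constant platform offset). Also summarizes how closely
#' an island's neighbor positions track the target (mean per-sample
#' correlation).
#'
#' @param beta a [beta_matrix()] containing the target CpGs.
#' @param pyro a `pyro_profiles` data.frame (see [read_pyro_csv()]).
#' @param design a [study_design()].
#' @param spec a [contrast_spec()] defining the two groups.
#' @return list with `per_cpg` (data.frame per target: group means on both
#'   platforms, `offset`, `delta_array`, `delta_pyro`,
#'   `neighbor_correlation`), and `delta_correlation` across targets.
#' @export
compare_platforms <- function(beta, pyro, design, spec) {
  design <- apply_subset(design, spec$subset)
  design <- design[design$sample_id %in% colnames(beta), , drop = FALSE]
  g <- design[[spec$variable]]
  ids_a <- design$sample_id[g == spec$level_a]
  ids_b <- design$sample_id[g == spec$level_b]
  if (length(ids_a) == 0 || length(ids_b) == 0)
    stopf("missing samples for contrast group(s)")
  targets <- unique(pyro$target_cpg_id)
  miss <- setdiff(targets, rownames(beta))
  if (length(miss) > 0)
    stopf("pyro target(s) absent from beta matrix: %s",
          paste(miss, collapse = ", "))
  rows <- lapply(targets, function(cg) {
    pr <- pyro[pyro$target_cpg_id == cg, , drop = FALSE]
    tgt <- pr[pr$position_bp == 0, , drop = FALSE]
    pyro_frac <- setNames(tgt$percent_meth / 100, tgt$sample_id)
    used <- intersect(names(pyro_frac), c(ids_a, ids_b))
    arr <- unclass(beta)[cg, used]
    pyr <- pyro_frac[used]
    a_idx <- used %in% ids_a
    nb <- pr[pr$position_bp != 0, , drop = FALSE]
    neighbor_cor <- if (nrow(nb) > 0) {
      mean(vapply(split(nb, nb$position_bp), function(d) {
        v <- setNames(d$percent_meth / 100, d$sample_id)[used]
        if (stats::sd(v) == 0 || stats::sd(arr) == 0) return(NA_real_)
        stats::cor(v, arr)
      }, 0), na.rm = TRUE)
    } else NA_real_
    data.frame(cpg_id = cg,
               array_mean_a = mean(arr[a_idx]),
               array_mean_b = mean(arr[!a_idx]),
               pyro_mean_a = mean(pyr[a_idx]),
               pyro_mean_b = mean(pyr[!a_idx]),
               offset = mean(pyr - arr),
               delta_array = mean(arr[!a_idx]) - mean(arr[a_idx]),
               delta_pyro = mean(pyr[!a_idx]) - mean(pyr[a_idx]),
               neighbor_correlation = neighbor_cor,
               stringsAsFactors = FALSE)
  })
  per_cpg <- do.call(rbind, rows)
  delta_correlation <- if (nrow(per_cpg) >= 2 &&
                           stats::sd(per_cpg$delta_array) > 0 &&
                           stats::sd(per_cpg$delta_pyro) > 0) {
    stats::cor(per_cpg$delta_array, per_cpg$delta_pyro)
  } else NA_real_
  list(per_cpg = per_cpg, delta_correlation = delta_correlation)
}
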