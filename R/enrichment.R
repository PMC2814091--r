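# Hypergeometric over-representation of DM gene lists in functional gene
# sets, cytogenetic bands, and transcription-factor target sets.

#' Gene symbols behind labelled CpGs
#'
#' Maps CpGs carrying the requested DM label to deduplicated gene symbols
#' ("nonredundant genes"); CpGs without a symbol are dropped and counted.
#'
#' @param result a labelled `contrast_result` (see [classify_dm()]).
#' @param annotation a [cpg_annotation()] covering the CpG universe.
#' @param direction `"hyper"` or `"hypo"`.
#' @return character vector of gene symbols with attribute
#'   `n_unannotated` (CpGs lacking a symbol).
#' @export
genes_from_cpgs <- function(result, annotation,
                            direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  if (is.null(result$dm_label)) stopf("run classify_dm() first")
  miss <- setdiff(result$cpg_id, annotation$cpg_id)
  if (length(miss) > 0)
    stopf("annotation does not cover %d CpG(s), e.g. %s", length(miss),
          miss[1])
  cpgs <- result$cpg_id[result$dm_label == direction]
  sym <- annotation$gene_symbol[match(cpgs, annotation$cpg_id)]
  n_unannot <- sum(is.na(sym))
  genes <- unique(sym[!is.na(sym)])
  attr(genes, "n_unannotated") <- n_unannot
  genes
}

#' Upper-tail hypergeometric p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` set members among `n` selected genes when the set
#' has `K` members in a universe of `N`.
#'
#' @param k overlap count.
#' @param K set size within the universe.
#' @param n number of selected genes.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (k > min(n, K)) stopf("k cannot exceed min(n, K)")
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a gene list in a gene-set collection
#'
#' For each set, intersects the set with the universe and computes the
#' upper hypergeometric tail p-value of the overlap with the selected
#' genes, then Benjamini-Hochberg adjusts across all tested sets. Sets with
#' no member in the universe are skipped.
#'
#' @param selected character vector of selected gene symbols (must be a
#'   subset of `universe`).
#' @param collection a [gene_set_collection()].
#' @param universe character vector of all eligible gene symbols (typically
#'   all genes with >= 1 CpG surviving preprocessing).
#' @param min_set_size skip sets smaller than this within the universe.
#' @param direction optional tag recorded in the output (e.g. which DM list
#'   was tested).
#' @return data.frame of class `enrichment_result`, one row per tested set:
#'   `set_name`, `k`, `n`, `K`, `N`, `p`, `q`, `direction`, `overlap`
#'   (comma-separated overlapping symbols), sorted by `p`.
#' @export
overrepresentation <- function(selected, collection, universe,
                               min_set_size = 1, direction = NA_character_) {
  universe <- unique(toupper(universe))
  selected <- unique(toupper(selected))
  outside <- setdiff(selected, universe)
  if (length(outside) > 0)
    stopf("selected gene(s) outside universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    K <- length(members)
    if (K < min_set_size || K == 0) return(NULL)
    hit <- intersect(selected, members)
    k <- length(hit)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               p = hypergeom_tail(k, K, n, N),
               direction = direction,
               overlap = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set_name = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), direction = character(0),
                      overlap = character(0), stringsAsFactors = FALSE)
  } else {
    res$q <- stats::p.adjust(res$p, method = "BH")
    res <- res[order(res$p, res$set_name),
               c("set_name", "k", "n", "K", "N", "p", "q", "direction",
                 "overlap")]
    rownames(res) <- NULL
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' One gene set per cytogenetic band in the annotation
#'
#' Builds positional gene sets (e.g. all genes on 10q22) for
#' chromosome-region enrichment. Genes whose band string does not parse are
#' excluded with a warning; each gene belongs to exactly one band set.
#'
#' @param annotation a [cpg_annotation()].
#' @return a [gene_set_collection()] keyed by band (prefixed `chr`).
#' @export
band_sets <- function(annotation) {
  ann <- annotation[!is.na(annotation$gene_symbol), , drop = FALSE]
  gene_band <- unique(ann[, c("gene_symbol", "band")])
  parsed <- parse_band(gene_band$band)
  bad <- is.na(parsed$chromosome)
  if (any(bad)) {
    warnf("%d gene(s) with unparseable band excluded from band sets",
          sum(bad))
    gene_band <- gene_band[!bad, , drop = FALSE]
  }
  if (nrow(gene_band) == 0)
    return(gene_set_collection(list()))
  sets <- split(gene_band$gene_symbol, gene_band$band)
  names(sets) <- paste0("chr", names(sets))
  desc <- setNames(sprintf("genes at cytogenetic band %s",
                           sub("^chr", "", names(sets))), names(sets))
  gene_set_collection(sets, desc)
}
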