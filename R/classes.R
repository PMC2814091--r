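#' Construct a validated beta-value matrix
#'
#' The central object of the pipeline: a CpG-by-sample matrix of methylation
#' fractions (beta values) in \[0, 1\], with unique CpG identifiers as row
#' names and unique sample identifiers as column names. Missing entries are
#' allowed and represented as `NA`.
#'
#' @param values numeric matrix of methylation fractions.
#' @param cpg_ids optional character vector of CpG identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to `colnames(values)`.
#' @return a numeric matrix of class `beta_matrix`.
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.4), 2,
#'                  dimnames = list(c("cg1", "cg2"), c("s1", "s2"))))
#' @export
beta_matrix <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("beta values must be a numeric matrix")
  if (!is.null(cpg_ids)) rownames(values) <- cpg_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_beta_matrix(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Validate the beta-matrix invariants
#'
#' Checks: numeric matrix, unique non-missing row and column names, and all
#' non-missing values in \[0, 1\].
#'
#' @param values numeric matrix.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(values) {
  if (is.null(rownames(values)) || anyNA(rownames(values)))
    stopf("beta matrix requires CpG ids as row names")
  if (is.null(colnames(values)) || anyNA(colnames(values)))
    stopf("beta matrix requires sample ids as column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate CpG ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("beta value out of [0,1] at CpG '%s', sample '%s' (value %g)",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
          values[bad[1, 1], bad[1, 2]])
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  y <- unclass(x)
  print(y[seq_len(min(5, nrow(y))), seq_len(min(6, ncol(y))), drop = FALSE],
        ...)
  if (nrow(x) > 5) cat(sprintf("... %d more CpGs\n", nrow(x) - 5L))
  invisible(x)
}

# subsetting keeps the class when the result is still a matrix
#' @export
`[.beta_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("beta_matrix", "matrix", "array")
  out
}

#' Construct a validated study design table
#'
#' One row per sample. Enforces the study structure: each donor contributes
#' at most one sample per passage group, and a donor's age group is
#' constant.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param donor_id character vector of donor identifiers.
#' @param passage_group factor/character, one of `"early"`, `"late"`.
#' @param age_group factor/character, one of `"young"`, `"elderly"`.
#' @param age_years optional numeric donor age in years.
#' @param passage_number optional integer passage index.
#' @return a `data.frame` of class `study_design`.
#' @export
study_design <- function(sample_id, donor_id, passage_group, age_group,
                         age_years = NA_real_, passage_number = NA_integer_) {
  d <- data.frame(sample_id = as.character(sample_id),
                  donor_id = as.character(donor_id),
                  passage_group = as.character(passage_group),
                  age_group = as.character(age_group),
                  age_years = as.numeric(age_years),
                  passage_number = as.integer(passage_number),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id))
    stopf("duplicate sample ids in study design")
  if (!all(d$passage_group %in% c("early", "late")))
    stopf("passage_group must be 'early' or 'late'")
  if (!all(d$age_group %in% c("young", "elderly")))
    stopf("age_group must be 'young' or 'elderly'")
  if (anyDuplicated(d[, c("donor_id", "passage_group")]))
    stopf("a donor has more than one sample in the same passage group")
  byd <- tapply(d$age_group, d$donor_id, function(g) length(unique(g)))
  if (any(byd > 1))
    stopf("age_group differs within donor(s): %s",
          paste(names(byd)[byd > 1], collapse = ", "))
  class(d) <- c("study_design", "data.frame")
  d
}

#' Construct a gene-set collection
#'
#' A named list of gene sets (GO-style categories, cytogenetic bands,
#' transcription-factor target lists) used by the over-representation test.
#' Member symbols are uppercased and deduplicated per set.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional named character vector of set descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stopf("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stopf("duplicate gene-set names")
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    if (length(g) == 0) stopf("gene sets must be non-empty")
    g
  })
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- setNames(as.character(descriptions[names(sets)]),
                             names(sets))
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %s\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else "NA"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Construct an expression matrix with present/absent calls
#'
#' Carrier for oligonucleotide expression-array data: log2 intensities and
#' per-cell detection calls (`"P"` present, `"M"` marginal, `"A"` absent),
#' plus the probe-to-gene-symbol map used for matching with methylation
#' data. Symbols are uppercased.
#'
#' @param intensity numeric probe-by-sample matrix of log2 intensities.
#' @param calls character matrix of the same shape with values in P/M/A.
#' @param probe_to_symbol named character vector mapping probe ids to gene
#'   symbols (`NA` allowed for unannotated probes).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensity, calls, probe_to_symbol) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stopf("intensity must be a numeric matrix")
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stopf("intensity requires unique probe ids as row names")
  if (!identical(dim(intensity), dim(calls)))
    stopf("intensity and call matrices must share shape")
  if (!all(calls %in% c("P", "M", "A")))
    stopf("calls must be 'P', 'M' or 'A'")
  dimnames(calls) <- dimnames(intensity)
  sym <- toupper(as.character(probe_to_symbol))
  sym[probe_to_symbol %in% c(NA, "", "NA")] <- NA_character_
  names(sym) <- names(probe_to_symbol)
  missing_probes <- setdiff(rownames(intensity), names(sym))
  if (length(missing_probes) > 0)
    sym[missing_probes] <- NA_character_
  structure(list(intensity = intensity, calls = calls,
                 probe_to_symbol = sym[rownames(intensity)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d with symbol)\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(!is.na(x$probe_to_symbol))))
  invisible(x)
}

#' Parse a cytogenetic band string
#'
#' Splits strings such as `"10q22"` or `"Xp11.2"` into chromosome, arm and
#' band components.
#'
#' @param band character vector of band strings.
#' @return a data.frame with columns `chromosome`, `arm`, `band` (`NA` rows
#'   for unparseable input).
#' @export
parse_band <- function(band) {
  m <- regmatches(band, regexec("^([0-9]{1,2}|X|Y)([pq])([0-9]+(\\.[0-9]+)?)$",
                                as.character(band)))
  out <- data.frame(chromosome = NA_character_, arm = NA_character_,
                    band = NA_character_, stringsAsFactors = FALSE)[rep(1, length(band)), , drop = FALSE]
  rownames(out) <- NULL
  ok <- lengths(m) >= 4
  out$chromosome[ok] <- vapply(m[ok], `[`, "", 2)
  out$arm[ok] <- vapply(m[ok], `[`, "", 3)
  out$band[ok] <- vapply(m[ok], `[`, "", 4)
  out
}

#' Validate a CpG annotation table
#'
#' @param ann data.frame with columns `cpg_id`, `gene_symbol`, `chromosome`,
#'   `band`, `island_id`, `neighbor_offsets` (comma-separated base-pair
#'   offsets, possibly empty).
#' @return the annotation with symbols uppercased, class `cpg_annotation`.
#' @export
cpg_annotation <- function(ann) {
  need <- c("cpg_id", "gene_symbol", "chromosome", "band", "island_id",
            "neighbor_offsets")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cpg_id)) stopf("duplicate cpg_id in annotation")
  ann$gene_symbol <- toupper(as.character(ann$gene_symbol))
  ann$gene_symbol[ann$gene_symbol %in% c("", "NA")] <- NA_character_
  for (col in c("island_id", "band", "chromosome")) {
    ann[[col]] <- as.character(ann[[col]])
    ann[[col]][ann[[col]] %in% c("", "NA")] <- NA_character_
  }
  ann$neighbor_offsets <- as.character(ann$neighbor_offsets)
  ann$neighbor_offsets[is.na(ann$neighbor_offsets)] <- ""
  parsed <- parse_band(ann$band)
  bad <- !is.na(ann$band) & ann$band != "" & is.na(parsed$chromosome)
  if (any(bad))
    warnf("%d annotation band string(s) do not parse (e.g. '%s')",
          sum(bad), ann$band[which(bad)[1]])
  class(ann) <- c("cpg_annotation", "data.frame")
  ann
}

#' Split comma-separated neighbor offsets into integer vectors
#'
#' @param offsets character vector as stored in the annotation.
#' @return list of integer vectors (empty for CpGs without island neighbors).
#' @export
neighbor_offset_list <- function(offsets) {
  lapply(strsplit(as.character(offsets), ","), function(x) {
    x <- x[x != "" & !is.na(x)]
    as.integer(x)
  })
}
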