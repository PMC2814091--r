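# Readers and writers for every external format the pipeline touches.
# All tables are tab-separated UTF-8 with "." as decimal separator; missing
# beta values are accepted as empty cells or "NA" and written as "NA".

read_table_checked <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "",
                    na.strings = character(0))
}

#' Read a CpG-by-sample beta matrix from TSV
#'
#' Expects a header row of sample ids and a first column of CpG ids; all
#' remaining cells are methylation fractions in \[0, 1\] (empty or `"NA"`
#' for missing). Values outside the range and non-numeric cells are hard
#' errors naming the offending cell.
#'
#' @param path file path.
#' @return a [beta_matrix()].
#' @seealso [write_beta_tsv()]
#' @export
read_beta_tsv <- function(path) {
  tab <- read_table_checked(path)
  if (ncol(tab) < 2) stopf("beta TSV needs a CpG-id column plus >=1 sample")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate CpG ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-numeric beta value '%s' at CpG '%s', sample '%s'",
          vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
          colnames(vals)[bad[1, 2]])
  dimnames(num) <- list(ids, colnames(vals))
  beta_matrix(num)
}

#' Write a beta matrix to TSV
#'
#' @param beta a [beta_matrix()] (or plain numeric matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(cpg_id = rownames(beta), unclass(beta),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GEO series-matrix text file
#'
#' Parses the series-matrix dialect: `!`-prefixed header lines followed by
#' one data table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end`. Quoted fields are dequoted.
#' `!Sample_characteristics_ch1` lines of the form `"key: value"` are
#' exposed as per-sample key-value metadata for study-design construction.
#'
#' @param path file path.
#' @return a list with elements `matrix` (numeric, probe-by-sample; values
#'   of `"null"`/`"NA"`/empty become `NA`) and `sample_metadata` (data.frame
#'   with one row per sample: `sample_id`, `title`, plus one column per
#'   characteristics key).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stopf("series-matrix table sentinels missing or malformed in %s", path)

  dequote <- function(x) gsub('^"|"$', "", x)
  split_line <- function(l) dequote(strsplit(l, "\t", fixed = TRUE)[[1]])

  header <- lines[seq_len(beg - 1)]
  meta <- list()
  for (l in grep("^!Sample_", header, value = TRUE)) {
    f <- split_line(l)
    key <- sub("^!", "", f[1])
    meta[[key]] <- c(meta[[key]], list(f[-1]))
  }
  accession <- meta[["Sample_geo_accession"]][[1]] %||% NULL
  title <- meta[["Sample_title"]][[1]] %||% NULL

  tab_lines <- lines[(beg + 1):(end - 1)]
  fields <- lapply(tab_lines, split_line)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1)
    stopf("ragged series-matrix table: rows of width %s",
          paste(unique(widths), collapse = ", "))
  hdr <- fields[[1]]
  sample_ids <- hdr[-1]
  body <- fields[-1]
  ids <- vapply(body, `[`, "", 1)
  raw <- t(vapply(body, function(f) f[-1], character(length(sample_ids))))
  if (length(sample_ids) == 1) raw <- matrix(raw, ncol = 1)
  raw[raw %in% c("null", "NA", "")] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  dimnames(num) <- list(ids, sample_ids)

  md <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(title) && length(title) == length(sample_ids))
    md$title <- title
  if (!is.null(accession) && length(accession) == length(sample_ids))
    md$geo_accession <- accession
  for (chars in meta[["Sample_characteristics_ch1"]] %||% list()) {
    if (length(chars) != length(sample_ids)) next
    kv <- regmatches(chars, regexec("^\\s*([^:]+):\\s*(.*)$", chars))
    keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else NA_character_, "")
    vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else NA_character_, "")
    key <- unique(keys[!is.na(keys)])
    if (length(key) == 1) {
      md[[make.names(key)]] <- vals
    } else {
      md[[paste0("characteristics_", ncol(md))]] <- chars
    }
  }
  list(matrix = num, sample_metadata = md)
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: name, description, member symbols.
#' Symbols are uppercased and deduplicated. A line with fewer than three
#' fields is an error reporting the line number.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("GMT line %d has %d field(s); need name, description, members",
            i, length(f))
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CpG annotation manifest from TSV
#'
#' Columns: `cpg_id`, `gene_symbol`, `chromosome`, `band`, `island_id`,
#' `neighbor_offsets` (comma-separated base-pair offsets of adjacent island
#' CpGs).
#'
#' @param path file path.
#' @return a [cpg_annotation()] data.frame.
#' @export
read_annotation_tsv <- function(path) {
  cpg_annotation(read_table_checked(path))
}

#' Write a CpG annotation manifest to TSV
#'
#' @param ann a [cpg_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix with present/absent calls from TSV
#'
#' Layout written by [write_expression_tsv()]: columns `probe_id`,
#' `gene_symbol`, one log2-intensity column per sample, then one `_call`
#' column per sample with values in P/M/A.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  tab <- read_table_checked(path)
  call_cols <- grep("_call$", names(tab), value = TRUE)
  samp <- sub("_call$", "", call_cols)
  if (length(samp) == 0 || !all(samp %in% names(tab)))
    stopf("expression TSV needs paired '<sample>' and '<sample>_call' columns")
  intensity <- as.matrix(tab[, samp, drop = FALSE])
  intensity <- matrix(as.numeric(intensity), nrow(tab),
                      dimnames = list(tab$probe_id, samp))
  calls <- as.matrix(tab[, call_cols, drop = FALSE])
  dimnames(calls) <- list(tab$probe_id, samp)
  expression_matrix(intensity, calls,
                    setNames(tab$gene_symbol, tab$probe_id))
}

#' Write an expression matrix with present/absent calls to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr$intensity),
                   gene_symbol = unname(expr$probe_to_symbol),
                   expr$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  calls <- expr$calls
  colnames(calls) <- paste0(colnames(calls), "_call")
  df <- cbind(df, calls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a study design table from TSV
#'
#' @param path file path with columns `sample_id`, `donor_id`,
#'   `passage_group`, `age_group` and optionally `age_years`,
#'   `passage_number`.
#' @return a [study_design()].
#' @export
read_design_tsv <- function(path) {
  tab <- read_table_checked(path)
  study_design(tab$sample_id, tab$donor_id, tab$passage_group, tab$age_group,
               age_years = suppressWarnings(as.numeric(tab$age_years %||% NA)),
               passage_number = suppressWarnings(
                 as.integer(tab$passage_number %||% NA)))
}

#' Write a study design table to TSV
#'
#' @param design a [study_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read pyrosequencing percent-methylation profiles from CSV
#'
#' Long format, one row per island CpG position per sample:
#' `island_id, target_cpg_id, position_bp, sample_id, percent_meth`.
#' Percentages must lie in \[0, 100\].
#'
#' @param path file path.
#' @return a data.frame of class `pyro_profiles`.
#' @export
read_pyro_csv <- function(path) {
  tab <- read_table_checked(path, sep = ",")
  need <- c("island_id", "target_cpg_id", "position_bp", "sample_id",
            "percent_meth")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stopf("pyro CSV lacks column(s): %s", paste(miss, collapse = ", "))
  tab$position_bp <- as.integer(tab$position_bp)
  tab$percent_meth <- as.numeric(tab$percent_meth)
  if (any(!is.na(tab$percent_meth) &
          (tab$percent_meth < 0 | tab$percent_meth > 100)))
    stopf("pyro percent methylation outside [0,100] in %s", path)
  class(tab) <- c("pyro_profiles", "data.frame")
  tab
}

#' Write pyrosequencing profiles to CSV
#'
#' @param pyro a `pyro_profiles` data.frame (see [read_pyro_csv()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pyro_csv <- function(pyro, path) {
  utils::write.table(as.data.frame(pyro), path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a synthetic ground-truth table from TSV
#'
#' @param path file path.
#' @return data.frame with per-CpG true deltas and labels per contrast.
#' @export
read_truth_tsv <- function(path) {
  tab <- read_table_checked(path)
  tab$delta_culture <- as.numeric(tab$delta_culture)
  tab$delta_aging <- as.numeric(tab$delta_aging)
  tab
}

#' Write a synthetic ground-truth table to TSV
#'
#' @param truth truth table from [generate_methylation_study()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
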