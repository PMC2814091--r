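# fixture builders shared across test files; everything is generated in
# code, nothing is read from disk except files the tests write themselves

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_vals <- function(x) pmin(0.99, pmax(0.01, x))

rand_beta <- function(n = 5, m = 4, na_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(round(runif(n * m), 6), n, m,
              dimnames = list(sprintf("cg%03d", seq_len(n)),
                              sprintf("S%d", seq_len(m))))
  if (na_frac > 0) v[sample(length(v), ceiling(na_frac * length(v)))] <- NA
  beta_matrix(v)
}

# the standard 16-sample design: 8 donors, 4 young / 4 elderly, early+late
design16 <- function() {
  donors <- sprintf("D%d", 1:8)
  study_design(
    sample_id = paste0(rep(donors, each = 2), "_",
                       rep(c("early", "late"), 8)),
    donor_id = rep(donors, each = 2),
    passage_group = rep(c("early", "late"), 8),
    age_group = rep(rep(c("young", "elderly"), each = 4), each = 2),
    age_years = rep(c(25, 30, 40, 48, 55, 60, 70, 81), each = 2),
    passage_number = rep(c(2L, 10L), 8))
}

# deterministic beta matrix for the 16-sample design: baseline + culture
# effect (late) + aging effect (elderly), plus small fixed jitter
design_beta <- function(n = 50, culture = numeric(n), aging = numeric(n),
                        baseline = rep(0.4, n), noise_sd = 0.005,
                        seed = 42) {
  set.seed(seed)
  d <- design16()
  v <- matrix(NA_real_, n, nrow(d),
              dimnames = list(sprintf("cg%03d", seq_len(n)), d$sample_id))
  for (j in seq_len(nrow(d))) {
    mu <- baseline + culture * (d$passage_group[j] == "late") +
      aging * (d$age_group[j] == "elderly")
    v[, j] <- pmin(0.999, pmax(0.001, mu + rnorm(n, 0, noise_sd)))
  }
  list(beta = beta_matrix(v), design = d)
}

write_geo_fixture <- function(path, quoted = TRUE, end_sentinel = TRUE,
                              ragged = FALSE) {
  q <- function(x) if (quoted) sprintf('"%s"', x) else x
  lines <- c(
    "!Series_title\t\"tiny fixture\"",
    paste("!Sample_title", q("donor 1 early"), q("donor 1 late"),
          sep = "\t"),
    paste("!Sample_geo_accession", q("GSM0001"), q("GSM0002"), sep = "\t"),
    paste("!Sample_characteristics_ch1", q("age: 25"), q("age: 25"),
          sep = "\t"),
    paste("!Sample_characteristics_ch1", q("passage: P2"), q("passage: P10"),
          sep = "\t"),
    "!series_matrix_table_begin",
    paste(q("ID_REF"), q("GSM0001"), q("GSM0002"), sep = "\t"),
    paste(q("cg001"), "0.10", "0.90", sep = "\t"),
    if (ragged) paste(q("cg002"), "0.20", sep = "\t")
    else paste(q("cg002"), "0.20", "0.80", sep = "\t"),
    paste(q("cg003"), "null", "0.70", sep = "\t"),
    if (end_sentinel) "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

tiny_annotation <- function() {
  cpg_annotation(data.frame(
    cpg_id = sprintf("cg%03d", 1:6),
    gene_symbol = c("DLX5", "DLX5", "RUNX3", "CDKN2B", NA, "HOXA5"),
    chromosome = c("7", "7", "1", "9", "3", "7"),
    band = c("7q21", "7q21", "1p36", "9p21", "3q11", "7p15"),
    island_id = c("isl_DLX5", "isl_DLX5", "isl_RUNX3", NA, NA, "isl_HOXA5"),
    neighbor_offsets = c("-24,12,36", "-12,24", "-36,-12,12", "", "", "12,24"),
    stringsAsFactors = FALSE))
}
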