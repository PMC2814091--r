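mk_expr <- function(int, calls, symbols) {
  expression_matrix(int, calls, symbols)
}

test_that("present_filter uses a strict fraction threshold", {
  int <- matrix(8, 3, 6, dimnames = list(c("p1", "p2", "p3"),
                                         sprintf("S%d", 1:6)))
  calls <- matrix("A", 3, 6, dimnames = dimnames(int))
  calls["p1", 1:3] <- "P"   # 3 of 6 = 0.5: excluded (strict >)
  calls["p2", 1:4] <- "P"   # 4 of 6: retained
  ex <- mk_expr(int, calls, c(p1 = "A1", p2 = "A2", p3 = "A3"))
  expect_equal(present_filter(ex), "p2")
  expect_setequal(present_filter(ex, 0.4), c("p1", "p2"))
})

test_that("match_by_symbol aggregates a gene's probe sets and counts misses", {
  set.seed(9)
  int <- matrix(c(10, 6, 8, 9, 5, 8), 3, 2,
                dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  calls <- matrix("P", 3, 2, dimnames = dimnames(int))
  ex <- mk_expr(int, calls, c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB"))
  ann <- cpg_annotation(data.frame(
    cpg_id = c("cg1", "cg2", "cg3"),
    gene_symbol = c("GENEA", "NOMATCH", NA),
    chromosome = "1", band = "1q21", island_id = NA,
    neighbor_offsets = "", stringsAsFactors = FALSE))
  m <- match_by_symbol(ann, ex)
  expect_equal(m$gene_expression["GENEA", ],
               c(S1 = mean(c(10, 6)), S2 = mean(c(9, 5))))
  expect_equal(m$cpg_gene$cpg_id, "cg1")
  expect_equal(m$n_cpgs_unmatched, 1L)
  expect_equal(m$n_cpgs_unannotated, 1L)
  # max aggregation picks the probe set with the highest mean intensity
  mx <- match_by_symbol(ann, ex, aggregation = "max")
  expect_equal(mx$gene_expression["GENEA", ], c(S1 = 10, S2 = 9))
})

test_that("present_filter and match_by_symbol commute", {
  p <- simulation_params(n_cpgs = 300, n_dm_culture = c(hyper = 5, hypo = 5),
                         n_dm_aging = c(hyper = 5, hypo = 5))
  gen <- generate_annotation(p, seed = 21)
  s <- generate_methylation_study(p, seed = 21)
  ex <- generate_expression(s$beta, gen$annotation, seed = 21)
  kept <- present_filter(ex)
  m1 <- match_by_symbol(gen$annotation, ex, probes = kept)
  # matching first, then dropping filtered probes
  m_all <- match_by_symbol(gen$annotation, ex)
  genes_kept <- unique(ex$probe_to_symbol[kept])
  expect_setequal(rownames(m1$gene_expression),
                  intersect(rownames(m_all$gene_expression),
                            genes_kept[!is.na(genes_kept)]))
})

test_that("expression bins decrease with methylation under negative coupling", {
  p <- simulation_params(n_cpgs = 500, n_dm_culture = c(hyper = 5, hypo = 5),
                         n_dm_aging = c(hyper = 5, hypo = 5))
  gen <- generate_annotation(p, seed = 31)
  s <- generate_methylation_study(p, seed = 31)
  ex <- generate_expression(s$beta, gen$annotation, slope = -4, seed = 31)
  m <- match_by_symbol(gen$annotation, ex)
  bins <- methylation_expression_summary(s$beta, m)
  filled <- bins[!bins$empty, ]
  expect_true(all(diff(filled$mean_intensity) < 0))
  # slope 0, noise 0: all bins share one mean
  ex0 <- generate_expression(s$beta, gen$annotation, slope = 0, noise_sd = 0,
                             seed = 31)
  m0 <- match_by_symbol(gen$annotation, ex0)
  bins0 <- methylation_expression_summary(s$beta, m0)
  expect_lt(diff(range(bins0$mean_intensity[!bins0$empty])), 1e-12)
})

test_that("an empty middle bin is flagged", {
  v <- matrix(rep(c(0.05, 0.95), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("S%d", 1:4)))
  ann <- cpg_annotation(data.frame(
    cpg_id = c("cg1", "cg2"), gene_symbol = c("GA", "GB"), chromosome = "1",
    band = "1q21", island_id = NA, neighbor_offsets = "",
    stringsAsFactors = FALSE))
  int <- matrix(8, 2, 4, dimnames = list(c("p1", "p2"), sprintf("S%d", 1:4)))
  calls <- matrix("P", 2, 4, dimnames = dimnames(int))
  ex <- mk_expr(int, calls, c(p1 = "GA", p2 = "GB"))
  m <- match_by_symbol(ann, ex)
  expect_warning(bins <- methylation_expression_summary(beta_matrix(v), m),
                 "empty")
  expect_true(bins$empty[2])
})

test_that("delta_vs_expression: exact anticoupling and agreement bookkeeping", {
  f <- design_beta(20, culture = c(0, seq(-0.3, 0.3, length.out = 19)),
                   noise_sd = 0, seed = 3)
  res <- contrast_stats(f$beta, f$design, culture_contrast())
  ann <- cpg_annotation(data.frame(
    cpg_id = rownames(f$beta), gene_symbol = sprintf("G%02d", 1:20),
    chromosome = "1", band = "1q21", island_id = NA, neighbor_offsets = "",
    stringsAsFactors = FALSE))
  int <- matrix(8, 20, 16, dimnames = list(sprintf("p%02d", 1:20),
                                           colnames(f$beta)))
  calls <- matrix("P", 20, 16, dimnames = dimnames(int))
  ex <- mk_expr(int, calls, setNames(sprintf("G%02d", 1:20),
                                     sprintf("p%02d", 1:20)))
  m <- match_by_symbol(ann, ex)
  ratios <- setNames(-2 * res$delta, sprintf("G%02d", 1:20))
  out <- delta_vs_expression(res, ratios, m, candidates = sprintf("G%02d", 1:6))
  expect_equal(out$correlation, -1, tolerance = 1e-10)
  expect_equal(out$candidate_agreement, 1)
  # a zero delta is excluded from the agreement denominator
  zero_gene <- out$pairs$gene_symbol[abs(out$pairs$delta) < 1e-12]
  expect_true(all(is.na(out$pairs$agreement[out$pairs$gene_symbol %in% zero_gene])))
  # independent ratios: correlation small
  set.seed(10)
  out2 <- delta_vs_expression(res, setNames(rnorm(20), names(ratios)), m)
  expect_lt(abs(out2$correlation), 0.6)
})

test_that("compare_platforms recovers offsets and is shift-invariant in deltas", {
  # baseline 0.5 keeps all shifted values clear of the [0, 1] clip bounds
  f <- design_beta(6, culture = c(0.3, -0.25, 0.2, 0.15, -0.3, 0.1),
                   baseline = rep(0.5, 6), noise_sd = 0.002, seed = 8)
  ann <- cpg_annotation(data.frame(
    cpg_id = rownames(f$beta), gene_symbol = sprintf("G%d", 1:6),
    chromosome = "1", band = "1q21", island_id = paste0("isl_", 1:6),
    neighbor_offsets = "-12,12", stringsAsFactors = FALSE))
  # pyro identical to the array
  pyro0 <- generate_pyro_profiles(f$beta, ann, target_cpgs = rownames(f$beta),
                                  platform_offset = 0, jitter_sd = 0, seed = 1)
  plat0 <- compare_platforms(f$beta, pyro0, f$design, culture_contrast())
  expect_equal(plat0$per_cpg$offset, rep(0, 6), tolerance = 1e-12)
  expect_equal(plat0$delta_correlation, 1, tolerance = 1e-10)
  # constant platform shift: offset recovered, deltas identical
  pyro1 <- generate_pyro_profiles(f$beta, ann, target_cpgs = rownames(f$beta),
                                  platform_offset = -0.1, jitter_sd = 0,
                                  seed = 1)
  plat1 <- compare_platforms(f$beta, pyro1, f$design, culture_contrast())
  expect_equal(plat1$per_cpg$offset, rep(-0.1, 6), tolerance = 1e-12)
  expect_equal(plat1$per_cpg$delta_pyro, plat1$per_cpg$delta_array,
               tolerance = 1e-12)
  expect_equal(plat1$delta_correlation, plat0$delta_correlation,
               tolerance = 1e-10)
  # a missing target CpG is an error
  expect_error(
    compare_platforms(f$beta[-1, ], pyro0, f$design, culture_contrast()),
    "absent from beta")
})
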