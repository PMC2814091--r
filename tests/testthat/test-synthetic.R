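small_params <- function(...) {
  defaults <- list(n_cpgs = 600, n_dm_culture = c(hyper = 10, hypo = 10),
                   n_dm_aging = c(hyper = 15, hypo = 15))
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

test_that("parameter validation catches invalid settings", {
  expect_error(simulation_params(n_cpgs = 0), "n_cpgs")
  expect_error(simulation_params(phi = -1), "phi")
  expect_error(simulation_params(n_cpgs = 10,
                                 n_dm_culture = c(hyper = 20, hypo = 0)),
               "exceed")
  expect_error(simulation_params(shared_fraction = 1.5), "shared_fraction")
  expect_error(simulation_params(effect_range = c(0.4, 0.2)), "effect_range")
})

test_that("generators are deterministic under a fixed seed", {
  p <- small_params()
  a1 <- generate_annotation(p, seed = 11)
  a2 <- generate_annotation(p, seed = 11)
  expect_identical(a1, a2)
  s1 <- generate_methylation_study(p, seed = 11)
  s2 <- generate_methylation_study(p, seed = 11)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_methylation_study(p, seed = 12)
  expect_false(identical(unclass(s1$beta), unclass(s3$beta)))
  e1 <- generate_expression(s1$beta, a1$annotation, seed = 5)
  e2 <- generate_expression(s1$beta, a1$annotation, seed = 5)
  expect_identical(e1, e2)
})

test_that("annotation structure: genes, bands, sets, islands", {
  p <- small_params()
  gen <- generate_annotation(p, seed = 2)
  ann <- gen$annotation
  expect_equal(nrow(ann), p$n_cpgs)
  expect_false(anyDuplicated(ann$cpg_id) > 0)
  cpgs_per_gene <- table(ann$gene_symbol)
  expect_true(all(cpgs_per_gene >= 1 & cpgs_per_gene <= 3))
  # set members are drawn from the gene universe
  universe <- unique(ann$gene_symbol)
  for (s in gen$gene_sets$sets) expect_true(all(s %in% universe))
  expect_true("SP1_TARGETS" %in% names(gen$gene_sets$sets))
  # band strings parse and round-trip through the annotation reader
  parsed <- parse_band(ann$band)
  expect_false(anyNA(parsed$chromosome))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, path)
  expect_equal(as.data.frame(read_annotation_tsv(path)), as.data.frame(ann))
  # island CpGs carry neighbor offsets
  offs <- neighbor_offset_list(ann$neighbor_offsets)
  has_isl <- !is.na(ann$island_id)
  expect_true(all(lengths(offs[has_isl]) >= 2))
  expect_true(all(lengths(offs[!has_isl]) == 0))
})

test_that("methylation study honors design, bounds and truth labels", {
  p <- small_params()
  s <- generate_methylation_study(p, seed = 3)
  expect_equal(dim(s$beta), c(600L, 16L))
  expect_true(all(unclass(s$beta) >= 0 & unclass(s$beta) <= 1))
  d <- s$design
  expect_equal(sum(d$passage_group == "early"), 8L)
  expect_equal(length(unique(d$donor_id)), 8L)
  expect_equal(length(unique(d$donor_id[d$age_group == "young"])), 4L)
  expect_true(all(d$passage_number[d$passage_group == "early"] == 2L))
  expect_true(all(d$passage_number[d$passage_group == "late"] %in% 8:15))
  tr <- s$truth
  expect_equal(sum(tr$label_culture == "hyper"), 10L)
  expect_equal(sum(tr$label_culture == "hypo"), 10L)
  expect_equal(sum(tr$label_aging != "null"), 30L)
  expect_true(all((tr$delta_culture == 0) == (tr$label_culture == "null")))
  expect_true(all(sign(tr$delta_culture[tr$label_culture == "hyper"]) == 1))
  expect_true(all(abs(tr$delta_aging) <= p$effect_range[2]))
  # shared fraction: overlap of DM sets matches the parameter
  n_shared <- sum(tr$label_culture != "null" & tr$label_aging != "null")
  expect_equal(n_shared, round(0.5 * 20))
})

test_that("generated effects are recovered in the observed group means", {
  # law-of-large-numbers check: 100 hyper CpGs at exactly +0.30, phi = 200
  p <- simulation_params(n_cpgs = 2000,
                         n_dm_culture = c(hyper = 100, hypo = 0),
                         n_dm_aging = c(hyper = 0, hypo = 0),
                         effect_range = c(0.30, 0.30), phi = 200)
  s <- generate_methylation_study(p, seed = 8)
  res <- contrast_stats(s$beta, s$design, culture_contrast())
  # clipped CpGs (baseline too high for a +0.30 shift) are flagged in the
  # truth table and excluded: their realized effect is deliberately smaller
  dm <- s$truth$label_culture == "hyper" & !s$truth$mean_clipped
  expect_equal(mean(res$delta[dm]), 0.30, tolerance = 0.02 / 0.30)
  expect_lt(abs(mean(res$delta[!dm])), 0.005)
})

test_that("passage drift scales the culture effect with passage number", {
  p <- small_params(passage_drift = 0.125, effect_range = c(0.3, 0.3),
                    n_dm_culture = c(hyper = 40, hypo = 0),
                    n_dm_aging = c(hyper = 0, hypo = 0), phi = 5000)
  s <- generate_methylation_study(p, seed = 9)
  dm <- s$truth$label_culture == "hyper" & !s$truth$mean_clipped
  d <- s$design
  late <- d[d$passage_group == "late", ]
  # realized effect ~ 0.3 * min(1, 0.125 * (p - 2)); P10 and beyond saturate
  early_mean <- rowMeans(unclass(s$beta)[dm, d$sample_id[d$passage_group == "early"]])
  for (j in seq_len(nrow(late))) {
    eff <- mean(unclass(s$beta)[dm, late$sample_id[j]] - early_mean)
    expect_equal(eff, 0.3 * min(1, 0.125 * (late$passage_number[j] - 2)),
                 tolerance = 0.15)
  }
})

test_that("intensity generation round-trips through compute_beta", {
  b <- rand_beta(50, 4, seed = 7)
  # zero noise, zero offset: exact identity
  ip <- generate_intensities(b, total_intensity = 4000, alpha = 0,
                             noise_sd = 0, seed = 1)
  expect_equal(unclass(compute_beta(ip, alpha = 0)), unclass(b),
               tolerance = 1e-12)
  # zero noise with the default offset: still exact (the generator inverts
  # the offset) for betas below total/(total+alpha), the invertible range
  b_inv <- beta_matrix(pmin(unclass(b), 0.985))
  ip2 <- generate_intensities(b_inv, alpha = 100, noise_sd = 0, seed = 1)
  expect_equal(unclass(compute_beta(ip2, alpha = 100)), unclass(b_inv),
               tolerance = 1e-9)
  # beta = 0 produces an empty methylated channel
  b0 <- beta_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  ip0 <- generate_intensities(b0, noise_sd = 0, seed = 1)
  expect_true(all(ip0$M == 0))
  # default noise: mean absolute round-trip error below 0.02 over 1000 CpGs
  bb <- rand_beta(1000, 2, seed = 8)
  ip3 <- generate_intensities(bb, seed = 3)
  err <- abs(unclass(compute_beta(ip3, alpha = 100)) - unclass(bb))
  expect_lt(mean(err), 0.02)
})

test_that("expression coupling: constant at slope 0, negative at slope -4", {
  p <- small_params()
  gen <- generate_annotation(p, seed = 4)
  s <- generate_methylation_study(p, seed = 4)
  e0 <- generate_expression(s$beta, gen$annotation, slope = 0, noise_sd = 0,
                            seed = 1)
  expect_true(all(abs(e0$intensity - e0$intensity[1, 1]) < 1e-12))
  e <- generate_expression(s$beta, gen$annotation, slope = -4, seed = 1)
  ann <- gen$annotation
  gene_beta <- tapply(rowMeans(unclass(s$beta)), ann$gene_symbol, mean)
  probe_beta <- gene_beta[e$probe_to_symbol]
  expect_gt(length(probe_beta), 100)
  expect_lt(cor(probe_beta, rowMeans(e$intensity)), -0.8)
})

test_that("pyro profiles: exact offset at zero jitter, clipping, correlation", {
  b <- beta_matrix(matrix(seq(0.2, 0.7, length.out = 8), 2, 4, byrow = TRUE,
                          dimnames = list(c("cg001", "cg002"),
                                          paste0("S", 1:4))))
  ann <- cpg_annotation(data.frame(
    cpg_id = c("cg001", "cg002"), gene_symbol = c("G1", "G2"),
    chromosome = "1", band = "1q21", island_id = c("isl_G1", NA),
    neighbor_offsets = c("-12,12", ""), stringsAsFactors = FALSE))
  pyro <- generate_pyro_profiles(b, ann, target_cpgs = "cg001",
                                 platform_offset = -0.1, jitter_sd = 0,
                                 seed = 1)
  tgt <- pyro[pyro$position_bp == 0, ]
  expect_equal(tgt$percent_meth,
               100 * (unclass(b)["cg001", tgt$sample_id] - 0.1),
               ignore_attr = TRUE)
  expect_equal(sort(unique(pyro$position_bp)), c(-12L, 0L, 12L))
  # island with no neighbors: single-position profile
  single <- generate_pyro_profiles(b, ann, target_cpgs = "cg002",
                                   platform_offset = 0, jitter_sd = 0,
                                   seed = 1)
  expect_equal(unique(single$position_bp), 0L)
  # clipping keeps values in [0, 100]
  b2 <- beta_matrix(matrix(c(0.01, 0.99), 1, 2,
                           dimnames = list("cg001", c("S1", "S2"))))
  pyro2 <- generate_pyro_profiles(b2, ann[1, ], target_cpgs = "cg001",
                                  platform_offset = -0.2, jitter_sd = 0.3,
                                  seed = 2)
  expect_true(all(pyro2$percent_meth >= 0 & pyro2$percent_meth <= 100))
})

test_that("neighbor CpGs track the target at default jitter", {
  p <- small_params(n_dm_culture = c(hyper = 20, hypo = 0),
                    effect_range = c(0.3, 0.3))
  gen <- generate_annotation(p, seed = 6)
  s <- generate_methylation_study(p, seed = 6)
  targets <- s$truth$cpg_id[s$truth$label_culture == "hyper" &
                              !s$truth$mean_clipped &
                              !is.na(gen$annotation$island_id)]
  pyro <- generate_pyro_profiles(s$beta, gen$annotation,
                                 target_cpgs = head(targets, 8), seed = 6)
  plat <- compare_platforms(s$beta, pyro, s$design, culture_contrast())
  expect_true(all(plat$per_cpg$neighbor_correlation >= 0.8))
})
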