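# deterministic matrix on the 16-sample design where group values are set
# per CpG explicitly
two_group_beta <- function(vals_a, vals_b) {
  d <- design16()
  stopifnot(length(vals_a) == 8, length(vals_b) == 8)
  n <- 1
  v <- matrix(NA_real_, n, 16, dimnames = list("cg001", d$sample_id))
  v[1, d$sample_id[d$passage_group == "early"]] <- vals_a
  v[1, d$sample_id[d$passage_group == "late"]] <- vals_b
  list(beta = beta_matrix(v), design = d)
}

test_that("contrast_stats computes exact means, deltas and the textbook t", {
  f <- design_beta(3, culture = c(0.25, 0, -0.2), baseline = c(0.2, 0.5, 0.7),
                   noise_sd = 0)
  res <- contrast_stats(f$beta, f$design, culture_contrast())
  expect_equal(res$delta, c(0.25, 0, -0.2))
  expect_equal(res$mean_a, c(0.2, 0.5, 0.7))
  # identical groups: delta = 0, t = 0, p = 1
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)
  # nonzero delta with zero variance: p = 0
  expect_equal(res$p[1], 0)

  # hand-computed pooled-variance example: A=(.1,.2,.3), B=(.4,.5,.6)
  d3 <- study_design(sprintf("s%d", 1:6), sprintf("d%d", c(1:3, 1:3)),
                     rep(c("early", "late"), each = 3), rep("young", 6))
  b3 <- beta_matrix(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 1,
                           dimnames = list("cg1", d3$sample_id)))
  r3 <- contrast_stats(b3, d3, culture_contrast())
  expect_equal(r3$delta, 0.3)
  expect_equal(r3$t, 0.3 / sqrt(0.01 * (2 / 3)), tolerance = 1e-12)
  expect_equal(r3$p, 2 * pt(-0.3 / sqrt(0.01 * (2 / 3)), df = 4),
               tolerance = 1e-12)
})

test_that("unpaired and paired t match stats::t.test on random instances", {
  set.seed(501)
  d <- design16()
  for (i in 1:100) {
    v <- matrix(runif(16), 1, dimnames = list("cg1", d$sample_id))
    b <- beta_matrix(v)
    res <- contrast_stats(b, d, culture_contrast())
    a_vals <- v[1, d$passage_group == "early"]
    b_vals <- v[1, d$passage_group == "late"]
    tt <- t.test(b_vals, a_vals, var.equal = TRUE)
    expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)

    resp <- contrast_stats(b, d, culture_contrast(paired = TRUE))
    tp <- t.test(b_vals, a_vals, paired = TRUE)
    expect_equal(resp$t, unname(tp$statistic), tolerance = 1e-10)
    expect_equal(resp$p, tp$p.value, tolerance = 1e-10)
  }
})

test_that("q-values are BH over all tested CpGs and never below p", {
  f <- design_beta(60, culture = c(rep(0.3, 5), rep(0, 55)), seed = 2)
  res <- contrast_stats(f$beta, f$design, culture_contrast())
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("swapping contrast levels negates deltas and preserves |t|, p", {
  f <- design_beta(20, culture = runif(20, -0.3, 0.3), seed = 5)
  fwd <- contrast_stats(f$beta, f$design, culture_contrast())
  rev <- contrast_stats(f$beta, f$design,
                        contrast_spec("rev", "passage_group", "late",
                                      "early"))
  expect_equal(rev$delta, -fwd$delta)
  expect_equal(abs(rev$t), abs(fwd$t))
  expect_equal(rev$p, fwd$p)
  lab_f <- classify_dm(fwd, 0.2, NULL)$dm_label
  lab_r <- classify_dm(rev, 0.2, NULL)$dm_label
  expect_equal(lab_r[lab_f == "hyper"],
               rep("hypo", sum(lab_f == "hyper")))
  expect_equal(lab_r[lab_f == "hypo"],
               rep("hyper", sum(lab_f == "hypo")))
})

test_that("contrast preconditions and subsets", {
  f <- design_beta(3)
  d_small <- f$design[f$design$sample_id %in%
                        c("D1_early", "D1_late", "D2_late"), ]
  expect_error(contrast_stats(f$beta[, d_small$sample_id], d_small,
                              culture_contrast()),
               "'early' has 1 sample")
  # aging contrast restricts to early-passage samples
  res <- contrast_stats(f$beta, f$design, aging_contrast())
  expect_equal(res$n_a[1] + res$n_b[1], 8L)
  # subgroup subset: culture within young donors only
  res_y <- contrast_stats(f$beta, f$design,
                          culture_contrast(subset = list(age_group = "young")))
  expect_equal(res_y$n_a[1], 4L)
})

test_that("classify_dm uses strict thresholds and optional p gate", {
  res <- data.frame(cpg_id = c("a", "b", "c", "d", "e"),
                    delta = c(0.25, 0.20, -0.19, -0.21, 0.30),
                    p = c(1e-4, 1e-4, 1e-4, 1e-4, 0.5))
  class(res) <- c("contrast_result", "data.frame")
  lab <- classify_dm(res, 0.20, 0.01)$dm_label
  expect_equal(lab, c("hyper", "unchanged", "unchanged", "hypo", "unchanged"))
  # without a p gate the large-p CpG passes on delta alone
  lab2 <- classify_dm(res, 0.20, NULL)$dm_label
  expect_equal(lab2[5], "hyper")
  expect_error(classify_dm(res, 1.5), "delta_threshold")
})

test_that("hierarchical clustering: Euclidean average linkage, deterministic", {
  # two identical samples merge at height 0
  b <- beta_matrix(matrix(c(0.3, 0.3, 0.7, 0.3, 0.3, 0.7), 3,
                          dimnames = list(c("x", "y", "z"), c("S1", "S2"))))
  cl <- hierarchical_cluster(b, "samples")
  expect_equal(cl$height[1], 0)
  # 1-D points {0, 0.1, 0.9}: the close pair merges first at 0.1
  b2 <- beta_matrix(matrix(c(0, 0.1, 0.9), 3,
                           dimnames = list(c("a", "b", "c"), "S1")))
  cl2 <- hierarchical_cluster(b2, "cpgs")
  expect_equal(cl2$height[1], 0.1)
  expect_setequal(-cl2$merge[1, ], c(1, 2))
  # average linkage: the final merge height is mean(|0.9-0|, |0.9-0.1|)
  expect_equal(cl2$height[2], mean(c(0.9, 0.8)))
  # relabeling equivariance of the leaf ordering
  x <- rand_beta(8, 4, seed = 12)
  ord <- hierarchical_cluster(x, "cpgs")$labels
  perm <- sample(8)
  ord_p <- hierarchical_cluster(x[perm, ], "cpgs")$labels
  expect_setequal(ord_p, ord)
  expect_error(hierarchical_cluster(x[1, , drop = FALSE], "cpgs"), ">= 2")
})
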