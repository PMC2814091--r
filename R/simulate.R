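# Synthetic-data generator: annotation, methylation study, intensity-level
# data, coupled expression, and pyrosequencing profiles, with ground truth
# for recovery tests.

# JSON configs serialize named count vectors as plain arrays; accept an
# unnamed pair positionally as (hyper, hypo)
as_dm_counts <- function(v) {
  v <- unlist(v)
  if (is.null(names(v)) && length(v) == 2) names(v) <- c("hyper", "hypo")
  v
}

#' Simulation parameters for the synthetic methylation study
#'
#' Defaults emulate the study design the pipeline targets: 8 bone-marrow
#' donors (4 young, 4 elderly), each sampled at an early (P2) and a late
#' (P8--P15) passage, 16 samples in total, assayed at promoter-biased CpGs
#' whose baseline methylation follows a low/intermediate/high beta mixture.
#' True differential methylation is additive on the beta scale; a fraction
#' of affected CpGs is shared between the long-term-culture and the aging
#' contrast with mostly concordant sign. Per-sample noise is beta-distributed
#' around the CpG mean with concentration `phi`.
#'
#' @param n_cpgs number of CpG sites.
#' @param n_donors total donors; `n_young` of them young, the rest elderly.
#' @param n_young number of young donors.
#' @param baseline_weights mixture weights of the low / intermediate / high
#'   baseline methylation modes (sum to 1).
#' @param baseline_shapes list of `c(shape1, shape2)` beta parameters for
#'   the three modes.
#' @param phi beta-distribution concentration of per-sample noise
#'   (variance `mu(1-mu)/(phi+1)`); larger is less noisy.
#' @param n_dm_culture named counts `c(hyper=, hypo=)` of truly
#'   differentially methylated CpGs in the culture (early vs late) contrast.
#' @param n_dm_aging same for the aging (young vs elderly) contrast.
#' @param effect_range range of true absolute delta-beta effects (fraction).
#' @param shared_fraction fraction of the smaller contrast's DM set that is
#'   shared with the other contrast.
#' @param sign_concordance probability that a shared CpG's aging effect has
#'   the same sign as its culture effect.
#' @param passage_drift optional fraction of the full culture effect gained
#'   per passage beyond P2; `NULL` (default) applies the full effect to all
#'   late-passage samples regardless of passage number.
#' @param expression_slope log2-intensity change per unit gene-mean beta
#'   (negative couples methylation to silencing).
#' @param expression_intercept log2 intensity of an unmethylated gene.
#' @param expression_noise_sd per-cell log2 noise standard deviation.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_cpgs = 27578,
                              n_donors = 8,
                              n_young = 4,
                              baseline_weights = c(low = 0.55, mid = 0.15,
                                                   high = 0.30),
                              baseline_shapes = list(low = c(2, 18),
                                                     mid = c(5, 5),
                                                     high = c(18, 2)),
                              phi = 200,
                              n_dm_culture = c(hyper = 29, hypo = 55),
                              n_dm_aging = c(hyper = 295, hypo = 349),
                              effect_range = c(0.15, 0.40),
                              shared_fraction = 0.5,
                              sign_concordance = 0.9,
                              passage_drift = NULL,
                              expression_slope = -4,
                              expression_intercept = 10,
                              expression_noise_sd = 0.5) {
  # coerce list-shaped input (e.g. from a JSON config) to numeric vectors
  p <- list(n_cpgs = as.integer(n_cpgs), n_donors = as.integer(n_donors),
            n_young = as.integer(n_young),
            baseline_weights = unlist(baseline_weights),
            baseline_shapes = lapply(baseline_shapes, unlist), phi = phi,
            n_dm_culture = as_dm_counts(n_dm_culture),
            n_dm_aging = as_dm_counts(n_dm_aging),
            effect_range = unlist(effect_range),
            shared_fraction = shared_fraction,
            sign_concordance = sign_concordance,
            passage_drift = passage_drift,
            expression_slope = expression_slope,
            expression_intercept = expression_intercept,
            expression_noise_sd = expression_noise_sd)
  if (!is_count(p$n_cpgs)) stopf("n_cpgs must be a positive integer")
  if (!is_count(p$n_donors) || p$n_donors < 2)
    stopf("n_donors must be an integer >= 2")
  if (p$n_young < 1 || p$n_young >= p$n_donors)
    stopf("n_young must leave at least one elderly donor")
  if (length(p$baseline_weights) != 3 ||
      abs(sum(p$baseline_weights) - 1) > 1e-8 || any(p$baseline_weights < 0))
    stopf("baseline_weights must be 3 non-negative weights summing to 1")
  if (!(is.numeric(p$phi) && p$phi > 0)) stopf("phi must be > 0")
  for (nm in c("n_dm_culture", "n_dm_aging")) {
    v <- p[[nm]]
    if (!all(c("hyper", "hypo") %in% names(v)) || any(v < 0))
      stopf("%s must be named non-negative counts c(hyper=, hypo=)", nm)
  }
  if (sum(p$n_dm_culture) > p$n_cpgs || sum(p$n_dm_aging) > p$n_cpgs)
    stopf("true DM counts exceed n_cpgs")
  if (length(p$effect_range) != 2 || any(p$effect_range <= 0) ||
      any(p$effect_range > 1) || p$effect_range[1] > p$effect_range[2])
    stopf("effect_range must be an increasing pair in (0, 1]")
  if (!is_fraction(p$shared_fraction))
    stopf("shared_fraction must be in [0, 1]")
  if (!is_fraction(p$sign_concordance))
    stopf("sign_concordance must be in [0, 1]")
  if (!is.null(p$passage_drift) &&
      !(is.numeric(p$passage_drift) && p$passage_drift > 0))
    stopf("passage_drift must be NULL or a positive fraction per passage")
  class(p) <- "simulation_params"
  p
}

#' Generate a synthetic CpG annotation and gene-set collection
#'
#' CpGs are grouped into genes (1--3 CpGs per gene, emulating promoter
#' assays), genes placed on cytogenetic bands, and organised into a
#' gene-set collection of GO-style functional categories plus one designated
#' transcription-factor target set (`SP1_TARGETS`). About 80% of CpGs belong
#' to a CpG island and carry base-pair offsets of neighboring island CpGs
#' for pyrosequencing emulation.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_sets number of GO-style functional sets.
#' @return list with `annotation` (a [cpg_annotation()]) and `gene_sets`
#'   (a [gene_set_collection()]).
#' @export
generate_annotation <- function(params, seed, n_sets = 12) {
  n <- params$n_cpgs
  with_seed(child_seed(seed, "annotation"), {
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, sample(1:3, max(16, ceiling(n / 2)), replace = TRUE,
                               prob = c(0.45, 0.40, 0.15)))
    sizes <- sizes[cumsum(sizes) - sizes < n]
    sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
    n_genes <- length(sizes)
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    chrom <- as.character(sample(1:22, n_genes, replace = TRUE))
    band <- paste0(chrom, sample(c("p", "q"), n_genes, replace = TRUE),
                   sample(11:25, n_genes, replace = TRUE))
    gene_of_cpg <- rep(seq_len(n_genes), sizes)
    cpg_id <- sprintf("cg%07d", seq_len(n))
    has_island <- stats::runif(n) < 0.8
    island_id <- ifelse(has_island, paste0("isl_", genes[gene_of_cpg]),
                        NA_character_)
    offsets <- vapply(seq_len(n), function(i) {
      if (!has_island[i]) return("")
      k <- sample(2:5, 1)
      paste(sort(sample(c(-(1:16) * 12, (1:16) * 12), k)), collapse = ",")
    }, "")
    ann <- cpg_annotation(data.frame(
      cpg_id = cpg_id,
      gene_symbol = genes[gene_of_cpg],
      chromosome = chrom[gene_of_cpg],
      band = band[gene_of_cpg],
      island_id = island_id,
      neighbor_offsets = offsets,
      stringsAsFactors = FALSE))
    sets <- list()
    desc <- character(0)
    for (k in seq_len(n_sets)) {
      nm <- sprintf("GO_SET_%02d", k)
      sz <- max(3, round(n_genes * stats::runif(1, 0.02, 0.08)))
      sets[[nm]] <- sample(genes, min(sz, n_genes))
      desc[nm] <- sprintf("synthetic functional category %d", k)
    }
    sets[["SP1_TARGETS"]] <- sample(genes, max(3, round(n_genes * 0.10)))
    desc["SP1_TARGETS"] <- "genes with SP1 binding sites in the promoter"
    list(annotation = ann, gene_sets = gene_set_collection(sets, desc))
  })
}

# allocate true effects for both contrasts, honoring per-direction counts,
# the shared fraction, and the sign-concordance probability. Each effect
# slot is placed on a CpG whose baseline leaves room for it (hypermethylation
# needs an unmethylated baseline and vice versa; a doubly affected CpG must
# accommodate both effects at once); only when no feasible CpG remains does
# the effect land on an infeasible one, where the sample mean will clip.
allocate_effects <- function(params, baseline) {
  n <- params$n_cpgs
  n_c <- sum(params$n_dm_culture)
  n_a <- sum(params$n_dm_aging)
  n_shared <- round(params$shared_fraction * min(n_c, n_a))
  if (n_c + n_a - n_shared > n) stopf("DM allocation exceeds n_cpgs")

  draw_mag <- function(k) stats::runif(k, params$effect_range[1],
                                       params$effect_range[2])
  sign_c <- rep(c(1, -1), c(params$n_dm_culture["hyper"],
                            params$n_dm_culture["hypo"]))[sample.int(n_c)]
  mag_c <- draw_mag(n_c)
  # the first n_shared culture slots are shared; their aging sign copies the
  # culture sign with probability sign_concordance
  sign_shared <- sign_c[seq_len(n_shared)] *
    ifelse(stats::runif(n_shared) < params$sign_concordance, 1, -1)
  want_hyper <- max(0, params$n_dm_aging["hyper"] - sum(sign_shared > 0))
  want_hypo <- max(0, params$n_dm_aging["hypo"] - sum(sign_shared < 0))
  k_only <- n_a - n_shared
  sign_only <- rep(c(1, -1), c(want_hyper, want_hypo))
  if (length(sign_only) > k_only) sign_only <- sign_only[seq_len(k_only)]
  if (length(sign_only) < k_only)
    sign_only <- c(sign_only, sample(c(1, -1), k_only - length(sign_only),
                                     replace = TRUE))
  sign_only <- sign_only[sample.int(max(k_only, 1))][seq_len(k_only)]

  # one row per affected CpG slot: culture and aging effect to co-place
  slot_c <- c(sign_c * mag_c, rep(0, k_only))
  slot_a <- c(sign_shared * draw_mag(n_shared), rep(0, n_c - n_shared),
              sign_only * draw_mag(k_only))
  available <- rep(TRUE, n)
  delta_c <- numeric(n)
  delta_a <- numeric(n)
  for (s in seq_along(slot_c)) {
    lo <- min(0, slot_c[s]) + min(0, slot_a[s])
    hi <- max(0, slot_c[s]) + max(0, slot_a[s])
    feas <- which(available & baseline + lo >= 0.01 & baseline + hi <= 0.99)
    if (length(feas) == 0) feas <- which(available)
    pick <- feas[sample.int(length(feas), 1)]
    available[pick] <- FALSE
    delta_c[pick] <- slot_c[s]
    delta_a[pick] <- slot_a[s]
  }
  list(delta_culture = delta_c, delta_aging = delta_a)
}

#' Generate a synthetic methylation study with ground truth
#'
#' Draws a baseline mean per CpG from the configured beta mixture, applies
#' true culture effects to late-passage samples and true aging effects to
#' elderly donors (both passages) additively on the beta scale, clips the
#' per-sample mean into \[0.01, 0.99\], and draws each observed beta value
#' from a beta distribution with that mean and concentration `phi`.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return list with `beta` (a [beta_matrix()]), `design` (a
#'   [study_design()]) and `truth` (data.frame of class `truth_table` with
#'   per-CpG true deltas, labels in hyper/hypo/null per contrast, the
#'   baseline mean, and a flag for CpGs whose mean was clipped).
#' @export
generate_methylation_study <- function(params, seed) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(child_seed(seed, "methylation"), {
    n <- params$n_cpgs
    mode <- sample(1:3, n, replace = TRUE, prob = params$baseline_weights)
    sh <- params$baseline_shapes
    m <- stats::rbeta(n, c(sh$low[1], sh$mid[1], sh$high[1])[mode],
                      c(sh$low[2], sh$mid[2], sh$high[2])[mode])
    eff <- allocate_effects(params, m)

    donors <- sprintf("D%d", seq_len(params$n_donors))
    age_group <- rep(c("young", "elderly"),
                     c(params$n_young, params$n_donors - params$n_young))
    age_years <- ifelse(age_group == "young",
                        round(stats::runif(params$n_donors, 21, 50)),
                        round(stats::runif(params$n_donors, 53, 85)))
    late_passage <- sample(8:15, params$n_donors, replace = TRUE)
    design <- study_design(
      sample_id = paste0(rep(donors, each = 2), "_",
                         rep(c("early", "late"), params$n_donors)),
      donor_id = rep(donors, each = 2),
      passage_group = rep(c("early", "late"), params$n_donors),
      age_group = rep(age_group, each = 2),
      age_years = rep(age_years, each = 2),
      passage_number = as.vector(rbind(2L, late_passage)))

    n_samp <- nrow(design)
    cpg_id <- sprintf("cg%07d", seq_len(n))
    vals <- matrix(NA_real_, n, n_samp,
                   dimnames = list(cpg_id, design$sample_id))
    clipped <- logical(n)
    for (j in seq_len(n_samp)) {
      mult <- 1
      if (design$passage_group[j] == "late" &&
          !is.null(params$passage_drift)) {
        mult <- min(1, (design$passage_number[j] - 2) * params$passage_drift)
      }
      mu <- m +
        eff$delta_culture * (design$passage_group[j] == "late") * mult +
        eff$delta_aging * (design$age_group[j] == "elderly")
      out_of_range <- mu < 0.01 | mu > 0.99
      clipped <- clipped | out_of_range
      mu <- clip(mu, 0.01, 0.99)
      vals[, j] <- stats::rbeta(n, mu * params$phi, (1 - mu) * params$phi)
    }
    label <- function(d) ifelse(d > 0, "hyper", ifelse(d < 0, "hypo", "null"))
    truth <- data.frame(cpg_id = cpg_id,
                        baseline_mean = m,
                        delta_culture = eff$delta_culture,
                        delta_aging = eff$delta_aging,
                        label_culture = label(eff$delta_culture),
                        label_aging = label(eff$delta_aging),
                        mean_clipped = clipped,
                        stringsAsFactors = FALSE)
    class(truth) <- c("truth_table", "data.frame")
    list(beta = beta_matrix(vals), design = design, truth = truth)
  })
}

#' Generate two-channel bead intensities consistent with a beta matrix
#'
#' Inverts the beta formula `beta = M / (M + U + alpha)`: noise-free signals
#' satisfy `M + U = total_intensity` (up to the offset correction), so that
#' [compute_beta()] with the same `alpha` recovers the input exactly at zero
#' noise. Multiplicative lognormal noise is then applied per channel.
#'
#' @param beta a [beta_matrix()].
#' @param total_intensity target summed fluorescence per assay.
#' @param alpha offset used in the beta formula (match [compute_beta()]).
#' @param noise_sd standard deviation of the lognormal log-noise per channel.
#' @param seed integer seed.
#' @return list of numeric matrices `M` and `U` (same dimnames as `beta`).
#' @export
generate_intensities <- function(beta, total_intensity = 10000, alpha = 100,
                                 noise_sd = 0.05, seed = 1) {
  if (total_intensity <= 0) stopf("total_intensity must be > 0")
  if (alpha < 0) stopf("alpha must be >= 0")
  with_seed(child_seed(seed, "intensities"), {
    b <- unclass(beta)
    M <- b * (total_intensity + alpha)
    U <- (1 - b) * (total_intensity + alpha) - alpha
    U[U < 0] <- 0
    if (noise_sd > 0) {
      M <- M * exp(stats::rnorm(length(M), 0, noise_sd))
      U <- U * exp(stats::rnorm(length(U), 0, noise_sd))
    }
    dimnames(M) <- dimnames(U) <- dimnames(b)
    list(M = M, U = U)
  })
}

#' Generate expression data negatively coupled to promoter methylation
#'
#' Per gene and sample, the log2 intensity is
#' `intercept + slope * (gene-mean beta) + noise`; with a negative slope,
#' methylated promoters silence expression. Each gene gets 1--2 probe sets.
#' Present/marginal/absent calls are drawn with presence probability
#' increasing in intensity (logistic around 7 log2 units).
#'
#' @param beta a [beta_matrix()].
#' @param annotation a [cpg_annotation()] covering the beta CpGs.
#' @param slope,intercept,noise_sd coupling parameters (see
#'   [simulation_params()] for defaults and units).
#' @param seed integer seed.
#' @return an [expression_matrix()].
#' @export
generate_expression <- function(beta, annotation, slope = -4, intercept = 10,
                                noise_sd = 0.5, seed = 1) {
  with_seed(child_seed(seed, "expression"), {
    ann <- annotation[match(rownames(beta), annotation$cpg_id), ]
    keep <- !is.na(ann$gene_symbol)
    gene_beta <- rowsum(unclass(beta)[keep, , drop = FALSE],
                        ann$gene_symbol[keep])
    counts <- as.vector(table(ann$gene_symbol[keep])[rownames(gene_beta)])
    gene_beta <- gene_beta / counts
    genes <- rownames(gene_beta)
    n_probes <- sample(1:2, length(genes), replace = TRUE, prob = c(0.6, 0.4))
    probe_gene <- rep(genes, n_probes)
    dup <- stats::ave(seq_along(probe_gene), probe_gene, FUN = seq_along)
    probe_id <- paste0("PS_", probe_gene, "_", dup, "_at")
    mu <- intercept + slope * gene_beta[probe_gene, , drop = FALSE]
    intensity <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd),
                             nrow(mu), ncol(mu))
    dimnames(intensity) <- list(probe_id, colnames(beta))
    p_present <- stats::plogis(intensity - 7)
    u <- matrix(stats::runif(length(intensity)), nrow(intensity))
    calls <- ifelse(u < p_present, "P",
                    ifelse(u < p_present + 0.1 * (1 - p_present), "M", "A"))
    dimnames(calls) <- dimnames(intensity)
    expression_matrix(intensity, calls, setNames(probe_gene, probe_id))
  })
}

#' Generate pyrosequencing percent-methylation profiles
#'
#' Emulates the orthogonal validation platform: for each target CpG, the
#' whole CpG island (target plus annotated neighbor positions) is profiled.
#' Every position's percent methylation is
#' `100 * clip(array beta + island jitter + position jitter + offset)`,
#' where the island jitter is shared by all positions of an island within a
#' sample (neighboring CpGs of one island co-vary) and the platform offset
#' captures the systematically lower pyrosequencing levels.
#'
#' @param beta a [beta_matrix()].
#' @param annotation a [cpg_annotation()].
#' @param target_cpgs CpG ids to profile; default: the first 6 island CpGs.
#' @param platform_offset constant platform shift on the beta scale, in
#'   (-0.3, 0.3).
#' @param jitter_sd standard deviation of island and position jitter.
#' @param seed integer seed.
#' @return a `pyro_profiles` data.frame (long format; the target CpG is the
#'   row with `position_bp == 0`).
#' @export
generate_pyro_profiles <- function(beta, annotation, target_cpgs = NULL,
                                   platform_offset = -0.05, jitter_sd = 0.03,
                                   seed = 1) {
  if (abs(platform_offset) >= 0.3)
    stopf("platform_offset must lie in (-0.3, 0.3)")
  ann <- annotation[match(rownames(beta), annotation$cpg_id), ]
  if (is.null(target_cpgs)) {
    target_cpgs <- utils::head(ann$cpg_id[!is.na(ann$island_id)], 6)
  }
  miss <- setdiff(target_cpgs, rownames(beta))
  if (length(miss) > 0)
    stopf("target CpG(s) absent from beta matrix: %s",
          paste(miss, collapse = ", "))
  with_seed(child_seed(seed, "pyro"), {
    out <- list()
    for (cg in target_cpgs) {
      a <- ann[ann$cpg_id == cg, ]
      offs <- neighbor_offset_list(a$neighbor_offsets)[[1]]
      positions <- sort(unique(c(0L, offs)))
      isl <- if (is.na(a$island_id)) paste0("isl_", cg) else a$island_id
      b <- unclass(beta)[cg, ]
      island_jit <- stats::rnorm(length(b), 0, jitter_sd)
      for (pos in positions) {
        pos_jit <- if (pos == 0L) 0 else stats::rnorm(length(b), 0, jitter_sd)
        val <- 100 * clip(b + island_jit + pos_jit + platform_offset, 0, 1)
        out[[length(out) + 1L]] <- data.frame(
          island_id = isl, target_cpg_id = cg, position_bp = pos,
          sample_id = names(b), percent_meth = val,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("pyro_profiles", "data.frame")
    res
  })
}
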