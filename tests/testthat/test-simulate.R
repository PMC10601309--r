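test_that("genome simulation places the configured genes deterministically", {
  cfg <- sim_config(n_genes = 100, frac_short_genes = 0.1, seed = 7)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  len <- g1$genes$end - g1$genes$start
  expect_equal(sum(len < 1000), 10)
  expect_true(all(g1$genes$start < g1$genes$end))
  # non-overlapping gene bodies
  ord <- order(g1$genes$start)
  expect_true(all(diff(g1$genes$start[ord]) >=
                    (g1$genes$end - g1$genes$start)[ord][-100]))
  # TSS inside the body on both strands
  expect_true(all(g1$genes$tss >= g1$genes$start &
                    g1$genes$tss < g1$genes$end))
  # TREs on both sides of gene bodies
  expect_true(any(g1$tres$intragenic) && any(!g1$tres$intragenic))

  cfg0 <- sim_config(n_genes = 50, frac_short_genes = 0, seed = 1)
  g0 <- simulate_genome(cfg0)
  expect_true(all(g0$genes$end - g0$genes$start >= 1000))

  too_many <- sim_config(n_genes = 400, chrom_length = 1e5, seed = 1)
  expect_error(simulate_genome(too_many), "cannot place")
})

test_that("read simulation respects the pause window and scales with effects", {
  cfg <- sim_config(n_genes = 30, pause_fraction = 1, tre_per_gene_rate = 0,
                    frac_short_genes = 0, seed = 5)
  truth <- simulate_truth(cfg)
  gen <- simulate_genome(cfg)
  gen$tres <- gen$tres[0, ] # gene-derived reads only
  reads <- simulate_chro_reads(gen$genes, gen$tres, truth, cfg)
  # with pause_fraction = 1 every read sits within 150 b of its gene's TSS,
  # in the direction of transcription
  hit <- vapply(seq_len(nrow(reads)), function(i) {
    any(vapply(seq_len(nrow(gen$genes)), function(g) {
      if (gen$genes$strand[g] != reads$strand[i]) return(FALSE)
      tss <- gen$genes$tss[g]
      if (gen$genes$strand[g] == "+") {
        reads$position[i] >= tss && reads$position[i] < tss + 150
      } else {
        reads$position[i] <= tss && reads$position[i] > tss - 150
      }
    }, logical(1)))
  }, logical(1))
  expect_true(all(hit))

  # a zero-rate gene emits no reads
  truth0 <- truth
  truth0$genes$base_mean[1] <- 0
  reads0 <- simulate_chro_reads(gen$genes, gen$tres, truth0, cfg)
  g1 <- gen$genes[1, ]
  in_g1 <- reads0$position >= g1$start & reads0$position < g1$end &
    reads0$strand == g1$strand
  expect_equal(sum(reads0$count[in_g1]), 0)

  expect_identical(reads, simulate_chro_reads(gen$genes, gen$tres, truth, cfg))
})

test_that("transcriptional effects double body read rates in expectation", {
  # one gene, log2FC +1 between stages: stage-B read rate should be ~2x
  cfg <- sim_config(n_genes = 1, frac_short_genes = 0, tre_per_gene_rate = 0,
                    pause_fraction = 0, samples_per_group = 400, seed = 21)
  truth <- simulate_truth(cfg)
  truth$genes$transcriptional_log2fc <- 1
  truth$genes$base_mean <- 500
  gen <- simulate_genome(cfg)
  gen$tres <- gen$tres[0, ]
  reads <- simulate_chro_reads(gen$genes, gen$tres, truth, cfg)
  by_stage <- tapply(reads$count, reads$stage, sum)
  # per-sample depth is log-uniform [0.5, 2] in both stages, so averaging
  # over many replicate samples cancels it and the ratio estimates 2^1
  ratio <- by_stage[[cfg$stages[2]]] / by_stage[[cfg$stages[1]]]
  expect_equal(unname(ratio), 2, tolerance = 0.05)
})

test_that("count matrices carry the designed interaction structure", {
  cfg <- sim_config(n_genes = 300, frac_pt = 0, frac_transcriptional = 0.3,
                    seed = 13)
  truth <- simulate_truth(cfg)
  mats <- simulate_count_matrices(truth, cfg)
  expect_identical(mats, simulate_count_matrices(truth, cfg))
  # with no PT effects the expected interaction log2FC is zero everywhere:
  # chro and rna share means gene by gene up to size factors
  expect_true(all(truth$genes$pt_log2fc == 0))
  inter <- two_factor_interaction(mats$chro, mats$rna, mats$metadata,
                                  cfg$stages[1], cfg$stages[2])
  expect_lt(abs(median(inter$log2FC, na.rm = TRUE)), 0.1)

  # planted PT effect at high counts and low dispersion is recovered
  cfg2 <- sim_config(n_genes = 150, frac_pt = 0.2, frac_transcriptional = 0,
                     effect_log2fc = 2, nb_dispersion = 0.01,
                     mean_expression_log_range = c(3.7, 4.3), seed = 17)
  truth2 <- simulate_truth(cfg2)
  mats2 <- simulate_count_matrices(truth2, cfg2)
  inter2 <- two_factor_interaction(mats2$chro, mats2$rna, mats2$metadata,
                                   "DE", "Duo")
  planted <- truth2$genes$gene_id[truth2$genes$pt_log2fc > 0]
  est <- inter2$log2FC[match(planted, inter2$feature)]
  expect_equal(median(est), 2, tolerance = 0.15)
})

test_that("simulated counts follow the NB mean-variance relation", {
  # marginal check at n = 10,000 draws: var ~ mu + alpha mu^2
  cfg <- sim_config(n_genes = 10000, nb_dispersion = 0.1,
                    frac_transcriptional = 0, frac_pt = 0,
                    mean_expression_log_range = c(3, 3), samples_per_group = 1,
                    seed = 99)
  truth <- simulate_truth(cfg)
  mats <- simulate_count_matrices(truth, cfg)
  x <- mats$chro[[2]]
  sf <- mats$size_factors[names(mats$chro)[2]]
  mu <- unname(1000 * sf)
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu + 0.1 * mu^2, tolerance = 0.06)
})

test_that("miRNA counts plant DE signal and an expression floor", {
  cfg <- sim_config(seed = 23)
  truth <- simulate_truth(cfg)
  mir <- simulate_mirna_counts(truth, cfg)
  expect_identical(mir, simulate_mirna_counts(truth, cfg))
  rp <- rpmmm_normalize(mir$counts)
  rpm <- as.matrix(rp[, -1])
  stage_max <- pmax(
    rowMeans(rpm[, mir$metadata$stage == "DE"]),
    rowMeans(rpm[, mir$metadata$stage == "Duo"])
  )
  # a configured subset sits below the RPMMM-1000 floor
  expect_gte(sum(stage_max < 1000), round(0.3 * cfg$n_mirnas) * 0.8)
  # causal miRNAs are comfortably above it
  ci <- match(cfg$causal_mirnas$mirna, mir$counts$mirna)
  expect_true(all(stage_max[ci] > 1000))
})

test_that("target-site tables encode causal enrichment and conservation", {
  cfg <- sim_config(seed = 31)
  truth <- simulate_truth(cfg)
  sites <- simulate_target_sites(truth, cfg)
  expect_identical(sites, simulate_target_sites(truth, cfg))
  expect_true(all(grepl("human", sites$species)))
  expect_true(all(sites$site_type %in% c("8mer", "7mer-m8", "7mer-A1")))

  # causal miRNA site density on its targets far exceeds background
  m_down <- cfg$causal_mirnas$mirna[1]
  tgt <- truth$causal_targets[[m_down]]
  dens_causal <- sum(sites$mirna == m_down & sites$gene %in% tgt) / length(tgt)
  other <- setdiff(truth$genes$gene_id, tgt)
  dens_bg <- sum(sites$mirna == m_down & sites$gene %in% other) / length(other)
  expect_gt(dens_causal, 10 * max(dens_bg, 0.01))

  # all-human sites vanish under cons1
  cfg_h <- sim_config(frac_conserved_sites = 0, seed = 31)
  sites_h <- simulate_target_sites(simulate_truth(cfg_h), cfg_h)
  expect_equal(nrow(filter_cons1(sites_h)), 0)
})
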