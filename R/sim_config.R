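#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration describing a two-stage, two-assay
#' differentiation experiment at desk scale: paired nascent-transcription
#' ("chro") and steady-state ("rna") negative-binomial counts with designed
#' transcriptional and post-transcriptional effects, stage-structured miRNA
#' profiles, a small synthetic genome for read-level quantification, and
#' miRNA target-site tables in which designated causal miRNAs preferentially
#' target the genes they are meant to regulate.
#'
#' The defaults define the study conditions used throughout the package's
#' verification suite: 2 stages (DE, Duo) x 2 assays x 3 replicates, gene
#' base means drawn log-uniformly over `mean_expression_log_range` (log10
#' counts), negative-binomial dispersion `nb_dispersion` under the
#' parameterization var = mu + dispersion * mu^2, and one causal miRNA per
#' direction whose targets are the planted post-transcriptionally regulated
#' genes.
#'
#' @param n_genes Number of genes in the synthetic gene universe.
#' @param n_mirnas Number of miRNAs.
#' @param samples_per_group Replicates per (stage, assay) cell.
#' @param stages Ordered pair of stage labels (transition is stage 1 -> 2).
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param mean_expression_log_range log10 range for gene base means.
#' @param frac_transcriptional Fraction of genes with a purely
#'   transcriptional effect between stages.
#' @param frac_pt Fraction of genes with a post-transcriptional effect
#'   (steady-state change discordant with transcription).
#' @param effect_log2fc Magnitude of planted gene effects (log2).
#' @param mirna_effect_log2fc Magnitude of planted miRNA differential
#'   expression (log2).
#' @param frac_short_genes Fraction of genes given a body < 1 kb, to
#'   exercise the gene-length exclusion.
#' @param tre_per_gene_rate Poisson rate of intragenic regulatory elements
#'   (TREs) per gene.
#' @param pause_fraction Fraction of a gene's run-on reads confined to the
#'   promoter-proximal pause window [TSS, TSS + 150).
#' @param causal_mirnas Data frame with columns `mirna`, `direction`
#'   ("down" miRNAs target the planted stable genes, "up" miRNAs the
#'   planted unstable genes), or `NULL` for no causal miRNAs.
#' @param n_bg_de_mirnas Number of non-causal differentially expressed
#'   miRNAs (split between directions) that carry no target enrichment.
#' @param frac_low_mirnas Fraction of miRNAs kept below the RPMMM-1000
#'   expression floor.
#' @param site_rate_causal Probability that a causal miRNA receives a
#'   target site on each of its designated target genes.
#' @param site_rate_background Per (miRNA, gene) background site
#'   probability.
#' @param frac_conserved_sites Probability a site is conserved beyond human
#'   (receives at least one of chicken/dog/mouse/rat).
#' @param chrom_length Length of the single synthetic chromosome (bp).
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 7)
#' @export
sim_config <- function(n_genes = 400,
                       n_mirnas = 60,
                       samples_per_group = 3,
                       stages = c("DE", "Duo"),
                       nb_dispersion = 0.05,
                       mean_expression_log_range = c(1.5, 3.5),
                       frac_transcriptional = 0.2,
                       frac_pt = 0.2,
                       effect_log2fc = 1.5,
                       mirna_effect_log2fc = 1.5,
                       frac_short_genes = 0.1,
                       tre_per_gene_rate = 0.5,
                       pause_fraction = 0.3,
                       causal_mirnas = NULL,
                       n_bg_de_mirnas = 8,
                       frac_low_mirnas = 0.3,
                       site_rate_causal = 0.9,
                       site_rate_background = 0.02,
                       frac_conserved_sites = 0.75,
                       chrom_length = 1e7,
                       seed = 1L) {
  if (is.null(causal_mirnas)) {
    causal_mirnas <- tibble(
      mirna = mirna_ids(2L),
      direction = c("down", "up")
    )
  } else if (is.data.frame(causal_mirnas)) {
    causal_mirnas <- as_tibble(causal_mirnas)
  } else {
    abort("`causal_mirnas` must be NULL or a data frame with columns mirna, direction")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    samples_per_group = as.integer(samples_per_group),
    stages = as.character(stages), nb_dispersion = nb_dispersion,
    mean_expression_log_range = mean_expression_log_range,
    frac_transcriptional = frac_transcriptional, frac_pt = frac_pt,
    effect_log2fc = effect_log2fc, mirna_effect_log2fc = mirna_effect_log2fc,
    frac_short_genes = frac_short_genes,
    tre_per_gene_rate = tre_per_gene_rate, pause_fraction = pause_fraction,
    causal_mirnas = causal_mirnas, n_bg_de_mirnas = as.integer(n_bg_de_mirnas),
    frac_low_mirnas = frac_low_mirnas,
    site_rate_causal = site_rate_causal,
    site_rate_background = site_rate_background,
    frac_conserved_sites = frac_conserved_sites,
    chrom_length = chrom_length, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 1, cfg$n_mirnas >= 1, cfg$samples_per_group >= 1,
    length(cfg$stages) == 2, !anyDuplicated(cfg$stages),
    cfg$nb_dispersion >= 0,
    length(cfg$mean_expression_log_range) == 2,
    diff(cfg$mean_expression_log_range) >= 0
  )
  fracs <- c(
    cfg$frac_transcriptional, cfg$frac_pt, cfg$frac_short_genes,
    cfg$pause_fraction, cfg$frac_low_mirnas, cfg$site_rate_causal,
    cfg$site_rate_background, cfg$frac_conserved_sites
  )
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$frac_transcriptional + cfg$frac_pt > 1) {
    abort("frac_transcriptional + frac_pt must not exceed 1")
  }
  if (cfg$effect_log2fc < 0 || cfg$mirna_effect_log2fc < 0) {
    abort("effect sizes must be non-negative")
  }
  if (nrow(cfg$causal_mirnas) > 0) {
    stopifnot(all(c("mirna", "direction") %in% names(cfg$causal_mirnas)))
    if (!all(cfg$causal_mirnas$direction %in% c("down", "up"))) {
      abort("causal miRNA direction must be 'down' or 'up'")
    }
  }
  invisible(cfg)
}

#' @keywords internal
gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' @keywords internal
mirna_ids <- function(n) sprintf("miR-sim-%03d", seq_len(n))

#' Draw the ground truth underlying a synthetic experiment
#'
#' Assigns each gene a base mean, a transcriptional log2 fold change and a
#' post-transcriptional (PT) log2 fold change between the two stages, and
#' each miRNA a differential-expression log2 fold change.  Genes with a PT
#' effect are the designated targets of the causal miRNAs: planted stable
#' genes (pt_log2fc > 0, i.e. lost suppression) are targeted by "down"
#' causal miRNAs and planted unstable genes by "up" causal miRNAs.  The
#' per-gene `pt_label` is a deterministic function of `pt_log2fc`:
#' stable if > 0.5, unstable if < -0.5, none otherwise.
#'
#' @param config A [sim_config()].
#' @return A list of class `pt_sim_truth` with tibbles `genes` (gene_id,
#'   base_mean, transcriptional_log2fc, pt_log2fc, pt_label), `mirnas`
#'   (mirna, base_mean, de_log2fc, causal, direction) and a named list
#'   `causal_targets` mapping causal miRNA ids to gene-id vectors.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    ids <- gene_ids(n)
    base <- 10^runif(n, config$mean_expression_log_range[1],
                     config$mean_expression_log_range[2])
    n_tr <- round(config$frac_transcriptional * n)
    n_pt <- round(config$frac_pt * n)
    idx <- sample.int(n, n_tr + n_pt)
    tr_idx <- idx[seq_len(n_tr)]
    pt_idx <- idx[n_tr + seq_len(n_pt)]
    trans <- numeric(n)
    trans[tr_idx] <- sample(c(-1, 1), n_tr, replace = TRUE) * config$effect_log2fc
    pt <- numeric(n)
    # split PT genes near-evenly between gained and lost suppression
    pt_sign <- rep_len(c(1, -1), n_pt)
    if (n_pt > 0) pt[pt_idx] <- sample(pt_sign) * config$effect_log2fc
    label <- dplyr::case_when(pt > 0.5 ~ "stable", pt < -0.5 ~ "unstable",
                              TRUE ~ "none")
    genes <- tibble(
      gene_id = ids, base_mean = base,
      transcriptional_log2fc = trans, pt_log2fc = pt, pt_label = label
    )

    m <- config$n_mirnas
    mids <- mirna_ids(m)
    causal <- config$causal_mirnas
    if (nrow(causal) > 0 && !all(causal$mirna %in% mids)) {
      abort("causal miRNA ids must be among the simulated miRNA ids")
    }
    is_causal <- mids %in% causal$mirna
    n_low <- round(config$frac_low_mirnas * m)
    low_pool <- which(!is_causal)
    low_idx <- low_pool[seq_len(min(n_low, length(low_pool)))]
    mbase <- 10^runif(m, 2.5, 4)
    mbase[low_idx] <- 10^runif(length(low_idx), 0, 1.2)
    mbase[is_causal] <- 10^runif(sum(is_causal), 3.2, 3.8)
    de <- numeric(m)
    direction <- rep(NA_character_, m)
    if (nrow(causal) > 0) {
      ci <- match(causal$mirna, mids)
      direction[ci] <- causal$direction
      de[ci] <- ifelse(causal$direction == "down", -1, 1) *
        config$mirna_effect_log2fc
    }
    bg_pool <- setdiff(which(!is_causal & !(seq_len(m) %in% low_idx)), integer(0))
    n_bg <- min(config$n_bg_de_mirnas, length(bg_pool))
    bg_idx <- sample(bg_pool, n_bg)
    bg_sign <- sample(rep_len(c(1, -1), n_bg))
    de[bg_idx] <- bg_sign * config$mirna_effect_log2fc
    direction[bg_idx] <- ifelse(bg_sign > 0, "up", "down")
    mirnas <- tibble(
      mirna = mids, base_mean = mbase, de_log2fc = de,
      causal = is_causal, direction = direction
    )

    causal_targets <- list()
    for (i in seq_len(nrow(causal))) {
      tgt <- if (causal$direction[i] == "down") {
        genes$gene_id[genes$pt_label == "stable"]
      } else {
        genes$gene_id[genes$pt_label == "unstable"]
      }
      causal_targets[[causal$mirna[i]]] <- tgt
    }

    structure(
      list(genes = genes, mirnas = mirnas, causal_targets = causal_targets),
      class = "pt_sim_truth"
    )
  })
}
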