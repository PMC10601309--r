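#' Simulate a synthetic genome: gene models and regulatory elements
#'
#' Places non-overlapping gene bodies on a single synthetic chromosome
#' (0-based half-open coordinates, BED convention) and scatters
#' transcriptional regulatory elements (TREs) both inside and outside gene
#' bodies.  Exactly `round(frac_short_genes * n_genes)` genes receive a
#' body shorter than 1 kb so that the gene-length exclusion downstream is
#' exercised.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `genes` (gene_id, chrom, start, end, strand,
#'   tss) and `tres` (tre_id, chrom, start, end, activity, active_stages,
#'   intragenic).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    n_short <- round(config$frac_short_genes * n)
    len <- c(
      sample(200:999, n_short, replace = TRUE),
      sample(1500:8000, n - n_short, replace = TRUE)
    )
    len <- len[sample.int(length(len))] # shuffle short genes along the chromosome
    min_gap <- 10
    if (sum(len) + (n + 1) * min_gap > config$chrom_length) {
      abort("cannot place genes without overlap on the configured chromosome")
    }
    free <- config$chrom_length - sum(len) - (n + 1) * min_gap
    w <- runif(n + 1)
    gaps <- min_gap + floor(w / sum(w) * free)
    start <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- ifelse(strand == "+", start, end - 1)
    genes <- tibble(
      gene_id = gene_ids(n), chrom = "chrS",
      start = as.integer(start), end = as.integer(end),
      strand = strand, tss = as.integer(tss)
    )

    # intragenic TREs
    n_intra <- rpois(n, config$tre_per_gene_rate)
    intra <- purrr::map2(seq_len(n), n_intra, function(i, k) {
      if (k == 0) return(NULL)
      w <- sample(150:350, k, replace = TRUE)
      ok <- w <= (len[i] - 20)
      if (!any(ok)) return(NULL)
      w <- w[ok]
      s <- start[i] + vapply(len[i] - w - 10, function(m) sample.int(m, 1), 1L)
      tibble(chrom = "chrS", start = as.integer(s), end = as.integer(s + w),
             intragenic = TRUE)
    })
    n_inter <- max(2L, ceiling(0.25 * n))
    w_inter <- sample(150:350, n_inter, replace = TRUE)
    s_inter <- vapply(
      config$chrom_length - w_inter,
      function(m) sample.int(m, 1), 1L
    )
    inter <- tibble(chrom = "chrS", start = as.integer(s_inter),
                    end = as.integer(s_inter + w_inter), intragenic = FALSE)
    tres <- dplyr::bind_rows(c(intra, list(inter)))
    tres <- dplyr::arrange(tres, .data$start)
    tres <- dplyr::mutate(
      tres,
      tre_id = sprintf("tre%04d", dplyr::row_number()),
      activity = 10^runif(dplyr::n(), 1, 2),
      active_stages = vapply(
        seq_len(dplyr::n()),
        function(i) {
          act <- config$stages[runif(2) < 0.7]
          if (length(act) == 0) act <- sample(config$stages, 1)
          paste(act, collapse = ",")
        },
        character(1)
      ),
      .before = 1
    )
    list(genes = genes, tres = dplyr::relocate(tres, "tre_id", "chrom",
                                               "start", "end"))
  })
}

#' Simulate single-base polymerase-position reads
#'
#' Emulates a run-on assay: for every nascent-transcription sample, each
#' gene emits Poisson-distributed sense-strand reads at a rate proportional
#' to `base_mean * 2^transcriptional_log2fc(stage)`, with a fraction
#' `pause_fraction` of them confined to the promoter-proximal pause window
#' `[TSS, TSS + 150)` (in the direction of transcription) and the rest
#' uniform over the gene body.  TREs active in the sample's stage emit
#' additional bidirectional reads.  Per-sample depth varies log-uniformly
#' over [0.5, 2] to exercise normalization.
#'
#' @param genes,tres Output of [simulate_genome()].
#' @param truth A [simulate_truth()] object covering all genes.
#' @param config The [sim_config()].
#' @return Tibble of read positions: sample, stage, chrom, position
#'   (0-based single base), strand, count.
#' @export
simulate_chro_reads <- function(genes, tres, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "pt_sim_truth"))
  if (!all(genes$gene_id %in% truth$genes$gene_id)) {
    abort("ground truth must cover all simulated genes")
  }
  gt <- truth$genes[match(genes$gene_id, truth$genes$gene_id), ]
  pause_w <- 150L
  withr::with_seed(config$seed + 2L, {
    out <- list()
    for (stage_i in seq_along(config$stages)) {
      stage <- config$stages[stage_i]
      eff <- if (stage_i == 1) 0 else gt$transcriptional_log2fc
      for (r in seq_len(config$samples_per_group)) {
        smp <- sprintf("chro_%s_%d", stage, r)
        depth <- exp(runif(1, log(0.5), log(2)))
        lam <- gt$base_mean * 2^eff * depth
        n_reads <- rpois(nrow(genes), lam)
        pos_list <- purrr::map(which(n_reads > 0), function(i) {
          k <- n_reads[i]
          k_pause <- rbinom(1, k, config$pause_fraction)
          if (genes$strand[i] == "+") {
            lo <- genes$tss[i]
            hi <- min(genes$end[i] - 1L, genes$tss[i] + pause_w - 1L)
          } else {
            lo <- max(genes$start[i], genes$tss[i] - pause_w + 1L)
            hi <- genes$tss[i]
          }
          p_pause <- if (k_pause > 0) sample(lo:hi, k_pause, replace = TRUE) else integer(0)
          p_body <- if (k - k_pause > 0) {
            sample(genes$start[i]:(genes$end[i] - 1L), k - k_pause, replace = TRUE)
          } else integer(0)
          tibble(position = c(p_pause, p_body), strand = genes$strand[i])
        })
        tre_active <- purrr::map_lgl(
          split_list_col(tres$active_stages), function(s) stage %in% s
        )
        tre_n <- rpois(nrow(tres), ifelse(tre_active, tres$activity * depth, 0))
        tre_list <- purrr::map(which(tre_n > 0), function(i) {
          k <- tre_n[i]
          tibble(
            position = sample(tres$start[i]:(tres$end[i] - 1L), k, replace = TRUE),
            strand = sample(c("+", "-"), k, replace = TRUE)
          )
        })
        reads <- dplyr::bind_rows(c(pos_list, tre_list))
        if (nrow(reads) == 0) {
          reads <- tibble(position = integer(0), strand = character(0))
        }
        out[[smp]] <- reads |>
          dplyr::count(.data$position, .data$strand, name = "count") |>
          dplyr::mutate(sample = smp, stage = stage, chrom = "chrS",
                        .before = 1)
        }
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$sample, .data$position,
                   .data$strand)
  })
}

#' @keywords internal
rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate paired nascent and steady-state count matrices
#'
#' For gene g in stage s, the nascent ("chro") negative-binomial mean is
#' `base_g * 2^trans_gs` and the steady-state ("rna") mean is the nascent
#' mean times `2^pt_gs`, so the ground-truth interaction log2 fold change
#' for the stage transition equals `pt_gB - pt_gA` by construction
#' (`pt_gA = 0`).  A shared dispersion and per-sample size factors
#' (log-uniform in [0.5, 2]) are applied.
#'
#' @inheritParams simulate_chro_reads
#' @return List with count tibbles `chro` and `rna` (gene_id + sample
#'   columns), `metadata` (sample, assay, stage) and `size_factors`.
#' @export
simulate_count_matrices <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "pt_sim_truth"))
  gt <- truth$genes
  withr::with_seed(config$seed + 3L, {
    meta <- tidyr::expand_grid(
      assay = c("chro", "rna"), stage = config$stages,
      rep = seq_len(config$samples_per_group)
    ) |>
      dplyr::mutate(sample = sprintf("%s_%s_%d", .data$assay, .data$stage,
                                     .data$rep)) |>
      dplyr::select("sample", "assay", "stage")
    sf <- exp(runif(nrow(meta), log(0.5), log(2)))
    names(sf) <- meta$sample
    mats <- list(chro = NULL, rna = NULL)
    for (a in c("chro", "rna")) {
      cols <- list()
      for (j in which(meta$assay == a)) {
        stage_i <- match(meta$stage[j], config$stages)
        eff <- if (stage_i == 1) 0 else gt$transcriptional_log2fc +
          (if (a == "rna") gt$pt_log2fc else 0)
        mu <- gt$base_mean * 2^eff * sf[j]
        cols[[meta$sample[j]]] <- rnbinom_mu(nrow(gt), mu, config$nb_dispersion)
      }
      mats[[a]] <- dplyr::bind_cols(tibble(gene_id = gt$gene_id),
                                    as_tibble(cols))
    }
    list(chro = mats$chro, rna = mats$rna, metadata = meta, size_factors = sf)
  })
}

#' Simulate stage-structured miRNA counts
#'
#' Causal and background differentially expressed miRNAs change between the
#' two stages with their ground-truth log2 fold change; a configured subset
#' of miRNAs is kept below the RPMMM-1000 expression floor to exercise the
#' expression filter in differential miRNA calling.
#'
#' @inheritParams simulate_chro_reads
#' @return List with count tibble `counts` (mirna + sample columns),
#'   `metadata` (sample, assay, stage) and `size_factors`.
#' @export
simulate_mirna_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "pt_sim_truth"))
  mt <- truth$mirnas
  withr::with_seed(config$seed + 4L, {
    meta <- tidyr::expand_grid(
      stage = config$stages, rep = seq_len(config$samples_per_group)
    ) |>
      dplyr::mutate(sample = sprintf("mirna_%s_%d", .data$stage, .data$rep),
                    assay = "mirna") |>
      dplyr::select("sample", "assay", "stage")
    sf <- exp(runif(nrow(meta), log(0.5), log(2)))
    names(sf) <- meta$sample
    cols <- list()
    for (j in seq_len(nrow(meta))) {
      stage_i <- match(meta$stage[j], config$stages)
      eff <- if (stage_i == 1) 0 else mt$de_log2fc
      mu <- mt$base_mean * 2^eff * sf[j]
      cols[[meta$sample[j]]] <- rnbinom_mu(nrow(mt), mu, config$nb_dispersion)
    }
    counts <- dplyr::bind_cols(tibble(mirna = mt$mirna), as_tibble(cols))
    list(counts = counts, metadata = meta, size_factors = sf)
  })
}

#' Simulate a miRNA target-site table
#'
#' Produces a TargetScan-like long table of predicted sites.  Causal
#' miRNAs receive sites on their designated target genes at elevated
#' density (`site_rate_causal`, 1-2 sites per targeted gene); every
#' (miRNA, gene) pair additionally receives background sites at rate
#' `site_rate_background`.  Each site carries a type in
#' {8mer, 7mer-m8, 7mer-A1} and a conserving-species set that always
#' includes human; with probability `frac_conserved_sites` it also includes
#' at least one of chicken, dog, mouse, rat (the cons1 species).
#'
#' @inheritParams simulate_chro_reads
#' @return Tibble with columns mirna, gene, site_type, species
#'   (comma-separated list, always containing "human").
#' @export
simulate_target_sites <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "pt_sim_truth"))
  genes <- truth$genes$gene_id
  mirnas <- truth$mirnas$mirna
  withr::with_seed(config$seed + 5L, {
    pairs <- tidyr::expand_grid(mirna = mirnas, gene = genes)
    bg <- pairs[runif(nrow(pairs)) < config$site_rate_background, ]
    causal <- purrr::imap(truth$causal_targets, function(tgt, m) {
      hit <- tgt[runif(length(tgt)) < config$site_rate_causal]
      if (length(hit) == 0) return(NULL)
      n_sites <- sample(1:2, length(hit), replace = TRUE)
      tibble(mirna = m, gene = rep(hit, n_sites))
    })
    sites <- dplyr::bind_rows(c(list(bg), causal))
    if (nrow(sites) == 0) {
      return(tibble(mirna = character(0), gene = character(0),
                    site_type = character(0), species = character(0)))
    }
    k <- nrow(sites)
    cons_pool <- c("chicken", "dog", "mouse", "rat")
    species <- vapply(seq_len(k), function(i) {
      if (runif(1) < config$frac_conserved_sites) {
        extra <- sample(cons_pool, sample.int(4, 1))
        paste(c("human", sort(extra)), collapse = ",")
      } else "human"
    }, character(1))
    sites |>
      dplyr::mutate(
        site_type = sample(c("8mer", "7mer-m8", "7mer-A1"), k,
                           replace = TRUE, prob = c(0.25, 0.35, 0.4)),
        species = species
      ) |>
      dplyr::arrange(.data$mirna, .data$gene)
  })
}
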