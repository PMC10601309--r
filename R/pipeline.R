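#' @keywords internal
write_bed12 <- function(genes, path) {
  bed <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = genes$start, thickEnd = genes$end, itemRgb = "0,0,0",
    blockCount = 1L, blockSizes = paste0(genes$end - genes$start, ","),
    blockStarts = "0,"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @keywords internal
read_bed12 <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "gene_id", "score",
                        "strand", "thickStart", "thickEnd", "itemRgb",
                        "blockCount", "blockSizes", "blockStarts"),
    col_types = "ciiciciicicc", progress = FALSE
  )
  tibble(
    gene_id = bed$gene_id, chrom = bed$chrom, start = bed$start,
    end = bed$end, strand = bed$strand,
    tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L)
  )
}

#' @keywords internal
write_reads_bed <- function(reads, dir) {
  paths <- character(0)
  for (smp in unique(reads$sample)) {
    sub <- reads[reads$sample == smp, , drop = FALSE]
    bed <- tibble(chrom = sub$chrom, start = sub$position,
                  end = sub$position + 1L, name = smp,
                  score = sub$count, strand = sub$strand)
    p <- file.path(dir, paste0("reads_", smp, ".bed"))
    readr::write_tsv(bed, p, col_names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @keywords internal
read_reads_bed <- function(paths) {
  purrr::map(paths, function(p) {
    bed <- readr::read_tsv(
      p, col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "ciicic", progress = FALSE
    )
    tibble(sample = bed$name, chrom = bed$chrom, position = bed$start,
           strand = bed$strand, count = bed$score)
  }) |>
    dplyr::bind_rows()
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs every generator of the synthetic-data module under the
#' configuration's seed and writes the results in plain-text interchange
#' formats: gene models as BED12, TREs as BED6 (plus a full TSV carrying
#' activity and stage annotations), per-sample single-base reads as
#' 6-column BED, count matrices / metadata / target sites / ground truth
#' as TSV, and the configuration as YAML.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects that were written.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config)
  genome <- simulate_genome(config)
  reads <- simulate_chro_reads(genome$genes, genome$tres, truth, config)
  mats <- simulate_count_matrices(truth, config)
  mir <- simulate_mirna_counts(truth, config)
  sites <- simulate_target_sites(truth, config)

  write_bed12(genome$genes, file.path(dir, "genes.bed"))
  readr::write_tsv(
    tibble(chrom = genome$tres$chrom, start = genome$tres$start,
           end = genome$tres$end, name = genome$tres$tre_id,
           score = round(genome$tres$activity), strand = "."),
    file.path(dir, "tres.bed"), col_names = FALSE
  )
  readr::write_tsv(genome$tres, file.path(dir, "tres.tsv"))
  write_reads_bed(reads, dir)
  readr::write_tsv(mats$chro, file.path(dir, "chro_counts.tsv"))
  readr::write_tsv(mats$rna, file.path(dir, "rna_counts.tsv"))
  readr::write_tsv(mir$counts, file.path(dir, "mirna_counts.tsv"))
  metadata <- dplyr::bind_rows(mats$metadata, mir$metadata)
  readr::write_tsv(metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sites, file.path(dir, "target_sites.tsv"))
  readr::write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(truth$mirnas, file.path(dir, "truth_mirnas.tsv"))

  # paired reference series for the correlation screen: the first causal
  # miRNA's expected expression in each steady-state sample, with noise
  if (nrow(config$causal_mirnas) > 0) {
    m1 <- config$causal_mirnas$mirna[1]
    mt <- truth$mirnas[truth$mirnas$mirna == m1, ]
    rna_meta <- mats$metadata[mats$metadata$assay == "rna", ]
    series <- withr::with_seed(config$seed + 6L, {
      eff <- ifelse(rna_meta$stage == config$stages[1], 0, mt$de_log2fc)
      mt$base_mean * 2^eff * exp(rnorm(nrow(rna_meta), 0, 0.1))
    })
    readr::write_tsv(
      tibble(sample = rna_meta$sample, mirna = m1, value = series),
      file.path(dir, "mirna_series.tsv")
    )
  }

  cfg <- unclass(config)
  cfg$causal_mirnas <- as.list(as.data.frame(config$causal_mirnas))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(truth = truth, genome = genome, reads = reads,
                 counts = mats, mirna = mir, sites = sites))
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a `config.yaml` written by [simulate_bundle()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$causal_mirnas <- if (length(cfg$causal_mirnas) > 0) {
    as_tibble(cfg$causal_mirnas)
  } else NULL
  do.call(sim_config, cfg)
}

#' @keywords internal
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Run the full transition analysis on an input bundle
#'
#' Composes the package's stages on a directory of inputs (as written by
#' [simulate_bundle()], or assembled by hand in the same formats):
#' read-level gene-body quantification and track normalization when reads
#' and gene models are present, the two-factor interaction test and
#' per-assay stage tests, post-transcriptional classification, differential
#' miRNA expression, target-site enrichment on the classified gene sets
#' with direction-matched candidate regulators, and the correlation screen
#' when a paired reference series is available.  Stages whose inputs are
#' missing are skipped with an explicit log line, never silently.
#'
#' All result tables are written as TSV under `out_dir` together with a
#' `summary.json` (label counts, differential miRNA counts, candidate
#' regulators, thresholds, seed) and a `run.log`.  Outputs are
#' deterministic for fixed inputs and seed.
#'
#' @param input_dir Directory of inputs.
#' @param out_dir Output directory (created if needed).
#' @param stageA,stageB Stage transition; defaults to the configured stage
#'   order in `config.yaml`, else the first two stages in the metadata.
#' @param thresholds A [pt_thresholds()].
#' @param quant A [quant_params()].
#' @param score A [score_params()]; its Monte-Carlo stream is seeded from
#'   `seed` when it carries no seed of its own.
#' @param seed Integer seed controlling all randomness of the run.
#' @return Invisibly, a list of the computed results.
#' @export
run_transition_analysis <- function(input_dir, out_dir,
                                    stageA = NULL, stageB = NULL,
                                    thresholds = pt_thresholds(),
                                    quant = quant_params(),
                                    score = score_params(),
                                    seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  path <- function(f) file.path(input_dir, f)
  has <- function(f) file.exists(path(f))
  logit("ptseq run; seed=", seed)

  if (has("config.yaml") && (is.null(stageA) || is.null(stageB))) {
    cfg <- read_sim_config(path("config.yaml"))
    stageA <- stageA %||% cfg$stages[1]
    stageB <- stageB %||% cfg$stages[2]
  }
  if (!has("metadata.tsv")) abort("metadata.tsv is required")
  metadata <- readr::read_tsv(path("metadata.tsv"), col_types = "ccc",
                              progress = FALSE)
  if (is.null(stageA) || is.null(stageB)) {
    st <- unique(metadata$stage)
    stageA <- st[1]; stageB <- st[2]
  }
  logit("transition: ", stageA, " -> ", stageB)

  genes <- if (has("genes.bed")) read_bed12(path("genes.bed")) else NULL
  tres <- if (has("tres.tsv")) {
    readr::read_tsv(path("tres.tsv"), col_types = readr::cols(),
                    progress = FALSE)
  } else NULL

  results <- list(stageA = stageA, stageB = stageB)

  # --- read-level quantification -------------------------------------------
  read_files <- list.files(input_dir, pattern = "^reads_.*\\.bed$",
                           full.names = TRUE)
  if (length(read_files) > 0 && !is.null(genes)) {
    reads <- read_reads_bed(sort(read_files))
    gb <- count_gene_body(reads, genes, tres, params = quant)
    readr::write_tsv(gb, file.path(out_dir, "gene_body_counts.tsv"))
    track <- normalize_track(reads, params = quant)
    write_track_bedgraph(track, file.path(out_dir, "chro_track"))
    results$gene_body_counts <- gb
    logit("quantified ", nrow(gb), " genes from ", length(read_files),
          " read files")
  } else {
    logit("skipping read-level quantification (no reads_*.bed or genes.bed)")
  }

  # --- differential machinery ----------------------------------------------
  if (has("chro_counts.tsv") && has("rna_counts.tsv")) {
    chro <- read_counts_tsv(path("chro_counts.tsv"))
    rna <- read_counts_tsv(path("rna_counts.tsv"))
    if (!is.null(genes)) {
      keep <- genes$gene_id[genes$end - genes$start >= quant$min_gene_length_bp]
      n0 <- nrow(chro)
      chro <- chro[chro[[1]] %in% keep, , drop = FALSE]
      rna <- rna[rna[[1]] %in% keep, , drop = FALSE]
      logit("gene-length filter: ", n0 - nrow(chro), " genes removed")
    }
    interaction <- two_factor_interaction(chro, rna, metadata, stageA, stageB)
    chro_de <- nb_stage_test(chro, metadata[metadata$assay == "chro", ],
                             stageA, stageB)
    rna_de <- nb_stage_test(rna, metadata[metadata$assay == "rna", ],
                            stageA, stageB)
    readr::write_tsv(interaction, file.path(out_dir, "interaction.tsv"))
    readr::write_tsv(chro_de, file.path(out_dir, "chro_de.tsv"))
    readr::write_tsv(rna_de, file.path(out_dir, "rna_de.tsv"))

    if (!is.null(genes)) {
      tpm <- tpm_normalize(chro, genes)
    } else {
      # without gene models lengths are unknown; fall back to
      # depth-normalized counts-per-million as the expression gate
      logit("no genes.bed: TPM gate computed from counts per million")
      m <- count_table_to_matrix(chro)
      cpm <- sweep(m, 2, pmax(colSums(m), 1), "/") * 1e6
      tpm <- matrix_to_count_table(cpm, id_col = "gene_id")
    }
    chro_meta <- metadata[metadata$assay == "chro", ]
    classification <- classify_pt(interaction, chro_de, rna_de, tpm,
                                  chro_meta, stageA, stageB, thresholds)
    readr::write_tsv(classification, file.path(out_dir, "classification.tsv"))
    label_counts <- summarize_transition(classification)
    readr::write_tsv(label_counts, file.path(out_dir, "label_counts.tsv"))
    results$interaction <- interaction
    results$chro_de <- chro_de
    results$rna_de <- rna_de
    results$classification <- classification
    results$label_counts <- label_counts
    logit("classification: ",
          paste(label_counts$label, label_counts$n, sep = "=",
                collapse = ", "))
  } else {
    logit("skipping differential analysis (need chro_counts.tsv and rna_counts.tsv)")
  }

  # --- miRNA differential expression ---------------------------------------
  de_set <- NULL
  if (has("mirna_counts.tsv")) {
    mir_counts <- read_counts_tsv(path("mirna_counts.tsv"))
    mir_meta <- metadata[metadata$assay == "mirna", ]
    de_set <- diff_mirna(mir_counts, mir_meta, stageA, stageB, thresholds)
    readr::write_tsv(de_set$table, file.path(out_dir, "mirna_de.tsv"))
    writeLines(sort(de_set$up), file.path(out_dir, "mirna_up.txt"))
    writeLines(sort(de_set$down), file.path(out_dir, "mirna_down.txt"))
    results$de_mirna <- de_set
    logit("differential miRNAs: ", length(de_set$up), " up, ",
          length(de_set$down), " down")
  } else {
    logit("skipping miRNA differential expression (no mirna_counts.tsv)")
  }

  # --- target-site enrichment ----------------------------------------------
  if (has("target_sites.tsv") && !is.null(results$classification)) {
    sites <- readr::read_tsv(path("target_sites.tsv"), col_types = "cccc",
                             progress = FALSE)
    sets <- pt_gene_sets(results$classification)
    if (is.null(score$seed)) score$seed <- seed + 100L
    mirhub <- list()
    for (nm in names(sets)) {
      if (length(sets[[nm]]) < 2) {
        logit("skipping enrichment for ", nm, " (fewer than 2 genes)")
        next
      }
      score_nm <- score
      score_nm$seed <- score$seed + match(nm, names(sets))
      mirhub[[nm]] <- monte_carlo_enrichment(sites, sets[[nm]],
                                             params = score_nm)
      readr::write_tsv(mirhub[[nm]],
                       file.path(out_dir, paste0("mirhub_", nm, ".tsv")))
    }
    results$mirhub <- mirhub
    if (!is.null(de_set)) {
      cand <- list()
      if (!is.null(mirhub$stable)) {
        cand$stable <- candidate_regulators(mirhub$stable, de_set, "down")
      }
      if (!is.null(mirhub$unstable)) {
        cand$unstable <- candidate_regulators(mirhub$unstable, de_set, "up")
      }
      candidates <- dplyr::bind_rows(cand, .id = "gene_set")
      readr::write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
      results$candidates <- candidates
      logit("candidate regulators: ",
            if (nrow(candidates) > 0) {
              paste(candidates$mirna, collapse = ", ")
            } else "none")
    }
  } else {
    logit("skipping target-site enrichment (no target_sites.tsv or no classification)")
  }

  # --- correlation screen ---------------------------------------------------
  if (has("mirna_series.tsv") && has("rna_counts.tsv")) {
    ser <- readr::read_tsv(path("mirna_series.tsv"), col_types = "ccd",
                           progress = FALSE)
    rna <- read_counts_tsv(path("rna_counts.tsv"))
    m <- count_table_to_matrix(rna)
    m <- m[, ser$sample, drop = FALSE]
    sf <- estimate_size_factors(m)
    norm <- matrix_to_count_table(sweep(m, 2, sf, "/"), id_col = "gene_id")
    series <- setNames(ser$value, ser$sample)
    screen <- correlate_with_series(norm, series, threshold = 0.8)
    readr::write_tsv(screen, file.path(out_dir, "correlation_screen.tsv"))
    results$correlation_screen <- screen
    logit("correlation screen: ", sum(screen$passing), " genes passing")
  } else {
    logit("skipping correlation screen (no mirna_series.tsv)")
  }

  # --- summary --------------------------------------------------------------
  summary <- list(
    seed = seed, stageA = stageA, stageB = stageB,
    thresholds = unclass(thresholds),
    label_counts = if (!is.null(results$label_counts)) {
      setNames(as.list(results$label_counts$n), results$label_counts$label)
    },
    de_mirna = if (!is.null(de_set)) {
      list(up = length(de_set$up), down = length(de_set$down))
    },
    candidate_regulators = if (!is.null(results$candidates) &&
                               nrow(results$candidates) > 0) {
      results$candidates$mirna
    } else character(0),
    correlation_passing = if (!is.null(results$correlation_screen)) {
      sum(results$correlation_screen$passing)
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(log_lines, log_path)
  invisible(results)
}
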