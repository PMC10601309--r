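#' Quantification parameters
#'
#' Defaults follow standard practice for run-on data: reads in the first
#' 150 b downstream of the TSS are excluded to avoid promoter-proximal
#' pausing bias, genes with a body under 1 kb are excluded, miRNA loci are
#' quantified over a +/- 5 kb flank of the mature coordinate, and browser
#' tracks are scaled to a total signal of 1e6 reads.
#'
#' @param tss_exclusion_bp Width of the TSS-downstream exclusion window.
#' @param min_gene_length_bp Minimum gene-body length retained.
#' @param mirna_flank_bp Flank added on each side of a mature miRNA locus.
#' @param track_norm_total Target total signal for normalized tracks.
#' @return List of class `quant_params`.
#' @export
quant_params <- function(tss_exclusion_bp = 150L,
                         min_gene_length_bp = 1000L,
                         mirna_flank_bp = 5000L,
                         track_norm_total = 1e6) {
  p <- list(
    tss_exclusion_bp = as.integer(tss_exclusion_bp),
    min_gene_length_bp = as.integer(min_gene_length_bp),
    mirna_flank_bp = as.integer(mirna_flank_bp),
    track_norm_total = track_norm_total
  )
  if (any(unlist(p) < 0)) abort("quantification parameters must be >= 0")
  structure(p, class = "quant_params")
}

# Overlap of single-base read positions with 0-based half-open intervals.
# Returns a tibble of (read_row, interval_row) pairs; both inputs must be
# restricted to one chromosome by the caller.
#' @keywords internal
overlap_pairs <- function(positions, starts, ends) {
  if (length(positions) == 0 || length(starts) == 0) {
    return(tibble(read_row = integer(0), interval_row = integer(0)))
  }
  fo <- IRanges::findOverlaps(
    IRanges::IRanges(positions + 1L, positions + 1L),
    IRanges::IRanges(starts + 1L, ends)
  )
  tibble(read_row = S4Vectors::queryHits(fo),
         interval_row = S4Vectors::subjectHits(fo))
}

#' @keywords internal
prepare_reads <- function(reads, known_chroms) {
  stopifnot(is.data.frame(reads))
  need <- c("chrom", "position", "strand")
  if (!all(need %in% names(reads))) {
    abort("reads must have columns chrom, position, strand (plus count, sample)")
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  if (any(reads$count < 1)) abort("read counts must be >= 1")
  unknown <- setdiff(unique(reads$chrom), known_chroms)
  if (length(unknown) > 0) {
    warn(paste0("skipping reads on unknown chromosome(s): ",
                paste(unknown, collapse = ", ")))
    reads <- reads[reads$chrom %in% known_chroms, , drop = FALSE]
  }
  as_tibble(reads)
}

#' Count sense-strand reads over gene bodies with pause and TRE exclusion
#'
#' Counts single-base polymerase-position reads falling in gene bodies,
#' applying three rules: (i) genes with a body shorter than
#' `min_gene_length_bp` are dropped from the output entirely; (ii) reads in
#' the `tss_exclusion_bp` window downstream of the TSS (in the direction of
#' transcription) are excluded; (iii) reads overlapping any TRE interval
#' within the gene body are excluded.  Only reads on the gene's own strand
#' are counted.
#'
#' @param reads Tibble of read positions: chrom, position (0-based single
#'   base), strand, and optionally count (default 1), sample, stage.
#' @param genes Tibble of gene models: gene_id, chrom, start, end (0-based
#'   half-open), strand, tss.
#' @param tres Tibble of TRE intervals (chrom, start, end); `NULL` or empty
#'   for no TRE exclusion.  With `per_stage = TRUE`, a column
#'   `active_stages` (comma-separated stage labels) restricts each TRE's
#'   masking to reads from samples of those stages.
#' @param params A [quant_params()].
#' @param per_stage Mask TREs only in the stages they are active in
#'   (requires a `stage` column on `reads` and `active_stages` on `tres`).
#'   The default masks the union of all TREs in every sample.
#' @return Wide tibble: gene_id plus one count column per sample; genes
#'   failing the length filter are absent.
#' @export
count_gene_body <- function(reads, genes, tres = NULL,
                            params = quant_params(), per_stage = FALSE) {
  stopifnot(inherits(params, "quant_params"), is.data.frame(genes))
  if (any(genes$start >= genes$end)) abort("gene start must be < end")
  if (any(genes$tss < genes$start | genes$tss >= genes$end)) {
    abort("gene tss outside gene body")
  }
  genes <- genes[genes$end - genes$start >= params$min_gene_length_bp, ,
                 drop = FALSE]
  reads <- prepare_reads(reads, unique(genes$chrom))
  samples <- unique(reads$sample)
  if (per_stage &&
      (!"stage" %in% names(reads) || !"active_stages" %in% names(tres))) {
    abort("per_stage masking needs reads$stage and tres$active_stages")
  }

  pairs <- list()
  for (ch in unique(genes$chrom)) {
    g <- which(genes$chrom == ch)
    r <- which(reads$chrom == ch)
    ov <- overlap_pairs(reads$position[r], genes$start[g], genes$end[g])
    if (nrow(ov) == 0) next
    ridx <- r[ov$read_row]
    gidx <- g[ov$interval_row]
    keep <- reads$strand[ridx] == genes$strand[gidx]
    ridx <- ridx[keep]; gidx <- gidx[keep]
    # TSS-downstream pause window, in the direction of transcription
    excl <- params$tss_exclusion_bp
    pos <- reads$position[ridx]
    tss <- genes$tss[gidx]
    in_pause <- ifelse(genes$strand[gidx] == "+",
                       pos >= tss & pos < tss + excl,
                       pos <= tss & pos > tss - excl)
    ridx <- ridx[!in_pause]; gidx <- gidx[!in_pause]
    # TRE masking
    if (!is.null(tres) && nrow(tres) > 0) {
      tr <- which(tres$chrom == ch)
      if (length(tr) > 0 && length(ridx) > 0) {
        ur <- unique(ridx)
        ovt <- overlap_pairs(reads$position[ur], tres$start[tr], tres$end[tr])
        if (nrow(ovt) > 0) {
          if (per_stage) {
            tre_stage <- split_list_col(tres$active_stages[tr])
            masked <- vapply(seq_len(nrow(ovt)), function(i) {
              reads$stage[ur[ovt$read_row[i]]] %in%
                tre_stage[[ovt$interval_row[i]]]
            }, logical(1))
            bad <- unique(ur[ovt$read_row[masked]])
            # a read is masked only for samples whose stage activates the TRE,
            # so filter pairwise below
            drop <- ridx %in% bad
          } else {
            bad <- unique(ur[ovt$read_row])
            drop <- ridx %in% bad
          }
          ridx <- ridx[!drop]; gidx <- gidx[!drop]
        }
      }
    }
    if (length(ridx) > 0) {
      pairs[[ch]] <- tibble(gene_id = genes$gene_id[gidx],
                            sample = reads$sample[ridx],
                            count = reads$count[ridx])
    }
  }
  assemble_counts(dplyr::bind_rows(pairs), "gene_id", genes$gene_id, samples)
}

# long (id, sample, count) records -> dense wide table with zeros filled,
# stable row/column order even when no record or no sample exists
#' @keywords internal
assemble_counts <- function(long, id_col, ids, samples) {
  if (length(samples) == 0) samples <- "sample1"
  out <- matrix(0, length(ids), length(samples),
                dimnames = list(ids, samples))
  if (!is.null(long) && nrow(long) > 0) {
    agg <- long |>
      dplyr::group_by(dplyr::across(1:2)) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    out[cbind(match(agg[[1]], ids), match(agg[[2]], samples))] <- agg$count
  }
  matrix_to_count_table(out, id_col = id_col)
}

#' Length-normalize gene counts to transcripts per million
#'
#' `TPM_g = (count_g / length_kb_g) / sum_h(count_h / length_kb_h) * 1e6`,
#' using the full gene-body length.  An all-zero sample stays all-zero.
#'
#' @param counts Wide count tibble (gene_id + sample columns), typically
#'   from [count_gene_body()].
#' @param genes Gene models providing start/end for lengths.
#' @return Tibble of the same shape with TPM values; every column with any
#'   signal sums to 1e6.
#' @export
tpm_normalize <- function(counts, genes) {
  m <- count_table_to_matrix(counts)
  len <- (genes$end - genes$start)[match(rownames(m), genes$gene_id)]
  if (anyNA(len)) abort("all counted genes must be present in `genes`")
  rate <- m / (len / 1000)
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  matrix_to_count_table(tpm, id_col = "gene_id")
}

#' Count sense-strand reads over flanked miRNA loci
#'
#' Counts reads within `[start - flank, end + flank)` of each mature miRNA
#' coordinate (flank clipped at position 0), on the miRNA's strand.  No TSS
#' or TRE exclusion is applied: primary miRNA transcripts extend well
#' beyond the mature coordinate, which the flank is meant to capture.
#'
#' @param reads Read positions as in [count_gene_body()].
#' @param mirna_coords Tibble: mirna, chrom, start, end, strand.
#' @param params A [quant_params()].
#' @return Wide tibble: mirna plus one count column per sample.
#' @export
count_mirna_locus <- function(reads, mirna_coords, params = quant_params()) {
  stopifnot(inherits(params, "quant_params"), is.data.frame(mirna_coords))
  reads <- prepare_reads(reads, unique(mirna_coords$chrom))
  samples <- unique(reads$sample)
  fl <- params$mirna_flank_bp
  win_start <- pmax(0L, mirna_coords$start - fl)
  win_end <- mirna_coords$end + fl
  pairs <- list()
  for (ch in unique(mirna_coords$chrom)) {
    g <- which(mirna_coords$chrom == ch)
    r <- which(reads$chrom == ch)
    ov <- overlap_pairs(reads$position[r], win_start[g], win_end[g])
    if (nrow(ov) == 0) next
    ridx <- r[ov$read_row]
    gidx <- g[ov$interval_row]
    keep <- reads$strand[ridx] == mirna_coords$strand[gidx]
    if (!any(keep)) next
    pairs[[ch]] <- tibble(mirna = mirna_coords$mirna[gidx[keep]],
                          sample = reads$sample[ridx[keep]],
                          count = reads$count[ridx[keep]])
  }
  assemble_counts(dplyr::bind_rows(pairs), "mirna", mirna_coords$mirna,
                  samples)
}

#' Normalize a position track to a fixed total signal
#'
#' Aggregates read counts per (chrom, position, strand) and rescales so the
#' absolute sum of the signal equals `track_norm_total` (default 1e6).
#' Minus-strand signal is emitted as negative values, the usual convention
#' for stranded run-on browser tracks.
#'
#' @param reads Read positions (all samples are pooled; merge upstream if a
#'   per-sample track is wanted).
#' @param params A [quant_params()].
#' @return Tibble: chrom, start, end (position, position + 1), strand,
#'   score.  Empty input gives an empty tibble.
#' @export
normalize_track <- function(reads, params = quant_params()) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), score = numeric(0)))
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  agg <- reads |>
    dplyr::group_by(.data$chrom, .data$position, .data$strand) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  total <- sum(agg$count)
  agg |>
    dplyr::transmute(
      .data$chrom, start = .data$position, end = .data$position + 1L,
      .data$strand,
      score = ifelse(.data$strand == "-", -1, 1) * .data$count *
        params$track_norm_total / total
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

#' Write a normalized track as per-strand bedGraph files
#'
#' @param track Output of [normalize_track()].
#' @param path_prefix Files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written.
#' @return Invisibly, the paths written.
#' @export
write_track_bedgraph <- function(track, path_prefix) {
  paths <- c(plus = paste0(path_prefix, "_plus.bedGraph"),
             minus = paste0(path_prefix, "_minus.bedGraph"))
  for (s in c("plus", "minus")) {
    sub <- track[track$strand == ifelse(s == "plus", "+", "-"),
                 c("chrom", "start", "end", "score")]
    readr::write_tsv(sub, paths[[s]], col_names = FALSE)
  }
  invisible(paths)
}
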