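#' Proportional assignment of multi-mapped small-RNA reads
#'
#' Reads aligning equally well to several miRNA loci contribute their count
#' split across those loci.  The default splits equally
#' (`count / n_loci` to each locus); `weights = "unique"` instead splits in
#' proportion to each locus's uniquely mapped support, falling back to an
#' equal split when none of a read's loci has unique support.
#'
#' @param records Data frame: read_id, loci (comma-separated locus ids or a
#'   list column), count (positive).
#' @param weights `"equal"` or `"unique"`.
#' @return Tibble locus, count (fractional); total mass equals the input
#'   total exactly.
#' @export
assign_multimapped <- function(records, weights = c("equal", "unique")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(records),
            all(c("read_id", "loci", "count") %in% names(records)))
  loci <- split_list_col(records$loci)
  if (any(lengths(loci) == 0)) abort("every record needs at least one locus")
  if (any(records$count <= 0)) abort("record counts must be positive")
  n_loc <- lengths(loci)
  long <- tibble(
    read_id = rep(records$read_id, n_loc),
    locus = unlist(loci),
    total = rep(records$count, n_loc),
    n_loc = rep(n_loc, n_loc)
  )
  if (weights == "equal") {
    long$count <- long$total / long$n_loc
  } else {
    uniq <- long |>
      dplyr::filter(.data$n_loc == 1) |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(unique_support = sum(.data$total), .groups = "drop")
    long <- long |>
      dplyr::left_join(uniq, by = "locus") |>
      dplyr::mutate(unique_support = dplyr::coalesce(.data$unique_support, 0)) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::mutate(
        w = dplyr::if_else(rep(sum(.data$unique_support) > 0, dplyr::n()),
                           .data$unique_support / sum(.data$unique_support),
                           1 / dplyr::n()),
        count = .data$total * .data$w
      ) |>
      dplyr::ungroup()
  }
  long |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Reads-per-million-mapped-to-miRNAs normalization
#'
#' `RPMMM_ij = count_ij / sum_i(count_ij) * 1e6`; every sample with signal
#' sums to exactly one million.  All-zero samples stay zero.
#'
#' @param counts miRNA count table (mirna + sample columns).
#' @return Tibble of the same shape with RPMMM values.
#' @export
rpmmm_normalize <- function(counts) {
  m <- count_table_to_matrix(counts)
  tot <- colSums(m)
  r <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  out <- matrix_to_count_table(r, id_col = names(counts)[1])
  out
}

#' Differentially expressed miRNAs between two stages
#'
#' NB Wald testing on raw miRNA counts via the package engine, followed by
#' the standard filters: adjusted P below `mirna_alpha`, |log2FC| above
#' `mirna_abs_log2fc`, and maximum stage-mean RPMMM above
#' `mirna_rpmmm_min`.  Inputs that look like an RPMMM matrix (all column
#' sums equal to one million) are rejected: testing needs raw counts.
#' Fractional counts from multi-mapper splitting are accepted.
#'
#' @param counts Raw miRNA count table.
#' @param metadata Sample metadata (sample, stage).
#' @param stageA,stageB The comparison (log2FC is stageB vs stageA).
#' @param thresholds A [pt_thresholds()] (the miRNA fields are used).
#' @return List of class `de_mirna`: `transition`, `up`, `down` (miRNA id
#'   vectors) and `table`, the full results with `rpmmm_max_stage_mean` and
#'   a `de` flag.
#' @export
diff_mirna <- function(counts, metadata, stageA, stageB,
                       thresholds = pt_thresholds()) {
  stopifnot(inherits(thresholds, "pt_thresholds"))
  m <- count_table_to_matrix(counts)
  tot <- colSums(m)
  if (all(abs(tot - 1e6) < 1e-6 * 1e6)) {
    abort("counts look RPMMM-normalized (columns sum to 1e6); supply raw counts")
  }
  metadata <- check_metadata(metadata, colnames(m))
  fit <- nb_stage_test(counts, metadata, stageA, stageB)
  rp <- count_table_to_matrix(rpmmm_normalize(counts))
  stage_mean <- vapply(c(stageA, stageB), function(s) {
    j <- which(metadata$stage == s)
    rowMeans(rp[, j, drop = FALSE])
  }, numeric(nrow(rp)))
  rp_max <- apply(stage_mean, 1, max)
  th <- thresholds
  tab <- fit |>
    dplyr::mutate(
      rpmmm_max_stage_mean = rp_max[match(.data$feature, names(rp_max))],
      de = !is.na(.data$padj) & .data$padj < th$mirna_alpha &
        abs(.data$log2FC) > th$mirna_abs_log2fc &
        .data$rpmmm_max_stage_mean > th$mirna_rpmmm_min
    )
  structure(
    list(
      transition = paste0(stageA, "_to_", stageB),
      up = tab$feature[tab$de & tab$log2FC > 0],
      down = tab$feature[tab$de & tab$log2FC < 0],
      table = tab
    ),
    class = "de_mirna"
  )
}

#' @export
print.de_mirna <- function(x, ...) {
  cat("Differential miRNA set (", x$transition, "): ",
      length(x$up), " up, ", length(x$down), " down of ",
      nrow(x$table), " tested\n", sep = "")
  invisible(x)
}

#' @rdname diff_mirna
#' @param x A `de_mirna` object.
#' @param ... Unused.
#' @export
tidy.de_mirna <- function(x, ...) x$table

#' @rdname diff_mirna
#' @export
glance.de_mirna <- function(x, ...) {
  tibble(transition = x$transition, n_tested = nrow(x$table),
         n_up = length(x$up), n_down = length(x$down))
}
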