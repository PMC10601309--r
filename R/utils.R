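#' Convert a tidy count table to a numeric matrix
#'
#' Count tables throughout the package are tibbles whose first column holds
#' feature identifiers (genes or miRNAs) and whose remaining columns are one
#' numeric column per sample.
#'
#' @param counts A data frame: feature-id column followed by sample columns.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @keywords internal
count_table_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) abort("duplicate feature identifiers in count table")
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("sample columns of a count table must be numeric")
  if (any(m < 0, na.rm = TRUE)) abort("counts must be non-negative")
  rownames(m) <- ids
  m
}

#' @keywords internal
matrix_to_count_table <- function(m, id_col = "feature") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- character(nrow(m))
  dplyr::bind_cols(tibble(!!id_col := ids), as_tibble(m, .name_repair = "minimal"))
}

#' @keywords internal
check_metadata <- function(metadata, samples, need_stage = TRUE) {
  stopifnot(is.data.frame(metadata))
  if (!all(c("sample") %in% names(metadata))) {
    abort("metadata must contain a `sample` column")
  }
  if (need_stage && !"stage" %in% names(metadata)) {
    abort("metadata must contain a `stage` column")
  }
  missing <- setdiff(samples, metadata$sample)
  if (length(missing) > 0) {
    abort(paste0("samples absent from metadata: ", paste(missing, collapse = ", ")))
  }
  metadata[match(samples, metadata$sample), , drop = FALSE]
}

# Split "a,b,c" species/locus strings into character vectors; pass lists through.
#' @keywords internal
split_list_col <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  strsplit(as.character(x), ",", fixed = TRUE)
}

#' @keywords internal
`%||%` <- rlang::`%||%`
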