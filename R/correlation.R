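#' Spearman rank correlation with exact small-sample p-values
#'
#' Ranks are tie-averaged and rho is the Pearson correlation of the ranks.
#' For n <= 10 the two-sided p-value is computed by exact permutation
#' (enumeration over all arrangements, tie-aware); for larger n the usual
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble: rho, p, n, method ("exact_permutation" or "t_approx").
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("spearman correlation needs >= 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("spearman correlation undefined for a constant input")
  }
  rho <- cor(rx, ry)
  if (n <= 10) {
    p <- .perm_spearman_pvalue(rx, ry)
    method <- "exact_permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approx"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  tibble(rho = rho, p = p, n = n, method = method)
}

#' Correlate every gene with a reference expression series
#'
#' Ranks genes by their Spearman correlation with a single series (e.g. a
#' miRNA's expression) across matched samples or conditions, flagging the
#' genes that pass a correlation threshold.
#'
#' @param gene_matrix Expression table (gene id + sample columns).
#' @param series Named numeric vector (names matching the sample columns)
#'   or unnamed vector in column order.
#' @param threshold Cutoff on rho (one-sided: passing means
#'   `rho > threshold`).
#' @param use_squared Apply the threshold to rho^2 instead, in which case
#'   passing additionally requires rho > 0 (a positive-correlation screen).
#' @return Tibble sorted by decreasing rho: gene, rho, p, passing.
#' @export
correlate_with_series <- function(gene_matrix, series, threshold = 0.8,
                                  use_squared = FALSE) {
  m <- count_table_to_matrix(gene_matrix)
  if (!is.null(names(series))) {
    missing <- setdiff(colnames(m), names(series))
    if (length(missing) > 0) {
      abort(paste0("series lacks values for samples: ",
                   paste(missing, collapse = ", ")))
    }
    series <- series[colnames(m)]
  } else if (length(series) != ncol(m)) {
    abort("unnamed series must match the number of sample columns")
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (sd(rank(row)) == 0) {
      return(tibble(rho = NA_real_, p = NA_real_))
    }
    spearman_cor(row, series)[, c("rho", "p")]
  })
  out <- dplyr::bind_cols(tibble(gene = rownames(m)), dplyr::bind_rows(res))
  out |>
    dplyr::mutate(
      passing = !is.na(.data$rho) &
        if (use_squared) .data$rho > 0 & .data$rho^2 > threshold
        else .data$rho > threshold
    ) |>
    dplyr::arrange(dplyr::desc(.data$rho))
}

#' Correlation between summed promoter and enhancer TRE activity
#'
#' Sums per-sample activity within the promoter group and within the
#' enhancer group, then computes the Spearman correlation of the two sums
#' across samples.
#'
#' @param activities TRE activity table (tre_id + sample columns).
#' @param promoter_ids,enhancer_ids TRE ids of the two groups.
#' @return Tibble as from [spearman_cor()].
#' @export
tre_activity_correlation <- function(activities, promoter_ids, enhancer_ids) {
  m <- count_table_to_matrix(activities)
  missing <- setdiff(c(promoter_ids, enhancer_ids), rownames(m))
  if (length(missing) > 0) {
    abort(paste0("unknown TRE ids: ", paste(missing, collapse = ", ")))
  }
  prom <- colSums(m[promoter_ids, , drop = FALSE])
  enh <- colSums(m[enhancer_ids, , drop = FALSE])
  spearman_cor(prom, enh)
}
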