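# Independent brute-force oracles used to verify the package implementations.
# These deliberately use naive per-record loops and explicit formulas, never
# the code paths they check.

oracle_count_gene_body <- function(reads, genes, tres, params) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  genes <- genes[genes$end - genes$start >= params$min_gene_length_bp, ,
                 drop = FALSE]
  samples <- unique(reads$sample)
  out <- matrix(0, nrow(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  for (ri in seq_len(nrow(reads))) {
    pos <- reads$position[ri]
    in_tre <- FALSE
    if (!is.null(tres) && nrow(tres) > 0) {
      for (ti in seq_len(nrow(tres))) {
        if (tres$chrom[ti] == reads$chrom[ri] &&
            pos >= tres$start[ti] && pos < tres$end[ti]) {
          in_tre <- TRUE
          break
        }
      }
    }
    for (gi in seq_len(nrow(genes))) {
      if (genes$chrom[gi] != reads$chrom[ri]) next
      if (genes$strand[gi] != reads$strand[ri]) next
      if (pos < genes$start[gi] || pos >= genes$end[gi]) next
      excl <- params$tss_exclusion_bp
      tss <- genes$tss[gi]
      in_pause <- if (genes$strand[gi] == "+") {
        pos >= tss && pos < tss + excl
      } else {
        pos <= tss && pos > tss - excl
      }
      if (in_pause || in_tre) next
      out[gi, reads$sample[ri]] <- out[gi, reads$sample[ri]] + reads$count[ri]
    }
  }
  out
}

oracle_count_mirna <- function(reads, mirna_coords, params) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  samples <- unique(reads$sample)
  out <- matrix(0, nrow(mirna_coords), length(samples),
                dimnames = list(mirna_coords$mirna, samples))
  for (ri in seq_len(nrow(reads))) {
    for (mi in seq_len(nrow(mirna_coords))) {
      if (mirna_coords$chrom[mi] != reads$chrom[ri]) next
      if (mirna_coords$strand[mi] != reads$strand[ri]) next
      lo <- max(0, mirna_coords$start[mi] - params$mirna_flank_bp)
      hi <- mirna_coords$end[mi] + params$mirna_flank_bp
      pos <- reads$position[ri]
      if (pos >= lo && pos < hi) {
        out[mi, reads$sample[ri]] <- out[mi, reads$sample[ri]] + reads$count[ri]
      }
    }
  }
  out
}

# wide count tibble -> sorted long tibble, for shape-insensitive comparison
as_long_counts <- function(tab) {
  tab |>
    tidyr::pivot_longer(-1, names_to = "sample", values_to = "count") |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
}

oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- order(p[ok])
  sorted <- p[ok][ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m)) # step-up: min over j >= i
    adj[i] <- min(adj[i], 1)
  }
  out[ok[ord]] <- adj
  out
}

# tie-averaged ranks computed from first principles
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# all permutations of 1..n (recursive; only for tiny n)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# exact two-sided permutation p over all n! index permutations
oracle_perm_p <- function(x, y) {
  n <- length(x)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0L
  perms <- all_perms(n)
  for (p in perms) {
    r <- oracle_spearman_rho(x, y[p])
    if (abs(r) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / length(perms)
}

# small random genome instance for counting property tests
random_count_instance <- function(seed) {
  withr::with_seed(seed, {
    n_genes <- sample(4:9, 1)
    chroms <- c("chr1", "chr2")
    g_chrom <- sample(chroms, n_genes, replace = TRUE)
    g_start <- sample(0:8000, n_genes)
    g_len <- sample(80:1500, n_genes, replace = TRUE)
    g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = sprintf("G%02d", seq_len(n_genes)), chrom = g_chrom,
      start = g_start, end = g_start + g_len, strand = g_strand,
      tss = ifelse(g_strand == "+", g_start, g_start + g_len - 1L)
    )
    n_tre <- sample(0:5, 1)
    t_start <- sample(0:9000, n_tre)
    tres <- tibble::tibble(
      chrom = sample(chroms, n_tre, replace = TRUE),
      start = t_start, end = t_start + sample(50:400, n_tre, replace = TRUE)
    )
    n_reads <- sample(50:250, 1)
    reads <- tibble::tibble(
      chrom = sample(chroms, n_reads, replace = TRUE),
      position = sample(0:9500, n_reads, replace = TRUE),
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      count = sample(1:3, n_reads, replace = TRUE),
      sample = sample(c("s1", "s2"), n_reads, replace = TRUE)
    )
    params <- ptseq::quant_params(
      tss_exclusion_bp = sample(c(0L, 20L, 150L), 1),
      min_gene_length_bp = sample(c(50L, 500L, 1000L), 1),
      mirna_flank_bp = sample(c(100L, 1000L), 1)
    )
    list(genes = genes, tres = tres, reads = reads, params = params)
  })
}
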