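#' Scoring and Monte-Carlo parameters for target-site enrichment
#'
#' Site-type weights default to 3 (8mer), 2 (7mer-m8) and 1 (7mer-A1),
#' reflecting the usual strength ordering of canonical seed matches; the
#' weights are configurable and the enrichment statistics are
#' rank-invariant to their exact values.  The null distribution uses 1000
#' random gene sets by default.
#'
#' @param site_type_weights Named numeric weights per site type.
#' @param n_iterations Monte-Carlo iterations for the sampled null.
#' @param null_mode `"sampled"` draws `n_iterations` random sets;
#'   `"exhaustive"` enumerates all subsets when there are at most
#'   `exhaustive_limit`.
#' @param exhaustive_limit Maximum number of subsets enumerated.
#' @param conservation `"cons1"` keeps sites conserved in human plus at
#'   least one of chicken/dog/mouse/rat before scoring; `"none"` scores
#'   all sites.
#' @param seed Optional integer seed for the sampled null.
#' @return List of class `score_params`.
#' @export
score_params <- function(site_type_weights = c("8mer" = 3, "7mer-m8" = 2,
                                               "7mer-A1" = 1),
                         n_iterations = 1000L,
                         null_mode = c("sampled", "exhaustive"),
                         exhaustive_limit = 1e5,
                         conservation = c("cons1", "none"),
                         seed = NULL) {
  null_mode <- match.arg(null_mode)
  conservation <- match.arg(conservation)
  if (any(site_type_weights <= 0)) abort("site-type weights must be positive")
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  structure(
    list(site_type_weights = site_type_weights,
         n_iterations = as.integer(n_iterations), null_mode = null_mode,
         exhaustive_limit = exhaustive_limit, conservation = conservation,
         seed = seed),
    class = "score_params"
  )
}

#' Keep target sites conserved beyond human (cons1 filter)
#'
#' Retains sites whose conserving-species set contains human and at least
#' one of chicken, dog, mouse or rat.
#'
#' @param sites Site table: mirna, gene, site_type, species
#'   (comma-separated or list column).
#' @return Filtered tibble of the same shape.
#' @export
filter_cons1 <- function(sites) {
  stopifnot(is.data.frame(sites), "species" %in% names(sites))
  sp <- split_list_col(sites$species)
  extra <- c("chicken", "dog", "mouse", "rat")
  keep <- vapply(sp, function(s) "human" %in% s && any(extra %in% s),
                 logical(1))
  as_tibble(sites[keep, , drop = FALSE])
}

#' @keywords internal
site_weights <- function(sites, params) {
  w <- params$site_type_weights[as.character(sites$site_type)]
  if (anyNA(w)) abort("site table contains site types without a configured weight")
  unname(w)
}

#' Targeting score of a gene set for one miRNA
#'
#' The sum, over genes in the set, of the site-type weights of that gene's
#' sites for the miRNA in the supplied table (genes absent from the table
#' contribute 0).  Conservation filtering is *not* applied here; filter
#' with [filter_cons1()] first if wanted (the Monte-Carlo driver does this
#' according to its parameters).
#'
#' @param sites Site table.
#' @param gene_set Character vector of gene ids.
#' @param mirna Single miRNA id.
#' @param params A [score_params()] (for the weights).
#' @return Non-negative numeric score.
#' @export
set_targeting_score <- function(sites, gene_set, mirna,
                                params = score_params()) {
  sub <- sites[sites$mirna == mirna & sites$gene %in% gene_set, ,
               drop = FALSE]
  if (nrow(sub) == 0) return(0)
  sum(site_weights(sub, params))
}

# gene x mirna matrix of summed site weights (dense; desk-scale tables)
#' @keywords internal
weight_matrix <- function(sites, background, mirnas, params) {
  W <- matrix(0, length(background), length(mirnas),
              dimnames = list(background, mirnas))
  sub <- sites[sites$gene %in% background & sites$mirna %in% mirnas, ,
               drop = FALSE]
  if (nrow(sub) > 0) {
    w <- site_weights(sub, params)
    ij <- cbind(match(sub$gene, background), match(sub$mirna, mirnas))
    agg <- tapply(w, list(ij[, 1], ij[, 2]), sum)
    idx <- which(!is.na(agg), arr.ind = TRUE)
    W[cbind(as.integer(rownames(agg))[idx[, 1]],
            as.integer(colnames(agg))[idx[, 2]])] <- agg[idx]
  }
  W
}

#' Monte-Carlo target-site enrichment (miRhub-style)
#'
#' Tests, for each miRNA, whether the number and strength of its predicted
#' target sites in `gene_set` exceed chance expectation.  The null draws
#' random gene sets of the same size without replacement from the
#' background universe and scores them identically; the empirical p-value
#' is `(r + 1) / (n + 1)` with `r` the number of null scores at or above
#' the observed one (never zero by construction).  In exhaustive mode all
#' subsets are enumerated (when at most `exhaustive_limit`), giving the
#' exact tail probability `r / n` alongside.
#'
#' @param sites Site table; filtered per `params$conservation` first.
#' @param gene_set Gene ids whose enrichment is tested (must lie in the
#'   background).
#' @param mirnas miRNA ids to test; defaults to all miRNAs in the table.
#' @param params A [score_params()].
#' @param background Gene universe for null draws; defaults to all genes in
#'   the (filtered) site table, plus the gene set itself.
#' @return Tibble of class `mirhub_result`: mirna, observed_score,
#'   null_mean, null_sd, n_null, n_ge (null scores >= observed),
#'   empirical_p, exact_tail_p (exhaustive mode only, else NA).
#' @export
monte_carlo_enrichment <- function(sites, gene_set, mirnas = NULL,
                                   params = score_params(),
                                   background = NULL) {
  stopifnot(inherits(params, "score_params"))
  if (params$conservation == "cons1") sites <- filter_cons1(sites)
  mirnas <- mirnas %||% sort(unique(sites$mirna))
  background <- background %||% sort(unique(c(sites$gene, gene_set)))
  offenders <- setdiff(gene_set, background)
  if (length(offenders) > 0) {
    abort(paste0("gene_set members outside the background universe: ",
                 paste(head(offenders, 10), collapse = ", ")))
  }
  k <- length(gene_set)
  if (k > length(background)) abort("gene_set larger than background")
  W <- weight_matrix(sites, background, mirnas, params)
  observed <- colSums(W[match(gene_set, background), , drop = FALSE])

  exhaustive <- params$null_mode == "exhaustive"
  if (exhaustive) {
    n_subsets <- choose(length(background), k)
    if (n_subsets > params$exhaustive_limit) {
      abort("too many subsets for exhaustive mode; use null_mode = 'sampled'")
    }
    combs <- utils::combn(length(background), k)
    null_scores <- t(apply(combs, 2, function(ix) {
      colSums(W[ix, , drop = FALSE])
    }))
    if (length(mirnas) == 1) null_scores <- matrix(null_scores, ncol = 1)
  } else {
    draw <- function() {
      ix <- sample.int(length(background), k)
      colSums(W[ix, , drop = FALSE])
    }
    run <- function() {
      ns <- vapply(seq_len(params$n_iterations), function(i) draw(),
                   numeric(length(mirnas)))
      if (is.matrix(ns)) t(ns) else matrix(ns, ncol = 1)
    }
    null_scores <- if (!is.null(params$seed)) {
      withr::with_seed(params$seed, run())
    } else {
      run()
    }
  }
  n_null <- nrow(null_scores)
  n_ge <- vapply(seq_along(mirnas), function(j) {
    sum(null_scores[, j] >= observed[j] - 1e-12)
  }, numeric(1))
  out <- tibble(
    mirna = mirnas,
    observed_score = unname(observed),
    null_mean = colMeans(null_scores),
    null_sd = apply(null_scores, 2, sd),
    n_null = n_null,
    n_ge = n_ge,
    empirical_p = (n_ge + 1) / (n_null + 1),
    exact_tail_p = if (exhaustive) n_ge / n_null else NA_real_
  )
  class(out) <- c("mirhub_result", class(out))
  out
}

#' Candidate master regulators: enrichment meets differential expression
#'
#' Intersects miRNAs enriched for target sites in a gene set
#' (empirical P below `alpha`) with the direction-matched differential
#' set: stabilized genes implicate *down*-regulated miRNAs (suppression
#' lost) and destabilized genes implicate *up*-regulated miRNAs.
#'
#' @param mirhub_results A [monte_carlo_enrichment()] result for the gene
#'   set of interest.
#' @param de_set A [diff_mirna()] result.
#' @param direction `"down"` or `"up"`: which differential set to match.
#' @param alpha Empirical-p cutoff.
#' @return Tibble of candidate miRNAs sorted by empirical p.
#' @export
candidate_regulators <- function(mirhub_results, de_set,
                                 direction = c("down", "up"), alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(de_set, "de_mirna"))
  pool <- de_set[[direction]]
  mirhub_results |>
    dplyr::filter(.data$empirical_p < alpha, .data$mirna %in% pool) |>
    dplyr::arrange(.data$empirical_p) |>
    dplyr::mutate(direction = direction)
}

#' Screen up-regulated miRNAs for conserved sites on listed genes
#'
#' Returns the miRNAs of an up-regulated differential set that carry at
#' least one conserved (cons1) site on at least one of the listed genes
#' (or on all of them with `require_all = TRUE`), with one presence column
#' per gene.
#'
#' @param sites Site table.
#' @param tf_genes Character vector of gene ids of interest.
#' @param de_up Character vector of up-regulated miRNA ids (e.g.
#'   `de_set$up`).
#' @param require_all Require a site on every listed gene.
#' @return Tibble: mirna plus one logical column per listed gene.
#' @export
screen_de_mirna_sites <- function(sites, tf_genes, de_up,
                                  require_all = FALSE) {
  cons <- filter_cons1(sites)
  sub <- cons[cons$mirna %in% de_up & cons$gene %in% tf_genes, ,
              drop = FALSE]
  if (nrow(sub) == 0) {
    out <- tibble(mirna = character(0))
    for (g in tf_genes) out[[g]] <- logical(0)
    return(out)
  }
  wide <- sub |>
    dplyr::distinct(.data$mirna, .data$gene) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "present",
                       values_fill = FALSE)
  for (g in setdiff(tf_genes, names(wide))) wide[[g]] <- FALSE
  wide <- wide[, c("mirna", tf_genes)]
  if (require_all) {
    keep <- rowSums(as.matrix(wide[, tf_genes])) == length(tf_genes)
    wide <- wide[keep, , drop = FALSE]
  }
  dplyr::arrange(wide, .data$mirna)
}
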