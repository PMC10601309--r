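#' Decision thresholds for post-transcriptional classification
#'
#' Defaults are the published decision rules: interaction |log2FC| > 0.5 at
#' adjusted P < 0.05, expression gates of nascent TPM > 20 and steady-state
#' base mean > 100, the stringent criterion of nascent adjusted P > 0.1
#' with steady-state adjusted P < 0.05 and |log2FC| > 0.5, and the miRNA
#' filters RPMMM > 1000 (at least one stage), |log2FC| > 0.5, adjusted
#' P < 0.05.
#'
#' @param interaction_abs_log2fc,interaction_alpha Interaction-term cutoffs.
#' @param chro_tpm_min,rna_basemean_min Expression gates.
#' @param stringent_chro_alpha_floor Nascent adjusted-P floor ("no
#'   transcriptional change").
#' @param stringent_rna_alpha,stringent_rna_abs_log2fc Steady-state cutoffs
#'   for the stringent criterion.
#' @param mirna_rpmmm_min,mirna_abs_log2fc,mirna_alpha Differential-miRNA
#'   filters.
#' @return List of class `pt_thresholds`.
#' @export
pt_thresholds <- function(interaction_abs_log2fc = 0.5,
                          interaction_alpha = 0.05,
                          chro_tpm_min = 20,
                          rna_basemean_min = 100,
                          stringent_chro_alpha_floor = 0.1,
                          stringent_rna_alpha = 0.05,
                          stringent_rna_abs_log2fc = 0.5,
                          mirna_rpmmm_min = 1000,
                          mirna_abs_log2fc = 0.5,
                          mirna_alpha = 0.05) {
  th <- list(
    interaction_abs_log2fc = interaction_abs_log2fc,
    interaction_alpha = interaction_alpha,
    chro_tpm_min = chro_tpm_min, rna_basemean_min = rna_basemean_min,
    stringent_chro_alpha_floor = stringent_chro_alpha_floor,
    stringent_rna_alpha = stringent_rna_alpha,
    stringent_rna_abs_log2fc = stringent_rna_abs_log2fc,
    mirna_rpmmm_min = mirna_rpmmm_min,
    mirna_abs_log2fc = mirna_abs_log2fc, mirna_alpha = mirna_alpha
  )
  if (any(unlist(th) <= 0)) abort("all thresholds must be positive")
  alphas <- c(th$interaction_alpha, th$stringent_chro_alpha_floor,
              th$stringent_rna_alpha, th$mirna_alpha)
  if (any(alphas >= 1)) abort("alpha thresholds must lie in (0, 1)")
  structure(th, class = "pt_thresholds")
}

#' Classify genes as post-transcriptionally stable or unstable
#'
#' Applies the decision rules to one stage transition.  A gene passes the
#' expression gates when its maximum stage-mean nascent TPM exceeds
#' `chro_tpm_min` and its steady-state base mean exceeds
#' `rna_basemean_min`.  Gated genes with a significant interaction term
#' (adjusted P below `interaction_alpha`) are `stable` when the interaction
#' log2FC exceeds `interaction_abs_log2fc` (steady-state change outran
#' transcription: suppression lost) and `unstable` when it falls below the
#' negated cutoff.  Stable/unstable genes additionally showing no
#' transcriptional change (nascent adjusted P > floor) but a significant
#' steady-state change in the matching direction are promoted to
#' `stringent_stable` / `stringent_unstable`.  Remaining gated genes that
#' are significant in both assays in the same direction are `concordant`;
#' everything else (including genes whose GLM did not converge) is `none`.
#'
#' @param interaction Interaction-term results from
#'   [two_factor_interaction()].
#' @param chro_de,rna_de Per-assay stage tests from [nb_stage_test()].
#' @param chro_tpm Nascent TPM table (gene_id + sample columns).
#' @param metadata Sample metadata (sample, stage) covering the TPM
#'   columns, used for stage means.
#' @param stageA,stageB The transition's stages.
#' @param thresholds A [pt_thresholds()].
#' @return Tibble of class `pt_classification`: gene, label, provenance and
#'   the statistics the rules consulted.  Genes missing from any input
#'   table are excluded (a message reports how many).
#' @export
classify_pt <- function(interaction, chro_de, rna_de, chro_tpm, metadata,
                        stageA, stageB, thresholds = pt_thresholds()) {
  stopifnot(inherits(thresholds, "pt_thresholds"))
  tpm_m <- count_table_to_matrix(chro_tpm)
  metadata <- check_metadata(metadata, colnames(tpm_m))
  stage_means <- vapply(c(stageA, stageB), function(s) {
    j <- which(metadata$stage == s)
    if (length(j) == 0) abort(paste0("no TPM samples for stage ", s))
    rowMeans(tpm_m[, j, drop = FALSE])
  }, numeric(nrow(tpm_m)))
  tpm_max <- tibble(gene = rownames(tpm_m),
                    chro_tpm_max = apply(stage_means, 1, max))

  universe <- Reduce(intersect, list(interaction$feature, chro_de$feature,
                                     rna_de$feature, tpm_max$gene))
  n_drop <- length(unique(c(interaction$feature, chro_de$feature,
                            rna_de$feature, tpm_max$gene))) - length(universe)
  if (n_drop > 0) {
    inform(paste0(n_drop, " gene(s) absent from at least one input table; excluded"))
  }

  tab <- tibble(gene = universe) |>
    dplyr::left_join(
      dplyr::select(interaction, gene = "feature",
                    interaction_log2FC = "log2FC",
                    interaction_padj = "padj",
                    interaction_converged = "converged"),
      by = "gene") |>
    dplyr::left_join(
      dplyr::select(chro_de, gene = "feature", chro_log2FC = "log2FC",
                    chro_padj = "padj"),
      by = "gene") |>
    dplyr::left_join(
      dplyr::select(rna_de, gene = "feature", rna_log2FC = "log2FC",
                    rna_padj = "padj", rna_basemean = "baseMean"),
      by = "gene") |>
    dplyr::left_join(tpm_max, by = "gene")

  th <- thresholds
  tab <- tab |>
    dplyr::mutate(
      gates = !is.na(.data$chro_tpm_max) & !is.na(.data$rna_basemean) &
        .data$chro_tpm_max > th$chro_tpm_min &
        .data$rna_basemean > th$rna_basemean_min,
      sig_int = .data$interaction_converged &
        !is.na(.data$interaction_padj) &
        .data$interaction_padj < th$interaction_alpha,
      stable0 = .data$gates & .data$sig_int &
        .data$interaction_log2FC > th$interaction_abs_log2fc,
      unstable0 = .data$gates & .data$sig_int &
        .data$interaction_log2FC < -th$interaction_abs_log2fc,
      chro_quiet = !is.na(.data$chro_padj) &
        .data$chro_padj > th$stringent_chro_alpha_floor,
      rna_up = !is.na(.data$rna_padj) &
        .data$rna_padj < th$stringent_rna_alpha &
        .data$rna_log2FC > th$stringent_rna_abs_log2fc,
      rna_down = !is.na(.data$rna_padj) &
        .data$rna_padj < th$stringent_rna_alpha &
        .data$rna_log2FC < -th$stringent_rna_abs_log2fc,
      both_sig_same_dir = !is.na(.data$chro_padj) & !is.na(.data$rna_padj) &
        .data$chro_padj < th$stringent_rna_alpha &
        .data$rna_padj < th$stringent_rna_alpha &
        sign(.data$chro_log2FC) == sign(.data$rna_log2FC),
      label = dplyr::case_when(
        stable0 & chro_quiet & rna_up ~ "stringent_stable",
        unstable0 & chro_quiet & rna_down ~ "stringent_unstable",
        stable0 ~ "stable",
        unstable0 ~ "unstable",
        gates & both_sig_same_dir ~ "concordant",
        TRUE ~ "none"
      ),
      provenance = dplyr::case_when(
        label == "stringent_stable" ~ "interaction+gates+chro_quiet+rna_up",
        label == "stringent_unstable" ~ "interaction+gates+chro_quiet+rna_down",
        label %in% c("stable", "unstable") ~ "interaction+gates",
        label == "concordant" ~ "both_assays_same_direction",
        !gates ~ "failed_expression_gates",
        TRUE ~ "no_rule_fired"
      )
    ) |>
    dplyr::select("gene", "label", "provenance", "interaction_log2FC",
                  "interaction_padj", "chro_log2FC", "chro_padj",
                  "rna_log2FC", "rna_padj", "chro_tpm_max", "rna_basemean")
  class(tab) <- c("pt_classification", class(tab))
  tab
}

#' Tally classification labels
#'
#' @param classification A [classify_pt()] result.
#' @return Tibble `label`, `n` with one row per label (zeros included);
#'   counts sum to the classified gene universe.
#' @export
summarize_transition <- function(classification) {
  lv <- c("stable", "unstable", "stringent_stable", "stringent_unstable",
          "concordant", "none")
  classification |>
    dplyr::count(label = factor(.data$label, levels = lv), .drop = FALSE) |>
    dplyr::mutate(label = as.character(.data$label))
}

#' Extract gene sets from a classification
#'
#' The stringent labels are subsets of the broad ones: `stable` returns
#' genes labelled stable or stringent_stable, and likewise for unstable.
#'
#' @param classification A [classify_pt()] result.
#' @return Named list of gene-id vectors: stable, unstable,
#'   stringent_stable, stringent_unstable.
#' @export
pt_gene_sets <- function(classification) {
  lab <- classification$label
  g <- classification$gene
  list(
    stable = g[lab %in% c("stable", "stringent_stable")],
    unstable = g[lab %in% c("unstable", "stringent_unstable")],
    stringent_stable = g[lab == "stringent_stable"],
    stringent_unstable = g[lab == "stringent_unstable"]
  )
}
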