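#' Run the full differential-methylation pipeline
#'
#' Chains the preprocessing and differential steps in the fixed order of the
#' analysis: platform intersection, stacking, empirical-Bayes batch adjustment
#' (skipped when only one platform is present), sex-probe removal, replicate
#' averaging, then DMP calling, sliding-window MANOVA DMR calling and the
#' stringent separation filter.
#'
#' @param beta_450k,beta_epic platform beta matrices (either may be `NULL`).
#' @param sheet sample sheet (see [as_sample_sheet()]).
#' @param annotation probe annotation.
#' @param alpha BH threshold for DMPs and DMR windows.
#' @param delta_min DMP effect-size threshold (beta scale).
#' @param gap_min stringent-filter separation margin.
#' @param batch_adjust run ComBat on the stacked matrix (default TRUE when
#'   both platforms are present).
#' @param extra_sex_probes optional extra probe ids removed with the X/Y probes.
#' @return list: `beta` (processed probes x samples), `dmp`, `dmr`,
#'   `stringent` (DMR table with `is_stringent` set), `enrichment`,
#'   `pca`, `n_probes` (probe counts after each filter step).
#' @export
run_pipeline <- function(beta_450k, beta_epic, sheet, annotation,
                         alpha = 0.05, delta_min = 0.10, gap_min = 0.0,
                         batch_adjust = TRUE, extra_sex_probes = NULL) {
  counts <- c()
  if (!is.null(beta_450k) && !is.null(beta_epic)) {
    ip <- intersect_platforms(beta_450k, beta_epic)
    counts["shared"] <- nrow(ip$m450)
    comb <- combine_platforms(ip$m450, ip$mepic)
    if (batch_adjust) {
      phen <- sheet$phenotype[match(comb$sample_id, sheet$sample_id)]
      comb$beta <- combat_adjust(comb$beta, comb$batch, covariate = phen)
    }
    stacked <- comb$beta
  } else {
    stacked <- if (is.null(beta_epic)) beta_450k else beta_epic
    counts["shared"] <- nrow(stacked)
    colnames(stacked) <- paste0(colnames(stacked), "@single")
  }
  stacked <- drop_sex_probes(stacked, annotation, extra_sex_probes)
  counts["autosomal"] <- nrow(stacked)
  beta <- merge_replicates(stacked)
  dmp <- call_dmps(beta, sheet, alpha = alpha, delta_min = delta_min)
  dmr <- call_dmrs(beta, sheet, annotation, alpha = alpha, dmp_table = dmp)
  stringent <- stringent_filter(dmr, beta, sheet, gap_min = gap_min)
  enr <- region_enrichment(dmp, annotation)
  pca <- pca_overview(beta, k = min(4, ncol(beta) - 1L))
  list(beta = beta, dmp = dmp, dmr = dmr, stringent = stringent,
       enrichment = enr, pca = pca, n_probes = counts)
}
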