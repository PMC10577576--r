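#' Validate a sample sheet and derive the phenotype factor
#'
#' The phenotype contrast of the whole analysis is fully determined by the
#' condition: CS samples form the Progeroid group, WT and UVSS samples are
#' merged into the NonProgeroid group.
#'
#' @param sheet data.frame with columns `sample_id`, `condition` (WT/UVSS/CS),
#'   `subtype`, `sex`, `age_years`, `age_is_censored`, `platforms`.
#' @return the sheet with a `phenotype` column added.
#' @export
as_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids")
  if (!all(sheet$condition %in% c("WT", "UVSS", "CS")))
    stop("condition must be WT, UVSS or CS")
  sheet$phenotype <- ifelse(sheet$condition == "CS", "Progeroid", "NonProgeroid")
  sheet
}

#' Restrict two beta matrices to their shared probes
#'
#' Mirrors the cross-platform step of the pipeline: both matrices are cut down
#' to the identical, sorted set of probes present on both arrays.
#'
#' @param m450,mepic probes x samples beta matrices with probe ids as rownames.
#' @return list of the two matrices restricted to the shared probe set.
#' @export
intersect_platforms <- function(m450, mepic) {
  if (!nrow(m450) || !nrow(mepic)) stop("empty beta matrix")
  shared <- sort(intersect(rownames(m450), rownames(mepic)))
  if (!length(shared)) stop("no probes shared between the two platforms")
  list(m450 = m450[shared, , drop = FALSE],
       mepic = mepic[shared, , drop = FALSE])
}

#' Stack the two platform matrices into one measurement matrix
#'
#' Columns are measurements, named `sample@platform`, so a sample replicated on
#' both platforms contributes two columns. Input matrices must already share
#' the same probe set (see [intersect_platforms()]).
#'
#' @param m450,mepic matrices over the same probes.
#' @return list `beta` (probes x measurements), `batch` (platform per column),
#'   `sample_id` (sample per column).
#' @export
combine_platforms <- function(m450, mepic) {
  if (!identical(rownames(m450), rownames(mepic)))
    stop("matrices must share the same probe rows; run intersect_platforms() first")
  beta <- cbind(m450, mepic)
  batch <- c(rep("450k", ncol(m450)), rep("EPIC", ncol(mepic)))
  sample_id <- c(colnames(m450), colnames(mepic))
  colnames(beta) <- paste0(sample_id, "@", batch)
  list(beta = beta, batch = batch, sample_id = sample_id)
}

#' Empirical-Bayes batch adjustment of beta values
#'
#' Adjusts per-probe location/scale batch effects with the parametric
#' empirical-Bayes ComBat model (per-probe standardisation; per-batch per-probe
#' location and scale estimates shrunk toward batch-level normal /
#' inverse-gamma priors; adjust, rescale, restore), protecting an optional
#' biological covariate. Output is clipped back to \[0, 1\].
#'
#' A single batch level is a no-op (returned unchanged). Probes with zero
#' variance across all samples cannot be standardised and are passed through
#' unchanged with a warning.
#'
#' @param beta probes x samples (or measurements) matrix.
#' @param batch per-column batch label; every batch needs >= 2 columns.
#' @param covariate optional per-column group label protected during adjustment.
#' @return adjusted matrix, same dimensions and dimnames.
#' @export
combat_adjust <- function(beta, batch, covariate = NULL) {
  stopifnot(is.matrix(beta), length(batch) == ncol(beta))
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) return(beta)
  if (any(table(batch) < 2))
    stop("every batch needs at least 2 samples")
  v <- apply(beta, 1, stats::var)
  const <- !is.na(v) & v == 0
  if (any(const))
    warning(sum(const), " zero-variance probe(s) passed through unadjusted")
  work <- beta[!const, , drop = FALSE]
  mod <- NULL
  if (!is.null(covariate)) mod <- stats::model.matrix(~ as.factor(covariate))
  adj <- suppressMessages(sva::ComBat(dat = work, batch = batch, mod = mod))
  out <- beta
  out[!const, ] <- pmin(pmax(adj, 0), 1)
  out
}

#' Remove probes on the sex chromosomes
#'
#' Drops all probes annotated to chromosomes X or Y; optionally also removes a
#' user-supplied list of sex-associated autosomal probes.
#'
#' @param beta probes x samples matrix.
#' @param annotation probe annotation with `probe_id` and `chr`.
#' @param extra_probes optional character vector of additional probe ids to drop.
#' @return the filtered matrix.
#' @export
drop_sex_probes <- function(beta, annotation, extra_probes = NULL) {
  sex <- annotation$probe_id[annotation$chr %in% c("X", "Y")]
  drop <- union(sex, extra_probes)
  beta[!(rownames(beta) %in% drop), , drop = FALSE]
}

#' Average replicate measurements of the same sample
#'
#' Applied after batch adjustment: columns carrying the same sample id (from
#' `sample@platform` column names, or an explicit `sample_ids` vector) are
#' averaged; a value missing on one platform falls back to the other.
#'
#' @param beta probes x measurements matrix.
#' @param sample_ids optional per-column sample ids; defaults to column names
#'   with a trailing `@platform` suffix removed.
#' @return probes x samples matrix, one column per sample, in first-appearance
#'   order.
#' @export
merge_replicates <- function(beta, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sub("@[^@]*$", "", colnames(beta))
  stopifnot(length(sample_ids) == ncol(beta))
  ids <- unique(sample_ids)
  out <- matrix(NA_real_, nrow(beta), length(ids),
                dimnames = list(rownames(beta), ids))
  for (s in ids) {
    cols <- beta[, sample_ids == s, drop = FALSE]
    out[, s] <- rowMeans(cols, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' PCA overview of samples
#'
#' Principal components of the sample x probe matrix after per-probe mean
#' centering (no scaling: beta values share a common scale).
#'
#' @param beta probes x samples matrix (no missing values).
#' @param k number of components to return.
#' @return list `scores` (samples x k), `explained` (variance fractions,
#'   non-increasing), `sdev`.
#' @export
pca_overview <- function(beta, k = 2) {
  k <- min(k, ncol(beta) - 1L, nrow(beta))
  pc <- stats::prcomp(t(beta), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], sdev = pc$sdev)
}

#' Hierarchical clustering of samples on a probe subset
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of samples
#' on the given probes; the 2-cluster cut is returned alongside the tree.
#'
#' @param beta probes x samples matrix.
#' @param probes optional probe-id subset (default: all rows).
#' @param k number of clusters for the cut.
#' @return list `hclust` (the tree, `NULL` for a single sample) and `labels`
#'   (named cluster assignment).
#' @export
hierarchical_cluster <- function(beta, probes = NULL, k = 2) {
  if (!is.null(probes)) beta <- beta[rownames(beta) %in% probes, , drop = FALSE]
  n <- ncol(beta)
  if (n == 1)
    return(list(hclust = NULL, labels = stats::setNames(1L, colnames(beta))))
  hc <- stats::hclust(stats::dist(t(beta)), method = "complete")
  labels <- stats::cutree(hc, k = min(k, n))
  list(hclust = hc, labels = labels)
}
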