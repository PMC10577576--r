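#' Per-dataset methylation change summary
#'
#' Wraps a dataset's per-probe methylation change (mean beta in cases minus
#' mean beta in controls) and its own significance calls into the container
#' used by the cross-dataset comparisons.
#'
#' @param label dataset name.
#' @param delta named numeric vector of per-probe deltas.
#' @param significant named logical (or character vector of significant probe
#'   ids); defaults to none.
#' @return list of class `dataset_delta`.
#' @export
dataset_delta <- function(label, delta, significant = NULL) {
  stopifnot(!is.null(names(delta)))
  if (is.null(significant)) {
    sig <- character(0)
  } else if (is.logical(significant)) {
    sig <- names(delta)[significant]
  } else sig <- as.character(significant)
  structure(list(label = label, delta = delta, significant = sig),
            class = "dataset_delta")
}

#' Pairwise correlation of methylation changes across datasets
#'
#' Pearson correlation of per-probe delta vectors for every dataset pair,
#' computed on the probes shared by the pair (optionally intersected with a
#' probe subset, e.g. a DMP list). Diagonal is 1.
#'
#' @param deltas list of [dataset_delta()] objects.
#' @param probe_subset optional character vector restricting the probes.
#' @return symmetric correlation matrix with dataset labels.
#' @export
delta_correlation_matrix <- function(deltas, probe_subset = NULL) {
  labels <- vapply(deltas, `[[`, character(1), "label")
  k <- length(deltas)
  m <- diag(1, k); dimnames(m) <- list(labels, labels)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    shared <- intersect(names(deltas[[i]]$delta), names(deltas[[j]]$delta))
    if (!is.null(probe_subset)) shared <- intersect(shared, probe_subset)
    if (length(shared) < 3) { m[i, j] <- m[j, i] <- NA_real_; next }
    r <- stats::cor(deltas[[i]]$delta[shared], deltas[[j]]$delta[shared])
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Overlap of two differential lists with direction concordance
#'
#' Builds the 2x2 table of membership in list A against membership in list B
#' over a common universe, tests it with a two-sided Fisher exact test, and —
#' when per-item deltas are given — counts common items whose changes have the
#' same sign (concordant hypo-/hypermethylation).
#'
#' @param listA,listB character vectors (subsets of `universe`).
#' @param universe character vector of all comparable items.
#' @param deltasA,deltasB optional named deltas for the concordance count.
#' @return list: `contingency`, `n_common`, `odds_ratio` (cross-product, 0.5
#'   correction flagged via `zero_cell`), `p`, `n_concordant`,
#'   `pct_concordant` (`NA` when no common items or no deltas).
#' @export
overlap_test <- function(listA, listB, universe, deltasA = NULL, deltasB = NULL) {
  if (!length(universe)) stop("empty universe")
  if (!all(listA %in% universe) || !all(listB %in% universe))
    stop("lists must be subsets of the universe")
  inA <- universe %in% listA
  inB <- universe %in% listB
  a <- sum(inA & inB); b <- sum(inA & !inB)
  c <- sum(!inA & inB); d <- sum(!inA & !inB)
  zero <- any(c(a, b, c, d) == 0)
  or <- if (zero) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5)) else (a * d) / (b * c)
  p <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
  n_conc <- NA_integer_; pct <- NA_real_
  common <- universe[inA & inB]
  if (length(common) && !is.null(deltasA) && !is.null(deltasB)) {
    sa <- sign(deltasA[common]); sb <- sign(deltasB[common])
    ok <- !is.na(sa) & !is.na(sb)
    n_conc <- sum(sa[ok] == sb[ok])
    pct <- 100 * n_conc / sum(ok)
  }
  list(contingency = matrix(c(a, b, c, d), 2, byrow = TRUE,
                            dimnames = list(c("inA", "notA"), c("inB", "notB"))),
       n_common = a, odds_ratio = or, p = p, zero_cell = zero,
       n_concordant = n_conc, pct_concordant = pct)
}

#' Correlation between regional methylation and expression
#'
#' Pearson correlation of per-sample mean beta over a region with per-sample
#' expression; R squared and the two-sided p-value from
#' t = r sqrt((n-2)/(1-r^2)). The strength classification follows the bands
#' used in the study: strong for 0.4 <= R^2 <= 0.9, moderate for
#' 0.2 <= R^2 < 0.4, weak otherwise; significant when p < 0.05.
#'
#' @param meth,expr paired numeric vectors (>= 3 samples).
#' @return list: `r`, `r_squared`, `p`, `n`, `strength`, `significant`. All
#'   statistics `NA` when either vector is constant.
#' @export
methylation_expression_correlation <- function(meth, expr) {
  ok <- !is.na(meth) & !is.na(expr)
  meth <- meth[ok]; expr <- expr[ok]
  n <- length(meth)
  if (n < 3) stop("need at least 3 paired samples")
  if (stats::sd(meth) == 0 || stats::sd(expr) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n,
                strength = NA_character_, significant = NA))
  r <- stats::cor(meth, expr)
  r2 <- r^2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  strength <- if (r2 >= 0.4 && r2 <= 0.9) "strong" else
    if (r2 >= 0.2) "moderate" else "weak"
  list(r = r, r_squared = r2, p = p, n = n, strength = strength,
       significant = p < 0.05)
}

#' Overlap of differentially methylated genes with differentially expressed genes
#'
#' Fisher overlap of the two gene lists over a universe, plus a cross-table of
#' methylation direction (hypo/hyper) against expression direction (up/down)
#' on the common genes and the inverse-correlation fraction
#' (hypo&up + hyper&down over common).
#'
#' @param dmr_genes data.frame `gene`, `direction` (hypo/hyper).
#' @param de_genes data.frame `gene`, `direction` (up/down).
#' @param universe character vector of all comparable genes.
#' @return list: `overlap` ([overlap_test()] result), `cross_table` (2x2),
#'   `inverse_fraction` (`NA` when no common genes).
#' @export
de_overlap <- function(dmr_genes, de_genes, universe) {
  ov <- overlap_test(unique(dmr_genes$gene), unique(de_genes$gene), universe)
  common <- intersect(dmr_genes$gene, de_genes$gene)
  ct <- matrix(0L, 2, 2, dimnames = list(c("hypo", "hyper"), c("up", "down")))
  inv <- NA_real_
  if (length(common)) {
    md <- dmr_genes$direction[match(common, dmr_genes$gene)]
    ed <- de_genes$direction[match(common, de_genes$gene)]
    for (g in seq_along(common)) ct[md[g], ed[g]] <- ct[md[g], ed[g]] + 1L
    inv <- (ct["hypo", "up"] + ct["hyper", "down"]) / length(common)
  }
  list(overlap = ov, cross_table = ct, inverse_fraction = inv)
}
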