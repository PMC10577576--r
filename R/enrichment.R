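#' Aggregate probe-level significance to genes (best-probe Sidak)
#'
#' Each gene is scored by its best (smallest) raw probe p-value, corrected for
#' the number of probes annotated to the gene with the Sidak best-of-n rule
#' p_gene = 1 - (1 - min p)^n. Under the null this is uniform regardless of
#' probe count, which removes the probe-number bias of array gene scoring.
#'
#' @param dmp_table [call_dmps()] output.
#' @param annotation probe annotation with comma-separated `genes`.
#' @return data.frame `gene`, `n_probes`, `min_p`, `p_gene`.
#' @export
aggregate_gene_p <- function(dmp_table, annotation) {
  ann <- annotation[match(dmp_table$probe_id, annotation$probe_id), ]
  keep <- !is.na(dmp_table$p) & !is.na(ann$genes) & ann$genes != ""
  genes <- strsplit(ann$genes[keep], ",", fixed = TRUE)
  reps <- lengths(genes)
  long <- data.frame(gene = unlist(genes),
                     p = rep(dmp_table$p[keep], reps),
                     stringsAsFactors = FALSE)
  n <- tapply(long$p, long$gene, length)
  minp <- tapply(long$p, long$gene, min)
  p_gene <- 1 - (1 - minp)^n
  p_gene <- pmin(pmax(p_gene, .Machine$double.xmin), 1)
  data.frame(gene = names(n), n_probes = as.integer(n),
             min_p = as.numeric(minp), p_gene = as.numeric(p_gene),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probe-count-adjusted gene-set test
#'
#' Logistic regression of set membership on -log10(p_gene) with log(n_probes)
#' as covariate; a positive coefficient on -log10(p_gene) indicates that
#' significant genes are enriched in the set, and the reported p is the
#' one-sided Wald p for that coefficient. On complete separation (or
#' non-convergence) the p-value falls back to a seeded membership permutation
#' test on the difference of mean -log10(p_gene) between set and complement.
#'
#' @param scores [aggregate_gene_p()] output.
#' @param set character vector of gene symbols (or a list with a `genes`
#'   element, as read by [read_gmt()]).
#' @param n_perm permutations for the fallback.
#' @param seed seed for the fallback permutations.
#' @return list `coefficient`, `se`, `p`, `n_overlap`, `method`
#'   (`"wald"` or `"permutation"`).
#' @export
geneset_test <- function(scores, set, n_perm = 10000L, seed = 1L) {
  if (is.list(set) && !is.null(set$genes)) set <- set$genes
  if (nrow(scores) < 10) stop("need at least 10 scored genes")
  member <- scores$gene %in% set
  if (!any(member)) stop("gene set does not overlap the scored genes")
  if (all(member)) stop("degenerate gene set: contains every scored gene")
  x <- -log10(scores$p_gene)
  lp <- log(scores$n_probes)
  fit <- suppressWarnings(stats::glm(member ~ x + lp, family = stats::binomial()))
  co <- summary(fit)$coefficients
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
    any(fit$fitted.values < 1e-10) || co["x", 2] > 1e3
  if (!separated) {
    z <- co["x", 1] / co["x", 2]
    return(list(coefficient = co["x", 1], se = co["x", 2],
                p = stats::pnorm(z, lower.tail = FALSE),
                n_overlap = sum(member), method = "wald"))
  }
  set.seed(seed)
  obs <- mean(x[member]) - mean(x[!member])
  k <- sum(member)
  perm <- replicate(n_perm, {
    pm <- sample(length(x), k)
    mean(x[pm]) - mean(x[-pm])
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(coefficient = co["x", 1], se = NA_real_, p = p,
       n_overlap = sum(member), method = "permutation")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, genes.
#'
#' @param path GMT file.
#' @return named list of gene sets, each `list(set_id, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    list(set_id = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "set_id"))
}

#' Test a collection of gene sets and BH-adjust
#'
#' @param scores [aggregate_gene_p()] output.
#' @param sets list of gene sets from [read_gmt()].
#' @param ... passed to [geneset_test()].
#' @return data.frame `set_id`, `n_overlap`, `coefficient`, `p`, `p_adj`,
#'   `method`.
#' @export
geneset_test_all <- function(scores, sets, ...) {
  rows <- lapply(sets, function(s) {
    r <- geneset_test(scores, s, ...)
    data.frame(set_id = s$set_id, n_overlap = r$n_overlap,
               coefficient = r$coefficient, p = r$p, method = r$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("set_id", "n_overlap", "coefficient", "p", "p_adj", "method")]
}
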