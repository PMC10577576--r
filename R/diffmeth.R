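#' Call differentially methylated positions (DMPs)
#'
#' Per-probe one-way ANOVA of beta on the Progeroid vs NonProgeroid contrast
#' (with two groups the F statistic is the squared pooled-variance t), BH
#' correction across all tested probes, then the joint significance /
#' effect-size rule: a probe is a DMP when the BH-adjusted p is below `alpha`
#' and the absolute group difference in mean beta exceeds `delta_min` (default
#' 10%). Direction is named from the progeroid side: `hypo` means lower
#' methylation in the progeroid group.
#'
#' Probes with missing values use the available samples; probes with fewer
#' than 2 usable samples in either group get a missing p and are excluded from
#' the BH multiplicity count.
#'
#' @param beta probes x samples matrix (sex probes already removed).
#' @param sheet sample sheet with `phenotype` (see [as_sample_sheet()]).
#' @param alpha BH-adjusted significance threshold.
#' @param delta_min minimum absolute difference in mean beta.
#' @return data.frame: `probe_id`, `f_stat`, `p`, `p_adj`, `delta`
#'   (Progeroid - NonProgeroid), `direction`, `is_dmp`.
#' @export
call_dmps <- function(beta, sheet, alpha = 0.05, delta_min = 0.10) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  if (anyNA(sheet$phenotype)) stop("samples missing from the sample sheet")
  g1 <- sheet$phenotype == "Progeroid"
  g2 <- !g1
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 samples per phenotype group")
  st <- .two_group_f(beta[, g1, drop = FALSE], beta[, g2, drop = FALSE])
  p_adj <- bh_adjust(st$p)
  direction <- ifelse(st$delta > 0, "hyper", ifelse(st$delta < 0, "hypo", NA))
  is_dmp <- !is.na(p_adj) & p_adj < alpha & abs(st$delta) > delta_min
  data.frame(probe_id = rownames(beta), f_stat = st$f, p = st$p, p_adj = p_adj,
             delta = st$delta, direction = direction, is_dmp = is_dmp,
             stringsAsFactors = FALSE, row.names = NULL)
}

## vectorized two-group F over matrix rows, NA-tolerant
.two_group_f <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  usable <- n1 >= 2 & n2 >= 2
  df2 <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df2
  f <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  zerovar <- usable & sp2 == 0
  f[zerovar & m1 == m2] <- 0
  p[zerovar & m1 == m2] <- 1
  f[zerovar & m1 != m2] <- Inf
  p[zerovar & m1 != m2] <- 0
  f[!usable] <- NA_real_; p[!usable] <- NA_real_
  delta <- m1 - m2
  delta[n1 == 0 | n2 == 0] <- NA_real_
  list(f = f, p = p, delta = delta, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; missing p-values stay missing and do not
#' count toward the number of tests.
#'
#' @param pvals numeric vector of raw p-values (may contain `NA`).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Pillai trace MANOVA of a probe window on a two-level grouping
#'
#' Computes the between (H) and within (E) sums-of-squares-and-cross-products
#' matrices of the window's beta vectors, the Pillai trace
#' V = tr(H (H+E)^-1), and the exact F for the two-group case:
#' F = V/(1-V) * (n-p-1)/p on (p, n-p-1) degrees of freedom.
#'
#' @param y samples x probes matrix for one window.
#' @param grouping two-level factor over the samples.
#' @param ridge diagonal regularisation added to H+E when singular (set to 0
#'   to disable).
#' @return list `pillai`, `f`, `df1`, `df2`, `p`.
#' @export
pillai_window <- function(y, grouping, ridge = 1e-6) {
  y <- as.matrix(y)
  grouping <- factor(grouping)
  n <- nrow(y); p <- ncol(y)
  if (nlevels(grouping) != 2) stop("two groups required")
  if (n - p - 1 < 1) stop("too few samples for a ", p, "-probe window")
  gm <- colMeans(y)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lev in levels(grouping)) {
    yk <- y[grouping == lev, , drop = FALSE]
    mk <- colMeans(yk)
    H <- H + nrow(yk) * tcrossprod(mk - gm)
    E <- E + crossprod(sweep(yk, 2, mk))
  }
  T <- H + E
  inv <- tryCatch(solve(T), error = function(e) NULL)
  if (is.null(inv)) {
    if (ridge <= 0) stop("singular total SSCP and regularisation disabled")
    warning("singular within-group covariance; ridge-regularised")
    inv <- solve(T + diag(ridge, p))
  }
  V <- sum(diag(H %*% inv))
  V <- min(max(V, 0), 1 - 1e-12)
  f <- (V / (1 - V)) * (n - p - 1) / p
  list(pillai = V, f = f, df1 = p, df2 = n - p - 1,
       p = stats::pf(f, p, n - p - 1, lower.tail = FALSE))
}

#' Call differentially methylated regions (DMRs) by sliding-window MANOVA
#'
#' Probes sharing an `island_id` (the island plus its annotated shores and
#' shelves) form a block; only gene-annotated blocks are scanned, Open Sea
#' probes are excluded. Every window of `window` chromosomally adjacent probes
#' (step 1) is tested by one-way MANOVA (Pillai trace, exact F) of the probe
#' vector on the Progeroid/NonProgeroid phenotype; BH correction runs across
#' all windows. Significant windows overlapping within a block are merged into
#' one region: probe set = union, p and adjusted p = minimum across merged
#' windows, Pillai trace from the best window. Direction follows the lead
#' probe — the member probe with the smallest BH-adjusted per-probe ANOVA p
#' (ties broken by larger |delta|, then probe id).
#'
#' @param beta probes x samples matrix.
#' @param sheet sample sheet with `phenotype`.
#' @param annotation probe annotation.
#' @param alpha BH threshold for window significance.
#' @param window window width in probes.
#' @param dmp_table optional precomputed [call_dmps()] table for the lead-probe
#'   rule; computed internally when absent.
#' @param ridge regularisation for singular windows (see [pillai_window()]).
#' @return data.frame of merged significant regions: `island_id`, `chr`,
#'   `relation`, `genes`, `probe_ids` (comma-separated), `n_probes`, `pillai`,
#'   `p`, `p_adj`, `lead_probe`, `delta`, `direction`, `is_stringent` (`NA`
#'   until [stringent_filter()] runs). Attribute `n_windows` carries the
#'   number of windows tested, `n_blocks_skipped` the blocks with < `window`
#'   probes.
#' @export
call_dmrs <- function(beta, sheet, annotation, alpha = 0.05, window = 3L,
                      dmp_table = NULL, ridge = 1e-6) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  grouping <- factor(sheet$phenotype)
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  eligible <- !is.na(ann$island_id) & ann$island_id != ""
  blocks <- split(which(eligible), ann$island_id[eligible])
  gene_assoc <- vapply(blocks, function(ix) any(ann$genes[ix] != ""), logical(1))
  blocks <- blocks[gene_assoc]
  skipped <- sum(vapply(blocks, length, integer(1)) < window)
  blocks <- blocks[vapply(blocks, length, integer(1)) >= window]

  wins <- list(); wi <- 0L
  for (id in names(blocks)) {
    ix <- blocks[[id]]
    ix <- ix[order(ann$pos[ix])]
    for (s in seq_len(length(ix) - window + 1L)) {
      sel <- ix[s:(s + window - 1L)]
      res <- pillai_window(t(beta[sel, , drop = FALSE]), grouping, ridge)
      wi <- wi + 1L
      wins[[wi]] <- list(island_id = id, probes = rownames(beta)[sel],
                         pillai = res$pillai, p = res$p)
    }
  }
  empty <- data.frame(island_id = character(0), chr = character(0),
                      relation = character(0), genes = character(0),
                      probe_ids = character(0), n_probes = integer(0),
                      pillai = numeric(0), p = numeric(0), p_adj = numeric(0),
                      lead_probe = character(0), delta = numeric(0),
                      direction = character(0), is_stringent = logical(0),
                      stringsAsFactors = FALSE)
  if (!wi) {
    attr(empty, "n_windows") <- 0L; attr(empty, "n_blocks_skipped") <- skipped
    return(empty)
  }
  p_raw <- vapply(wins, `[[`, numeric(1), "p")
  p_adj <- bh_adjust(p_raw)
  sig <- which(p_adj < alpha)
  if (!length(sig)) {
    attr(empty, "n_windows") <- wi; attr(empty, "n_blocks_skipped") <- skipped
    return(empty)
  }
  if (is.null(dmp_table)) dmp_table <- call_dmps(beta, sheet)

  ## merge overlapping significant windows within a block
  regions <- list()
  for (id in unique(vapply(wins[sig], `[[`, character(1), "island_id"))) {
    wix <- sig[vapply(wins[sig], `[[`, character(1), "island_id") == id]
    ord_ix <- blocks[[id]][order(ann$pos[blocks[[id]]])]
    probe_order <- rownames(beta)[ord_ix]
    starts <- vapply(wix, function(w) match(wins[[w]]$probes[1], probe_order),
                     integer(1))
    o <- order(starts)
    wix <- wix[o]; starts <- starts[o]
    cur <- list(w = wix[1], lo = starts[1], hi = starts[1] + window - 1L)
    flush <- function(cur) {
      members <- probe_order[cur$lo:cur$hi]
      ws <- cur$w
      best <- ws[which.min(p_raw[ws])]
      lead <- .lead_probe(members, dmp_table)
      data.frame(island_id = id,
                 chr = ann$chr[match(lead$probe_id, ann$probe_id)],
                 relation = ann$relation[match(lead$probe_id, ann$probe_id)],
                 genes = paste(setdiff(unique(
                   ann$genes[match(members, ann$probe_id)]), ""), collapse = ","),
                 probe_ids = paste(members, collapse = ","),
                 n_probes = length(members),
                 pillai = wins[[best]]$pillai,
                 p = min(p_raw[ws]), p_adj = min(p_adj[ws]),
                 lead_probe = lead$probe_id, delta = lead$delta,
                 direction = ifelse(lead$delta > 0, "hyper", "hypo"),
                 is_stringent = NA, stringsAsFactors = FALSE)
    }
    for (j in seq_along(wix)[-1]) {
      if (starts[j] <= cur$hi) {        # windows share >=1 probe: extend
        cur$hi <- max(cur$hi, starts[j] + window - 1L)
        cur$w <- c(cur$w, wix[j])
      } else {
        regions[[length(regions) + 1L]] <- flush(cur)
        cur <- list(w = wix[j], lo = starts[j], hi = starts[j] + window - 1L)
      }
    }
    regions[[length(regions) + 1L]] <- flush(cur)
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$p_adj, out$p, out$island_id), ]
  rownames(out) <- NULL
  attr(out, "n_windows") <- wi
  attr(out, "n_blocks_skipped") <- skipped
  out
}

.lead_probe <- function(members, dmp_table) {
  d <- dmp_table[match(members, dmp_table$probe_id), ]
  d <- d[!is.na(d$p_adj), , drop = FALSE]
  if (!nrow(d)) return(list(probe_id = members[1], delta = 0))
  d <- d[order(d$p_adj, -abs(d$delta), d$probe_id), ]
  list(probe_id = d$probe_id[1], delta = d$delta[1])
}

#' Flag stringent DMRs: unambiguous group separation
#'
#' For each region, the per-sample mean beta over the region's probes is
#' computed; the region is stringent when the progeroid and non-progeroid
#' value ranges are disjoint with margin at least `gap_min` (the maximum of
#' one group plus `gap_min` does not exceed the minimum of the other). This
#' rejects regions where UVSS samples sit between WT and CS, which separate
#' the phenotype groups only ambiguously.
#'
#' @param dmrs [call_dmrs()] output.
#' @param beta probes x samples matrix used for the regions.
#' @param sheet sample sheet with `phenotype`.
#' @param gap_min required separation margin on the beta scale.
#' @return `dmrs` with `is_stringent` filled in.
#' @export
stringent_filter <- function(dmrs, beta, sheet, gap_min = 0.0) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  prog <- sheet$phenotype == "Progeroid"
  flag <- logical(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    pr <- intersect(strsplit(dmrs$probe_ids[i], ",", fixed = TRUE)[[1]],
                    rownames(beta))
    m <- colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
    a <- m[prog]; b <- m[!prog]
    flag[i] <- (max(a) + gap_min <= min(b)) || (max(b) + gap_min <= min(a))
  }
  dmrs$is_stringent <- flag
  dmrs
}

#' Genomic-region enrichment of DMPs
#'
#' For every island-relation category and direction, builds the 2x2 table of
#' category membership against DMP status (DMPs of the given direction versus
#' non-DMP probes; DMPs of the opposite direction are excluded from the
#' comparison) over all tested probes, and tests it with a two-sided Fisher
#' exact test. The odds ratio is the cross-product (a d)/(b c); when a zero
#' cell occurs, 0.5 is added to every cell for the ratio and the record is
#' flagged.
#'
#' @param dmps [call_dmps()] output (all tested probes).
#' @param annotation probe annotation.
#' @return data.frame: `category`, `direction`, `a`,`b`,`c`,`d` (counts:
#'   in-category DMP, in-category non-DMP, out-category DMP, out-category
#'   non-DMP), `odds_ratio`, `p`, `zero_cell`.
#' @export
region_enrichment <- function(dmps, annotation) {
  ann <- annotation[match(dmps$probe_id, annotation$probe_id), ]
  tested <- !is.na(dmps$p_adj)
  out <- list()
  for (dir in c("hypo", "hyper")) {
    isd <- tested & dmps$is_dmp & dmps$direction == dir
    bg <- tested & !dmps$is_dmp
    for (cat in .relation_levels) {
      inc <- ann$relation == cat
      a <- sum(isd & inc); c <- sum(isd & !inc)
      b <- sum(bg & inc); d <- sum(bg & !inc)
      zero <- any(c(a, b, c, d) == 0)
      or <- if (zero) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5)) else (a * d) / (b * c)
      p <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
      out[[length(out) + 1L]] <- data.frame(
        category = cat, direction = dir, a = a, b = b, c = c, d = d,
        odds_ratio = or, p = p, zero_cell = zero, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Export DMRs as a BED file
#'
#' Writes 0-based half-open intervals spanning the first to last probe of each
#' region; name is `gene|island_id`, score is -10 log10(adjusted p) capped at
#' 1000.
#'
#' @param dmrs [call_dmrs()] output.
#' @param annotation probe annotation (for positions).
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
export_dmrs_bed <- function(dmrs, annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# DMR intervals: chrom start end name score (BED, 0-based half-open)",
             con)
  if (!nrow(dmrs)) return(invisible(data.frame()))
  rows <- lapply(seq_len(nrow(dmrs)), function(i) {
    pr <- strsplit(dmrs$probe_ids[i], ",", fixed = TRUE)[[1]]
    pos <- annotation$pos[match(pr, annotation$probe_id)]
    chr <- annotation$chr[match(pr[1], annotation$probe_id)]
    gene <- strsplit(dmrs$genes[i], ",", fixed = TRUE)[[1]][1]
    if (is.na(gene) || gene == "") gene <- "NA"
    score <- if (dmrs$p_adj[i] <= 0) 1000 else
      min(1000, -10 * log10(dmrs$p_adj[i]))
    data.frame(chrom = paste0("chr", chr), start = min(pos) - 1L,
               end = max(pos), name = paste0(gene, "|", dmrs$island_id[i]),
               score = round(score, 2), stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
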