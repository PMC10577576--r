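#' Simulation configuration for a synthetic dual-platform methylation cohort
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate the
#' study cohort: 12 fibroblast samples (3 wild-type, 2 UVSS, 7 Cockayne-syndrome
#' patients across four clinical subtypes), seven of which are measured on both
#' the 450k and EPIC platforms, with a platform-level batch shift, CpG-island
#' block structure along chromosomes, and planted differential positions and
#' regions with known signed effects.
#'
#' @param n_islands number of CpG-island blocks to generate.
#' @param probes_per_island integer range `c(min, max)` of island probes per block.
#' @param opensea_probes number of isolated (Open Sea) probes.
#' @param shore_probes_per_side,shelf_probes_per_side probes flanking each island
#'   on each side, labelled `N_Shore`/`S_Shore` and `N_Shelf`/`S_Shelf`.
#' @param n_samples_per_group named counts for groups
#'   `WT`, `UVSS`, `CS-I_CSA`, `CS-I_CSB`, `CS-II`, `CS-III`.
#' @param replicated_samples number of samples measured on both platforms.
#' @param batch_shift_sd sd (beta scale) of the per-probe offset applied to the
#'   EPIC platform.
#' @param noise_sd within-group measurement sd on the beta scale.
#' @param n_dmp_true number of planted isolated differential positions.
#' @param n_dmr_true number of planted 3-probe differential regions.
#' @param dmr_effect signed-magnitude beta-scale effect (progeroid minus
#'   non-progeroid) used for planted positions and regions.
#' @param n_uvss_intermediate number of additional planted regions where UVSS
#'   samples sit halfway between WT and CS means (full effect in CS, half in
#'   UVSS); these are the regions the stringent separation filter must reject.
#' @param sexprobe_fraction fraction of probes placed on chromosomes X/Y.
#'   Default 0.023 mirrors the 10,585 / 452,567 sex-probe share of the shared
#'   450k/EPIC manifest.
#' @param gene_fraction fraction of island blocks annotated to a gene.
#' @param platform_shared fraction of probes present on both platforms.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_islands = 300,
                       probes_per_island = c(3L, 8L),
                       opensea_probes = 500,
                       shore_probes_per_side = 1L,
                       shelf_probes_per_side = 1L,
                       n_samples_per_group = c(WT = 3L, UVSS = 2L,
                                               `CS-I_CSA` = 2L, `CS-I_CSB` = 2L,
                                               `CS-II` = 2L, `CS-III` = 1L),
                       replicated_samples = 7L,
                       batch_shift_sd = 0.05,
                       noise_sd = 0.05,
                       n_dmp_true = 100L,
                       n_dmr_true = 20L,
                       dmr_effect = 0.30,
                       n_uvss_intermediate = 5L,
                       sexprobe_fraction = 0.023,
                       gene_fraction = 0.8,
                       platform_shared = 0.9,
                       seed = 1L) {
  stopifnot(n_islands >= 1, opensea_probes >= 0,
            length(probes_per_island) == 2, probes_per_island[1] >= 1,
            probes_per_island[2] >= probes_per_island[1],
            shore_probes_per_side >= 0, shelf_probes_per_side >= 0,
            replicated_samples >= 0, batch_shift_sd >= 0, noise_sd >= 0,
            n_dmp_true >= 0, n_dmr_true >= 0, n_uvss_intermediate >= 0,
            sexprobe_fraction >= 0, sexprobe_fraction <= 1,
            gene_fraction >= 0, gene_fraction <= 1,
            platform_shared > 0, platform_shared <= 1)
  grp <- c(WT = 0L, UVSS = 0L, `CS-I_CSA` = 0L, `CS-I_CSB` = 0L,
           `CS-II` = 0L, `CS-III` = 0L)
  grp[names(n_samples_per_group)] <- as.integer(n_samples_per_group)
  if (sum(grp) < 3) stop("need at least 3 samples in total")
  if (replicated_samples > sum(grp)) stop("more replicated samples than samples")
  cfg <- list(n_islands = as.integer(n_islands),
              probes_per_island = as.integer(probes_per_island),
              opensea_probes = as.integer(opensea_probes),
              shore_probes_per_side = as.integer(shore_probes_per_side),
              shelf_probes_per_side = as.integer(shelf_probes_per_side),
              n_samples_per_group = grp,
              replicated_samples = as.integer(replicated_samples),
              batch_shift_sd = batch_shift_sd, noise_sd = noise_sd,
              n_dmp_true = as.integer(n_dmp_true),
              n_dmr_true = as.integer(n_dmr_true),
              dmr_effect = dmr_effect,
              n_uvss_intermediate = as.integer(n_uvss_intermediate),
              sexprobe_fraction = sexprobe_fraction,
              gene_fraction = gene_fraction,
              platform_shared = platform_shared,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.relation_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
.chrom_levels <- c(as.character(1:22), "X", "Y")

#' Generate a synthetic probe annotation table
#'
#' Lays out CpG-island blocks (shelf, shore, island probes, shore, shelf, in
#' strictly increasing genomic position) plus isolated Open Sea probes over
#' chromosomes 1-22 with a configurable fraction on X/Y. Each block shares an
#' `island_id` of the form `chrN:start-end` (1-based inclusive, spanning the
#' island probes) and is optionally annotated to a gene. Platform membership
#' (`on_450k`, `on_epic`) marks a shared subset plus platform-exclusive probes.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `probe_id`, `chr`, `pos`, `relation`,
#'   `island_id`, `genes` (comma-separated, `""` if none), `on_450k`, `on_epic`,
#'   sorted by chromosome then position.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  total_blocks <- config$n_islands
  if (total_blocks + config$opensea_probes == 0) stop("zero probes requested")
  set.seed(config$seed)

  island_chr <- .sim_chromosomes(total_blocks, config$sexprobe_fraction)
  sea_chr <- .sim_chromosomes(config$opensea_probes, config$sexprobe_fraction)
  n_isl_probes <- sample(seq(config$probes_per_island[1],
                             config$probes_per_island[2]),
                         total_blocks, replace = TRUE)
  has_gene <- stats::runif(total_blocks) < config$gene_fraction

  cursor <- stats::setNames(rep(1000L, length(.chrom_levels)), .chrom_levels)
  rows <- vector("list", total_blocks + (config$opensea_probes > 0))
  gene_idx <- 0L
  for (b in seq_len(total_blocks)) {
    chr <- island_chr[b]
    start <- cursor[chr]
    nshelf <- config$shelf_probes_per_side
    nshore <- config$shore_probes_per_side
    ni <- n_isl_probes[b]
    pos <- integer(0); rel <- character(0)
    p <- start
    if (nshelf > 0) { pos <- c(pos, p + seq_len(nshelf) * 500L); rel <- c(rel, rep("N_Shelf", nshelf)); p <- max(pos) }
    if (nshore > 0) { pos <- c(pos, p + seq_len(nshore) * 400L); rel <- c(rel, rep("N_Shore", nshore)); p <- max(pos) }
    isl_pos <- p + cumsum(sample(30:80, ni, replace = TRUE))
    pos <- c(pos, isl_pos); rel <- c(rel, rep("Island", ni)); p <- max(pos)
    if (nshore > 0) { pos <- c(pos, p + seq_len(nshore) * 400L); rel <- c(rel, rep("S_Shore", nshore)); p <- max(pos) }
    if (nshelf > 0) { pos <- c(pos, p + seq_len(nshelf) * 500L); rel <- c(rel, rep("S_Shelf", nshelf)); p <- max(pos) }
    cursor[chr] <- p + sample(5000:20000, 1L)
    island_id <- sprintf("chr%s:%d-%d", chr, min(isl_pos), max(isl_pos))
    gene <- ""
    if (has_gene[b]) { gene_idx <- gene_idx + 1L; gene <- sprintf("GENE%04d", gene_idx) }
    rows[[b]] <- data.frame(chr = chr, pos = as.integer(pos), relation = rel,
                            island_id = island_id, genes = gene,
                            stringsAsFactors = FALSE)
  }
  if (config$opensea_probes > 0) {
    sea_pos <- integer(config$opensea_probes)
    for (i in seq_len(config$opensea_probes)) {
      chr <- sea_chr[i]
      sea_pos[i] <- cursor[chr] + sample(1000:5000, 1L)
      cursor[chr] <- sea_pos[i]
    }
    sea_gene <- ifelse(stats::runif(config$opensea_probes) < 0.3,
                       sprintf("GENE%04d", gene_idx + seq_len(config$opensea_probes)), "")
    rows[[total_blocks + 1L]] <- data.frame(chr = sea_chr, pos = sea_pos,
                                            relation = "OpenSea", island_id = "",
                                            genes = sea_gene,
                                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann$probe_id <- sprintf("cg%08d", seq_len(nrow(ann)))
  shared <- stats::runif(nrow(ann)) < config$platform_shared
  excl_epic <- !shared & stats::runif(nrow(ann)) < 0.5
  ann$on_450k <- shared | !excl_epic
  ann$on_epic <- shared | excl_epic
  ord <- order(match(ann$chr, .chrom_levels), ann$pos)
  ann <- ann[ord, c("probe_id", "chr", "pos", "relation", "island_id",
                    "genes", "on_450k", "on_epic")]
  rownames(ann) <- NULL
  ann
}

.sim_chromosomes <- function(n, sex_fraction) {
  if (n == 0) return(character(0))
  is_sex <- stats::runif(n) < sex_fraction
  chr <- sample(as.character(1:22), n, replace = TRUE)
  chr[is_sex] <- sample(c("X", "Y"), sum(is_sex), replace = TRUE)
  chr
}

#' Simulate a dual-platform methylation cohort with planted ground truth
#'
#' Draws per-probe baseline methylation from the bimodal mixture
#' 0.5 Beta(2,8) + 0.5 Beta(8,2), plants signed effects (`dmr_effect`) on
#' isolated positions and on runs of three adjacent probes within
#' gene-annotated island blocks, adds i.i.d. Gaussian noise on the beta scale,
#' applies a per-probe platform offset (sd `batch_shift_sd`) to the EPIC
#' matrix, and clips all values to \[0, 1\]. Effects are added to CS
#' (progeroid) samples; in "UVSS-intermediate" regions UVSS samples receive
#' half the effect, placing them between WT and CS. Replicated samples appear
#' in both matrices under the same sample id. Planted signs are hypo-biased
#' (3:1), matching the predominance of hypomethylation in the progeroid group.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()] for the same config.
#' @return list with `beta_450k`, `beta_epic` (probes x samples matrices),
#'   `sheet` (sample sheet data.frame with derived `phenotype`), and `truth`
#'   (list `dmp` = data.frame(probe_id, effect); `dmr` = data.frame(island_id,
#'   probe_ids, effect, uvss_intermediate); `uvss_intermediate` = island ids).
#' @export
simulate_cohort <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sheet <- .sim_sample_sheet(config)
  n_probe <- nrow(annotation)

  ## baseline bimodal methylome
  lo <- stats::rbinom(n_probe, 1, 0.5) == 1
  mu <- ifelse(lo, stats::rbeta(n_probe, 2, 8), stats::rbeta(n_probe, 8, 2))
  names(mu) <- annotation$probe_id

  truth <- .plant_effects(config, annotation)
  eff <- stats::setNames(numeric(n_probe), annotation$probe_id)
  eff[truth$probe_effects$probe_id] <- truth$probe_effects$effect
  ## redraw baselines of planted probes so mean +/- effect stays inside (0,1)
  planted <- truth$probe_effects$probe_id
  if (length(planted)) {
    e <- eff[planted]
    lo_b <- 0.05 - pmin(e, 0)
    hi_b <- 0.95 - pmax(e, 0)
    bad <- lo_b >= hi_b
    if (any(bad)) {
      warning(sum(bad), " planted effect(s) push the mean outside (0,1); clipped")
      mid <- pmin(pmax((lo_b + hi_b) / 2, 0), 1)
      lo_b[bad] <- mid[bad]; hi_b[bad] <- mid[bad]
    }
    mu[planted] <- stats::runif(length(planted), lo_b, hi_b)
  }

  ## per-sample mean matrix: effect in CS; half effect for UVSS in intermediate regions
  half <- stats::setNames(numeric(n_probe), annotation$probe_id)
  inter_probes <- unlist(strsplit(
    truth$dmr$probe_ids[truth$dmr$uvss_intermediate], ",", fixed = TRUE))
  half[inter_probes] <- eff[inter_probes] / 2
  is_cs <- sheet$condition == "CS"
  is_uvss <- sheet$condition == "UVSS"
  M <- matrix(mu, n_probe, nrow(sheet),
              dimnames = list(annotation$probe_id, sheet$sample_id))
  M[, is_cs] <- M[, is_cs] + eff
  M[, is_uvss] <- M[, is_uvss] + half

  plat_offset <- stats::rnorm(n_probe, 0, config$batch_shift_sd)
  draw <- function(samples, platform) {
    keep <- if (platform == "450k") annotation$on_450k else annotation$on_epic
    mm <- M[keep, samples, drop = FALSE]
    if (platform == "EPIC") mm <- mm + plat_offset[keep]
    x <- mm + stats::rnorm(length(mm), 0, config$noise_sd)
    pmin(pmax(x, 0), 1)
  }
  on450 <- vapply(strsplit(sheet$platforms, ","), function(p) "450k" %in% p, logical(1))
  onepic <- vapply(strsplit(sheet$platforms, ","), function(p) "EPIC" %in% p, logical(1))
  beta_450k <- draw(sheet$sample_id[on450], "450k")
  beta_epic <- draw(sheet$sample_id[onepic], "EPIC")

  list(beta_450k = beta_450k, beta_epic = beta_epic, sheet = sheet,
       truth = list(dmp = truth$dmp, dmr = truth$dmr,
                    uvss_intermediate = truth$dmr$island_id[truth$dmr$uvss_intermediate]))
}

.sim_sample_sheet <- function(config) {
  grp <- config$n_samples_per_group
  grp <- grp[grp > 0]
  ids <- unlist(lapply(names(grp), function(g)
    sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", g), seq_len(grp[g]))))
  subtype <- rep(names(grp), grp)
  condition <- ifelse(subtype == "WT", "WT",
                      ifelse(subtype == "UVSS", "UVSS", "CS"))
  ## CS-I CSA patients male, CS-I CSB female (mirrors the cohort's sex split);
  ## others alternate
  sex <- rep(c("F", "M"), length.out = length(ids))
  sex[subtype == "CS-I_CSA"] <- "M"
  sex[subtype == "CS-I_CSB"] <- "F"
  age <- numeric(length(ids))
  age[condition == "WT"] <- round(stats::runif(sum(condition == "WT"), 20, 50), 1)
  age[condition == "UVSS"] <- round(stats::runif(sum(condition == "UVSS"), 15, 45), 1)
  age[condition == "CS"] <- round(stats::runif(sum(condition == "CS"), 3, 25), 1)
  censored <- condition == "CS" & stats::runif(length(ids)) < 0.5
  plat <- character(length(ids))
  rep_idx <- seq_len(min(config$replicated_samples, length(ids)))
  plat[rep_idx] <- "450k,EPIC"
  rest <- setdiff(seq_along(ids), rep_idx)
  plat[rest] <- rep(c("450k", "EPIC"), length.out = length(rest))
  sheet <- data.frame(sample_id = ids, condition = condition, subtype = subtype,
                      sex = sex, age_years = age, age_is_censored = censored,
                      platforms = plat, stringsAsFactors = FALSE)
  as_sample_sheet(sheet)
}

## choose planted probes/regions; returns probe-level effects and truth tables
.plant_effects <- function(config, annotation) {
  shared <- annotation$on_450k & annotation$on_epic &
    !(annotation$chr %in% c("X", "Y"))
  sign_draw <- function(n) ifelse(stats::runif(n) < 0.75, -1, 1)

  ## candidate blocks: gene-annotated islands with >=3 adjacent shared probes
  blocky <- annotation$island_id != "" & shared
  blocks <- split(which(blocky), annotation$island_id[blocky])
  blocks <- blocks[vapply(blocks, function(ix)
    length(ix) >= 3 && any(annotation$genes[ix] != ""), logical(1))]
  n_regions <- config$n_dmr_true + config$n_uvss_intermediate
  if (n_regions > length(blocks))
    stop("not enough eligible island blocks to plant ", n_regions, " regions")
  picked <- sample(names(blocks), n_regions)
  dmr_rows <- lapply(picked, function(id) {
    ix <- blocks[[id]]
    ix <- ix[order(annotation$pos[ix])]
    start <- sample(seq_len(length(ix) - 2L), 1L)
    sel <- ix[start:(start + 2L)]
    data.frame(island_id = id,
               probe_ids = paste(annotation$probe_id[sel], collapse = ","),
               effect = sign_draw(1) * config$dmr_effect,
               stringsAsFactors = FALSE)
  })
  dmr <- if (length(dmr_rows)) do.call(rbind, dmr_rows) else
    data.frame(island_id = character(0), probe_ids = character(0),
               effect = numeric(0), stringsAsFactors = FALSE)
  dmr$uvss_intermediate <- seq_len(nrow(dmr)) > config$n_dmr_true

  region_probes <- unlist(strsplit(dmr$probe_ids, ",", fixed = TRUE))
  free <- which(shared & !(annotation$probe_id %in% region_probes))
  if (config$n_dmp_true > length(free))
    stop("not enough free probes to plant ", config$n_dmp_true, " positions")
  dmp_ix <- sample(free, config$n_dmp_true)
  dmp <- data.frame(probe_id = annotation$probe_id[dmp_ix],
                    effect = sign_draw(config$n_dmp_true) * config$dmr_effect,
                    stringsAsFactors = FALSE)

  reg_eff <- data.frame(
    probe_id = region_probes,
    effect = rep(dmr$effect, times = vapply(strsplit(dmr$probe_ids, ","),
                                            length, integer(1))),
    stringsAsFactors = FALSE)
  list(dmp = dmp, dmr = dmr, probe_effects = rbind(dmp, reg_eff))
}

#' Simulate expression coupled to regional methylation
#'
#' For genes of planted differential regions, a configurable fraction are
#' inversely coupled to methylation: expression is a negative-slope linear
#' function of the gene's per-sample mean beta plus Gaussian noise. The
#' remaining planted genes and a set of null genes are drawn independently of
#' methylation.
#'
#' @param beta probes x samples beta matrix (post-preprocessing).
#' @param annotation probe annotation (for the probe-to-gene map).
#' @param truth truth set from [simulate_cohort()].
#' @param inverse_fraction fraction of planted genes inversely coupled.
#' @param noise_sd sd of expression noise.
#' @param n_null_genes uncoupled genes to add.
#' @param seed integer seed.
#' @return list `expr` (genes x samples matrix) and `gene_truth`
#'   (data.frame gene, inverse).
#' @export
simulate_expression <- function(beta, annotation, truth, inverse_fraction = 0.6,
                                noise_sd = 0.5, n_null_genes = 50L, seed = 1L) {
  stopifnot(inverse_fraction >= 0, inverse_fraction <= 1)
  set.seed(seed)
  dmr <- truth$dmr
  genes <- character(nrow(dmr))
  for (i in seq_len(nrow(dmr))) {
    pr <- strsplit(dmr$probe_ids[i], ",", fixed = TRUE)[[1]]
    g <- setdiff(unique(annotation$genes[match(pr, annotation$probe_id)]), "")
    if (!length(g)) {
      g <- setdiff(unique(
        annotation$genes[annotation$island_id == dmr$island_id[i]]), "")
    }
    genes[i] <- if (length(g)) g[1] else NA_character_
  }
  keep <- !is.na(genes) & !duplicated(genes)
  dmr <- dmr[keep, , drop = FALSE]; genes <- genes[keep]
  ns <- ncol(beta)
  inverse <- stats::runif(length(genes)) < inverse_fraction
  expr <- matrix(NA_real_, length(genes) + n_null_genes, ns)
  for (i in seq_along(genes)) {
    pr <- intersect(strsplit(dmr$probe_ids[i], ",", fixed = TRUE)[[1]],
                    rownames(beta))
    mb <- colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
    expr[i, ] <- if (inverse[i]) 5 - 3 * mb + stats::rnorm(ns, 0, noise_sd)
                 else stats::rnorm(ns, 5, max(noise_sd, 1e-12))
  }
  null_names <- sprintf("NULLG%03d", seq_len(n_null_genes))
  if (n_null_genes > 0)
    expr[length(genes) + seq_len(n_null_genes), ] <-
      stats::rnorm(n_null_genes * ns, 5, max(noise_sd, 1e-12))
  rownames(expr) <- c(genes, null_names)
  colnames(expr) <- colnames(beta)
  list(expr = expr,
       gene_truth = data.frame(gene = c(genes, null_names),
                               inverse = c(inverse, rep(FALSE, n_null_genes)),
                               stringsAsFactors = FALSE))
}
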