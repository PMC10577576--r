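test_that("per-probe F matches the explicit sum-of-squares oracle", {
  set.seed(14)
  sheet <- toy_sheet(3, 5)
  for (i in 1:50) {
    b <- matrix(runif(8, .1, .9), 1, 8, dimnames = list("p1", sheet$sample_id))
    d <- call_dmps(b, sheet, alpha = 1, delta_min = 0)
    o <- oracle_f(b[1, ], sheet$phenotype)
    expect_equal(d$f_stat, o$f, tolerance = 1e-10)
    expect_equal(d$p, o$p, tolerance = 1e-10)
    # and against the standard linear-model ANOVA
    a <- anova(lm(b[1, ] ~ factor(sheet$phenotype)))
    expect_equal(d$f_stat, a$`F value`[1], tolerance = 1e-10)
  }
})

test_that("DMP flags follow the joint significance and delta rule", {
  set.seed(15)
  sheet <- toy_sheet(5, 7)
  n <- 400
  b <- runif(n, .2, .8) + matrix(rnorm(n * 12, 0, 0.03), n, 12,
             dimnames = list(sprintf("p%04d", 1:n), sheet$sample_id))
  # plant a clear hyper effect on the first 20 probes
  b[1:20, sheet$phenotype == "Progeroid"] <-
    b[1:20, sheet$phenotype == "Progeroid"] + 0.25
  dmp <- call_dmps(b, sheet)
  expect_true(all(dmp$is_dmp ==
    (!is.na(dmp$p_adj) & dmp$p_adj < 0.05 & abs(dmp$delta) > 0.10)))
  expect_true(all(dmp$direction[dmp$is_dmp & dmp$delta > 0] == "hyper"))
  expect_true(all(dmp$is_dmp[1:20]))
  expect_true(all(dmp$direction[1:20] == "hyper"))

  # constant probe: delta 0, not a DMP
  b2 <- b; b2[5, ] <- 0.5
  d2 <- call_dmps(b2, sheet)
  expect_equal(d2$delta[5], 0)
  expect_false(d2$is_dmp[5])

  # invariance to sample column order and probe row order
  perm_s <- sample(ncol(b)); perm_p <- sample(nrow(b))
  d3 <- call_dmps(b[perm_p, perm_s], sheet)
  expect_equal(d3[match(dmp$probe_id, d3$probe_id), , drop = FALSE]$p, dmp$p)
  expect_equal(d3[match(dmp$probe_id, d3$probe_id), , drop = FALSE]$delta,
               dmp$delta)
})

test_that("probes with too few usable samples are excluded from the BH count", {
  sheet <- toy_sheet(3, 4)
  b <- matrix(runif(14, .2, .8), 2, 7,
              dimnames = list(c("p1", "p2"), sheet$sample_id))
  b[2, sheet$phenotype == "Progeroid"][1:3] <- NA  # one usable progeroid sample
  d <- call_dmps(b, sheet)
  expect_true(is.na(d$p[2]))
  expect_equal(d$p_adj[1], d$p[1])  # m = 1: BH leaves a single p unchanged
})

test_that("BH adjustment matches the closed-form step-up", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.7), 0.7)
})

test_that("window Pillai trace matches eigen oracle and stats::manova", {
  set.seed(16)
  g <- rep(c("A", "B"), c(5, 7))
  for (i in 1:50) {
    y <- matrix(runif(36, .1, .9), 12, 3)
    res <- pillai_window(y, g)
    expect_equal(res$pillai, oracle_pillai(y, g), tolerance = 1e-8)
    mv <- summary(manova(y ~ factor(g)), test = "Pillai")$stats
    expect_equal(res$pillai, mv[1, "Pillai"], tolerance = 1e-8)
    expect_equal(res$p, mv[1, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("null windows give Pillai near 0 and a 1-D window collapses to ANOVA", {
  set.seed(17)
  g <- rep(c("A", "B"), each = 6)
  # equal population means, nonzero within-group spread: force the observed
  # group means equal so the between-group SSCP is exactly zero
  y <- matrix(rnorm(36, 0.5, 0.05), 12, 3)
  y[g == "A", ] <- sweep(y[g == "A", ], 2,
                         colMeans(y[g == "A", ]) - colMeans(y[g == "B", ]))
  res <- pillai_window(y, g)
  expect_lt(res$pillai, 1e-10)
  expect_gt(res$p, 0.999)

  # single varying probe + two constant probes, regularisation disabled,
  # reduces to the univariate ANOVA p
  x <- runif(12, .2, .8)
  y1 <- cbind(x)
  r1 <- pillai_window(y1, g, ridge = 0)
  o <- oracle_f(x, g)
  expect_equal(r1$p, o$p, tolerance = 1e-10)
})

test_that("DMR calling scans blocks, merges windows, and recovers planted regions", {
  fx <- small_cohort(seed = 19, n_dmp_true = 0, noise_sd = 0.05,
                     dmr_effect = 0.3)
  sim <- fx$sim
  b <- merge_replicates(do.call(combine_platforms,
    intersect_platforms(sim$beta_450k, sim$beta_epic))$beta)
  b <- drop_sex_probes(b, fx$ann)
  dmp <- call_dmps(b, sim$sheet)
  dmrs <- call_dmrs(b, sim$sheet, fx$ann, dmp_table = dmp)
  # window combinatorics: a block of n probes yields n-2 windows
  ann_b <- fx$ann[match(rownames(b), fx$ann$probe_id), ]
  eligible <- ann_b$island_id != ""
  blocks <- split(seq_len(nrow(ann_b))[eligible], ann_b$island_id[eligible])
  blocks <- blocks[vapply(blocks, function(ix)
    any(ann_b$genes[ix] != ""), logical(1))]
  sizes <- vapply(blocks, length, integer(1))
  expect_equal(attr(dmrs, "n_windows"), sum(pmax(sizes - 2L, 0L)))
  # every planted (non-intermediate and intermediate) region is recovered
  expect_true(all(sim$truth$dmr$island_id %in% dmrs$island_id))
  # merged regions have >= 3 probes and direction consistent with lead delta
  expect_true(all(dmrs$n_probes >= 3))
  expect_true(all(dmrs$direction == ifelse(dmrs$delta > 0, "hyper", "hypo")))
  # planted effect signs are reflected in the recovered direction
  pl <- sim$truth$dmr[!sim$truth$dmr$uvss_intermediate, ]
  hit <- dmrs[match(pl$island_id, dmrs$island_id), ]
  expect_true(all(hit$direction == ifelse(pl$effect > 0, "hyper", "hypo")))
})

test_that("stringent filter demands disjoint group ranges with margin", {
  sheet <- toy_sheet(2, 3)
  b <- matrix(0, 3, 5, dimnames = list(paste0("p", 1:3), sheet$sample_id))
  dmr <- data.frame(island_id = "chr1:1-100", probe_ids = "p1,p2,p3",
                    is_stringent = NA, stringsAsFactors = FALSE)
  # progeroid {0.2, 0.25, 0.3} vs non-progeroid {0.5, 0.6}: disjoint
  b[] <- rep(c(0.5, 0.6, 0.2, 0.25, 0.3), each = 3)
  out <- stringent_filter(dmr, b, sheet)
  expect_true(out$is_stringent)
  expect_true(stringent_filter(dmr, b, sheet, gap_min = 0.15)$is_stringent)
  expect_false(stringent_filter(dmr, b, sheet, gap_min = 0.25)$is_stringent)
  # overlap: progeroid {0.2, 0.45, 0.45} vs non-progeroid {0.4, 0.6}
  b[] <- rep(c(0.4, 0.6, 0.2, 0.45, 0.45), each = 3)
  expect_false(stringent_filter(dmr, b, sheet)$is_stringent)
})

test_that("stringent filter rejects UVSS-intermediate regions; count monotone in gap", {
  fx <- small_cohort(seed = 23, n_dmp_true = 0, n_dmr_true = 8,
                     n_uvss_intermediate = 4, noise_sd = 0.03)
  sim <- fx$sim
  b <- merge_replicates(do.call(combine_platforms,
    intersect_platforms(sim$beta_450k, sim$beta_epic))$beta)
  dmrs <- call_dmrs(b, sim$sheet, fx$ann)
  s0 <- stringent_filter(dmrs, b, sim$sheet, gap_min = 0)
  s1 <- stringent_filter(dmrs, b, sim$sheet, gap_min = 0.1)
  s2 <- stringent_filter(dmrs, b, sim$sheet, gap_min = 0.2)
  expect_true(sum(s1$is_stringent) <= sum(s0$is_stringent))
  expect_true(sum(s2$is_stringent) <= sum(s1$is_stringent))
  # stringent regions are a subset of the significant regions
  expect_true(all(s1$island_id[s1$is_stringent] %in% dmrs$island_id))
  # UVSS halfway between WT and CS: rejected at gap 0.1
  inter <- s1$island_id[s1$is_stringent] %in% sim$truth$uvss_intermediate
  expect_equal(sum(inter), 0)
})

test_that("region enrichment odds ratios and Fisher p match oracles", {
  # cross-product check on a fixed table: [[3,1],[1,3]] -> OR 9
  expect_equal((3 * 3) / (1 * 1), 9)
  set.seed(26)
  sheet <- toy_sheet(5, 7)
  n <- 300
  b <- runif(n, .2, .8) + matrix(rnorm(n * 12, 0, 0.03), n, 12,
             dimnames = list(sprintf("p%04d", 1:n), sheet$sample_id))
  b[1:30, sheet$phenotype == "Progeroid"] <-
    pmin(b[1:30, sheet$phenotype == "Progeroid"] + 0.3, 1)
  ann <- data.frame(probe_id = rownames(b),
                    relation = sample(c("Island", "OpenSea", "N_Shore"),
                                      n, replace = TRUE),
                    stringsAsFactors = FALSE)
  dmp <- call_dmps(b, sheet)
  en <- region_enrichment(dmp, ann)
  expect_equal(nrow(en), 12)  # 6 categories x 2 directions
  for (i in seq_len(nrow(en))) {
    expect_equal(en$p[i],
                 fisher.test(matrix(c(en$a[i], en$b[i], en$c[i], en$d[i]),
                                    2))$p.value, tolerance = 1e-12)
    if (!en$zero_cell[i])
      expect_equal(en$odds_ratio[i],
                   (en$a[i] * en$d[i]) / (en$b[i] * en$c[i]))
  }
  # a category with the same frequency among DMPs and background: OR ~ 1
  # (constructed directly)
  d2 <- data.frame(probe_id = sprintf("q%03d", 1:200),
                   p = 0.5, p_adj = 0.5,
                   delta = rep(c(0.2, 0.01), each = 100),
                   direction = "hyper",
                   is_dmp = rep(c(TRUE, FALSE), each = 100),
                   stringsAsFactors = FALSE)
  a2 <- data.frame(probe_id = d2$probe_id,
                   relation = rep(c("Island", "OpenSea"), 100),
                   stringsAsFactors = FALSE)
  e2 <- region_enrichment(d2, a2)
  or_isl <- e2$odds_ratio[e2$category == "Island" & e2$direction == "hyper"]
  expect_equal(or_isl, 1, tolerance = 0.05)
})

test_that("BED export uses 0-based half-open coordinates and the score formula", {
  ann <- data.frame(probe_id = c("p1", "p2"), chr = c("3", "3"),
                    pos = c(100L, 300L), stringsAsFactors = FALSE)
  dmr <- data.frame(island_id = "chr3:100-300", probe_ids = "p1,p2",
                    genes = "GENE1", p_adj = 0.01, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  bed <- export_dmrs_bed(dmr, ann, path)
  expect_equal(bed$start, 99L)
  expect_equal(bed$end, 300L)
  expect_equal(bed$score, 20)
  expect_equal(bed$name, "GENE1|chr3:100-300")
  lines <- readLines(path)
  expect_match(lines[1], "^#")
  expect_length(lines, 2)
  # empty table: header-only file
  path2 <- withr::local_tempfile(fileext = ".bed")
  export_dmrs_bed(dmr[0, ], ann, path2)
  expect_length(readLines(path2), 1)
})
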