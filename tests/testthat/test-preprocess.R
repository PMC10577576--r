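test_that("platform intersection restricts both matrices to the shared probes", {
  m1 <- matrix(0.5, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  m2 <- matrix(0.5, 3, 2, dimnames = list(c("p2", "p3", "p4"), c("c", "d")))
  out <- intersect_platforms(m1, m2)
  expect_equal(rownames(out$m450), c("p2", "p3"))
  expect_equal(rownames(out$mepic), c("p2", "p3"))

  # identical probe sets: identity up to canonical row order
  out2 <- intersect_platforms(m1, m1)
  expect_equal(out2$m450, m1[sort(rownames(m1)), ])

  m3 <- matrix(0.5, 1, 1, dimnames = list("q9", "x"))
  expect_error(intersect_platforms(m1, m3), "no probes shared")
})

test_that("batch adjustment removes planted platform offsets", {
  set.seed(8)
  n <- 50
  mu <- runif(n, 0.2, 0.8)
  batch <- rep(c("450k", "EPIC"), each = 10)
  off <- sample(c(-0.1, 0.1), n, replace = TRUE)
  b <- mu + matrix(rnorm(n * 20, 0, 0.03), n, 20)
  b[, batch == "EPIC"] <- b[, batch == "EPIC"] + off
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(sprintf("p%03d", 1:n), sprintf("s%02d@%s", 1:20, batch))
  adj <- combat_adjust(b, batch)
  batch_diff <- abs(rowMeans(adj[, batch == "450k"]) -
                    rowMeans(adj[, batch == "EPIC"]))
  expect_lt(mean(batch_diff), 0.01)
  expect_true(all(adj >= 0 & adj <= 1))
})

test_that("batch adjustment increases replicate cross-platform correlation", {
  fx <- small_cohort(seed = 17, batch_shift_sd = 0.08)
  ip <- intersect_platforms(fx$sim$beta_450k, fx$sim$beta_epic)
  comb <- combine_platforms(ip$m450, ip$mepic)
  rep_ids <- intersect(colnames(ip$m450), colnames(ip$mepic))
  expect_gte(length(rep_ids), 5)
  xcor <- function(m) mean(vapply(rep_ids, function(s)
    cor(m[, paste0(s, "@450k")], m[, paste0(s, "@EPIC")]), numeric(1)))
  phen <- fx$sim$sheet$phenotype[match(comb$sample_id, fx$sim$sheet$sample_id)]
  adj <- combat_adjust(comb$beta, comb$batch, covariate = phen)
  expect_gt(xcor(adj), xcor(comb$beta))
})

test_that("batch adjustment edge cases: single batch, small batch, constant probe", {
  b <- matrix(runif(40, .3, .7), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  # single batch: exact no-op
  expect_identical(combat_adjust(b, rep("A", 4)), b)
  # a batch with one sample: error
  expect_error(combat_adjust(b, c("A", "A", "A", "B")), "at least 2")
  # constant probe passes through with a warning
  b2 <- cbind(b, b + 0.05); colnames(b2) <- paste0("s", 1:8)
  b2[3, ] <- 0.5
  expect_warning(adj <- combat_adjust(b2, rep(c("A", "B"), each = 4)),
                 "zero-variance")
  expect_equal(adj[3, ], b2[3, ])
})

test_that("a second batch adjustment changes little once batch effects are removed", {
  # EB shrinkage leaves a small residual, so exact idempotency is not a
  # property of the estimator; the second pass must be a strong contraction
  # relative to the original batch effect.
  set.seed(12)
  n <- 80
  batch <- rep(c("A", "B"), each = 8)
  b <- runif(n, .2, .8) + matrix(rnorm(n * 16, 0, 0.03), n, 16)
  b[, batch == "B"] <- b[, batch == "B"] + rnorm(n, 0, 0.1)
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(paste0("p", 1:n), paste0("s", 1:16))
  a1 <- combat_adjust(b, batch)
  a2 <- combat_adjust(a1, batch)
  expect_lt(max(abs(a2 - a1)), 0.1 * max(abs(a1 - b)))
})

test_that("sex-probe removal drops X/Y and optional extra probes, idempotently", {
  ann <- data.frame(probe_id = paste0("p", 1:10),
                    chr = c(rep("1", 6), "X", "X", "2", "Y"),
                    stringsAsFactors = FALSE)
  b <- matrix(0.5, 10, 3, dimnames = list(ann$probe_id, c("a", "b", "c")))
  out <- drop_sex_probes(b, ann)
  expect_equal(nrow(out), 7)
  expect_false(any(c("p7", "p8", "p10") %in% rownames(out)))
  expect_identical(drop_sex_probes(out, ann), out)
  out2 <- drop_sex_probes(b, ann, extra_probes = c("p1", "p9"))
  expect_equal(nrow(out2), 5)
  # no sex probes: identity
  ann2 <- ann; ann2$chr <- "5"
  expect_identical(drop_sex_probes(b, ann2), b)
})

test_that("replicate averaging merges platforms and conserves the grand mean", {
  b <- matrix(c(0.4, 0.6, 0.2, 0.8, NA, 0.3), 1,
              dimnames = list("p1", c("s1@450k", "s1@EPIC", "s2@450k",
                                      "s2@EPIC", "s3@450k", "s3@EPIC")))
  m <- merge_replicates(b)
  expect_equal(m["p1", "s1"], 0.5)      # arithmetic mean
  expect_equal(m["p1", "s2"], 0.5)
  expect_equal(m["p1", "s3"], 0.3)      # missing falls back to the other value
  # unreplicated column unchanged
  b2 <- matrix(1:6 / 10, 2, 3, dimnames = list(c("p1", "p2"),
                                               c("u1@450k", "u2@450k", "u3@EPIC")))
  expect_equal(unname(merge_replicates(b2)), unname(b2))
  # equal sample sets on both platforms: per-probe grand mean conserved
  set.seed(3)
  x <- matrix(runif(20), 4, 5, dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  y <- matrix(runif(20), 4, 5, dimnames = dimnames(x))
  comb <- combine_platforms(x, y)
  expect_equal(rowMeans(merge_replicates(comb$beta)), rowMeans(comb$beta))
})

test_that("PCA separates planted groups and normalises explained variance", {
  set.seed(5)
  n <- 200
  g <- rep(c(0, 1), each = 6)
  b <- matrix(runif(n, .3, .7), n, 12) + matrix(rnorm(n * 12, 0, 0.01), n, 12)
  b[1:100, g == 1] <- b[1:100, g == 1] + 0.2
  dimnames(b) <- list(paste0("p", 1:n), paste0("s", 1:12))
  pc <- pca_overview(b, k = 3)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1)
  # PC1 linearly separates the groups
  s1 <- pc$scores[g == 0, 1]; s2 <- pc$scores[g == 1, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # duplicate samples get identical scores
  b2 <- cbind(b, dup = b[, 1])
  pc2 <- pca_overview(b2, k = 2)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores["s1", ]))
})

test_that("hierarchical clustering recovers well-separated groups", {
  set.seed(9)
  b <- matrix(runif(50 * 8, .4, .6), 50, 8,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:8)))
  b[, 5:8] <- b[, 5:8] + 0.3
  hc <- hierarchical_cluster(b)
  expect_equal(length(unique(hc$labels[1:4])), 1)
  expect_equal(length(unique(hc$labels[5:8])), 1)
  expect_false(hc$labels[1] == hc$labels[5])
  # identical samples merge at height zero
  b2 <- b; b2[, 2] <- b2[, 1]
  hc2 <- hierarchical_cluster(b2)
  expect_equal(min(hc2$hclust$height), 0)
  # one sample: single leaf
  hc3 <- hierarchical_cluster(b[, 1, drop = FALSE])
  expect_null(hc3$hclust)
  expect_equal(unname(hc3$labels), 1L)
})
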