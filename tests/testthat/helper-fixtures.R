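# Shared fixtures and independent oracles used across the suite.

# small default cohort used by several tests
small_cohort <- function(seed = 11, ...) {
  args <- list(n_islands = 60, opensea_probes = 80, n_dmp_true = 10,
               n_dmr_true = 5, n_uvss_intermediate = 2, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(sim_config, args)
  ann <- simulate_annotation(cfg)
  sim <- simulate_cohort(cfg, ann)
  list(cfg = cfg, ann = ann, sim = sim)
}

# a 12-sample sheet matching the study group sizes, single platform
toy_sheet <- function(n1 = 5, n2 = 7) {
  as_sample_sheet(data.frame(
    sample_id = paste0("S", seq_len(n1 + n2)),
    condition = rep(c("WT", "CS"), c(n1, n2)),
    subtype = rep(c("WT", "CS-II"), c(n1, n2)),
    sex = rep(c("F", "M"), length.out = n1 + n2),
    age_years = rep(c(6, 32, 15, 48, 22, 55, 9, 41, 27, 12, 36, 19),
                    length.out = n1 + n2),
    age_is_censored = FALSE, platforms = "450k",
    stringsAsFactors = FALSE))
}

# brute-force one-way F from explicit between/within sums of squares
oracle_f <- function(x, g) {
  g <- factor(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(x, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(x) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# brute-force Pillai trace via eigenvalues of H (H+E)^-1
oracle_pillai <- function(y, g) {
  g <- factor(g)
  p <- ncol(y)
  gm <- colMeans(y)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lev in levels(g)) {
    yk <- y[g == lev, , drop = FALSE]
    mk <- colMeans(yk)
    H <- H + nrow(yk) * tcrossprod(mk - gm)
    E <- E + crossprod(sweep(yk, 2, mk))
  }
  sum(Re(eigen(H %*% solve(H + E))$values))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # col 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}
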