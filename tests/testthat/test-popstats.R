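mk_dist <- function(n, seed) {
  set.seed(seed)
  m <- as.matrix(stats::dist(cbind(runif(n), runif(n))))
  dimnames(m) <- list(sprintf("u%d", 1:n), sprintf("u%d", 1:n))
  m
}

test_that("mantel: self-correlation, p-value floor, label alignment", {
  X <- mk_dist(8, 1)
  r <- mantel(X, X, n_perm = 999, seed = 3)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 1000)
  # permuting the label order consistently changes nothing
  idx <- sample(8)
  Y <- X[idx, idx]
  r2 <- mantel(X, Y, n_perm = 99, seed = 3)
  expect_equal(r2$r, 1)
  expect_error(mantel(X[1:3, 1:3], X[1:3, 1:3]), "at least 4")
  expect_error(mantel(X, matrix(0, 8, 8, dimnames = dimnames(X))), "constant")
})

test_that("mantel p at n = 4 equals exhaustive 24-permutation enumeration", {
  X <- mk_dist(4, 11)
  Y <- mk_dist(4, 12)
  pm <- perms(4)
  x <- X[lower.tri(X)]
  r_all <- apply(pm, 1, function(ix) stats::cor(x, (Y[ix, ix])[lower.tri(Y)]))
  r_obs <- stats::cor(x, Y[lower.tri(Y)])
  for (tail in c("two_sided", "greater", "less")) {
    hits <- switch(tail,
                   two_sided = sum(abs(r_all) >= abs(r_obs) - 1e-12),
                   greater = sum(r_all >= r_obs - 1e-12),
                   less = sum(r_all <= r_obs + 1e-12))
    p_exact <- hits / 24
    res <- mantel(X, Y, tail = tail, exact = TRUE)
    expect_identical(res$p, p_exact)
    # the sampled estimator converges on the same value
    res_s <- mantel(X, Y, n_perm = 4999, tail = tail, seed = 21)
    expect_equal(res_s$p, p_exact, tolerance = 0.05)
    expect_gte(res_s$p, 1 / 5000)
  }
})

test_that("mantel agrees with vegan on the one-sided test", {
  skip_if_not_installed("vegan")
  X <- mk_dist(10, 31)
  set.seed(32)
  Y <- X + matrix(rnorm(100, 0, 0.1), 10, 10)
  Y <- (Y + t(Y)) / 2; diag(Y) <- 0
  dimnames(Y) <- dimnames(X)
  ours <- mantel(X, Y, n_perm = 999, tail = "greater", seed = 33)
  ref <- vegan::mantel(stats::as.dist(X), stats::as.dist(Y),
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$signif, tolerance = 0.02)
})

test_that("mantel type-I error is nominal over null replicates", {
  rej <- vapply(1:400, function(s) {
    X <- mk_dist(7, 10000 + s)
    Y <- mk_dist(7, 20000 + s)
    mantel(X, Y, n_perm = 199, seed = 30000 + s)$p <= 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("partial mantel removes a shared covariate and nothing else", {
  # Y == Z: partial r is ~0
  X <- mk_dist(9, 41); Z <- mk_dist(9, 42)
  pr <- partial_mantel(X, Z, Z, n_perm = 99, seed = 43)
  expect_lt(abs(pr$r), 1e-10)
  # Z unrelated: partial r tracks simple r
  set.seed(44)
  rs <- vapply(1:30, function(s) {
    X <- mk_dist(9, 5000 + s); Y <- mk_dist(9, 6000 + s)
    Z <- mk_dist(9, 7000 + s)
    c(mantel(X, Y, n_perm = 49, seed = s)$r,
      partial_mantel(X, Y, Z, n_perm = 49, seed = s)$r)
  }, numeric(2))
  expect_gt(stats::cor(rs[1, ], rs[2, ]), 0.9)
  # confounding: X and Y both driven by Z; partial rejection near nominal
  rej <- vapply(1:150, function(s) {
    Z <- mk_dist(8, 8000 + s)
    set.seed(9000 + s)
    noise <- function() {
      E <- matrix(rnorm(64, 0, 0.15), 8, 8); E <- (E + t(E)) / 2; diag(E) <- 0
      E
    }
    X <- Z + noise(); Y <- Z + noise()
    dimnames(X) <- dimnames(Y) <- dimnames(Z)
    c(simple = mantel(X, Y, n_perm = 99, seed = s)$p <= 0.05,
      partial = partial_mantel(X, Y, Z, n_perm = 99, seed = s)$p <= 0.05)
  }, logical(2))
  expect_gt(mean(rej["simple", ]), 0.5)
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lt(mean(rej["partial", ]), 0.05 + 4 * se)
})

test_that("genotype PCA separates populations and fixes signs", {
  fx <- small_mosaic()
  keep <- unname(fx$counts$populations) %in% c("P1", "P8")
  gp <- fx$freqs$genotype_posterior
  gp_sub <- structure(list(probs = gp$probs[keep, , , drop = FALSE],
                           individuals = gp$individuals[keep],
                           loci = gp$loci,
                           populations = gp$populations[keep]),
                      class = "genotype_posterior")
  for (mode in c("two_state", "three_state")) {
    pc <- genotype_pca(gp_sub, mode = mode)
    s1 <- pc$scores[unname(gp_sub$populations) == "P1", 1]
    s8 <- pc$scores[unname(gp_sub$populations) == "P8", 1]
    expect_true(max(s1) < min(s8) || max(s8) < min(s1))  # zero overlap
  }
  # identical rows: zero variance flagged
  probs0 <- array(rep(c(0.25, 0.5, 0.25), each = 6), c(3, 2, 3))
  gp0 <- structure(list(probs = probs0, individuals = letters[1:3],
                        loci = c("l1", "l2"),
                        populations = stats::setNames(rep("P", 3), letters[1:3])),
                   class = "genotype_posterior")
  pc0 <- genotype_pca(gp0)
  expect_true(pc0$zero_variance)
  expect_true(all(pc0$scores == 0))
})

test_that("PC distances recover isolation by distance on the mosaic", {
  fx <- small_mosaic()
  pc <- genotype_pca(fx$freqs$genotype_posterior)
  sc <- pc$scores[, 1:2]
  pops <- sort(unique(unname(fx$counts$populations)))
  cent <- t(vapply(pops, function(p)
    colMeans(sc[unname(fx$counts$populations) == p, , drop = FALSE]),
    numeric(2)))
  gen_d <- as.matrix(stats::dist(cent))
  dimnames(gen_d) <- list(pops, pops)
  geo <- as.matrix(stats::dist(fx$truth$config$coords))
  dimnames(geo) <- list(pops, pops)
  mt <- mantel(geo, gen_d, n_perm = 999, tail = "greater", seed = 3)
  expect_gt(mt$r, 0)
  expect_lte(mt$p, 0.05)
})

test_that("cline regression recovers exact linear structure and degenerate cases", {
  set.seed(51)
  cov <- data.frame(climPC1 = rnorm(10), climPC2 = rnorm(10),
                    longitude = rnorm(10))
  f <- 0.1 + 0.05 * cov$climPC1
  cf <- suppressWarnings(cline_regression(f, cov))  # exact fit warns in lm
  est <- cf$coefficients
  expect_equal(est$estimate[est$term == "climPC1"],
               0.05 * stats::sd(cov$climPC1), tolerance = 1e-10)
  expect_lt(max(abs(est$estimate[est$term != "climPC1"])), 1e-10)
  # constant frequencies: all slopes 0, all p = 1
  cf0 <- cline_regression(rep(0.4, 10), cov)
  expect_true(all(cf0$coefficients$estimate == 0))
  expect_true(all(cf0$coefficients$p == 1))
  # collinear design is refused with the offending column named
  cov_bad <- cov; cov_bad$longitude <- cov$climPC1
  expect_error(cline_regression(f, cov_bad), "climPC1|longitude")
  expect_error(cline_regression(f[1:4], cov[1:4, ]), "more populations")
})

test_that("cline regression type-I error is nominal on pure noise", {
  set.seed(61)
  cov <- data.frame(climPC1 = rnorm(12), climPC2 = rnorm(12),
                    longitude = rnorm(12))
  rej <- colMeans(t(vapply(1:400, function(s) {
    set.seed(1000 + s)
    f <- runif(12, 0.2, 0.8)
    cline_regression(f, cov)$coefficients$p <= 0.05
  }, logical(3))))
  se <- sqrt(0.05 * 0.95 / 400)
  expect_true(all(abs(rej - 0.05) < 3 * se + 0.01))
})

test_that("isolation index and morph divergence follow their formulas", {
  expect_equal(isolation_index(50, 50), 0)
  expect_equal(isolation_index(50, 0), 1)
  expect_equal(isolation_index(50, 25), 0.5)
  expect_equal(isolation_index(40, 60), -0.5)  # not clamped
  expect_error(isolation_index(0, 10), "undefined")
  expect_equal(morph_divergence(90, 6), 84)
  expect_equal(morph_divergence(6, 90), -84)
  expect_equal(morph_divergence(30, 30), 0)
  expect_error(morph_divergence(120, 10), "\\[0, 100\\]")
})

test_that("pooled t-test matches stats::t.test and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  ours <- two_sample_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$df, 4)                    # n1 + n2 - 2 convention
  w <- two_sample_ttest(a, c(2, 3, 4, 7), variant = "welch")
  refw <- stats::t.test(a, c(2, 3, 4, 7))
  expect_equal(w$t, unname(refw$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
  same <- two_sample_ttest(c(1, 1), c(1, 1))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  apart <- two_sample_ttest(c(1, 1), c(2, 2))
  expect_true(apart$degenerate)
  expect_equal(apart$p, 0)
})

test_that("covariate PCA yields standardized orthogonal axes", {
  set.seed(71)
  env <- data.frame(temp = rnorm(10), prec = rnorm(10), cv = rnorm(10))
  pcs <- covariate_pca(env, n_axes = 2)
  expect_identical(names(pcs), c("envPC1", "envPC2"))
  expect_equal(unname(vapply(pcs, stats::sd, numeric(1))), c(1, 1),
               tolerance = 1e-12)
  expect_lt(abs(stats::cor(pcs$envPC1, pcs$envPC2)), 1e-10)
  expect_identical(covariate_pca(env, 2), pcs)   # deterministic
  env$flat <- 1
  expect_error(covariate_pca(env), "constant")
})
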