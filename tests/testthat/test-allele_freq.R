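test_that("genotype likelihoods are the stated binomial forms", {
  # no data: all genotypes equally likely
  expect_equal(unname(genotype_likelihood(0L, 0L, 0.01)), c(1, 1, 1))
  # frozen values: dbinom(2, 4, .) at e0 = 0.01, 1/2, 1 - 0.01
  lk <- genotype_likelihood(2L, 4L, 0.01)
  expect_equal(unname(lk[2]), 0.375, tolerance = 1e-12)
  expect_equal(unname(lk[1]), 6 * 0.01^2 * 0.99^2, tolerance = 1e-12)
  expect_equal(unname(lk[1]), unname(lk[3]), tolerance = 1e-12)
  # impossible outcome under zero error
  expect_equal(unname(genotype_likelihood(3L, 5L, 0)[3]), 0)
  expect_error(genotype_likelihood(1L, 2L, 0.6), "error_rate")
  expect_error(genotype_likelihood(3L, 2L, 0.01), "alt_reads")
})

test_that("zero coverage falls back to the prior structure", {
  # no data at all: posterior mean is the Beta(1,1) prior mean
  cnt <- one_pop_counts(rep(0L, 8), mean_coverage = 0, seed = 3)
  af <- estimate_allele_frequencies(cnt, mcmc = mcmc_control(4000, 500, 2,
                                                             seed = 11))
  expect_lt(abs(af$mean[1, 1] - 0.5), 0.02)
  expect_equal(sum(af$genotype_posterior$probs[1, 1, ]), 1, tolerance = 1e-9)
  # an uncovered individual among covered ones carries the HWE prior at
  # the posterior allele frequency
  set.seed(12)
  g <- rbinom(20, 2, 0.35)
  cnt2 <- one_pop_counts(g, mean_coverage = 8, seed = 13)
  cnt2$n_reads[1, 1] <- cnt2$alt_reads[1, 1] <- 0L
  af2 <- estimate_allele_frequencies(cnt2, mcmc = mcmc_control(6000, 1000, 2,
                                                               seed = 14))
  p_hat <- af2$mean[1, 1]
  expect_lt(max(abs(af2$genotype_posterior$probs[1, 1, ] -
                      c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2))),
            0.02)
})

test_that("MCMC matches deterministic quadrature on tiny instances", {
  cases <- list(list(alt = 5L, n = 5L, e = 0.001),
                list(alt = c(2L, 0L), n = c(4L, 1L), e = 0.005),
                list(alt = c(1L, 1L, 0L), n = c(2L, 3L, 0L), e = 0.005))
  for (cs in cases) {
    oracle <- grid_freq_posterior(cs$alt, cs$n, cs$e)
    cnt <- read_count_matrix(
      matrix(cs$n, length(cs$n), 1), matrix(cs$alt, length(cs$alt), 1),
      individuals = sprintf("i%d", seq_along(cs$alt)), loci = "c1:1",
      populations = stats::setNames(rep("A", length(cs$alt)),
                                    sprintf("i%d", seq_along(cs$alt))))
    af <- estimate_allele_frequencies(cnt, error_rate = cs$e,
                                      mcmc = mcmc_control(12000, 2000, 2,
                                                          seed = 101))
    draws <- af$samples[1, 1, ]
    mcse <- stats::sd(draws) / sqrt(length(draws) / 10)  # lag-conservative
    expect_lt(abs(mean(draws) - oracle["mean"]), 3 * mcse)
    expect_lt(abs(stats::var(draws) - oracle["var"]),
              3 * stats::sd((draws - mean(draws))^2) / sqrt(length(draws) / 10))
  }
})

test_that("posterior summaries respect the retained-draw bookkeeping", {
  cnt <- one_pop_counts(c(0L, 1L, 2L), mean_coverage = 3, seed = 5)
  af <- estimate_allele_frequencies(cnt, mcmc = mcmc_control(1000, 200, 4,
                                                             seed = 1))
  expect_equal(af$mcmc_meta$retained, 200L)
  expect_equal(dim(af$samples), c(1L, 1L, 200L))
  expect_true(all(af$samples >= 0 & af$samples <= 1))
  expect_true(all(af$ci_lower <= af$median & af$median <= af$ci_upper))
  expect_error(mcmc_control(100, 100, 4), "config error")
})

test_that("permuting individuals leaves posterior summaries unchanged", {
  set.seed(8)
  g <- rbinom(12, 2, 0.4)
  cnt <- one_pop_counts(g, mean_coverage = 2, seed = 21)
  af1 <- estimate_allele_frequencies(cnt, mcmc = mcmc_control(6000, 1000, 2,
                                                              seed = 31))
  idx <- sample(12)
  cnt2 <- read_count_matrix(cnt$n_reads[idx, , drop = FALSE],
                            cnt$alt_reads[idx, , drop = FALSE],
                            cnt$individuals[idx], cnt$loci,
                            populations = cnt$populations[idx])
  af2 <- estimate_allele_frequencies(cnt2, mcmc = mcmc_control(6000, 1000, 2,
                                                               seed = 31))
  mcse <- stats::sd(af1$samples[1, 1, ]) / sqrt(af1$mcmc_meta$retained / 10)
  expect_lt(abs(af1$mean[1, 1] - af2$mean[1, 1]), 3 * mcse)
  # and the per-individual posteriors travel with the permutation
  expect_equal(af1$genotype_posterior$probs[idx, 1, ],
               af2$genotype_posterior$probs[, 1, ], tolerance = 0.05)
})

test_that("more coverage means less genotype uncertainty", {
  set.seed(9)
  g <- rbinom(15, 2, 0.5)
  ent <- vapply(c(0.5, 5, 50), function(cov) {
    cnt <- one_pop_counts(g, mean_coverage = cov, seed = 300 + cov)
    af <- estimate_allele_frequencies(cnt, mcmc = mcmc_control(1500, 300, 2,
                                                               seed = 41))
    genotype_entropy(af$genotype_posterior)
  }, numeric(1))
  expect_true(all(diff(ent) < 0))
})

test_that("credible intervals are calibrated over replicate simulations", {
  hits <- vapply(1:40, function(s) {
    set.seed(1200 + s)
    p_true <- runif(1, 0.15, 0.85)
    g <- rbinom(15, 2, p_true)
    cnt <- one_pop_counts(g, mean_coverage = 3, seed = 1300 + s)
    af <- estimate_allele_frequencies(cnt, ci_level = 0.90,
                                      mcmc = mcmc_control(1500, 300, 2,
                                                          seed = 1400 + s))
    af$ci_lower[1, 1] <= p_true && p_true <= af$ci_upper[1, 1]
  }, logical(1))
  se <- sqrt(0.9 * 0.1 / 40)
  expect_lt(abs(mean(hits) - 0.9), 3 * se + 0.025)
})

test_that("modal genotypes break ties toward the heterozygote", {
  probs <- array(0, c(2, 2, 3))
  probs[1, 1, ] <- c(0.5, 0.5, 0)      # tie 0/1 -> het
  probs[1, 2, ] <- c(0.2, 0.3, 0.5)    # clear hom alt
  probs[2, 1, ] <- c(0.6, 0.3, 0.1)    # clear hom ref
  probs[2, 2, ] <- c(0.1, 0.45, 0.45)  # tie 1/2 -> het
  gp <- structure(list(probs = probs, individuals = c("a", "b"),
                       loci = c("l1", "l2"),
                       populations = c(a = "P", b = "P")),
                  class = "genotype_posterior")
  expect_identical(unname(modal_genotype(gp)),
                   matrix(c(1L, 0L, 2L, 1L), 2, 2))
})
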