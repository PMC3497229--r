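# Shared fixtures, built in code and memoized so expensive objects are
# computed once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# small default-mosaic landscape + low-coverage reads + posteriors
small_mosaic <- function() {
  memo("small_mosaic", {
    lc <- landscape_config(n_loci = 150, n_sampled = 10, seed = 42)
    tr <- simulate_landscape(lc)
    cnt <- simulate_reads(tr, mean_coverage = 2, error_rate = 0.005, seed = 7)
    af <- estimate_allele_frequencies(
      cnt, mcmc = mcmc_control(1000, 300, 2, seed = 1), keep_samples = FALSE)
    list(truth = tr, counts = cnt, freqs = af)
  })
}

# deterministic quadrature oracle for the single-locus allele-frequency
# posterior: integrates over p on a fine grid, summing over genotypes
grid_freq_posterior <- function(alt, n, error_rate = 0.005, grid = 4001) {
  p <- seq(1 / (2 * grid), 1 - 1 / (2 * grid), length.out = grid)
  lik <- rep(1, grid)
  for (k in seq_along(alt)) {
    lk <- genotype_likelihood(alt[k], n[k], error_rate)
    lik <- lik * (lk[1] * (1 - p)^2 + lk[2] * 2 * p * (1 - p) + lk[3] * p^2)
  }
  w <- lik / sum(lik)
  m <- sum(w * p)
  c(mean = m, var = sum(w * p^2) - m^2)
}

# independent genotype-category-count oracle for Burrows' Delta
delta_category_oracle <- function(ga, gb) {
  n <- length(ga)
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  # n(AABB) etc. with A = non-reference allele; dosage 2 = hom non-ref
  pa <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * n)
  pb <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * n)
  (2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + tab[2, 2] / 2) / n - 2 * pa * pb
}

# all permutations of 1..n (tiny n only), for exhaustive Mantel nulls
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# one-population read-count matrix from a genotype vector
one_pop_counts <- function(g, mean_coverage, error_rate = 0.005, seed = 1) {
  ids <- sprintf("i%02d", seq_along(g))
  simulate_reads(matrix(g, length(g), 1, dimnames = list(ids, "c1:1")),
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 seed = seed,
                 populations = stats::setNames(rep("A", length(g)), ids))
}
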