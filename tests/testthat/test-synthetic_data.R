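test_that("migration kernel: hard zero beyond cutoff, monotone non-increasing", {
  d <- seq(0, 30, by = 0.25)
  m <- migration_kernel(d, m0 = 0.12, delta_km = 3, cutoff_km = 12)
  expect_identical(m[d > 12], rep(0, sum(d > 12)))
  expect_true(all(diff(m) <= 0))
  expect_equal(m[1], 0.12)
})

test_that("identical config + seed gives bit-identical landscapes and reads", {
  lc <- landscape_config(n_loci = 60, n_sampled = 6, seed = 99)
  t1 <- simulate_landscape(lc)
  t2 <- simulate_landscape(lc)
  expect_identical(t1$true_freqs, t2$true_freqs)
  expect_identical(t1$genotypes, t2$genotypes)
  r1 <- simulate_reads(t1, mean_coverage = 1, seed = 5)
  r2 <- simulate_reads(t2, mean_coverage = 1, seed = 5)
  expect_identical(r1$alt_reads, r2$alt_reads)
})

test_that("no generations means no divergence", {
  lc <- landscape_config(n_loci = 300, n_generations = 0, seed = 3)
  tr <- simulate_landscape(lc)
  expect_true(all(apply(tr$true_freqs, 2, function(x) diff(range(x))) == 0))
})

test_that("without migration, distance does not order divergence", {
  # two seeds; group means of direct F_ST for near vs far separated pairs
  # agree within Monte-Carlo error when m0 = 0
  fst_direct <- function(p1, p2) {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num[den > 0]) / sum(den[den > 0])
  }
  diffs <- vapply(c(11, 12), function(s) {
    lc <- landscape_config(n_loci = 1500, m0 = 0, pop_size = 50,
                           n_generations = 200,
                           locus_class_fractions = c(neutral = 1,
                                                     host_selected = 0,
                                                     adjacency_specific = 0,
                                                     climate_clinal = 0),
                           seed = s)
    tr <- simulate_landscape(lc)
    pr <- tr$pair_table
    f <- vapply(seq_len(nrow(pr)), function(k)
      fst_direct(tr$true_freqs[pr$pop_a[k], ], tr$true_freqs[pr$pop_b[k], ]),
      numeric(1))
    near <- pr$distance_km <= stats::median(pr$distance_km)
    mean(f[near]) - mean(f[!near])
  }, numeric(1))
  expect_true(all(abs(diffs) < 0.05))
})

test_that("migration creates isolation by distance (replicate seeds)", {
  # 1 km pair vs 20 km pair under a decaying kernel: the near pair is
  # less diverged in >= 95% of 20 replicate simulations
  fst_direct <- function(p1, p2) {
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ok <- den > 0
    sum(((p1 - p2)^2)[ok]) / sum(den[ok])
  }
  coords <- cbind(c(0, 1, 0, 20), c(0, 0, 0.5, 0))
  wins <- vapply(1:20, function(s) {
    lc <- landscape_config(n_pops = 4, coords = coords,
                           hosts = rep(c("Adenostoma", "Ceanothus"), 2),
                           adjacency_pairs = cbind(1L, 3L),
                           n_loci = 400, m0 = 0.25, delta_km = 2,
                           cutoff_km = 12, pop_size = 60,
                           n_generations = 80,
                           locus_class_fractions = c(neutral = 1,
                                                     host_selected = 0,
                                                     adjacency_specific = 0,
                                                     climate_clinal = 0),
                           seed = 7000 + s)
    tr <- simulate_landscape(lc)
    near <- fst_direct(tr$true_freqs[1, ], tr$true_freqs[2, ])
    far <- fst_direct(tr$true_freqs[1, ], tr$true_freqs[4, ])
    near < far
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("read simulator matches its stated model", {
  # zero coverage everywhere at rate 0
  tr0 <- matrix(1L, 5, 4, dimnames = list(paste0("i", 1:5), paste0("c", 1:4, ":1")))
  r0 <- simulate_reads(tr0, mean_coverage = 0, seed = 1,
                       populations = stats::setNames(rep("A", 5), paste0("i", 1:5)))
  expect_true(all(r0$n_reads == 0L) && all(r0$alt_reads == 0L))
  # error-free homozygote reference yields zero alt reads
  g0 <- matrix(0L, 20, 10, dimnames = list(sprintf("i%d", 1:20),
                                           sprintf("c%d:1", 1:10)))
  re <- simulate_reads(g0, mean_coverage = 4, error_rate = 0, seed = 2,
                       populations = stats::setNames(rep("A", 20), rownames(g0)))
  expect_true(all(re$alt_reads == 0L))
  # Poisson moment: mean depth within 3 SE at coverage 5 over 1e4 cells
  gbig <- matrix(1L, 100, 100, dimnames = list(sprintf("i%d", 1:100),
                                               sprintf("c%d:1", 1:100)))
  rb <- simulate_reads(gbig, mean_coverage = 5, seed = 3,
                       populations = stats::setNames(rep("A", 100), rownames(gbig)))
  se <- sqrt(5 / 1e4)
  expect_lt(abs(mean(rb$n_reads) - 5), 3 * se)
})

test_that("read model calibration: P(alt read | genotype) matches e_g", {
  err <- 0.01
  for (g in 0:2) {
    gm <- matrix(g, 60, 60, dimnames = list(sprintf("i%d", 1:60),
                                            sprintf("c%d:1", 1:60)))
    r <- simulate_reads(gm, mean_coverage = 3, error_rate = err,
                        seed = 10 + g,
                        populations = stats::setNames(rep("A", 60), rownames(gm)))
    e_hat <- sum(r$alt_reads) / sum(r$n_reads)
    e_true <- c(err, 0.5, 1 - err)[g + 1]
    se <- sqrt(max(e_true * (1 - e_true), 1e-4) / sum(r$n_reads))
    expect_lt(abs(e_hat - e_true), 4 * se)
  }
})

test_that("selected locus classes separate qualitatively on simulator truth", {
  # large demes, strong effects: host-selected loci diverge only between
  # hosts; each zone's adjacency loci diverge only within that contact
  # zone's pair
  lc <- landscape_config(n_loci = 400, pop_size = 400, seed = 31)
  tr <- simulate_landscape(lc)
  fst_direct <- function(p1, p2) {
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ok <- den > 0
    sum(((p1 - p2)^2)[ok]) / sum(den[ok])
  }
  pr <- tr$pair_table
  cls <- tr$locus_class
  f_by_class <- function(k, class) {
    sel <- cls == class
    fst_direct(tr$true_freqs[pr$pop_a[k], sel], tr$true_freqs[pr$pop_b[k], sel])
  }
  dh <- which(!pr$same_host & pr$adjacency == "separated")
  sh <- which(pr$same_host & pr$adjacency == "separated")
  expect_gt(mean(vapply(dh, f_by_class, numeric(1), class = "host_selected")),
            mean(vapply(sh, f_by_class, numeric(1), class = "host_selected")))
  adj <- which(pr$adjacency == "adjacent")
  sep <- which(pr$adjacency == "separated")
  f_adj_loci <- vapply(seq_len(nrow(pr)), f_by_class, numeric(1),
                       class = "adjacency_specific")
  expect_gt(mean(f_adj_loci[adj]), mean(f_adj_loci[sep][pr$distance_km[sep] < 6]))
})

test_that("mating-trial simulator matches the isolation-index arithmetic", {
  # equal probabilities: expected isolation 0; zero between-mating: exactly 1
  tr <- simulate_mating_trials(0.6, 0, n_trials_per_cell = 50, seed = 2)
  iso <- isolation_from_trials(tr)
  expect_equal(iso$isolation, 1)
  # p_within 0.6, p_between 0.276 -> isolation 0.54; estimate within 0.1
  # in >= 90% of 50 seeds at n = 500 (binomial error bound by simulation)
  hits <- vapply(1:50, function(s) {
    t2 <- simulate_mating_trials(0.6, 0.276, n_trials_per_cell = 500, seed = s)
    abs(isolation_from_trials(t2)$isolation - 0.54) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
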