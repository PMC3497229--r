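# Bayesian population allele frequencies from read counts.  Genotypes
# and allele frequencies are joint model parameters: a Gibbs sampler
# alternates per-individual genotype draws (read likelihood x HWE prior)
# with a conjugate Beta update of the population frequency, so genotype
# uncertainty from low or zero coverage propagates into the posterior.

#' Genotype likelihoods from read counts
#'
#' `L(g) = Binomial(alt_reads | n_reads, e_g)` with `e_0 = error_rate`,
#' `e_1 = 1/2`, `e_2 = 1 - error_rate`, unnormalized.  Zero coverage
#' gives `(1, 1, 1)`: no data, all genotypes equally likely.
#'
#' @param alt_reads Non-reference read count(s).
#' @param n_reads Total read count(s), same length.
#' @param error_rate Sequencing error probability in `[0, 0.5)`.
#' @return For scalar input a length-3 vector `(L0, L1, L2)`; for vector
#'   input an `n x 3` matrix.
#' @export
genotype_likelihood <- function(alt_reads, n_reads, error_rate = 0.005) {
  stop_if(error_rate < 0 || error_rate >= 0.5,
          "error_rate must be in [0, 0.5)")
  stop_if(any(alt_reads < 0) || any(alt_reads > n_reads),
          "need 0 <= alt_reads <= n_reads")
  out <- cbind(L0 = stats::dbinom(alt_reads, n_reads, error_rate),
               L1 = stats::dbinom(alt_reads, n_reads, 0.5),
               L2 = stats::dbinom(alt_reads, n_reads, 1 - error_rate))
  if (length(alt_reads) == 1L) out[1, ] else out
}

#' MCMC control settings
#'
#' Defaults follow the analysis the package reimplements: 20,000
#' iterations thinned to every fourth sample; burn-in is a package
#' default (2,000) and everything is configurable.
#'
#' @param iterations Total MCMC iterations.
#' @param burn_in Discarded initial iterations.
#' @param thinning Keep every `thinning`-th post-burn-in sample.
#' @param seed Integer seed or `NULL` (use current RNG state).
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 20000L, burn_in = 2000L,
                         thinning = 4L, seed = NULL) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  stop_if(iterations <= burn_in || thinning < 1L ||
            (iterations - burn_in) %/% thinning < 1L,
          "config error: no retained iterations after burn-in/thinning")
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning, seed = seed),
            class = "mcmc_control")
}

#' Estimate population allele frequencies with genotype uncertainty
#'
#' Per population and locus, a Gibbs sampler alternates (a) each
#' individual's genotype `g ~ L(g) * Binomial(g | 2, p)` and (b) the
#' frequency `p | g ~ Beta(1 + sum g, 1 + 2N - sum g)` (Beta(1,1) prior,
#' Hardy-Weinberg genotype prior).  Populations and loci are
#' conditionally independent.  Genotype posteriors are Rao-Blackwellized
#' averages of the conditional genotype probabilities over retained
#' iterations.
#'
#' @param counts A [read_count_matrix()] with populations assigned.
#' @param error_rate Fixed sequencing error probability.
#' @param mcmc An [mcmc_control()].
#' @param ci_level Credible-interval level for the frequency summaries.
#' @param keep_samples Keep the full array of retained frequency draws
#'   (`pops x loci x retained`)?  Disable for large runs.
#' @return List of class `allele_freq_posterior`: `mean`, `median`,
#'   `ci_lower`, `ci_upper` (pops x loci), optional `samples`,
#'   `genotype_posterior` (class `genotype_posterior`, with `probs` an
#'   individuals x loci x 3 array), and `mcmc_meta`.
#' @export
estimate_allele_frequencies <- function(counts, error_rate = 0.005,
                                        mcmc = mcmc_control(),
                                        ci_level = 0.90,
                                        keep_samples = TRUE) {
  stopifnot(inherits(counts, "read_count_matrix"))
  stop_if(is.null(counts$populations),
          "every individual must be assigned to a population")
  stopifnot(inherits(mcmc, "mcmc_control"))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  pops <- unique(unname(counts$populations))
  L <- length(counts$loci)
  S <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  dim_pl <- list(pops, counts$loci)
  p_mean <- p_med <- p_lo <- p_hi <- matrix(NA_real_, length(pops), L,
                                            dimnames = dim_pl)
  samples <- if (keep_samples)
    array(NA_real_, c(length(pops), L, S),
          dimnames = c(dim_pl, list(NULL))) else NULL
  gprobs <- array(NA_real_, c(length(counts$individuals), L, 3L),
                  dimnames = list(counts$individuals, counts$loci,
                                  c("g0", "g1", "g2")))
  for (pi in seq_along(pops)) {
    ind <- which(unname(counts$populations) == pops[pi])
    fit <- gibbs_freq_one_pop(
      alt = t(counts$alt_reads[ind, , drop = FALSE]),
      n = t(counts$n_reads[ind, , drop = FALSE]),
      error_rate = error_rate, mcmc = mcmc, ci_level = ci_level,
      keep_samples = keep_samples)
    p_mean[pi, ] <- fit$mean
    p_med[pi, ] <- fit$median
    p_lo[pi, ] <- fit$lo
    p_hi[pi, ] <- fit$hi
    if (keep_samples) samples[pi, , ] <- fit$samples
    gprobs[ind, , 1L] <- t(fit$g0)
    gprobs[ind, , 2L] <- t(fit$g1)
    gprobs[ind, , 3L] <- t(fit$g2)
  }
  structure(list(mean = p_mean, median = p_med,
                 ci_lower = p_lo, ci_upper = p_hi, ci_level = ci_level,
                 samples = samples,
                 genotype_posterior = structure(
                   list(probs = gprobs,
                        individuals = counts$individuals,
                        loci = counts$loci,
                        populations = counts$populations),
                   class = "genotype_posterior"),
                 populations = pops, loci = counts$loci,
                 mcmc_meta = c(mcmc, list(retained = S,
                                          error_rate = error_rate))),
            class = "allele_freq_posterior")
}

# Gibbs sampler for one population; alt/n are loci x individuals.
gibbs_freq_one_pop <- function(alt, n, error_rate, mcmc, ci_level,
                               keep_samples) {
  L <- nrow(alt)
  N <- ncol(alt)
  l0 <- stats::dbinom(alt, n, error_rate)
  l1 <- stats::dbinom(alt, n, 0.5)
  l2 <- stats::dbinom(alt, n, 1 - error_rate)
  S <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  p <- (rowSums(alt) + 1) / (rowSums(n) + 2)
  keep <- matrix(NA_real_, L, S)
  g0 <- g1 <- g2 <- matrix(0, L, N)
  s_idx <- 0L
  for (it in seq_len(mcmc$iterations)) {
    w0 <- l0 * (1 - p)^2
    w1 <- l1 * (2 * p * (1 - p))
    w2 <- l2 * p^2
    tot <- w0 + w1 + w2
    c0 <- w0 / tot
    c1 <- w1 / tot
    u <- matrix(stats::runif(L * N), L, N)
    g <- (u > c0) + (u > (c0 + c1))
    s <- rowSums(g)
    p <- stats::rbeta(L, 1 + s, 1 + 2 * N - s)
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
      s_idx <- s_idx + 1L
      keep[, s_idx] <- p
      g0 <- g0 + c0
      g1 <- g1 + c1
      g2 <- g2 + (1 - c0 - c1)
    }
  }
  a <- (1 - ci_level) / 2
  qs <- matrixStats_quantiles(keep, c(a, 0.5, 1 - a))
  list(mean = rowMeans(keep), median = qs[, 2L], lo = qs[, 1L],
       hi = qs[, 3L], samples = if (keep_samples) keep else NULL,
       g0 = g0 / S, g1 = g1 / S, g2 = g2 / S)
}

# row-wise quantiles without extra dependencies
matrixStats_quantiles <- function(m, probs) {
  t(apply(m, 1L, stats::quantile, probs = probs, names = FALSE))
}

#' @export
print.allele_freq_posterior <- function(x, ...) {
  cat("allele_freq_posterior:", length(x$populations), "populations x",
      length(x$loci), "loci;", x$mcmc_meta$retained, "retained draws\n")
  invisible(x)
}

#' Posterior-modal genotypes
#'
#' Collapses a genotype posterior to a dosage matrix, breaking ties
#' toward the heterozygote.
#'
#' @param gpost A `genotype_posterior`.
#' @return Integer matrix (individuals x loci) with values in {0, 1, 2}.
#' @export
modal_genotype <- function(gpost) {
  stopifnot(inherits(gpost, "genotype_posterior"))
  p0 <- gpost$probs[, , 1L]
  p1 <- gpost$probs[, , 2L]
  p2 <- gpost$probs[, , 3L]
  g <- matrix(0L, nrow(p0), ncol(p0), dimnames = dimnames(p0))
  g[p2 > p0 & p2 > p1] <- 2L
  g[p1 >= p0 & p1 >= p2] <- 1L      # het wins ties
  g
}

#' Mean posterior genotype entropy
#'
#' Average Shannon entropy (nats) of the per-cell genotype posterior;
#' decreases as coverage (information) grows.
#'
#' @param gpost A `genotype_posterior`.
#' @return Scalar mean entropy.
#' @export
genotype_entropy <- function(gpost) {
  p <- gpost$probs
  p[p < 1e-12] <- 1e-12
  mean(-(p[, , 1] * log(p[, , 1]) + p[, , 2] * log(p[, , 2]) +
           p[, , 3] * log(p[, , 3])))
}
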