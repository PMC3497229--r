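# Approximate Bayesian computation for a population pair: model choice
# between divergence without gene flow and divergence with gene flow
# under an isolation-with-migration parameterization, plus estimation of
# the scaled migration rate 4*Ne*m.  The per-locus simulator is a
# forward diffusion-scale Wright-Fisher: time in units of 2N
# generations, migration as 4Nm, run on a fixed scaled grid of N_sim
# diploids.

#' Isolation-with-migration simulation parameters
#'
#' @param theta Shape of the ancestral frequency distribution
#'   `Beta(theta, theta)` (truncated to clearly polymorphic
#'   frequencies).
#' @param t_div Divergence time in units of `2N` generations.
#' @param mig Scaled migration rate `4 Ne m` (0 = no gene flow).
#' @param n_loci Number of independent loci.
#' @param n_chrom_1,n_chrom_2 Chromosomes sampled per population.
#' @param n_sim_pop Diploid size of the scaled simulation grid.  The
#'   default (50) keeps per-generation binomial drift tractable while
#'   preserving the diffusion scaling.
#' @return List of class `iso_mig_params`.
#' @export
iso_mig_params <- function(theta = 1, t_div = 1, mig = 0, n_loci = 500L,
                           n_chrom_1 = 40L, n_chrom_2 = 40L,
                           n_sim_pop = 50L) {
  stop_if(any(c(theta, t_div, mig) < 0), "parameters must be non-negative")
  structure(list(theta = theta, t_div = t_div, mig = mig,
                 n_loci = as.integer(n_loci),
                 n_chrom_1 = as.integer(n_chrom_1),
                 n_chrom_2 = as.integer(n_chrom_2),
                 n_sim_pop = as.integer(n_sim_pop)),
            class = "iso_mig_params")
}

#' Summary statistics for a population pair
#'
#' The declared statistic set used on both observed and simulated data:
#' mean and SD of per-locus F_ST (Hudson-type moment estimator; the
#' mean is a ratio of averages, unbiased around zero divergence), mean
#' expected heterozygosity per population, the fraction of loci fixed
#' for alternative alleles, and the fraction polymorphic in exactly one
#' population.
#'
#' @param x1,x2 Non-reference allele counts per locus.
#' @param n1,n2 Chromosomes sampled per locus (scalars or vectors).
#' @return Named numeric vector `mean_fst, sd_fst, mean_het_1,
#'   mean_het_2, prop_fixed, prop_private`.
#' @export
pair_summary_stats <- function(x1, n1, x2, n2) {
  n1 <- rep_len(n1, length(x1))
  n2 <- rep_len(n2, length(x2))
  ok <- n1 > 1L & n2 > 1L
  x1 <- x1[ok]; n1 <- n1[ok]; x2 <- x2[ok]; n2 <- n2[ok]
  p1 <- x1 / n1
  p2 <- x2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  poly <- den > 0
  fst_i <- num[poly] / den[poly]
  c(mean_fst = if (any(poly)) sum(num[poly]) / sum(den[poly]) else 0,
    sd_fst = if (sum(poly) > 1L) stats::sd(fst_i) else 0,
    mean_het_1 = mean(2 * p1 * (1 - p1)),
    mean_het_2 = mean(2 * p2 * (1 - p2)),
    prop_fixed = mean(abs(p1 - p2) == 1),
    prop_private = mean((p1 > 0 & p1 < 1) != (p2 > 0 & p2 < 1)))
}

#' Simulate pair summary statistics under isolation with migration
#'
#' Each locus starts at an ancestral frequency drawn from
#' `Beta(theta, theta)` truncated to (0.01, 0.99); the two daughter
#' frequencies then drift for `round(t_div * 2 * n_sim_pop)` forward
#' generations with symmetric per-generation migration
#' `min(mig / (4 n_sim_pop), 0.5)`; finally `n_chrom` binomial allele
#' copies are sampled per population and summarized.
#'
#' @param params An [iso_mig_params()].
#' @param seed Integer seed or `NULL` (use current RNG state).
#' @return Named statistic vector from [pair_summary_stats()].
#' @export
simulate_pair_stats <- function(params, seed = NULL) {
  stopifnot(inherits(params, "iso_mig_params"))
  if (!is.null(seed)) set.seed(seed)
  L <- params$n_loci
  p0 <- stats::rbeta(L, params$theta, params$theta)
  for (r in 1:20) {
    bad <- p0 < 0.01 | p0 > 0.99
    if (!any(bad)) break
    p0[bad] <- stats::rbeta(sum(bad), params$theta, params$theta)
  }
  p0[p0 < 0.01] <- 0.01
  p0[p0 > 0.99] <- 0.99
  n_gen <- as.integer(round(params$t_div * 2 * params$n_sim_pop))
  m <- min(params$mig / (4 * params$n_sim_pop), 0.5)
  P <- drift_pair_cpp(p0, n_gen, params$n_sim_pop, m)
  x1 <- stats::rbinom(L, params$n_chrom_1, P[1, ])
  x2 <- stats::rbinom(L, params$n_chrom_2, P[2, ])
  pair_summary_stats(x1, params$n_chrom_1, x2, params$n_chrom_2)
}

#' Build a rejection-ABC reference table
#'
#' Simulates `n_sims` parameter draws, half from the no-gene-flow model
#' (`mig = 0`) and half from the with-gene-flow model (`log10(mig)`
#' uniform), with `t_div` and `theta` drawn from their priors, and
#' records the summary statistics of each simulation.  A reference
#' table depends only on the priors and can be reused across observed
#' datasets.
#'
#' @param n_sims Total simulations (split evenly between models).
#' @param priors List with `t_div` (range), `log10_mig` (range),
#'   `theta` (range).
#' @param sim_config List with `n_loci, n_chrom_1, n_chrom_2,
#'   n_sim_pop`.
#' @param seed Integer seed.
#' @return Data frame of class `abc_reference`: `model` ("no_flow" /
#'   "with_flow"), parameters, statistic columns.
#' @export
abc_reference_table <- function(n_sims = 10000L,
                                priors = list(t_div = c(0.05, 4),
                                              log10_mig = c(0, 2),
                                              theta = c(0.2, 2)),
                                sim_config = list(n_loci = 500L,
                                                  n_chrom_1 = 40L,
                                                  n_chrom_2 = 40L,
                                                  n_sim_pop = 50L),
                                seed = 1L) {
  stop_if(n_sims < 2L, "need at least 2 simulations")
  set.seed(seed)
  n_half <- floor(n_sims / 2)
  n_tot <- 2L * n_half
  model <- rep(c("no_flow", "with_flow"), each = n_half)
  t_div <- stats::runif(n_tot, priors$t_div[1], priors$t_div[2])
  theta <- stats::runif(n_tot, priors$theta[1], priors$theta[2])
  mig <- c(rep(0, n_half),
           10^stats::runif(n_half, priors$log10_mig[1], priors$log10_mig[2]))
  stats_m <- matrix(NA_real_, n_tot, 6L)
  for (s in seq_len(n_tot)) {
    pars <- iso_mig_params(theta = theta[s], t_div = t_div[s], mig = mig[s],
                           n_loci = sim_config$n_loci,
                           n_chrom_1 = sim_config$n_chrom_1,
                           n_chrom_2 = sim_config$n_chrom_2,
                           n_sim_pop = sim_config$n_sim_pop)
    stats_m[s, ] <- simulate_pair_stats(pars)
  }
  colnames(stats_m) <- c("mean_fst", "sd_fst", "mean_het_1", "mean_het_2",
                         "prop_fixed", "prop_private")
  out <- data.frame(model = model, t_div = t_div, mig = mig, theta = theta,
                    stats_m, stringsAsFactors = FALSE)
  class(out) <- c("abc_reference", class(out))
  attr(out, "priors") <- priors
  attr(out, "sim_config") <- sim_config
  out
}

#' ABC model choice: divergence with vs. without gene flow
#'
#' Rejection ABC with equal model priors: accepts the
#' `tolerance_fraction` of simulations nearest the observed statistics
#' in Euclidean distance after per-statistic standardization by the
#' median absolute deviation of the simulated pool.  Statistics with
#' zero spread are dropped from the distance with a warning.
#'
#' @param observed Named statistic vector from [pair_summary_stats()].
#' @param reference An [abc_reference_table()], or `NULL` to build one.
#' @param n_sims,priors,sim_config,seed Passed to
#'   [abc_reference_table()] when `reference` is `NULL`; `seed` also
#'   governs nothing else (rejection is deterministic given the table).
#' @param tolerance_fraction Fraction of simulations accepted, in
#'   (0, 1].
#' @return Object of class `abc_result`: `p_zero_flow`, `m_posterior`
#'   (mean / median / 90% interval of accepted `4Nm` under the
#'   with-flow model), `n_accepted`, `accepted` (data frame), `n_sims`,
#'   `tolerance_fraction`, `seed`.
#' @export
abc_model_choice <- function(observed, reference = NULL, n_sims = 10000L,
                             tolerance_fraction = 0.005,
                             priors = list(t_div = c(0.05, 4),
                                           log10_mig = c(0, 2),
                                           theta = c(0.2, 2)),
                             sim_config = list(n_loci = 500L,
                                               n_chrom_1 = 40L,
                                               n_chrom_2 = 40L,
                                               n_sim_pop = 50L),
                             seed = 1L) {
  stop_if(tolerance_fraction <= 0 || tolerance_fraction > 1,
          "tolerance_fraction must be in (0, 1]")
  if (is.null(reference)) {
    stop_if(n_sims < 1000L, "need n_sims >= 1000")
    reference <- abc_reference_table(n_sims, priors, sim_config, seed)
  }
  stat_cols <- c("mean_fst", "sd_fst", "mean_het_1", "mean_het_2",
                 "prop_fixed", "prop_private")
  S <- as.matrix(reference[, stat_cols])
  obs <- observed[stat_cols]
  scale <- apply(S, 2L, stats::mad)
  # a zero MAD with positive spread is not degenerate; fall back to SD
  zero_mad <- scale == 0
  scale[zero_mad] <- apply(S[, zero_mad, drop = FALSE], 2L, stats::sd)
  usable <- scale > 0
  if (!all(usable))
    warning("statistic(s) with zero spread dropped from the distance: ",
            paste(stat_cols[!usable], collapse = ", "))
  d2 <- rowSums(scale(S[, usable, drop = FALSE],
                      center = obs[usable],
                      scale = scale[usable])^2)
  n_acc <- max(1L, round(tolerance_fraction * nrow(reference)))
  acc <- order(d2)[seq_len(n_acc)]
  accepted <- reference[acc, c("model", "t_div", "mig", "theta")]
  accepted$distance <- sqrt(d2[acc])
  mig_ii <- accepted$mig[accepted$model == "with_flow"]
  m_post <- if (length(mig_ii))
    c(mean = mean(mig_ii), median = stats::median(mig_ii),
      q05 = unname(stats::quantile(mig_ii, 0.05)),
      q95 = unname(stats::quantile(mig_ii, 0.95)))
  else c(mean = NA_real_, median = NA_real_, q05 = NA_real_, q95 = NA_real_)
  structure(list(p_zero_flow = mean(accepted$model == "no_flow"),
                 m_posterior = m_post, n_accepted = n_acc,
                 accepted = accepted, n_sims = nrow(reference),
                 tolerance_fraction = tolerance_fraction, seed = seed),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("abc_result: P(zero gene flow) = %.3f (%d accepted of %d)\n",
              x$p_zero_flow, x$n_accepted, x$n_sims))
  if (is.finite(x$m_posterior["median"]))
    cat(sprintf("  4Nm | gene flow: median %.3g  [%.3g, %.3g]\n",
                x$m_posterior["median"], x$m_posterior["q05"],
                x$m_posterior["q95"]))
  invisible(x)
}

#' Observed pair statistics from estimated allele frequencies
#'
#' Converts the expected allele counts of a pair (the same counts the
#' F-model consumes) into the ABC summary-statistic vector.
#'
#' @param pair_counts Data frame `locus, x1, n1, x2, n2`.
#' @return Named statistic vector.
#' @export
observed_pair_stats <- function(pair_counts) {
  pair_summary_stats(pair_counts$x1, pair_counts$n1,
                     pair_counts$x2, pair_counts$n2)
}
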