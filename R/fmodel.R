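# Hierarchical Bayesian F-model for pairwise genomic differentiation.
# Population allele frequencies at locus i are Beta-distributed around
# an ancestral frequency pi_i with dispersion governed by a per-locus
# F_ST whose logit (alpha_i) follows a genome-wide Normal(mu, 1/tau)
# hyperdistribution.  Integrating the Beta over the population
# frequencies yields a beta-binomial likelihood for the observed allele
# counts, sampled here by Metropolis-within-Gibbs.

#' Allele counts for a population pair from genotype posteriors
#'
#' Default data interface of the F-model: per population and locus,
#' expected non-reference allele counts `sum_k E[g_k]` from the
#' genotype posterior, rounded to integers, out of `2 N` chromosomes.
#'
#' @param gpost A `genotype_posterior` from
#'   [estimate_allele_frequencies()].
#' @param pops Character vector of two population labels.
#' @return Data frame `locus, x1, n1, x2, n2`.
#' @export
pair_allele_counts <- function(gpost, pops) {
  stopifnot(inherits(gpost, "genotype_posterior"), length(pops) == 2L)
  stop_if(!all(pops %in% gpost$populations),
          "unknown population(s): ",
          paste(setdiff(pops, gpost$populations), collapse = ", "))
  dose <- gpost$probs[, , 2L] + 2 * gpost$probs[, , 3L]
  one <- function(p) {
    ind <- which(unname(gpost$populations) == p)
    list(x = as.integer(round(colSums(dose[ind, , drop = FALSE]))),
         n = 2L * length(ind))
  }
  a <- one(pops[1]); b <- one(pops[2])
  data.frame(locus = gpost$loci, x1 = a$x, n1 = a$n, x2 = b$x, n2 = b$n,
             stringsAsFactors = FALSE)
}

#' Pooled read counts for a population pair
#'
#' Alternative data interface: per population and locus, pooled
#' non-reference and total read counts, used with the same binomial
#' sampling layer (reads sample population allele copies).
#'
#' @param counts A [read_count_matrix()] with populations.
#' @param pops Two population labels.
#' @return Data frame `locus, x1, n1, x2, n2` (n varies per locus).
#' @export
pair_read_counts <- function(counts, pops) {
  stopifnot(inherits(counts, "read_count_matrix"), length(pops) == 2L)
  one <- function(p) {
    ind <- which(unname(counts$populations) == p)
    list(x = colSums(counts$alt_reads[ind, , drop = FALSE]),
         n = colSums(counts$n_reads[ind, , drop = FALSE]))
  }
  a <- one(pops[1]); b <- one(pops[2])
  data.frame(locus = counts$loci, x1 = a$x, n1 = a$n, x2 = b$x, n2 = b$n,
             stringsAsFactors = FALSE)
}

# beta-binomial log likelihood up to the binomial coefficient
lbetabinom <- function(x, n, a, b) {
  lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Fit the pairwise hierarchical F-model
#'
#' Model: allele counts `x_j ~ BetaBinomial(n_j, pi_i c_i, (1 - pi_i)
#' c_i)` for pair member `j`, with `c_i = (1 - F_i)/F_i` and `alpha_i =
#' logit(F_i) ~ Normal(mu, 1/tau)`.  Priors: `mu ~ Normal(0, var 10)`,
#' `tau ~ Gamma(0.01, 0.01)`, `pi_i ~ Uniform(0, 1)`.  Loci monomorphic
#' in both populations (F_ST undefined) are excluded with a logged
#' count.  Proposal scales adapt toward ~30% acceptance during burn-in
#' and are frozen afterwards.
#'
#' @param pair_counts Data frame `locus, x1, n1, x2, n2` (from
#'   [pair_allele_counts()] or [pair_read_counts()]).
#' @param mcmc An [mcmc_control()]; default 5,000 iterations, 1,000
#'   burn-in, thin 2.
#' @param point `"median"` (default) or `"mean"` posterior point
#'   estimate for `alpha`.
#' @param q Posterior-predictive quantile level for outlier calling.
#' @param k_pred Predictive draws of `alpha*` per retained
#'   hyperparameter draw.
#' @param pair Optional character vector of the two population labels.
#' @return Object of class `pair_divergence`: per-locus `alpha_point`,
#'   `fst_point`, `outlier_flags`; retained draws `alpha_samples`,
#'   `pi_samples`, `mu_samples`, `tau_samples`; `predictive_q`;
#'   bookkeeping (`loci`, `kept`, `n_excluded`).
#' @export
fit_fmodel <- function(pair_counts,
                       mcmc = mcmc_control(iterations = 5000L,
                                           burn_in = 1000L, thinning = 2L),
                       point = c("median", "mean"),
                       q = 0.95, k_pred = 10L, pair = NULL) {
  point <- match.arg(point)
  stopifnot(all(c("locus", "x1", "n1", "x2", "n2") %in% names(pair_counts)))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  x1 <- pair_counts$x1; n1 <- pair_counts$n1
  x2 <- pair_counts$x2; n2 <- pair_counts$n2
  kept <- n1 > 0L & n2 > 0L & !(x1 == 0L & x2 == 0L) &
    !(x1 == n1 & x2 == n2)
  n_excluded <- sum(!kept)
  if (n_excluded > 0L)
    message(n_excluded,
            " locus/loci monomorphic or empty in both populations excluded")
  stop_if(sum(kept) < 2L, "pair has fewer than 2 polymorphic loci")
  x1 <- x1[kept]; n1 <- n1[kept]; x2 <- x2[kept]; n2 <- n2[kept]
  L <- sum(kept)
  S <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning

  # initial values from sample frequencies; alpha starts at per-locus
  # moment estimates of F_ST so its spread is realistic from iteration
  # one (a collapsed start makes tau explode and the funnel mixes
  # slowly)
  p1 <- (x1 + 1) / (n1 + 2)
  p2 <- (x2 + 1) / (n2 + 2)
  pi_ <- (p1 + p2) / 2
  fst0 <- (p1 - p2)^2 / (p1 * (1 - p2) + p2 * (1 - p1))
  alpha <- logit(pmin(pmax(fst0, 0.005), 0.95))
  mu <- mean(alpha)
  tau <- 1 / max(stats::var(alpha), 0.05)

  loglik <- function(alpha, pi_) {
    cc <- exp(-alpha)
    a <- pi_ * cc
    b <- (1 - pi_) * cc
    lbetabinom(x1, n1, a, b) + lbetabinom(x2, n2, a, b)
  }
  ll <- loglik(alpha, pi_)

  sd_a <- rep(0.8, L)
  sd_p <- rep(0.8, L)
  alpha_s <- matrix(NA_real_, L, S)
  pi_s <- matrix(NA_real_, L, S)
  mu_s <- tau_s <- numeric(S)
  s_idx <- 0L
  sigma <- 1 / sqrt(tau)
  for (it in seq_len(mcmc$iterations)) {
    # alpha block (random-walk MH, vectorized over loci)
    prop <- alpha + stats::rnorm(L) * sd_a
    ll_p <- loglik(prop, pi_)
    logr <- ll_p - ll +
      stats::dnorm(prop, mu, sigma, log = TRUE) -
      stats::dnorm(alpha, mu, sigma, log = TRUE)
    acc <- log(stats::runif(L)) < logr
    alpha[acc] <- prop[acc]
    ll[acc] <- ll_p[acc]
    # pi block on the logit scale (Jacobian gives Uniform(0,1) prior)
    lp <- logit(pi_)
    lp_prop <- lp + stats::rnorm(L) * sd_p
    pi_prop <- ilogit(lp_prop)
    ll_p <- loglik(alpha, pi_prop)
    logr <- ll_p - ll +
      log(pi_prop * (1 - pi_prop)) - log(pi_ * (1 - pi_))
    acc2 <- log(stats::runif(L)) < logr
    pi_[acc2] <- pi_prop[acc2]
    ll[acc2] <- ll_p[acc2]
    # conjugate hyperparameter updates
    prec <- 0.1 + L * tau
    mu <- stats::rnorm(1, tau * sum(alpha) / prec, 1 / sqrt(prec))
    tau <- stats::rgamma(1, 0.01 + L / 2,
                         0.01 + 0.5 * sum((alpha - mu)^2))
    # joint rescale of (alpha - mu, tau): the slow funnel direction.
    # alpha' = mu + e^s (alpha - mu), tau' = e^{-2s} tau; the Normal
    # prior cancels against the Jacobian, leaving the likelihood and
    # Gamma-prior terms.
    s <- stats::rnorm(1, 0, 0.1)
    alpha_r <- mu + exp(s) * (alpha - mu)
    tau_r <- exp(-2 * s) * tau
    ll_r <- loglik(alpha_r, pi_)
    logr <- sum(ll_r - ll) - 2 * s * 0.01 - 0.01 * (tau_r - tau)
    if (log(stats::runif(1)) < logr) {
      alpha <- alpha_r
      tau <- tau_r
      ll <- ll_r
    }
    sigma <- 1 / sqrt(tau)
    if (it <= mcmc$burn_in) {          # adaptive scaling, frozen after burn-in
      sd_a <- sd_a * exp(0.05 * (acc - 0.3))
      sd_p <- sd_p * exp(0.05 * (acc2 - 0.3))
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
      s_idx <- s_idx + 1L
      alpha_s[, s_idx] <- alpha
      pi_s[, s_idx] <- pi_
      mu_s[s_idx] <- mu
      tau_s[s_idx] <- tau
    }
  }
  alpha_point <- if (point == "median") apply(alpha_s, 1L, stats::median)
                 else rowMeans(alpha_s)
  pred_q <- genomewide_alpha_quantiles(mu_s, tau_s, q = q, k = k_pred)
  fit <- structure(list(pair = pair,
                        loci = pair_counts$locus, kept = kept,
                        n_excluded = n_excluded,
                        alpha_samples = alpha_s, pi_samples = pi_s,
                        mu_samples = mu_s, tau_samples = tau_s,
                        alpha_point = alpha_point,
                        fst_point = ilogit(alpha_point),
                        predictive_q = pred_q, q = q,
                        point = point, mcmc_meta = mcmc),
                   class = "pair_divergence")
  fit$outlier_flags <- call_outliers(fit, q = q)
  fit
}

#' @export
print.pair_divergence <- function(x, ...) {
  cat("pair_divergence", if (!is.null(x$pair)) paste(x$pair, collapse = " x "),
      ":", sum(x$kept), "polymorphic loci (", x$n_excluded, "excluded )\n")
  cat("  genome-level F_ST (inv-logit posterior mean mu):",
      round(ilogit(mean(x$mu_samples)), 4), "\n")
  cat("  outliers: high", sum(x$outlier_flags == "high"),
      "/ low", sum(x$outlier_flags == "low"), "\n")
  invisible(x)
}

#' Posterior-predictive quantiles of the genome-wide alpha distribution
#'
#' Integrates over hyperparameter uncertainty: for each retained draw
#' `(mu_t, tau_t)`, samples `k` values `alpha* ~ Normal(mu_t, 1/tau_t)`
#' and returns the empirical `1 - q` and `q` quantiles of the pooled
#' sample.
#'
#' @param mu_samples,tau_samples Retained hyperparameter draws (>= 100).
#' @param q Quantile level in (0.5, 1).
#' @param k Predictive draws per hyperparameter draw.
#' @return Named vector `c(q_low, q_high)`.
#' @export
genomewide_alpha_quantiles <- function(mu_samples, tau_samples, q = 0.95,
                                       k = 10L) {
  stop_if(q <= 0.5 || q >= 1, "q must be in (0.5, 1)")
  stop_if(length(mu_samples) < 100L || length(mu_samples) != length(tau_samples),
          "need >= 100 paired hyperparameter draws")
  a_star <- stats::rnorm(length(mu_samples) * k,
                         mean = rep(mu_samples, each = k),
                         sd = rep(1 / sqrt(tau_samples), each = k))
  qs <- stats::quantile(a_star, c(1 - q, q), names = FALSE)
  c(q_low = qs[1], q_high = qs[2])
}

#' Call F_ST outliers against the genome-wide distribution
#'
#' A locus is flagged `high` (`low`) if its `alpha` point estimate lies
#' above (below) the posterior-predictive interval.  Both tails are
#' flagged; the headline outlier count used in the per-pair summaries is
#' the high tail.
#'
#' @param pair A `pair_divergence`.
#' @param q Quantile level; if it differs from the fitted one the
#'   predictive quantiles are recomputed.
#' @return Factor with levels `none, high, low`, one per kept locus.
#' @export
call_outliers <- function(pair, q = 0.95) {
  stopifnot(inherits(pair, "pair_divergence"))
  pq <- if (!is.null(pair$predictive_q) && isTRUE(all.equal(q, pair$q)))
    pair$predictive_q
  else genomewide_alpha_quantiles(pair$mu_samples, pair$tau_samples, q = q)
  flags <- rep("none", length(pair$alpha_point))
  flags[pair$alpha_point > pq["q_high"]] <- "high"
  flags[pair$alpha_point < pq["q_low"]] <- "low"
  factor(flags, levels = c("none", "high", "low"))
}

#' Shape summaries of a per-locus F_ST distribution
#'
#' Central-moment summaries (denominator `n`): mean, variance, skewness
#' `g1 = m3 / m2^{3/2}`, and kurtosis reported both raw (`m4 / m2^2`)
#' and excess (raw minus 3), with the convention labelled by the field
#' names.
#'
#' @param x A `pair_divergence` (uses `fst_point`) or numeric vector.
#' @return List of class `fst_distribution_summary`: `mean, variance,
#'   skewness, kurtosis_raw, kurtosis_excess, n_loci, n_outliers_high`.
#' @export
fst_distribution_summary <- function(x) {
  n_high <- NA_integer_
  if (inherits(x, "pair_divergence")) {
    n_high <- sum(x$outlier_flags == "high")
    x <- x$fst_point
  }
  x <- as.numeric(x)
  stop_if(length(x) < 3L, "need >= 3 loci for shape summaries")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  stop_if(m2 == 0, "summaries undefined for a constant F_ST vector")
  structure(list(mean = m, variance = m2,
                 skewness = mean(d^3) / m2^1.5,
                 kurtosis_raw = mean(d^4) / m2^2,
                 kurtosis_excess = mean(d^4) / m2^2 - 3,
                 n_loci = length(x), n_outliers_high = n_high),
            class = "fst_distribution_summary")
}

#' @export
print.fst_distribution_summary <- function(x, ...) {
  cat(sprintf(paste0("F_ST distribution: mean %.4f, var %.5f, skewness %.3f, ",
                     "kurtosis %.2f (raw) / %.2f (excess), n = %d\n"),
              x$mean, x$variance, x$skewness, x$kurtosis_raw,
              x$kurtosis_excess, x$n_loci))
  invisible(x)
}

#' Simulate allele counts from the F-model's generative process
#'
#' Draws `alpha_i ~ Normal(mu, 1/tau)`, `pi_i ~ Uniform(pi_range)`,
#' population frequencies from the defining Beta, and binomial allele
#' counts; used for parameter-recovery and calibration checks.
#'
#' @param n_loci Number of loci.
#' @param mu,tau Hyperparameters of the logit-F_ST distribution.
#' @param n_chrom Chromosomes sampled per population (scalar or 2).
#' @param pi_range Range of the ancestral frequency distribution.
#' @param seed Integer seed or `NULL`.
#' @return List: `counts` data frame (as [fit_fmodel()] input), plus
#'   the true `alpha`, `pi`, `fst` vectors.
#' @export
simulate_fmodel_counts <- function(n_loci, mu, tau, n_chrom = 40L,
                                   pi_range = c(0, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_chrom <- rep_len(as.integer(n_chrom), 2L)
  alpha <- stats::rnorm(n_loci, mu, 1 / sqrt(tau))
  fst <- ilogit(alpha)
  pi_ <- stats::runif(n_loci, pi_range[1], pi_range[2])
  cc <- (1 - fst) / fst
  p1 <- stats::rbeta(n_loci, pi_ * cc, (1 - pi_) * cc)
  p2 <- stats::rbeta(n_loci, pi_ * cc, (1 - pi_) * cc)
  counts <- data.frame(locus = sprintf("L%05d", seq_len(n_loci)),
                       x1 = stats::rbinom(n_loci, n_chrom[1], p1),
                       n1 = n_chrom[1],
                       x2 = stats::rbinom(n_loci, n_chrom[2], p2),
                       n2 = n_chrom[2], stringsAsFactors = FALSE)
  list(counts = counts, alpha = alpha, pi = pi_, fst = fst)
}
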