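# Orchestration: simulate -> freqs -> divergence / ld / abc -> mantel /
# clines -> report, as a configured, logged, seed-deterministic run
# producing a per-pair master table.

#' Pipeline run configuration
#'
#' Collects stage toggles and per-module parameter blocks.  Per-stage
#' seeds are derived by hashing the global seed with the stage name, so
#' toggling one stage never perturbs another stage's random stream.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of enabled stages, a subset of
#'   `simulate, freqs, divergence, ld, abc, mantel, clines`.
#' @param landscape A [landscape_config()] (its own seed is overridden
#'   by the derived stage seed).
#' @param reads List: `mean_coverage`, `error_rate`.
#' @param freqs List: `error_rate`, `iterations`, `burn_in`,
#'   `thinning`.  The defaults (2,000 / 500 / 4) are a scaled-down
#'   desk setting; pass the full 20,000 / 2,000 / 4 for production-size
#'   runs.
#' @param divergence List: `iterations`, `burn_in`, `thinning`, `q`.
#' @param ld List: `n_pairs` subsampled per population.
#' @param abc List: `n_sims`, `tolerance_fraction`, `n_sim_pop`,
#'   `n_loci` (loci per ABC simulation), `priors`.
#' @param clines List: `n_outlier_loci`, `n_random_loci`.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "freqs", "divergence", "ld",
                                  "abc", "mantel", "clines"),
                       landscape = landscape_config(),
                       reads = list(mean_coverage = 0.77, error_rate = 0.005),
                       freqs = list(error_rate = 0.005, iterations = 2000L,
                                    burn_in = 500L, thinning = 4L),
                       divergence = list(iterations = 3000L, burn_in = 1000L,
                                         thinning = 2L, q = 0.95),
                       ld = list(n_pairs = 20000L),
                       abc = list(n_sims = 4000L, tolerance_fraction = 0.01,
                                  n_sim_pop = 50L, n_loci = 300L,
                                  priors = list(t_div = c(0.05, 4),
                                                log10_mig = c(0, 2),
                                                theta = c(0.2, 2))),
                       clines = list(n_outlier_loci = 8L, n_random_loci = 8L)) {
  all_stages <- c("simulate", "freqs", "divergence", "ld", "abc", "mantel",
                  "clines")
  stop_if(!all(stages %in% all_stages),
          "unknown stage(s): ", paste(setdiff(stages, all_stages),
                                      collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages,
                 landscape = landscape, reads = reads, freqs = freqs,
                 divergence = divergence, ld = ld, abc = abc,
                 clines = clines),
            class = "run_config")
}

log_line <- function(log_path, ...) {
  cat(paste0(format(Sys.time(), "%H:%M:%S"), "  ", ..., "\n"),
      file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated
#' landscape, writing per-stage outputs, a log of every parameter
#' default actually used, and a per-pair master table
#' (`master_table.tsv`) with columns `pair, distance_km, adjacency,
#' same_host, mean_fst, n_outliers_high, skewness, kurtosis_excess,
#' p_zero_flow, mig_estimate`.  Reruns with an identical configuration
#' and seed reproduce all numerical outputs exactly; every output file
#' carries the configuration hash.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @return List of class `pipeline_run` with the in-memory stage
#'   results, the master table, and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(unclass(config))
  stamp <- paste0("config_hash=", chash)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line(log_path, "run start; ", stamp, "; global seed ", config$seed)
  on <- function(stage) stage %in% config$stages
  res <- list(config = config, config_hash = chash, out_dir = out_dir)

  # --- simulate -------------------------------------------------------
  stop_if(!on("simulate"), "the simulate stage is required")
  lc <- config$landscape
  lc$seed <- derive_seed(config$seed, "simulate")
  truth <- simulate_landscape(lc)
  counts <- simulate_reads(truth,
                           mean_coverage = config$reads$mean_coverage,
                           error_rate = config$reads$error_rate,
                           seed = derive_seed(config$seed, "reads"))
  write_landscape(truth, counts, file.path(out_dir, "simulate"))
  log_line(log_path, "simulate: ", lc$n_pops, " pops, ", lc$n_loci,
           " loci, coverage ", config$reads$mean_coverage,
           "x, error ", config$reads$error_rate)
  res$truth <- truth
  res$counts <- counts
  pairs <- truth$pair_table

  # --- freqs ----------------------------------------------------------
  freqs <- NULL
  if (on("freqs")) {
    freqs <- estimate_allele_frequencies(
      counts, error_rate = config$freqs$error_rate,
      mcmc = mcmc_control(config$freqs$iterations, config$freqs$burn_in,
                          config$freqs$thinning,
                          seed = derive_seed(config$seed, "freqs")),
      keep_samples = FALSE)
    log_line(log_path, "freqs: ", config$freqs$iterations, " iterations, ",
             "burn-in ", config$freqs$burn_in, ", thin ",
             config$freqs$thinning, ", error rate ",
             config$freqs$error_rate, " (fixed, not estimated)")
    fr <- data.frame(locus = freqs$loci, t(freqs$mean), check.names = FALSE)
    write_dtsv(fr, file.path(out_dir, "allele_freq_mean.tsv"), stamp)
    res$freqs <- freqs
  }

  # --- divergence (pairwise F-model) ---------------------------------
  div <- NULL
  per_locus <- NULL
  if (on("divergence")) {
    stop_if(is.null(freqs), "divergence requires the freqs stage")
    q <- config$divergence$q %||% 0.95
    div <- vector("list", nrow(pairs))
    names(div) <- pairs$pair
    pl_rows <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      pp <- c(pairs$pop_a[k], pairs$pop_b[k])
      pc <- pair_allele_counts(freqs$genotype_posterior, pp)
      fit <- suppressMessages(fit_fmodel(
        pc, mcmc = mcmc_control(config$divergence$iterations,
                                config$divergence$burn_in,
                                config$divergence$thinning,
                                seed = derive_seed(config$seed,
                                                   paste0("fmodel:", pairs$pair[k]))),
        q = q, pair = pp))
      div[[k]] <- fit
      pl_rows[[k]] <- data.frame(
        pair = pairs$pair[k], locus = fit$loci[fit$kept],
        alpha = fit$alpha_point, fst = fit$fst_point,
        outlier = as.character(fit$outlier_flags),
        stringsAsFactors = FALSE)
    }
    per_locus <- do.call(rbind, pl_rows)
    log_line(log_path, "divergence: F-model on ", nrow(pairs),
             " pairs, q = ", q, ", point = posterior median")
    res$divergence <- div
  }

  # --- ld -------------------------------------------------------------
  if (on("ld")) {
    stop_if(is.null(freqs), "ld requires the freqs stage")
    gmode <- modal_genotype(freqs$genotype_posterior)
    pops <- unique(unname(counts$populations))
    ld_rows <- lapply(pops, function(p) {
      g <- gmode[unname(counts$populations) == p, , drop = FALSE]
      ds <- delta_survey(g, pairs = config$ld$n_pairs,
                         seed = derive_seed(config$seed, paste0("ld:", p)))
      data.frame(population = p, mean_delta = ds$mean_delta,
                 mean_abs_delta = ds$mean_abs_delta,
                 within_contig_mean_abs = ds$within_contig_mean_abs,
                 between_contig_mean_abs = ds$between_contig_mean_abs,
                 n_pairs = ds$n_pairs_evaluated, stringsAsFactors = FALSE)
    })
    res$ld <- do.call(rbind, ld_rows)
    write_dtsv(res$ld, file.path(out_dir, "ld_summary.tsv"), stamp)
    log_line(log_path, "ld: modal genotypes, ", config$ld$n_pairs,
             " subsampled pairs per population")
  }

  # --- abc ------------------------------------------------------------
  abc_res <- NULL
  if (on("abc")) {
    stop_if(is.null(freqs), "abc requires the freqs stage")
    sim_cfg <- list(n_loci = config$abc$n_loci,
                    n_chrom_1 = 2L * min(table(counts$populations)),
                    n_chrom_2 = 2L * min(table(counts$populations)),
                    n_sim_pop = config$abc$n_sim_pop)
    ref <- abc_reference_table(config$abc$n_sims, config$abc$priors,
                               sim_cfg,
                               seed = derive_seed(config$seed, "abc"))
    abc_res <- vector("list", nrow(pairs))
    names(abc_res) <- pairs$pair
    for (k in seq_len(nrow(pairs))) {
      pc <- pair_allele_counts(freqs$genotype_posterior,
                               c(pairs$pop_a[k], pairs$pop_b[k]))
      abc_res[[k]] <- abc_model_choice(
        observed_pair_stats(pc), reference = ref,
        tolerance_fraction = config$abc$tolerance_fraction)
    }
    log_line(log_path, "abc: ", config$abc$n_sims, " sims, tolerance ",
             config$abc$tolerance_fraction, ", N_sim ",
             config$abc$n_sim_pop, ", shared reference table")
    res$abc <- abc_res
  }

  # --- master table ---------------------------------------------------
  master <- pairs[, c("pair", "distance_km", "adjacency", "same_host")]
  master$mean_fst <- master$min_fst <- master$max_fst <-
    master$n_outliers_high <- master$skewness <-
    master$kurtosis_excess <- master$p_zero_flow <-
    master$mig_estimate <- NA_real_
  if (!is.null(div)) {
    for (k in seq_len(nrow(pairs))) {
      s <- fst_distribution_summary(div[[k]])
      master$mean_fst[k] <- s$mean
      master$min_fst[k] <- min(div[[k]]$fst_point)
      master$max_fst[k] <- max(div[[k]]$fst_point)
      master$n_outliers_high[k] <- s$n_outliers_high
      master$skewness[k] <- s$skewness
      master$kurtosis_excess[k] <- s$kurtosis_excess
    }
  }
  if (!is.null(abc_res)) {
    master$p_zero_flow <- vapply(abc_res, function(a) a$p_zero_flow, 0)
    master$mig_estimate <- vapply(abc_res, function(a)
      unname(a$m_posterior["median"]) * (1 - a$p_zero_flow), 0)
  }
  master <- master[, c("pair", "distance_km", "adjacency", "same_host",
                       "mean_fst", "min_fst", "max_fst",
                       "n_outliers_high", "skewness",
                       "kurtosis_excess", "p_zero_flow", "mig_estimate")]
  res$master <- master
  write_results_tables(list(per_locus = per_locus, per_pair = master),
                       out_dir, stamp)
  file.rename(file.path(out_dir, "per_pair.tsv"),
              file.path(out_dir, "master_table.tsv"))

  # --- mantel ---------------------------------------------------------
  if (on("mantel") && !is.null(div)) {
    n_pops <- nrow(truth$pop_table)
    labs <- truth$pop_table$population
    geo <- as.matrix(stats::dist(truth$config$coords))
    dimnames(geo) <- list(labs, labs)
    gen <- matrix(0, n_pops, n_pops, dimnames = list(labs, labs))
    for (k in seq_len(nrow(pairs)))
      gen[pairs$pop_a[k], pairs$pop_b[k]] <-
        gen[pairs$pop_b[k], pairs$pop_a[k]] <- master$mean_fst[k]
    mt <- mantel(geo, gen, n_perm = 999L, tail = "greater",
                 seed = derive_seed(config$seed, "mantel"))
    res$mantel_ibd <- mt
    log_line(log_path, "mantel: geographic vs mean F_ST, r = ",
             round(mt$r, 3), ", p = ", round(mt$p, 4))
    write_dtsv(data.frame(test = "geo_vs_fst", r = mt$r, p = mt$p,
                          n_perm = mt$n_perm, tail = mt$tail),
               file.path(out_dir, "mantel.tsv"), stamp)
  }

  # --- clines ---------------------------------------------------------
  if (on("clines") && !is.null(div) && !is.null(freqs)) {
    n_out <- config$clines$n_outlier_loci
    n_rand <- config$clines$n_random_loci
    out_count <- table(per_locus$locus[per_locus$outlier == "high"])
    top <- names(sort(out_count, decreasing = TRUE))
    top <- utils::head(top, n_out)
    set.seed(derive_seed(config$seed, "clines"))
    rand <- sample(setdiff(freqs$loci, top), n_rand)
    cov_df <- truth$covariates
    cline_rows <- lapply(c(top, rand), function(lc_id) {
      f <- freqs$mean[, lc_id]
      cf <- cline_regression(f, cov_df, locus = lc_id)
      data.frame(locus = lc_id,
                 class = if (lc_id %in% top) "outlier" else "random",
                 term = cf$coefficients$term,
                 estimate = cf$coefficients$estimate,
                 p = cf$coefficients$p, stringsAsFactors = FALSE)
    })
    res$clines <- do.call(rbind, cline_rows)
    write_dtsv(res$clines, file.path(out_dir, "clines.tsv"), stamp)
    log_line(log_path, "clines: ", length(top), " top outlier loci + ",
             n_rand, " random loci, covariates z-scored")
  }

  log_line(log_path, "run complete")
  structure(res, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run in", x$out_dir, "\n")
  print(utils::head(x$master))
  invisible(x)
}

#' Report figures for a pipeline run
#'
#' Reads the master table of a completed run and emits (a) a log-log
#' outliers-vs-distance scatter with adjacency coded, (b) per-pair
#' logit-F_ST histograms with the genome-wide predictive density and
#' its 95th-quantile line, and (c) gene flow vs. distance.  Figures for
#' stages that did not run are skipped with a notice.
#'
#' @param run A `pipeline_run` (or a run directory containing
#'   `master_table.tsv`).
#' @param out_dir Figure directory (default `<run>/figures`).
#' @param pairs_to_plot Pair labels for the distribution panels
#'   (default: nearest adjacent, median, and farthest pair).
#' @return Character vector of written figure paths, invisibly.
#' @export
report_run <- function(run, out_dir = NULL, pairs_to_plot = NULL) {
  if (inherits(run, "pipeline_run")) {
    master <- run$master
    run_dir <- run$out_dir
  } else {
    run_dir <- run
    mt <- file.path(run_dir, "master_table.tsv")
    stop_if(!file.exists(mt), "master table not found in ", run_dir)
    master <- read_dtsv(mt)
  }
  out_dir <- out_dir %||% file.path(run_dir, "figures")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  if (!all(is.na(master$n_outliers_high))) {
    d <- master[!is.na(master$n_outliers_high), ]
    gg <- ggplot2::ggplot(d, ggplot2::aes(
      x = log10(pmax(distance_km, 0.05)),
      y = log10(pmax(n_outliers_high, 0.5)),
      shape = adjacency)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_shape_manual(values = c(adjacent = 1, separated = 16)) +
      ggplot2::labs(x = "log10 distance (km)",
                    y = "log10 number of high outliers") +
      ggplot2::theme_classic()
    if (sum(d$adjacency == "separated") > 2)
      gg <- gg + ggplot2::geom_smooth(
        data = d[d$adjacency == "separated", ],
        method = "lm", formula = y ~ x, se = FALSE, colour = "grey40")
    p <- file.path(out_dir, "outliers_vs_distance.png")
    ggplot2::ggsave(p, gg, width = 5, height = 4, dpi = 150)
    paths <- c(paths, p)
  } else message("divergence outputs missing; skipping outlier figure")

  if (inherits(run, "pipeline_run") && !is.null(run$divergence)) {
    if (is.null(pairs_to_plot)) {
      ord <- order(master$distance_km)
      pairs_to_plot <- master$pair[unique(c(ord[1], ord[ceiling(length(ord) / 2)],
                                            ord[length(ord)]))]
    }
    p <- file.path(out_dir, "fst_distributions.png")
    grDevices::png(p, width = 450 * length(pairs_to_plot), height = 420,
                   res = 100)
    op <- graphics::par(mfrow = c(1, length(pairs_to_plot)))
    for (pid in pairs_to_plot) {
      fit <- run$divergence[[pid]]
      if (is.null(fit)) next
      xs <- fit$alpha_point
      graphics::hist(xs, breaks = 30, freq = FALSE,
                     main = pid, xlab = "logit F_ST")
      mu_hat <- mean(fit$mu_samples)
      sd_hat <- sqrt(mean(1 / fit$tau_samples))
      curve_x <- seq(min(xs) - 1, max(xs) + 1, length.out = 200)
      graphics::lines(curve_x, stats::dnorm(curve_x, mu_hat, sd_hat),
                      lty = 2)
      graphics::abline(v = fit$predictive_q["q_high"], lwd = 2)
    }
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, p)
  } else message("per-pair fits unavailable; skipping distribution panels")

  if (!all(is.na(master$p_zero_flow))) {
    d <- master[!is.na(master$p_zero_flow), ]
    gg <- ggplot2::ggplot(d, ggplot2::aes(x = distance_km, y = mig_estimate,
                                          shape = adjacency)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_shape_manual(values = c(adjacent = 1, separated = 16)) +
      ggplot2::labs(x = "distance (km)", y = "estimated 4Nm",
                    caption = "point labels: P(zero gene flow)") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", p_zero_flow)),
                         vjust = -0.8, size = 2.6) +
      ggplot2::theme_classic()
    p <- file.path(out_dir, "gene_flow_vs_distance.png")
    ggplot2::ggsave(p, gg, width = 5, height = 4, dpi = 150)
    paths <- c(paths, p)
  } else message("abc outputs missing; skipping gene-flow figure")

  invisible(paths)
}

#' Read a pipeline configuration from YAML
#'
#' Builds a [run_config()] from a YAML (or JSON) file.  Recognized
#' top-level keys are the arguments of `run_config()` (`seed`,
#' `stages`, `reads`, `freqs`, `divergence`, `ld`, `abc`, `clines`)
#' plus `landscape`, a block of [landscape_config()] arguments.  Keys
#' omitted from a block keep the package defaults, so a minimal file
#' can set only what it changes.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  y <- yaml::read_yaml(path)
  stop_if(!is.list(y), "config must be a YAML mapping")
  known <- c("seed", "stages", "landscape", "reads", "freqs", "divergence",
             "ld", "abc", "clines")
  unknown <- setdiff(names(y), known)
  stop_if(length(unknown) > 0L,
          "unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- run_config()
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  if (!is.null(y$landscape))
    args$landscape <- do.call(landscape_config, y$landscape)
  for (blk in c("reads", "freqs", "divergence", "ld", "abc", "clines"))
    if (!is.null(y[[blk]]))
      args[[blk]] <- utils::modifyList(defaults[[blk]], y[[blk]])
  do.call(run_config, args)
}
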