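# Forward Wright-Fisher landscape simulator.  Generates the geographic
# mosaic the analysis assumes: populations on two host plants, adjacent
# or separated, distance-decaying gene flow with a hard cutoff, and four
# locus classes (neutral, host-selected, adjacency-specific,
# climate-clinal).  Loci evolve independently (free recombination).

#' Landscape simulation configuration
#'
#' Defaults emulate the structure of the study design the package
#' targets: 8 populations up to ~25 km apart, two host classes, two
#' adjacent pairs in direct contact, 20 sampled individuals per
#' population, gene flow decaying with distance and reaching exactly
#' zero beyond `cutoff_km`, and a majority-neutral genome with small
#' host-selected, adjacency-specific and climate-clinal fractions.
#'
#' @param n_pops Number of populations.
#' @param coords Matrix/data.frame of planar coordinates in km
#'   (`n_pops` x 2), or `NULL` for the default mosaic layout.
#' @param hosts Character vector of host classes (`"Adenostoma"` /
#'   `"Ceanothus"`), or `NULL` to alternate.
#' @param adjacency_pairs 2-column matrix/data.frame of population index
#'   pairs in direct contact, or `NULL` for the default two contact
#'   zones.
#' @param n_loci Number of biallelic SNP loci.
#' @param locus_class_fractions Named numeric summing to 1 over
#'   `neutral, host_selected, adjacency_specific, climate_clinal`.
#' @param n_generations Forward generations of migration/selection/drift.
#' @param pop_size Diploid N per deme.
#' @param m0 Migration proportion at distance 0 (per generation).
#' @param delta_km Exponential decay scale of the migration kernel (km).
#' @param cutoff_km Distance beyond which migration is exactly zero (km).
#' @param s_host Selection coefficient scale on host-selected loci (sign
#'   set by host class).  Each selected locus draws an effect-size
#'   multiplier in Uniform(0.25, 1), so class effects span a range of
#'   strengths.
#' @param s_adj Divergent push scale applied to adjacency-specific loci
#'   in the two members of an adjacent pair (opposite directions).  Each
#'   contact zone maintains its own subset of adjacency loci, with
#'   effect multipliers in Uniform(0.6, 1): divergence maintained
#'   against contact-zone gene flow requires selection stronger than
#'   the migration rate.
#' @param cline_slope Per-generation pull scale of climate-clinal loci,
#'   multiplied by the standardized climate covariate of each deme and
#'   the per-locus effect multiplier.
#' @param covariates Data frame of per-population covariates with
#'   columns `climPC1, climPC2, longitude`, or `NULL` to derive them
#'   from the coordinates (climPC1 tracks x, climPC2 tracks y).
#' @param n_sampled Individuals sampled per population (scalar or
#'   vector).
#' @param ancestral_range Range of the uniform ancestral allele
#'   frequency distribution.
#' @param seed Integer seed.
#' @return A validated object of class `landscape_config`.
#' @export
landscape_config <- function(n_pops = 8L,
                             coords = NULL,
                             hosts = NULL,
                             adjacency_pairs = NULL,
                             n_loci = 2000L,
                             locus_class_fractions = c(neutral = 0.94,
                                                       host_selected = 0.02,
                                                       adjacency_specific = 0.02,
                                                       climate_clinal = 0.02),
                             n_generations = 60L,
                             pop_size = 100L,
                             m0 = 0.12,
                             delta_km = 3,
                             cutoff_km = 12,
                             s_host = 0.2,
                             s_adj = 0.7,
                             cline_slope = 0.12,
                             covariates = NULL,
                             n_sampled = 20L,
                             ancestral_range = c(0.05, 0.95),
                             seed = 1L) {
  if (is.null(coords)) {
    stopifnot(n_pops == 8L)
    coords <- cbind(x_km = c(0, 0.3, 4, 4.3, 9, 14, 19, 24),
                    y_km = c(0, 0,   1, 1,   3, 5,  2,  6))
  }
  coords <- as.matrix(coords)
  stop_if(nrow(coords) != n_pops || ncol(coords) != 2L,
          "coords must be n_pops x 2")
  stop_if(!all(is.finite(coords)), "coordinates must be finite")
  if (is.null(hosts))
    hosts <- rep(c("Adenostoma", "Ceanothus"), length.out = n_pops)
  stop_if(!all(hosts %in% c("Adenostoma", "Ceanothus")),
          "hosts must be 'Adenostoma' or 'Ceanothus'")
  if (is.null(adjacency_pairs)) adjacency_pairs <- rbind(c(1L, 2L), c(3L, 4L))
  adjacency_pairs <- matrix(as.integer(as.matrix(adjacency_pairs)), ncol = 2L)
  frac <- locus_class_fractions
  need <- c("neutral", "host_selected", "adjacency_specific", "climate_clinal")
  stop_if(!setequal(names(frac), need), "locus_class_fractions must name ",
          paste(need, collapse = ", "))
  frac <- frac[need]
  stop_if(abs(sum(frac) - 1) > 1e-8, "locus class fractions must sum to 1")
  stop_if(m0 < 0 || m0 > 0.5, "m0 must be in [0, 0.5]")
  stop_if(cutoff_km <= 0, "cutoff_km must be positive")
  stop_if(pop_size < 2L, "pop_size must be at least 2")
  stop_if(n_generations < 0L, "n_generations must be non-negative")
  n_sampled <- rep_len(as.integer(n_sampled), n_pops)
  if (is.null(covariates)) {
    # climate tracks geography without duplicating it: the first axis
    # follows the main spatial gradient, the second carries
    # deterministic local (micro-relief) variability independent of the
    # planar position, so the three covariates are never collinear
    z <- function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    relief <- sin(7 * seq_len(n_pops)) *
      max(stats::sd(coords[, 1]), stats::sd(coords[, 2]), 1) / 2
    covariates <- data.frame(
      climPC1 = z(0.8 * coords[, 1] + 0.6 * coords[, 2]),
      climPC2 = z(0.8 * coords[, 2] - 0.6 * coords[, 1] + relief),
      longitude = coords[, 1])
  }
  stop_if(!all(c("climPC1", "climPC2", "longitude") %in% names(covariates)),
          "covariates need columns climPC1, climPC2, longitude")
  stop_if(!all(is.finite(as.matrix(covariates))),
          "covariates must be finite")
  structure(list(n_pops = as.integer(n_pops), coords = coords,
                 hosts = hosts, adjacency_pairs = adjacency_pairs,
                 n_loci = as.integer(n_loci),
                 locus_class_fractions = frac,
                 n_generations = as.integer(n_generations),
                 pop_size = as.integer(pop_size),
                 m0 = m0, delta_km = delta_km, cutoff_km = cutoff_km,
                 s_host = s_host, s_adj = s_adj, cline_slope = cline_slope,
                 covariates = covariates, n_sampled = n_sampled,
                 ancestral_range = ancestral_range,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Distance-decaying migration kernel
#'
#' `m(d) = m0 * exp(-d / delta_km)` for `d <= cutoff_km`, exactly zero
#' beyond the cutoff.  Monotone non-increasing in distance.
#'
#' @param d Distances (km).
#' @param m0 Migration proportion at distance zero.
#' @param delta_km Decay scale (km).
#' @param cutoff_km Hard cutoff (km).
#' @return Per-generation migration proportions.
#' @export
migration_kernel <- function(d, m0, delta_km, cutoff_km) {
  stop_if(any(d < 0), "distances must be non-negative")
  ifelse(d <= cutoff_km, m0 * exp(-d / delta_km), 0)
}

# population x population per-generation migration matrix (off-diagonal
# entries only); errors if any row's immigrant mass would exceed 1
migration_matrix <- function(config) {
  d <- as.matrix(stats::dist(config$coords))
  M <- migration_kernel(d, config$m0, config$delta_km, config$cutoff_km)
  diag(M) <- 0
  rs <- rowSums(M)
  stop_if(any(rs > 1),
          "migration kernel gives off-diagonal row mass > 1; lower m0")
  M
}

#' Simulate a landscape of diverging populations
#'
#' Forward-in-time Wright-Fisher simulation, one allele frequency per
#' locus per deme.  Each generation applies (1) migration with the
#' distance-decaying kernel, (2) class-specific selection, (3) binomial
#' drift with `2 * pop_size` draws.  Loci are independent.  Selection
#' (every push scaled by the locus's effect multiplier, see
#' [landscape_config()]): host-selected loci are pushed up on
#' Adenostoma and down on Ceanothus by `s_host * p(1-p)`; each contact
#' zone's own subset of adjacency-specific loci is pushed in opposite
#' directions in the two members of that adjacent pair by `s_adj *
#' p(1-p)`; climate-clinal loci are pulled by `cline_slope * climPC1 *
#' p(1-p)`.  Frequencies are clamped to [0, 1].  Sampled genotypes are
#' `Binomial(2, p)` per individual.
#'
#' @param config A [landscape_config()].
#' @return An object of class `landscape_truth`: true frequencies
#'   (`pops x loci`), locus classes, per-locus effect multipliers and
#'   contact-zone assignments, migration matrix, sampled genotypes,
#'   individual/population bookkeeping, population and pair tables.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  n_pops <- config$n_pops
  L <- config$n_loci
  # deterministic class assignment in blocks (loci are exchangeable)
  n_class <- round(config$locus_class_fractions * L)
  n_class[1] <- L - sum(n_class[-1])
  locus_class <- rep(names(n_class), times = n_class)
  is_host <- locus_class == "host_selected"
  is_adj <- locus_class == "adjacency_specific"
  is_clin <- locus_class == "climate_clinal"

  # per-locus effect-size multipliers: selected loci span a range of
  # strengths rather than sharing one coefficient, so the number of
  # detectably diverged loci grows smoothly with the selective contrast.
  # Adjacency loci draw from a stronger range: divergence maintained in
  # the face of contact-zone gene flow requires selection that beats the
  # migration rate, so weaker effects would never be observable there.
  eff <- stats::runif(L, 0.25, 1)
  eff[is_adj] <- stats::runif(sum(is_adj), 0.6, 1)
  # each contact zone maintains its own set of adjacency-specific loci
  n_zone <- nrow(config$adjacency_pairs)
  adj_zone <- integer(L)
  adj_zone[is_adj] <- rep_len(seq_len(n_zone), sum(is_adj))

  M <- migration_matrix(config)
  Mfull <- M
  diag(Mfull) <- 1 - rowSums(M)

  host_dir <- ifelse(config$hosts == "Adenostoma", 1, -1)
  clim <- config$covariates$climPC1

  p_anc <- stats::runif(L, config$ancestral_range[1], config$ancestral_range[2])
  P <- matrix(rep(p_anc, each = n_pops), n_pops, L)
  two_n <- 2L * config$pop_size
  for (g in seq_len(config$n_generations)) {
    P <- Mfull %*% P
    pq <- P * (1 - P)
    if (any(is_host))
      P[, is_host] <- P[, is_host] + config$s_host * host_dir *
        sweep(pq[, is_host, drop = FALSE], 2L, eff[is_host], `*`)
    for (r in seq_len(n_zone)) {
      lr <- which(adj_zone == r)
      if (!length(lr)) next
      a <- config$adjacency_pairs[r, 1]
      b <- config$adjacency_pairs[r, 2]
      P[a, lr] <- P[a, lr] + config$s_adj * eff[lr] * pq[a, lr]
      P[b, lr] <- P[b, lr] - config$s_adj * eff[lr] * pq[b, lr]
    }
    if (any(is_clin))
      P[, is_clin] <- P[, is_clin] + config$cline_slope * clim *
        sweep(pq[, is_clin, drop = FALSE], 2L, eff[is_clin], `*`)
    P[P < 0] <- 0
    P[P > 1] <- 1
    P <- matrix(stats::rbinom(n_pops * L, two_n, P) / two_n, n_pops, L)
  }

  pop_labels <- sprintf("P%d", seq_len(n_pops))
  # loci live on synthetic contigs, two SNPs per contig
  contig <- sprintf("ctg%05d", ceiling(seq_len(L) / 2))
  pos <- ifelse(seq_len(L) %% 2 == 1L, 25L, 60L)
  loci <- paste0(contig, ":", pos)

  individuals <- unlist(lapply(seq_len(n_pops), function(i)
    sprintf("%s_i%02d", pop_labels[i], seq_len(config$n_sampled[i]))))
  pop_of_ind <- rep(pop_labels, times = config$n_sampled)
  names(pop_of_ind) <- individuals
  G <- matrix(stats::rbinom(length(individuals) * L, 2L,
                            P[rep(seq_len(n_pops), times = config$n_sampled), ]),
              length(individuals), L,
              dimnames = list(individuals, loci))

  pop_table <- data.frame(population = pop_labels, host = config$hosts,
                          x_km = config$coords[, 1], y_km = config$coords[, 2],
                          n_sampled = config$n_sampled,
                          stringsAsFactors = FALSE)
  adj_df <- data.frame(pop_a = pop_labels[config$adjacency_pairs[, 1]],
                       pop_b = pop_labels[config$adjacency_pairs[, 2]],
                       stringsAsFactors = FALSE)
  pair_table <- make_pair_table(pop_table, config$coords, "planar", adj_df)

  dimnames(P) <- list(pop_labels, loci)
  structure(list(config = config, true_freqs = P, locus_class = locus_class,
                 effect_size = eff, adj_zone = adj_zone,
                 migration_matrix = M, genotypes = G,
                 individuals = individuals, populations = pop_of_ind,
                 pop_table = pop_table, pair_table = pair_table,
                 covariates = cbind(population = pop_labels,
                                    config$covariates)),
            class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat("landscape_truth:", nrow(x$true_freqs), "populations x",
      ncol(x$true_freqs), "loci;",
      length(x$individuals), "sampled individuals\n")
  print(table(x$locus_class))
  invisible(x)
}

#' Simulate low-coverage sequencing reads
#'
#' Per individual and locus, total depth is `Poisson(mean_coverage)` and
#' non-reference reads are `Binomial(depth, e_g)` with `e_0 =
#' error_rate`, `e_1 = 0.5`, `e_2 = 1 - error_rate` for genotype `g`.
#' Default coverage matches the study design the simulator emulates
#' (~0.77x per individual).
#'
#' @param truth A `landscape_truth`, or a genotype dosage matrix
#'   (individuals x loci) with dimnames.
#' @param mean_coverage Mean reads per individual per locus.
#' @param error_rate Sequencing error probability, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param populations Individual -> population map (taken from `truth`
#'   when it is a `landscape_truth`).
#' @return A [read_count_matrix()] with populations assigned.
#' @export
simulate_reads <- function(truth, mean_coverage = 0.77, error_rate = 0.005,
                           seed = 1L, populations = NULL) {
  stop_if(mean_coverage < 0, "mean coverage must be non-negative")
  stop_if(error_rate < 0 || error_rate >= 0.5,
          "error_rate must be in [0, 0.5)")
  if (inherits(truth, "landscape_truth")) {
    G <- truth$genotypes
    populations <- truth$populations
  } else {
    G <- as.matrix(truth)
  }
  set.seed(seed)
  n <- matrix(stats::rpois(length(G), mean_coverage), nrow(G), ncol(G))
  e_g <- c(error_rate, 0.5, 1 - error_rate)[G + 1L]
  a <- matrix(stats::rbinom(length(G), n, e_g), nrow(G), ncol(G))
  read_count_matrix(n, a, individuals = rownames(G), loci = colnames(G),
                    populations = populations)
}

#' Simulate no-choice mating trials
#'
#' Bernoulli mating outcomes for within- and between-population pairings
#' of one or more population pairs.
#'
#' @param p_within Probability of copulation in within-population
#'   pairings.
#' @param p_between Probability in between-population pairings (scalar
#'   or one value per pair).
#' @param n_trials_per_cell Trials per pair per pairing type.
#' @param seed Integer seed.
#' @param pairs Character vector of pair labels (default one generic
#'   pair).
#' @return Data frame with columns `pair, type, n_trials, n_matings`.
#' @export
simulate_mating_trials <- function(p_within, p_between, n_trials_per_cell,
                                   seed = 1L, pairs = "pair1") {
  stop_if(any(c(p_within, p_between) < 0 | c(p_within, p_between) > 1),
          "mating probabilities must be in [0, 1]")
  set.seed(seed)
  p_between <- rep_len(p_between, length(pairs))
  out <- lapply(seq_along(pairs), function(i) {
    data.frame(pair = pairs[i], type = c("within", "between"),
               n_trials = n_trials_per_cell,
               n_matings = c(stats::rbinom(1, n_trials_per_cell, p_within),
                             stats::rbinom(1, n_trials_per_cell, p_between[i])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write simulator outputs to disk
#'
#' Emits the read counts (VCF and TSV), population metadata, adjacency
#' list, and ground-truth tables (true frequencies, locus classes),
#' all round-trip readable.
#'
#' @param truth A `landscape_truth`.
#' @param counts A [read_count_matrix()] from [simulate_reads()].
#' @param out_dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_landscape <- function(truth, counts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(out_dir, "counts.vcf"),
    counts_tsv = file.path(out_dir, "counts.tsv"),
    populations = file.path(out_dir, "populations.tsv"),
    adjacency = file.path(out_dir, "adjacency.tsv"),
    individuals = file.path(out_dir, "individuals.tsv"),
    true_freqs = file.path(out_dir, "true_freqs.tsv"),
    locus_classes = file.path(out_dir, "locus_classes.tsv"))
  write_counts_vcf(counts, paths["vcf"])
  write_counts_tsv(counts, paths["counts_tsv"])
  write_dtsv(truth$pop_table, paths["populations"])
  ap <- truth$config$adjacency_pairs
  write_dtsv(data.frame(pop_a = truth$pop_table$population[ap[, 1]],
                        pop_b = truth$pop_table$population[ap[, 2]]),
             paths["adjacency"])
  write_dtsv(data.frame(individual = truth$individuals,
                        population = unname(truth$populations)),
             paths["individuals"])
  tf <- data.frame(locus = colnames(truth$true_freqs),
                   t(truth$true_freqs), check.names = FALSE)
  write_dtsv(tf, paths["true_freqs"])
  write_dtsv(data.frame(locus = colnames(truth$true_freqs),
                        class = truth$locus_class),
             paths["locus_classes"])
  invisible(paths)
}
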