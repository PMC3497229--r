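# Burrows' composite measure of Hardy-Weinberg and linkage
# disequilibrium (Delta): a genotype-based joint measure of within- and
# between-locus disequilibrium that needs neither phase nor HWE.  It is
# a population-level quantity, so surveys are computed per population.

#' Burrows' composite disequilibrium for one locus pair
#'
#' Moment estimator from unphased dosages:
#' `Delta = (1/(2n)) * sum_k gA_k * gB_k - 2 * pA * pB` with
#' `p = sum(g) / (2n)`.  No small-sample correction is applied (plain
#' moment estimator).  Individuals missing (NA) at either locus are
#' dropped pairwise.
#'
#' @param genotypes_a,genotypes_b Dosage vectors in {0, 1, 2}, same
#'   individuals.
#' @return List `delta`, `n` (individuals used).
#' @export
burrows_delta <- function(genotypes_a, genotypes_b) {
  stop_if(length(genotypes_a) != length(genotypes_b),
          "dosage vectors must cover the same individuals")
  ok <- !is.na(genotypes_a) & !is.na(genotypes_b)
  ga <- genotypes_a[ok]
  gb <- genotypes_b[ok]
  n <- length(ga)
  stop_if(n == 0L, "no individuals left after missing-data removal")
  stop_if(!all(ga %in% 0:2) || !all(gb %in% 0:2),
          "dosages must be 0, 1 or 2")
  pa <- sum(ga) / (2 * n)
  pb <- sum(gb) / (2 * n)
  list(delta = sum(ga * gb) / (2 * n) - 2 * pa * pb, n = n)
}

#' Survey composite LD across locus pairs within a population
#'
#' Computes Burrows' Delta for all locus pairs or a seed-deterministic
#' uniform subsample, and summarizes the values overall and stratified
#' by whether the two loci share a contig.
#'
#' @param genotypes Dosage matrix (individuals x loci), e.g. posterior
#'   modal genotypes from [modal_genotype()]; column names are locus
#'   IDs.
#' @param pairs `"all"` or an integer number of random pairs (clamped
#'   with a warning if it exceeds the pair universe).
#' @param contig_map Named character vector locus -> contig; by default
#'   parsed from `"contig:pos"` locus names.
#' @param seed Integer seed for the subsample.
#' @param keep_pairs Return the per-pair table as well?
#' @return List of class `delta_summary`: `mean_delta, mean_abs_delta,
#'   within_contig_mean, within_contig_mean_abs, between_contig_mean,
#'   between_contig_mean_abs, n_pairs_evaluated, n_within_contig`, and
#'   optionally `pairs`.
#' @export
delta_survey <- function(genotypes, pairs = 1e5, contig_map = NULL,
                         seed = 1L, keep_pairs = FALSE) {
  genotypes <- as.matrix(genotypes)
  L <- ncol(genotypes)
  stop_if(L < 2L, "need at least two loci")
  loci <- colnames(genotypes) %||% sprintf("L%d", seq_len(L))
  if (is.null(contig_map)) {
    contig_map <- sub(":.*$", "", loci)
    names(contig_map) <- loci
  }
  M <- L * (L - 1) / 2
  idx <- utils::combn(L, 2L)
  if (!identical(pairs, "all")) {
    n_req <- as.numeric(pairs)
    if (n_req > M) {
      warning("requested ", n_req, " pairs but only ", M,
              " exist; using all")
      n_req <- M
    }
    set.seed(seed)
    idx <- idx[, sample.int(M, n_req), drop = FALSE]
  }
  i <- idx[1, ]; j <- idx[2, ]
  n <- nrow(genotypes)
  p <- colSums(genotypes) / (2 * n)
  cross <- colSums(genotypes[, i, drop = FALSE] *
                     genotypes[, j, drop = FALSE]) / (2 * n)
  delta <- cross - 2 * p[i] * p[j]
  within <- contig_map[loci[i]] == contig_map[loci[j]]
  res <- structure(list(
    mean_delta = mean(delta),
    mean_abs_delta = mean(abs(delta)),
    within_contig_mean = if (any(within)) mean(delta[within]) else NA_real_,
    within_contig_mean_abs = if (any(within)) mean(abs(delta[within])) else NA_real_,
    between_contig_mean = if (any(!within)) mean(delta[!within]) else NA_real_,
    between_contig_mean_abs = if (any(!within)) mean(abs(delta[!within])) else NA_real_,
    n_pairs_evaluated = length(delta),
    n_within_contig = sum(within)), class = "delta_summary")
  if (keep_pairs)
    res$pairs <- data.frame(locus_a = loci[i], locus_b = loci[j],
                            delta = delta, within_contig = within,
                            stringsAsFactors = FALSE)
  res
}

#' @export
print.delta_summary <- function(x, ...) {
  cat(sprintf("delta_summary: %d pairs, mean %.5f, mean|.| %.5f\n",
              x$n_pairs_evaluated, x$mean_delta, x$mean_abs_delta))
  cat(sprintf("  within-contig (%d pairs) mean|.| %.5f; between %.5f\n",
              x$n_within_contig, x$within_contig_mean_abs,
              x$between_contig_mean_abs))
  invisible(x)
}
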