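# Matrix-correlation tests, ordination, clines, and the behavioural /
# phenotypic indices.

as_dist_matrix <- function(m, arg = "matrix") {
  m <- as.matrix(m)
  stop_if(nrow(m) != ncol(m), arg, " must be square")
  stop_if(max(abs(m - t(m))) > 1e-12, arg, " must be symmetric")
  stop_if(any(abs(diag(m)) > 1e-12), arg, " must have a zero diagonal")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- sprintf("u%d", seq_len(nrow(m)))
  m
}

align_labels <- function(X, Y, argY) {
  stop_if(!setequal(rownames(X), rownames(Y)),
          "matrix labels do not match (", argY, ")")
  Y[rownames(X), rownames(X)]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; the null distribution is
#' built by simultaneous row/column permutation of `Y`.  The p-value is
#' `(1 + #{permuted r at least as extreme}) / (1 + n_perm)`, so it
#' respects the discrete floor `1/(n_perm + 1)`.
#'
#' @param X,Y Symmetric matrices with matching labels, zero diagonal.
#' @param n_perm Number of permutations (ignored when `exact = TRUE`).
#' @param tail `"two_sided"` (on |r|), `"greater"` or `"less"`.
#' @param seed Integer seed or `NULL`.
#' @param exact Enumerate all `n!` row/column permutations instead of
#'   sampling (allowed for `n <= 7`); the p-value is then the exact
#'   permutation p `#{r_perm at least as extreme} / n!` (the identity
#'   permutation counts, so `p >= 1/n!`).
#' @return List of class `mantel_result`: `r, p, n_perm, tail, seed`.
#' @export
mantel <- function(X, Y, n_perm = 999L, tail = c("two_sided", "greater", "less"),
                   seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  X <- as_dist_matrix(X, "X")
  Y <- align_labels(X, as_dist_matrix(Y, "Y"), "Y")
  n <- nrow(X)
  stop_if(n < 4L, "need at least 4 units")
  x <- lower_tri(X)
  stop_if(stats::sd(x) == 0 || stats::sd(lower_tri(Y)) == 0,
          "constant distance triangle: correlation undefined")
  r_obs <- stats::cor(x, lower_tri(Y))
  if (exact) {
    stop_if(n > 7L, "exact enumeration supported for n <= 7 only")
    pm <- all_perms(n)
    r_all <- apply(pm, 1L, function(idx) stats::cor(x, lower_tri(Y[idx, idx])))
    hits <- switch(tail,
                   two_sided = sum(abs(r_all) >= abs(r_obs) - 1e-12),
                   greater = sum(r_all >= r_obs - 1e-12),
                   less = sum(r_all <= r_obs + 1e-12))
    return(structure(list(r = r_obs, p = hits / nrow(pm),
                          n_perm = nrow(pm), tail = tail, seed = NULL),
                     class = "mantel_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    stats::cor(x, lower_tri(Y[idx, idx]))
  }, numeric(1))
  p <- perm_pvalue(r_obs, r_perm, tail)
  structure(list(r = r_obs, p = p, n_perm = n_perm, tail = tail,
                 seed = seed), class = "mantel_result")
}

# all permutations of 1..n as rows (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

perm_pvalue <- function(r_obs, r_perm, tail) {
  hits <- switch(tail,
                 two_sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12),
                 greater = sum(r_perm >= r_obs - 1e-12),
                 less = sum(r_perm <= r_obs + 1e-12))
  (1 + hits) / (1 + length(r_perm))
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$tail, x$n_perm))
  invisible(x)
}

#' Partial Mantel test controlling for a third matrix
#'
#' Correlates the residuals of `X` and `Y` after regressing each
#' triangle on `Z`'s; the null permutes the row/column structure of
#' `Y`'s residual matrix.
#'
#' @inheritParams mantel
#' @param Z Covariate distance matrix.
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(X, Y, Z, n_perm = 999L,
                           tail = c("two_sided", "greater", "less"),
                           seed = NULL) {
  tail <- match.arg(tail)
  X <- as_dist_matrix(X, "X")
  Y <- align_labels(X, as_dist_matrix(Y, "Y"), "Y")
  Z <- align_labels(X, as_dist_matrix(Z, "Z"), "Z")
  n <- nrow(X)
  stop_if(n < 4L, "need at least 4 units")
  z <- lower_tri(Z)
  resid_tri <- function(v) if (stats::sd(z) == 0) v - mean(v)
                           else stats::resid(stats::lm(v ~ z))
  rx <- resid_tri(lower_tri(X))
  ry <- resid_tri(lower_tri(Y))
  # a triangle fully explained by the covariate leaves numerically-zero
  # residuals: the partial correlation is 0 by convention
  tol_x <- 1e-10 * stats::sd(lower_tri(X))
  tol_y <- 1e-10 * stats::sd(lower_tri(Y))
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y)
    return(structure(list(r = 0, p = 1, n_perm = n_perm, tail = tail,
                          seed = seed), class = "mantel_result"))
  ry_mat <- matrix(0, n, n, dimnames = dimnames(Y))
  ry_mat[lower.tri(ry_mat)] <- ry
  ry_mat <- ry_mat + t(ry_mat)
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(rx, lower_tri(ry_mat))
  r_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    stats::cor(rx, lower_tri(ry_mat[idx, idx]))
  }, numeric(1))
  structure(list(r = r_obs, p = perm_pvalue(r_obs, r_perm, tail),
                 n_perm = n_perm, tail = tail, seed = seed),
            class = "mantel_result")
}

#' PCA of genotype-state posterior probabilities
#'
#' Column-centred principal components of the individuals x (loci x
#' states) posterior-probability matrix; no scaling beyond centring
#' (the inputs are probabilities on a common scale).  `two_state` uses
#' P(het) and P(hom alt) per locus; `three_state` uses all three.
#' Component signs are fixed by making each component's
#' largest-magnitude loading positive.
#'
#' @param gpost A `genotype_posterior`.
#' @param mode `"two_state"` or `"three_state"`.
#' @return List of class `genotype_pca`: `scores` (individuals x PCs),
#'   `explained` (proportion of variance, or `NA` with
#'   `zero_variance = TRUE` when there is no variation), `loadings`.
#' @export
genotype_pca <- function(gpost, mode = c("two_state", "three_state")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gpost, "genotype_posterior"))
  p <- gpost$probs
  stop_if(dim(p)[1] < 2L || dim(p)[2] < 2L,
          "need >= 2 individuals and >= 2 loci")
  X <- if (mode == "two_state") cbind(p[, , 2L], p[, , 3L])
       else cbind(p[, , 1L], p[, , 2L], p[, , 3L])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    k <- min(dim(X)) - 1L
    return(structure(list(
      scores = matrix(0, nrow(X), max(k, 1L),
                      dimnames = list(rownames(p), NULL)),
      explained = NA_real_, zero_variance = TRUE, loadings = NULL),
      class = "genotype_pca"))
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    v <- fit$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2L, flip, `*`)
  rownames(scores) <- gpost$individuals
  structure(list(scores = scores,
                 explained = fit$sdev^2 / sum(fit$sdev^2),
                 zero_variance = FALSE,
                 loadings = sweep(fit$rotation, 2L, flip, `*`)),
            class = "genotype_pca")
}

#' Allele-frequency cline regression
#'
#' Ordinary least squares of per-population allele frequencies at one
#' locus on standardized (z-scored) climatic and spatial covariates,
#' with per-coefficient t-test p-values and partial residuals for
#' plotting.
#'
#' @param freq Per-population allele frequencies (point estimates).
#' @param covariates Data frame with columns `climPC1, climPC2,
#'   longitude` (one row per population, same order as `freq`).
#' @param locus Optional locus label.
#' @return List of class `cline_fit`: `locus`, `coefficients` (data
#'   frame: term, estimate, se, t, p), `partial_residuals` (data frame
#'   with the standardized covariates and per-term partial residuals).
#' @export
cline_regression <- function(freq, covariates, locus = NULL) {
  terms <- c("climPC1", "climPC2", "longitude")
  stop_if(!all(terms %in% names(covariates)),
          "covariates need columns ", paste(terms, collapse = ", "))
  n <- length(freq)
  stop_if(n != nrow(covariates), "freq and covariates lengths differ")
  stop_if(n <= length(terms) + 1L,
          "need more populations than covariates + 1")
  sds <- vapply(covariates[terms], stats::sd, numeric(1))
  stop_if(any(sds == 0),
          "rank deficiency: constant covariate column(s): ",
          paste(terms[sds == 0], collapse = ", "))
  Z <- as.data.frame(scale(covariates[terms]))
  qr_rank <- qr(cbind(1, as.matrix(Z)))$rank
  if (qr_rank < length(terms) + 1L) {
    cm <- abs(stats::cor(as.matrix(Z)))
    diag(cm) <- 0
    bad <- terms[apply(cm, 1L, max) == max(cm)]
    stop("rank deficiency: collinear covariate column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (stats::sd(freq) == 0) {
    coefs <- data.frame(term = terms, estimate = 0, se = 0, t = 0, p = 1,
                        stringsAsFactors = FALSE)
    pr <- cbind(Z, matrix(0, n, length(terms),
                          dimnames = list(NULL, paste0("pr_", terms))))
    return(structure(list(locus = locus, coefficients = coefs,
                          partial_residuals = pr, r_squared = 0),
                     class = "cline_fit"))
  }
  df <- cbind(freq = freq, Z)
  fit <- stats::lm(freq ~ climPC1 + climPC2 + longitude, data = df)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = terms,
                      estimate = sm[terms, 1], se = sm[terms, 2],
                      t = sm[terms, 3], p = sm[terms, 4],
                      stringsAsFactors = FALSE, row.names = NULL)
  res <- stats::resid(fit)
  pr <- cbind(Z, vapply(terms, function(tm)
    res + stats::coef(fit)[tm] * Z[[tm]], numeric(n)))
  names(pr)[length(terms) + seq_along(terms)] <- paste0("pr_", terms)
  structure(list(locus = locus, coefficients = coefs,
                 partial_residuals = pr,
                 r_squared = summary(fit)$r.squared),
            class = "cline_fit")
}

#' Sexual isolation index
#'
#' `1 - (% between-population mating / % within-population mating)`.
#' 0 = random mating, 1 = complete isolation; may be negative and is
#' not clamped.
#'
#' @param pct_within Within-population mating percentage (> 0).
#' @param pct_between Between-population mating percentage.
#' @return The isolation index.
#' @export
isolation_index <- function(pct_within, pct_between) {
  stop_if(any(pct_within <= 0),
          "isolation index undefined: within-population mating is 0")
  1 - pct_between / pct_within
}

#' Host morph-frequency divergence
#'
#' Signed difference in percentage points:
#' `% striped on Adenostoma - % striped on Ceanothus`.
#'
#' @param pct_striped_adenostoma,pct_striped_ceanothus Percentages in
#'   `[0, 100]`.
#' @return Signed difference.
#' @export
morph_divergence <- function(pct_striped_adenostoma, pct_striped_ceanothus) {
  v <- c(pct_striped_adenostoma, pct_striped_ceanothus)
  stop_if(any(v < 0 | v > 100), "percentages must be in [0, 100]")
  pct_striped_adenostoma - pct_striped_ceanothus
}

#' Two-sample t-test (pooled or Welch)
#'
#' Student's pooled-variance test by default (df = n1 + n2 - 2),
#' two-sided.  Degenerate inputs are handled explicitly: zero pooled
#' variance with equal means gives `t = 0, p = 1`; with unequal means
#' the statistic diverges and the result is flagged.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return List `t, df, p, degenerate`.
#' @export
two_sample_ttest <- function(group_a, group_b,
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stop_if(length(group_a) < 2L || length(group_b) < 2L,
          "each group needs >= 2 values")
  n1 <- length(group_a); n2 <- length(group_b)
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t_stat <- (m1 - m2) / se
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       degenerate = FALSE)
}

#' Isolation index from a mating-trial table
#'
#' @param trials Data frame `pair, type, n_trials, n_matings` as
#'   produced by [simulate_mating_trials()].
#' @return Data frame `pair, pct_within, pct_between, isolation`.
#' @export
isolation_from_trials <- function(trials) {
  stopifnot(all(c("pair", "type", "n_trials", "n_matings") %in% names(trials)))
  sp <- split(trials, trials$pair)
  out <- lapply(sp, function(d) {
    w <- d[d$type == "within", ]
    b <- d[d$type == "between", ]
    pw <- 100 * sum(w$n_matings) / sum(w$n_trials)
    pb <- 100 * sum(b$n_matings) / sum(b$n_trials)
    data.frame(pair = d$pair[1], pct_within = pw, pct_between = pb,
               isolation = isolation_index(pw, pb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' PCA of environmental covariates
#'
#' Convenience helper turning a table of raw per-population
#' environmental variables into orthogonal standardized axes usable as
#' cline covariates: z-scores each column, runs a centred PCA, and
#' returns the scores (again z-scored) with deterministic signs.
#'
#' @param env Data frame or matrix of per-population environmental
#'   variables (rows = populations).
#' @param n_axes Number of leading axes to return.
#' @return Data frame of standardized principal-component scores
#'   (`envPC1`, `envPC2`, ...), with the proportion of variance
#'   explained as attribute `"explained"`.
#' @export
covariate_pca <- function(env, n_axes = 2L) {
  env <- as.matrix(env)
  stop_if(!all(is.finite(env)), "environmental covariates must be finite")
  sds <- apply(env, 2L, stats::sd)
  stop_if(any(sds == 0), "constant covariate column(s): ",
          paste(colnames(env)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  n_axes <- min(n_axes, ncol(fit$x))
  flip <- vapply(seq_len(n_axes), function(j) {
    v <- fit$rotation[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  scores <- sweep(fit$x[, seq_len(n_axes), drop = FALSE], 2L, flip, `*`)
  out <- as.data.frame(scale(scores))
  names(out) <- paste0("envPC", seq_len(n_axes))
  attr(out, "explained") <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_axes)]
  out
}
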