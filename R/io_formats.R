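# Reading and writing the on-disk formats: per-sample variant read
# counts (VCF or long TSV), population metadata, pair tables, results.

#' Construct a read-count matrix
#'
#' Container for per-individual, per-locus sequencing depth at biallelic
#' SNPs: total reads and non-reference reads.  Missing data are plain
#' zero coverage, which the downstream Bayesian model treats identically
#' to any other low-coverage cell.
#'
#' @param n_reads Integer matrix, individuals x loci, total read depth.
#' @param alt_reads Integer matrix, same shape, non-reference reads.
#' @param individuals Character vector of individual IDs (rownames).
#' @param loci Character vector of locus IDs, `"contig:pos"` (colnames).
#' @param populations Named character vector mapping individual ->
#'   population label, or `NULL` if not yet assigned.
#' @return An object of class `read_count_matrix`.
#' @export
read_count_matrix <- function(n_reads, alt_reads, individuals = rownames(n_reads),
                              loci = colnames(n_reads), populations = NULL) {
  n_reads <- as.matrix(n_reads)
  alt_reads <- as.matrix(alt_reads)
  stop_if(!all(dim(n_reads) == dim(alt_reads)),
          "n_reads and alt_reads must have identical dimensions")
  stop_if(is.null(individuals) || is.null(loci),
          "individual and locus IDs are required")
  stop_if(anyDuplicated(loci) > 0L, "locus IDs must be unique")
  stop_if(anyDuplicated(individuals) > 0L, "individual IDs must be unique")
  stop_if(any(n_reads < 0) || any(alt_reads < 0),
          "read counts must be non-negative")
  stop_if(any(alt_reads > n_reads),
          "validation error: alt_reads > n_reads at ",
          sum(alt_reads > n_reads), " cell(s)")
  dimnames(n_reads) <- dimnames(alt_reads) <- list(individuals, loci)
  storage.mode(n_reads) <- "integer"
  storage.mode(alt_reads) <- "integer"
  if (!is.null(populations)) {
    stop_if(!all(individuals %in% names(populations)),
            "every individual needs a population assignment")
    populations <- populations[individuals]
  }
  structure(list(n_reads = n_reads, alt_reads = alt_reads,
                 individuals = individuals, loci = loci,
                 populations = populations),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat("read_count_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci\n")
  cat("  mean coverage:", round(mean(x$n_reads), 3), "reads/cell\n")
  if (!is.null(x$populations))
    cat("  populations:", paste(unique(x$populations), collapse = ", "), "\n")
  invisible(x)
}

#' Assign populations to a read-count matrix
#'
#' @param counts A [read_count_matrix()].
#' @param populations Named character vector, individual -> population.
#' @return The updated `read_count_matrix`.
#' @export
set_populations <- function(counts, populations) {
  read_count_matrix(counts$n_reads, counts$alt_reads,
                    counts$individuals, counts$loci, populations)
}

#' Read per-sample variant read counts
#'
#' Accepts either a VCF 4.x file with per-sample `AD` (allele depth) and
#' `DP` fields, or a long-format TSV with columns
#' `individual, locus, n_reads, alt_reads`.  Only biallelic SNP records
#' enter the pipeline; multiallelic records are skipped (default) or
#' raise an error.  Samples with missing depth at a record get zero
#' coverage.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param multiallelic `"skip"` or `"error"`.
#' @return A [read_count_matrix()] (populations unset).
#' @export
read_variant_counts <- function(path, format = c("auto", "vcf", "tsv"),
                                multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  stop_if(!file.exists(path), "file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") read_counts_vcf(path, multiallelic)
  else read_counts_tsv(path)
}

read_counts_vcf <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  stop_if(multiallelic == "error" && any(multi),
          "multiallelic record(s) at ",
          paste(head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 5),
                collapse = ", "))
  keep <- !multi
  stop_if(!any(keep), "no biallelic records in ", path)
  loci <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])
  ad <- vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(vcf, element = "DP")[keep, , drop = FALSE]
  inds <- colnames(ad)
  # AD is "ref,alt"; missing entries ("." or NA) mean zero coverage
  parse_ad <- function(x, which) {
    out <- rep(0L, length(x))
    ok <- !is.na(x) & x != "." & x != ""
    parts <- strsplit(x[ok], ",", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(p[which]))
      if (is.na(v)) 0L else v
    }, integer(1))
    out
  }
  ref_m <- apply(ad, 2, parse_ad, which = 1L)
  alt_m <- apply(ad, 2, parse_ad, which = 2L)
  if (length(loci) == 1L) {
    ref_m <- matrix(ref_m, nrow = 1)
    alt_m <- matrix(alt_m, nrow = 1)
  }
  dp_m <- suppressWarnings(apply(dp, 2, function(x) {
    v <- as.integer(x); v[is.na(v)] <- 0L; v
  }))
  if (length(loci) == 1L) dp_m <- matrix(dp_m, nrow = 1)
  n_m <- ref_m + alt_m
  # prefer DP when AD absent entirely
  use_dp <- n_m == 0L & dp_m > 0L & alt_m == 0L
  n_m[use_dp] <- dp_m[use_dp]
  read_count_matrix(t(n_m), t(alt_m), individuals = inds, loci = loci)
}

read_counts_tsv <- function(path) {
  df <- read_dtsv(path)
  need <- c("individual", "locus", "n_reads", "alt_reads")
  stop_if(!all(need %in% names(df)),
          "parse error: TSV must have columns ", paste(need, collapse = ", "))
  bad <- which(df$alt_reads > df$n_reads)
  stop_if(length(bad) > 0L,
          "validation error: alt_reads > n_reads at data row ", bad[1])
  inds <- unique(df$individual)
  loci <- unique(df$locus)
  n_m <- matrix(0L, length(inds), length(loci), dimnames = list(inds, loci))
  a_m <- n_m
  i <- match(df$individual, inds)
  j <- match(df$locus, loci)
  n_m[cbind(i, j)] <- as.integer(df$n_reads)
  a_m[cbind(i, j)] <- as.integer(df$alt_reads)
  read_count_matrix(n_m, a_m, individuals = inds, loci = loci)
}

#' Write a read-count matrix as long-format TSV
#'
#' @param counts A [read_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(
    individual = rep(counts$individuals, times = length(counts$loci)),
    locus = rep(counts$loci, each = length(counts$individuals)),
    n_reads = as.vector(counts$n_reads),
    alt_reads = as.vector(counts$alt_reads),
    stringsAsFactors = FALSE)
  write_dtsv(df, path)
}

#' Write a read-count matrix as VCF
#'
#' Emits a minimal VCF 4.2 with per-sample `DP:AD` fields (AD as
#' `ref,alt`), REF/ALT fixed to A/T placeholders: the pipeline works on
#' counts of non-reference reads and never interprets the bases.
#'
#' @param counts A [read_count_matrix()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path) {
  loc <- strsplit(counts$loci, ":", fixed = TRUE)
  chrom <- vapply(loc, `[`, "", 1L)
  pos <- vapply(loc, `[`, "", 2L)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=divscape",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", counts$individuals), collapse = "\t"))
  n <- counts$n_reads
  a <- counts$alt_reads
  body <- vapply(seq_along(counts$loci), function(j) {
    cells <- paste0(n[, j], ":", n[, j] - a[, j], ",", a[, j])
    paste(c(chrom[j], pos[j], counts$loci[j], "A", "T", ".", "PASS",
            paste0("NS=", length(counts$individuals)), "DP:AD", cells),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read population metadata and build the pair table
#'
#' The metadata TSV needs columns `population, host, x_km, y_km,
#' n_sampled` (or `lon, lat` with `coords = "lonlat"`).  Adjacency is a
#' categorical field observation, never inferred from distance, so it is
#' supplied as an explicit pair list (TSV with columns `pop_a, pop_b`,
#' or a data frame).
#'
#' @param path Metadata TSV path (or data frame).
#' @param adjacency Pair-list TSV path, data frame, or `NULL` (no pair
#'   adjacent).
#' @param coords `"planar"` (x_km/y_km, Euclidean km) or `"lonlat"`
#'   (lon/lat degrees, haversine km).
#' @return List with `populations` (data frame) and `pairs` (one row per
#'   unordered pair: `pair, pop_a, pop_b, distance_km, adjacency,
#'   same_host`).
#' @export
read_population_table <- function(path, adjacency = NULL,
                                  coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  pops <- if (is.data.frame(path)) path else read_dtsv(path)
  need <- c("population", "host",
            if (coords == "planar") c("x_km", "y_km") else c("lon", "lat"))
  stop_if(!all(need %in% names(pops)),
          "metadata must have columns ", paste(need, collapse = ", "))
  stop_if(anyDuplicated(pops$population) > 0L,
          "duplicate population label: ",
          pops$population[duplicated(pops$population)][1])
  xy <- if (coords == "planar") as.matrix(pops[, c("x_km", "y_km")])
        else as.matrix(pops[, c("lon", "lat")])
  stop_if(!all(is.finite(xy)), "population coordinates must be finite")
  adj <- NULL
  if (!is.null(adjacency)) {
    adj <- if (is.data.frame(adjacency)) adjacency else read_dtsv(adjacency)
    stop_if(!all(c("pop_a", "pop_b") %in% names(adj)),
            "adjacency list needs columns pop_a, pop_b")
    unknown <- setdiff(c(adj$pop_a, adj$pop_b), pops$population)
    stop_if(length(unknown) > 0L,
            "adjacency names unknown population(s): ",
            paste(unknown, collapse = ", "))
  }
  pairs <- make_pair_table(pops, xy, coords, adj)
  list(populations = pops, pairs = pairs)
}

make_pair_table <- function(pops, xy, coords, adj) {
  n <- nrow(pops)
  stop_if(n < 2L, "need at least two populations")
  idx <- utils::combn(n, 2L)
  a <- pops$population[idx[1, ]]
  b <- pops$population[idx[2, ]]
  d <- if (coords == "planar") {
    sqrt((xy[idx[1, ], 1] - xy[idx[2, ], 1])^2 +
         (xy[idx[1, ], 2] - xy[idx[2, ], 2])^2)
  } else {
    geosphere::distHaversine(xy[idx[1, ], , drop = FALSE],
                             xy[idx[2, ], , drop = FALSE]) / 1000
  }
  key <- pair_id(a, b)
  adjacent <- rep("separated", length(key))
  if (!is.null(adj) && nrow(adj))
    adjacent[key %in% pair_id(adj$pop_a, adj$pop_b)] <- "adjacent"
  data.frame(pair = key, pop_a = a, pop_b = b, distance_km = d,
             adjacency = adjacent,
             same_host = pops$host[idx[1, ]] == pops$host[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Check that every individual's population exists in the metadata
#'
#' @param counts A [read_count_matrix()] with populations assigned.
#' @param populations Population metadata data frame.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_counts_populations <- function(counts, populations) {
  stop_if(is.null(counts$populations),
          "read-count matrix has no population assignments")
  missing <- setdiff(unique(counts$populations), populations$population)
  stop_if(length(missing) > 0L,
          "validation error: individuals assigned to unknown population(s): ",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write per-locus and per-pair results tables
#'
#' Deterministic column order, `#`-prefixed headers, round-trip readable
#' with [read_dtsv()].
#'
#' @param results List with elements `per_locus` and/or `per_pair` (data
#'   frames).
#' @param out_dir Output directory (created if needed).
#' @param comments Extra comment lines stamped into each file.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results_tables <- function(results, out_dir, comments = character()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  stop_if(!ok || file.access(out_dir, 2L) != 0L,
          "cannot write to directory: ", out_dir)
  paths <- c()
  if (!is.null(results$per_locus)) {
    p <- file.path(out_dir, "per_locus.tsv")
    write_dtsv(results$per_locus, p, comments)
    paths["per_locus"] <- p
  }
  if (!is.null(results$per_pair)) {
    p <- file.path(out_dir, "per_pair.tsv")
    write_dtsv(results$per_pair, p, comments)
    paths["per_pair"] <- p
  }
  invisible(paths)
}
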