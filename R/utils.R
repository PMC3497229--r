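# Internal helpers: triangles, hashing, seeded TSV i/o conventions.

logit <- function(p) stats::qlogis(p)
ilogit <- function(x) stats::plogis(x)

# lower-triangle vectorization used by all matrix-correlation code
lower_tri <- function(m) m[lower.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# FNV-1a 32-bit hash of a character scalar, returned as a double in
# [0, 2^32).  Multiplication is split into 16-bit halves so every
# intermediate stays inside the exactly-representable double range.
fnv1a32 <- function(x) {
  bytes <- as.integer(utf8ToInt(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32 without integer overflow
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Derive a per-stage seed from a global seed
#'
#' Hashes the global seed together with a stage name so that toggling one
#' pipeline stage never perturbs the random stream of another.  Result is
#' a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed in `[1, 2^31 - 60)`.
#' @export
derive_seed <- function(seed, stage) {
  as.integer(fnv1a32(paste0(format(seed), "::", stage)) %% 2147483587) + 1L
}

# short hex hash of an arbitrary R object (used to stamp outputs so that
# tables from different configurations refuse to combine)
config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a tab-separated table with '#'-prefixed header
#'
#' The on-disk convention used throughout the package: optional comment
#' lines (`#key=value`), then a `#`-prefixed header line with column
#' names, then tab-separated data rows.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector of extra comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_dtsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("#", comments), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a table written by [write_dtsv()]
#'
#' @param path File path.
#' @return Data frame; leading comment lines (all but the header) are
#'   attached as attribute `"comments"`.
#' @export
read_dtsv <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  head_lines <- character()
  con <- file(path, open = "rt", encoding = "UTF-8")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    head_lines <- c(head_lines, ln)
  }
  close(con)
  stop_if(length(head_lines) == 0L,
          "malformed table (no '#'-prefixed header): ", path)
  cols <- strsplit(sub("^#", "", head_lines[length(head_lines)]), "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", skip = length(head_lines),
                          header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE)
  if (nrow(df) == 0L) df <- df[0, , drop = FALSE]
  attr(df, "comments") <- sub("^#", "", head_lines[-length(head_lines)])
  df
}

# canonical unordered pair label
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "x")
}
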