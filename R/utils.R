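# Internal helpers shared across modules.

#' @importFrom stats cor median rexp rnorm runif
#' @importFrom utils read.delim write.table
NULL

# Split one TSV line, padding dropped trailing empty fields up to `min_fields`.
split_tsv <- function(line, min_fields = 0L) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < min_fields) parts <- c(parts, rep("", min_fields - length(parts)))
  parts
}

# Read a text table file, dropping '#' comment lines and blank lines,
# keeping original line numbers for error messages.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s: line %d: %s", path, lineno, msg), call. = FALSE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library RNG state is untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Nearest-rank percentile: the order statistic at index ceiling(p/100 * n).
nearest_rank_percentile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to take a percentile of", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100)
    stop("percentile p must lie in (0, 100]", call. = FALSE)
  xs <- sort(x)
  xs[max(1L, as.integer(ceiling(p / 100 * length(xs))))]
}

# Row-standardize a genes x samples matrix so that each row has zero mean and
# unit sum of squares; rows with zero variance become all-NA (undefined r).
standardize_rows <- function(m) {
  ctr <- m - rowMeans(m)
  ss <- sqrt(rowSums(ctr^2))
  z <- ctr / ss
  z[ss == 0, ] <- NA_real_
  z
}

# Map 1-based indices k into the ordered list of pairs (i < j) over 1..n
# (row-major: (1,2),(1,3),...,(1,n),(2,3),...). Returns a 2-column matrix.
pair_from_index <- function(k, n) {
  k0 <- k - 1
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  # guard against floating-point drift at block boundaries
  base <- i * (2 * n - i - 1) / 2
  lo <- k0 < base
  i[lo] <- i[lo] - 1
  base <- i * (2 * n - i - 1) / 2
  hi <- k0 >= base + (n - 1 - i)
  i[hi] <- i[hi] + 1
  base <- i * (2 * n - i - 1) / 2
  j <- k0 - base + i + 1
  cbind(as.integer(i + 1), as.integer(j + 1))
}

n_pairs <- function(n) n * (n - 1) / 2

# Deterministic TSV writer (no quoting, no row names).
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

# Join a character set deterministically for report columns.
join_set <- function(x) paste(sort(unique(x)), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a
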