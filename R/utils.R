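# Internal helpers: argument checks, seeded evaluation, TSV/JSON I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name, allow_one = TRUE) {
  if (!is.numeric(p) || anyNA(p)) {
    stop2(name, " must be numeric and non-missing")
  }
  hi_ok <- if (allow_one) all(p <= 1) else all(p < 1)
  if (!all(p > 0) || !hi_ok) {
    stop2(name, " must lie in (0, 1", if (allow_one) "]" else ")")
  }
  invisible(p)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop2(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream. All exported stochastic operations funnel through this.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seeds: one base seed per call, one derived
# seed per dataset, all below 2^31.
derive_seed <- function(seed, index) {
  (as.double(seed) * 1103L + 7919 * as.double(index)) %% 2147483647
}

#' Write and read tab-separated tables
#'
#' Plain single-header TSV used for probe tables, binding summaries and
#' differential-expression tables.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write and read expression matrices as TSV
#'
#' Layout: first header row `gene_id` plus sample ids, second row
#' `!label` plus the per-sample group or cohort label, then one row per
#' gene.
#'
#' @param mat numeric genes x samples matrix with dimnames.
#' @param labels character vector of per-sample labels.
#' @param path file path.
#' @return `read_expression_tsv()` returns `list(values, labels)`;
#'   the writer returns `path` invisibly.
#' @export
write_expression_tsv <- function(mat, labels, path) {
  stopifnot(ncol(mat) == length(labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(c("!label", labels), collapse = "\t"), con)
  write.table(mat, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, n = 2L)
  samples <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  labels <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- read.delim(path, skip = 2L, header = FALSE,
                     stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(body[, -1L, drop = FALSE])
  dimnames(values) <- list(body[[1L]], samples)
  list(values = values, labels = setNames(labels, samples))
}
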