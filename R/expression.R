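# Expression analysis: quantile normalization, empirical-Bayes
# moderated-t differential expression, per-gene standardization,
# multi-cohort merging and marker-gene quantile stratification.

#' Configuration for differential-expression analysis
#'
#' @param alpha unadjusted significance cutoff (default 0.05, matching
#'   the reproduce-then-improve default; set `adjust = "BH"` for
#'   Benjamini-Hochberg control instead).
#' @param top_k optional count: when set, `significant` marks the
#'   `top_k` smallest p-values instead of the `p < alpha` set.
#' @param d0,s0_2 empirical-Bayes prior degrees of freedom and prior
#'   variance.  `NULL` (default) estimates both by moment matching on
#'   `log(s^2)`; fixed values override the estimate (use `d0 = 0` for
#'   the ordinary pooled t, `d0 = Inf` for full shrinkage to `s0_2`).
#' @param stratify_quantile proportion `q` in (0, 0.5] used by
#'   [stratify_by_gene()] (default 0.35).
#' @param adjust `"none"` or `"BH"`.
#' @param sd_mode `"sample"` (n-1 denominator, default) or
#'   `"population"` for [standardize_genes()].
#' @return A list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, top_k = NULL, d0 = NULL, s0_2 = NULL,
                      stratify_quantile = 0.35,
                      adjust = c("none", "BH"),
                      sd_mode = c("sample", "population")) {
  if (!(alpha > 0 && alpha < 1)) stop2("alpha must be in (0,1)")
  if (!(stratify_quantile > 0 && stratify_quantile <= 0.5)) {
    stop2("stratify_quantile must be in (0, 0.5]")
  }
  structure(list(alpha = alpha, top_k = top_k, d0 = d0, s0_2 = s0_2,
                 stratify_quantile = stratify_quantile,
                 adjust = match.arg(adjust),
                 sd_mode = match.arg(sd_mode)),
            class = "de_config")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share the same empirical
#' distribution: the row-wise mean of the column-sorted values.  Tied
#' values within a column receive the mean of the target values their
#' tied ranks span.
#'
#' @param mat numeric genes x samples matrix, at least two columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop2("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) stop2("missing values are not supported")
  n <- nrow(mat)
  target <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

# Newton solve of trigamma(y) = x, vectorized; used by the moment-
# matching estimator of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Moment-matching estimate of (d0, s0^2) from gene-wise variances s2
# with d residual df each: match mean and variance of log(s2) to the
# scaled-F model via digamma/trigamma.
estimate_prior <- function(s2, d) {
  ok <- is.finite(log(s2))
  if (!any(ok)) stop2("cannot estimate prior: all gene variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  list(d0 = d0, s0_2 = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

#' Empirical-Bayes moderated-t differential expression
#'
#' Two-group comparison with gene-wise pooled variances shrunk toward a
#' common prior: `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, with the
#' moderated t referred to `d0 + d` degrees of freedom.  The prior
#' `(d0, s0^2)` is estimated by moment matching on `log(s2)` unless
#' fixed in `config`.
#'
#' @param mat numeric genes x samples matrix (log2 scale).
#' @param groups per-sample group labels, exactly two levels, each with
#'   at least two samples.
#' @param positive label of the group whose mean enters `logFC` with a
#'   plus sign (default: first label in order of appearance).
#' @param config a [de_config()].
#' @return A data frame of class `de_table`: `gene_id`, `logFC`,
#'   `t_mod`, `p`, `direction` (`up`/`down`/`zero`), `significant`.
#'   Attributes `d0` and `s0_2` record the prior actually used.
#' @export
moderated_t <- function(mat, groups, positive = NULL, config = de_config()) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (ncol(mat) != length(groups)) stop2("groups must match columns")
  lev <- unique(groups)
  if (length(lev) != 2L) stop2("exactly two groups are required")
  positive <- positive %||% lev[1L]
  if (!positive %in% lev) stop2("unknown positive label")
  negative <- setdiff(lev, positive)
  i1 <- groups == positive
  i2 <- groups == negative
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop2("each group needs >= 2 replicates")
  d <- n1 + n2 - 2L

  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  logfc <- m1 - m2
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  d0 <- config$d0; s0_2 <- config$s0_2
  if (is.null(d0) || is.null(s0_2)) {
    est <- estimate_prior(s2, d)
    d0 <- d0 %||% est$d0
    s0_2 <- s0_2 %||% est$s0_2
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, logfc / se,
                  ifelse(abs(logfc) < 1e-12, 0, sign(logfc) * Inf))
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)

  direction <- ifelse(abs(logfc) < 1e-12, "zero",
                      ifelse(logfc > 0, "up", "down"))
  p_crit <- if (config$adjust == "BH") stats::p.adjust(p, "BH") else p
  significant <- if (!is.null(config$top_k)) {
    rank(p, ties.method = "first") <= config$top_k
  } else {
    p_crit < config$alpha
  }
  out <- data.frame(gene_id = rownames(mat) %||% as.character(seq_along(logfc)),
                    logFC = logfc, t_mod = t_mod, p = p,
                    direction = direction, significant = significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "groups") <- c(positive = positive, negative = negative)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Standardize each gene to mean 0, sd 1
#'
#' Applied per cohort before merging so that differently scaled
#' platforms become comparable.  Constant gene rows cannot be
#' standardized and are dropped with a warning.
#'
#' @param mat numeric genes x samples matrix.
#' @param sd_mode `"sample"` (n-1, default) or `"population"` (n).
#' @return Matrix with the surviving rows centered and scaled.
#' @export
standardize_genes <- function(mat, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  cen <- mat - mu
  n <- ncol(mat)
  denom <- if (sd_mode == "sample") n - 1L else n
  sdv <- sqrt(rowSums(cen^2) / denom)
  bad <- sdv == 0
  if (any(bad)) {
    warning(sum(bad), " constant gene row(s) excluded from standardization")
    cen <- cen[!bad, , drop = FALSE]
    sdv <- sdv[!bad]
  }
  cen / sdv
}

norm_gene_ids <- function(ids) toupper(trimws(ids))

#' Merge expression cohorts on their common genes
#'
#' Gene identifiers are matched exactly after uppercasing and
#' whitespace stripping; the merged matrix holds the intersection of
#' the cohorts' gene sets with columns concatenated and the cohort
#' label retained per sample.
#'
#' @param cohorts named list of genes x samples matrices (or
#'   `list(values=, labels=)` pairs as produced by
#'   [simulate_expression()]).
#' @return `list(values, labels)` where `labels` maps each sample to
#'   its cohort.
#' @export
merge_cohorts <- function(cohorts) {
  if (length(cohorts) < 2L) stop2("need >= 2 cohorts")
  mats <- lapply(cohorts, function(co) {
    m <- if (is.list(co) && !is.null(co$values)) co$values else as.matrix(co)
    rownames(m) <- norm_gene_ids(rownames(m))
    if (anyDuplicated(rownames(m))) stop2("duplicate gene ids after normalization")
    m
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L) stop2("empty gene intersection across cohorts")
  names(mats) <- names(mats) %||% paste0("cohort", seq_along(mats))
  values <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  labels <- rep(names(mats), vapply(mats, ncol, 1L))
  names(labels) <- colnames(values)
  list(values = values, labels = labels)
}

#' Split samples by the upper and lower quantiles of one gene
#'
#' The `floor(q * n)` samples with the highest expression of `gene_id`
#' form the positive stratum, the same number with the lowest form the
#' negative stratum, and the middle is discarded.  Ties are broken by
#' stable sample-id order.
#'
#' @param mat genes x samples matrix (or `list(values=, ...)`).
#' @param gene_id marker gene (matched after uppercase normalization).
#' @param q stratum proportion in (0, 0.5].
#' @return `list(positive, negative)` of sample ids.
#' @export
stratify_by_gene <- function(mat, gene_id, q = 0.35) {
  if (is.list(mat) && !is.null(mat$values)) mat <- mat$values
  if (!(q > 0 && q <= 0.5)) stop2("q must be in (0, 0.5]")
  ids <- norm_gene_ids(rownames(mat))
  hit <- which(ids == norm_gene_ids(gene_id))
  if (length(hit) != 1L) stop2("gene_id not found (or not unique): ", gene_id)
  x <- mat[hit, ]
  n <- length(x)
  k <- floor(q * n)
  if (k < 1L) stop2("stratum size floor(q*n) < 1")
  samples <- colnames(mat) %||% as.character(seq_len(n))
  ord <- order(-x, samples, method = "radix")
  list(positive = samples[ord[seq_len(k)]],
       negative = samples[rev(ord)[seq_len(k)]])
}

#' qPCR delta-delta-Ct fold change
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_A - dCt_B`; fold change of condition A over condition B
#' is `2^(-ddCt)`.
#'
#' @param ct_target_a,ct_ref_a,ct_target_b,ct_ref_b positive cycle
#'   thresholds (vectorized).
#' @return Fold change(s).
#' @export
ddct_fold_change <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  ct <- c(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b)
  if (!all(is.finite(ct)) || any(ct <= 0)) stop2("Ct values must be positive")
  ddct <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-ddct)
}
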