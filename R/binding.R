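# POL II binding calls from promoter tiling-array probes: the
# probe-triple neighborhood rule, gene-level p-value combination
# (Fisher joint and geometric average), tight/loose classification and
# the promoter-proximal stalling index.

#' Configuration for the binding caller
#'
#' @param alpha_central significance cutoff for the composite triple
#'   p-value `p_x_bar` (default 0.05).
#' @param alpha_neighbor_strict cutoff used by clause 1 of the
#'   neighborhood rule (central and one neighbor below it; default 0.05).
#' @param alpha_neighbor_relaxed cutoff used by clause 2 (one neighbor
#'   below it; default 0.1).
#' @param triple_window_nt maximum span, in nucleotides, between the
#'   outermost probes of an eligible triple (default 1100).
#' @param tight_cut,loose_cut gene-level geometric-average p-value
#'   cutoffs for the tight (`p < tight_cut`) and loose
#'   (`tight_cut <= p < loose_cut`) binder classes.
#' @param si_proximal_window,si_distal_window numeric length-2 windows,
#'   in nt relative to the TSS, over which the stalling index numerator
#'   (max enrichment) and denominator (mean enrichment) are taken.
#' @param si_log_scale if `TRUE` the stalling index uses log2 ratios
#'   directly instead of linear `2^log_ratio` enrichment.
#' @param pseudo_floor lower clamp applied to p-values before logs.
#' @return A list of class `binding_config`.
#' @export
binding_config <- function(alpha_central = 0.05,
                           alpha_neighbor_strict = 0.05,
                           alpha_neighbor_relaxed = 0.1,
                           triple_window_nt = 1100,
                           tight_cut = 0.05,
                           loose_cut = 0.13,
                           si_proximal_window = c(-300, 300),
                           si_distal_window = c(300, 2500),
                           si_log_scale = FALSE,
                           pseudo_floor = 1e-300) {
  if (alpha_central <= 0 || alpha_central > alpha_neighbor_relaxed ||
      alpha_neighbor_relaxed >= 1) {
    stop2("need 0 < alpha_central <= alpha_neighbor_relaxed < 1")
  }
  if (triple_window_nt <= 0) stop2("triple_window_nt must be positive")
  if (diff(si_proximal_window) <= 0 || diff(si_distal_window) <= 0) {
    stop2("stalling-index windows must be non-degenerate")
  }
  if (!(tight_cut > 0 && tight_cut < loose_cut && loose_cut < 1)) {
    stop2("need 0 < tight_cut < loose_cut < 1")
  }
  structure(list(alpha_central = alpha_central,
                 alpha_neighbor_strict = alpha_neighbor_strict,
                 alpha_neighbor_relaxed = alpha_neighbor_relaxed,
                 triple_window_nt = triple_window_nt,
                 tight_cut = tight_cut, loose_cut = loose_cut,
                 si_proximal_window = si_proximal_window,
                 si_distal_window = si_distal_window,
                 si_log_scale = si_log_scale,
                 pseudo_floor = pseudo_floor),
            class = "binding_config")
}

#' Per-probe one-sided p-values from array log-ratios
#'
#' Stands in for the array vendor's error model: log-ratios are
#' standardized robustly against the whole array (center = median,
#' scale = 1.4826 x median absolute deviation) and converted to
#' one-sided upper-tail normal probabilities, so enrichment above the
#' array background yields small `p_probe`.
#'
#' @param probes data frame with at least columns `probe_id`,
#'   `gene_id`, `offset_nt`, `log_ratio` (one array).
#' @return The input with a `p_probe` column filled in.
#' @export
probe_pvalues <- function(probes) {
  stopifnot(is.data.frame(probes), "log_ratio" %in% names(probes))
  lr <- probes$log_ratio
  if (anyNA(lr)) stop2("log_ratio contains missing values")
  s <- mad(lr)  # constant 1.4826 included
  if (s == 0) stop2("degenerate array: MAD of log_ratio is zero")
  # floored so extreme enrichment cannot underflow to an invalid p = 0
  probes$p_probe <- pmax(pnorm((lr - median(lr)) / s, lower.tail = FALSE),
                         1e-300)
  probes
}

#' Composite p-value of a probe triple
#'
#' Equal-weight Stouffer combination: the three p-values are mapped to
#' upper-tail normal quantiles, averaged with weight 1/sqrt(3), and the
#' combined z is mapped back to an upper-tail probability.  Symmetric
#' and monotone in each argument.
#'
#' @param p_left,p_center,p_right probabilities in (0, 1]; vectorized.
#' @param pseudo_floor lower clamp before the probit transform.
#' @return `p_x_bar`, same length as the inputs.
#' @export
composite_triple_p <- function(p_left, p_center, p_right,
                               pseudo_floor = 1e-300) {
  check_prob(c(p_left, p_center, p_right), "triple p-values")
  z <- function(p) qnorm(pmin(pmax(p, pseudo_floor), 1 - 1e-16),
                         lower.tail = FALSE)
  # floored: three very small inputs would otherwise underflow to 0
  pmax(pnorm((z(p_left) + z(p_center) + z(p_right)) / sqrt(3),
             lower.tail = FALSE),
       pseudo_floor)
}

#' Call bound sites within one gene's promoter by the neighborhood rule
#'
#' Every interior probe of a gene is a candidate central probe of the
#' triple formed with its two flanking neighbors.  A triple is eligible
#' if its outermost probes lie within `triple_window_nt` of each other.
#' The central probe is called bound if the composite triple p-value
#' `p_x_bar` is below `alpha_central` and either (1) the central probe
#' and at least one neighbor are individually below
#' `alpha_neighbor_strict`, or (2) at least one neighbor is below
#' `alpha_neighbor_relaxed`.
#'
#' @param probes data frame for one gene with columns `probe_id`,
#'   `offset_nt`, `p_probe` (any input order; sorting is internal).
#' @param config a [binding_config()].
#' @return Data frame of one row per eligible central probe with
#'   columns `gene_id`, `central_probe_id`, `offset_nt`, `p_x_bar`,
#'   `bound`.  Fewer than three probes yield a zero-row frame.
#' @export
call_sites <- function(probes, config = binding_config()) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "offset_nt", "p_probe") %in% names(probes)))
  gene <- if ("gene_id" %in% names(probes)) probes$gene_id[1L] else NA_character_
  empty <- data.frame(gene_id = character(), central_probe_id = character(),
                      offset_nt = numeric(), p_x_bar = numeric(),
                      bound = logical(), stringsAsFactors = FALSE)
  n <- nrow(probes)
  if (n < 3L) return(empty)
  probes <- probes[order(probes$offset_nt), , drop = FALSE]
  i <- 2:(n - 1L)
  pl <- probes$p_probe[i - 1L]
  pc <- probes$p_probe[i]
  pr <- probes$p_probe[i + 1L]
  eligible <- (probes$offset_nt[i + 1L] - probes$offset_nt[i - 1L]) <=
    config$triple_window_nt
  pxb <- composite_triple_p(pl, pc, pr, config$pseudo_floor)
  clause1 <- pc < config$alpha_neighbor_strict &
    pmin(pl, pr) < config$alpha_neighbor_strict
  clause2 <- pmin(pl, pr) < config$alpha_neighbor_relaxed
  bound <- pxb < config$alpha_central & (clause1 | clause2)
  out <- data.frame(gene_id = gene,
                    central_probe_id = probes$probe_id[i],
                    offset_nt = probes$offset_nt[i],
                    p_x_bar = pxb,
                    bound = bound,
                    stringsAsFactors = FALSE)
  out[eligible, , drop = FALSE]
}

#' Fisher's joint p-value over a gene's bound sites
#'
#' Transforms the product of site p-values to a chi-square statistic,
#' `-2 * sum(log p)`, referred to the chi-square distribution with
#' `2n` degrees of freedom.
#'
#' @param site_pvals non-empty vector of probabilities in (0, 1].
#' @param pseudo_floor lower clamp before logs.
#' @return `p_jt`, a single probability.
#' @export
fisher_joint_p <- function(site_pvals, pseudo_floor = 1e-300) {
  if (length(site_pvals) == 0L) stop2("site_pvals must be non-empty")
  check_prob(site_pvals, "site_pvals")
  stat <- -2 * sum(log(pmax(site_pvals, pseudo_floor)))
  pchisq(stat, df = 2 * length(site_pvals), lower.tail = FALSE)
}

#' Geometric-average p-value over a gene's bound sites
#'
#' The geometric mean `g` of the site p-values is transformed via the
#' chi-square distribution with 2 degrees of freedom; because the
#' chi-square-2 survival function is `exp(-x/2)`, the result equals `g`
#' exactly.  Unlike `p_jt` it does not reward site count, so binding
#' strengths of genes with different numbers of sites are comparable.
#'
#' @inheritParams fisher_joint_p
#' @return `p_gav`, a single probability.
#' @export
geometric_average_p <- function(site_pvals, pseudo_floor = 1e-300) {
  if (length(site_pvals) == 0L) stop2("site_pvals must be non-empty")
  check_prob(site_pvals, "site_pvals")
  g <- exp(mean(log(pmax(site_pvals, pseudo_floor))))
  pchisq(-2 * log(g), df = 2, lower.tail = FALSE)
}

#' Tight/loose/unbound classification of one gene
#'
#' A gene with no bound site is unbound.  Otherwise the promoter-wide
#' geometric-average p-value (`p_gene`, computed over all eligible
#' triples, not only the bound ones) decides: tight if
#' `p_gene < tight_cut`, loose if `tight_cut <= p_gene < loose_cut`,
#' unbound beyond.  Using the promoter-wide statistic keeps the loose
#' class reachable (bound sites alone all have `p_x_bar < 0.05` by
#' construction) and suppresses isolated chance triples.
#'
#' @param n_sites number of bound sites.
#' @param p_gene promoter-wide geometric-average p-value.
#' @param config a [binding_config()].
#' @return One of `"tight"`, `"loose"`, `"unbound"`.
#' @export
classify_binder <- function(n_sites, p_gene, config = binding_config()) {
  if (is.na(n_sites) || n_sites == 0L || is.na(p_gene)) return("unbound")
  if (p_gene < config$tight_cut) return("tight")
  if (p_gene < config$loose_cut) return("loose")
  "unbound"
}

#' Promoter-proximal stalling index
#'
#' Ratio of the maximum enrichment over probes in the TSS-proximal
#' window to the mean enrichment over probes in the downstream window;
#' enrichment is linear-scale `2^log_ratio` by default.  Values well
#' above 1 indicate POL II concentrated at the promoter (stalled or
#' poised polymerase) rather than distributed across the transcribed
#' region.
#'
#' @param probes data frame for one gene with `offset_nt`, `log_ratio`.
#' @param config a [binding_config()] providing the two windows.
#' @return A single number, or `NA_real_` (with a message) when either
#'   window holds no probe.
#' @export
stalling_index <- function(probes, config = binding_config()) {
  stopifnot(all(c("offset_nt", "log_ratio") %in% names(probes)))
  w1 <- config$si_proximal_window
  w2 <- config$si_distal_window
  prox <- probes$log_ratio[probes$offset_nt >= w1[1] & probes$offset_nt <= w1[2]]
  dist <- probes$log_ratio[probes$offset_nt > w2[1] & probes$offset_nt <= w2[2]]
  if (length(prox) == 0L || length(dist) == 0L) {
    message("stalling_index: empty proximal or distal window for gene ",
            if ("gene_id" %in% names(probes)) probes$gene_id[1L] else "?")
    return(NA_real_)
  }
  if (config$si_log_scale) {
    max(prox) / mean(dist)
  } else {
    max(2^prox) / mean(2^dist)
  }
}

#' Per-gene binding summary for one array
#'
#' Runs [probe_pvalues()] (unless `p_probe` is already present),
#' [call_sites()] per gene, combines bound-site `p_x_bar` values with
#' [fisher_joint_p()] and [geometric_average_p()], computes the
#' promoter-wide `p_gene`, classifies each gene and attaches the
#' stalling index.
#'
#' @param probes probe table for one array (all genes).
#' @param config a [binding_config()].
#' @return A data frame of class `binding_summary`, one row per gene:
#'   `gene_id`, `n_sites`, `p_jt`, `p_gav` (both over bound sites, NA
#'   when there are none), `p_gene`, `binder_class`, `stalling_index`.
#' @export
summarize_binding <- function(probes, config = binding_config()) {
  stopifnot(all(c("probe_id", "gene_id", "offset_nt", "log_ratio") %in%
                  names(probes)))
  if (!"p_probe" %in% names(probes)) probes <- probe_pvalues(probes)
  by_gene <- split(probes, probes$gene_id)
  rows <- lapply(by_gene, function(g) {
    sites <- call_sites(g, config)
    bp <- sites$p_x_bar[sites$bound]
    n_sites <- length(bp)
    p_gene <- if (nrow(sites)) {
      geometric_average_p(sites$p_x_bar, config$pseudo_floor)
    } else {
      NA_real_
    }
    data.frame(gene_id = g$gene_id[1L],
               n_sites = n_sites,
               p_jt = if (n_sites) fisher_joint_p(bp, config$pseudo_floor) else NA_real_,
               p_gav = if (n_sites) geometric_average_p(bp, config$pseudo_floor) else NA_real_,
               p_gene = p_gene,
               binder_class = classify_binder(n_sites, p_gene, config),
               stalling_index = stalling_index(g, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_summary", "data.frame")
  out
}
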