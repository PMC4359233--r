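# Independent oracles used across the suite. These deliberately avoid
# the package's code paths: explicit loops, direct formulas.

# Brute-force neighborhood rule on one gene's probes: enumerate every
# interior probe, recompute the composite p by hand, apply the two
# clauses literally.
brute_force_sites <- function(offset_nt, p_probe,
                              alpha_central = 0.05,
                              alpha_strict = 0.05,
                              alpha_relaxed = 0.1,
                              window = 1100) {
  ord <- order(offset_nt)
  offset_nt <- offset_nt[ord]
  p_probe <- p_probe[ord]
  n <- length(p_probe)
  if (n < 3) return(logical(0))
  out <- rep(NA, n - 2)
  for (i in 2:(n - 1)) {
    if (offset_nt[i + 1] - offset_nt[i - 1] > window) next
    zl <- qnorm(1 - p_probe[i - 1])
    zc <- qnorm(1 - p_probe[i])
    zr <- qnorm(1 - p_probe[i + 1])
    p_xbar <- 1 - pnorm((zl + zc + zr) / sqrt(3))
    clause1 <- p_probe[i] < alpha_strict &&
      (p_probe[i - 1] < alpha_strict || p_probe[i + 1] < alpha_strict)
    clause2 <- p_probe[i - 1] < alpha_relaxed || p_probe[i + 1] < alpha_relaxed
    out[i - 1] <- (p_xbar < alpha_central) && (clause1 || clause2)
  }
  out[!is.na(out)]
}

# Algebraic identity for Cohen's kappa on a 2x2 table.
kappa_identity <- function(a, b, c, d) {
  2 * (a * d - b * c) / ((a + b) * (b + d) + (a + c) * (c + d))
}

# Minimal DE-table constructor for concordance/cascade tests.
fake_de <- function(genes, direction, significant = TRUE, p = 0.01) {
  structure(data.frame(gene_id = genes,
                       logFC = ifelse(direction == "up", 1,
                                      ifelse(direction == "down", -1, 0)),
                       t_mod = 0, p = p,
                       direction = direction,
                       significant = rep_len(significant, length(genes)),
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

# Minimal binding-summary constructor for regulon tests.
fake_summary <- function(genes, classes) {
  structure(data.frame(gene_id = genes, n_sites = ifelse(classes == "unbound", 0L, 2L),
                       p_jt = NA_real_, p_gav = NA_real_, p_gene = NA_real_,
                       binder_class = classes, stalling_index = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("binding_summary", "data.frame"))
}

# Small probe table for one gene with chosen per-probe p-values.
probe_frame <- function(p, spacing = 200, gene = "G1") {
  data.frame(probe_id = paste0(gene, "_P", seq_along(p)),
             gene_id = gene,
             offset_nt = seq(0, by = spacing, length.out = length(p)),
             p_probe = p,
             stringsAsFactors = FALSE)
}
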