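# Synthetic promoter-array ChIP-chip and expression data with planted
# ground truth. The generator states one world: probe grids and window
# sizes follow the tiling design being emulated (probes ~200 nt apart
# across -5000..+2500 of each TSS), cell-line panels mimic three
# HER2-high lines plus one HER2-negative control, and five tumor
# cohorts of 197/173/115/247/80 samples carry a continuous HER2
# gradient with per-cohort affine distortions.

#' Simulation configuration
#'
#' @param n_genes number of genes on the synthetic array.
#' @param probe_spacing probe spacing in nt (default 200).
#' @param promoter_window numeric length-2, promoter window around the
#'   TSS in nt (default `c(-5000, 2500)`).
#' @param cell_lines data frame with columns `name`, `her2_status`
#'   (`"+"`/`"-"`) and `n_expr_replicates`.  Default: three HER2-high
#'   lines and one HER2-negative control, three replicates each.
#' @param n_cohorts,cohort_sizes tumor cohorts; defaults: five cohorts
#'   of 197, 173, 115, 247 and 80 samples (812 total).
#' @param fraction_bound_in_her2pos fraction of genes POL II-bound in
#'   every HER2-positive line (and unbound in the control).
#' @param fraction_regulated_of_bound fraction of the bound genes that
#'   are also transcriptionally regulated in cell lines.
#' @param fraction_stalled_of_bound fraction of bound genes whose
#'   signal concentrates at the TSS (stalled profile) rather than
#'   spreading across the window (elongating profile).
#' @param fraction_poised_expressed_in_tumor fraction of the poised
#'   genes (bound but unregulated in cell lines) that respond to the
#'   HER2 gradient in tumors.
#' @param peak_height peak log2-ratio of a planted binding peak.
#' @param peak_width full width at half maximum of the stalled peak, nt.
#' @param noise_sd i.i.d. probe noise, log2 units.
#' @param effect_size_de planted expression effect in standardized
#'   (noise-sd) units; used both for the cell-line group difference of
#'   regulated genes and for the expected difference between the upper
#'   and lower HER2 strata of tissue-dependent genes in tumors.
#' @param expr_noise_sd replicate/sample noise of expression values,
#'   log2 units (0 gives the noiseless world).
#' @param her2_gene row name of the HER2 marker gene added to the
#'   tumor cohorts for stratification.
#' @param seed base seed; every dataset derives its own sub-stream
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600,
                       probe_spacing = 200,
                       promoter_window = c(-5000, 2500),
                       cell_lines = data.frame(
                         name = c("LINE_H1", "LINE_H2", "LINE_H3", "CTRL"),
                         her2_status = c("+", "+", "+", "-"),
                         n_expr_replicates = 3L,
                         stringsAsFactors = FALSE),
                       n_cohorts = 5,
                       cohort_sizes = c(197, 173, 115, 247, 80),
                       fraction_bound_in_her2pos = 0.15,
                       fraction_regulated_of_bound = 0.15,
                       fraction_stalled_of_bound = 0.5,
                       fraction_poised_expressed_in_tumor = 0.16,
                       peak_height = 2,
                       peak_width = 500,
                       noise_sd = 0.25,
                       effect_size_de = 4,
                       expr_noise_sd = 0.5,
                       her2_gene = "HER2",
                       seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  if (probe_spacing <= 0) stop2("probe_spacing must be positive")
  if (peak_width <= 0) stop2("peak_width must be positive")
  if (noise_sd < 0 || expr_noise_sd < 0) stop2("noise sds must be >= 0")
  if (length(promoter_window) != 2L || diff(promoter_window) <= 0) {
    stop2("promoter_window must be an increasing length-2 vector")
  }
  fr <- c(fraction_bound_in_her2pos, fraction_regulated_of_bound,
          fraction_stalled_of_bound, fraction_poised_expressed_in_tumor)
  if (any(fr < 0 | fr > 1)) stop2("all fractions must lie in [0,1]")
  n_cohorts <- check_count(n_cohorts, "n_cohorts")
  if (length(cohort_sizes) != n_cohorts) {
    stop2("cohort_sizes must have length n_cohorts")
  }
  stopifnot(is.data.frame(cell_lines),
            all(c("name", "her2_status", "n_expr_replicates") %in%
                  names(cell_lines)),
            all(cell_lines$her2_status %in% c("+", "-")))
  structure(list(n_genes = n_genes, probe_spacing = probe_spacing,
                 promoter_window = promoter_window, cell_lines = cell_lines,
                 n_cohorts = n_cohorts, cohort_sizes = cohort_sizes,
                 fraction_bound_in_her2pos = fraction_bound_in_her2pos,
                 fraction_regulated_of_bound = fraction_regulated_of_bound,
                 fraction_stalled_of_bound = fraction_stalled_of_bound,
                 fraction_poised_expressed_in_tumor =
                   fraction_poised_expressed_in_tumor,
                 peak_height = peak_height, peak_width = peak_width,
                 noise_sd = noise_sd, effect_size_de = effect_size_de,
                 expr_noise_sd = expr_noise_sd, her2_gene = her2_gene,
                 seed = seed),
            class = "sim_config")
}

sim_gene_ids <- function(config) sprintf("G%04d", seq_len(config$n_genes))

probe_offsets <- function(config) {
  seq(config$promoter_window[1], config$promoter_window[2],
      by = config$probe_spacing)
}

# Plant the gene classes once; every dataset reuses this truth.
make_ground_truth <- function(config) {
  genes <- sim_gene_ids(config)
  n_bound <- round(config$fraction_bound_in_her2pos * config$n_genes)
  bound <- genes[seq_len(n_bound)]
  n_reg <- round(config$fraction_regulated_of_bound * n_bound)
  regulated_genes <- bound[seq_len(n_reg)]
  poised <- setdiff(bound, regulated_genes)
  n_td <- round(config$fraction_poised_expressed_in_tumor * length(poised))
  tissue <- poised[seq_len(n_td)]
  n_st <- round(config$fraction_stalled_of_bound * n_bound)
  dirs <- function(g, offset = 0) {
    setNames(ifelse((seq_along(g) + offset) %% 2 == 0, "down", "up"), g)
  }
  lines <- config$cell_lines
  bound_per_line <- setNames(
    lapply(seq_len(nrow(lines)), function(i) {
      if (lines$her2_status[i] == "+") bound else character()
    }),
    lines$name)
  truth <- list(bound_genes_per_line = bound_per_line,
                regulated_genes = dirs(regulated_genes),
                poised_genes = poised,
                tissue_dependent_genes = dirs(tissue, offset = 1),
                stalled_genes = bound[seq_len(n_st)])
  class(truth) <- "ground_truth"
  truth
}

#' Simulate promoter tiling-array ChIP-chip data
#'
#' Probes sit on a fixed grid every `probe_spacing` nt across the
#' promoter window.  In HER2-positive lines, planted bound genes carry
#' either a Gaussian log2-ratio peak centered at the TSS (stalled
#' profile; height `peak_height`, FWHM `peak_width`) or a uniform
#' elevation of `0.6 * peak_height` across the whole window
#' (elongating profile).  The control line and all unbound genes are
#' pure noise.  All probes receive i.i.d. normal noise with sd
#' `noise_sd`.  Identical configuration (including seed) reproduces
#' identical output.
#'
#' @param config a [sim_config()].
#' @return `list(probes, truth, offsets)`: `probes` is a named list
#'   (one data frame per cell line with columns `probe_id`, `gene_id`,
#'   `offset_nt`, `log_ratio`), `truth` the planted [ground
#'   truth][make_ground_truth], `offsets` the probe grid.
#' @export
simulate_chipchip <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  truth <- make_ground_truth(config)
  offsets <- probe_offsets(config)
  genes <- sim_gene_ids(config)
  np <- length(offsets)
  sigma <- config$peak_width / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  stalled_mu <- config$peak_height * exp(-offsets^2 / (2 * sigma^2))
  elong_mu <- rep(0.6 * config$peak_height, np)
  lines <- config$cell_lines
  probes <- lapply(seq_len(nrow(lines)), function(i) {
    line <- lines$name[i]
    mu <- matrix(0, nrow = length(genes), ncol = np,
                 dimnames = list(genes, NULL))
    for (g in truth$bound_genes_per_line[[line]]) {
      mu[g, ] <- if (g %in% truth$stalled_genes) stalled_mu else elong_mu
    }
    lr <- with_seed(derive_seed(config$seed, i), {
      mu + matrix(rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
    })
    data.frame(
      probe_id = paste0(rep(genes, each = np), "_P",
                        formatC(rep(seq_len(np), length(genes)),
                                width = 2, flag = "0")),
      gene_id = rep(genes, each = np),
      offset_nt = rep(offsets, length(genes)),
      log_ratio = as.vector(t(lr)),
      stringsAsFactors = FALSE)
  })
  names(probes) <- lines$name
  list(probes = probes, truth = truth, offsets = offsets)
}

# Expected gap, in sd units of the HER2 score, between the means of the
# top-q and bottom-q strata of a normal gradient; calibrates the
# planted tumor effect so `effect_size_de` is the standardized
# strata difference.
strata_gap <- function(q) 2 * dnorm(qnorm(1 - q)) / q

#' Simulate cell-line and tumor-cohort expression data
#'
#' Cell-line matrices carry the configured replicate counts; planted
#' regulated genes differ between HER2-positive lines and the control
#' by `effect_size_de * expr_noise_sd` in the planted direction, while
#' poised genes show no group difference.  Each tumor cohort draws a
#' continuous HER2 score per sample; tissue-dependent genes follow that
#' score in their planted direction (scaled so the expected top-35% vs
#' bottom-35% strata difference is `effect_size_de` noise-sd units),
#' and every cohort applies its own per-gene affine distortion (scale
#' and shift) so that per-gene standardization before merging is
#' consequential.  A marker-gene row tracking the HER2 score itself is
#' appended to every cohort for stratification.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_chipchip()] (or built
#'   manually with the same fields).
#' @return `list(cell_lines, cohorts)`; `cell_lines` is
#'   `list(values, labels)` with one column per replicate and the line
#'   name as label, `cohorts` a named list of such pairs, one per
#'   cohort, labels holding the cohort name.
#' @export
simulate_expression <- function(config = sim_config(), truth) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$cell_lines$n_expr_replicates < 2L)) {
    stop2("every cell line needs >= 2 expression replicates")
  }
  genes <- sim_gene_ids(config)
  ns <- config$expr_noise_sd
  eff <- config$effect_size_de * if (ns > 0) ns else 1
  reg_dir <- truth$regulated_genes
  td_dir <- truth$tissue_dependent_genes

  baseline <- with_seed(derive_seed(config$seed, 101L),
                        setNames(rnorm(length(genes), 7, 1), genes))

  lines <- config$cell_lines
  cl_values <- NULL; cl_labels <- character()
  for (i in seq_len(nrow(lines))) {
    nrep <- lines$n_expr_replicates[i]
    mu <- baseline
    if (lines$her2_status[i] == "+" && length(reg_dir)) {
      mu[names(reg_dir)] <- mu[names(reg_dir)] +
        ifelse(reg_dir == "up", eff, -eff)
    }
    vals <- with_seed(derive_seed(config$seed, 200L + i), {
      matrix(mu, nrow = length(genes), ncol = nrep) +
        matrix(rnorm(length(genes) * nrep, 0, ns), nrow = length(genes))
    })
    colnames(vals) <- paste0(lines$name[i], "_R", seq_len(nrep))
    cl_values <- cbind(cl_values, vals)
    cl_labels <- c(cl_labels, rep(lines$name[i], nrep))
  }
  rownames(cl_values) <- genes
  names(cl_labels) <- colnames(cl_values)

  beta <- setNames(numeric(length(genes)), genes)
  if (length(td_dir)) {
    beta[names(td_dir)] <- ifelse(td_dir == "up", 1, -1) *
      eff / strata_gap(0.35)
  }
  cohorts <- lapply(seq_len(config$n_cohorts), function(ci) {
    nsamp <- config$cohort_sizes[ci]
    with_seed(derive_seed(config$seed, 300L + ci), {
      her2 <- rnorm(nsamp)
      vals <- outer(baseline, rep(1, nsamp)) + outer(beta, her2) +
        matrix(rnorm(length(genes) * nsamp, 0, ns), nrow = length(genes))
      # marker gene: tracks the gradient exactly in the noiseless world
      vals <- rbind(vals, outer(1, her2) + rnorm(nsamp, 0, ns / 5))
      rownames(vals) <- c(genes, config$her2_gene)
      # per-cohort, per-gene affine distortion
      sc <- exp(runif(nrow(vals), -0.3, 0.3))
      sh <- rnorm(nrow(vals), 0, 0.5)
      vals <- vals * sc + sh
      colnames(vals) <- sprintf("C%d_S%03d", ci, seq_len(nsamp))
      list(values = vals,
           labels = setNames(rep(paste0("cohort", ci), nsamp),
                             colnames(vals)))
    })
  })
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  list(cell_lines = list(values = cl_values, labels = cl_labels),
       cohorts = cohorts)
}

#' Write a simulated dataset to plain-text files
#'
#' Probe tables and expression matrices go to TSV, the promoter
#' annotation to a BED-like TSV (gene, window start/end relative to
#' the TSS) and the ground truth to JSON.
#'
#' @param sim result of [simulate_chipchip()].
#' @param expr result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @param config the [sim_config()] used.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, expr, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (line in names(sim$probes)) {
    write_tsv(sim$probes[[line]],
              file.path(dir, paste0("probes_", line, ".tsv")))
  }
  ann <- data.frame(gene_id = sim_gene_ids(config),
                    window_start = config$promoter_window[1],
                    window_end = config$promoter_window[2])
  write_tsv(ann, file.path(dir, "promoters.tsv"))
  write_expression_tsv(expr$cell_lines$values, expr$cell_lines$labels,
                       file.path(dir, "expression_cell_lines.tsv"))
  for (co in names(expr$cohorts)) {
    write_expression_tsv(expr$cohorts[[co]]$values, expr$cohorts[[co]]$labels,
                         file.path(dir, paste0("expression_", co, ".tsv")))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(bound_genes_per_line = truth$bound_genes_per_line,
         regulated_genes = as.list(truth$regulated_genes),
         poised_genes = truth$poised_genes,
         tissue_dependent_genes = as.list(truth$tissue_dependent_genes),
         stalled_genes = truth$stalled_genes),
    file.path(dir, "ground_truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
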