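# End-to-end pipeline: simulate (or load) -> binding calls -> cell-line
# and tumor differential expression -> concordance -> cascade, with a
# run manifest recording seeds, versions and planted-truth recovery.

#' Pipeline configuration
#'
#' @param outdir output directory for all artifacts.
#' @param sim a [sim_config()]; the data source of the run.
#' @param binding a [binding_config()].
#' @param de a [de_config()].
#' @param rounds_kappa rounds for the kappa permutation null.
#' @param rounds_overlap rounds for the overlap resampling test.
#' @param require_all_regulated passed to [classify_cascade()].
#' @param seed master seed for the resampling stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("pol2run"),
                            sim = sim_config(),
                            binding = binding_config(),
                            de = de_config(),
                            rounds_kappa = 1000,
                            rounds_overlap = 10000,
                            require_all_regulated = FALSE,
                            seed = 1) {
  structure(list(outdir = outdir, sim = sim, binding = binding, de = de,
                 rounds_kappa = check_count(rounds_kappa, "rounds_kappa"),
                 rounds_overlap = check_count(rounds_overlap, "rounds_overlap"),
                 require_all_regulated = isTRUE(require_all_regulated),
                 seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full pipeline on a simulated dataset
#'
#' Stages: simulate ChIP-chip and expression data; per-line binding
#' summaries; quantile-normalized cell-line DE (each HER2-positive
#' line vs the control); per-cohort standardization, merge and
#' HER2-stratified tumor DE; per-comparison concordance (direction
#' table, kappa, permutation null) plus the cell-line/tumor overlap
#' resampling test; classification cascade.  All artifacts are written
#' under `config$outdir` together with a JSON manifest holding seeds,
#' class counts and sensitivity/specificity/FDR of poised-set recovery
#' against the planted truth.  Identical configuration reproduces
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every intermediate result (`sim`,
#'   `expr`, `binding`, `cellline_de`, `tumor_de`, `concordance`,
#'   `overlap`, `cascade`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sim <- stage("simulate", simulate_chipchip(config$sim))
  expr <- stage("simulate", simulate_expression(config$sim, sim$truth))
  stage("simulate", write_simulation(sim, expr, file.path(outdir, "inputs"),
                                     config$sim))

  summaries <- stage("callbind", {
    out <- lapply(sim$probes, summarize_binding, config = config$binding)
    for (line in names(out)) {
      write_tsv(out[[line]],
                file.path(outdir, paste0("binding_", line, ".tsv")))
    }
    out
  })

  lines <- config$sim$cell_lines
  pos_lines <- lines$name[lines$her2_status == "+"]
  ctrl_lines <- lines$name[lines$her2_status == "-"]

  cellline_de <- stage("de", {
    cl <- expr$cell_lines
    norm <- quantile_normalize(cl$values)
    out <- lapply(pos_lines, function(line) {
      keep <- cl$labels %in% c(line, ctrl_lines)
      grp <- ifelse(cl$labels[keep] == line, "pos", "neg")
      de <- moderated_t(norm[, keep, drop = FALSE], grp, positive = "pos",
                        config = config$de)
      write_tsv(de, file.path(outdir, paste0("de_", line, ".tsv")))
      de
    })
    names(out) <- pos_lines
    out
  })

  tumor <- stage("de", {
    std <- lapply(expr$cohorts, function(co) {
      suppressWarnings(standardize_genes(co$values,
                                         sd_mode = config$de$sd_mode))
    })
    merged <- merge_cohorts(std)
    strata <- stratify_by_gene(merged$values, config$sim$her2_gene,
                               q = config$de$stratify_quantile)
    keep <- c(strata$positive, strata$negative)
    grp <- ifelse(keep %in% strata$positive, "pos", "neg")
    mat <- merged$values[setdiff(rownames(merged$values),
                                 norm_gene_ids(config$sim$her2_gene)),
                         keep, drop = FALSE]
    de <- moderated_t(mat, grp, positive = "pos", config = config$de)
    write_tsv(de, file.path(outdir, "de_tumor.tsv"))
    list(de = de, merged = merged, strata = strata)
  })

  concordance <- stage("concord", {
    # mirror the published design: the tumor p<alpha gene count sets k,
    # and each cell line contributes its top-k most significant genes;
    # k is floored at a quarter of the universe so the comparison stays
    # populated in small simulations
    k <- max(sum(tumor$de$significant),
             ceiling(0.25 * nrow(tumor$de)))
    out <- lapply(pos_lines, function(line) {
      cl_de <- cellline_de[[line]]
      cl_de$significant <- rank(cl_de$p, ties.method = "first") <= k
      tab <- tryCatch(direction_table(cl_de, tumor$de),
                      error = function(e) NULL)
      if (is.null(tab)) {
        return(list(table = NULL, kappa = NA, note = "empty overlap"))
      }
      kap <- cohens_kappa(tab)
      null <- kappa_permutation_null(
        universe_a = cl_de$gene_id,
        universe_b = tumor$de$gene_id,
        de_b_directions = sig_dirs(tumor$de),
        n_draw = k,
        rounds = config$rounds_kappa,
        seed = derive_seed(config$seed, 11L))
      list(table = unclass(tab)[c("a", "b", "c", "d", "n")],
           top_k = k, kappa = kap$kappa, se = kap$se, se_alt = kap$se_alt,
           z = kap$z, p = kap$p,
           null_mean = null$mean, null_sd = null$sd,
           null_rounds = null$rounds, null_seed = null$seed)
    })
    names(out) <- pos_lines
    jsonlite::write_json(out, file.path(outdir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  overlap <- stage("concord", {
    de1 <- cellline_de[[1L]]
    ov <- overlap_resampling_test(
      list_a = de1$gene_id[de1$significant],
      universe_a = de1$gene_id,
      list_b = tumor$de$gene_id[tumor$de$significant],
      universe_b = tumor$de$gene_id,
      rounds = config$rounds_overlap,
      seed = derive_seed(config$seed, 12L))
    jsonlite::write_json(
      unclass(ov)[c("observed_overlap", "null_mean", "p_empirical",
                    "p_ratio", "rounds", "seed")],
      file.path(outdir, "overlap.json"), auto_unbox = TRUE, digits = NA)
    ov
  })

  cascade <- stage("classify", {
    her2 <- setNames(lines$her2_status, lines$name)
    reg <- build_regulon(summaries, her2)
    casc <- classify_cascade(reg, cellline_de, tumor$de,
                             require_all = config$require_all_regulated)
    write_cascade(casc, file.path(outdir, "cascade"))
    casc
  })

  manifest <- stage("manifest", {
    truth_poised <- sim$truth$poised_genes
    called <- cascade$poised
    tp <- length(intersect(called, truth_poised))
    man <- list(
      package_version = as.character(utils::packageVersion("pol2regulon")),
      seed = config$seed, sim_seed = config$sim$seed,
      rounds_kappa = config$rounds_kappa,
      rounds_overlap = config$rounds_overlap,
      counts = as.list(cascade$counts),
      poised_recovery = list(
        truth_size = length(truth_poised), called_size = length(called),
        sensitivity = if (length(truth_poised)) tp / length(truth_poised) else NA,
        fdr = if (length(called)) 1 - tp / length(called) else NA))
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(sim = sim, expr = expr, binding = summaries,
                 cellline_de = cellline_de, tumor_de = tumor$de,
                 concordance = concordance, overlap = overlap,
                 cascade = cascade, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic dataset only) and
#' `run` (full pipeline).  Flags: `--outdir`, `--seed`, `--alpha`,
#' `--rounds`, `--genes`.  Exit codes: 0 ok, 1 input error, 2 stage
#' failure.  Installed as `inst/cli/pol2regulon.R`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pol2regulon.R <simulate|run> [--outdir DIR] [--seed N] [--alpha A] [--rounds N] [--genes N]"
  if (length(args) < 1L || !args[1L] %in% c("simulate", "run")) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(flag, default, cast = identity) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) cast(args[i + 1L]) else default
  }
  parsed <- tryCatch(list(
    cmd = args[1L],
    outdir = opt("--outdir", file.path(getwd(), "pol2regulon_out")),
    seed = opt("--seed", 1, as.numeric),
    alpha = opt("--alpha", 0.05, as.numeric),
    rounds = opt("--rounds", 1000, as.numeric),
    genes = opt("--genes", 600, as.numeric)
  ), warning = function(w) NULL, error = function(e) NULL)
  if (is.null(parsed) || is.na(parsed$seed) || is.na(parsed$alpha)) {
    message(usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    sim <- sim_config(n_genes = parsed$genes, seed = parsed$seed)
    if (parsed$cmd == "simulate") {
      s <- simulate_chipchip(sim)
      e <- simulate_expression(sim, s$truth)
      write_simulation(s, e, parsed$outdir, sim)
    } else {
      cfg <- pipeline_config(outdir = parsed$outdir, sim = sim,
                             de = de_config(alpha = parsed$alpha),
                             rounds_kappa = parsed$rounds,
                             rounds_overlap = parsed$rounds,
                             seed = parsed$seed)
      run_pipeline(cfg)
    }
    message("artifacts written to ", parsed$outdir)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    2L
  })
  invisible(status)
}
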