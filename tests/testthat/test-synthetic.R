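# Synthetic-data generator: probe grids, determinism, planted-truth
# invariants, null configurations and planted-signal recovery.

test_that("probe grid matches the window arithmetic", {
  cfg <- sim_config(n_genes = 5)
  sim <- simulate_chipchip(cfg)
  counts <- table(sim$probes$CTRL$gene_id)
  expect_true(all(counts == 38))  # (5000+2500)/200 grid, inclusive start
  expect_true(all(sim$probes$CTRL$offset_nt >= -5000 &
                    sim$probes$CTRL$offset_nt <= 2500))
})

test_that("configuration errors are raised", {
  expect_error(sim_config(probe_spacing = 0), "positive")
  expect_error(sim_config(peak_width = -1), "positive")
  expect_error(sim_config(cohort_sizes = c(10, 10)), "length")
  expect_error(sim_config(fraction_bound_in_her2pos = 1.2), "fractions")
  bad_reps <- sim_config(n_genes = 10)
  bad_reps$cell_lines$n_expr_replicates <- 1L
  expect_error(simulate_expression(bad_reps, simulate_chipchip(bad_reps)$truth),
               ">= 2")
})

test_that("identical seeds give identical output; different seeds differ", {
  a <- simulate_chipchip(sim_config(n_genes = 40, seed = 3))
  b <- simulate_chipchip(sim_config(n_genes = 40, seed = 3))
  d <- simulate_chipchip(sim_config(n_genes = 40, seed = 4))
  expect_identical(a, b)
  expect_false(identical(a$probes, d$probes))
  ea <- simulate_expression(sim_config(n_genes = 40, seed = 3), a$truth)
  eb <- simulate_expression(sim_config(n_genes = 40, seed = 3), b$truth)
  expect_identical(ea, eb)
})

test_that("planted ground truth satisfies its invariants", {
  for (seed in 1:3) {
    cfg <- sim_config(n_genes = 50 + 17 * seed, seed = seed,
                      fraction_bound_in_her2pos = 0.1 * seed)
    truth <- simulate_chipchip(cfg)$truth
    pos <- cfg$cell_lines$name[cfg$cell_lines$her2_status == "+"]
    for (line in pos) {
      expect_true(all(truth$poised_genes %in%
                        truth$bound_genes_per_line[[line]]))
    }
    expect_true(all(names(truth$tissue_dependent_genes) %in%
                      truth$poised_genes))
    expect_length(intersect(names(truth$regulated_genes),
                            truth$poised_genes), 0)
    expect_true(all(truth$tissue_dependent_genes %in% c("up", "down")))
  }
})

test_that("null ChIP configuration yields no called binders and the
           site rate matches the rule's chance level", {
  cfg <- sim_config(n_genes = 150, peak_height = 0, seed = 21)
  sim <- simulate_chipchip(cfg)
  summ <- summarize_binding(sim$probes$LINE_H1)
  # gene-level classification is driven by the promoter-wide p_gene,
  # which never approaches the loose cutoff on pure-noise promoters
  expect_identical(unique(summ$binder_class), "unbound")
  # spurious single sites do occur at the rule's intrinsic chance rate
  expect_gt(mean(summ$n_sites > 0), 0.3)
})

test_that("planted bound genes are recovered with few false positives", {
  # stated example: 100 genes, 20 planted, peak 3, noise 0.3
  cfg <- sim_config(n_genes = 100, fraction_bound_in_her2pos = 0.2,
                    peak_height = 3, noise_sd = 0.3, seed = 8)
  sim <- simulate_chipchip(cfg)
  summ <- summarize_binding(sim$probes$LINE_H1)
  called <- summ$gene_id[summ$binder_class != "unbound"]
  planted <- sim$truth$bound_genes_per_line$LINE_H1
  expect_gte(length(intersect(called, planted)), 19)
  expect_lte(length(setdiff(called, planted)), 2)
  # the control line carries no signal; chance calls stay rare
  ctrl <- summarize_binding(sim$probes$CTRL)
  expect_lte(sum(ctrl$binder_class != "unbound"), 2)
})

test_that("expression: planted directions and replicate structure", {
  cfg <- sim_config(n_genes = 80, seed = 13)
  sim <- simulate_chipchip(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  expect_identical(ncol(expr$cell_lines$values),
                   sum(cfg$cell_lines$n_expr_replicates))
  expect_identical(vapply(expr$cohorts, function(co) ncol(co$values), 1L),
                   setNames(as.integer(cfg$cohort_sizes),
                            names(expr$cohorts)))
  # a tissue-dependent "up" gene has positive logFC between HER2 strata
  merged <- merge_cohorts(lapply(expr$cohorts, function(co)
    standardize_genes(co$values)))
  strata <- stratify_by_gene(merged$values, cfg$her2_gene)
  td <- sim$truth$tissue_dependent_genes
  for (g in names(td)) {
    lfc <- mean(merged$values[g, strata$positive]) -
      mean(merged$values[g, strata$negative])
    expect_true((td[[g]] == "up") == (lfc > 0), info = g)
  }
  # poised genes show no cell-line group difference beyond noise
  poised <- setdiff(sim$truth$poised_genes, names(td))
  cl <- expr$cell_lines
  grp_pos <- cl$labels %in% c("LINE_H1", "LINE_H2", "LINE_H3")
  lfc_poised <- rowMeans(cl$values[poised, grp_pos, drop = FALSE]) -
    rowMeans(cl$values[poised, !grp_pos, drop = FALSE])
  expect_lt(max(abs(lfc_poised)), 1)
})

test_that("null expression configuration flags ~alpha of genes", {
  cfg <- sim_config(n_genes = 400, effect_size_de = 0, seed = 17)
  sim <- simulate_chipchip(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  cl <- expr$cell_lines
  keep <- cl$labels %in% c("LINE_H1", "CTRL")
  de <- moderated_t(cl$values[, keep], cl$labels[keep], positive = "LINE_H1")
  rate <- mean(de$p < 0.05)
  bound99 <- 2.576 * sqrt(0.05 * 0.95 / nrow(de))
  expect_lt(abs(rate - 0.05), bound99 + 1e-9)
})

test_that("merged-cohort DE recovers planted tissue-dependent genes", {
  # stated example: 200 genes, 30 tissue-dependent, effect 1.5 sd,
  # 5 cohorts x 60 samples -> >= 27/30 recovered at p < 0.05
  cfg <- sim_config(n_genes = 200, cohort_sizes = rep(60, 5),
                    fraction_bound_in_her2pos = 0.5,
                    fraction_regulated_of_bound = 0,
                    fraction_poised_expressed_in_tumor = 0.3,
                    effect_size_de = 1.5, seed = 23)
  sim <- simulate_chipchip(cfg)
  truth <- sim$truth
  expect_length(names(truth$tissue_dependent_genes), 30)
  expr <- simulate_expression(cfg, truth)
  merged <- merge_cohorts(lapply(expr$cohorts, function(co)
    standardize_genes(co$values)))
  strata <- stratify_by_gene(merged$values, cfg$her2_gene)
  keep <- c(strata$positive, strata$negative)
  grp <- ifelse(keep %in% strata$positive, "pos", "neg")
  mat <- merged$values[setdiff(rownames(merged$values), cfg$her2_gene), keep]
  de <- moderated_t(mat, grp, positive = "pos")
  hits <- de$gene_id[de$significant]
  expect_gte(length(intersect(hits, names(truth$tissue_dependent_genes))), 27)
})

test_that("write_simulation round-trips through plain text", {
  cfg <- sim_config(n_genes = 12, seed = 2)
  sim <- simulate_chipchip(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  dir <- withr::local_tempdir()
  write_simulation(sim, expr, dir, cfg)
  probes <- read_tsv(file.path(dir, "probes_LINE_H1.tsv"))
  expect_equal(probes$log_ratio, sim$probes$LINE_H1$log_ratio,
               tolerance = 1e-12)
  rt <- read_expression_tsv(file.path(dir, "expression_cell_lines.tsv"))
  expect_equal(rt$values, expr$cell_lines$values, tolerance = 1e-12)
  expect_identical(unname(rt$labels), unname(expr$cell_lines$labels))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(unlist(truth$poised_genes)),
                   sort(sim$truth$poised_genes))
})
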