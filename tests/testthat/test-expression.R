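# Expression module: quantile normalization, moderated t,
# standardization, cohort merging, stratification and ddCt.

test_that("quantile_normalize matches its definition and the limma oracle", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(quantile_normalize(m), m)
  m2 <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m2)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  expect_error(quantile_normalize(matrix(1:3)), ">= 2 samples")

  set.seed(31)
  r <- matrix(rnorm(300), 50, 6)
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  # independent implementation in limma (ties = TRUE path included)
  r[3, ] <- r[3, 1]  # inject ties across part of a row
  r[4, 2] <- r[5, 2]
  expect_equal(unname(quantile_normalize(r)),
               unname(limma::normalizeQuantiles(r, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("moderated_t reduces to the pooled t at d0 = 0", {
  set.seed(5)
  mat <- matrix(rnorm(60 * 8), 60, 8,
                dimnames = list(sprintf("g%02d", 1:60), NULL))
  grp <- rep(c("pos", "neg"), each = 4)
  de <- moderated_t(mat, grp, positive = "pos",
                    config = de_config(d0 = 0, s0_2 = 1))
  for (i in c(1, 17, 60)) {
    tt <- t.test(mat[i, grp == "pos"], mat[i, grp == "neg"],
                 var.equal = TRUE)
    expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$logFC[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("moderated_t shrinks fully to s0^2 at d0 = Inf", {
  set.seed(6)
  mat <- matrix(rnorm(40 * 6), 40, 6)
  grp <- rep(c("A", "B"), each = 3)
  de <- moderated_t(mat, grp, positive = "A",
                    config = de_config(d0 = Inf, s0_2 = 0.25))
  expect_equal(de$t_mod, de$logFC / sqrt(0.25 * (1 / 3 + 1 / 3)),
               tolerance = 1e-12)
  expect_equal(de$p, 2 * pnorm(-abs(de$t_mod)), tolerance = 1e-12)
})

test_that("moderated_t agrees with limma as an independent oracle", {
  set.seed(7)
  mat <- matrix(rnorm(500 * 10, sd = rep(sqrt(rchisq(500, 4) / 4), 10)),
                500, 10, dimnames = list(sprintf("g%03d", 1:500), NULL))
  grp <- rep(c("pos", "neg"), each = 5)
  fit <- limma::lmFit(mat, cbind(1, grp == "pos"))
  eb <- limma::eBayes(fit)
  # hyperparameter estimation matches limma's moment matching closely
  de_est <- moderated_t(mat, grp, positive = "pos")
  expect_equal(attr(de_est, "d0"), eb$df.prior, tolerance = 0.05)
  expect_equal(attr(de_est, "s0_2"), eb$s2.prior, tolerance = 0.05)
  # with the prior fixed at limma's values the statistics match exactly
  de <- moderated_t(mat, grp, positive = "pos",
                    config = de_config(d0 = eb$df.prior, s0_2 = eb$s2.prior))
  expect_equal(de$t_mod, unname(eb$t[, 2]), tolerance = 1e-9)
  expect_equal(de$p, unname(eb$p.value[, 2]), tolerance = 1e-9)
  expect_equal(de$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-9)
})

test_that("moderated_t input validation and direction mapping", {
  mat <- matrix(rnorm(20), 4, 5)
  expect_error(moderated_t(mat, c("a", "a", "b", "b", "b"), positive = "x"),
               "unknown positive")
  expect_error(moderated_t(mat, c("a", "a", "a", "a", "b")), ">= 2")
  expect_error(moderated_t(mat, rep("a", 5)), "two groups")
  m <- rbind(up = c(2, 2, 0, 0), down = c(0, 0, 2, 2), zero = c(1, 1, 1, 1))
  de <- moderated_t(m, c("p", "p", "n", "n"), positive = "p",
                    config = de_config(d0 = 4, s0_2 = 0.1))
  expect_identical(de$direction, c("up", "down", "zero"))
  # logFC sign invariant under common affine rescaling of all samples
  de2 <- moderated_t(3 * m + 5, c("p", "p", "n", "n"), positive = "p",
                     config = de_config(d0 = 4, s0_2 = 0.1))
  expect_identical(de2$direction, de$direction)
})

test_that("standardize_genes centers and scales per convention", {
  m <- rbind(g1 = c(2, 4, 6))
  expect_equal(unname(standardize_genes(m)[1, ]), c(-1, 0, 1))
  expect_equal(unname(standardize_genes(m, "population")[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # idempotence and affine invariance (up to sign of the scale)
  set.seed(8)
  r <- matrix(rnorm(50), 5, 10)
  s1 <- standardize_genes(r)
  expect_equal(standardize_genes(s1), s1, tolerance = 1e-12)
  expect_equal(standardize_genes(2.7 * r - 3), s1, tolerance = 1e-12)
  expect_true(all(abs(rowMeans(s1)) < 1e-10))
  expect_equal(apply(s1, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_warning(out <- standardize_genes(rbind(r, const = 1)), "constant")
  expect_identical(nrow(out), 5L)
})

test_that("merge_cohorts intersects gene sets and keeps cohort labels", {
  m1 <- matrix(rnorm(9), 3, 3, dimnames = list(c("A", "B", "C"),
                                               paste0("s", 1:3)))
  m2 <- matrix(rnorm(8), 4, 2, dimnames = list(c("b", "c ", "D", "E"),
                                               paste0("t", 1:2)))
  merged <- merge_cohorts(list(one = m1, two = m2))
  expect_setequal(rownames(merged$values), c("B", "C"))
  expect_identical(ncol(merged$values), 5L)
  expect_identical(unname(merged$labels),
                   c(rep("one", 3), rep("two", 2)))
  expect_error(merge_cohorts(list(m1)), ">= 2")
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("X", "Y"), c("u1", "u2")))
  expect_error(merge_cohorts(list(m1, m3)), "empty gene intersection")
})

test_that("stratify_by_gene takes the floor(q*n) extremes", {
  set.seed(9)
  m <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("HER2", "other"), sprintf("s%02d", 1:20)))
  st <- stratify_by_gene(m, "her2", q = 0.35)
  expect_length(st$positive, 7)
  expect_length(st$negative, 7)
  expect_length(intersect(st$positive, st$negative), 0)
  expect_true(min(m["HER2", st$positive]) >= max(m["HER2",
    setdiff(colnames(m), c(st$positive, st$negative))]))
  # q = 0.5 on even n with no ties partitions all samples
  st2 <- stratify_by_gene(m, "HER2", q = 0.5)
  expect_setequal(c(st2$positive, st2$negative), colnames(m))
  expect_error(stratify_by_gene(m, "absent"), "not found")
  expect_error(stratify_by_gene(m[, 1:2], "HER2", q = 0.3), "< 1")
})

test_that("ddct_fold_change matches its closed form", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)   # equal dCt
  expect_equal(ddct_fold_change(20, 16, 22, 17), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(25, 17, 22, 17), 0.125)  # ddCt = 3
  expect_error(ddct_fold_change(-1, 15, 22, 17), "positive")
})

test_that("top_k selection at the p<alpha count reproduces the p<alpha set", {
  set.seed(10)
  mat <- matrix(rnorm(800 * 8), 800, 8,
                dimnames = list(sprintf("g%03d", 1:800), NULL))
  grp <- rep(c("p", "n"), each = 4)
  de_a <- moderated_t(mat, grp, positive = "p")
  k <- sum(de_a$significant)
  de_k <- moderated_t(mat, grp, positive = "p",
                      config = de_config(top_k = k))
  expect_setequal(de_a$gene_id[de_a$significant],
                  de_k$gene_id[de_k$significant])
})

test_that("quantile_normalize and standardize_genes are each idempotent", {
  # note: the *composition* is not idempotent (row standardization
  # breaks the equal-column-distribution property again), so the two
  # fixed points are asserted separately
  set.seed(11)
  r <- matrix(rnorm(120), 20, 6)
  qn <- quantile_normalize(r)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  st <- standardize_genes(r)
  expect_equal(standardize_genes(st), st, tolerance = 1e-12)
})
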