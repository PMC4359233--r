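# Directional concordance between two differential-expression analyses
# (Cohen's kappa with a random-gene permutation null) and gene-list
# overlap significance by resampling.

#' Cross-tabulate up/down directions of two DE tables
#'
#' Both tables are restricted to their significant genes with a
#' non-zero direction; counts are taken over the intersection of the
#' two gene sets.
#'
#' @param de_a,de_b [moderated_t()] results (or any data frame with
#'   `gene_id`, `direction`, `significant`).
#' @return A list of class `direction_table` with counts `a`
#'   (up in both), `b` (up in A / down in B), `c` (down in A / up in
#'   B), `d` (down in both) and `n = a+b+c+d`.
#' @export
direction_table <- function(de_a, de_b) {
  pick <- function(de) {
    de <- de[de$significant & de$direction %in% c("up", "down"), ]
    setNames(de$direction, norm_gene_ids(de$gene_id))
  }
  da <- pick(de_a)
  db <- pick(de_b)
  genes <- intersect(names(da), names(db))
  if (length(genes) == 0L) stop2("empty overlap between the two DE tables")
  da <- da[genes]; db <- db[genes]
  out <- list(a = sum(da == "up" & db == "up"),
              b = sum(da == "up" & db == "down"),
              c = sum(da == "down" & db == "up"),
              d = sum(da == "down" & db == "down"))
  out$n <- out$a + out$b + out$c + out$d
  structure(out, class = "direction_table")
}

as_direction_table <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop2("counts must be non-negative")
  if (any(c(a, b, c, d) != round(c(a, b, c, d)))) stop2("counts must be whole")
  a <- as.integer(a); b <- as.integer(b)
  c <- as.integer(c); d <- as.integer(d)
  n <- a + b + c + d
  if (n < 1) stop2("need n >= 1")
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "direction_table")
}

#' Cohen's kappa for a 2x2 direction table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with
#' observed agreement `po = (a+d)/n` and chance agreement `pe` from the
#' marginal products.  The primary standard error is the large-sample
#' null-hypothesis (Fleiss) form, matching the use of `z = kappa/se`
#' as a significance test; Cohen's alternative-hypothesis standard
#' error is reported alongside as `se_alt`.
#'
#' @param table a [direction_table()], or the count `a` when `b`, `c`,
#'   `d` are given.
#' @param b,c,d optional counts when `table` is the scalar `a`.
#' @return A list of class `kappa_result`: `kappa`, `se`, `se_alt`,
#'   `z`, `p` (one-sided upper tail), `po`, `pe`, `n`.  Degenerate
#'   marginals (`pe = 1`) yield `kappa = NA` with `note`.
#' @export
cohens_kappa <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!inherits(table, "direction_table")) {
    table <- as_direction_table(table, b, c, d)
  }
  n <- table$n
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  po <- (a + d) / n
  r1 <- (a + b) / n; r2 <- (c + d) / n  # row marginals (side A up/down)
  c1 <- (a + c) / n; c2 <- (b + d) / n  # column marginals (side B)
  pe <- r1 * c1 + r2 * c2
  if (pe >= 1) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          se_alt = NA_real_, z = NA_real_, p = NA_real_,
                          po = po, pe = pe, n = n,
                          note = "degenerate marginals (pe = 1)"),
                     class = "kappa_result"))
  }
  kappa <- (po - pe) / (1 - pe)
  # inner term can dip below 0 by rounding on tiny extreme tables
  v <- pe + pe^2 - (r1 * c1 * (r1 + c1) + r2 * c2 * (r2 + c2))
  se <- if (v > 0) sqrt(v) / ((1 - pe) * sqrt(n)) else NA_real_
  se_alt <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- kappa / se
  structure(list(kappa = kappa, se = se, se_alt = se_alt, z = z,
                 p = pnorm(z, lower.tail = FALSE), po = po, pe = pe,
                 n = n, note = NULL),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Cohen's kappa:", format(x$kappa, digits = 4),
      " (po =", format(x$po, digits = 4),
      ", pe =", format(x$pe, digits = 4), ", n =", x$n, ")\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n") else {
    cat("  se0 =", format(x$se, digits = 4),
        " z =", format(x$z, digits = 4),
        " p =", format(x$p, digits = 3), "\n")
  }
  invisible(x)
}

#' Random-gene permutation null for kappa
#'
#' Each round draws `n_draw` genes from `universe_a` without
#' replacement, assigns them random directions (fair coin per gene, or
#' a permutation of the observed side-A directions), intersects with
#' the side-B direction calls and computes kappa.  Rounds with an empty
#' overlap or degenerate marginals are recorded as `NA`, not dropped.
#'
#' @param universe_a character vector of genes side A can draw from.
#' @param universe_b character vector containing the side-B universe
#'   (checked to cover `names(de_b_directions)`).
#' @param de_b_directions named character vector (`up`/`down`) of the
#'   fixed side-B calls.
#' @param n_draw genes drawn per round.
#' @param rounds number of rounds (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @param mode `"coin"` (default) or `"permute"`.
#' @param de_a_directions observed side-A directions, required for
#'   `mode = "permute"`.
#' @return `list(values, mean, sd, n_missing, rounds, seed)`.
#' @export
kappa_permutation_null <- function(universe_a, universe_b, de_b_directions,
                                   n_draw, rounds = 1000, seed = 1,
                                   mode = c("coin", "permute"),
                                   de_a_directions = NULL) {
  mode <- match.arg(mode)
  universe_a <- unique(norm_gene_ids(universe_a))
  names(de_b_directions) <- norm_gene_ids(names(de_b_directions))
  if (!all(names(de_b_directions) %in% norm_gene_ids(universe_b))) {
    stop2("de_b_directions must lie inside universe_b")
  }
  n_draw <- check_count(n_draw, "n_draw")
  rounds <- check_count(rounds, "rounds")
  if (n_draw > length(universe_a)) stop2("n_draw exceeds |universe_a|")
  if (mode == "permute" && is.null(de_a_directions)) {
    stop2("mode = 'permute' needs de_a_directions")
  }
  values <- with_seed(seed, vapply(seq_len(rounds), function(r) {
    drawn <- sample(universe_a, n_draw)
    dirs <- if (mode == "coin") {
      sample(c("up", "down"), n_draw, replace = TRUE)
    } else {
      sample(as.character(de_a_directions), n_draw, replace = TRUE)
    }
    names(dirs) <- drawn
    genes <- intersect(drawn, names(de_b_directions))
    if (length(genes) == 0L) return(NA_real_)
    da <- dirs[genes]; db <- de_b_directions[genes]
    k <- cohens_kappa(sum(da == "up" & db == "up"),
                      sum(da == "up" & db == "down"),
                      sum(da == "down" & db == "up"),
                      sum(da == "down" & db == "down"))
    k$kappa
  }, numeric(1)))
  list(values = values,
       mean = mean(values, na.rm = TRUE),
       sd = sd(values, na.rm = TRUE),
       n_missing = sum(is.na(values)),
       rounds = rounds, seed = seed, mode = mode)
}

#' Gene-list overlap significance by resampling
#'
#' Draws `|list_a|` genes from `universe_a` and `|list_b|` from
#' `universe_b` each round and counts the intersection.  Reports the
#' add-one empirical tail probability (primary) and, flagged as
#' non-standard, the ratio estimator `null_mean / observed_overlap`
#' used historically for this comparison.
#'
#' @param list_a,list_b observed gene lists (subsets of their
#'   universes).
#' @param universe_a,universe_b the universes sampled from.
#' @param rounds resampling rounds (default 10000).
#' @param seed RNG seed, recorded in the result.
#' @return A list of class `overlap_test`: `observed_overlap`,
#'   `null_mean`, `p_empirical`, `p_ratio`, `null_overlaps`, `rounds`,
#'   `seed`.
#' @export
overlap_resampling_test <- function(list_a, universe_a, list_b, universe_b,
                                    rounds = 10000, seed = 1) {
  rounds <- check_count(rounds, "rounds")
  list_a <- unique(norm_gene_ids(list_a))
  list_b <- unique(norm_gene_ids(list_b))
  universe_a <- unique(norm_gene_ids(universe_a))
  universe_b <- unique(norm_gene_ids(universe_b))
  if (!all(list_a %in% universe_a)) stop2("list_a must be a subset of universe_a")
  if (!all(list_b %in% universe_b)) stop2("list_b must be a subset of universe_b")
  observed <- length(intersect(list_a, list_b))
  if (length(intersect(universe_a, universe_b)) == 0L && observed > 0L) {
    stop2("inconsistent input: disjoint universes but non-empty list overlap")
  }
  # integer coding over the union keeps the per-round cost linear
  union_ids <- union(universe_a, universe_b)
  ua <- match(universe_a, union_ids)
  ub <- match(universe_b, union_ids)
  ka <- length(list_a); kb <- length(list_b)
  member <- logical(length(union_ids))
  null_overlaps <- with_seed(seed, vapply(seq_len(rounds), function(r) {
    xa <- ua[sample.int(length(ua), ka)]
    xb <- ub[sample.int(length(ub), kb)]
    member[xa] <- TRUE
    hits <- sum(member[xb])
    member[xa] <- FALSE
    hits
  }, numeric(1)))
  null_mean <- mean(null_overlaps)
  structure(list(observed_overlap = observed,
                 null_mean = null_mean,
                 p_empirical = (1 + sum(null_overlaps >= observed)) /
                   (rounds + 1),
                 p_ratio = if (observed > 0) null_mean / observed else NA_real_,
                 p_ratio_note = "ratio estimator, non-standard; prefer p_empirical",
                 null_overlaps = null_overlaps,
                 rounds = rounds, seed = seed),
            class = "overlap_test")
}
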