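# The set-algebra cascade: binding regulon -> regulated -> concordant,
# with the complement "poised" class and its tumor-responsive
# ("tissue-context-dependent") subset.

#' Build the binding regulon across cell lines
#'
#' A gene belongs to the regulon when its binder class is tight or
#' loose in **every** HER2-positive line and unbound in **every**
#' control line.  Gene universes that differ across lines are reduced
#' to their common intersection with a message.
#'
#' @param summaries named list of [summarize_binding()] results, one
#'   per cell line.
#' @param her2_status named character vector (`"+"`/`"-"`) or logical
#'   vector over the same line names.
#' @return Character vector of regulon gene ids.
#' @export
build_regulon <- function(summaries, her2_status) {
  stopifnot(length(summaries) >= 2L, !is.null(names(summaries)))
  if (is.logical(her2_status)) {
    her2_status <- ifelse(her2_status, "+", "-")
  }
  her2_status <- her2_status[names(summaries)]
  if (anyNA(her2_status)) stop2("her2_status must cover every line")
  if (!any(her2_status == "+") || !any(her2_status == "-")) {
    stop2("need >= 1 HER2-positive and >= 1 control line")
  }
  universes <- lapply(summaries, function(s) s$gene_id)
  common <- Reduce(intersect, universes)
  dropped <- length(unique(unlist(universes))) - length(common)
  if (dropped > 0L) {
    message("build_regulon: ", dropped,
            " gene(s) absent from some line; restricted to the common universe")
  }
  bound <- vapply(summaries, function(s) {
    setNames(s$binder_class %in% c("tight", "loose"), s$gene_id)[common]
  }, logical(length(common)))
  pos <- her2_status == "+"
  keep <- rowSums(bound[, pos, drop = FALSE]) == sum(pos) &
    rowSums(bound[, !pos, drop = FALSE]) == 0L
  common[keep]
}

sig_dirs <- function(de) {
  de <- de[de$significant & de$direction %in% c("up", "down"), ]
  setNames(de$direction, norm_gene_ids(de$gene_id))
}

#' Classify the regulon into its expression-defined subclasses
#'
#' Given the regulon and the cell-line differential-expression tables
#' (one per HER2-positive vs control comparison):
#'
#' * **regulated** — regulon genes significant in at least one
#'   comparison (all comparisons when `require_all = TRUE`);
#' * **concordant** — regulated genes significant with the same
#'   direction in *every* comparison;
#' * **concordant_partial** — regulated genes significant with one
#'   shared direction in exactly two of three comparisons;
#' * **poised** — the regulon minus the concordant genes;
#' * **tissue_dependent** — poised genes significant in the tumor DE
#'   table, partitioned by tumor direction.  Poised genes missing from
#'   the tumor universe are flagged `not_assayed`.
#'
#' @param regulon character vector from [build_regulon()].
#' @param cellline_de named list of [moderated_t()] tables, one per
#'   HER2-positive comparison.
#' @param tumor_de a [moderated_t()] table for the tumor comparison,
#'   or `NULL` to skip the tissue stage.
#' @param require_all if `TRUE`, "regulated" demands significance in
#'   every comparison.
#' @return A list of class `classification_cascade` with the gene
#'   sets, the `tissue_dependent` direction map and a `counts` vector.
#' @export
classify_cascade <- function(regulon, cellline_de, tumor_de = NULL,
                             require_all = FALSE) {
  stopifnot(is.list(cellline_de), length(cellline_de) >= 1L)
  regulon <- sort(unique(norm_gene_ids(regulon)))
  dir_maps <- lapply(cellline_de, sig_dirs)
  n_cmp <- length(dir_maps)

  n_sig <- vapply(regulon, function(g) {
    sum(vapply(dir_maps, function(m) g %in% names(m), logical(1)))
  }, integer(1))
  regulated <- regulon[if (require_all) n_sig == n_cmp else n_sig >= 1L]

  shared_dir <- function(g, need) {
    dirs <- unlist(lapply(dir_maps, function(m) m[g]), use.names = FALSE)
    dirs <- dirs[!is.na(dirs)]
    if (length(dirs) == need && length(unique(dirs)) == 1L) dirs[1L] else NA_character_
  }
  conc_dir <- vapply(regulated, shared_dir, character(1), need = n_cmp)
  concordant <- conc_dir[!is.na(conc_dir)]
  part_dir <- vapply(regulated, shared_dir, character(1), need = max(n_cmp - 1L, 1L))
  concordant_partial <- setdiff(names(part_dir[!is.na(part_dir)]),
                                names(concordant))

  poised <- setdiff(regulon, names(concordant))

  tissue_dependent <- character(0)
  not_assayed <- character(0)
  if (!is.null(tumor_de)) {
    tumor_universe <- norm_gene_ids(tumor_de$gene_id)
    not_assayed <- setdiff(poised, tumor_universe)
    td <- sig_dirs(tumor_de)
    tissue_dependent <- td[intersect(poised, names(td))]
  }

  out <- list(regulon = regulon,
              regulated = regulated,
              concordant = concordant,
              concordant_partial = concordant_partial,
              poised = poised,
              tissue_dependent = tissue_dependent,
              not_assayed = not_assayed)
  out$counts <- c(regulon = length(regulon),
                  regulated = length(regulated),
                  concordant = length(concordant),
                  concordant_partial = length(concordant_partial),
                  poised = length(poised),
                  tissue_dependent = length(tissue_dependent),
                  tissue_dependent_up = sum(tissue_dependent == "up"),
                  tissue_dependent_down = sum(tissue_dependent == "down"),
                  not_assayed = length(not_assayed))
  class(out) <- "classification_cascade"
  validate_cascade(out)
  out
}

# Structural invariants; every cascade is checked on construction.
validate_cascade <- function(x) {
  stopifnot(
    all(names(x$concordant) %in% x$regulated),
    all(x$regulated %in% x$regulon),
    setequal(x$poised, setdiff(x$regulon, names(x$concordant))),
    length(x$poised) + length(x$concordant) == length(x$regulon),
    all(names(x$tissue_dependent) %in% x$poised),
    sum(x$tissue_dependent == "up") + sum(x$tissue_dependent == "down") ==
      length(x$tissue_dependent)
  )
  invisible(x)
}

#' @export
print.classification_cascade <- function(x, ...) {
  cat(cascade_diagram(x), sep = "\n")
  invisible(x)
}

#' Text diagram of the cascade counts
#'
#' @param x a `classification_cascade`.
#' @return Character vector of diagram lines.
#' @export
cascade_diagram <- function(x) {
  n <- x$counts
  c(sprintf("regulon (bound in all HER2+ lines, none in control): %d",
            n[["regulon"]]),
    sprintf("|- regulated (DE in cell lines):          %d", n[["regulated"]]),
    sprintf("|   '- concordant (same direction, all):  %d  (%d up / %d down)",
            n[["concordant"]],
            sum(x$concordant == "up"), sum(x$concordant == "down")),
    sprintf("'- poised (regulon \\ concordant):         %d", n[["poised"]]),
    sprintf("    '- tissue-dependent (tumor DE):       %d  (%d up / %d down; %d not assayed)",
            n[["tissue_dependent"]], n[["tissue_dependent_up"]],
            n[["tissue_dependent_down"]], n[["not_assayed"]]))
}

#' Write the cascade to per-class TSV files plus a JSON summary
#'
#' @param cascade a `classification_cascade`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cascade <- function(cascade, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_set <- function(genes, dirs, file) {
    df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    if (!is.null(dirs)) df$direction <- unname(dirs[genes])
    write_tsv(df, file.path(dir, file))
  }
  write_set(cascade$regulon, NULL, "regulon.tsv")
  write_set(cascade$regulated, NULL, "regulated.tsv")
  write_set(names(cascade$concordant), cascade$concordant, "concordant.tsv")
  write_set(cascade$poised, NULL, "poised.tsv")
  write_set(names(cascade$tissue_dependent), cascade$tissue_dependent,
            "tissue_dependent.tsv")
  jsonlite::write_json(as.list(cascade$counts),
                       file.path(dir, "cascade_counts.json"),
                       auto_unbox = TRUE)
  writeLines(cascade_diagram(cascade), file.path(dir, "cascade_diagram.txt"))
  invisible(dir)
}
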