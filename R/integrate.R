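# Integration of the clinical candidate set with the screen resistance set:
# intersection with per-gene provenance, cell-line support breakdown, and
# the significant-and-screen-supported resistance matrix.

#' Intersect the clinical and screen resistance gene sets
#'
#' Gene symbols are uppercased and whitespace-stripped on both sides before
#' intersection; symbols present on only one side are kept in a
#' reconciliation log rather than silently dropped. Every member carries its
#' clinical association fields and its per-condition screen support.
#'
#' @param clinical A `clinical_gene_set` from [clinical_candidate_set()].
#' @param screen_union A `screen_gene_set` from [screen_resistant_union()].
#' @param results Per-condition gene results from [screen_rra()] (used for
#'   best screen p / lfc of members).
#' @return An `integrated_set`: list with `members`, `table` (per-gene
#'   clinical fields, per-condition `sel_*` flags, `n_conditions_selected`,
#'   `best_screen_p`, `best_screen_lfc`), `conditions`, and
#'   `unmatched` (symbols unique to one side).
#' @export
intersect_sets <- function(clinical, screen_union, results) {
  stopifnot(inherits(clinical, "clinical_gene_set"),
            inherits(screen_union, "screen_gene_set"))
  norm_sym <- function(x) toupper(trimws(x))
  ctab <- clinical$table
  ctab$gene <- norm_sym(ctab$gene)
  smem <- norm_sym(screen_union$members)
  support <- screen_union$support
  support$gene <- norm_sym(support$gene)

  members <- sort(intersect(ctab$gene, smem))
  if (!length(intersect(norm_sym(clinical$members), smem)) &&
      length(clinical$members) && length(smem)) {
    warn("Clinical and screen gene sets share no symbols; empty intersection.")
  }

  conds <- screen_union$conditions
  cond_ids <- condition_id(conds)
  support$condition <- condition_id(support)
  flags <- tidyr::pivot_wider(
    mutate(support[support$gene %in% members,
                   c("gene", "condition")], value = TRUE),
    names_from = "condition", values_from = "value", values_fill = FALSE,
    names_prefix = "sel_"
  )
  for (id in paste0("sel_", cond_ids)) {
    if (!id %in% names(flags)) flags[[id]] <- logical(nrow(flags))
  }
  flags <- flags[, c("gene", paste0("sel_", cond_ids))]
  best <- if (length(members)) {
    support |>
      filter(.data$gene %in% members) |>
      group_by(.data$gene) |>
      summarise(best_screen_p = min(.data$p),
                best_screen_lfc = max(.data$lfc),
                n_conditions_selected = dplyr::n(), .groups = "drop")
  } else {
    tibble(gene = character(0), best_screen_p = numeric(0),
           best_screen_lfc = numeric(0), n_conditions_selected = integer(0))
  }

  table <- ctab[match(members, ctab$gene),
                c("gene", "category", "provenance", "or_raw", "or_flag",
                  "or_corrected", "p", "q", "mut_freq")]
  table <- rename(table, clinical_p = "p", clinical_q = "q")
  table <- left_join(table, flags, by = "gene")
  table <- left_join(table, best, by = "gene")

  structure(
    list(members = members,
         table = as_tibble(table),
         conditions = conds,
         unmatched = list(clinical_only = setdiff(ctab$gene, smem),
                          screen_only = setdiff(smem, ctab$gene)),
         alpha = clinical$alpha,
         significant_subset = intersect(norm_sym(clinical$significant_subset),
                                        members)),
    class = "integrated_set"
  )
}

#' @export
print.integrated_set <- function(x, ...) {
  cat("<integrated_set> ", length(x$members),
      " genes supported by both clinical association and drug screening\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.integrated_set <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.integrated_set <- function(x, ...) {
  bd <- condition_breakdown(x)
  wide <- tidyr::pivot_wider(bd[, c("group", "n")], names_from = "group",
                             values_from = "n", names_prefix = "n_")
  dplyr::bind_cols(
    tibble(n_members = length(x$members),
           n_significant_supported = length(x$significant_subset)),
    wide
  )
}

#' Cell-line support breakdown of an integrated set
#'
#' Partitions the members by which cell lines' screens support them
#' (each `<cell line>_only` group, plus `multiple`); the groups always
#' partition the members exactly.
#'
#' @param x An `integrated_set` from [intersect_sets()].
#' @return Tibble with columns `group`, `n`, `fraction`.
#' @export
condition_breakdown <- function(x) {
  stopifnot(inherits(x, "integrated_set"))
  cond_ids <- condition_id(x$conditions)
  lines <- x$conditions$cell_line
  sel <- as.matrix(x$table[, paste0("sel_", cond_ids), drop = FALSE])
  per_gene_lines <- lapply(seq_len(nrow(sel)),
                           function(i) sort(unique(lines[sel[i, ]])))
  grp <- vapply(per_gene_lines, function(l) {
    if (length(l) > 1) "multiple" else paste0(l, "_only")
  }, character(1))
  lvls <- c(paste0(sort(unique(lines)), "_only"), "multiple")
  counts <- table(factor(grp, levels = lvls))
  tibble(group = names(counts), n = as.integer(counts),
         fraction = if (length(x$members)) {
           as.integer(counts) / length(x$members)
         } else rep(NA_real_, length(counts)))
}

#' Resistance matrix of significant, screen-supported genes
#'
#' Rows are members of the clinical significant subset that are also
#' screen-supported; columns are screened conditions; cells are selection
#' flags. Rows are annotated with cohort mutation frequency and clinical
#' Fisher p, and ordered by ascending clinical p.
#'
#' @param x An `integrated_set` from [intersect_sets()].
#' @return A `resistance_matrix`: list with `mat` (logical gene x condition
#'   matrix) and `annotations` (tibble: `gene`, `mut_freq`, `clinical_p`).
#' @export
significant_cluster <- function(x) {
  stopifnot(inherits(x, "integrated_set"))
  rows <- x$significant_subset
  cond_ids <- condition_id(x$conditions)
  tab <- x$table[match(rows, x$table$gene), , drop = FALSE]
  tab <- tab[order(tab$clinical_p, tab$gene), , drop = FALSE]
  mat <- as.matrix(tab[, paste0("sel_", cond_ids), drop = FALSE])
  mode(mat) <- "logical"
  dimnames(mat) <- list(tab$gene, cond_ids)
  structure(
    list(mat = mat,
         annotations = tibble(gene = tab$gene, mut_freq = tab$mut_freq,
                              clinical_p = tab$clinical_p)),
    class = "resistance_matrix"
  )
}

#' @export
print.resistance_matrix <- function(x, ...) {
  cat("<resistance_matrix> ", nrow(x$mat), " genes x ", ncol(x$mat),
      " conditions\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.resistance_matrix <- function(x, ...) {
  if (!nrow(x$mat)) {
    return(tibble(gene = character(0), condition = character(0),
                  selected = logical(0), mut_freq = numeric(0),
                  clinical_p = numeric(0)))
  }
  long <- as_tibble(x$mat, rownames = "gene")
  long <- tidyr::pivot_longer(long, -"gene", names_to = "condition",
                              values_to = "selected")
  left_join(long, x$annotations, by = "gene")
}
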