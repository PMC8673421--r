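# Hypergeometric over-representation analysis against GMT annotation
# collections, reporting gene ratios alongside p/q values.

#' Read a GMT annotation collection
#'
#' One term per line: term id, description, then member gene symbols, all
#' tab-separated. Gene symbols are uppercased and whitespace-stripped;
#' duplicate genes within a term are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `term`, `name`, `genes` (list column) and
#'   `size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("Empty GMT file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(paste0("GMT line(s) with fewer than 3 fields: line ",
                 paste(which(short), collapse = ", ")))
  }
  tibble(
    term = vapply(fields, `[`, character(1), 1),
    name = vapply(fields, `[`, character(1), 2),
    genes = purrr::map(fields, ~ unique(toupper(trimws(.x[-(1:2)])))),
  ) |>
    mutate(size = lengths(.data$genes))
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query gene set hits the term
#' more often than expected by chance: `p = P[X >= k]` with
#' `X ~ Hypergeometric(N, K, n)` where `N` is the universe size, `K` the
#' term size within the universe, `n` the annotated query size and `k` the
#' overlap. The gene ratio is `k / n`. Terms are restricted to the universe
#' and size-filtered before testing; BH q-values are computed over the
#' tested terms. Terms with `k = 0` are reported with `p = 1` and can be
#' filtered by the caller.
#'
#' @param query Character vector of gene symbols.
#' @param annotation Tibble from [read_gmt()], or a named list of gene
#'   vectors.
#' @param universe Character vector defining the background; the
#'   recommended default is every gene in the cohort matrix namespace.
#' @param min_size,max_size Term-size filters applied after universe
#'   restriction. Defaults 5 and 2000.
#' @return Tibble sorted by p: `term`, `name`, `k`, `K`, `n`, `N`,
#'   `gene_ratio`, `bg_ratio`, `p`, `q`, `genes` (overlap, comma-joined).
#' @export
#' @examples
#' ann <- list(TERM1 = c("A", "B", "C", "D", "E"),
#'             TERM2 = c("F", "G", "H", "I", "J"))
#' ora(c("A", "B", "C", "F"), ann, universe = LETTERS[1:20], min_size = 2)
ora <- function(query, annotation, universe, min_size = 5, max_size = 2000) {
  norm_sym <- function(x) unique(toupper(trimws(x)))
  universe <- norm_sym(universe)
  if (!length(universe)) abort("Empty universe.")
  query <- intersect(norm_sym(query), universe)
  if (!length(query)) {
    abort("Query is empty after restriction to the universe.")
  }
  if (is.data.frame(annotation)) {
    terms <- annotation$term
    names_ <- annotation$name
    sets <- annotation$genes
  } else {
    terms <- names(annotation)
    names_ <- terms
    sets <- unname(annotation)
  }
  sets <- purrr::map(sets, ~ intersect(norm_sym(.x), universe))
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  if (!any(keep)) {
    abort("No annotation term passes the universe/size filters.")
  }
  terms <- terms[keep]; names_ <- names_[keep]; sets <- sets[keep]

  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  hits <- purrr::map(sets, intersect, query)
  k <- lengths(hits)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(
    term = terms, name = names_,
    k = as.integer(k), K = as.integer(K),
    n = as.integer(n), N = as.integer(N),
    gene_ratio = k / n, bg_ratio = K / N,
    p = p, q = p.adjust(p, method = "BH"),
    genes = vapply(hits, paste, character(1), collapse = ",")
  )
  arrange(out, .data$p, .data$term)
}
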