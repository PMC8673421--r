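# Case-control association of mutation (or CNV-event) status with treatment
# response: per-feature 2x2 tables, odds ratios, Fisher exact tests, and the
# clinical candidate drug-resistant gene set.

#' Variant classes excluded by the nonsynonymous filter
#'
#' MAF `Variant_Classification` values treated as non-protein-altering and
#' dropped when `nonsynonymous_only = TRUE` in [build_cohort_matrix()]. The
#' list is a documented, configurable constant, not an attempt to cover
#' every MAF dialect.
#'
#' @export
maf_silent_classes <- c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA",
                        "3'Flank", "5'Flank")

#' Build a cohort mutation-status matrix from MAF-like records
#'
#' Collapses per-variant records to gene-level binary status:
#' `status[p, g] = 1` iff patient `p` carries at least one qualifying
#' mutation in gene `g`. Patients listed in `labels` but absent from
#' `mutations` are retained with all-zero rows, so cohort-level fractions
#' use the full cohort as denominator.
#'
#' @param mutations Tibble of mutation records with at least columns
#'   `Tumor_Sample_Barcode`, `Hugo_Symbol` and (when filtering)
#'   `Variant_Classification`.
#' @param labels Tibble with columns `patient` (or `sample`) and `response`
#'   in `{"resistant", "sensitive"}`; defines the patient universe.
#' @param nonsynonymous_only Drop variant classes in `excluded_classes`.
#'   Default `TRUE`.
#' @param excluded_classes Character vector of excluded
#'   `Variant_Classification` values. Default [maf_silent_classes].
#' @return A [cohort_matrix] object. Gene symbols are uppercased and
#'   whitespace-stripped.
#' @export
#' @examples
#' maf <- tibble::tibble(Tumor_Sample_Barcode = c("P1", "P1", "P2"),
#'                       Hugo_Symbol = c("TTN", "TTN", "PLXNB2"),
#'                       Variant_Classification = "Missense_Mutation")
#' labs <- tibble::tibble(patient = c("P1", "P2", "P3"),
#'                        response = c("resistant", "sensitive", "sensitive"))
#' build_cohort_matrix(maf, labs)
build_cohort_matrix <- function(mutations, labels,
                                nonsynonymous_only = TRUE,
                                excluded_classes = maf_silent_classes) {
  labels <- as_tibble(labels)
  if ("sample" %in% names(labels) && !"patient" %in% names(labels)) {
    labels <- rename(labels, patient = "sample")
  }
  stopifnot(all(c("patient", "response") %in% names(labels)))
  mutations <- as_tibble(mutations)
  required <- c("Tumor_Sample_Barcode", "Hugo_Symbol")
  missing <- setdiff(required, names(mutations))
  if (length(missing)) {
    abort(paste0("`mutations` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(mutations) == 0) {
    warn("No mutation records; returning an all-zero cohort matrix.")
    status <- matrix(0L, nrow(labels), 0,
                     dimnames = list(labels$patient, NULL))
    return(new_cohort_matrix(status, labels))
  }
  unknown <- setdiff(unique(mutations$Tumor_Sample_Barcode), labels$patient)
  if (length(unknown)) {
    abort(paste0("Mutation records for patient(s) absent from `labels`: ",
                 paste(unknown, collapse = ", ")))
  }
  if (nonsynonymous_only) {
    if (!"Variant_Classification" %in% names(mutations)) {
      abort("`nonsynonymous_only = TRUE` requires a Variant_Classification column.")
    }
    mutations <- filter(mutations,
                        !.data$Variant_Classification %in% excluded_classes)
  }
  mutations <- mutate(mutations,
                      gene = toupper(trimws(.data$Hugo_Symbol)))
  genes <- sort(unique(mutations$gene))
  status <- matrix(0L, nrow(labels), length(genes),
                   dimnames = list(labels$patient, genes))
  if (nrow(mutations)) {
    idx <- cbind(match(mutations$Tumor_Sample_Barcode, labels$patient),
                 match(mutations$gene, genes))
    status[idx] <- 1L
  }
  new_cohort_matrix(status, labels)
}

#' Odds ratio of a 2x2 response-by-status table
#'
#' The table is oriented so that `a` = resistant & mutated, `b` = resistant
#' & unmutated, `c` = sensitive & mutated, `d` = sensitive & unmutated, and
#' `or_raw = (a*d)/(b*c)`: OR > 1 means the feature is enriched among
#' resistant patients. Structural zeros are flagged rather than silently
#' propagated; `or_corrected` applies the Haldane-Anscombe continuity
#' correction (0.5 added to every cell) and is always finite.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @return Tibble with columns `or_raw`, `or_flag` (one of `"finite"`,
#'   `"inf"`, `"zero"`, `"undefined"`) and `or_corrected`.
#' @export
#' @examples
#' odds_ratio(6, 42, 1, 86)   # ~12.29
#' odds_ratio(3, 10, 0, 20)   # raw flagged inf, corrected ~13.67
odds_ratio <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  or_raw <- (a * d) / (b * c)
  or_flag <- dplyr::case_when(
    is.nan(or_raw) ~ "undefined",
    is.infinite(or_raw) ~ "inf",
    or_raw == 0 ~ "zero",
    TRUE ~ "finite"
  )
  tibble(
    or_raw = or_raw,
    or_flag = or_flag,
    or_corrected = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  )
}

check_counts <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Contingency counts must be non-negative integers.")
  }
  invisible(TRUE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided by the point-probability method: the p-value sums the
#' hypergeometric probabilities (fixed margins) of every table whose point
#' probability does not exceed that of the observed table (up to the
#' standard relative tolerance guarding floating-point ties). Vectorized
#' over tables; repeated tables are computed once.
#'
#' @inheritParams odds_ratio
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisher_exact(6, 42, 1, 86)
fisher_exact <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  tbl <- tibble(a = a, b = b, c = c, d = d)
  key <- paste(a, b, c, d)
  uniq <- !duplicated(key)
  p_uniq <- vapply(which(uniq), function(i) {
    stats::fisher.test(matrix(c(tbl$a[i], tbl$b[i], tbl$c[i], tbl$d[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  unname(p_uniq[match(key, key[uniq])])
}

#' Per-gene association with treatment response
#'
#' Builds the 2x2 table of mutation status by response group for every gene
#' and reports raw/continuity-corrected odds ratios, two-sided Fisher exact
#' p, Benjamini-Hochberg q (over genes mutated in at least one patient), a
#' structural category, and the cohort mutation frequency.
#'
#' @param cohort A [cohort_matrix] object.
#' @param alpha Significance level used downstream; stored as an attribute.
#' @return Tibble with one row per gene: `gene`, `a`, `b`, `c`, `d`,
#'   `or_raw`, `or_flag`, `or_corrected`, `p`, `q`, `category` (one of
#'   `resistant_only`, `sensitive_only`, `shared`, `unmutated`), `mut_freq`.
#' @export
associate_genes <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (ncol(cohort$status) == 0) {
    return(empty_assoc("gene"))
  }
  assoc_from_matrix(cohort$status,
                    cohort$labels$response == "resistant",
                    feature_col = "gene")
}

empty_assoc <- function(feature_col) {
  out <- tibble(feature = character(0), a = integer(0), b = integer(0),
                c = integer(0), d = integer(0), or_raw = numeric(0),
                or_flag = character(0), or_corrected = numeric(0),
                p = numeric(0), q = numeric(0), category = character(0),
                mut_freq = numeric(0))
  names(out)[1] <- feature_col
  out
}

assoc_from_matrix <- function(status, is_resistant, feature_col = "gene") {
  a <- unname(colSums(status[is_resistant, , drop = FALSE]))
  cc <- unname(colSums(status[!is_resistant, , drop = FALSE]))
  b <- sum(is_resistant) - a
  d <- sum(!is_resistant) - cc
  or <- odds_ratio(a, b, cc, d)
  mutated <- (a + cc) > 0
  p <- rep(1, length(a))
  p[mutated] <- fisher_exact(a[mutated], b[mutated], cc[mutated], d[mutated])
  q <- rep(NA_real_, length(a))
  q[mutated] <- p.adjust(p[mutated], method = "BH")
  category <- dplyr::case_when(
    a > 0 & cc == 0 ~ "resistant_only",
    a == 0 & cc > 0 ~ "sensitive_only",
    a > 0 & cc > 0 ~ "shared",
    TRUE ~ "unmutated"
  )
  out <- tibble(
    feature = colnames(status),
    a = as.integer(a), b = as.integer(b),
    c = as.integer(cc), d = as.integer(d),
    or_raw = or$or_raw, or_flag = or$or_flag,
    or_corrected = or$or_corrected,
    p = p, q = q, category = category,
    mut_freq = (a + cc) / nrow(status)
  )
  names(out)[1] <- feature_col
  out
}

#' Construct the clinical candidate drug-resistant gene set
#'
#' Members are the genes mutated only in the resistant group
#' (`resistant_only`, included directly) plus the genes mutated in both
#' groups with raw odds ratio above 1 (`shared_or_gt1`). The significant
#' subset applies a raw Fisher `p < alpha` cut within the members (BH q is
#' carried alongside but, matching the reported convention, does not gate
#' membership).
#'
#' @param assoc Gene association tibble from [associate_genes()].
#' @param alpha Raw-p significance level for the significant subset.
#'   Default 0.05.
#' @return A `clinical_gene_set`: list with `members`, `significant_subset`
#'   (character vectors), `table` (per-member association rows plus a
#'   `provenance` column) and `alpha`.
#' @export
clinical_candidate_set <- function(assoc, alpha = 0.05) {
  stopifnot(is.data.frame(assoc), alpha > 0, alpha <= 1)
  keep <- assoc$category == "resistant_only" |
    (assoc$category == "shared" & assoc$or_raw > 1)
  table <- assoc[keep, , drop = FALSE]
  table <- mutate(as_tibble(table),
                  provenance = if_else(.data$category == "resistant_only",
                                       "resistant_only", "shared_or_gt1"),
                  significant = .data$p < alpha)
  structure(
    list(members = table$gene,
         significant_subset = table$gene[table$significant],
         table = table,
         alpha = alpha),
    class = "clinical_gene_set"
  )
}

#' @export
print.clinical_gene_set <- function(x, ...) {
  cat("<clinical_gene_set> ", length(x$members), " genes (",
      sum(x$table$provenance == "resistant_only"), " resistant-only + ",
      sum(x$table$provenance == "shared_or_gt1"), " shared with OR > 1); ",
      length(x$significant_subset), " significant at p < ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clinical_gene_set <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.clinical_gene_set <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    n_resistant_only = sum(x$table$provenance == "resistant_only"),
    n_shared_or_gt1 = sum(x$table$provenance == "shared_or_gt1"),
    n_significant = length(x$significant_subset),
    alpha = x$alpha
  )
}

#' Associate binary CNV events with treatment response
#'
#' Applies the identical 2x2 statistics as [associate_genes()] to a
#' sample x event 0/1 matrix, and flags events with OR > 1 and raw
#' `p < alpha` as response-related.
#'
#' @param event_matrix Binary matrix, samples in rows (dimnamed), events in
#'   columns.
#' @param labels Tibble with `patient` (or `sample`) and `response`; every
#'   sample in the matrix must be labelled.
#' @param alpha Raw-p threshold for the `response_related` flag. Default
#'   0.05.
#' @return Tibble as [associate_genes()] with `event` in place of `gene`,
#'   plus a logical `response_related` column.
#' @export
associate_cnv_events <- function(event_matrix, labels, alpha = 0.05) {
  labels <- as_tibble(labels)
  if ("sample" %in% names(labels) && !"patient" %in% names(labels)) {
    labels <- rename(labels, patient = "sample")
  }
  stopifnot(is.matrix(event_matrix))
  if (ncol(event_matrix) == 0) {
    out <- empty_assoc("event")
    out$response_related <- logical(0)
    return(out)
  }
  unlabelled <- setdiff(rownames(event_matrix), labels$patient)
  if (length(unlabelled)) {
    abort(paste0("Unlabelled sample(s): ", paste(unlabelled, collapse = ", ")))
  }
  response <- labels$response[match(rownames(event_matrix), labels$patient)]
  out <- assoc_from_matrix(event_matrix, response == "resistant",
                           feature_col = "event")
  mutate(out, response_related = !is.na(.data$or_raw) & .data$or_raw > 1 &
           .data$p < alpha)
}
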