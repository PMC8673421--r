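# Lightweight S3 containers. Both are thin wrappers around a matrix plus
# tabular metadata, with broom-style tidy()/glance() methods.

#' Cohort mutation-status container
#'
#' A patients x genes binary mutation-status matrix together with the
#' resistant/sensitive response labels. Build one from MAF-like records with
#' [build_cohort_matrix()] or simulate one with [simulate_cohort()].
#'
#' @param status Integer 0/1 matrix, patients in rows, genes in columns,
#'   both dimnamed.
#' @param labels Tibble with columns `patient`, `response` (values
#'   `"resistant"`/`"sensitive"`), one row per matrix row.
#' @return An object of class `cohort_matrix`.
#' @name cohort_matrix
NULL

new_cohort_matrix <- function(status, labels) {
  stopifnot(is.matrix(status), !is.null(rownames(status)))
  labels <- as_tibble(labels)
  stopifnot(all(c("patient", "response") %in% names(labels)))
  if (!setequal(rownames(status), labels$patient) ||
      anyDuplicated(labels$patient)) {
    abort("Every patient must carry exactly one response label.")
  }
  if (length(status) && !all(status %in% c(0L, 1L))) {
    abort("Mutation status entries must be 0/1.")
  }
  bad <- setdiff(unique(labels$response), c("resistant", "sensitive"))
  if (length(bad)) {
    abort(paste0("Unknown response label(s): ", paste(bad, collapse = ", ")))
  }
  labels <- labels[match(rownames(status), labels$patient), ]
  structure(list(status = status, labels = labels), class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  n_res <- sum(x$labels$response == "resistant")
  cat("<cohort_matrix> ", nrow(x$status), " patients (",
      n_res, " resistant / ", nrow(x$status) - n_res, " sensitive) x ",
      ncol(x$status), " genes\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_matrix <- function(x, ...) {
  long <- as_tibble(x$status, rownames = "patient")
  long <- tidyr::pivot_longer(long, -"patient", names_to = "gene",
                              values_to = "mutated")
  left_join(long, x$labels, by = "patient")
}

#' @exportS3Method generics::glance
glance.cohort_matrix <- function(x, ...) {
  tibble(
    n_patients = nrow(x$status),
    n_resistant = sum(x$labels$response == "resistant"),
    n_sensitive = sum(x$labels$response == "sensitive"),
    n_genes = ncol(x$status),
    n_patients_mutated = sum(rowSums(x$status) > 0),
    frac_patients_mutated = if (nrow(x$status)) {
      sum(rowSums(x$status) > 0) / nrow(x$status)
    } else NA_real_
  )
}

#' CRISPR screen experiment container
#'
#' An sgRNA x sample count matrix, the sgRNA-to-gene map, and per-sample
#' metadata defining conditions (cell line x drug x timepoint) and arms
#' (treated/control).
#'
#' @param counts Non-negative integer matrix, sgRNAs in rows (dimnamed),
#'   samples in columns.
#' @param sgrna_map Tibble with columns `sgrna`, `gene`; every sgRNA maps to
#'   exactly one gene.
#' @param samples Tibble with columns `sample`, `cell_line`, `drug`,
#'   `timepoint`, `arm` (`"treated"`/`"control"`), `replicate`.
#' @return An object of class `screen_experiment`.
#' @export
screen_experiment <- function(counts, sgrna_map, samples) {
  new_screen_experiment(counts, sgrna_map, samples)
}

new_screen_experiment <- function(counts, sgrna_map, samples) {
  sgrna_map <- as_tibble(sgrna_map)
  samples <- as_tibble(samples)
  stopifnot(is.matrix(counts),
            all(c("sgrna", "gene") %in% names(sgrna_map)),
            all(c("sample", "cell_line", "drug", "timepoint", "arm",
                  "replicate") %in% names(samples)))
  if (anyDuplicated(sgrna_map$sgrna)) {
    abort("Every sgRNA must map to exactly one gene.")
  }
  if (!identical(rownames(counts), sgrna_map$sgrna)) {
    abort("Count matrix rows must match `sgrna_map$sgrna` in order.")
  }
  if (!identical(colnames(counts), samples$sample)) {
    abort("Count matrix columns must match `samples$sample` in order.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  bad <- setdiff(unique(samples$arm), c("treated", "control"))
  if (length(bad)) abort(paste0("Unknown arm(s): ", paste(bad, collapse = ", ")))
  treated <- distinct(samples[samples$arm == "treated",
                              c("cell_line", "drug", "timepoint")])
  controls <- distinct(samples[samples$arm == "control",
                               c("cell_line", "drug", "timepoint")])
  orphan <- anti_join(treated, controls,
                      by = c("cell_line", "drug", "timepoint"))
  if (nrow(orphan)) {
    abort(paste0("Treated condition without a control arm: ",
                 paste(condition_id(orphan), collapse = ", ")))
  }
  structure(list(counts = counts, sgrna_map = sgrna_map, samples = samples),
            class = "screen_experiment")
}

condition_id <- function(cond) {
  paste(cond$cell_line, cond$drug, paste0("d", cond$timepoint), sep = "_")
}

#' @export
print.screen_experiment <- function(x, ...) {
  cond <- distinct(x$samples[, c("cell_line", "drug", "timepoint")])
  cat("<screen_experiment> ", nrow(x$counts), " sgRNAs (",
      dplyr::n_distinct(x$sgrna_map$gene), " genes) x ", ncol(x$counts),
      " samples, ", nrow(cond), " conditions\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.screen_experiment <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "sgrna")
  long <- tidyr::pivot_longer(long, -"sgrna", names_to = "sample",
                              values_to = "count")
  long <- left_join(long, x$sgrna_map, by = "sgrna")
  left_join(long, x$samples, by = "sample")
}

#' @exportS3Method generics::glance
glance.screen_experiment <- function(x, ...) {
  tibble(
    n_sgrnas = nrow(x$counts),
    n_genes = dplyr::n_distinct(x$sgrna_map$gene),
    n_samples = ncol(x$counts),
    n_conditions = nrow(distinct(x$samples[, c("cell_line", "drug",
                                               "timepoint")])),
    median_count = median(x$counts)
  )
}
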