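# Shared readers and writers. All writes are atomic: content goes to a
# temporary file in the target directory which is then renamed, so partial
# outputs never masquerade as complete.

write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(paste0("Failed to move temporary file into place: ", path))
  }
  invisible(path)
}

#' Write / read a tab-separated table
#'
#' Writers are atomic (write-then-rename); tables round-trip bit-identically
#' through their readers.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `write_tsv_atomic()` returns `path` invisibly; `read_tsv_strict()`
#'   returns a tibble with all columns typed by readr's default guesser.
#' @export
write_tsv_atomic <- function(x, path) {
  write_atomic(function(tmp) readr::write_tsv(x, tmp, progress = FALSE), path)
}

#' @rdname write_tsv_atomic
#' @export
read_tsv_strict <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

write_json_atomic <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, path)
}

#' Write a simulated cohort as MAF-like TSV plus a label table
#'
#' Each mutated (patient, gene) cell becomes one MAF-like record with a
#' `Missense_Mutation` classification and a decorative protein position
#' (site-level detail is not modelled; downstream statistics are
#' gene-level).
#'
#' @param cohort A [cohort_matrix] object.
#' @param maf_path,labels_path Output paths.
#' @param seed Seed for the decorative protein positions.
#' @return Invisibly, a list of the two paths.
#' @export
write_cohort_maf <- function(cohort, maf_path, labels_path, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  idx <- which(cohort$status == 1L, arr.ind = TRUE)
  maf <- tibble(
    Tumor_Sample_Barcode = rownames(cohort$status)[idx[, 1]],
    Hugo_Symbol = colnames(cohort$status)[idx[, 2]],
    Variant_Classification = "Missense_Mutation",
    Protein_position = withr::with_seed(seed,
                                        sample.int(1000, nrow(idx),
                                                   replace = TRUE))
  )
  maf <- arrange(maf, .data$Tumor_Sample_Barcode, .data$Hugo_Symbol)
  write_tsv_atomic(maf, maf_path)
  write_tsv_atomic(cohort$labels, labels_path)
  invisible(list(maf = maf_path, labels = labels_path))
}

#' Read MAF-like mutation records and response labels
#'
#' @param maf_path MAF-like TSV with at least `Tumor_Sample_Barcode`,
#'   `Hugo_Symbol` and `Variant_Classification` columns.
#' @param labels_path Two-column TSV (`patient`/`sample`, `response`).
#' @return `read_maf()`: tibble of records; `read_labels()`: tibble with
#'   `patient`, `response`.
#' @export
read_maf <- function(maf_path) {
  x <- read_tsv_strict(maf_path)
  missing <- setdiff(c("Tumor_Sample_Barcode", "Hugo_Symbol"), names(x))
  if (length(missing)) {
    abort(paste0("MAF is missing columns: ", paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname read_maf
#' @export
read_labels <- function(labels_path) {
  x <- read_tsv_strict(labels_path)
  if ("sample" %in% names(x) && !"patient" %in% names(x)) {
    x <- rename(x, patient = "sample")
  }
  missing <- setdiff(c("patient", "response"), names(x))
  if (length(missing)) {
    abort(paste0("Label table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  x
}

#' Write / read a screen experiment as count and metadata TSVs
#'
#' The count table has columns `sgrna`, `gene`, then one column per sample;
#' the metadata table mirrors the `samples` tibble.
#'
#' @param screen A [screen_experiment] object.
#' @param counts_path,meta_path File paths.
#' @return `write_screen_tsv()` returns the paths invisibly;
#'   `read_screen_tsv()` returns a [screen_experiment].
#' @export
write_screen_tsv <- function(screen, counts_path, meta_path) {
  stopifnot(inherits(screen, "screen_experiment"))
  counts <- dplyr::bind_cols(screen$sgrna_map,
                             as_tibble(screen$counts, .name_repair = "minimal"))
  write_tsv_atomic(counts, counts_path)
  write_tsv_atomic(screen$samples, meta_path)
  invisible(list(counts = counts_path, meta = meta_path))
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(counts_path, meta_path) {
  counts <- read_tsv_strict(counts_path)
  meta <- read_tsv_strict(meta_path)
  missing <- setdiff(c("sgrna", "gene"), names(counts))
  if (length(missing)) {
    abort(paste0("Count table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(counts[, setdiff(names(counts), c("sgrna", "gene"))])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$sgrna
  m <- m[, meta$sample, drop = FALSE]
  new_screen_experiment(m, counts[, c("sgrna", "gene")], meta)
}

#' Write a binary event matrix as TSV
#'
#' @param mat Binary matrix with sample rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_matrix <- function(mat, path) {
  write_tsv_atomic(as_tibble(mat, rownames = "sample"), path)
}

#' @rdname write_event_matrix
#' @export
read_event_matrix <- function(path) {
  x <- read_tsv_strict(path)
  m <- as.matrix(x[, setdiff(names(x), "sample")])
  storage.mode(m) <- "integer"
  rownames(m) <- x$sample
  m
}
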