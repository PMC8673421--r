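# Parameter constructors for the synthetic-data generators. Seeds are
# explicit fields; generators never touch the global RNG state.

#' Parameters for simulating a case-control mutation cohort
#'
#' Describes a cohort of patients split into drug-resistant and
#' drug-sensitive groups, with per-gene binary mutation status. Non-planted
#' genes mutate i.i.d. at `background_mut_prob` in both groups; planted genes
#' have a group-dependent probability derived from a target odds ratio (see
#' [simulate_cohort()]).
#'
#' @param n_patients Total cohort size. Default 135.
#' @param n_resistant Number of drug-resistant (non-responder) patients;
#'   must satisfy `0 < n_resistant < n_patients`. Default 48.
#' @param n_genes Number of genes in the simulated exome.
#' @param background_mut_prob Per-gene, per-patient mutation probability for
#'   non-planted genes, identical in both groups. Default 0.03.
#' @param planted Optional tibble of planted signal genes with columns
#'   `gene`, `target_or` (odds ratio of mutation in resistant vs sensitive,
#'   > 0) and `sensitive_mut_prob` (mutation probability in the sensitive
#'   group, in (0, 1)). See [planted_clinical()].
#' @param seed Integer seed; identical parameters (including seed) give
#'   bitwise-identical simulations.
#'
#' @return A `cohort_sim_params` list, validated.
#' @export
#' @examples
#' cohort_sim_params(n_genes = 100, planted = planted_clinical("BRCA2"))
cohort_sim_params <- function(n_patients = 135, n_resistant = 48,
                              n_genes = 2000, background_mut_prob = 0.03,
                              planted = NULL, seed = 1L) {
  stopifnot(n_patients >= 2, n_genes >= 0)
  if (!(n_resistant > 0 && n_resistant < n_patients)) {
    abort("`n_resistant` must satisfy 0 < n_resistant < n_patients.")
  }
  if (!(background_mut_prob > 0 && background_mut_prob < 1)) {
    abort("`background_mut_prob` must lie in (0, 1).")
  }
  planted <- validate_planted_clinical(planted)
  structure(
    list(n_patients = as.integer(n_patients),
         n_resistant = as.integer(n_resistant),
         n_genes = as.integer(n_genes),
         background_mut_prob = background_mut_prob,
         planted = planted,
         seed = as.integer(seed)),
    class = "cohort_sim_params"
  )
}

#' Build a planted-gene table for cohort simulation
#'
#' @param genes Character vector of gene symbols.
#' @param target_or Target odds ratio(s) of mutation (resistant vs
#'   sensitive), recycled across genes. Default 10.
#' @param sensitive_mut_prob Mutation probability in the sensitive group,
#'   recycled. Default 0.02.
#' @return Tibble with columns `gene`, `target_or`, `sensitive_mut_prob`.
#' @export
planted_clinical <- function(genes, target_or = 10, sensitive_mut_prob = 0.02) {
  tibble(gene = as.character(genes),
         target_or = as.numeric(target_or),
         sensitive_mut_prob = as.numeric(sensitive_mut_prob))
}

validate_planted_clinical <- function(planted) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(planted_clinical(character(0))[0, ])
  }
  planted <- as_tibble(planted)
  required <- c("gene", "target_or", "sensitive_mut_prob")
  missing <- setdiff(required, names(planted))
  if (length(missing)) {
    abort(paste0("`planted` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(planted$gene)) abort("`planted` genes must be unique.")
  if (any(planted$target_or <= 0)) abort("`target_or` must be > 0.")
  bad_p <- planted$sensitive_mut_prob <= 0 | planted$sensitive_mut_prob >= 1
  if (any(bad_p)) abort("`sensitive_mut_prob` must lie in (0, 1).")
  # odds transform: p_r = OR * o_s / (1 + OR * o_s), o_s = p_s / (1 - p_s)
  p_r <- resistant_prob(planted$target_or, planted$sensitive_mut_prob)
  if (any(p_r >= 1)) {
    abort(paste0("Derived resistant-group mutation probability >= 1 for: ",
                 paste(planted$gene[p_r >= 1], collapse = ", ")))
  }
  planted
}

resistant_prob <- function(target_or, sensitive_mut_prob) {
  o_s <- sensitive_mut_prob / (1 - sensitive_mut_prob)
  (target_or * o_s) / (1 + target_or * o_s)
}

#' Default CRISPR screen condition grid
#'
#' Two cervical cancer cell lines crossed with two chemotherapy drugs and
#' two selection timepoints, the full factorial screened in the study design
#' this package emulates.
#'
#' @return Tibble with columns `cell_line`, `drug`, `timepoint` (days).
#' @export
default_screen_conditions <- function() {
  tidyr::expand_grid(cell_line = c("HeLa", "SiHa"),
                     drug = c("cisplatin", "paclitaxel"),
                     timepoint = c(7L, 14L))
}

#' Parameters for simulating a CRISPR knockout screen
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`.
#' Treated-arm counts of sgRNAs targeting planted genes (in their matching
#' conditions) have their mean multiplied by `fold`. Per-sample library-size
#' factors are drawn log-uniform in \[0.7, 1.3\] and rescaled to geometric
#' mean 1.
#'
#' @param n_genes Number of genes in the library.
#' @param sgrnas_per_gene sgRNAs targeting each gene. Default 6.
#' @param conditions Tibble of screened conditions (`cell_line`, `drug`,
#'   `timepoint`); default [default_screen_conditions()].
#' @param replicates_per_arm Replicates per treated and per control arm.
#'   Default 2.
#' @param baseline_mean Expected control count per sgRNA. Default 300.
#' @param dispersion Negative-binomial overdispersion (> 0). Default 0.2.
#' @param planted Optional tibble from [planted_screen()]: columns `gene`,
#'   `fold` (>= 1) and optional `cell_line`/`drug`/`timepoint` restrictions
#'   (NA = all).
#' @param seed Integer seed.
#' @return A validated `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_genes = 2000, sgrnas_per_gene = 6,
                              conditions = default_screen_conditions(),
                              replicates_per_arm = 2, baseline_mean = 300,
                              dispersion = 0.2, planted = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, sgrnas_per_gene >= 1, replicates_per_arm >= 1,
            baseline_mean > 0)
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  conditions <- as_tibble(conditions)
  stopifnot(all(c("cell_line", "drug", "timepoint") %in% names(conditions)),
            nrow(conditions) >= 1)
  planted <- validate_planted_screen(planted)
  structure(
    list(n_genes = as.integer(n_genes),
         sgrnas_per_gene = as.integer(sgrnas_per_gene),
         conditions = conditions,
         replicates_per_arm = as.integer(replicates_per_arm),
         baseline_mean = baseline_mean,
         dispersion = dispersion,
         planted = planted,
         seed = as.integer(seed)),
    class = "screen_sim_params"
  )
}

#' Build a planted-gene table for screen simulation
#'
#' @param genes Character vector of gene symbols.
#' @param fold Multiplicative enrichment of treated-arm means (>= 1),
#'   recycled. Default 8.
#' @param cell_line,drug,timepoint Optional condition restriction; `NA`
#'   (default) plants the gene in every condition along that axis.
#' @return Tibble with columns `gene`, `fold`, `cell_line`, `drug`,
#'   `timepoint`.
#' @export
planted_screen <- function(genes, fold = 8, cell_line = NA_character_,
                           drug = NA_character_, timepoint = NA_integer_) {
  tibble(gene = as.character(genes), fold = as.numeric(fold),
         cell_line = cell_line, drug = drug,
         timepoint = as.integer(timepoint))
}

validate_planted_screen <- function(planted) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(planted_screen(character(0))[0, ])
  }
  planted <- as_tibble(planted)
  missing <- setdiff(c("gene", "fold"), names(planted))
  if (length(missing)) {
    abort(paste0("`planted` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("cell_line", "drug", "timepoint")) {
    if (!col %in% names(planted)) planted[[col]] <- NA
  }
  if (any(planted$fold < 1)) {
    abort("Planted resistance genes require `fold` >= 1.")
  }
  planted
}

gene_universe <- function(n_genes, planted_genes = character(0)) {
  planted_genes <- unique(as.character(planted_genes))
  if (length(planted_genes) > n_genes) {
    abort("More planted genes than `n_genes`.")
  }
  filler <- sprintf("G%04d", seq_len(n_genes))
  filler <- setdiff(filler, planted_genes)
  c(planted_genes, filler)[seq_len(n_genes)]
}
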