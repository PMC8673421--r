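# End-to-end orchestration: simulate -> clinical -> screen -> integrate ->
# enrich, with a validated configuration, atomic stage outputs and a
# machine-readable run manifest.

#' Pipeline configuration with documented defaults
#'
#' Returns the default configuration of [run_all()]; any element can be
#' overridden through `...` (or, for nested lists, by passing a modified
#' list). Thresholds are validated before any stage runs.
#'
#' Defaults: a 135-patient cohort split 48 resistant / 87 sensitive over
#' `n_genes` genes with background mutation probability 0.03; clinical
#' signal planted at odds ratio 10 on sensitive-group probability 0.02;
#' 60 CNV events with 8 planted at odds ratio 4 / sensitive probability
#' 0.15; a 6 sgRNA-per-gene screen over two cell lines x two drugs x two
#' timepoints with negative-binomial counts (mean 300, dispersion 0.2) and
#' 8-fold enrichment planted in the screen truth set. Ten genes are planted
#' in both modalities.
#'
#' @param ... Named overrides of the default elements.
#' @return A validated `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 42, n_genes = 200)
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 500L,
    cohort = list(n_patients = 135L, n_resistant = 48L,
                  background_mut_prob = 0.03,
                  n_planted = 15L, planted_or = 10, planted_prob = 0.02),
    cnv = list(n_events = 60L, n_planted = 8L, planted_or = 4,
               planted_prob = 0.15),
    screen = list(sgrnas_per_gene = 6L, replicates_per_arm = 2L,
                  baseline_mean = 300, dispersion = 0.2,
                  n_planted = 15L, planted_fold = 8, n_perm = 1000L),
    n_overlap = 10L,
    thresholds = list(alpha = 0.05, p_threshold = 0.05,
                      alpha_frac = 0.25, quantile = 0.25),
    gmt = NULL
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from the documented defaults of
#' [pipeline_config()].
#'
#' @param path Path to a YAML file whose top-level keys match
#'   [pipeline_config()] elements.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  thr <- cfg$thresholds
  for (nm in c("alpha", "p_threshold", "alpha_frac", "quantile")) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(paste0("Configuration threshold `", nm,
                   "` must be a number in (0, 1]."))
    }
  }
  if (cfg$n_overlap > min(cfg$cohort$n_planted, cfg$screen$n_planted)) {
    abort("`n_overlap` cannot exceed either planted-gene count.")
  }
  if (cfg$cohort$n_planted + cfg$screen$n_planted - cfg$n_overlap >
      cfg$n_genes) {
    abort("Planted genes exceed `n_genes`.")
  }
  structure(cfg, class = "pipeline_config")
}

planted_names <- function(cfg) {
  nc <- cfg$cohort$n_planted
  ns <- cfg$screen$n_planted
  ov <- cfg$n_overlap
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  list(clinical = genes[seq_len(nc)],
       screen = genes[seq(nc - ov + 1, nc - ov + ns)])
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> clinical -> screen -> integrate -> enrich with the
#' given configuration, writing every stage output plus a machine-readable
#' `manifest.json` (package version, seed, thresholds, per-stage record
#' counts, output file digests) under `out_dir`. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]), or a path to
#'   a YAML configuration.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `assoc`, `clinical_set`, `cnv_assoc`, `screen_results`, `screen_union`,
#'   `consensus`, `integrated`, `enrichment`, `truth`, `manifest`).
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  stages <- list()
  note_stage <- function(name, ...) {
    stages[[name]] <<- c(list(status = "completed"), list(...))
  }

  run_stage("simulate", {
    pl <- planted_names(config)
    cohort_par <- cohort_sim_params(
      n_patients = config$cohort$n_patients,
      n_resistant = config$cohort$n_resistant,
      n_genes = config$n_genes,
      background_mut_prob = config$cohort$background_mut_prob,
      planted = planted_clinical(pl$clinical, config$cohort$planted_or,
                                 config$cohort$planted_prob),
      seed = config$seed
    )
    cohort_sim <- simulate_cohort(cohort_par)
    cnv_sim <- simulate_cnv_events(
      cohort_sim_params(
        n_patients = config$cohort$n_patients,
        n_resistant = config$cohort$n_resistant,
        n_genes = config$n_genes,
        background_mut_prob = config$cnv$planted_prob / 2,
        seed = config$seed + 1L
      ),
      n_events = config$cnv$n_events,
      planted_events = planted_clinical(
        sprintf("EVP%02d", seq_len(config$cnv$n_planted)),
        config$cnv$planted_or, config$cnv$planted_prob)
    )
    screen_sim <- simulate_screen(screen_sim_params(
      n_genes = config$n_genes,
      sgrnas_per_gene = config$screen$sgrnas_per_gene,
      replicates_per_arm = config$screen$replicates_per_arm,
      baseline_mean = config$screen$baseline_mean,
      dispersion = config$screen$dispersion,
      planted = planted_screen(pl$screen, config$screen$planted_fold),
      seed = config$seed + 2L
    ))
    truth <- sim_truth(cohort_sim$truth, screen_sim$truth)
    write_cohort_maf(cohort_sim$cohort,
                     file.path(out_dir, "cohort_mutations.maf.tsv"),
                     file.path(out_dir, "cohort_labels.tsv"),
                     seed = config$seed)
    write_event_matrix(cnv_sim$events, file.path(out_dir, "cnv_events.tsv"))
    write_tsv_atomic(cnv_sim$labels, file.path(out_dir, "cnv_labels.tsv"))
    write_screen_tsv(screen_sim$screen,
                     file.path(out_dir, "screen_counts.tsv"),
                     file.path(out_dir, "screen_samples.tsv"))
    write_json_atomic(
      list(clinical_planted = truth$clinical_planted,
           screen_planted = truth$screen_planted,
           overlap_planted = truth$overlap_planted),
      file.path(out_dir, "truth.json"))
    note_stage("simulate",
               n_patients = config$cohort$n_patients,
               n_genes = config$n_genes,
               n_cnv_events = config$cnv$n_events,
               n_sgrnas = nrow(screen_sim$screen$counts))
  })

  run_stage("clinical", {
    maf <- read_maf(file.path(out_dir, "cohort_mutations.maf.tsv"))
    labels <- read_labels(file.path(out_dir, "cohort_labels.tsv"))
    cohort <- build_cohort_matrix(maf, labels)
    assoc <- associate_genes(cohort, alpha = thr$alpha)
    clinical_set <- clinical_candidate_set(assoc, alpha = thr$alpha)
    cnv_assoc <- associate_cnv_events(
      read_event_matrix(file.path(out_dir, "cnv_events.tsv")),
      read_labels(file.path(out_dir, "cnv_labels.tsv")),
      alpha = thr$alpha)
    write_tsv_atomic(assoc, file.path(out_dir, "gene_associations.tsv"))
    write_tsv_atomic(tidy(clinical_set),
                     file.path(out_dir, "clinical_gene_set.tsv"))
    write_tsv_atomic(cnv_assoc, file.path(out_dir, "cnv_associations.tsv"))
    note_stage("clinical",
               n_genes_tested = nrow(assoc),
               n_candidates = length(clinical_set$members),
               n_significant = length(clinical_set$significant_subset),
               n_cnv_response_related = sum(cnv_assoc$response_related))
  })

  run_stage("screen", {
    screen <- read_screen_tsv(file.path(out_dir, "screen_counts.tsv"),
                              file.path(out_dir, "screen_samples.tsv"))
    screen_results <- screen_rra(screen, alpha_frac = thr$alpha_frac,
                                 n_perm = config$screen$n_perm,
                                 seed = config$seed,
                                 p_threshold = thr$p_threshold)
    screen_union <- screen_resistant_union(screen_results,
                                           p_threshold = thr$p_threshold)
    consensus <- top_quantile_consensus(screen_results, screen_union,
                                        quantile = thr$quantile)
    write_tsv_atomic(screen_results,
                     file.path(out_dir, "screen_gene_results.tsv"))
    write_tsv_atomic(tidy(screen_union),
                     file.path(out_dir, "screen_union.tsv"))
    write_tsv_atomic(consensus, file.path(out_dir, "screen_consensus.tsv"))
    note_stage("screen",
               n_conditions = nrow(screen_union$conditions),
               n_union = length(screen_union$members),
               n_consensus = nrow(consensus))
  })

  run_stage("integrate", {
    integrated <- intersect_sets(clinical_set, screen_union, screen_results)
    breakdown <- condition_breakdown(integrated)
    cluster <- significant_cluster(integrated)
    write_tsv_atomic(tidy(integrated),
                     file.path(out_dir, "integrated_set.tsv"))
    write_json_atomic(breakdown, file.path(out_dir, "breakdown.json"))
    write_tsv_atomic(tidy(cluster),
                     file.path(out_dir, "resistance_matrix.tsv"))
    note_stage("integrate",
               n_integrated = length(integrated$members),
               n_cluster_rows = nrow(cluster$mat))
  })

  run_stage("enrich", {
    gmt_path <- config$gmt %||%
      system.file("extdata", "synthetic_pathways.gmt", package = "mutscreen")
    gmt <- read_gmt(gmt_path)
    enrichment <- ora(integrated$members, gmt,
                      universe = colnames(cohort$status))
    write_tsv_atomic(enrichment, file.path(out_dir, "enrichment.tsv"))
    note_stage("enrich",
               n_terms_tested = nrow(enrichment),
               n_terms_significant = sum(enrichment$p < thr$alpha))
  })

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "mutscreen",
    version = as.character(utils::packageVersion("mutscreen")),
    seed = config$seed,
    thresholds = thr,
    stages = stages,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, assoc = assoc, clinical_set = clinical_set,
                 cnv_assoc = cnv_assoc, screen_results = screen_results,
                 screen_union = screen_union, consensus = consensus,
                 integrated = integrated, enrichment = enrichment,
                 truth = truth, manifest = manifest))
}

# Evaluate a stage in the caller's frame so stage results remain visible to
# later stages; any error aborts with the stage name attached.
run_stage <- function(name, expr) {
  env <- parent.frame()
  tryCatch(
    eval(substitute(expr), envir = env),
    error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    }
  )
}
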