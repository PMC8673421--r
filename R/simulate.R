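# Synthetic-data generators: cohorts, CNV-event matrices and sgRNA count
# screens with planted, recoverable signal. All randomness is scoped with
# withr::with_seed so generators are pure functions of their parameters.

#' Simulate a case-control somatic-mutation cohort
#'
#' Generates a patients x genes binary mutation-status matrix with
#' resistant/sensitive labels. For a planted gene, the mutation probability
#' in the resistant group is derived from the sensitive-group probability
#' and the target odds ratio via the odds transform
#' `p_r = (OR * o_s) / (1 + OR * o_s)` with `o_s = p_s / (1 - p_s)`.
#' Non-planted genes mutate i.i.d. at `background_mut_prob` in both groups.
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with elements `cohort` (a [cohort_matrix] object) and
#'   `truth` (tibble of planted genes with their target odds ratios and the
#'   derived group probabilities).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_params(n_genes = 50, seed = 7))
#' glance(sim$cohort)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  genes <- gene_universe(params$n_genes, params$planted$gene)
  p_sens <- rep(params$background_mut_prob, params$n_genes)
  p_res <- p_sens
  names(p_sens) <- names(p_res) <- genes
  if (nrow(params$planted)) {
    p_sens[params$planted$gene] <- params$planted$sensitive_mut_prob
    p_res[params$planted$gene] <- resistant_prob(params$planted$target_or,
                                                 params$planted$sensitive_mut_prob)
  }
  patients <- sprintf("P%03d", seq_len(params$n_patients))
  labels <- tibble(
    patient = patients,
    response = rep(c("resistant", "sensitive"),
                   c(params$n_resistant,
                     params$n_patients - params$n_resistant))
  )
  status <- withr::with_seed(params$seed, {
    res <- matrix(rbinom(params$n_resistant * params$n_genes, 1L,
                         rep(p_res, each = params$n_resistant)),
                  nrow = params$n_resistant)
    sen <- matrix(rbinom((params$n_patients - params$n_resistant) *
                           params$n_genes, 1L,
                         rep(p_sens, each = params$n_patients -
                               params$n_resistant)),
                  nrow = params$n_patients - params$n_resistant)
    rbind(res, sen)
  })
  dimnames(status) <- list(patients, genes)
  truth <- params$planted
  if (nrow(truth)) {
    truth$resistant_mut_prob <- resistant_prob(truth$target_or,
                                               truth$sensitive_mut_prob)
  } else {
    truth$resistant_mut_prob <- numeric(0)
  }
  list(cohort = new_cohort_matrix(status, labels), truth = truth)
}

#' Simulate a binary CNV-event matrix over a high-purity sample subset
#'
#' Same generative scheme as [simulate_cohort()], over recurrent CNV events
#' instead of genes, restricted to a seeded random subset of samples
#' (emulating the exclusion of low-tumour-purity samples before CNV
#' calling).
#'
#' @param params A [cohort_sim_params()] object (patient structure and
#'   background event probability).
#' @param n_events Number of CNV events (columns); 0 gives an empty matrix.
#' @param planted_events Optional tibble as in [planted_clinical()] with
#'   column `gene` naming the event.
#' @param high_purity_frac Fraction of samples retained. Default 2/3.
#' @return List with `events` (samples x events 0/1 matrix), `labels`
#'   (tibble for the retained samples) and `truth`.
#' @export
simulate_cnv_events <- function(params, n_events, planted_events = NULL,
                                high_purity_frac = 2 / 3) {
  stopifnot(inherits(params, "cohort_sim_params"), n_events >= 0)
  stopifnot(high_purity_frac > 0, high_purity_frac <= 1)
  planted <- validate_planted_clinical(planted_events)
  if (nrow(planted) > n_events) abort("More planted events than `n_events`.")
  ids <- unique(c(planted$gene, sprintf("EV%03d", seq_len(max(n_events, 0)))))
  ids <- ids[seq_len(n_events)]
  p_sens <- rep(params$background_mut_prob, n_events)
  p_res <- p_sens
  names(p_sens) <- names(p_res) <- ids
  if (nrow(planted)) {
    p_sens[planted$gene] <- planted$sensitive_mut_prob
    p_res[planted$gene] <- resistant_prob(planted$target_or,
                                          planted$sensitive_mut_prob)
  }
  patients <- sprintf("P%03d", seq_len(params$n_patients))
  response <- rep(c("resistant", "sensitive"),
                  c(params$n_resistant,
                    params$n_patients - params$n_resistant))
  out <- withr::with_seed(params$seed, {
    keep <- sort(sample.int(params$n_patients,
                            round(high_purity_frac * params$n_patients)))
    is_res <- response[keep] == "resistant"
    prob <- rbind(
      matrix(rep(p_res, each = sum(is_res)), nrow = sum(is_res)),
      matrix(rep(p_sens, each = sum(!is_res)), nrow = sum(!is_res))
    )
    m <- matrix(rbinom(length(prob), 1L, prob), nrow = nrow(prob))
    # rows currently grouped resistant-first; map back onto sorted keep order
    ord <- order(c(which(is_res), which(!is_res)))
    list(keep = keep, m = m[ord, , drop = FALSE])
  })
  events <- out$m
  dimnames(events) <- list(patients[out$keep], ids)
  labels <- tibble(patient = patients[out$keep],
                   response = response[out$keep])
  list(events = events, labels = labels, truth = planted)
}

#' Simulate a genome-wide CRISPR knockout screen
#'
#' Control-arm counts are negative binomial with mean
#' `baseline_mean * size_factor` and variance `mu + dispersion * mu^2`.
#' Treated-arm counts of sgRNAs targeting planted genes have their mean
#' multiplied by `fold` in the matching conditions. Library-size factors are
#' drawn log-uniform in \[0.7, 1.3\] and rescaled to geometric mean 1.
#'
#' @param params A [screen_sim_params()] object.
#' @return List with `screen` (a [screen_experiment] object) and `truth`
#'   (the planted tibble).
#' @export
#' @examples
#' p <- screen_sim_params(n_genes = 20, planted = planted_screen("G0001"),
#'                        seed = 3)
#' sim <- simulate_screen(p)
#' dim(sim$screen$counts)
simulate_screen <- function(params) {
  stopifnot(inherits(params, "screen_sim_params"))
  genes <- gene_universe(params$n_genes, params$planted$gene)
  sgrna_map <- tibble(
    sgrna = paste0(rep(genes, each = params$sgrnas_per_gene), "_sg",
                   seq_len(params$sgrnas_per_gene)),
    gene = rep(genes, each = params$sgrnas_per_gene)
  )
  samples <- tidyr::expand_grid(
    params$conditions,
    arm = c("treated", "control"),
    replicate = seq_len(params$replicates_per_arm)
  )
  samples$sample <- with(samples, paste(cell_line, drug,
                                        paste0("d", timepoint), arm,
                                        paste0("r", replicate), sep = "_"))
  samples <- samples[, c("sample", "cell_line", "drug", "timepoint",
                         "arm", "replicate")]
  n_sg <- nrow(sgrna_map)
  n_samp <- nrow(samples)

  # fold matrix: per sgRNA per sample multiplicative enrichment
  fold <- matrix(1, n_sg, n_samp)
  if (nrow(params$planted)) {
    for (i in seq_len(nrow(params$planted))) {
      pl <- params$planted[i, ]
      sg_rows <- sgrna_map$gene == pl$gene
      cond <- samples$arm == "treated"
      if (!is.na(pl$cell_line)) cond <- cond & samples$cell_line == pl$cell_line
      if (!is.na(pl$drug)) cond <- cond & samples$drug == pl$drug
      if (!is.na(pl$timepoint)) cond <- cond & samples$timepoint == pl$timepoint
      fold[sg_rows, cond] <- pl$fold
    }
  }

  counts <- withr::with_seed(params$seed, {
    sf <- exp(runif(n_samp, log(0.7), log(1.3)))
    sf <- sf / exp(mean(log(sf)))
    mu <- params$baseline_mean * fold *
      matrix(rep(sf, each = n_sg), nrow = n_sg)
    m <- matrix(rnbinom(n_sg * n_samp, size = 1 / params$dispersion,
                        mu = mu),
                nrow = n_sg)
    storage.mode(m) <- "integer"
    m
  })
  dimnames(counts) <- list(sgrna_map$sgrna, samples$sample)
  list(screen = new_screen_experiment(counts, sgrna_map, samples),
       truth = params$planted)
}

#' Combine clinical and screen planted truths
#'
#' @param clinical_planted Tibble of clinically planted genes (`gene`, ...).
#' @param screen_planted Tibble of screen-planted genes (`gene`, ...).
#' @return List with `clinical_planted`, `screen_planted` and
#'   `overlap_planted` (genes planted in both).
#' @export
sim_truth <- function(clinical_planted, screen_planted) {
  list(clinical_planted = clinical_planted,
       screen_planted = screen_planted,
       overlap_planted = intersect(clinical_planted$gene,
                                   screen_planted$gene))
}
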