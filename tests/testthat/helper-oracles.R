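# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: Fisher p by direct combinatorial
# summation over the hypergeometric support, RRA rho via the binomial-tail
# identity, and the hypergeometric upper tail as an explicit choose() sum.

# Two-sided Fisher exact p for one 2x2 table by brute-force enumeration of
# all tables with the observed margins; the point-probability convention
# with the standard relative guard against floating-point ties.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b           # resistant margin
  n2 <- c + d          # sensitive margin
  k <- a + c           # mutated margin
  if (k == 0) return(1)
  x <- max(0, k - n2):min(k, m)
  prob <- choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  obs <- prob[x == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# RRA rho via P[Beta(k, n-k+1) <= u] = P[Bin(n, u) >= k], truncated.
rra_rho_oracle <- function(u, alpha_frac) {
  u <- sort(u)
  n <- length(u)
  scores <- vapply(seq_len(n), function(k) {
    stats::pbinom(k - 1, n, u[k], lower.tail = FALSE)
  }, numeric(1))
  scores[u > alpha_frac] <- Inf
  out <- min(scores)
  if (!is.finite(out)) 1 else min(out, 1)
}

# Exact RRA permutation p by exhaustive enumeration of all rank subsets.
rra_p_oracle <- function(obs_ranks, N, alpha_frac) {
  s <- length(obs_ranks)
  rho_obs <- rra_rho_oracle(obs_ranks / N, alpha_frac)
  sets <- utils::combn(N, s)
  rho_null <- apply(sets, 2, function(r) rra_rho_oracle(r / N, alpha_frac))
  sum(rho_null <= rho_obs + 1e-12) / ncol(sets)
}

# Hypergeometric upper tail P[X >= k] as a direct choose() sum.
ora_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Tiny hand-built cohort: `muts` gives per-patient mutated genes.
toy_cohort <- function(muts, response) {
  patients <- names(muts)
  genes <- sort(unique(unlist(muts)))
  status <- matrix(0L, length(patients), length(genes),
                   dimnames = list(patients, genes))
  for (p in patients) status[p, muts[[p]]] <- 1L
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = rep(patients, lengths(muts)),
    Hugo_Symbol = unlist(muts, use.names = FALSE),
    Variant_Classification = "Missense_Mutation"
  )
  labels <- tibble::tibble(patient = patients, response = response)
  build_cohort_matrix(maf, labels)
}

# Small screen with hand-set counts: one condition, one replicate per arm.
toy_screen <- function(counts_treated, counts_control, genes) {
  sg <- paste0("sg", seq_along(genes))
  counts <- cbind(t1 = counts_treated, c1 = counts_control)
  rownames(counts) <- sg
  samples <- tibble::tibble(
    sample = c("t1", "c1"), cell_line = "HeLa", drug = "cisplatin",
    timepoint = 7L, arm = c("treated", "control"), replicate = 1L
  )
  screen_experiment(counts, tibble::tibble(sgrna = sg, gene = genes),
                    samples)
}

# Per-condition results tibble shaped like screen_rra() output, for set
# logic tests.
toy_results <- function(gene, cell_line, drug = "cisplatin", timepoint = 7L,
                        p, lfc = 1, score = p) {
  tibble::tibble(cell_line = cell_line, drug = drug, timepoint = timepoint,
                 gene = gene, n_sgrna = 6L, lfc = lfc, score = score, p = p,
                 rank = rank(score), selected = p < 0.05 & lfc > 0)
}

# Minimal clinical_gene_set built from an assoc-shaped tibble.
toy_clinical_set <- function(assoc, alpha = 0.05) {
  clinical_candidate_set(assoc, alpha = alpha)
}

toy_assoc_row <- function(gene, a, c, n_res = 48, n_sens = 87) {
  or <- odds_ratio(a, n_res - a, c, n_sens - c)
  tibble::tibble(
    gene = gene, a = a, b = n_res - a, c = c, d = n_sens - c,
    or_raw = or$or_raw, or_flag = or$or_flag,
    or_corrected = or$or_corrected,
    p = fisher_exact(a, n_res - a, c, n_sens - c),
    q = NA_real_,
    category = dplyr::case_when(a > 0 & c == 0 ~ "resistant_only",
                                a == 0 & c > 0 ~ "sensitive_only",
                                a > 0 & c > 0 ~ "shared",
                                TRUE ~ "unmutated"),
    mut_freq = (a + c) / (n_res + n_sens)
  )
}
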