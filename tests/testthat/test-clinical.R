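test_that("MAF records collapse to gene-level binary status", {
  cohort <- toy_cohort(
    list(P1 = c("TTN", "TTN", "PIK3CA"), P2 = "TTN", P3 = character(0)),
    response = c("resistant", "sensitive", "sensitive")
  )
  expect_equal(cohort$status["P1", "TTN"], 1L)       # many-to-one collapse
  expect_equal(cohort$status["P3", ], c(PIK3CA = 0L, TTN = 0L))
  expect_equal(glance(cohort)$n_patients_mutated, 2)
})

test_that("unknown patients error and empty input warns", {
  labs <- tibble::tibble(patient = "P1", response = "resistant")
  bad <- tibble::tibble(Tumor_Sample_Barcode = "P9", Hugo_Symbol = "TTN",
                        Variant_Classification = "Missense_Mutation")
  expect_error(build_cohort_matrix(bad, labs), "P9")
  expect_warning(build_cohort_matrix(bad[0, ], labs), "No mutation records")
})

test_that("nonsynonymous filter drops silent classes and uppercases symbols", {
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = c("P1", "P1", "P2"),
    Hugo_Symbol = c("ttn ", "BRCA2", "brca2"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation")
  )
  labs <- tibble::tibble(patient = c("P1", "P2"),
                         response = c("resistant", "sensitive"))
  cohort <- build_cohort_matrix(maf, labs)
  expect_setequal(colnames(cohort$status), c("TTN", "BRCA2"))
  expect_equal(cohort$status["P1", "BRCA2"], 0L)
  all_in <- build_cohort_matrix(maf, labs, nonsynonymous_only = FALSE)
  expect_equal(all_in$status["P1", "BRCA2"], 1L)
})

test_that("cohort mutation frequencies reproduce printed percentages", {
  # 45 of 135 patients mutated in one gene -> 33.33%
  pts <- sprintf("P%03d", 1:135)
  maf <- tibble::tibble(Tumor_Sample_Barcode = pts[1:45],
                        Hugo_Symbol = "TTN",
                        Variant_Classification = "Missense_Mutation")
  labs <- tibble::tibble(patient = pts,
                         response = rep(c("resistant", "sensitive"),
                                        c(48, 87)))
  cohort <- build_cohort_matrix(maf, labs)
  assoc <- associate_genes(cohort)
  expect_equal(round(100 * assoc$mut_freq[assoc$gene == "TTN"], 2), 33.33)
  # 102 of 135 patients carrying any mutation -> 75.56%
  maf2 <- tibble::tibble(Tumor_Sample_Barcode = pts[1:102],
                         Hugo_Symbol = paste0("GENE", 1:102),
                         Variant_Classification = "Missense_Mutation")
  cohort2 <- build_cohort_matrix(maf2, labs)
  expect_equal(round(100 * glance(cohort2)$frac_patients_mutated, 2), 75.56)
})

test_that("odds ratios match direct evaluation and flag structural zeros", {
  expect_equal(odds_ratio(5, 5, 5, 5)$or_raw, 1)
  expect_equal(odds_ratio(6, 42, 1, 86)$or_raw, 516 / 42)
  cc <- odds_ratio(3, 10, 0, 20)
  expect_equal(cc$or_flag, "inf")
  expect_equal(cc$or_corrected, (3.5 * 20.5) / (10.5 * 0.5))
  expect_equal(odds_ratio(0, 10, 3, 20)$or_flag, "zero")
  expect_equal(odds_ratio(0, 48, 0, 87)$or_flag, "undefined")
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p matches brute-force enumeration on small tables", {
  expect_equal(fisher_exact(0, 48, 0, 87), 1)
  expect_equal(fisher_exact(2, 2, 2, 2), 1)
  set.seed(42)
  for (i in 1:50) {
    t <- as.integer(rmultinom(1, sample(4:24, 1), rep(1 / 4, 4)))
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4]),
                 fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
  }
})

test_that("gene association categories partition the gene set", {
  sim <- simulate_cohort(cohort_sim_params(n_genes = 300, seed = 3))
  assoc <- associate_genes(sim$cohort)
  expect_equal(nrow(assoc), 300)
  expect_setequal(unique(assoc$category),
                  intersect(c("resistant_only", "sensitive_only", "shared",
                              "unmutated"), assoc$category))
  expect_equal(sum(table(assoc$category)), 300)
  expect_true(all(assoc$p[assoc$category == "unmutated"] == 1))
  # BH q dominates p and is monotone in p
  mutated <- !is.na(assoc$q)
  expect_true(all(assoc$q[mutated] >= assoc$p[mutated]))
  ord <- order(assoc$p[mutated])
  expect_true(!is.unsorted(assoc$q[mutated][ord]))
})

test_that("label swap inverts the odds ratio and preserves p", {
  sim <- simulate_cohort(cohort_sim_params(
    n_genes = 50, planted = planted_clinical("PG1", 6, 0.05), seed = 8))
  assoc <- associate_genes(sim$cohort)
  flipped <- sim$cohort
  flipped$labels$response <- ifelse(flipped$labels$response == "resistant",
                                    "sensitive", "resistant")
  cohort2 <- build_cohort_matrix(
    tidyr::pivot_longer(tibble::as_tibble(flipped$status,
                                          rownames = "patient"),
                        -patient, names_to = "gene",
                        values_to = "mut") |>
      dplyr::filter(mut == 1) |>
      dplyr::transmute(Tumor_Sample_Barcode = patient, Hugo_Symbol = gene,
                       Variant_Classification = "Missense_Mutation"),
    flipped$labels)
  assoc2 <- associate_genes(cohort2)
  shared <- assoc$gene[assoc$category == "shared"]
  m <- match(shared, assoc2$gene)
  expect_equal(assoc2$or_raw[m], 1 / assoc$or_raw[match(shared, assoc$gene)])
  expect_equal(assoc2$p[m], assoc$p[match(shared, assoc$gene)])
})

test_that("moving a patient into the mutated-resistant cell never lowers OR", {
  set.seed(11)
  for (i in 1:25) {
    a <- sample(0:10, 1); b <- sample(1:10, 1)
    c <- sample(0:10, 1); d <- sample(0:10, 1)
    or1 <- odds_ratio(a, b, c, d)$or_corrected
    or2 <- odds_ratio(a + 1, b - 1, c, d)$or_corrected
    expect_gte(or2, or1)
  }
})

test_that("planted clinical genes are classified resistant-enriched", {
  r <- vapply(1:200, function(s) {
    sim <- simulate_cohort(cohort_sim_params(
      n_genes = 5, planted = planted_clinical("PG1"), seed = s))
    g <- associate_genes(sim$cohort)
    g <- g[g$gene == "PG1", ]
    c(enriched = g$or_corrected > 1, shared = g$category == "shared",
      window = g$or_corrected >= 3 & g$or_corrected <= 30)
  }, c(enriched = TRUE, shared = TRUE, window = TRUE))
  expect_gte(mean(r["enriched", ]), 0.90)
  # point estimate near truth among genes seen in both groups
  expect_gte(sum(r["shared", ] & r["window", ]) / sum(r["shared", ]), 0.90)
})

test_that("candidate set applies the resistant-only / shared-OR>1 rule", {
  assoc <- dplyr::bind_rows(
    toy_assoc_row("R1", 3, 0), toy_assoc_row("R2", 2, 0),
    toy_assoc_row("R3", 5, 0),
    toy_assoc_row("S1", 6, 2), toy_assoc_row("S2", 8, 3),  # shared OR > 1
    toy_assoc_row("S3", 1, 9),                             # shared OR < 1
    toy_assoc_row("N1", 0, 4)                              # sensitive only
  )
  cset <- clinical_candidate_set(assoc)
  expect_setequal(cset$members, c("R1", "R2", "R3", "S1", "S2"))
  expect_equal(sum(cset$table$provenance == "resistant_only"), 3)
  expect_true(all(cset$significant_subset %in% cset$members))
  empty <- clinical_candidate_set(assoc[0, ])
  expect_length(empty$members, 0)
})

test_that("CNV association flags degenerate and response-related events", {
  m <- cbind(ALLONE = rep(1L, 10), GOOD = c(rep(1L, 4), rep(0L, 6)))
  rownames(m) <- sprintf("S%02d", 1:10)
  labs <- tibble::tibble(patient = rownames(m),
                         response = rep(c("resistant", "sensitive"), each = 5))
  a <- associate_cnv_events(m, labs)
  expect_equal(a$or_flag[a$event == "ALLONE"], "undefined")
  expect_equal(a$p[a$event == "ALLONE"], 1)
  expect_error(associate_cnv_events(m, labs[-1, ]), "Unlabelled")
})
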