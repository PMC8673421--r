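test_that("cohort simulation is a pure function of its parameters", {
  p <- cohort_sim_params(n_genes = 40, planted = planted_clinical("PG1"),
                         seed = 9)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort$status, s2$cohort$status)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(cohort_sim_params(n_genes = 40,
                                          planted = planted_clinical("PG1"),
                                          seed = 10))
  expect_false(identical(s1$cohort$status, s3$cohort$status))
})

test_that("planted genes follow the odds transform for the resistant group", {
  # large groups so empirical frequencies pin down the generative probs
  p <- cohort_sim_params(n_patients = 12000, n_resistant = 6000,
                         n_genes = 1,
                         planted = planted_clinical("PG1", target_or = 10,
                                                    sensitive_mut_prob = 0.02),
                         seed = 4)
  sim <- simulate_cohort(p)
  is_res <- sim$cohort$labels$response == "resistant"
  p_r_hat <- mean(sim$cohort$status[is_res, "PG1"])
  p_s_hat <- mean(sim$cohort$status[!is_res, "PG1"])
  o_s <- 0.02 / 0.98
  p_r <- 10 * o_s / (1 + 10 * o_s)
  expect_equal(p_r_hat, p_r, tolerance = 0.1)
  expect_equal(p_s_hat, 0.02, tolerance = 0.15)
  expect_equal(sim$truth$resistant_mut_prob, p_r)
})

test_that("impossible planted parameters are rejected with the gene named", {
  expect_error(
    cohort_sim_params(planted = planted_clinical("BADGENE", target_or = 0)),
    "target_or"
  )
  expect_error(
    cohort_sim_params(planted = planted_clinical("X", sensitive_mut_prob = 1)),
    "sensitive_mut_prob"
  )
  expect_error(cohort_sim_params(n_resistant = 0), "n_resistant")
})

test_that("CNV simulation handles degenerate input and subsets samples", {
  par <- cohort_sim_params(n_genes = 5, seed = 2)
  empty <- simulate_cnv_events(par, n_events = 0)
  expect_equal(ncol(empty$events), 0)
  expect_equal(nrow(empty$events), round(2 / 3 * 135))

  cnv <- simulate_cnv_events(par, n_events = 10)
  expect_identical(cnv$events,
                   simulate_cnv_events(par, n_events = 10)$events)
  expect_equal(nrow(cnv$events), 90)
  expect_true(all(cnv$events %in% 0:1))
  expect_setequal(rownames(cnv$events), cnv$labels$patient)
})

test_that("planted CNV events are recoverable at calibrated rates", {
  # fixed seeds; rates frozen from a prior larger oracle simulation
  r <- vapply(1:200, function(s) {
    par <- cohort_sim_params(n_genes = 2, seed = s)
    win <- simulate_cnv_events(par, 10, planted_clinical("EVP", 4, 0.1))
    sig <- simulate_cnv_events(par, 10, planted_clinical("EVP", 4, 0.15))
    aw <- associate_cnv_events(win$events, win$labels)
    as <- associate_cnv_events(sig$events, sig$labels)
    c(aw$or_corrected[aw$event == "EVP"] >= 2 &
        aw$or_corrected[aw$event == "EVP"] <= 8,
      as$p[as$event == "EVP"] < 0.05)
  }, logical(2))
  expect_gte(mean(r[1, ]), 0.70)
  expect_gte(mean(r[2, ]), 0.60)
})

test_that("screen simulation is deterministic and structurally sound", {
  p <- screen_sim_params(n_genes = 15, planted = planted_screen("G0001"),
                         seed = 5)
  s1 <- simulate_screen(p)
  s2 <- simulate_screen(p)
  expect_identical(s1$screen$counts, s2$screen$counts)
  expect_equal(nrow(s1$screen$counts), 15 * 6)
  # every sgRNA maps to exactly one gene
  expect_equal(anyDuplicated(s1$screen$sgrna_map$sgrna), 0)
  expect_equal(dplyr::n_distinct(s1$screen$sgrna_map$gene), 15)
  # 8 conditions x 2 arms x 2 replicates
  expect_equal(ncol(s1$screen$counts), 32)
  expect_error(screen_sim_params(dispersion = 0), "dispersion")
})

test_that("control-arm counts match the negative-binomial baseline mean", {
  # > 1e5 control draws; marginal mean within 2% of baseline_mean
  p <- screen_sim_params(n_genes = 8400, sgrnas_per_gene = 6,
                         conditions = default_screen_conditions()[1, ],
                         replicates_per_arm = 2, baseline_mean = 300,
                         seed = 21)
  sim <- simulate_screen(p)
  ctrl <- sim$screen$samples$sample[sim$screen$samples$arm == "control"]
  draws <- sim$screen$counts[, ctrl]
  expect_gte(length(draws), 1e5)
  expect_equal(mean(draws), 300, tolerance = 0.02)
  # planted enrichment appears only in treated arms
  p2 <- screen_sim_params(n_genes = 50,
                          conditions = default_screen_conditions()[1, ],
                          planted = planted_screen("PG1", fold = 8),
                          seed = 22)
  sim2 <- simulate_screen(p2)
  meta <- sim2$screen$samples
  sg <- sim2$screen$sgrna_map$gene == "PG1"
  m_t <- mean(sim2$screen$counts[sg, meta$sample[meta$arm == "treated"]])
  m_c <- mean(sim2$screen$counts[sg, meta$sample[meta$arm == "control"]])
  expect_gt(m_t / m_c, 4)
})

test_that("condition-restricted planting only enriches matching conditions", {
  p <- screen_sim_params(
    n_genes = 60,
    planted = planted_screen("PG1", fold = 8, cell_line = "HeLa"),
    seed = 7)
  sim <- simulate_screen(p)
  meta <- sim$screen$samples
  sg <- sim$screen$sgrna_map$gene == "PG1"
  hela_t <- meta$sample[meta$arm == "treated" & meta$cell_line == "HeLa"]
  siha_t <- meta$sample[meta$arm == "treated" & meta$cell_line == "SiHa"]
  siha_c <- meta$sample[meta$arm == "control" & meta$cell_line == "SiHa"]
  expect_gt(mean(sim$screen$counts[sg, hela_t]),
            4 * mean(sim$screen$counts[sg, siha_t]))
  expect_equal(mean(sim$screen$counts[sg, siha_t]) /
                 mean(sim$screen$counts[sg, siha_c]), 1, tolerance = 0.25)
})

test_that("combined truth exposes the planted overlap", {
  tr <- sim_truth(planted_clinical(c("A", "B", "C")),
                  planted_screen(c("B", "C", "D")))
  expect_setequal(tr$overlap_planted, c("B", "C"))
})
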