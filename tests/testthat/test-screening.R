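test_that("perfect-assay limits route patients down the expected branches", {
  cfg <- perfect_test_config()
  set.seed(1)
  res <- run_decision_tree(one_patient(TRUE, "MLH1"), "strategy1", cfg)
  expect_true(res$is_proband)
  expect_equal(res$tests_performed$assay, c("ihc", "braf", "sequencing_x1"))

  set.seed(1)
  res2 <- run_decision_tree(one_patient(TRUE, "MSH2"), "strategy1", cfg)
  expect_equal(res2$tests_performed$assay, c("ihc", "sequencing_x1"))

  set.seed(1)
  res3 <- run_decision_tree(one_patient(TRUE, "MSH6"), "strategy3", cfg)
  expect_true(res3$is_proband)
  expect_equal(res3$tests_performed$assay, c("msi", "sequencing_x4"))

  # with perfect specificity no unaffected patient becomes a proband
  unaffected <- tibble::tibble(patient_id = 1:500, has_ls = FALSE,
                               causal_gene = NA_character_)
  for (s in c("strategy1", "strategy2", "strategy3", "strategy4")) {
    set.seed(2)
    expect_equal(sum(screen_patients(unaffected, s, cfg)$is_proband), 0)
  }
})

test_that("IHC false positives trigger sequencing at the expected binomial rate", {
  cfg <- perfect_test_config()
  cfg$tests$ihc$specificity <- 0.95
  unaffected <- tibble::tibble(patient_id = 1:1000, has_ls = FALSE,
                               causal_gene = NA_character_)
  set.seed(42)
  res <- screen_patients(unaffected, "strategy2", cfg)
  n_seq <- sum(res$genes_sequenced > 0)
  # Binomial(1000, 0.05): expect 50, keep 3.3-sigma slack
  expect_lt(abs(n_seq - 50), 3.3 * sqrt(1000 * 0.05 * 0.95))
  # perfect sequencing specificity: none of them become probands
  expect_equal(sum(res$is_proband), 0)
})

test_that("BRAF reflex testing spares sporadic MLH1-deficient tumours from sequencing", {
  cfg <- perfect_test_config()
  cfg$tests$ihc$specificity <- 0 # every unaffected tumour shows MLH1 loss
  cfg$p_braf_pos_sporadic <- 1 # and every one is BRAF-positive
  unaffected <- tibble::tibble(patient_id = 1:200, has_ls = FALSE,
                               causal_gene = NA_character_)
  set.seed(3)
  s1 <- screen_patients(unaffected, "strategy1", cfg)
  expect_equal(sum(s1$genes_sequenced), 0)
  expect_true(all(s1$did_braf))
  set.seed(3)
  s2 <- screen_patients(unaffected, "strategy2", cfg)
  expect_equal(sum(s2$genes_sequenced), 200)
})

test_that("assay costs accumulate per patient according to the tree", {
  cfg <- perfect_test_config()
  set.seed(1)
  res <- screen_patients(one_patient(TRUE, "MLH1"), "strategy1", cfg)
  expect_equal(res$assay_cost,
               cfg$costs$ihc + cfg$costs$braf + cfg$costs$sequencing_per_gene)
  set.seed(1)
  res4 <- screen_patients(one_patient(FALSE), "strategy4", cfg)
  expect_equal(res4$assay_cost, 4 * cfg$costs$sequencing_per_gene)
})

test_that("perfect assays make strategies 2-4 find the same probands", {
  cfg <- perfect_test_config(small_config())
  coh <- simulate_cohort(cfg, seed = 9)
  probands <- lapply(c("strategy2", "strategy3", "strategy4"), function(s) {
    set.seed(77)
    scr <- screen_cohort(coh, s, cfg)
    scr$summary$n_probands
  })
  expect_equal(probands[[1]], probands[[2]])
  expect_equal(probands[[2]], probands[[3]])
})

test_that("cascade uptake matches the product of the published rates", {
  cfg <- perfect_test_config(small_config(3000L))
  coh <- simulate_cohort(cfg, seed = 13)
  set.seed(21)
  scr <- screen_cohort(coh, "strategy4", cfg)
  n_prob <- scr$summary$n_probands
  # 4 relatives x 52% counseling x 95% testing = 1.976 tested per proband
  expected_tested <- n_prob * 4 * 0.52 * 0.95
  expect_gt(n_prob, 10)
  expect_lt(abs(scr$summary$n_relatives_tested - expected_tested),
            4 * sqrt(expected_tested))
  # half of the tested relatives of true probands carry the family mutation
  expect_lt(abs(scr$summary$n_relatives_detected -
                  scr$summary$n_relatives_tested * 0.5),
            4 * sqrt(scr$summary$n_relatives_tested * 0.25) + 1)
  expect_lte(scr$summary$n_relatives_detected, scr$summary$n_relatives_tested)
})

test_that("acceptance gates the whole pipeline and the referent does nothing", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 4)
  cfg0 <- cfg
  cfg0$p_accept_testing <- 0
  set.seed(1)
  scr0 <- screen_cohort(coh, "strategy4", cfg0)
  expect_equal(scr0$summary$n_probands, 0)
  expect_equal(scr0$summary$cost_detect_probands, 0)
  expect_equal(scr0$summary$cost_detect_relatives, 0)

  set.seed(1)
  ref <- screen_cohort(coh, "referent", cfg)
  expect_equal(ref$summary$n_probands, 0)
  expect_equal(ref$summary$cost_detect_probands +
                 ref$summary$cost_detect_relatives, 0)
  expect_false(any(ref$relatives$detected))
  expect_error(screen_cohort(coh, "strategy9", cfg))
})
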