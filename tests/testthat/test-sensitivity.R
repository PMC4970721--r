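test_that("moment matching recovers the requested mean and spread", {
  cfg <- default_config()
  specs <- tibble::tibble(parameter = "p_adopt_surveillance",
                          family = "beta", mean = 0.5, sd = 0.1)
  set.seed(5)
  draws <- vapply(1:4000, function(i) {
    sample_parameters(cfg, specs)$p_adopt_surveillance
  }, numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * stats::sd(draws) / sqrt(4000))
  expect_lt(abs(stats::sd(draws) - 0.1), 0.01)
  expect_true(all(draws >= 0 & draws <= 1))

  # zero spread returns the base value untouched
  degenerate <- tibble::tibble(parameter = "prevalence_ls_crc",
                               family = "beta", mean = 0.023, sd = 0)
  expect_equal(sample_parameters(cfg, degenerate)$prevalence_ls_crc, 0.023)
})

test_that("sampling rejects unknown fields and impossible beta variances", {
  cfg <- default_config()
  expect_error(
    sample_parameters(cfg, tibble::tibble(parameter = "no_such_field",
                                          family = "beta", mean = 0.5, sd = 0.1)),
    "no_such_field"
  )
  expect_error(
    sample_parameters(cfg, tibble::tibble(parameter = "prevalence_ls_crc",
                                          family = "beta", mean = 0.023, sd = 0.5)),
    "prevalence_ls_crc"
  )
})

test_that("default PSA specification pairs families with parameter roles", {
  specs <- psa_default_specs(default_config())
  expect_true(all(specs$family[grepl("^costs\\.", specs$parameter)] == "gamma"))
  expect_equal(specs$family[specs$parameter == "mean_relatives"], "poisson")
  expect_equal(specs$family[specs$parameter == "risk_reduction_surveillance"],
               "lognormal")
  expect_true(all(specs$family[specs$parameter %in%
                                 c("prevalence_ls_crc", "p_counseling")] == "beta"))
  # bound-derived spread: (0.05 - 0.01) / (2 * 1.96)
  expect_equal(specs$sd[specs$parameter == "prevalence_ls_crc"], 0.04 / 3.92)
})

test_that("PSA produces one record per draw and strategy", {
  cfg <- small_config(800L)
  psa <- run_psa(cfg, n_draws = 4, seed = 1, n_patients = 800L)
  expect_equal(nrow(psa), 4 * 4)
  expect_equal(sort(unique(psa$strategy)), paste0("strategy", 1:4))
  expect_true(all(is.finite(psa$delta_cost)))
  # screening always spends money relative to the referent
  expect_true(all(psa$delta_cost > 0))
})

test_that("acceptability curves follow the net-monetary-benefit definition", {
  toy <- tibble::tibble(
    draw = c(1, 2), strategy = "strategy1",
    delta_ly = c(1, 1), delta_cost = c(10, 30)
  )
  curves <- ceac(toy, thresholds = c(0, 20, 50))
  expect_equal(curves$probability, c(0, 0.5, 1))

  toy2 <- tibble::tibble(draw = 1:3, strategy = "strategy1",
                         delta_ly = 0.01, delta_cost = 100)
  expect_equal(ceac(toy2, thresholds = 50000)$probability, 1)
  expect_equal(ceac(toy2, thresholds = 0)$probability, 0)
  expect_error(ceac(toy[0, ], thresholds = 0), "empty")
})

test_that("CEAC is non-decreasing in the threshold when all gains are positive", {
  cfg <- small_config(800L)
  psa <- run_psa(cfg, n_draws = 6, seed = 2, n_patients = 800L)
  psa$delta_ly <- abs(psa$delta_ly)
  curves <- ceac(psa, thresholds = seq(0, 100000, by = 10000))
  for (s in unique(curves$strategy)) {
    p <- curves$probability[curves$strategy == s][order(
      curves$threshold[curves$strategy == s])]
    expect_true(all(diff(p) >= 0))
  }
  # at a zero threshold the curve equals the fraction of cost-saving draws
  at0 <- ceac(psa, thresholds = 0)
  for (s in unique(psa$strategy)) {
    expect_equal(at0$probability[at0$strategy == s],
                 mean(psa$delta_cost[psa$strategy == s] < 0))
  }
})

test_that("degenerate tornado bounds give exactly zero ranges", {
  cfg <- small_config(600L)
  bounds <- list(
    prevalence_ls_crc = c(0.023, 0.023),
    p_adopt_surveillance = c(0.79, 0.79)
  )
  tor <- tornado(cfg, bounds = bounds, replicates = 2, seed = 4,
                 n_patients = 600L)
  expect_equal(tor$range, c(0, 0))
  expect_equal(tor$icer_low, tor$icer_high)
})

test_that("tornado rejects bounds outside the valid domain and keeps sort order", {
  cfg <- small_config(600L)
  expect_error(
    tornado(cfg, bounds = list(prevalence_ls_crc = c(-0.1, 0.5)),
            replicates = 1, seed = 1, n_patients = 600L),
    "prevalence_ls_crc"
  )
  tor <- tornado(
    cfg,
    bounds = list(prevalence_ls_crc = c(0.01, 0.05),
                  fit_participation = c(0.214, 0.214)),
    replicates = 3, seed = 9, n_patients = 4000L
  )
  expect_true(!is.unsorted(rev(tor$range)))
  expect_equal(tor$parameter[1], "prevalence_ls_crc")
  expect_gt(tor$range[1], 0)
})
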