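test_that("strategy evaluation satisfies the accounting identities", {
  cfg <- small_config(3000L)
  coh <- simulate_cohort(cfg, seed = 6)
  for (s in c("referent", "strategy1", "strategy4")) {
    res <- evaluate_strategy(coh, s, cfg, seed = 6)
    expect_equal(
      res$total_cost,
      res$cost_detect_probands + res$cost_detect_relatives +
        res$cost_surveillance_treatment,
      tolerance = 1e-9
    )
    expect_equal(res$cost_per_carrier * res$n_carriers, res$total_cost,
                 tolerance = 1e-9)
  }
  ref <- evaluate_strategy(coh, "referent", cfg, seed = 6)
  expect_equal(ref$cost_detect_probands, 0)
  expect_equal(ref$cost_detect_relatives, 0)
  expect_gt(ref$cost_surveillance_treatment, 0)
})

test_that("a cascade with zero uptake collapses to the referent outcome", {
  cfg <- small_config(3000L)
  cfg$p_counseling <- 0
  coh <- simulate_cohort(cfg, seed = 10)
  s1 <- evaluate_strategy(coh, "strategy1", cfg, seed = 10)
  ref <- evaluate_strategy(coh, "referent", cfg, seed = 10)
  # no relative is ever detected, so the lifetime draws coincide exactly
  expect_equal(s1$ly_per_carrier, ref$ly_per_carrier, tolerance = 1e-12)
  expect_equal(s1$cost_surveillance_treatment, ref$cost_surveillance_treatment,
               tolerance = 1e-9)
  expect_gt(s1$cost_detect_probands, 0)
})

test_that("icer_table reproduces hand arithmetic, ordering, and dominance", {
  toy <- tibble::tibble(
    strategy = c("referent", "strategy1", "strategy2"),
    ly_per_carrier = c(21.551, 21.834, 21.834),
    cost_per_carrier = c(4032, 5735, 5735)
  )
  tab <- icer_table(toy, gdp_per_capita = 21308)
  s1 <- tab[tab$strategy == "strategy1", ]
  # (5735 - 4032) / (21.834 - 21.551) = 6018.4
  expect_equal(s1$icer_vs_referent, 1703 / 0.283, tolerance = 1e-9)
  expect_equal(s1$icer_vs_previous, s1$icer_vs_referent)
  expect_equal(s1$who_category, "highly_cost_effective")
  # same cost and LY as previous: dominated vs previous, no ratio
  s2 <- tab[tab$strategy == "strategy2", ]
  expect_true(is.na(s2$icer_vs_previous))

  toy2 <- tibble::tibble(
    strategy = c("referent", "strategy1"),
    ly_per_carrier = c(1, 2),
    cost_per_carrier = c(0, 100)
  )
  expect_equal(icer_table(toy2, 21308)$icer_vs_referent[2], 100)
})

test_that("WHO categories split at one and three times GDP per capita", {
  gdp <- 21308
  expect_equal(who_category(6025, gdp), "highly_cost_effective")
  expect_equal(who_category(gdp, gdp), "cost_effective")
  expect_equal(who_category(3 * gdp, gdp), "cost_effective")
  expect_equal(who_category(145110, gdp), "not_cost_effective")
  expect_error(who_category(100, -1), "positive")
  expect_error(who_category(-5, gdp), "non-negative")
})

test_that("all screening strategies gain life-years over the referent", {
  cfg <- small_config(6000L)
  ev <- evaluate_strategies(cfg, seed = 2)
  ref_ly <- ev$ly_per_carrier[ev$strategy == "referent"]
  for (s in paste0("strategy", 1:4)) {
    expect_gte(ev$ly_per_carrier[ev$strategy == s], ref_ly)
  }
  # detection spending is ordered 1 < 2 < 3 < 4 under the base-case costs
  det <- ev$cost_detect_probands[match(paste0("strategy", 1:4), ev$strategy)]
  expect_true(all(diff(det) > 0))
})

test_that("tidy and glance expose the evaluation in broom form", {
  cfg <- small_config(1000L)
  ev <- evaluate_strategies(cfg, seed = 3, strategies = c("referent", "strategy1"))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  g <- glance(ev)
  expect_equal(g$n_strategies, 2)
  expect_equal(g$seed, 3)
  expect_equal(g$referent_ly_per_carrier,
               ev$ly_per_carrier[ev$strategy == "referent"])
})
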