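test_that("annual cancer death probability round-trips five-year survival", {
  expect_equal(annual_cancer_death_prob(1), 0)
  expect_equal(annual_cancer_death_prob(0), 1)
  for (s in c(0.12, 0.5, 0.86)) {
    d <- annual_cancer_death_prob(s)
    expect_equal((1 - d)^5, s, tolerance = 1e-12)
  }
  expect_equal(annual_cancer_death_prob(0.5), 1 - 0.5^0.2)
  expect_error(annual_cancer_death_prob(1.2), "\\[0, 1\\]")
})

test_that("stage-shift mixing hits the survival uplift target", {
  base <- c(0, 0, 0, 1)
  surv <- c(0.9, 0.8, 0.5, 0.1)
  shifted <- adjust_stage_distribution(base, surv, 0.2)
  # lambda solves 0.9 l + 0.1 (1 - l) = 0.12
  expect_equal(shifted, c(0.025, 0, 0, 0.975))
  expect_equal(sum(shifted * surv), 1.2 * sum(base * surv))

  expect_equal(adjust_stage_distribution(base, surv, 0), base)
  # already all stage 1: uplift unattainable, lambda capped
  expect_equal(adjust_stage_distribution(c(1, 0, 0, 0), surv, 0.5), c(1, 0, 0, 0))
  expect_error(adjust_stage_distribution(c(0, 0, 0, 1), c(0.9, 0.8, 0.5, 0), 0.2),
               "zero")
})

test_that("hazard-free life-years reduce to the closed-form annuity", {
  cfg <- hazard_free_config(horizon = 80, discount = 0)
  expect_equal(expected_outcomes(35, "none", cfg)$discounted_ly, 45)

  cfg10 <- hazard_free_config(horizon = 45, discount = 0.03)
  annuity <- sum(1.03^-(1:10))
  expect_equal(expected_outcomes(35, "none", cfg10)$discounted_ly, annuity)
  expect_equal(annuity, 8.5302, tolerance = 1e-4)
  set.seed(1)
  sim <- simulate_relatives(rep(35, 5), "none", cfg10)
  expect_equal(sim$discounted_ly, rep(annuity, 5))
})

test_that("state-probability mass is conserved through every cycle", {
  cfg <- default_config()
  for (md in c("none", "referent", "routine_fit", "colonoscopy")) {
    eo <- expected_outcomes(30, md, cfg)
    expect_lt(attr(eo, "conservation_gap"), 1e-10)
    expect_gte(eo$discounted_ly, 0)
    r <- cfg$discount_rate
    expect_lte(eo$discounted_ly, (1 - (1 + r)^-(cfg$horizon_age - 30)) / r)
  }
})

test_that("microsimulation means agree with the cohort expectation", {
  cfg <- default_config()
  n <- 20000
  for (md in c("referent", "colonoscopy")) {
    eo <- expected_outcomes(35, md, cfg)
    set.seed(7)
    sim <- simulate_relatives(rep(35, n), md, cfg)
    se_ly <- stats::sd(sim$discounted_ly) / sqrt(n)
    se_cost <- stats::sd(sim$discounted_cost) / sqrt(n)
    expect_lt(abs(mean(sim$discounted_ly) - eo$discounted_ly), 3 * se_ly)
    expect_lt(abs(mean(sim$discounted_cost) - eo$discounted_cost), 3 * se_cost)
    expect_lt(abs(mean(sim$n_crc_events) - eo$n_crc_events),
              3 * stats::sd(sim$n_crc_events) / sqrt(n))
  }
})

test_that("surveillance reduces incidence by the configured proportion", {
  cfg <- default_config()
  e_colo <- expected_outcomes(35, "colonoscopy", cfg)
  e_none <- expected_outcomes(35, "none", cfg)
  # stronger mortality under no surveillance removes at-risk person-time, so
  # the event ratio sits near, not exactly at, 1 - 0.59
  ratio <- e_colo$n_crc_events / e_none$n_crc_events
  expect_gt(ratio, 0.33)
  expect_lt(ratio, 0.50)
  expect_gt(e_colo$discounted_ly, e_none$discounted_ly)
})

test_that("discounting, hazards, and survival move life-years the right way", {
  cfg <- default_config()
  ly_at <- function(r) {
    c2 <- cfg
    c2$discount_rate <- r
    expected_outcomes(35, "referent", c2)$discounted_ly
  }
  expect_gt(ly_at(0), ly_at(0.03))
  expect_gt(ly_at(0.03), ly_at(0.05))

  # equal stage distributions + no risk reduction: all modes agree on LY
  c3 <- cfg
  c3$risk_reduction_surveillance <- 0
  c3$survival_uplift_colonoscopy <- 0
  c3$stage_dist_fit <- c3$stage_dist_none
  lys <- vapply(c("none", "referent", "routine_fit", "colonoscopy"),
                function(md) expected_outcomes(35, md, c3)$discounted_ly,
                numeric(1))
  expect_equal(max(lys) - min(lys), 0, tolerance = 1e-12)
  # surveillance costs still differ across modes
  costs <- vapply(c("none", "routine_fit", "colonoscopy"),
                  function(md) expected_outcomes(35, md, c3)$discounted_cost,
                  numeric(1))
  expect_gt(costs[["colonoscopy"]], costs[["none"]])

  # raising any stage's five-year survival never lowers expected LY
  for (i in 1:4) {
    c4 <- cfg
    c4$five_year_survival[i] <- min(1, c4$five_year_survival[i] + 0.1)
    expect_gte(expected_outcomes(35, "referent", c4)$discounted_ly,
               expected_outcomes(35, "referent", cfg)$discounted_ly)
  }
})

test_that("single-relative interface enforces carrier status", {
  cfg <- hazard_free_config()
  carrier <- tibble::tibble(age = 35, is_carrier = TRUE)
  set.seed(1)
  out <- simulate_relative(carrier, "none", cfg)
  expect_equal(nrow(out), 1)
  non_carrier <- tibble::tibble(age = 35, is_carrier = FALSE)
  expect_error(simulate_relative(non_carrier, "none", cfg), "carrier")
})

test_that("second primaries are capped and reuse the surveillance stage mix", {
  cfg <- default_config()
  set.seed(8)
  sim <- simulate_relatives(rep(35, 4000), "none", cfg)
  expect_lte(max(sim$n_crc_events), cfg$max_crc_episodes)
  expect_gt(sum(sim$n_crc_events == 2), 0)

  cfg1 <- cfg
  cfg1$max_crc_episodes <- 1L
  e1 <- expected_outcomes(35, "none", cfg1)
  e2 <- expected_outcomes(35, "none", cfg)
  expect_lt(e1$n_crc_events, e2$n_crc_events)
})
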