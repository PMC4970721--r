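SURVEILLANCE_MODES <- c("colonoscopy", "routine_fit", "referent", "none")

#' Annual cause-specific death probability from five-year survival
#'
#' Converts a stage-specific five-year survival probability `s` into the
#' constant annual cancer death probability `1 - s^(1/5)` that reproduces `s`
#' after five one-year cycles.
#'
#' @param five_year_survival probability (vectorised).
#' @return annual death probability.
#' @examples
#' annual_cancer_death_prob(0.5)          # ~0.1294
#' (1 - annual_cancer_death_prob(0.5))^5  # 0.5
#' @export
annual_cancer_death_prob <- function(five_year_survival) {
  if (any(five_year_survival < 0 | five_year_survival > 1 | !is.finite(five_year_survival))) {
    stop("five-year survival must lie in [0, 1]", call. = FALSE)
  }
  1 - five_year_survival^(1 / 5)
}

#' Shift a stage-at-diagnosis distribution to hit a survival uplift
#'
#' Models the earlier detection achieved by colonoscopic surveillance as a
#' mixture `(1 - lambda) * base + lambda * point-mass-on-Stage-1`, choosing
#' the smallest `lambda` for which the expected five-year survival
#' `sum(d * s)` reaches `(1 + uplift)` times its baseline value. `lambda` is
#' capped at 1 when even a pure Stage-1 distribution cannot attain the
#' target.
#'
#' @param base stage distribution (four probabilities summing to 1).
#' @param survivals stage-specific five-year survival probabilities.
#' @param uplift proportional increase in expected survival (e.g. 0.20).
#' @return adjusted stage distribution.
#' @examples
#' adjust_stage_distribution(c(0, 0, 0, 1), c(0.9, 0.8, 0.5, 0.1), 0.2)
#' @export
adjust_stage_distribution <- function(base, survivals, uplift) {
  stopifnot(length(base) == 4L, length(survivals) == 4L, uplift >= 0)
  if (abs(sum(base) - 1) > 1e-9 || any(base < 0)) {
    stop("base must be a probability distribution over the four stages", call. = FALSE)
  }
  s0 <- sum(base * survivals)
  if (uplift == 0) {
    return(base)
  }
  if (s0 <= 0) {
    stop("baseline expected survival is zero; uplift is undefined", call. = FALSE)
  }
  target <- (1 + uplift) * s0
  s_best <- survivals[1]
  if (s_best <= s0) {
    lambda <- 1
  } else {
    lambda <- min(1, (target - s0) / (s_best - s0))
  }
  out <- (1 - lambda) * base
  out[1] <- out[1] + lambda
  out
}

# stage-at-first-diagnosis distribution for a mode at a given age
first_stage_dist <- function(mode, age, config, colo_dist) {
  if (mode == "colonoscopy") {
    return(colo_dist)
  }
  if (mode == "routine_fit" && age >= 50 && age <= 69) {
    return(config$stage_dist_fit)
  }
  config$stage_dist_none
}

# expected surveillance cost incurred at integer age `age` in the well state
surveillance_cost_at <- function(mode, age, entry_age, config) {
  cc <- config$costs
  if (mode == "colonoscopy") {
    start <- max(entry_age, config$surveillance_start_age)
    if (age >= start && (age - start) %% config$surveillance_interval == 0) {
      return(cc$colonoscopy + cc$p_complication * cc$complication_cost)
    }
    return(0)
  }
  if (mode == "routine_fit" && age >= 50 && age <= 69 && (age - 50) %% 2 == 0) {
    return(cc$fit_test + config$p_fit_positive * cc$colonoscopy)
  }
  0
}

#' Deterministic lifetime expectation for a carrier relative
#'
#' Propagates the full state-probability vector of the natural-history model
#' (well, ill by episode/stage/years-since-diagnosis, cured, dead) one annual
#' cycle at a time from `age` to `horizon_age`, accumulating discounted
#' expected life-years and discounted expected costs. This is the analytic
#' counterpart (and test oracle) of [simulate_relative()]: both apply the
#' same within-cycle event order (background death, surveillance,
#' incidence, cancer death) to the same hazards.
#'
#' Mode `"referent"` is the participation-weighted mixture of the
#' routine-FIT and no-surveillance computations, because FIT participation
#' is a per-person trait.
#'
#' @param age entry age (years).
#' @param mode one of `"colonoscopy"`, `"routine_fit"`, `"referent"`, `"none"`.
#' @param config an `ls_config`.
#' @param incidence_multiplier scales the carrier incidence curve (0 gives a
#'   cancer-free cost stream, used for surveillance of non-carriers).
#' @return one-row tibble: `discounted_ly`, `discounted_cost`,
#'   `n_crc_events` (expected), with attribute `conservation_gap`, the
#'   largest absolute deviation of the state-vector mass from 1 over all
#'   cycles.
#' @examples
#' expected_outcomes(35, "none", default_config())
#' @export
expected_outcomes <- function(age, mode, config, incidence_multiplier = 1) {
  mode <- match.arg(mode, SURVEILLANCE_MODES)
  if (mode == "referent") {
    fp <- config$fit_participation
    a <- expected_outcomes(age, "routine_fit", config, incidence_multiplier)
    b <- expected_outcomes(age, "none", config, incidence_multiplier)
    out <- tibble::tibble(
      discounted_ly = fp * a$discounted_ly + (1 - fp) * b$discounted_ly,
      discounted_cost = fp * a$discounted_cost + (1 - fp) * b$discounted_cost,
      n_crc_events = fp * a$n_crc_events + (1 - fp) * b$n_crc_events
    )
    attr(out, "conservation_gap") <-
      max(attr(a, "conservation_gap"), attr(b, "conservation_gap"))
    return(out)
  }

  K <- as.integer(config$cure_years)
  E <- as.integer(config$max_crc_episodes)
  a0 <- floor(age)
  n_cycles <- max(0L, as.integer(config$horizon_age - a0))
  r <- config$discount_rate
  d_stage <- annual_cancer_death_prob(config$five_year_survival)
  colo_dist <- adjust_stage_distribution(
    config$stage_dist_none, config$five_year_survival,
    config$survival_uplift_colonoscopy
  )
  rr <- if (mode == "colonoscopy") 1 - config$risk_reduction_surveillance else 1
  h2 <- if (E >= 2L) config$second_crc_annual_risk else 0

  W <- 1
  ill <- array(0, dim = c(E, 4L, K)) # episode x stage x death-draws survived
  cured <- numeric(E)
  dead <- 0
  ly <- 0
  cost <- 0
  events <- 0
  gap <- 0

  for (t in seq_len(n_cycles)) {
    a <- a0 + t - 1L
    f <- (1 + r)^(-t)

    # background mortality
    q <- bg_mortality_at(config, a)
    dead <- dead + q * (W + sum(ill) + sum(cured))
    W <- W * (1 - q)
    ill <- ill * (1 - q)
    cured <- cured * (1 - q)

    # surveillance while well
    cost <- cost + f * W * surveillance_cost_at(mode, a, a0, config)

    # first incidence
    h1 <- incidence_multiplier * risk_at_age(config$carrier_incidence, a) * rr
    if (mode == "colonoscopy" && a < config$surveillance_start_age) {
      h1 <- incidence_multiplier * risk_at_age(config$carrier_incidence, a)
    }
    new1 <- W * h1
    W <- W - new1
    new1_stage <- new1 * first_stage_dist(mode, a, config, colo_dist)

    # second incidence (people diagnosed in an earlier cycle)
    new2_stage <- numeric(4L)
    if (h2 > 0) {
      src <- sum(ill[1L, , ]) + cured[1L]
      new2 <- src * h2
      ill[1L, , ] <- ill[1L, , ] * (1 - h2)
      cured[1L] <- cured[1L] * (1 - h2)
      new2_stage <- new2 * colo_dist
    }
    events <- events + sum(new1_stage) + sum(new2_stage)
    cost <- cost + f * sum(new1_stage * config$costs$treatment_first)
    cost <- cost + f * sum(new2_stage * config$costs$treatment_first *
                             config$costs$second_crc_multiplier)

    # cancer death, then advance the survived-death-draws clock; index j holds
    # people who have survived j annual cancer-death draws, cured at j == K
    for (e in seq_len(E)) {
      newly <- if (e == 1L) new1_stage else new2_stage
      surv_new <- newly * (1 - d_stage)
      dead <- dead + sum(newly * d_stage)
      for (s in 1:4) {
        dying <- ill[e, s, ] * d_stage[s]
        dead <- dead + sum(dying)
        ill[e, s, ] <- ill[e, s, ] - dying
      }
      if (K == 1L) {
        cured[e] <- cured[e] + sum(surv_new) + sum(ill[e, , ])
        ill[e, , ] <- 0
      } else {
        cured[e] <- cured[e] + sum(ill[e, , (K - 1L):K])
        if (K > 2L) {
          ill[e, , 2:(K - 1L)] <- ill[e, , 1:(K - 2L)]
        }
        ill[e, , K] <- 0
        ill[e, , 1L] <- surv_new
      }
    }

    alive <- W + sum(ill) + sum(cured)
    ly <- ly + f * alive
    gap <- max(gap, abs(alive + dead - 1))
  }

  out <- tibble::tibble(discounted_ly = ly, discounted_cost = cost,
                        n_crc_events = events)
  attr(out, "conservation_gap") <- gap
  out
}

#' Microsimulate carrier relatives through the natural-history model
#'
#' Vectorised individual-level simulation of the same annual-cycle model as
#' [expected_outcomes()]: background mortality, colorectal cancer incidence
#' (reduced under colonoscopic surveillance), stage at diagnosis by
#' surveillance mode, stage-specific cancer mortality calibrated to
#' five-year survival, cure after `cure_years` years, at most
#' `max_crc_episodes` cancers, and discounted surveillance and treatment
#' costs. Complication and FIT-follow-up costs are charged at their
#' per-procedure expectation. All people enter at program start, so a single
#' global discount clock applies; ages may differ.
#'
#' @param ages entry ages (one per person).
#' @param mode surveillance mode (see [expected_outcomes()]); either a
#'   single mode or one per person.
#' @param config an `ls_config`.
#' @param fit_participant optional logical vector: under `"referent"`,
#'   per-person FIT participation; drawn Bernoulli(`fit_participation`) when
#'   omitted.
#' @param incidence_multiplier scales the carrier incidence curve; single
#'   value or one per person.
#' @details A fixed number of uniforms is consumed per person per cycle
#'   regardless of each person's state, so two calls with the same RNG
#'   state, the same people in the same order, and different surveillance
#'   modes are driven by identical random streams — the common-random-number
#'   coupling used when comparing strategies.
#' @return tibble, one row per person: `discounted_ly`, `discounted_cost`,
#'   `n_crc_events`.
#' @export
simulate_relatives <- function(ages, mode, config, fit_participant = NULL,
                               incidence_multiplier = 1) {
  n <- length(ages)
  mode <- vapply(mode, match.arg, "", choices = SURVEILLANCE_MODES)
  if (length(mode) == 1L) mode <- rep(mode, n)
  stopifnot(length(mode) == n)
  if (length(incidence_multiplier) == 1L) {
    incidence_multiplier <- rep(incidence_multiplier, n)
  }
  if (n == 0L) {
    return(tibble::tibble(discounted_ly = numeric(), discounted_cost = numeric(),
                          n_crc_events = integer()))
  }
  u_part <- runif(n) # consumed unconditionally to keep streams aligned
  if (is.null(fit_participant)) {
    fit_participant <- u_part < config$fit_participation
  }
  use_fit <- mode == "routine_fit" | (mode == "referent" & fit_participant)
  colo <- mode == "colonoscopy"

  K <- as.integer(config$cure_years)
  E <- as.integer(config$max_crc_episodes)
  r <- config$discount_rate
  cc <- config$costs
  d_stage <- annual_cancer_death_prob(config$five_year_survival)
  colo_dist <- adjust_stage_distribution(
    config$stage_dist_none, config$five_year_survival,
    config$survival_uplift_colonoscopy
  )
  cum_colo <- cumsum(colo_dist)
  cum_none <- cumsum(config$stage_dist_none)
  cum_fit <- cumsum(config$stage_dist_fit)
  h2 <- if (E >= 2L) config$second_crc_annual_risk else 0
  colo_proc_cost <- cc$colonoscopy + cc$p_complication * cc$complication_cost
  fit_proc_cost <- cc$fit_test + config$p_fit_positive * cc$colonoscopy

  a0 <- floor(ages)
  alive <- rep(TRUE, n)
  state <- integer(n)            # 0 well, 1 ill, 2 cured
  episode <- integer(n)
  stage <- integer(n)
  jsurv <- integer(n)            # cancer-death draws survived this episode
  ly <- numeric(n)
  cost <- numeric(n)
  events <- integer(n)
  colo_start <- pmax(a0, config$surveillance_start_age)

  draw_stage <- function(u, cum) pmin(findInterval(u, cum) + 1L, 4L)

  max_cycles <- max(0L, as.integer(config$horizon_age - min(a0)))
  for (t in seq_len(max_cycles)) {
    a <- a0 + t - 1L
    # one block of uniforms per cycle, drawn for everyone
    u_bg <- runif(n); u_inc1 <- runif(n); u_inc2 <- runif(n)
    u_stage <- runif(n); u_die <- runif(n)

    active <- alive & a < config$horizon_age
    if (!any(active)) next
    f <- (1 + r)^(-t)

    # background mortality
    q <- bg_mortality_at(config, a)
    die_bg <- active & u_bg < q
    alive[die_bg] <- FALSE
    active <- active & !die_bg

    # surveillance while well
    well <- active & state == 0L
    colo_due <- well & colo & a >= colo_start &
      (a - colo_start) %% config$surveillance_interval == 0
    cost[colo_due] <- cost[colo_due] + f * colo_proc_cost
    fit_due <- well & use_fit & a >= 50 & a <= 69 & (a - 50) %% 2 == 0
    cost[fit_due] <- cost[fit_due] + f * fit_proc_cost

    # first incidence
    h1 <- incidence_multiplier * risk_at_age(config$carrier_incidence, a)
    h1 <- h1 * ifelse(colo & a >= config$surveillance_start_age,
                      1 - config$risk_reduction_surveillance, 1)
    inc1 <- well & u_inc1 < h1

    # second incidence (diagnosed in an earlier cycle)
    inc2 <- active & episode == 1L & state > 0L & u_inc2 < h2

    if (any(inc1)) {
      idx <- which(inc1)
      fit_now <- use_fit[idx] & a[idx] >= 50 & a[idx] <= 69
      stage[idx] <- ifelse(colo[idx], draw_stage(u_stage[idx], cum_colo),
                           ifelse(fit_now, draw_stage(u_stage[idx], cum_fit),
                                  draw_stage(u_stage[idx], cum_none)))
      state[idx] <- 1L
      episode[idx] <- 1L
      jsurv[idx] <- 0L
      events[idx] <- events[idx] + 1L
      cost[idx] <- cost[idx] + f * cc$treatment_first[stage[idx]]
    }
    if (any(inc2)) {
      idx <- which(inc2)
      stage[idx] <- draw_stage(u_stage[idx], cum_colo)
      state[idx] <- 1L
      episode[idx] <- 2L
      jsurv[idx] <- 0L
      events[idx] <- events[idx] + 1L
      cost[idx] <- cost[idx] + f * cc$treatment_first[stage[idx]] *
        cc$second_crc_multiplier[stage[idx]]
    }

    # cancer death, clock advance, cure
    ill <- active & alive & state == 1L
    if (any(ill)) {
      die_ca <- ill & u_die < d_stage[pmax(stage, 1L)]
      alive[die_ca] <- FALSE
      surv_ill <- ill & !die_ca
      jsurv[surv_ill] <- jsurv[surv_ill] + 1L
      cured_now <- surv_ill & jsurv >= K
      state[cured_now] <- 2L
    }

    got_year <- alive & a < config$horizon_age
    ly[got_year] <- ly[got_year] + f
  }

  tibble::tibble(discounted_ly = ly, discounted_cost = cost,
                 n_crc_events = events)
}

#' Simulate one carrier relative's lifetime
#'
#' Single-person interface to [simulate_relatives()]; the input must be a
#' mutation carrier (non-carriers have no excess colorectal cancer risk and
#' are handled by the economics layer).
#'
#' @param relative one-row data frame with columns `age` and `is_carrier`
#'   (as produced by [simulate_cohort()]), or a single age.
#' @param mode surveillance mode.
#' @param config an `ls_config`.
#' @return one-row tibble: `discounted_ly`, `discounted_cost`, `n_crc_events`.
#' @export
simulate_relative <- function(relative, mode, config) {
  if (is.data.frame(relative)) {
    stopifnot(nrow(relative) == 1L)
    if (!isTRUE(relative$is_carrier)) {
      stop("simulate_relative expects a mutation carrier", call. = FALSE)
    }
    age <- relative$age
  } else {
    age <- relative
  }
  simulate_relatives(age, mode, config)
}
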