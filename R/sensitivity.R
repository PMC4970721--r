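#' Default probabilistic sensitivity analysis specification
#'
#' Builds the per-parameter sampling distributions: beta for probabilities,
#' gamma for costs, lognormal for the relative risk underlying the
#' surveillance risk reduction, and Poisson for the per-patient relative
#' count. Beta/gamma/lognormal distributions are moment-matched to
#' (mean = base value, sd = (high - low) / (2 * 1.96)) using the one-way
#' bounds where available, otherwise sd = 20% of the base value.
#'
#' @param config an `ls_config`.
#' @param rel_sd fallback relative standard deviation for parameters without
#'   one-way bounds.
#' @return tibble with columns `parameter` (a config field, `costs.`-prefixed
#'   for monetary fields), `family`, `mean`, `sd`.
#' @export
psa_default_specs <- function(config, rel_sd = 0.2) {
  prob_fields <- c(
    "prevalence_ls_crc", "prevalence_ls_pop", "p_accept_testing",
    "p_counseling", "p_test_given_counseling", "p_adopt_surveillance",
    "fit_participation", "second_crc_annual_risk"
  )
  bound_sd <- function(f) {
    b <- config$oneway_bounds[[f]]
    if (is.null(b)) NA_real_ else (b[2] - b[1]) / (2 * 1.96)
  }
  probs <- tibble::tibble(
    parameter = prob_fields,
    family = "beta",
    mean = purrr::map_dbl(prob_fields, ~ config[[.x]]),
    sd = purrr::map_dbl(prob_fields, bound_sd)
  )
  cost_fields <- c("ihc", "msi", "braf", "sequencing_per_gene",
                   "counseling_proband", "counseling_relative",
                   "single_site_test", "colonoscopy")
  costs <- tibble::tibble(
    parameter = paste0("costs.", cost_fields),
    family = "gamma",
    mean = purrr::map_dbl(cost_fields, ~ config$costs[[.x]]),
    sd = NA_real_
  )
  other <- tibble::tibble(
    parameter = c("risk_reduction_surveillance", "mean_relatives"),
    family = c("lognormal", "poisson"),
    mean = c(config$risk_reduction_surveillance, config$mean_relatives),
    sd = c(bound_sd("risk_reduction_surveillance"), NA_real_)
  )
  out <- dplyr::bind_rows(probs, costs, other)
  out$sd <- ifelse(is.na(out$sd) & out$family != "poisson",
                   rel_sd * out$mean, out$sd)
  out
}

beta_params <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf("variance too large for a beta with mean %.4g", mean),
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

gamma_params <- function(mean, sd) {
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

lnorm_params <- function(mean, sd) {
  s2 <- log(1 + sd^2 / mean^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

config_get <- function(config, parameter) {
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  purrr::reduce(path, function(x, nm) x[[nm]], .init = config)
}

config_set <- function(config, parameter, value) {
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(path) == 1L) {
    config[[path]] <- value
  } else if (length(path) == 2L) {
    config[[path[1]]][[path[2]]] <- value
  } else {
    stop("config paths deeper than two levels are not supported", call. = FALSE)
  }
  config
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Samples each specified parameter from its assigned family, moment-matched
#' to the spec's mean and sd: beta for probabilities (so the support, not
#' post-hoc truncation, keeps them in \[0,1\]), gamma for costs, and
#' lognormal for the relative risk `1 - risk_reduction` (a sampled relative
#' risk above 1 maps to zero reduction). Poisson rows are left at their base
#' value: the Poisson applies to per-patient relative counts at cohort
#' simulation time (see [simulate_cohort()]'s `poisson_relatives`). A spec
#' with zero sd returns the base value. The sampled configuration is
#' re-validated before it is returned.
#'
#' @param config an `ls_config`.
#' @param specs tibble as produced by [psa_default_specs()].
#' @return a sampled, validated `ls_config`.
#' @export
sample_parameters <- function(config, specs) {
  unknown <- specs$parameter[purrr::map_lgl(
    specs$parameter, function(p) is.null(tryCatch(config_get(config, p),
                                                  error = function(e) NULL))
  )]
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(specs))) {
    fam <- specs$family[i]
    m <- specs$mean[i]
    s <- specs$sd[i]
    if (fam == "poisson") next
    if (!is.na(s) && s == 0) {
      value <- m
    } else if (fam == "beta") {
      p <- tryCatch(beta_params(m, s), error = function(e) {
        stop(sprintf("%s: %s", specs$parameter[i], conditionMessage(e)),
             call. = FALSE)
      })
      value <- rbeta(1, p["shape1"], p["shape2"])
    } else if (fam == "gamma") {
      p <- gamma_params(m, s)
      value <- rgamma(1, shape = p["shape"], rate = p["rate"])
    } else if (fam == "lognormal") {
      # sample the relative risk 1 - reduction and map back
      rr <- 1 - m
      p <- lnorm_params(rr, s)
      value <- max(0, 1 - rlnorm(1, p["meanlog"], p["sdlog"]))
    } else {
      stop("unknown distribution family: ", fam, call. = FALSE)
    }
    config <- config_set(config, specs$parameter[i], unname(value))
  }
  problems <- validate_config(config)
  if (length(problems)) {
    stop("sampled config invalid: ", problems[1], call. = FALSE)
  }
  config
}

#' Probabilistic sensitivity analysis
#'
#' For each draw: sample a parameter set, simulate a cohort (with
#' Poisson-distributed relative counts), evaluate all strategies with common
#' random numbers, and record each strategy's per-carrier incremental cost
#' and incremental life-years against the Referent strategy.
#'
#' @param config an `ls_config`.
#' @param specs sampling specification ([psa_default_specs()] by default).
#' @param n_draws number of parameter draws.
#' @param seed integer seed.
#' @param n_patients optional reduced cohort size per draw (the full
#'   registry cohort is used when `NULL`).
#' @return tibble of class `ls_psa`: `draw`, `strategy`, `delta_cost`,
#'   `delta_ly` (per carrier, vs Referent).
#' @export
run_psa <- function(config, specs = psa_default_specs(config), n_draws, seed,
                    n_patients = NULL) {
  stopifnot(n_draws >= 1)
  draws <- purrr::map_dfr(seq_len(n_draws), function(d) {
    draw_seed <- as.integer(seed) + d
    set.seed(draw_seed)
    cfg <- sample_parameters(config, specs)
    if (!is.null(n_patients)) {
      cfg$n_patients <- as.integer(n_patients)
    }
    cohort <- simulate_cohort(cfg, draw_seed, poisson_relatives = TRUE)
    ev <- evaluate_strategies(cfg, draw_seed, cohort = cohort)
    ref <- ev[ev$strategy == "referent", ]
    strat <- ev[ev$strategy != "referent", ]
    tibble::tibble(
      draw = d,
      strategy = strat$strategy,
      delta_cost = strat$cost_per_carrier - ref$cost_per_carrier,
      delta_ly = strat$ly_per_carrier - ref$ly_per_carrier
    )
  })
  structure(draws, class = c("ls_psa", class(draws)), seed = as.integer(seed))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability that a strategy is
#' cost-effective relative to the Referent: the fraction of PSA draws with
#' positive net monetary benefit `threshold * delta_ly - delta_cost`.
#'
#' @param psa an `ls_psa` (or any tibble with `strategy`, `delta_cost`,
#'   `delta_ly`).
#' @param thresholds willingness-to-pay thresholds, USD per life-year gained.
#' @return tibble of class `ls_ceac`: `threshold`, `strategy`, `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 200000, by = 5000)) {
  if (!nrow(psa)) {
    stop("empty PSA result", call. = FALSE)
  }
  out <- tidyr::crossing(threshold = thresholds,
                         strategy = unique(psa$strategy)) |>
    dplyr::left_join(psa, by = "strategy", relationship = "many-to-many") |>
    dplyr::group_by(.data$threshold, .data$strategy) |>
    dplyr::summarise(
      probability = mean(.data$threshold * .data$delta_ly - .data$delta_cost > 0),
      .groups = "drop"
    )
  structure(out, class = c("ls_ceac", class(out)))
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes a strategy's ICER against the Referent with each parameter in
#' turn set to its low and then its high bound, all other parameters at base
#' values, averaging over replicate cohorts with common seeds. Cost
#' parameters are deliberately absent from the default bounds (reimbursement
#' fees are treated as fixed). Entries are sorted by the induced ICER range,
#' the tornado-diagram order.
#'
#' @param config an `ls_config`.
#' @param bounds named list of `c(low, high)` per parameter; defaults to
#'   `config$oneway_bounds`.
#' @param strategy strategy whose ICER is examined.
#' @param replicates cohorts averaged per evaluation.
#' @param seed integer seed (same replicate seeds are reused at every bound).
#' @param n_patients optional reduced cohort size.
#' @return tibble of class `ls_tornado`: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `range`, sorted by `range` descending, with
#'   the base-case ICER in attribute `icer_base`.
#' @export
tornado <- function(config, bounds = config$oneway_bounds,
                    strategy = "strategy1", replicates = 10, seed = 1,
                    n_patients = NULL) {
  strategy <- match.arg(strategy, setdiff(STRATEGIES, "referent"))
  if (!is.null(n_patients)) {
    config$n_patients <- as.integer(n_patients)
  }

  # replicate-averaged per-carrier cost and LY first, one ratio afterwards
  # (the ICER of the averaged estimates, not an average of noisy ratios)
  icer_at <- function(cfg) {
    evs <- purrr::map_dfr(seq_len(replicates), function(rep) {
      evaluate_strategies(cfg, seed + rep,
                          strategies = c("referent", strategy))
    })
    avg <- evs |>
      dplyr::group_by(.data$strategy) |>
      dplyr::summarise(cost = mean(.data$cost_per_carrier),
                       ly = mean(.data$ly_per_carrier), .groups = "drop")
    d_cost <- avg$cost[avg$strategy == strategy] -
      avg$cost[avg$strategy == "referent"]
    d_ly <- avg$ly[avg$strategy == strategy] -
      avg$ly[avg$strategy == "referent"]
    if (d_ly <= 0) NA_real_ else d_cost / d_ly
  }

  rows <- purrr::imap_dfr(bounds, function(b, param) {
    base_value <- config_get(config, param)
    if (is.null(base_value)) {
      stop("unknown parameter in bounds: ", param, call. = FALSE)
    }
    cfg_lo <- config_set(config, param, b[1])
    cfg_hi <- config_set(config, param, b[2])
    for (cfg in list(cfg_lo, cfg_hi)) {
      problems <- validate_config(cfg)
      if (length(problems)) {
        stop(sprintf("bound for %s leaves the valid domain: %s",
                     param, problems[1]), call. = FALSE)
      }
    }
    tibble::tibble(
      parameter = param, low = b[1], high = b[2],
      icer_low = icer_at(cfg_lo), icer_high = icer_at(cfg_hi)
    )
  })
  rows$range <- abs(rows$icer_high - rows$icer_low)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$range))
  structure(rows, class = c("ls_tornado", class(rows)),
            icer_base = icer_at(config), strategy = strategy)
}
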