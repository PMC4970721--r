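#' Evaluate one strategy on a cohort
#'
#' Runs [screen_cohort()] and then the natural-history model for every
#' mutation-carrying relative: detected carriers who adopt surveillance get
#' biennial colonoscopy, detected decliners get routine FIT screening with
#' certain participation, and undetected carriers get the background
#' (Referent) behaviour — FIT participation at the population rate. Under
#' the Referent strategy nobody is detected, so all carriers follow the
#' background behaviour. Detected non-carriers (possible only when the
#' single-site assay is imperfect) accrue surveillance costs but no
#' life-year effects, since they have no excess cancer risk.
#'
#' Per-carrier averages are taken over ALL carrier relatives in the cohort,
#' detected or not, so that per-carrier cost times carrier count reproduces
#' the total cost.
#'
#' @param cohort an `ls_cohort`.
#' @param strategy strategy identifier.
#' @param config an `ls_config`.
#' @param seed optional seed set before screening (use the same seed across
#'   strategies for common random numbers).
#' @return one-row tibble: detection counts and costs,
#'   `cost_surveillance_treatment`, `total_cost`, `n_carriers`,
#'   `ly_per_carrier`, `cost_per_carrier`.
#' @export
evaluate_strategy <- function(cohort, strategy, config, seed = NULL) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (!is.null(seed)) set.seed(as.integer(seed))
  scr <- screen_cohort(cohort, strategy, config)
  rel <- scr$relatives

  carriers <- dplyr::filter(rel, .data$is_carrier)
  n_car <- nrow(carriers)
  mode_of <- dplyr::case_when(
    carriers$detected & carriers$adopts ~ "colonoscopy",
    carriers$detected ~ "routine_fit",
    TRUE ~ "referent"
  )

  # re-seed before the lifetime phase: screening consumes a
  # strategy-dependent number of draws, and simulate_relatives() consumes a
  # fixed stream per person, so identical `seed`s couple each carrier's
  # lifetime draws across strategies (common random numbers)
  if (!is.null(seed)) set.seed(as.integer(seed) + 1000003L)
  res <- simulate_relatives(carriers$age, mode_of, config)
  ly <- sum(res$discounted_ly)
  cost_nh <- sum(res$discounted_cost)

  # surveillance costs of detected non-carriers (zero excess cancer risk)
  fp <- dplyr::filter(rel, !.data$is_carrier, .data$detected)
  if (nrow(fp)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + 2000003L)
    fp_mode <- ifelse(fp$adopts, "colonoscopy", "routine_fit")
    res_fp <- simulate_relatives(fp$age, fp_mode, config, incidence_multiplier = 0)
    cost_nh <- cost_nh + sum(res_fp$discounted_cost)
  }

  s <- scr$summary
  total <- s$cost_detect_probands + s$cost_detect_relatives + cost_nh
  dplyr::mutate(
    s,
    cost_surveillance_treatment = cost_nh,
    total_cost = total,
    n_carriers = n_car,
    ly_per_carrier = ifelse(n_car > 0, ly / n_car, NA_real_),
    cost_per_carrier = ifelse(n_car > 0, total / n_car, NA_real_)
  )
}

#' Evaluate all strategies on a common cohort
#'
#' Evaluates the Referent strategy and Strategies 1-4 on the same simulated
#' cohort, re-seeding the generator identically before each strategy so that
#' acceptance, test, cascade and natural-history draws are common random
#' numbers across strategies.
#'
#' @param config an `ls_config`.
#' @param seed integer seed (drives both the cohort and the evaluations).
#' @param cohort optionally, a pre-built `ls_cohort` (otherwise simulated
#'   from `config` and `seed`).
#' @param strategies strategies to evaluate.
#' @return tibble of class `ls_evaluation`, one row per strategy.
#' @examples
#' \donttest{
#' ev <- evaluate_strategies(default_config(), seed = 1)
#' icer_table(ev)
#' }
#' @export
evaluate_strategies <- function(config, seed, cohort = NULL,
                                strategies = STRATEGIES) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config, seed)
  }
  out <- purrr::map_dfr(
    strategies,
    function(s) evaluate_strategy(cohort, s, config, seed = seed + 1L)
  )
  structure(out, class = c("ls_evaluation", class(out)),
            seed = as.integer(seed), gdp_per_capita = config$gdp_per_capita)
}

#' Incremental cost-effectiveness ratios
#'
#' Computes, per strategy, the ICER relative to the Referent strategy and
#' relative to the previous strategy in the conventional ordering (Strategy
#' 1's previous comparator is the Referent). Ratios use per-carrier
#' discounted costs and life-years; when the life-year gain is not positive
#' the strategy is flagged dominated and no ratio is reported.
#'
#' @param results an `ls_evaluation` (must contain a `referent` row), or any
#'   tibble with `strategy`, `ly_per_carrier`, `cost_per_carrier`.
#' @param gdp_per_capita GDP per capita used for the WHO classification;
#'   defaults to the value recorded on `results`.
#' @return tibble of class `ls_icer`: `strategy`, `ly_per_carrier`,
#'   `cost_per_carrier`, `icer_vs_referent`, `icer_vs_previous`, `dominated`,
#'   `who_category`.
#' @export
icer_table <- function(results, gdp_per_capita = NULL) {
  gdp <- gdp_per_capita %||% attr(results, "gdp_per_capita")
  stopifnot("referent" %in% results$strategy)
  results <- results[match(STRATEGIES[STRATEGIES %in% results$strategy],
                           results$strategy), ]
  ref <- results[results$strategy == "referent", ]
  strat <- results[results$strategy != "referent", ]

  icer_pair <- function(cost, ly, cost0, ly0) {
    d_ly <- ly - ly0
    ifelse(d_ly > 0, (cost - cost0) / d_ly, NA_real_)
  }
  prev_idx <- seq_len(nrow(strat)) - 1L
  prev_cost <- c(ref$cost_per_carrier, strat$cost_per_carrier)[prev_idx + 1L]
  prev_ly <- c(ref$ly_per_carrier, strat$ly_per_carrier)[prev_idx + 1L]

  out <- tibble::tibble(
    strategy = strat$strategy,
    ly_per_carrier = strat$ly_per_carrier,
    cost_per_carrier = strat$cost_per_carrier,
    icer_vs_referent = icer_pair(strat$cost_per_carrier, strat$ly_per_carrier,
                                 ref$cost_per_carrier, ref$ly_per_carrier),
    icer_vs_previous = icer_pair(strat$cost_per_carrier, strat$ly_per_carrier,
                                 prev_cost, prev_ly)
  )
  out$dominated <- is.na(out$icer_vs_referent)
  out$who_category <- ifelse(out$dominated, NA_character_,
                             who_category(pmax(out$icer_vs_referent, 0), gdp))
  structure(dplyr::bind_rows(
    tibble::tibble(strategy = "referent",
                   ly_per_carrier = ref$ly_per_carrier,
                   cost_per_carrier = ref$cost_per_carrier,
                   icer_vs_referent = NA_real_, icer_vs_previous = NA_real_,
                   dominated = FALSE, who_category = NA_character_),
    out
  ), class = c("ls_icer", "tbl_df", "tbl", "data.frame"))
}

#' WHO cost-effectiveness category
#'
#' Classifies an ICER against GDP per capita: highly cost-effective below
#' one GDP per life-year gained, cost-effective between one and three, and
#' not cost-effective above three.
#'
#' @param icer ICER in USD per life-year gained (vectorised, non-negative).
#' @param gdp_per_capita GDP per capita in USD.
#' @return character vector: `"highly_cost_effective"`, `"cost_effective"`,
#'   or `"not_cost_effective"`.
#' @examples
#' who_category(6025, 21308)
#' @export
who_category <- function(icer, gdp_per_capita) {
  if (any(gdp_per_capita <= 0)) {
    stop("gdp_per_capita must be positive", call. = FALSE)
  }
  if (any(icer < 0, na.rm = TRUE)) {
    stop("icer must be non-negative", call. = FALSE)
  }
  dplyr::case_when(
    icer < gdp_per_capita ~ "highly_cost_effective",
    icer <= 3 * gdp_per_capita ~ "cost_effective",
    TRUE ~ "not_cost_effective"
  )
}

#' @export
print.ls_icer <- function(x, ...) {
  cat("Cost-effectiveness summary (per mutation-carrying relative)\n")
  df <- as.data.frame(x)
  df$ly_per_carrier <- round(df$ly_per_carrier, 3)
  df$cost_per_carrier <- round(df$cost_per_carrier)
  df$icer_vs_referent <- round(df$icer_vs_referent)
  df$icer_vs_previous <- round(df$icer_vs_previous)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_strategies
#' @param x an `ls_evaluation`.
#' @param ... unused.
#' @method tidy ls_evaluation
#' @export
tidy.ls_evaluation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname evaluate_strategies
#' @method glance ls_evaluation
#' @export
glance.ls_evaluation <- function(x, ...) {
  ref <- x[x$strategy == "referent", ]
  tibble::tibble(
    n_strategies = nrow(x),
    n_carriers = if (nrow(ref)) ref$n_carriers[1] else x$n_carriers[1],
    referent_ly_per_carrier = if (nrow(ref)) ref$ly_per_carrier else NA_real_,
    referent_cost_per_carrier = if (nrow(ref)) ref$cost_per_carrier else NA_real_,
    seed = attr(x, "seed")
  )
}
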