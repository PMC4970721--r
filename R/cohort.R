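#' Simulate the screening population
#'
#' Generates a cohort of newly diagnosed CRC patients and their first-degree
#' relatives. Each patient has Lynch syndrome with probability
#' `prevalence_ls_crc`; an affected patient's causal gene follows
#' `mmr_proportions`. In the base case every patient has exactly
#' `mean_relatives` relatives (set `poisson_relatives = TRUE`, as the
#' probabilistic sensitivity analysis does, to draw the count from
#' Poisson(`mean_relatives`)). Relatives of affected patients carry the
#' family-specific mutation with probability `p_relative_carrier`
#' (dominant inheritance); relatives of unaffected patients are carriers at
#' the population prevalence, with a gene drawn from the population spectrum.
#' Relative ages are truncated-normal (mean `relative_age_mean`, sd
#' `relative_age_sd`, truncated to `relative_age_bounds`) via the
#' inverse-CDF, so the same seed always yields the same cohort.
#'
#' @param config an `ls_config`.
#' @param seed integer seed; identical seed and config give an identical cohort.
#' @param poisson_relatives draw per-patient relative counts from a Poisson?
#' @return list of class `ls_cohort`: `patients` (tibble: `patient_id`,
#'   `has_ls`, `causal_gene`), `relatives` (tibble: `patient_id`,
#'   `relative_id`, `age`, `is_carrier`, `carried_gene`), and `seed`.
#' @examples
#' coh <- simulate_cohort(default_config(), seed = 1)
#' sum(coh$relatives$is_carrier)
#' @export
simulate_cohort <- function(config, seed, poisson_relatives = FALSE) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid config: ", problems[1], call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- as.integer(config$n_patients)

  has_ls <- runif(n) < config$prevalence_ls_crc
  causal <- rep(NA_character_, n)
  n_ls <- sum(has_ls)
  if (n_ls > 0) {
    causal[has_ls] <- sample(MMR_GENES, n_ls, replace = TRUE,
                             prob = config$mmr_proportions)
  }
  patients <- tibble::tibble(
    patient_id = seq_len(n),
    has_ls = has_ls,
    causal_gene = causal
  )

  n_rel <- if (poisson_relatives) {
    rpois(n, config$mean_relatives)
  } else {
    rep(as.integer(round(config$mean_relatives)), n)
  }
  owner <- rep.int(patients$patient_id, n_rel)
  m <- length(owner)

  parent_ls <- has_ls[owner]
  p_carry <- ifelse(parent_ls, config$p_relative_carrier, config$prevalence_ls_pop)
  is_carrier <- runif(m) < p_carry
  gene <- rep(NA_character_, m)
  fam <- is_carrier & parent_ls
  gene[fam] <- causal[owner[fam]]
  spor <- is_carrier & !parent_ls
  if (any(spor)) {
    gene[spor] <- sample(MMR_GENES, sum(spor), replace = TRUE,
                         prob = config$mmr_proportions)
  }

  relatives <- tibble::tibble(
    patient_id = owner,
    relative_id = seq_len(m),
    age = rtruncnorm_icdf(m, config$relative_age_mean, config$relative_age_sd,
                          config$relative_age_bounds[1], config$relative_age_bounds[2]),
    is_carrier = is_carrier,
    carried_gene = gene
  )

  structure(list(patients = patients, relatives = relatives, seed = as.integer(seed)),
            class = "ls_cohort")
}

# inverse-CDF truncated normal draw (deterministic given the RNG stream)
rtruncnorm_icdf <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Closed-form expected cohort counts
#'
#' Analytic expectations for the simulated population: the number of Lynch
#' syndrome patients, the total number of relatives, and the number of
#' mutation-carrying relatives,
#' \deqn{E[\mathrm{carriers}] = n\pi m \tfrac12 + n(1-\pi) m \pi_{pop},}
#' with `n` patients, CRC-LS prevalence \eqn{\pi}, `m` relatives per patient
#' and population prevalence \eqn{\pi_{pop}}. Serves as the analytic oracle
#' for [simulate_cohort()].
#'
#' @param config an `ls_config`.
#' @return tibble with `ls_patients`, `total_relatives`, `carrier_relatives`.
#' @examples
#' expected_cohort_counts(default_config())$carrier_relatives  # ~742.6
#' @export
expected_cohort_counts <- function(config) {
  n <- config$n_patients
  pi_crc <- config$prevalence_ls_crc
  m <- config$mean_relatives
  tibble::tibble(
    ls_patients = n * pi_crc,
    total_relatives = n * m,
    carrier_relatives = n * pi_crc * m * config$p_relative_carrier +
      n * (1 - pi_crc) * m * config$prevalence_ls_pop
  )
}

#' @export
print.ls_cohort <- function(x, ...) {
  cat("<ls_cohort>\n")
  cat(sprintf("  %d patients (%d with Lynch syndrome), %d relatives (%d carriers), seed %d\n",
              nrow(x$patients), sum(x$patients$has_ls),
              nrow(x$relatives), sum(x$relatives$is_carrier), x$seed))
  invisible(x)
}

#' Export a cohort's relatives as CSV
#'
#' One row per relative: `patient_id`, `age`, `is_carrier`, `gene`.
#'
#' @param cohort an `ls_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- dplyr::select(cohort$relatives, "patient_id", "age",
                       "is_carrier", gene = "carried_gene")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
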