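#' Run a screening strategy's decision tree over patients
#'
#' Vectorised core of the proband-side decision trees:
#' \describe{
#'   \item{strategy1}{IHC for the four MMR proteins; MLH1-absent tumours get
#'     BRAF V600E reflex testing (a positive BRAF indicates sporadic origin
#'     and stops the work-up); BRAF-negative or other-protein-absent tumours
#'     have the implicated gene sequenced.}
#'   \item{strategy2}{IHC; the implicated gene is sequenced directly.}
#'   \item{strategy3}{MSI; MSI-high tumours have all four genes sequenced.}
#'   \item{strategy4}{direct germline sequencing of all four genes.}
#'   \item{referent}{no testing.}
#' }
#' For affected patients a positive IHC implicates the causal gene (assay
#' sensitivity); false-positive IHC in unaffected patients presents as
#' MLH1-absent, the sporadic MMR-deficiency phenotype. A patient becomes a
#' proband when the terminal sequencing reports a mutation: detection with
#' sequencing sensitivity for true carriers of a sequenced gene, and
#' `1 - specificity` per sequenced gene for everyone else.
#'
#' @param patients tibble with `patient_id`, `has_ls`, `causal_gene`
#'   (only patients who accepted testing should be passed).
#' @param strategy one of `"referent"`, `"strategy1"`, `"strategy2"`,
#'   `"strategy3"`, `"strategy4"`.
#' @param config an `ls_config`.
#' @return tibble, one row per patient: `patient_id`, `did_ihc`, `did_braf`,
#'   `did_msi`, `genes_sequenced`, `assay_cost`, `is_proband`.
#' @export
screen_patients <- function(patients, strategy, config) {
  strategy <- match.arg(strategy, STRATEGIES)
  n <- nrow(patients)
  ihc <- test_profile(config, "ihc")
  msi <- test_profile(config, "msi")
  seqp <- test_profile(config, "sequencing")
  braf_cost <- config$costs$braf

  did_ihc <- rep(FALSE, n)
  did_braf <- rep(FALSE, n)
  did_msi <- rep(FALSE, n)
  genes_seq <- integer(n)
  is_proband <- rep(FALSE, n)
  ls <- patients$has_ls

  seq_positive <- function(sequenced, n_genes) {
    # detection prob for the sequenced panel: true mutation found with
    # sequencing sensitivity when the causal gene is on the panel;
    # false positives at 1 - specificity per mutation-free gene
    p_tp <- ifelse(sequenced & ls, seqp$sensitivity, 0)
    n_clean <- ifelse(sequenced & ls, n_genes - 1L, n_genes)
    p_fp <- 1 - seqp$specificity^pmax(n_clean, 0L)
    sequenced & (runif(n) < 1 - (1 - p_tp) * (1 - p_fp))
  }

  if (strategy %in% c("strategy1", "strategy2")) {
    did_ihc[] <- TRUE
    implicated <- ifelse(ls, runif(n) < ihc$sensitivity,
                         runif(n) < 1 - ihc$specificity)
    implicated_gene <- ifelse(ls, patients$causal_gene, "MLH1")
    to_sequence <- implicated
    if (strategy == "strategy1") {
      braf_eligible <- implicated & implicated_gene == "MLH1"
      did_braf <- braf_eligible
      p_braf <- ifelse(ls, config$p_braf_pos_ls, config$p_braf_pos_sporadic)
      braf_pos <- braf_eligible & runif(n) < p_braf
      to_sequence <- implicated & !braf_pos
    }
    genes_seq[to_sequence] <- 1L
    is_proband <- seq_positive(to_sequence, 1L)
  } else if (strategy == "strategy3") {
    did_msi[] <- TRUE
    msi_high <- ifelse(ls, runif(n) < msi$sensitivity,
                       runif(n) < 1 - msi$specificity)
    genes_seq[msi_high] <- 4L
    is_proband <- seq_positive(msi_high, 4L)
  } else if (strategy == "strategy4") {
    genes_seq[] <- 4L
    is_proband <- seq_positive(rep(TRUE, n), 4L)
  }

  assay_cost <- did_ihc * ihc$cost + did_braf * braf_cost +
    did_msi * msi$cost + genes_seq * seqp$cost

  tibble::tibble(
    patient_id = patients$patient_id,
    did_ihc = did_ihc, did_braf = did_braf, did_msi = did_msi,
    genes_sequenced = genes_seq,
    assay_cost = as.numeric(assay_cost),
    is_proband = is_proband
  )
}

#' Decision tree for a single patient
#'
#' Convenience wrapper over [screen_patients()] for one patient, returning
#' the individual tests performed with their costs.
#'
#' @param patient one-row tibble with `patient_id`, `has_ls`, `causal_gene`.
#' @param strategy strategy identifier.
#' @param config an `ls_config`.
#' @return list with `tests_performed` (tibble `assay`, `cost`) and
#'   `is_proband`.
#' @export
run_decision_tree <- function(patient, strategy, config) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1L)
  res <- screen_patients(patient, strategy, config)
  tests <- tibble::tibble(assay = character(), cost = numeric())
  if (res$did_ihc) {
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      assay = "ihc", cost = config$costs$ihc))
  }
  if (res$did_msi) {
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      assay = "msi", cost = config$costs$msi))
  }
  if (res$did_braf) {
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      assay = "braf", cost = config$costs$braf))
  }
  if (res$genes_sequenced > 0L) {
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      assay = paste0("sequencing_x", res$genes_sequenced),
      cost = res$genes_sequenced * config$costs$sequencing_per_gene))
  }
  list(tests_performed = tests, is_proband = res$is_proband)
}

#' Screen a cohort and cascade to relatives
#'
#' Applies patient acceptance (`p_accept_testing`), runs the strategy's
#' decision tree over accepting patients, then runs the cascade for each
#' proband's relatives: contact, genetic counseling (probability
#' `p_counseling`), targeted single-site testing of counselled relatives
#' (probability `p_test_given_counseling`), and surveillance adoption among
#' detected carriers (probability `p_adopt_surveillance`). Probands whose
#' positive result is a sequencing false positive still trigger the cascade
#' and its costs; their relatives carry mutations only at the population
#' rate.
#'
#' Cost categories follow the payer perspective: `cost_detect_probands` is
#' proband counseling plus all proband assay costs; `cost_detect_relatives`
#' is relative contact, counseling, and single-site testing.
#'
#' @param cohort an `ls_cohort`.
#' @param strategy strategy identifier.
#' @param config an `ls_config`.
#' @return list of class `ls_screening`: `summary` (one-row tibble:
#'   `strategy`, `n_probands`, `n_relatives_tested`, `n_relatives_detected`,
#'   `cost_detect_probands`, `cost_detect_relatives`) and `relatives` (the
#'   cohort's relatives with logical columns `detected` and `adopts`).
#' @export
screen_cohort <- function(cohort, strategy, config) {
  strategy <- match.arg(strategy, STRATEGIES)
  patients <- cohort$patients
  relatives <- cohort$relatives
  n <- nrow(patients)
  cc <- config$costs
  ss <- test_profile(config, "single_site")

  accepts <- runif(n) < config$p_accept_testing

  if (strategy == "referent" || !any(accepts)) {
    out_rel <- dplyr::mutate(relatives, detected = FALSE, adopts = FALSE)
    summary <- tibble::tibble(
      strategy = strategy, n_probands = 0L, n_relatives_tested = 0L,
      n_relatives_detected = 0L, cost_detect_probands = 0,
      cost_detect_relatives = 0
    )
    return(structure(list(summary = summary, relatives = out_rel),
                     class = "ls_screening"))
  }

  screened <- screen_patients(patients[accepts, ], strategy, config)
  cost_probands <- sum(accepts) * cc$counseling_proband + sum(screened$assay_cost)
  proband_ids <- screened$patient_id[screened$is_proband]

  m <- nrow(relatives)
  in_cascade <- relatives$patient_id %in% proband_ids
  counselled <- in_cascade & runif(m) < config$p_counseling
  tested <- counselled & runif(m) < config$p_test_given_counseling
  detected <- tested & ifelse(relatives$is_carrier,
                              runif(m) < ss$sensitivity,
                              runif(m) < 1 - ss$specificity)
  adopts <- detected & runif(m) < config$p_adopt_surveillance

  cost_relatives <- sum(in_cascade) * cc$relative_contact +
    sum(counselled) * cc$counseling_relative +
    sum(tested) * ss$cost

  out_rel <- dplyr::mutate(relatives, detected = detected, adopts = adopts)
  summary <- tibble::tibble(
    strategy = strategy,
    n_probands = length(proband_ids),
    n_relatives_tested = sum(tested),
    n_relatives_detected = sum(detected),
    cost_detect_probands = cost_probands,
    cost_detect_relatives = cost_relatives
  )
  structure(list(summary = summary, relatives = out_rel), class = "ls_screening")
}
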