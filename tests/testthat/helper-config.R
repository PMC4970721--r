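# A reduced cohort keeps full-pipeline tests fast while leaving every rate
# and the natural-history model at base-case values.
small_config <- function(n_patients = 2000L) {
  cfg <- default_config()
  cfg$n_patients <- as.integer(n_patients)
  cfg
}

# Hazard-free variant: no cancer incidence, no background death. Useful for
# closed-form life-year checks.
hazard_free_config <- function(horizon = 45, discount = 0.03) {
  cfg <- default_config()
  cfg$carrier_incidence$annual_risk[] <- 0
  cfg$background_mortality[] <- 0
  cfg$horizon_age <- horizon
  cfg$discount_rate <- discount
  cfg
}

# Perfect assays: every test has sensitivity and specificity 1.
perfect_test_config <- function(cfg = default_config()) {
  for (assay in names(cfg$tests)) {
    cfg$tests[[assay]]$sensitivity <- 1
    cfg$tests[[assay]]$specificity <- 1
  }
  cfg$p_braf_pos_ls <- 0
  cfg
}

one_patient <- function(has_ls, gene = if (has_ls) "MLH1" else NA_character_) {
  tibble::tibble(patient_id = 1L, has_ls = has_ls, causal_gene = gene)
}
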