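# Full study-scale discovery run shared by the recovery and null-control
# suites: default cohort dimensions (1305 blood + 48 BAL analytes, 14/31
# COPD classes), preprocessing, 200-iteration elastic-net ranking and
# step-forward PLSDA with 6-fold CV up to 60 features.
full_scale_discovery <- function(seed, effect_size = 1.5, n_sex_assoc = 8) {
  cfg <- cohort_config(effect_size = effect_size, n_sex_assoc = n_sex_assoc,
                       seed = seed)
  d <- generate_cohort(cfg)
  lab <- label_progression(d$participants)
  copd <- lab$group == "COPD"
  classes <- lab$decline_class[copd]
  cens <- censor_bal_lod(d$bal, d$lod)
  balf <- filter_bal_analytes(cens$matrix, cens$flags)
  lg <- normalize_and_log(balf, d$bal_totals, d$blood)
  merged <- merge_compartments(lg$blood, lg$bal)
  mc <- proteomic_matrix(merged$values[lab$id[copd], , drop = FALSE],
                         merged$compartment, merged$scale)
  sx <- sex_association_filter(mc, lab$sex[copd])
  ranking <- enet_selection_frequencies(sx$filtered, classes,
                                        n_iterations = 200, seed = seed + 1)
  sf <- step_forward_search(ranking, sx$filtered, classes, k = 6,
                            max_size = 60, seed = seed + 2)
  truth <- d$truth
  planted <- paste0(truth$compartment, ":",
                    truth$analyte)[truth$role == "planted"]
  list(X = sx$filtered, classes = classes, ranking = ranking, search = sf,
       planted = planted, n_features = n_analytes(sx$filtered))
}
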