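# Shared fixtures: a small planted-signal cohort (generated once per run) and
# its preprocessed merged matrix, so discovery/profile tests stay fast.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    # decline SDs tightened so percentile labels coincide with the generating
    # classes: unit tests here exercise operations, not boundary overlap
    cfg <- cohort_config(
      n_blood = 120, n_bal = 48, n_planted = 6, n_planted_bal = 1,
      effect_size = 2.0, n_sex_assoc = 4,
      decline_sd_greater = 15, decline_sd_lesser = 10, seed = 42
    )
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

# preprocessed COPD-only merged matrix + classes + planted ids for the small cohort
small_prepared <- function() {
  if (is.null(.fixture_env$small_prep)) {
    d <- small_cohort()
    lab <- label_progression(d$participants)
    copd <- lab$group == "COPD"
    cens <- censor_bal_lod(d$bal, d$lod)
    balf <- filter_bal_analytes(cens$matrix, cens$flags)
    lg <- normalize_and_log(balf, d$bal_totals, d$blood)
    merged <- merge_compartments(lg$blood, lg$bal)
    merged_copd <- proteomic_matrix(
      merged$values[lab$id[copd], , drop = FALSE],
      merged$compartment, merged$scale
    )
    sx <- sex_association_filter(merged_copd, lab$sex[copd])
    truth <- d$truth
    planted <- paste0(truth$compartment, ":",
                      truth$analyte)[truth$role == "planted"]
    .fixture_env$small_prep <- list(
      data = d, participants = lab,
      merged = sx$filtered,
      merged_all = merged,
      classes = lab$decline_class[copd],
      planted = planted,
      sex_removed = sx$removed
    )
  }
  .fixture_env$small_prep
}

# deterministic toy matrix with named columns for PLSDA/evaluation tests
toy_classes <- function(n_greater = 6, n_lesser = 8) {
  factor(rep(c("greater", "lesser"), c(n_greater, n_lesser)),
         levels = c("greater", "lesser"))
}

toy_matrix <- function(n = 14, p = 5, seed = 1) {
  with_seed <- function(s, e) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    e
  }
  with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("S", 1:n), paste0("V", 1:p)))
    m
  })
}
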