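#' Configuration for a synthetic bronchoscopy-sub-study cohort
#'
#' Defaults reproduce the structure of the real cohort the pipeline targets:
#' 14 greater decliners vs 31 lesser decliners plus a 40-person reference group
#' of tobacco-exposed people with preserved spirometry (TEPPS); 1305 blood and
#' 48 BAL analytes; annualized declines of -104.6 (SD 32.0) vs -28.8 (SD 21.5)
#' mL/year over a 6.31 (SD 0.86)-year follow-up; 85.7% vs 54.8% male; 23 BAL
#' analytes constructed to fail the >= 50%-below-LLOD rule (so 25 survive);
#' 8 sex-associated blood analytes at 2 SD; and a planted discriminative
#' signature of 20 analytes (1 of them BAL) at a standardized log-scale effect
#' of 1.5 SD between decline classes.
#'
#' @param n_greater,n_lesser,n_tepps group sizes.
#' @param n_blood,n_bal panel sizes.
#' @param n_planted number of truly class-discriminative analytes.
#' @param effect_size standardized mean difference (log2-scale SD units)
#'   between decline classes for planted analytes.
#' @param n_planted_bal how many planted analytes sit in the BAL panel
#'   (among analytes that survive LOD filtering).
#' @param n_sex_assoc,sex_effect count and standardized effect of
#'   sex-associated blood analytes.
#' @param decline_mean_greater,decline_sd_greater,decline_mean_lesser,decline_sd_lesser
#'   annualized-decline moments per class, mL/year.
#' @param male_prop_greater,male_prop_lesser,male_prop_tepps male proportions.
#' @param bal_llod_quantile fraction of a non-censor-prone BAL analyte's
#'   concentration distribution placed below its LLOD.
#' @param n_bal_fail_lod BAL analytes constructed so that >= 50% of
#'   measurements fall below LLOD (they are removed by the filtering rule).
#' @param followup_years_mean,followup_years_sd follow-up length, years.
#' @param seed integer RNG seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_greater = 14, n_lesser = 31, n_tepps = 40,
                          n_blood = 1305, n_bal = 48,
                          n_planted = 20, effect_size = 1.5,
                          n_planted_bal = min(1, n_planted),
                          n_sex_assoc = 8, sex_effect = 2.0,
                          decline_mean_greater = -104.6,
                          decline_sd_greater = 32.0,
                          decline_mean_lesser = -28.8,
                          decline_sd_lesser = 21.5,
                          male_prop_greater = 0.857,
                          male_prop_lesser = 0.548,
                          male_prop_tepps = 0.65,
                          bal_llod_quantile = 0.05,
                          n_bal_fail_lod = 23,
                          followup_years_mean = 6.31,
                          followup_years_sd = 0.86,
                          seed = 1L) {
  cfg <- list(
    n_greater = n_greater, n_lesser = n_lesser, n_tepps = n_tepps,
    n_blood = n_blood, n_bal = n_bal,
    n_planted = n_planted, effect_size = effect_size,
    n_planted_bal = n_planted_bal,
    n_sex_assoc = n_sex_assoc, sex_effect = sex_effect,
    decline_mean_greater = decline_mean_greater,
    decline_sd_greater = decline_sd_greater,
    decline_mean_lesser = decline_mean_lesser,
    decline_sd_lesser = decline_sd_lesser,
    male_prop_greater = male_prop_greater,
    male_prop_lesser = male_prop_lesser,
    male_prop_tepps = male_prop_tepps,
    bal_llod_quantile = bal_llod_quantile,
    n_bal_fail_lod = n_bal_fail_lod,
    followup_years_mean = followup_years_mean,
    followup_years_sd = followup_years_sd,
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_greater", "n_lesser", "n_tepps", "n_blood", "n_bal",
                  "n_planted", "n_planted_bal", "n_sex_assoc",
                  "n_bal_fail_lod")]
  if (any(vapply(counts, function(x) x < 0, logical(1)))) {
    stop("configuration error: all counts must be >= 0")
  }
  if (cfg$n_greater == 0 || cfg$n_lesser == 0) {
    stop("configuration error: both decline classes need at least one participant")
  }
  if (cfg$n_planted > cfg$n_blood + cfg$n_bal) {
    stop("configuration error: n_planted exceeds the combined panel size")
  }
  if (cfg$n_sex_assoc > cfg$n_blood) {
    stop("configuration error: n_sex_assoc exceeds the blood panel")
  }
  if (cfg$n_bal_fail_lod > cfg$n_bal) {
    stop("configuration error: n_bal_fail_lod exceeds the BAL panel")
  }
  if (cfg$n_planted_bal > cfg$n_planted ||
      cfg$n_planted_bal > cfg$n_bal - cfg$n_bal_fail_lod) {
    stop("configuration error: n_planted_bal exceeds planted count or LOD-surviving BAL analytes")
  }
  if (cfg$n_planted - cfg$n_planted_bal > cfg$n_blood) {
    stop("configuration error: planted blood analytes exceed the blood panel")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic two-compartment cohort
#'
#' Draws a cohort per a [cohort_config()]: participant records with mutually
#' consistent V1/V5 FEV1, visit dates and annualized decline (the decline is
#' drawn first, then V5 FEV1 is back-computed from V1 FEV1 and the realized
#' calendar interval, so labeling round-trips exactly); log-normal blood and
#' BAL concentration panels with planted class effects and sex-associated
#' analytes; per-sample BAL total protein (raw BAL concentrations scale with
#' total protein, so ratio normalization recovers the latent level); and a
#' per-analyte LOD specification under which exactly `n_bal_fail_lod` BAL
#' analytes have >= 50% of measurements below their LLOD. TEPPS analyte
#' distributions follow the lesser-decliner parameters.
#'
#' @param config a [cohort_config()].
#' @return A list with `participants` (data frame; `decline_class_true` holds
#'   the generating class), `blood` and `bal` ([proteomic_matrix], raw scale,
#'   BAL uncensored), `bal_totals` (named per-sample total protein), `lod`
#'   (a [lod_spec()] for the BAL panel), and `truth` (data frame: analyte,
#'   compartment, role in planted/sex/noise).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("configuration error: `config` must be a cohort_config")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_copd <- cfg$n_greater + cfg$n_lesser
  n_all <- n_copd + cfg$n_tepps
  ids <- sprintf("P%04d", seq_len(n_all))
  cls <- rep(c("greater", "lesser", "tepps"),
             c(cfg$n_greater, cfg$n_lesser, cfg$n_tepps))
  group <- ifelse(cls == "tepps", "TEPPS", "COPD")

  rtrunc_norm <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }

  decline <- numeric(n_all)
  decline[cls == "greater"] <- stats::rnorm(
    cfg$n_greater, cfg$decline_mean_greater, cfg$decline_sd_greater
  )
  decline[cls == "lesser"] <- stats::rnorm(
    cfg$n_lesser, cfg$decline_mean_lesser, cfg$decline_sd_lesser
  )
  decline[cls == "tepps"] <- stats::rnorm(cfg$n_tepps, -15, 15)

  years_drawn <- rtrunc_norm(
    n_all, cfg$followup_years_mean, cfg$followup_years_sd, 2
  )
  v1_date <- as.Date("2010-11-10") + sample.int(750, n_all, replace = TRUE)
  v5_date <- v1_date + round(years_drawn * DAYS_PER_YEAR)
  years <- as.numeric(v5_date - v1_date) / DAYS_PER_YEAR

  v1_mean <- c(greater = 2.63, lesser = 2.11, tepps = 2.90)
  v1_sd <- c(greater = 0.60, lesser = 0.66, tepps = 0.60)
  v1_fev1 <- rtrunc_norm(n_all, v1_mean[cls], v1_sd[cls], 0.8)
  v5_fev1 <- v1_fev1 + decline * years / 1000
  low <- v5_fev1 < 0.3   # guard: clamp pathological draws, re-deriving decline
  v5_fev1[low] <- 0.3
  decline <- 1000 * (v5_fev1 - v1_fev1) / years

  pct_mean <- c(greater = 84.2, lesser = 71.1, tepps = 95)
  pct_sd <- c(greater = 13.1, lesser = 17.7, tepps = 10)
  v1_pct <- rtrunc_norm(n_all, pct_mean[cls], pct_sd[cls], 30)
  v5_pct <- v1_pct * v5_fev1 / v1_fev1

  male_prop <- c(greater = cfg$male_prop_greater,
                 lesser = cfg$male_prop_lesser,
                 tepps = cfg$male_prop_tepps)
  sex <- ifelse(stats::runif(n_all) < male_prop[cls], "male", "female")
  smoke_prop <- c(greater = 0.357, lesser = 0.323, tepps = 0.33)
  ics_prop <- c(greater = 0.214, lesser = 0.452, tepps = 0.30)

  participants <- data.frame(
    id = ids,
    group = group,
    decline_class_true = ifelse(cls == "tepps", NA, cls),
    sex = sex,
    age = rtrunc_norm(n_all, 63.4, 7.75, 40),
    race = sample(c("white", "other"), n_all, replace = TRUE,
                  prob = c(0.82, 0.18)),
    height = stats::rnorm(n_all, 170, 10),
    smoking_status = ifelse(stats::runif(n_all) < smoke_prop[cls],
                            "current", "former"),
    pack_years = rtrunc_norm(n_all, 50, 25, 20),
    ics_use = stats::runif(n_all) < ics_prop[cls],
    v1_fev1 = v1_fev1,
    v5_fev1 = v5_fev1,
    v1_fev1_pct_pred = v1_pct,
    v5_fev1_pct_pred = v5_pct,
    v1_date = v1_date,
    v5_date = v5_date,
    stringsAsFactors = FALSE
  )

  blood_ids <- sprintf("PROT%04d", seq_len(cfg$n_blood))
  bal_ids <- sprintf("CYT%02d", seq_len(cfg$n_bal))

  n_planted_blood <- cfg$n_planted - cfg$n_planted_bal
  planted_blood <- sample(cfg$n_blood, n_planted_blood)
  sexed_blood <- sample(setdiff(seq_len(cfg$n_blood), planted_blood),
                        cfg$n_sex_assoc)
  bal_fail <- sample(cfg$n_bal, cfg$n_bal_fail_lod)
  planted_bal <- sample(setdiff(seq_len(cfg$n_bal), bal_fail),
                        cfg$n_planted_bal)

  is_greater <- cls == "greater"
  is_male <- sex == "male"

  # analyte log2 levels: baseline + per-analyte SD, effects additive on log2
  draw_panel <- function(p, planted_idx, sexed_idx, mu_range) {
    mu <- stats::runif(p, mu_range[1], mu_range[2])
    sigma <- stats::runif(p, 0.5, 1.5)
    z <- matrix(stats::rnorm(n_all * p), n_all, p)
    z <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
    if (length(planted_idx)) {
      z[is_greater, planted_idx] <- z[is_greater, planted_idx] +
        rep(cfg$effect_size * sigma[planted_idx], each = sum(is_greater))
    }
    if (length(sexed_idx)) {
      z[is_male, sexed_idx] <- z[is_male, sexed_idx] +
        rep(cfg$sex_effect * sigma[sexed_idx], each = sum(is_male))
    }
    z
  }

  blood_log <- draw_panel(cfg$n_blood, planted_blood, sexed_blood, c(6, 14))
  bal_log <- draw_panel(cfg$n_bal, planted_bal, integer(0), c(2, 10))

  blood_raw <- 2^blood_log
  dimnames(blood_raw) <- list(ids, blood_ids)

  bal_totals <- 2^stats::rnorm(n_all, 0, 0.5)
  names(bal_totals) <- ids
  bal_raw <- 2^bal_log * bal_totals      # concentrations scale with total protein
  dimnames(bal_raw) <- list(ids, bal_ids)

  # LODs from empirical order statistics so the >=50% rule holds by construction
  k_half <- ceiling(n_all / 2)
  llod <- numeric(cfg$n_bal)
  for (j in seq_len(cfg$n_bal)) {
    v <- sort(bal_raw[, j])
    if (j %in% bal_fail) {
      llod[j] <- if (k_half < n_all) {
        (v[k_half] + v[k_half + 1L]) / 2
      } else {
        v[n_all] * 1.01
      }
    } else {
      llod[j] <- min(
        stats::quantile(v, cfg$bal_llod_quantile, names = FALSE),
        stats::quantile(v, 0.4, names = FALSE)
      )
    }
  }
  ulod <- apply(bal_raw, 2, stats::quantile, probs = 0.99, names = FALSE)
  lod <- lod_spec(bal_ids, llod, ulod)

  truth <- data.frame(
    analyte = c(blood_ids, bal_ids),
    compartment = rep(c("blood", "bal"), c(cfg$n_blood, cfg$n_bal)),
    role = "noise",
    stringsAsFactors = FALSE
  )
  truth$role[planted_blood] <- "planted"
  truth$role[sexed_blood] <- "sex"
  truth$role[cfg$n_blood + planted_bal] <- "planted"

  list(
    participants = participants,
    blood = proteomic_matrix(blood_raw, "blood", "raw"),
    bal = proteomic_matrix(bal_raw, "bal", "raw"),
    bal_totals = bal_totals,
    lod = lod,
    truth = truth
  )
}
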