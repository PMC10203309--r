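#' Configuration for a full pipeline run
#'
#' Either a synthetic cohort (via [cohort_config()]) or paths to delimited
#' inputs (blood matrix, BAL matrix, participants, LOD spec, BAL totals),
#' plus the numeric knobs of every stage. Defaults follow the analysis the
#' pipeline reproduces: 30th-percentile dichotomization, BH at 0.05 for the
#' sex filter, 2000 elastic-net resamples at mixing 0.5, 6-fold CV, 2000
#' random signatures.
#'
#' @param synthetic a [cohort_config()], or `NULL` when reading files.
#' @param paths named list (`blood`, `bal`, `participants`, `lod`,
#'   `bal_totals`) of input files; ignored when `synthetic` is given.
#' @param pct dichotomization percentile.
#' @param sex_alpha FDR level of the sex-association filter.
#' @param n_en_iterations elastic-net resamples.
#' @param alpha_mix elastic-net mixing parameter.
#' @param step_max_size largest signature size evaluated step-forward.
#' @param k CV folds.
#' @param n_lv PLSDA latent variables.
#' @param n_random random signatures for the null.
#' @param seed master seed; per-stage substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = cohort_config(), paths = NULL,
                       pct = 30, sex_alpha = 0.05,
                       n_en_iterations = 2000, alpha_mix = 0.5,
                       step_max_size = 100, k = 6, n_lv = 2,
                       n_random = 2000, seed = 1L) {
  if (is.null(synthetic) && is.null(paths)) {
    stop("configuration error: either `synthetic` or `paths` must be given")
  }
  if (!is.null(paths)) {
    need <- c("blood", "bal", "participants", "lod", "bal_totals")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      stop("configuration error: missing input paths: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(
    synthetic = synthetic, paths = paths, pct = pct, sex_alpha = sex_alpha,
    n_en_iterations = n_en_iterations, alpha_mix = alpha_mix,
    step_max_size = step_max_size, k = k, n_lv = n_lv,
    n_random = n_random, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full signature-discovery pipeline
#'
#' Sequences the analysis end to end: data (synthetic or from files) ->
#' progression labeling -> BAL LOD censoring and filtering -> total-protein
#' normalization and log2 transform -> sex-association filter (computed on
#' the COPD cohort) -> compartment merge -> univariate screen -> elastic-net
#' selection-frequency ranking -> step-forward PLSDA with k-fold CV ->
#' minimal signatures -> random-signature null -> orthogonalized optimal
#' model, LV1-decline association, signature PCA with Hotelling reduced-T2
#' outlier removal (one pass), permutation tests, Spearman-distance
#' clustering, and PC1 score ANOVA across greater/lesser/TEPPS.
#'
#' All tabular artifacts are written to `out_dir` alongside a JSON manifest
#' recording the configuration, seed and stage timings.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result (`data`,
#'   `participants`, `merged`, `screen`, `ranking`, `search`, `minimal`,
#'   `null`, `model`, `association`, `pca`, `permutation`, `clustering`,
#'   `anova`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 4)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  data <- clock("data", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic)
    } else {
      list(
        blood = read_proteomic_matrix(config$paths$blood),
        bal = read_proteomic_matrix(config$paths$bal),
        participants = read_participants(config$paths$participants),
        lod = read_lod_spec(config$paths$lod),
        bal_totals = {
          tt <- utils::read.delim(config$paths$bal_totals,
                                  stringsAsFactors = FALSE)
          stats::setNames(tt$total_protein, tt$sample)
        },
        truth = NULL
      )
    }
  })

  participants <- clock("label", label_progression(data$participants,
                                                   pct = config$pct))
  copd <- participants$group == "COPD"
  copd_ids <- participants$id[copd]
  classes <- stats::setNames(participants$decline_class[copd], copd_ids)

  pre <- clock("preprocess", {
    cens <- censor_bal_lod(data$bal, data$lod)
    bal_f <- filter_bal_analytes(cens$matrix, cens$flags)
    message(sprintf("BAL LOD filter: %d -> %d analytes",
                    n_analytes(data$bal), n_analytes(bal_f)))
    logged <- normalize_and_log(bal_f, data$bal_totals, data$blood)
    merged_all <- merge_compartments(logged$blood, logged$bal)
    merged_copd <- proteomic_matrix(
      merged_all$values[copd_ids, , drop = FALSE],
      merged_all$compartment, merged_all$scale
    )
    sexf <- sex_association_filter(
      merged_copd, participants$sex[copd], alpha = config$sex_alpha
    )
    message(sprintf("sex filter removed %d analytes; %d features remain",
                    length(sexf$removed), n_analytes(sexf$filtered)))
    keep <- colnames(sexf$filtered$values)
    list(
      merged_copd = sexf$filtered,
      merged_all = pm_select(merged_all, keep),
      sex_removed = sexf$removed
    )
  })
  merged <- pre$merged_copd

  screen <- clock("univariate",
                  univariate_screen(merged, classes))

  ranking <- clock("rank", enet_selection_frequencies(
    merged, classes, n_iterations = config$n_en_iterations,
    alpha_mix = config$alpha_mix, seed = seeds[1]
  ))

  search <- clock("select", step_forward_search(
    ranking, merged, classes, k = config$k,
    max_size = config$step_max_size, seed = seeds[2], n_lv = config$n_lv
  ))
  minimal <- minimal_signatures(search)

  null <- clock("null", random_signature_null(
    merged, classes, signature_size = search$optimal_size,
    n_random = config$n_random, k = config$k, seed = seeds[3],
    observed = search$optimal, n_lv = config$n_lv
  ))

  post <- clock("profile", {
    model <- orthogonalize(search$optimal$model)
    lv1 <- predict(model, merged)$scores[, 1]
    covars <- data.frame(
      age = participants$age[copd],
      race = participants$race[copd],
      height = participants$height[copd],
      sex = participants$sex[copd],
      fev1_pct = participants$v1_fev1_pct_pred[copd],
      smoking = participants$smoking_status[copd],
      pack_years = participants$pack_years[copd],
      ics = participants$ics_use[copd]
    )
    assoc <- adjusted_linear_association(
      lv1, participants$delta_fev1[copd], covars
    )

    sig_all <- pm_select(pre$merged_all, search$optimal_features)
    pca0 <- pca_fit(sig_all, n_components = 2)
    out_flags <- hotelling_outliers(pca0)$outlier
    kept_samples <- rownames(sig_all$values)[!out_flags]
    pca <- pca_fit(
      sig_all$values[kept_samples, , drop = FALSE], n_components = 2
    )
    grp <- stats::setNames(
      ifelse(participants$group == "TEPPS", "tepps",
             as.character(participants$decline_class)),
      participants$id
    )[kept_samples]
    perm <- permutation_group_test(
      pca$scores[grp != "lesser", ], grp[grp != "lesser"], seed = seeds[4]
    )
    anova <- group_score_anova(pca$scores[, 1], grp, posthoc = "tukey")
    clust <- hierarchical_cluster_eval(pm_select(merged,
                                                 search$optimal_features),
                                       classes)
    list(model = model, association = assoc, pca = pca,
         outliers = out_flags, permutation = perm, anova = anova,
         clustering = clust)
  })

  clock("write", {
    write_participants(participants, file.path(out_dir, "participants.tsv"))
    write_proteomic_matrix(merged, file.path(out_dir, "merged_matrix.tsv"))
    write_tsv(screen, file.path(out_dir, "univariate.tsv"))
    write_tsv(as.data.frame(ranking), file.path(out_dir, "ranking.tsv"))
    write_tsv(search$curve, file.path(out_dir, "step_forward_curve.tsv"))
    write_tsv(data.frame(analyte = search$optimal_features),
              file.path(out_dir, "optimal_signature.tsv"))
    write_tsv(minimal, file.path(out_dir, "minimal_signatures.tsv"))
    write_tsv(data.frame(cv_balanced_accuracy = null$null_accuracy),
              file.path(out_dir, "null_accuracies.tsv"))
    write_plsda(post$model, file.path(out_dir, "optimal_model.json"))
    write_tsv(data.frame(sample = rownames(post$pca$scores),
                         post$pca$scores),
              file.path(out_dir, "pca_scores.tsv"))
    write_dendrogram_newick(post$clustering$hclust,
                            file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(data$truth)) {
      write_tsv(data$truth, file.path(out_dir, "truth.tsv"))
    }
  })

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), c("synthetic", "paths"))],
    synthetic = if (is.null(config$synthetic)) NULL
                else unclass(config$synthetic),
    threshold_ml_per_year = attr(participants, "threshold"),
    n_features_merged = n_analytes(merged),
    optimal_size = search$optimal_size,
    cv_balanced_accuracy = search$optimal$cv$balanced_accuracy,
    null_p_empirical = null$p_empirical,
    stage_seconds = timings,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(
    out_dir = out_dir, data = data, participants = participants,
    merged = merged, screen = screen, ranking = ranking, search = search,
    minimal = minimal, null = null, model = post$model,
    association = post$association, pca = post$pca,
    outliers = post$outliers, permutation = post$permutation,
    clustering = post$clustering, anova = post$anova, manifest = manifest
  ))
}
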