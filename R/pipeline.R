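#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end experiment; all stochastic stages
#' have explicit seeds (derived from the cohort seed unless overridden), so a
#' config fully reproduces a run.
#'
#' @param cohort a [cohort_config].
#' @param bin_width gray-level bin width for texture discretization.
#' @param normalize_scale target SD of normalized intensities (see
#'   [normalize_volume]); 100 pairs with the default bin width 25.
#' @param keep_every,phase down-sampler settings for the
#'   simulated-conventional series.
#' @param split_seed,lasso_seed,forest_seed stage seeds; default
#'   `cohort$seed + 1, 2, 3`.
#' @param n_folds LASSO CV folds.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param ntree forest size.
#' @param occlusion list: `enabled`, `features` (names), `mask_size`,
#'   `stride` -- occlusion maps of the first validation case, computed on the
#'   thin and SC CE-T1 series.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              bin_width = 25, normalize_scale = 100,
                              keep_every = 5, phase = 0,
                              split_seed = NULL, lasso_seed = NULL,
                              forest_seed = NULL,
                              n_folds = 5, lambda_rule = "min", ntree = 500,
                              occlusion = list(enabled = FALSE,
                                               features = c("glcm_Correlation",
                                                            "firstorder_Maximum"),
                                               mask_size = 5, stride = 5)) {
  structure(list(cohort = cohort, bin_width = bin_width,
                 normalize_scale = normalize_scale,
                 keep_every = keep_every, phase = phase,
                 split_seed = if (is.null(split_seed)) cohort$seed + 1L else split_seed,
                 lasso_seed = if (is.null(lasso_seed)) cohort$seed + 2L else lasso_seed,
                 forest_seed = if (is.null(forest_seed)) cohort$seed + 3L else forest_seed,
                 n_folds = n_folds, lambda_rule = lambda_rule, ntree = ntree,
                 occlusion = occlusion),
            class = "experiment_config")
}

# extract the three per-case feature vectors (thin CE-T1, SC CE-T1, T2)
extract_case_features <- function(case, config) {
  sc_vol <- downsample_to_sc(case$thin_series, config$keep_every, config$phase)
  sc_roi <- downsample_mask(case$roi, config$keep_every, config$phase)
  norm <- function(v) normalize_volume(v, scale = config$normalize_scale)$volume
  f3 <- extract_all(norm(case$thin_series), case$roi, config$bin_width)
  fsc <- extract_all(norm(sc_vol), sc_roi, config$bin_width)
  ft2 <- extract_all(norm(case$t2_series), case$roi_t2, config$bin_width)
  names(f3) <- paste0("t1_3d_", names(f3))
  names(fsc) <- paste0("t1_sc_", names(fsc))
  names(ft2) <- paste0("t2_", names(ft2))
  c(f3, fsc, ft2)
}

build_tables <- function(cases, role, config) {
  feats <- t(vapply(cases, extract_case_features, numeric(321), config = config))
  rownames(feats) <- vapply(cases, `[[`, "", "case_id")
  labels <- vapply(cases, `[[`, "", "label")
  feature_table(feats, labels, role = role)
}

# build, from one modality-concatenated table pair, a fitted signature and
# its train/validation probabilities; a void LASSO selection yields a null
# signature predicting the training prevalence
build_signature <- function(train, valid, kind, config) {
  sc <- scale_features(train, valid)
  selected <- lasso_select(sc$train, seed = config$lasso_seed,
                           n_folds = config$n_folds, rule = config$lambda_rule)
  if (length(selected) == 0) {
    prev <- mean(train$labels == "codeleted")
    return(list(signature = NULL, selected = character(0),
                prob_train = rep(prev, nrow(train$x)),
                prob_valid = rep(prev, nrow(valid$x))))
  }
  sig <- fit_signature(sc$train, selected, seed = config$forest_seed,
                       kind = kind, scaler = sc$scaler, ntree = config$ntree)
  list(signature = sig, selected = sig$selected_features,
       prob_train = predict(sig, sc$train),
       prob_valid = predict(sig, sc$applied))
}

metric_row <- function(model, dataset, labels, probs) {
  cm <- confusion_metrics(labels, probs)
  both <- length(unique(as.character(labels))) == 2
  if (both) {
    dc <- delong_ci(labels, probs)
    auc <- dc$auc; lo <- dc$ci[1]; hi <- dc$ci[2]
  } else auc <- lo <- hi <- NA_real_
  data.frame(model = model, dataset = dataset, n = length(probs),
             accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity, auc = auc, auc_lo = lo,
             auc_hi = hi, stringsAsFactors = FALSE)
}

#' Run the full slice-spacing radiomics experiment
#'
#' Generates (or accepts) a synthetic cohort, splits it, builds the
#' simulated-conventional CE-T1 series, extracts the 107-feature vector from
#' each of the three modalities per case, constructs the 3D signature
#' (thin CE-T1 + T2 features) and the SC signature (SC CE-T1 + T2 features)
#' on the training set only, evaluates both on training and validation data,
#' compares them with the paired DeLong test, re-evaluates the 3D signature
#' in the IDH-mutant and WHO-grade subgroups, and optionally computes
#' occlusion maps on the first validation case.
#'
#' @param config an [experiment_config].
#' @param cases optional pre-generated cohort (defaults to
#'   `generate_cohort(config$cohort)`).
#' @return A `radiomics_experiment`: metrics table, DeLong comparisons,
#'   fitted signatures, selected features, subgroup table, case metadata and
#'   the config.
#' @export
run_experiment <- function(config = experiment_config(), cases = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cases)) cases <- generate_cohort(config$cohort)
  sp <- split_cohort(cases, config$cohort$train_fraction, config$split_seed)

  tr_tab <- build_tables(sp$train, "training", config)
  va_tab <- build_tables(sp$validation, "validation", config)
  pick <- function(tb, prefixes) {
    keep <- grepl(paste0("^(", paste(prefixes, collapse = "|"), ")_"),
                  colnames(tb$x))
    tb$x <- tb$x[, keep, drop = FALSE]
    tb
  }
  res3 <- build_signature(pick(tr_tab, c("t1_3d", "t2")),
                          pick(va_tab, c("t1_3d", "t2")), "3D", config)
  ressc <- build_signature(pick(tr_tab, c("t1_sc", "t2")),
                           pick(va_tab, c("t1_sc", "t2")), "SC", config)

  ytr <- tr_tab$labels; yva <- va_tab$labels
  metrics <- rbind(
    metric_row("3D", "training", ytr, res3$prob_train),
    metric_row("3D", "validation", yva, res3$prob_valid),
    metric_row("SC", "training", ytr, ressc$prob_train),
    metric_row("SC", "validation", yva, ressc$prob_valid))

  # paired comparison is undefined when a dataset holds a single class
  safe_delong <- function(y, a, b) {
    if (length(unique(as.character(y))) < 2) {
      return(structure(list(auc_a = NA_real_, auc_b = NA_real_,
                            delong_covariance = matrix(NA_real_, 2, 2),
                            z = NA_real_, p_value = NA_real_,
                            ci_a = c(NA_real_, NA_real_),
                            ci_b = c(NA_real_, NA_real_),
                            ci_a_raw = c(NA_real_, NA_real_),
                            ci_b_raw = c(NA_real_, NA_real_)),
                       class = "roc_comparison"))
    }
    delong_test(y, a, b)
  }
  comparison <- list(
    training = safe_delong(ytr, res3$prob_train, ressc$prob_train),
    validation = safe_delong(yva, res3$prob_valid, ressc$prob_valid))

  meta <- function(cs) data.frame(
    case_id = vapply(cs, `[[`, "", "case_id"),
    label = vapply(cs, `[[`, "", "label"),
    idh = vapply(cs, `[[`, "", "idh"),
    grade = vapply(cs, `[[`, "", "grade"), stringsAsFactors = FALSE)
  mtr <- meta(sp$train); mva <- meta(sp$validation)
  subgroup_of <- function(m) {
    g <- list(idh_mutant = m$idh == "mutant",
              grade_II = m$grade == "II",
              grade_III = m$grade == "III")
    g[vapply(g, any, logical(1))]  # drop subgroups absent from this dataset
  }
  subgroups <- rbind(
    cbind(dataset = "training",
          evaluate_subgroups(ytr, res3$prob_train, subgroup_of(mtr))),
    cbind(dataset = "validation",
          evaluate_subgroups(yva, res3$prob_valid, subgroup_of(mva))))

  occ <- NULL
  if (isTRUE(config$occlusion$enabled)) {
    cs <- sp$validation[[1]]
    nrm <- function(v) normalize_volume(v, scale = config$normalize_scale)$volume
    thin <- nrm(cs$thin_series)
    scv <- nrm(downsample_to_sc(cs$thin_series, config$keep_every, config$phase))
    scm <- downsample_mask(cs$roi, config$keep_every, config$phase)
    occ <- lapply(config$occlusion$features, function(fn) {
      m3 <- occlusion_map(thin, cs$roi, fn, config$occlusion$mask_size,
                          config$occlusion$stride, bin_width = config$bin_width)
      msc <- occlusion_map(scv, scm, fn, config$occlusion$mask_size,
                           config$occlusion$stride, bin_width = config$bin_width)
      list(feature = fn, map_3d = m3, map_sc = msc,
           comparison = compare_occlusion(m3, msc, config$keep_every,
                                          config$phase))
    })
    names(occ) <- config$occlusion$features
  }

  structure(list(metrics = metrics, comparison = comparison,
                 signature_3d = res3$signature, signature_sc = ressc$signature,
                 selected_3d = res3$selected, selected_sc = ressc$selected,
                 subgroups = subgroups, occlusion = occ,
                 train_meta = mtr, validation_meta = mva,
                 config = config),
            class = "radiomics_experiment")
}

#' @export
print.radiomics_experiment <- function(x, ...) {
  cat("Slice-spacing radiomics experiment\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat(sprintf("DeLong 3D vs SC: training p = %.3f, validation p = %.3f\n",
              x$comparison$training$p_value, x$comparison$validation$p_value))
  cat("3D signature features:", paste(x$selected_3d, collapse = ", "), "\n")
  cat("SC signature features:", paste(x$selected_sc, collapse = ", "), "\n")
  invisible(x)
}

#' Replicate the experiment over independent cohorts
#'
#' Derives one cohort seed per replicate deterministically from the master
#' seed, re-runs [run_experiment] on each independent cohort, and collects
#' per-replicate metrics and selected features.
#'
#' @param config an [experiment_config]; its cohort seed is the master seed.
#' @param n_replicates number of replicate cohorts (>= 1).
#' @return List with `metrics` (row-bound per-replicate metrics with a
#'   `replicate` column), `selected_3d` / `selected_sc` (lists of feature
#'   sets), `comparison_p` (validation DeLong p per replicate) and `summary`
#'   (mean AUC per model and dataset).
#' @export
replicate_experiment <- function(config = experiment_config(), n_replicates = 20) {
  stopifnot(n_replicates >= 1)
  set.seed(config$cohort$seed)
  seeds <- sample.int(2^31 - 10, n_replicates)
  runs <- lapply(seq_len(n_replicates), function(i) {
    co <- config$cohort
    co$seed <- seeds[i]
    cfg <- config
    cfg$cohort <- co
    cfg$split_seed <- seeds[i] + 1L
    cfg$lasso_seed <- seeds[i] + 2L
    cfg$forest_seed <- seeds[i] + 3L
    run_experiment(cfg)
  })
  metrics <- do.call(rbind, lapply(seq_along(runs), function(i)
    cbind(replicate = i, runs[[i]]$metrics)))
  summary <- stats::aggregate(auc ~ model + dataset, data = metrics, FUN = mean)
  list(metrics = metrics,
       selected_3d = lapply(runs, `[[`, "selected_3d"),
       selected_sc = lapply(runs, `[[`, "selected_sc"),
       comparison_p = vapply(runs, function(r) r$comparison$validation$p_value,
                             numeric(1)),
       summary = summary)
}
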