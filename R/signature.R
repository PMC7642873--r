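#' Case-by-feature table with labels
#'
#' @param x numeric matrix, cases in rows, named feature columns.
#' @param labels vector coercible to factor with levels
#'   `c("intact", "codeleted")`; co-deletion is the positive class throughout.
#' @param case_id optional case identifiers (default rownames of `x`).
#' @param role `"training"` or `"validation"`.
#' @return A `feature_table`.
#' @export
feature_table <- function(x, labels, case_id = rownames(x),
                          role = c("training", "validation")) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature columns must have unique names")
  if (anyNA(x)) stop("feature table contains missing values")
  labels <- factor(as.character(labels), levels = c("intact", "codeleted"))
  if (anyNA(labels)) stop("labels must be 'intact' or 'codeleted'")
  if (length(labels) != nrow(x)) stop("one label per row required")
  if (is.null(case_id)) case_id <- sprintf("case_%03d", seq_len(nrow(x)))
  structure(list(x = x, labels = labels, case_id = case_id,
                 role = match.arg(role)),
            class = "feature_table")
}

#' Scale features by the training-set standard deviation
#'
#' Each feature is divided by its SD computed on the training rows only; the
#' same training SDs are applied to any other table (never the table's own
#' SDs), so no information leaks from validation into the scaling. Features
#' with zero training SD are dropped with a warning.
#'
#' @param train a [feature_table] with role `"training"`.
#' @param apply_to optional second [feature_table] scaled with the training
#'   SDs.
#' @return List with scaled `train`, scaled `applied` (or `NULL`), and
#'   `scaler` (the named training SDs of the retained features).
#' @export
scale_features <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "feature_table"))
  sds <- apply(train$x, 2, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " constant training feature(s): ",
            paste(utils::head(names(sds)[bad], 5), collapse = ", "))
    }
  keep <- names(sds)[!bad]
  sc <- sds[keep]
  scale_one <- function(tb) {
    tb$x <- sweep(tb$x[, keep, drop = FALSE], 2, sc, `/`)
    tb
  }
  list(train = scale_one(train),
       applied = if (!is.null(apply_to)) scale_one(apply_to) else NULL,
       scaler = sc)
}

#' LASSO feature selection on the training set
#'
#' L1-penalized logistic regression with the penalty chosen by k-fold
#' cross-validated deviance on the training rows only; returns the features
#' with nonzero coefficients at the chosen penalty, ordered by decreasing
#' absolute coefficient.
#'
#' @param train a scaled training [feature_table] with both classes present.
#' @param seed RNG seed fixing the CV fold assignment.
#' @param n_folds number of CV folds (default 5).
#' @param rule `"min"` (minimum CV deviance, default) or `"1se"`.
#' @return Character vector of selected feature names (possibly empty).
#' @export
lasso_select <- function(train, seed, n_folds = 5, rule = c("min", "1se")) {
  stopifnot(inherits(train, "feature_table"))
  rule <- match.arg(rule)
  if (min(table(train$labels)) < 2)
    stop("need at least 2 cases per class in the training set")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(train$x)))
  cv <- glmnet::cv.glmnet(train$x, train$labels, family = "binomial",
                          alpha = 1, foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  cf <- cf[cf != 0]
  names(cf)[order(abs(cf), decreasing = TRUE)]
}

#' Fit a radiomics signature (random forest with feature reduction)
#'
#' Fits a random forest on the LASSO-selected features of the training table,
#' then performs one feature-reduction pass: features with out-of-bag
#' permutation importance at or below zero are dropped and the forest refit
#' once on the survivors. Returns a deployable signature object carrying the
#' training scaler, the final feature list and the fitted forest.
#'
#' @param train a scaled training [feature_table].
#' @param selected nonempty character vector of feature names (from
#'   [lasso_select]).
#' @param seed RNG seed for forest bootstrap/permutation.
#' @param kind signature label, `"3D"` or `"SC"`.
#' @param scaler named training SDs recorded for deployment (optional).
#' @param ntree number of trees (default 500).
#' @param reduce perform the importance-based reduction pass (default TRUE).
#' @return An object of class `radiomics_signature`.
#' @export
fit_signature <- function(train, selected, seed, kind = "3D", scaler = NULL,
                          ntree = 500, reduce = TRUE) {
  stopifnot(inherits(train, "feature_table"))
  if (length(selected) == 0) stop("empty feature selection")
  if (!all(selected %in% colnames(train$x)))
    stop("selected features missing from the training table")
  fit_rf <- function(feats) {
    set.seed(seed)
    randomForest::randomForest(
      x = train$x[, feats, drop = FALSE], y = train$labels,
      ntree = ntree, mtry = max(1, floor(sqrt(length(feats)))),
      importance = TRUE)
  }
  rf <- fit_rf(selected)
  final <- selected
  dropped <- character(0)
  if (reduce && length(selected) > 1) {
    imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    keep <- names(imp)[imp > 0]
    if (length(keep) > 0 && length(keep) < length(selected)) {
      dropped <- setdiff(selected, keep)
      final <- selected[selected %in% keep]
      rf <- fit_rf(final)
    }
  }
  structure(list(forest = rf, selected_features = final,
                 lasso_features = selected, dropped_features = dropped,
                 scaler = scaler, kind = kind, seed = seed, ntree = ntree),
            class = "radiomics_signature")
}

#' Predict co-deletion probability from a fitted signature
#'
#' @param object a `radiomics_signature`.
#' @param table a [feature_table] (or numeric matrix) containing all selected
#'   feature columns, scaled with the training scaler.
#' @param ... unused.
#' @return Numeric vector of per-case probabilities of 1p/19q co-deletion.
#' @export
predict.radiomics_signature <- function(object, table, ...) {
  x <- if (inherits(table, "feature_table")) table$x else as.matrix(table)
  miss <- setdiff(object$selected_features, colnames(x))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  p <- stats::predict(object$forest,
                      newdata = x[, object$selected_features, drop = FALSE],
                      type = "prob")
  unname(p[, "codeleted"])
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat(sprintf("<radiomics_signature %s> %d feature(s): %s\n", x$kind,
              length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  if (length(x$dropped_features))
    cat("  dropped by forest reduction:",
        paste(x$dropped_features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.radiomics_signature <- function(object, ...) {
  imp <- randomForest::importance(object$forest, type = 1, scale = FALSE)[, 1]
  out <- data.frame(feature = names(imp),
                    oob_permutation_importance = unname(imp))
  out <- out[order(-out$oob_permutation_importance), ]
  rownames(out) <- NULL
  cat(sprintf("Radiomics signature (%s), %d trees, OOB error %.3f\n",
              object$kind, object$ntree,
              mean(object$forest$err.rate[, "OOB"])))
  print(out)
  invisible(out)
}
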