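#' Accuracy, sensitivity and specificity
#'
#' Co-deletion is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). Numeric predictions are thresholded at 0.5.
#' A metric whose class is absent is returned as `NA` with a flag.
#'
#' @param labels true labels (`"codeleted"` / `"intact"`, or factor).
#' @param predictions predicted labels, or probabilities of co-deletion.
#' @param threshold probability cutoff (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity` and
#'   `undefined` (character vector naming metrics with an absent class).
#' @export
confusion_metrics <- function(labels, predictions, threshold = 0.5) {
  y <- as.character(labels) == "codeleted"
  if (is.numeric(predictions)) {
    yhat <- predictions >= threshold
  } else {
    yhat <- as.character(predictions) == "codeleted"
  }
  if (length(y) != length(yhat)) stop("length mismatch")
  undef <- character(0)
  sen <- if (any(y)) sum(yhat & y) / sum(y) else { undef <- c(undef, "sensitivity"); NA_real_ }
  spe <- if (any(!y)) sum(!yhat & !y) / sum(!y) else { undef <- c(undef, "specificity"); NA_real_ }
  list(accuracy = mean(yhat == y), sensitivity = sen, specificity = spe,
       undefined = undef)
}

#' Tie-aware AUC via midranks
#'
#' Computes the area under the empirical ROC curve as the midrank
#' (Mann-Whitney) statistic: `P(score+ > score-) + 0.5 P(score+ = score-)`.
#'
#' @param labels true labels; co-deletion positive.
#' @param scores numeric scores, higher = more co-deletion-like.
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(labels, scores) {
  y <- as.character(labels) == "codeleted"
  m <- sum(y); n <- sum(!y)
  if (m == 0 || n == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

# placement values (structural components): V10 over positives, V01 over
# negatives, for one score vector
placements <- function(y, s) {
  pos <- s[y]; neg <- s[!y]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance and 95% CI of one AUC
#'
#' @inheritParams auc_midrank
#' @param conf confidence level (default 0.95).
#' @return List with `auc`, `var`, `ci` (truncated to `[0, 1]`) and `ci_raw`.
#' @export
delong_ci <- function(labels, scores, conf = 0.95) {
  y <- as.character(labels) == "codeleted"
  if (sum(y) == 0 || sum(!y) == 0) stop("both classes must be present")
  pl <- placements(y, scores)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci_raw <- pl$auc + c(-1, 1) * z * sqrt(max(v, 0))
  list(auc = pl$auc, var = v, ci = pmin(pmax(ci_raw, 0), 1), ci_raw = ci_raw)
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same cases using
#' the structural-component (placement-value) covariance estimate:
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)`, two-sided normal
#' p-value, and 95% CIs per AUC (reported truncated to `[0, 1]`; raw bounds
#' retained). Degenerate variance (e.g. identical scores) yields p = 1.
#'
#' @param labels true labels on the shared cases; co-deletion positive.
#' @param scores_a,scores_b paired score vectors.
#' @return An object of class `roc_comparison`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  y <- as.character(labels) == "codeleted"
  if (sum(y) == 0 || sum(!y) == 0) stop("both classes must be present")
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores must be paired with labels")
  pa <- placements(y, scores_a)
  pb <- placements(y, scores_b)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  vdiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(vdiff) || vdiff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(vdiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(0.975)
  ci <- function(auc, v) pmin(pmax(auc + c(-1, 1) * zq * sqrt(max(v, 0)), 0), 1)
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 delong_covariance = S, z = z, p_value = p,
                 ci_a = ci(pa$auc, S[1, 1]), ci_b = ci(pb$auc, S[2, 2]),
                 ci_a_raw = pa$auc + c(-1, 1) * zq * sqrt(max(S[1, 1], 0)),
                 ci_b_raw = pb$auc + c(-1, 1) * zq * sqrt(max(S[2, 2], 0))),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired ROC comparison\n  AUC A %.3f (%.3f-%.3f) vs AUC B %.3f (%.3f-%.3f)\n  z = %.3f, two-sided p = %.4g\n",
              x$auc_a, x$ci_a[1], x$ci_a[2], x$auc_b, x$ci_b[1], x$ci_b[2],
              x$z, x$p_value))
  invisible(x)
}

#' Re-evaluate fixed predictions in subgroups
#'
#' Restricts already-computed signature scores to case subgroups (no
#' refitting) and reports accuracy, sensitivity, specificity and AUC with its
#' DeLong CI per subgroup. Subgroups lacking one class get `NA` AUC with a
#' flag.
#'
#' @param labels true labels.
#' @param scores predicted co-deletion probabilities for the same cases.
#' @param subgroups named list of logical vectors (or index vectors) defining
#'   the subgroups.
#' @param threshold classification cutoff for the confusion metrics.
#' @return data.frame with one row per subgroup.
#' @export
evaluate_subgroups <- function(labels, scores, subgroups, threshold = 0.5) {
  stopifnot(length(subgroups) > 0, !is.null(names(subgroups)))
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]]
    yl <- labels[sel]; sc <- scores[sel]
    if (length(sc) == 0) stop("empty subgroup: ", nm)
    cm <- confusion_metrics(yl, sc, threshold)
    both <- length(unique(as.character(yl))) == 2
    if (both) {
      dc <- delong_ci(yl, sc)
      auc <- dc$auc; lo <- dc$ci[1]; hi <- dc$ci[2]
    } else {
      auc <- NA_real_; lo <- NA_real_; hi <- NA_real_
    }
    data.frame(subgroup = nm, n = length(sc),
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity, auc = auc,
               auc_lo = lo, auc_hi = hi,
               auc_defined = both, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
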