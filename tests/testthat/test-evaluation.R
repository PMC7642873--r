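test_that("confusion metrics treat co-deletion as the positive class", {
  y <- c(rep("codeleted", 6), rep("intact", 12))
  perfect <- ifelse(y == "codeleted", 0.9, 0.1)
  cm <- confusion_metrics(y, perfect)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)

  # all-negative predictions on 6+/12-: accuracy 12/18, sen 0, spe 1
  cm2 <- confusion_metrics(y, rep(0.1, 18))
  expect_equal(cm2$accuracy, 12 / 18)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)

  # inverted predictions: all three at 0
  cm3 <- confusion_metrics(y, ifelse(y == "codeleted", 0.1, 0.9))
  expect_equal(unlist(cm3[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 0, sensitivity = 0, specificity = 0))

  # absent class flagged
  cm4 <- confusion_metrics(rep("intact", 5), rep(0.1, 5))
  expect_true(is.na(cm4$sensitivity))
  expect_equal(cm4$undefined, "sensitivity")
})

test_that("midrank AUC matches brute-force pair counting, including ties", {
  y <- c("codeleted", "codeleted", "intact", "intact")
  expect_equal(auc_midrank(y, c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(auc_midrank(y, rep(0.5, 4)), 0.5)
  set.seed(31)
  for (i in 1:10) {
    yy <- sample(c("codeleted", "intact"), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(yy)) < 2) next
    ss <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
    expect_equal(auc_midrank(yy, ss), auc_bruteforce(yy, ss))
  }
  expect_error(auc_midrank(rep("intact", 4), 1:4), "both classes")
})

test_that("midrank AUC equals the trapezoidal ROC area on tie-free data", {
  set.seed(17)
  for (i in 1:5) {
    y <- sample(c("codeleted", "intact"), 25, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- rnorm(25)
    ths <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    pts <- t(vapply(ths, function(t.) {
      c(fpr = mean(s[y == "intact"] >= t.), tpr = mean(s[y == "codeleted"] >= t.))
    }, numeric(2)))
    trap <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                        utils::tail(pts[, "tpr"], -1)) / 2)
    expect_equal(auc_midrank(y, s), trap)
  }
})

test_that("DeLong test agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    n <- 60
    y <- c(rep("codeleted", 15), rep("intact", 45))
    base <- ifelse(y == "codeleted", 1, 0)
    sa <- base + rnorm(n)
    sb <- 0.7 * base + rnorm(n)
    rc <- delong_test(y, sa, sb)
    ref <- pROC::roc.test(pROC::roc(y == "codeleted", sa, quiet = TRUE),
                          pROC::roc(y == "codeleted", sb, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(rc$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(rc$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
    ci <- pROC::ci.auc(pROC::roc(y == "codeleted", sa, quiet = TRUE),
                       method = "delong")
    expect_equal(rc$ci_a_raw, as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("DeLong test is symmetric and degenerate-safe", {
  set.seed(9)
  y <- c(rep("codeleted", 10), rep("intact", 20))
  sa <- rnorm(30); sb <- rnorm(30)
  ab <- delong_test(y, sa, sb)
  ba <- delong_test(y, sb, sa)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(all(eigen(ab$delong_covariance, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-12))
  expect_true(ab$ci_a[1] <= ab$auc_a && ab$auc_a <= ab$ci_a[2])
  # identical scores: difference 0, p = 1
  same <- delong_test(y, sa, sa)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
})

test_that("DeLong variance matches the bootstrap on small samples", {
  set.seed(13)
  n_pos <- 16; n_neg <- 62
  y <- c(rep("codeleted", n_pos), rep("intact", n_neg))
  s <- ifelse(y == "codeleted", 1.6, 0) + rnorm(n_pos + n_neg)
  dc <- delong_ci(y, s)
  boot <- replicate(2000, {
    i <- c(sample(seq_len(n_pos), replace = TRUE),
           n_pos + sample(seq_len(n_neg), replace = TRUE))
    auc_midrank(y[i], s[i])
  })
  expect_equal(dc$var, var(boot), tolerance = 0.3)
})

test_that("high AUC on an imbalanced sample truncates the upper CI bound at 1", {
  set.seed(21)
  y <- c(rep("codeleted", 16), rep("intact", 62))
  repeat {
    s <- ifelse(y == "codeleted", 2.2, 0) + rnorm(78)
    dc <- delong_ci(y, s)
    if (dc$auc > 0.9 && dc$auc < 0.98) break
  }
  expect_gt(dc$ci_raw[2], 1)
  expect_equal(dc$ci[2], 1)
  expect_lt(dc$ci[1], dc$auc)
})

test_that("subgroup evaluation restricts fixed predictions without refitting", {
  set.seed(3)
  y <- sample(c("codeleted", "intact"), 40, replace = TRUE, prob = c(0.3, 0.7))
  s <- ifelse(y == "codeleted", 0.8, 0.2) + rnorm(40, sd = 0.05)
  full <- evaluate_subgroups(y, s, list(all = rep(TRUE, 40)))
  expect_equal(full$auc, auc_midrank(y, s))
  expect_equal(full$accuracy, confusion_metrics(y, s)$accuracy)

  # perfectly predicted subgroup
  g <- y == "codeleted" | seq_along(y) %% 2 == 0
  sub <- evaluate_subgroups(y, s, list(sub = g))
  expect_equal(sub$accuracy, 1)
  expect_equal(sub$auc, 1)

  # single-class subgroup: AUC flagged undefined
  onec <- evaluate_subgroups(y, s, list(neg = y == "intact"))
  expect_false(onec$auc_defined)
  expect_true(is.na(onec$auc))
  expect_error(evaluate_subgroups(y, s, list(none = rep(FALSE, 40))), "empty")
})
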