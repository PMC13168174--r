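test_that("confusion matrices count pooled predictions in fixed class order", {
  lv <- yield_class_levels()
  perfect <- data.frame(true_class = lv, predicted_class = lv)
  cm <- confusion_matrix(perfect)
  expect_identical(unname(diag(unclass(cm))), rep(1L, 3))
  expect_identical(sum(cm), 3L)

  one <- data.frame(true_class = "low", predicted_class = "high")
  cm1 <- confusion_matrix(one)
  expect_identical(unclass(cm1)["low", "high"], 1L)
  expect_identical(sum(cm1), 1L)

  expect_error(confusion_matrix(data.frame(true_class = "med", predicted_class = "low")),
               "unknown class")

  # pooling is additive over repetitions
  p <- random_preds(120, seed = 1)
  p$repetition <- rep(1:3, each = 40)
  total <- unclass(confusion_matrix(p))
  by_rep <- Reduce(`+`, lapply(1:3, function(r)
    unclass(confusion_matrix(p[p$repetition == r, ]))))
  expect_identical(total, by_rep)
})

test_that("class metrics reproduce printed one-vs-rest identities", {
  # sensitivity 0.85 with specificity 0.93 -> balanced accuracy 0.89
  cm <- cm_from_counts(tp = 85, fn = 15, fp = 7, tn = 93)
  low <- class_metrics(cm, focal = "low")
  expect_equal(low$sensitivity, 0.85)
  expect_equal(low$specificity, 0.93)
  expect_equal(round(low$balanced_accuracy, 2), 0.89)

  # precision 0.76 with sensitivity 0.66 -> F1 = 0.71 at two decimals
  cm2 <- cm_from_counts(tp = 627, fn = 323, fp = 198, tn = 950,
                        focal = "high", other = "moderate")
  high <- class_metrics(cm2, focal = "high")
  expect_equal(high$precision, 0.76)
  expect_equal(high$sensitivity, 0.66)
  expect_equal(round(high$f1, 2), 0.71)
})

test_that("class metrics equal the record-enumeration oracle on random matrices", {
  set.seed(99)
  for (i in 1:25) {
    cm <- structure(as.table(matrix(rpois(9, 12), 3, 3,
                                    dimnames = list(true = yield_class_levels(),
                                                    predicted = yield_class_levels()))),
                    class = c("confusion3", "table"))
    for (cl in yield_class_levels()) {
      got <- class_metrics(cm, focal = cl)
      want <- enumerate_metrics(unclass(cm), cl)
      expect_equal(got$tp, unname(want["tp"]))
      for (nm in c("sensitivity", "specificity", "precision", "npv"))
        expect_equal(got[[nm]], unname(want[nm]), tolerance = 1e-12,
                     ignore_attr = TRUE)
      expect_equal(got$balanced_accuracy,
                   unname((want["sensitivity"] + want["specificity"]) / 2))
      expect_equal(got$detection_rate, unname(want["tp"] / sum(cm)))
      expect_lte(got$detection_rate, got$prevalence + 1e-15)
      expect_lte(got$detection_rate, got$detection_prevalence + 1e-15)
    }
  }
})

test_that("class metrics agree with the reference implementation in caret", {
  skip_if_not_installed("caret")
  set.seed(123)
  p <- random_preds(300, seed = 17)
  cm <- confusion_matrix(p)
  ref <- caret::confusionMatrix(
    factor(p$predicted_class, levels = yield_class_levels()),
    factor(p$true_class, levels = yield_class_levels()))
  ours <- class_metrics(cm)
  refc <- ref$byClass
  expect_equal(ours$sensitivity, unname(refc[, "Sensitivity"]), tolerance = 1e-12)
  expect_equal(ours$specificity, unname(refc[, "Specificity"]), tolerance = 1e-12)
  expect_equal(ours$precision, unname(refc[, "Pos Pred Value"]), tolerance = 1e-12)
  expect_equal(ours$npv, unname(refc[, "Neg Pred Value"]), tolerance = 1e-12)
  expect_equal(ours$balanced_accuracy, unname(refc[, "Balanced Accuracy"]), tolerance = 1e-12)
  ov <- overall_metrics(cm)
  expect_equal(ov$accuracy, unname(ref$overall["Accuracy"]), tolerance = 1e-12)
  expect_equal(ov$kappa, unname(ref$overall["Kappa"]), tolerance = 1e-12)
  expect_equal(ov$nir, unname(ref$overall["AccuracyNull"]), tolerance = 1e-12)
  expect_equal(ov$p_acc_gt_nir, unname(ref$overall["AccuracyPValue"]), tolerance = 1e-9)
})

test_that("zero denominators surface as undefined, never as zero", {
  cm <- cm_from_counts(tp = 0, fn = 0, fp = 0, tn = 50)
  row <- class_metrics(cm, focal = "low")
  expect_true(is.nan(row$sensitivity))
  expect_true(is.nan(row$precision))
  expect_true(row$undefined)
  expect_equal(row$specificity, 1)
})

test_that("overall metrics follow the printed formulas", {
  p <- random_preds(400, seed = 23)
  cm <- confusion_matrix(p)
  pc <- class_metrics(cm)
  ov <- overall_metrics(cm, pc)
  m <- unclass(cm); n <- sum(m)
  expect_equal(ov$accuracy, sum(diag(m)) / n)
  # Wald CI with z = 1.96 contains the accuracy
  half <- 1.96 * sqrt(ov$accuracy * (1 - ov$accuracy) / n)
  expect_equal(unname(ov$accuracy_ci95), c(ov$accuracy - half, ov$accuracy + half))
  expect_true(ov$accuracy >= ov$accuracy_ci95[1] && ov$accuracy <= ov$accuracy_ci95[2])
  # kappa from observed and chance agreement
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  expect_equal(ov$kappa, (ov$accuracy - pe) / (1 - pe))
  expect_equal(ov$nir, max(rowSums(m)) / n)
  # exact binomial tail
  expect_equal(ov$p_acc_gt_nir,
               stats::pbinom(sum(diag(m)) - 1, n, ov$nir, lower.tail = FALSE))
  # macro metrics are unweighted means of the class rows
  expect_equal(unname(ov$macro["macro_balanced_accuracy"]),
               mean(pc$balanced_accuracy))
  expect_equal(unname(ov$macro["macro_f1"]), mean(pc$f1))
  # kappa never exceeds accuracy when accuracy beats chance
  if (ov$accuracy >= ov$p_e) expect_lte(ov$kappa, ov$accuracy)
})

test_that("kappa attains its limits", {
  lv <- yield_class_levels()
  perfect <- data.frame(true_class = rep(lv, c(10, 20, 5)),
                        predicted_class = rep(lv, c(10, 20, 5)))
  expect_equal(overall_metrics(confusion_matrix(perfect))$kappa, 1)
  majority <- data.frame(true_class = rep(lv, c(10, 20, 5)),
                         predicted_class = "moderate")
  expect_equal(overall_metrics(confusion_matrix(majority))$kappa, 0)
})

test_that("McNemar statistics follow (b - c)^2 / (b + c)", {
  cm <- cm_from_counts(tp = 30, fn = 10, fp = 10, tn = 50)
  ov <- overall_metrics(cm)
  low <- ov$mcnemar[ov$mcnemar$class == "low", ]
  expect_equal(low$chisq, 0)  # b = c = 10
  cm2 <- cm_from_counts(tp = 30, fn = 0, fp = 5, tn = 50)
  ov2 <- overall_metrics(cm2)
  low2 <- ov2$mcnemar[ov2$mcnemar$class == "low", ]
  expect_equal(low2$chisq, 5)  # b = 5, c = 0
  # b + c = 0 is undefined and flagged
  cm3 <- cm_from_counts(tp = 30, fn = 0, fp = 0, tn = 50)
  ov3 <- overall_metrics(cm3)
  expect_true(ov3$mcnemar$undefined[ov3$mcnemar$class == "low"])
  expect_true(is.nan(ov3$mcnemar$chisq[ov3$mcnemar$class == "low"]))
})

test_that("misclassification severity counts ordinal steps", {
  p <- data.frame(true_class = c("low", "low", "high", "moderate"),
                  predicted_class = c("moderate", "high", "low", "moderate"))
  sv <- severity_analysis(p)
  expect_equal(unname(sv$proportions), c(0.25, 0.25, 0.5))
  expect_identical(sv$n_extreme, 2L)
  expect_equal(sum(sv$proportions), 1)

  # consistency with the confusion matrix off-diagonals
  rp <- random_preds(250, seed = 31)
  cm <- unclass(confusion_matrix(rp))
  sv2 <- severity_analysis(rp)
  expect_identical(sv2$n_extreme, cm["low", "high"] + cm["high", "low"])
  expect_equal(sv2$proportions[["correct"]], sum(diag(cm)) / sum(cm))
})

test_that("the discard rule is threshold-inclusive and validated", {
  p <- data.frame(genotype_id = c("a", "b", "c", "d"),
                  p_low = c(0.75, 0.70, 0.69, 0),
                  p_moderate = c(0.15, 0.20, 0.21, 0.4),
                  p_high = c(0.10, 0.10, 0.10, 0.6))
  d <- apply_decision_rule(p, 0.70)
  expect_identical(d$decision, c("discard", "discard", "advance", "advance"))
  expect_equal(attr(d, "discard_fraction"), 0.5)
  expect_error(apply_decision_rule(p, 0), "threshold")
  expect_error(apply_decision_rule(p, 1.2), "threshold")
  bad <- p; bad$p_low[1] <- 0.9
  expect_error(apply_decision_rule(bad), "sum to 1")
  # probabilities average per genotype across repetitions before the rule
  p2 <- rbind(p, p)
  p2$p_low[5] <- 0.55; p2$p_moderate[5] <- 0.35
  d2 <- apply_decision_rule(p2, 0.70)
  expect_identical(d2$decision[d2$genotype == "a"], "advance")  # mean p_low 0.65
})

test_that("the diversity diagnostic measures centroid overlap on PC1-PC2", {
  # identical (degenerate) groups overlap completely
  sc <- matrix(0, 20, 2, dimnames = list(paste0("g", 1:20), NULL))
  pca <- structure(list(scores = sc, explained_variance_fraction = c(0.5, 0.3)),
                   class = "pca_result")
  dec <- structure(data.frame(genotype = paste0("g", 1:20),
                              decision = rep(c("advance", "discard"), 10)),
                   class = c("decision_table", "data.frame"))
  dv <- diversity_diagnostic(pca, dec)
  expect_equal(dv$overlap, 1)

  # well-separated groups do not overlap
  sc2 <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 50, 0.1), 10, 2))
  rownames(sc2) <- paste0("g", 1:20)
  pca2 <- structure(list(scores = sc2, explained_variance_fraction = c(0.5, 0.3)),
                    class = "pca_result")
  dec2 <- structure(data.frame(genotype = paste0("g", 1:20),
                               decision = rep(c("advance", "discard"), each = 10)),
                    class = c("decision_table", "data.frame"))
  dv2 <- diversity_diagnostic(pca2, dec2)
  expect_equal(dv2$overlap, 0)
  expect_gt(dv2$groups$advance$dispersion, 0)

  # random decisions within one family give equal dispersions on average
  set.seed(12)
  ratios <- vapply(1:10, function(i) {
    sc3 <- matrix(rnorm(120), 60, 2, dimnames = list(paste0("g", 1:60), NULL))
    pca3 <- structure(list(scores = sc3, explained_variance_fraction = c(0.5, 0.3)),
                      class = "pca_result")
    dec3 <- structure(data.frame(genotype = paste0("g", 1:60),
                                 decision = sample(rep(c("advance", "discard"), 30))),
                      class = c("decision_table", "data.frame"))
    dv3 <- diversity_diagnostic(pca3, dec3)
    dv3$groups$advance$dispersion / dv3$groups$discard$dispersion
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.15)

  # tiny groups are flagged
  dec4 <- structure(data.frame(genotype = paste0("g", 1:4),
                               decision = c("advance", "advance", "advance", "discard")),
                    class = c("decision_table", "data.frame"))
  pca4 <- structure(list(scores = matrix(rnorm(8), 4, 2,
                                         dimnames = list(paste0("g", 1:4), NULL)),
                         explained_variance_fraction = c(0.5, 0.3)),
                    class = "pca_result")
  dv4 <- diversity_diagnostic(pca4, dec4)
  expect_true(dv4$groups$discard$flagged)
  expect_true(is.na(dv4$groups$discard$dispersion))
})
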