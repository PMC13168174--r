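#' 3 x 3 confusion matrix of pooled predictions
#'
#' Counts indexed (true class, predicted class) over the fixed order
#' low < moderate < high.
#'
#' @param preds a `cv_predictions` (or any data.frame with `true_class` and
#'   `predicted_class` columns); labels outside the three classes are an
#'   error.
#' @return a `confusion3` table.
#' @export
confusion_matrix <- function(preds) {
  stopifnot(is.data.frame(preds), nrow(preds) > 0,
            all(c("true_class", "predicted_class") %in% names(preds)))
  lv <- yield_class_levels()
  tc <- as.character(preds$true_class); pc <- as.character(preds$predicted_class)
  bad <- unique(c(tc[!tc %in% lv], pc[!pc %in% lv]))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  tab <- table(true = factor(tc, levels = lv), predicted = factor(pc, levels = lv))
  structure(tab, class = c("confusion3", class(tab)))
}

one_vs_rest <- function(cm, focal) {
  lv <- yield_class_levels()
  stopifnot(focal %in% lv)
  cm <- unclass(cm)
  tp <- cm[focal, focal]
  fn <- sum(cm[focal, ]) - tp
  fp <- sum(cm[, focal]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' One-vs-rest class metrics
#'
#' For each focal class the remaining classes are pooled as negative and the
#' standard confusion-matrix metrics are computed: sensitivity (recall)
#' TP/(TP+FN), specificity TN/(TN+FP), precision (positive predictive value)
#' TP/(TP+FP), negative predictive value TN/(TN+FN), F1 (harmonic mean of
#' precision and sensitivity), balanced accuracy (mean of sensitivity and
#' specificity), prevalence, detection rate and detection prevalence. A zero
#' denominator yields `NaN` and sets the `undefined` flag — never a silent 0.
#'
#' @param cm a [confusion_matrix()].
#' @param focal a single class, or NULL (default) for all three.
#' @return a `class_metrics` data.frame with one row per focal class,
#'   including the one-vs-rest TP/FN/FP/TN counts.
#' @export
class_metrics <- function(cm, focal = NULL) {
  stopifnot(inherits(cm, "confusion3"))
  lv <- if (is.null(focal)) yield_class_levels() else focal
  rows <- lapply(lv, function(cl) {
    ct <- one_vs_rest(cm, cl)
    tp <- ct["tp"]; fn <- ct["fn"]; fp <- ct["fp"]; tn <- ct["tn"]
    n <- tp + fn + fp + tn
    rat <- function(num, den) if (den == 0) NaN else num / den
    sens <- rat(tp, tp + fn); spec <- rat(tn, tn + fp)
    prec <- rat(tp, tp + fp); npv <- rat(tn, tn + fn)
    f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN else
      2 * prec * sens / (prec + sens)
    data.frame(class = cl, tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = sens, specificity = spec, precision = prec,
               npv = npv, f1 = f1,
               balanced_accuracy = (sens + spec) / 2,
               prevalence = rat(tp + fn, n), detection_rate = rat(tp, n),
               detection_prevalence = rat(tp + fp, n),
               undefined = is.nan(sens) || is.nan(spec) || is.nan(prec) ||
                 is.nan(npv) || is.nan(f1),
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("class_metrics", "data.frame"))
}

#' Overall and macro-averaged metrics
#'
#' Overall accuracy (trace over total) with a Wald 95% confidence interval
#' (z = 1.96, n = pooled prediction count); Cohen's kappa
#' \eqn{(P_o - P_e)/(1 - P_e)} with chance agreement from the row/column
#' marginals; the no-information rate (largest class prevalence) and the
#' one-sided exact binomial p-value for accuracy exceeding it; per-class
#' one-vs-rest McNemar statistics \eqn{(b-c)^2/(b+c)} (no continuity
#' correction, flagged undefined when b + c = 0); and macro averages
#' (unweighted means over the three classes) of sensitivity, specificity,
#' precision, NPV, F1 and balanced accuracy.
#'
#' @param cm a [confusion_matrix()].
#' @param per_class optionally the matching [class_metrics()] (recomputed if
#'   omitted).
#' @return an `overall_metrics` list.
#' @export
overall_metrics <- function(cm, per_class = NULL) {
  stopifnot(inherits(cm, "confusion3"))
  if (is.null(per_class)) per_class <- class_metrics(cm)
  m <- unclass(cm)
  n <- sum(m)
  acc <- sum(diag(m)) / n
  half <- 1.96 * sqrt(acc * (1 - acc) / n)
  po <- acc
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  nir <- max(rowSums(m)) / n
  p_acc <- stats::pbinom(sum(diag(m)) - 1, n, nir, lower.tail = FALSE)
  mcn <- lapply(yield_class_levels(), function(cl) {
    ct <- one_vs_rest(cm, cl)
    b <- ct[["fp"]]; cc <- ct[["fn"]]
    if (b + cc == 0)
      list(class = cl, b = b, c = cc, chisq = NaN, p = NaN, undefined = TRUE)
    else {
      chi <- (b - cc)^2 / (b + cc)
      list(class = cl, b = b, c = cc, chisq = chi,
           p = stats::pchisq(chi, 1, lower.tail = FALSE), undefined = FALSE)
    }
  })
  mcn <- do.call(rbind, lapply(mcn, as.data.frame))
  macro <- vapply(c("sensitivity", "specificity", "precision", "npv", "f1",
                    "balanced_accuracy"),
                  function(col) mean(per_class[[col]]), 0)
  names(macro) <- paste0("macro_", c("sensitivity", "specificity", "ppv", "npv",
                                     "f1", "balanced_accuracy"))
  structure(list(accuracy = acc,
                 accuracy_ci95 = c(lower = max(0, acc - half), upper = min(1, acc + half)),
                 kappa = kappa, p_o = po, p_e = pe, nir = nir,
                 p_acc_gt_nir = p_acc, mcnemar = mcn,
                 macro = macro, n = n), class = "overall_metrics")
}

#' @export
print.overall_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f (95%% CI %.2f-%.2f), kappa %.2f, NIR %.2f, P[acc > NIR] %.3g\n",
              x$accuracy, x$accuracy_ci95["lower"], x$accuracy_ci95["upper"],
              x$kappa, x$nir, x$p_acc_gt_nir))
  cat("macro:", paste(sprintf("%s %.2f", sub("macro_", "", names(x$macro)), x$macro),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Misclassification severity
#'
#' Predictions are graded by how many steps the predicted class lies from the
#' true class along the order low < moderate < high: 0 steps is correct, 1 is
#' a mild misclassification, 2 (confusing the low- and high-yielding
#' extremes) is extreme.
#'
#' @param preds a `cv_predictions` (or data.frame with `true_class`,
#'   `predicted_class`).
#' @return a `severity_report`: proportions of correct/mild/extreme (summing
#'   to 1) and the count of high-low confusions.
#' @export
severity_analysis <- function(preds) {
  lv <- yield_class_levels()
  tc <- match(as.character(preds$true_class), lv)
  pc <- match(as.character(preds$predicted_class), lv)
  if (anyNA(tc) || anyNA(pc)) stop("unknown class labels in predictions")
  d <- abs(tc - pc)
  n <- length(d)
  structure(list(proportions = c(correct = sum(d == 0) / n,
                                 mild = sum(d == 1) / n,
                                 extreme = sum(d == 2) / n),
                 n_extreme = sum(d == 2), n = n),
            class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("severity: %.1f%% correct, %.1f%% mild, %.1f%% extreme (%d high<->low confusions of %d)\n",
              100 * x$proportions["correct"], 100 * x$proportions["mild"],
              100 * x$proportions["extreme"], x$n_extreme, x$n))
  invisible(x)
}

#' Probability-threshold advancement decisions
#'
#' Designates a genotype for discard when its predicted probability of
#' belonging to the low-yielding class reaches the threshold (boundary
#' inclusive): `p_low >= threshold` discards, anything else advances. With
#' pooled cross-validation predictions the class probabilities are first
#' averaged per genotype across repetitions.
#'
#' @param preds a `cv_predictions`, the output of
#'   [predict.yieldclass_model()], or any data.frame with a genotype
#'   identifier column and `p_low`, `p_moderate`, `p_high`.
#' @param threshold discard threshold on `p_low`, in (0, 1]; default 0.70.
#' @return a `decision_table` data.frame: genotype, class probabilities,
#'   `decision` (advance/discard), `rule`; attribute `discard_fraction`.
#' @export
apply_decision_rule <- function(preds, threshold = 0.70) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold <= 1))
    stop("`threshold` must lie in (0, 1]")
  stopifnot(is.data.frame(preds),
            all(c("p_low", "p_moderate", "p_high") %in% names(preds)))
  idcol <- intersect(c("genotype_id", "genotype"), names(preds))[1]
  if (is.na(idcol)) stop("`preds` needs a genotype_id (or genotype) column")
  pr <- c("p_low", "p_moderate", "p_high")
  if (any(unlist(preds[pr]) < -1e-8) ||
      any(abs(rowSums(preds[pr]) - 1) > 1e-6))
    stop("class probabilities must be non-negative and sum to 1")
  agg <- stats::aggregate(preds[pr], by = list(genotype = preds[[idcol]]), FUN = mean)
  rule <- sprintf("discard if p_low >= %.2f", threshold)
  agg$decision <- ifelse(agg$p_low >= threshold, "discard", "advance")
  agg$rule <- rule
  structure(agg, discard_fraction = mean(agg$decision == "discard"),
            threshold = threshold,
            class = c("decision_table", "data.frame"))
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("decision_table: %d genotypes, %.1f%% designated for discard (%s)\n",
              nrow(x), 100 * attr(x, "discard_fraction"), x$rule[1]))
  invisible(x)
}

#' Genomic-diversity diagnostic of advancement decisions
#'
#' Checks whether advance/discard decisions merely track overall genetic
#' similarity: on the first two marker principal components it reports each
#' group's centroid and dispersion (mean distance to centroid) and an overlap
#' coefficient — the fraction of discarded genotypes lying inside the advance
#' group's 95% dispersion radius. Substantial overlap indicates decisions are
#' not explained by genome-wide relatedness alone.
#'
#' @param pca a [pca_markers()] result with scores for every decided genotype.
#' @param decisions a [apply_decision_rule()] table.
#' @return a `diversity_diagnostic` list: per-group centroid, dispersion
#'   (NA with a flag for groups of fewer than 3), and `overlap`.
#' @export
diversity_diagnostic <- function(pca, decisions) {
  stopifnot(inherits(pca, "pca_result"), inherits(decisions, "decision_table"))
  sc <- pca$scores[, 1:2, drop = FALSE]
  miss <- setdiff(decisions$genotype, rownames(sc))
  if (length(miss))
    stop("PCA scores missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  sc <- sc[decisions$genotype, , drop = FALSE]
  grp <- split(seq_len(nrow(sc)), decisions$decision)
  stats_of <- function(idx) {
    ctr <- colMeans(sc[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(sc[idx, , drop = FALSE], 2, ctr)^2))
    list(n = length(idx), centroid = ctr,
         dispersion = if (length(idx) >= 3) mean(d) else NA_real_,
         r95 = if (length(idx) >= 3) stats::quantile(d, 0.95, names = FALSE) else NA_real_,
         flagged = length(idx) < 3)
  }
  gs <- lapply(grp, stats_of)
  overlap <- NA_real_
  if (!is.null(gs$advance) && !is.null(gs$discard) && !gs$advance$flagged) {
    di <- grp$discard
    dist_adv <- sqrt(rowSums(sweep(sc[di, , drop = FALSE], 2, gs$advance$centroid)^2))
    overlap <- mean(dist_adv <= gs$advance$r95)
  }
  structure(list(groups = gs, overlap = overlap), class = "diversity_diagnostic")
}

#' @export
print.diversity_diagnostic <- function(x, ...) {
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("  %s: n = %d, dispersion = %s\n", g, s$n,
                if (is.na(s$dispersion)) "undefined (<3 members)" else sprintf("%.2f", s$dispersion)))
  }
  cat(sprintf("  overlap coefficient: %s\n",
              if (is.na(x$overlap)) "undefined" else sprintf("%.2f", x$overlap)))
  invisible(x)
}

#' Write the evaluation reports as CSV files
#'
#' Emits the confusion matrix, the class-level metric table (Table-3 style
#' layout), the overall metric summary (Table-2 style), the McNemar table,
#' the severity proportions and (optionally) the decision table into a
#' directory.
#'
#' @param dir output directory (created if needed).
#' @param preds a `cv_predictions`.
#' @param prefix file-name prefix (e.g. the model family).
#' @param decisions optional [apply_decision_rule()] table.
#' @return the directory, invisibly.
#' @export
write_evaluation_csv <- function(dir, preds, prefix = "model", decisions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- confusion_matrix(preds)
  pc <- class_metrics(cm)
  ov <- overall_metrics(cm, pc)
  sv <- severity_analysis(preds)
  utils::write.csv(as.data.frame(unclass(cm)),
                   file.path(dir, paste0(prefix, "_confusion.csv")))
  utils::write.csv(as.data.frame(pc),
                   file.path(dir, paste0(prefix, "_class_metrics.csv")), row.names = FALSE)
  ovdf <- data.frame(metric = c("accuracy", "ci_lower", "ci_upper", "kappa",
                                "nir", "p_acc_gt_nir", names(ov$macro)),
                     value = c(ov$accuracy, ov$accuracy_ci95, ov$kappa, ov$nir,
                               ov$p_acc_gt_nir, ov$macro))
  utils::write.csv(ovdf, file.path(dir, paste0(prefix, "_overall_metrics.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ov$mcnemar),
                   file.path(dir, paste0(prefix, "_mcnemar.csv")), row.names = FALSE)
  svdf <- data.frame(outcome = names(sv$proportions), proportion = sv$proportions)
  utils::write.csv(svdf, file.path(dir, paste0(prefix, "_severity.csv")),
                   row.names = FALSE)
  if (!is.null(decisions))
    utils::write.csv(as.data.frame(decisions),
                     file.path(dir, paste0(prefix, "_decisions.csv")), row.names = FALSE)
  invisible(dir)
}
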