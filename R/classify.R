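#' Cross-validation protocol
#'
#' Repeated, stratified evaluation: in each outer repetition the data are
#' split into 80% training / 20% testing preserving class proportions;
#' hyperparameters are chosen on the training part only, by inner k-fold
#' cross-validation repeated several times; the tuned model is refit on the
#' full training part and produces out-of-fold class predictions and
#' probabilities on the held-out 20%, pooled across repetitions.
#'
#' @param outer_reps number of outer repetitions (default 10).
#' @param outer_test_fraction held-out fraction per repetition (default 0.20).
#' @param inner_folds,inner_repeats inner tuning scheme (default 5-fold
#'   repeated 5 times).
#' @param stratified stratify all splits by class (default TRUE).
#' @param seed integer seed controlling every split and model fit.
#' @return a `cv_protocol` list.
#' @export
cv_protocol <- function(outer_reps = 10, outer_test_fraction = 0.20,
                        inner_folds = 5, inner_repeats = 5,
                        stratified = TRUE, seed = 1) {
  if (!(outer_test_fraction > 0 && outer_test_fraction < 1))
    stop("`outer_test_fraction` must be in (0, 1)")
  if (inner_folds < 2) stop("`inner_folds` must be at least 2")
  structure(list(outer_reps = outer_reps, outer_test_fraction = outer_test_fraction,
                 inner_folds = inner_folds, inner_repeats = inner_repeats,
                 stratified = stratified, seed = seed), class = "cv_protocol")
}

#' Classifier specification
#'
#' @param family `"elastic_net_multinomial"` (glmnet, multinomial link,
#'   predictors standardized internally) or `"random_forest"` (class
#'   probabilities from tree vote fractions).
#' @param tuning_grid optional named list of hyperparameter values. For the
#'   elastic net: `alpha` (mixing parameter, default \{0.1, 0.55, 1\}) and
#'   `lambda` (penalties; default 10 values log-spaced down from the
#'   data-derived maximum). For the random forest: `mtry` (default
#'   \{sqrt(m)/2, sqrt(m), 2 sqrt(m)\}).
#' @param final_metric tuning criterion: `"accuracy"` (default) or `"kappa"`.
#' @param ntree trees per random forest (default 500).
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("elastic_net_multinomial", "random_forest"),
                       tuning_grid = NULL, final_metric = c("accuracy", "kappa"),
                       ntree = 500) {
  family <- match.arg(family)
  if (!is.null(tuning_grid) && length(tuning_grid) == 0)
    stop("`tuning_grid` must be NULL or a non-empty named list")
  structure(list(family = family, tuning_grid = tuning_grid,
                 final_metric = match.arg(final_metric), ntree = ntree),
            class = "model_spec")
}

# stratified test indices: round(frac * n_c) per class
stratified_test_idx <- function(y, frac, stratified = TRUE) {
  if (!stratified) return(sample(length(y), round(frac * length(y))))
  idx <- integer(0)
  for (cl in levels(y)) {
    members <- which(y == cl)
    n_test <- round(frac * length(members))
    if (length(members)) idx <- c(idx, sample(members, n_test))
  }
  sort(idx)
}

# stratified fold assignment
make_folds <- function(y, k, stratified = TRUE) {
  fold <- integer(length(y))
  if (stratified) {
    for (cl in levels(y)) {
      members <- which(y == cl)
      fold[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  } else fold <- sample(rep_len(seq_len(k), length(y)))
  fold
}

tune_metric <- function(true, pred, metric) {
  if (metric == "accuracy") return(mean(pred == true))
  # Cohen's kappa
  tab <- table(factor(true, levels = levels(true)), factor(pred, levels = levels(true)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

default_grid <- function(spec, x, y) {
  if (spec$family == "elastic_net_multinomial") {
    g <- spec$tuning_grid
    alpha <- if (!is.null(g$alpha)) g$alpha else c(0.1, 0.55, 1.0)
    lambda <- g$lambda  # NULL -> derived per alpha from the data
    list(alpha = alpha, lambda = lambda)
  } else {
    g <- spec$tuning_grid
    m <- ncol(x)
    mtry <- if (!is.null(g$mtry)) g$mtry else
      unique(pmax(1, pmin(m, round(c(sqrt(m) / 2, sqrt(m), 2 * sqrt(m))))))
    list(mtry = mtry)
  }
}

# lambda grid: log-spaced down from the data-derived maximum
lambda_grid <- function(x, y, alpha, n = 10, min_ratio = 1e-3) {
  f0 <- glmnet::glmnet(x, y, family = "multinomial", alpha = max(alpha, 1e-3),
                       nlambda = 3)
  lmax <- max(f0$lambda)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n))
}

# inner repeated k-fold tuning; returns best hyperparameters
tune_model <- function(x, y, spec, protocol) {
  grid <- default_grid(spec, x, y)
  k <- protocol$inner_folds
  reps <- protocol$inner_repeats
  if (spec$family == "elastic_net_multinomial") {
    scores <- NULL
    for (a in grid$alpha) {
      lam <- if (!is.null(grid$lambda)) sort(grid$lambda, decreasing = TRUE) else
        lambda_grid(x, y, a)
      sc <- matrix(0, length(lam), 0)
      for (r in seq_len(reps)) {
        fold <- make_folds(y, k, protocol$stratified)
        for (fd in seq_len(k)) {
          tr <- fold != fd
          if (length(unique(y[tr])) < 2) next
          fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                                family = "multinomial", alpha = a, lambda = lam)
          pr <- predict(fit, x[!tr, , drop = FALSE], s = lam, type = "class")
          sc <- cbind(sc, vapply(seq_along(lam), function(j)
            tune_metric(y[!tr], factor(pr[, j], levels = levels(y)),
                        spec$final_metric), 0))
        }
      }
      scores <- rbind(scores, data.frame(alpha = a, lambda = lam,
                                         score = rowMeans(sc)))
    }
    best <- scores[which.max(scores$score), ]
    list(alpha = best$alpha, lambda = best$lambda, scores = scores)
  } else {
    scores <- data.frame(mtry = grid$mtry, score = NA_real_)
    for (i in seq_along(grid$mtry)) {
      accs <- c()
      for (r in seq_len(reps)) {
        fold <- make_folds(y, k, protocol$stratified)
        for (fd in seq_len(k)) {
          tr <- fold != fd
          if (length(unique(y[tr])) < 2) next
          fit <- randomForest::randomForest(x[tr, , drop = FALSE],
                                            droplevels(y[tr]),
                                            ntree = spec$ntree,
                                            mtry = grid$mtry[i])
          pr <- stats::predict(fit, x[!tr, , drop = FALSE])
          accs <- c(accs, tune_metric(y[!tr], factor(as.character(pr),
                                                     levels = levels(y)),
                                      spec$final_metric))
        }
      }
      scores$score[i] <- mean(accs)
    }
    best <- scores[which.max(scores$score), ]
    list(mtry = best$mtry, scores = scores)
  }
}

fit_family <- function(x, y, spec, tuned) {
  if (spec$family == "elastic_net_multinomial") {
    lam <- sort(unique(c(tuned$lambda, tuned$lambda * c(2, 1.5, 0.75, 0.5))),
                decreasing = TRUE)  # small path around the chosen penalty for a stable fit
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = tuned$alpha,
                          lambda = lam)
    list(fit = fit, s = tuned$lambda)
  } else {
    list(fit = randomForest::randomForest(x, y, ntree = spec$ntree,
                                          mtry = tuned$mtry))
  }
}

predict_family <- function(model, spec, xnew, levels) {
  if (spec$family == "elastic_net_multinomial") {
    pr <- predict(model$fit, xnew, s = model$s, type = "response")[, , 1]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
  } else {
    pr <- stats::predict(model$fit, xnew, type = "prob")
  }
  out <- matrix(0, nrow(pr), length(levels), dimnames = list(rownames(xnew), levels))
  out[, colnames(pr)] <- pr
  out / rowSums(out)
}

prepare_xy <- function(markers, classes) {
  markers <- as_marker_matrix(markers)
  if (anyNA(markers)) stop("marker matrix must be complete; run impute_markers() first")
  if (inherits(classes, "msi_result") || is.data.frame(classes)) {
    if (!all(c("genotype", "yield_class") %in% names(classes)))
      stop("`classes` must have genotype and yield_class columns")
    y <- stats::setNames(as.character(classes$yield_class), classes$genotype)
  } else if (!is.null(names(classes))) {
    y <- stats::setNames(as.character(classes), names(classes))
  } else stop("`classes` must be an msi_result, a data.frame or a named vector")
  missing_g <- setdiff(names(y), rownames(markers))
  if (length(missing_g))
    stop("classes refer to genotypes without markers: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  x <- unclass(markers)[names(y), , drop = FALSE]
  storage.mode(x) <- "double"
  y <- factor(y, levels = yield_class_levels())
  present <- table(y)
  if (sum(present > 0) < 2) stop("need at least two yield classes to train")
  if (any(present > 0 & present < 2))
    stop("each non-empty class needs at least 2 genotypes; too few in: ",
         paste(names(present)[present > 0 & present < 2], collapse = ", "))
  list(x = x, y = droplevels(y), levels_full = yield_class_levels())
}

#' Repeated stratified cross-validation of a genomic classifier
#'
#' Runs the full evaluation protocol of [cv_protocol()] for one model family
#' and pools the out-of-fold predictions. Within each repetition the held-out
#' 20% is never touched during tuning; a repetition whose training split
#' lacks one of the classes is rejected and redrawn (logged).
#'
#' @param markers complete [marker_matrix()] (the classifier's feature space).
#' @param classes an `msi_result` (or data.frame/named vector) giving the
#'   yield class of every genotype to use; checks, which have no marker data,
#'   are typically excluded upstream.
#' @param spec a [model_spec()].
#' @param protocol a [cv_protocol()].
#' @return a `cv_predictions` data.frame with columns `genotype_id`,
#'   `repetition`, `true_class`, `predicted_class`, `p_low`, `p_moderate`,
#'   `p_high`. Attributes: `model_card` (family, per-repetition chosen
#'   hyperparameters, seed, grid) and `log` (resampled repetitions).
#' @export
run_repeated_cv <- function(markers, classes, spec = model_spec(),
                            protocol = cv_protocol()) {
  d <- prepare_xy(markers, classes)
  x <- d$x; y <- d$y
  set.seed(protocol$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, protocol$outer_reps)
  res <- vector("list", protocol$outer_reps)
  cards <- vector("list", protocol$outer_reps)
  log <- character(0)
  for (r in seq_len(protocol$outer_reps)) {
    set.seed(rep_seeds[r])
    for (try in 1:100) {
      test_idx <- stratified_test_idx(y, protocol$outer_test_fraction,
                                      protocol$stratified)
      if (all(levels(y) %in% y[-test_idx])) break
      log <- c(log, sprintf("repetition %d: class missing from training split; resampled", r))
    }
    if (!all(levels(y) %in% y[-test_idx]))
      stop("could not draw a training split containing every class")
    xtr <- x[-test_idx, , drop = FALSE]; ytr <- y[-test_idx]
    xte <- x[test_idx, , drop = FALSE]
    tuned <- tune_model(xtr, ytr, spec, protocol)
    model <- fit_family(xtr, ytr, spec, tuned)
    prob <- predict_family(model, spec, xte, d$levels_full)
    pred <- d$levels_full[max.col(prob, ties.method = "first")]
    res[[r]] <- data.frame(
      genotype_id = rownames(x)[test_idx], repetition = r,
      true_class = as.character(y[test_idx]), predicted_class = pred,
      p_low = prob[, "low"], p_moderate = prob[, "moderate"],
      p_high = prob[, "high"], stringsAsFactors = FALSE, row.names = NULL)
    cards[[r]] <- tuned[setdiff(names(tuned), "scores")]
  }
  out <- do.call(rbind, res)
  out$true_class <- factor(out$true_class, levels = d$levels_full)
  out$predicted_class <- factor(out$predicted_class, levels = d$levels_full)
  structure(out,
            model_card = list(family = spec$family, final_metric = spec$final_metric,
                              seed = protocol$seed, chosen = cards,
                              protocol = unclass(protocol)),
            log = log,
            class = c("cv_predictions", "data.frame"))
}

#' @export
print.cv_predictions <- function(x, ...) {
  card <- attr(x, "model_card")
  cat(sprintf("cv_predictions: %d pooled out-of-fold predictions (%s, %d repetitions)\n",
              nrow(x), card$family, length(card$chosen)))
  cat(sprintf("  pooled accuracy %.3f\n", mean(x$true_class == x$predicted_class)))
  invisible(x)
}

#' Write pooled cross-validation predictions as CSV
#' @param preds a `cv_predictions`.
#' @param path output file.
#' @export
write_cv_csv <- function(preds, path) {
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE)
  invisible(path)
}

#' Train the deployment classifier on all data
#'
#' Tunes hyperparameters by the protocol's inner cross-validation on the full
#' data set, refits, and returns a predictor of class probabilities for new
#' genotypes (the pre-screening use: score candidates before any field
#' testing).
#'
#' @inheritParams run_repeated_cv
#' @return a `yieldclass_model`; use `predict()` on a new [marker_matrix()]
#'   with the same marker set to obtain class probabilities and labels.
#' @export
train_final_model <- function(markers, classes, spec = model_spec(),
                              protocol = cv_protocol()) {
  d <- prepare_xy(markers, classes)
  set.seed(protocol$seed)
  tuned <- tune_model(d$x, d$y, spec, protocol)
  model <- fit_family(d$x, d$y, spec, tuned)
  structure(list(family = spec$family, spec = spec, model = model,
                 tuned = tuned[setdiff(names(tuned), "scores")],
                 marker_ids = colnames(d$x), levels = d$levels_full,
                 seed = protocol$seed),
            class = "yieldclass_model")
}

#' @export
print.yieldclass_model <- function(x, ...) {
  cat(sprintf("yieldclass_model: %s on %d markers\n", x$family, length(x$marker_ids)))
  cat("  tuned: ", paste(names(x$tuned), vapply(x$tuned, function(v)
    paste(signif(unlist(v), 4), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @rdname train_final_model
#' @param object a `yieldclass_model`.
#' @param newdata a complete [marker_matrix()] whose marker IDs match the
#'   training set (mismatches are an error listing the offending IDs).
#' @param ... unused.
#' @export
predict.yieldclass_model <- function(object, newdata, ...) {
  newdata <- as_marker_matrix(newdata)
  if (anyNA(newdata)) stop("new marker data must be complete")
  miss <- setdiff(object$marker_ids, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$marker_ids)
  if (length(miss) || length(extra))
    stop("marker set mismatch; missing: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "",
         "; unexpected: ", paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) sprintf(" (+%d more)", length(extra) - 5) else "")
  xnew <- unclass(newdata)[, object$marker_ids, drop = FALSE]
  storage.mode(xnew) <- "double"
  prob <- predict_family(object$model, object$spec, xnew, object$levels)
  data.frame(genotype_id = rownames(xnew),
             predicted_class = factor(object$levels[max.col(prob, ties.method = "first")],
                                      levels = object$levels),
             p_low = prob[, "low"], p_moderate = prob[, "moderate"],
             p_high = prob[, "high"], stringsAsFactors = FALSE, row.names = NULL)
}
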