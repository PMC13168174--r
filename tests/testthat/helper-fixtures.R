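# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small trial campaign: 60 lines from 12 families + 3 checks, 4 locations x
# 2 years, moderate sparsity
small_config <- function(seed = 101, ...) {
  args <- list(n_families = 12, lines_per_family = 5, n_checks = 3,
               n_markers = 120, n_locations = 4, n_years = 2,
               lambda_loadings = c(180, 60, 130, 100),
               psi_diag = c(7000, 10000, 8000, 9000),
               location_effects = c(-250, 100, 0, 150),
               ly_effects = matrix(c(-120, 80, 150, -60, 50, -100, 90, 40), 4, 2),
               sparsity = matrix(0.75, 4, 2),
               missing_rate = 0, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_sim <- function() memo("small_sim", {
  cfg <- small_config()
  mk <- simulate_markers(cfg)
  list(cfg = cfg, markers = mk, trials = simulate_trials(mk, cfg))
})

# a fitted FA1 model plus downstream objects, reused across test files
small_fit <- function() memo("small_fit", {
  s <- small_sim()
  pheno <- s$trials$pheno
  lines <- !pheno$is_check
  grm <- compute_grm(s$markers[!attr(s$markers, "is_check"), ])
  fit <- suppressWarnings(
    fa1_gblup(pheno[lines, ], grm, fa1_control(max_iter = 40, tol = 1e-5)))
  gblups <- predict(fit)
  checkref <- suppressWarnings(
    fit_check_model(pheno[!lines, ], fa1_control(max_iter = 40, tol = 1e-5)))
  mg <- tapply(pheno$maturity_group, pheno$genotype, function(m) m[1])
  mg_map <- stats::setNames(as.vector(mg), names(mg))
  msi <- compute_msi(gblups, checkref, mg_map)
  list(sim = s, grm = grm, fit = fit, gblups = gblups, checkref = checkref,
       mg_map = mg_map, msi = msi)
})

# random pooled-prediction set with probabilities consistent with the labels
random_preds <- function(n, seed) {
  set.seed(seed)
  lv <- yield_class_levels()
  p <- matrix(stats::rexp(3 * n), n, 3)
  p <- p / rowSums(p)
  colnames(p) <- c("p_low", "p_moderate", "p_high")
  data.frame(genotype_id = paste0("G", seq_len(n)), repetition = 1L,
             true_class = factor(sample(lv, n, TRUE), levels = lv),
             predicted_class = factor(lv[max.col(p)], levels = lv),
             p, stringsAsFactors = FALSE)
}

# brute-force enumeration oracle: recompute metrics by expanding a confusion
# matrix into individual records and counting
enumerate_metrics <- function(cm, focal) {
  lv <- yield_class_levels()
  recs <- do.call(rbind, lapply(lv, function(t) do.call(rbind, lapply(lv, function(p)
    if (cm[t, p] > 0) data.frame(true = rep(t, cm[t, p]), pred = p)))))
  pos_t <- recs$true == focal; pos_p <- recs$pred == focal
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  c(tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    precision = tp / (tp + fp), npv = tn / (tn + fn),
    accuracy = mean(recs$true == recs$pred))
}

# a deterministic confusion matrix from one-vs-rest counts placed in two cells
cm_from_counts <- function(tp, fn, fp, tn, focal = "low", other = "moderate") {
  lv <- yield_class_levels()
  m <- matrix(0L, 3, 3, dimnames = list(true = lv, predicted = lv))
  m[focal, focal] <- tp
  m[focal, other] <- fn
  m[other, focal] <- fp
  m[other, other] <- tn
  structure(as.table(m), class = c("confusion3", "table"))
}
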