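test_that("single-location GBLUPs equal the closed-form ridge solution", {
  set.seed(42)
  n <- 40; m <- 100; r <- 2
  mk <- marker_matrix(matrix(sample(0:2, n * m, TRUE), n, m))
  G <- compute_grm(mk)
  sg <- 2; se <- 3
  u <- sqrt(sg) * as.numeric(crossprod(chol(unclass(G) + diag(1e-8, n)), rnorm(n)))
  ph <- data.frame(genotype = rep(rownames(mk), each = r), location = "locA",
                   yield = 10 + rep(u, each = r) + rnorm(n * r, 0, sqrt(se)))
  fit <- fa1_gblup(ph, G, fa1_control(fix = list(sigma2_g = sg, sigma2_e = se)))

  ybar <- tapply(ph$yield, ph$genotype, mean)[rownames(mk)]
  Gm <- unclass(G) + diag(1e-8 * mean(diag(G)), n)  # same ridge as the solver
  Vi <- solve(sg * Gm + diag(se / r, n))
  mu_gls <- sum(Vi %*% ybar) / sum(Vi)
  u_oracle <- as.numeric(sg * Gm %*% Vi %*% (ybar - mu_gls))
  expect_lt(max(abs(fit$u_hat - u_oracle)), 1e-7)
  expect_equal(fit$mu, mu_gls, tolerance = 1e-10)
})

test_that("the REML log-likelihood matches a direct dense-V evaluation", {
  s <- small_fit()
  fit <- s$fit
  # rebuild V = Z Gbar Z' + se2 W^-1 on the aggregated records and evaluate
  # the REML likelihood directly
  dat <- fit$data
  gids <- fit$genotype_ids
  locs <- fit$locations
  Gm <- unclass(s$grm)[gids, gids]
  Gm <- Gm + diag(1e-8 * mean(diag(Gm)), nrow(Gm))
  SigL <- fit$sigma2_g + tcrossprod(fit$loadings) + diag(fit$psi, length(locs))
  Gbar <- kronecker(SigL, Gm)
  cell <- (match(dat$location, locs) - 1L) * length(gids) + match(dat$genotype, gids)
  Zc <- matrix(0, nrow(dat), length(gids) * length(locs))
  Zc[cbind(seq_len(nrow(dat)), cell)] <- 1
  V <- Zc %*% Gbar %*% t(Zc) + diag(fit$sigma2_e / dat$weight)
  X <- stats::model.matrix(~ 0 + env, data = dat)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  y <- dat$yield
  ll_direct <- -0.5 * ((nrow(dat) - ncol(X)) * log(2 * pi) +
                         determinant(V)$modulus + determinant(XtViX)$modulus +
                         as.numeric(t(y) %*% P %*% y))
  expect_equal(fit$loglik, as.numeric(ll_direct), tolerance = 1e-4)
})

test_that("the REML log-likelihood is monotone over accepted iterations", {
  s <- small_fit()
  expect_true(all(diff(s$fit$loglik_trace) > -1e-6 * abs(s$fit$loglik)))
  # estimated genetic covariance is PSD by construction
  SigL <- s$fit$sigma2_g + tcrossprod(s$fit$loadings) + diag(s$fit$psi, 4)
  expect_gt(min(eigen(SigL, only.values = TRUE)$values), -1e-8)
  # sign anchor: first location loading non-negative
  expect_gte(s$fit$loadings[1], 0)
})

test_that("a constant phenotype yields zero variance components and zero GBLUPs", {
  set.seed(1)
  n <- 20
  mk <- marker_matrix(matrix(sample(0:2, n * 50, TRUE), n, 50))
  G <- compute_grm(mk)
  ph <- expand.grid(genotype = rownames(mk), location = c("A", "B"),
                    year = c("y1", "y2"), stringsAsFactors = FALSE)
  ph$yield <- 7
  fit <- fa1_gblup(ph, G)
  expect_lte(fit$sigma2_g, 1e-6)
  expect_lte(fit$sigma2_e, 1e-6)
  expect_true(all(fit$psi <= 1e-6))
  expect_true(all(abs(fit$u_hat) <= 1e-6))
  expect_true(all(abs(predict(fit, what = "genetic")) <= 1e-6))
  expect_equal(fit$mu, 7)
})

test_that("genotypes with identical markers get identical predictions", {
  set.seed(8)
  n <- 24; m <- 80
  codes <- matrix(sample(0:2, n * m, TRUE), n, m)
  codes[n, ] <- codes[1, ]  # duplicate genotype
  mk <- marker_matrix(codes)
  G <- compute_grm(mk)
  locs <- c("A", "B", "C")
  ph <- expand.grid(genotype = rownames(mk), location = locs,
                    stringsAsFactors = FALSE)
  # genotype n is unobserved in location C; its duplicate is observed
  ph <- ph[!(ph$genotype == rownames(mk)[n] & ph$location == "C"), ]
  set.seed(9)
  ph$yield <- 100 + rnorm(nrow(ph), 0, 2)
  # identical marker rows -> identical true effects
  ph$yield[ph$genotype == rownames(mk)[n]] <-
    ph$yield[ph$genotype == rownames(mk)[1] & ph$location != "C"]
  fit <- suppressWarnings(fa1_gblup(ph, G, fa1_control(max_iter = 30)))
  pred <- predict(fit, what = "genetic")
  expect_equal(pred[n, ], pred[1, ], tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("predictions are invariant to genotype relabeling", {
  s <- small_fit()
  fit1 <- s$fit
  pheno <- s$sim$trials$pheno
  lines <- pheno[!pheno$is_check, ]
  perm <- sample(nrow(s$grm))
  grm_p <- unclass(s$grm)[perm, perm]
  grm_p <- structure(grm_p, denom = attr(s$grm, "denom"),
                     class = c("grm", "matrix", "array"))
  fit2 <- suppressWarnings(fa1_gblup(lines, grm_p, fa1_control(max_iter = 40, tol = 1e-5)))
  p1 <- predict(fit1); p2 <- predict(fit2)
  expect_equal(p2[rownames(p1), colnames(p1)], unclass(p1)[, ],
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("with Lambda = Psi = 0 the model equals an independent main-effects GBLUP", {
  set.seed(21)
  n <- 30
  mk <- marker_matrix(matrix(sample(0:2, n * 60, TRUE), n, 60))
  G <- compute_grm(mk)
  u <- as.numeric(crossprod(chol(unclass(G) + diag(1e-8, n)), rnorm(n)))
  ph <- expand.grid(genotype = rownames(mk), location = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  ph$yield <- 50 + 2 * u[match(ph$genotype, rownames(mk))] + rnorm(nrow(ph))
  sg <- 4; se <- 1
  main <- fa1_gblup(ph, G, fa1_control(gxl = FALSE,
                                       fix = list(sigma2_g = sg, sigma2_e = se)))

  # independent dense-GLS oracle for the main-effects-only genomic model
  Gt <- unclass(G) + diag(1e-8 * mean(diag(G)), n)  # same numerical bend
  Zu <- matrix(0, nrow(ph), n)
  Zu[cbind(seq_len(nrow(ph)), match(ph$genotype, rownames(mk)))] <- 1
  X <- stats::model.matrix(~ 0 + location, data = ph)
  V <- sg * Zu %*% Gt %*% t(Zu) + diag(se, nrow(ph))
  Vi <- solve(V)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph$yield)
  u_oracle <- as.numeric(sg * Gt %*% t(Zu) %*% Vi %*% (ph$yield - X %*% bh))
  expect_lt(max(abs(main$u_hat - u_oracle)), 1e-6)

  # the FA1 parameterization approaches the same fit as Lambda, Psi -> 0
  lim <- fa1_gblup(ph, G, fa1_control(
    fix = list(lambda = 0, psi = sg * 1e-5, sigma2_g = sg, sigma2_e = se)))
  expect_equal(unclass(predict(lim, what = "genetic")),
               unclass(predict(main, what = "genetic")), tolerance = 1e-2)
})

test_that("sparse-testing predictions beat per-environment means for unobserved cells", {
  s <- small_fit()
  truth <- s$sim$trials$truth
  gids <- s$fit$genotype_ids
  locs <- s$fit$locations
  envs <- s$fit$environments
  true_cell <- truth$true_u[gids] + truth$true_w[gids, match(envs$location, locs)]
  pred <- predict(s$fit, what = "genetic")
  msk <- attr(pred, "observed_mask")
  # unobserved cells only: model vs per-environment-mean baseline (genetic
  # part of the baseline is 0, so its error is the true value itself)
  r_model <- cor(pred[!msk], true_cell[!msk])
  expect_gt(r_model, 0.3)
  rmse_model <- sqrt(mean((pred[!msk] - true_cell[!msk])^2))
  rmse_base <- sqrt(mean(true_cell[!msk]^2))
  expect_lt(rmse_model, rmse_base)
})

test_that("unknown environments and disconnected designs are rejected", {
  s <- small_fit()
  expect_error(predict(s$fit, environments = "nowhere_y9"), "absent")
  ph <- data.frame(genotype = c("a", "a", "b", "b"),
                   location = c("L1", "L1", "L2", "L2"),
                   yield = rnorm(4))
  g <- identity_grm(c("a", "b"))
  expect_error(fa1_gblup(ph, g), "disconnected")
})

test_that("non-convergence is reported, never silent", {
  s <- small_sim()
  pheno <- s$trials$pheno
  grm <- compute_grm(s$markers[!attr(s$markers, "is_check"), ])
  expect_warning(fa1_gblup(pheno[!pheno$is_check, ], grm,
                           fa1_control(max_iter = 3)), "did not converge")
})

test_that("the random location-by-year switch fits and reports its variance", {
  s <- small_sim()
  pheno <- s$trials$pheno
  grm <- compute_grm(s$markers[!attr(s$markers, "is_check"), ])
  fit <- suppressWarnings(fa1_gblup(pheno[!pheno$is_check, ], grm,
                                    fa1_control(max_iter = 25, ly_random = TRUE)))
  expect_true(is.numeric(fit$sigma2_ly) && fit$sigma2_ly >= 0)
  expect_identical(names(fit$env_means), fit$environments$env)
})

test_that("the check model recovers known environment references", {
  s <- small_fit()
  chk <- s$sim$trials$pheno[s$sim$trials$pheno$is_check, ]
  ref <- s$checkref
  true_ref <- s$sim$trials$truth$check_reference_true
  got <- mapply(function(e, m) ref$check_mean[ref$env == e & ref$maturity_group == m],
                rep(rownames(true_ref), ncol(true_ref)),
                rep(colnames(true_ref), each = nrow(true_ref)))
  # mean absolute error within ~2 standard errors of a 3-check x 2-rep cell mean
  se_cell <- sqrt(s$sim$cfg$sigma2_e / (3 * 2))
  expect_lt(mean(abs(got - as.vector(true_ref))), 2 * se_cell)
})

test_that("degenerate check data are rejected with explanatory errors", {
  s <- small_sim()
  chk <- s$trials$pheno[s$trials$pheno$is_check, ]
  one <- chk[chk$genotype == chk$genotype[1], ]
  expect_error(fit_check_model(one), "two reference checks")
  # remove every record of one env x maturity-group cell
  cell <- chk$env == chk$env[1] & chk$maturity_group == chk$maturity_group[1]
  expect_error(fit_check_model(chk[!cell, ]), "maturity group")
})

test_that("noise-free constant checks give a constant reference", {
  ph <- expand.grid(genotype = c("c1", "c2", "c3"), location = c("A", "B"),
                    year = c("y1", "y2"), stringsAsFactors = FALSE)
  ph$maturity_group <- 4
  ph$yield <- 120
  ref <- fit_check_model(ph)
  expect_true(all(abs(ref$check_mean - 120) < 1e-8))
})
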