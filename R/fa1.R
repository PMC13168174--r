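#' Control options for the FA1 genomic mixed model
#'
#' @param tol relative REML log-likelihood change declaring convergence.
#' @param tol_par maximum relative parameter change declaring convergence.
#' @param max_iter maximum EM iterations.
#' @param gxl model the genotype-by-location term (FA1)? Defaults to `TRUE`
#'   when more than one location is present. With one location the model
#'   reduces to a main-effects genomic model (u only): the FA1 term is not
#'   separately identifiable there.
#' @param ly_random treat the location-by-year effect as random iid instead
#'   of fixed (documented switch; the default treats both location and
#'   location-by-year as fixed).
#' @param blues how plot-level records are reduced before fitting:
#'   `"means"` averages replicates within genotype x environment (the
#'   resulting record carries the replicate count as a residual weight), or
#'   `"none"` for data already supplied as one BLUE per genotype x
#'   environment.
#' @param fix optional named list fixing parameters instead of estimating
#'   them: any of `sigma2_g`, `lambda` (length-L vector), `psi` (length-L),
#'   `sigma2_e`.
#' @param psi_floor lower bound keeping the specific variances away from zero
#'   during estimation (needed for an invertible prior); estimates at the
#'   floor are clamped to 0 and flagged as boundary.
#' @param verbose print the EM trace.
#' @return a list of class `fa1_control`.
#' @export
fa1_control <- function(tol = 1e-6, tol_par = 1e-4, max_iter = 200,
                        gxl = NULL, ly_random = FALSE,
                        blues = c("means", "none"), fix = list(),
                        psi_floor = NULL, verbose = FALSE) {
  structure(list(tol = tol, tol_par = tol_par, max_iter = max_iter,
                 gxl = gxl, ly_random = ly_random, blues = match.arg(blues),
                 fix = fix, psi_floor = psi_floor, verbose = verbose),
            class = "fa1_control")
}

# connectedness of the genotype x environment design
check_connected <- function(gid, env) {
  envs <- unique(env)
  if (length(envs) < 2) return(invisible(TRUE))
  comp <- seq_along(envs)
  sets <- lapply(envs, function(e) unique(gid[env == e]))
  for (i in seq_along(envs)) for (j in seq_len(i - 1L)) {
    if (length(intersect(sets[[i]], sets[[j]]))) {
      old <- comp[i]; comp[comp == old] <- comp[j]
    }
  }
  if (length(unique(comp)) > 1)
    stop("trial design is disconnected: no genotypes shared between some environments")
  invisible(TRUE)
}

#' Fit the genomic FA1 multi-environment mixed model
#'
#' REML fit (via an EM algorithm on Henderson's mixed-model equations) of
#' \deqn{y_{lyg} = \mu + L_l + (L{:}Y)_{ly} + u_g + w_{lg} + \epsilon_{lyg}}
#' with \eqn{u \sim N(0, \sigma^2_g G)} and a factor-analytic
#' genotype-by-location term \eqn{w_{lg} = \lambda_l f_g + \delta_{lg}},
#' \eqn{w \sim N(0, (\Lambda\Lambda^\top + \Psi) \otimes G)}. Location and
#' location-by-year effects are fixed by default (see [fa1_control()]).
#'
#' Internally the genetic effects are handled per (genotype, location) cell,
#' \eqn{a_{lg} = u_g + w_{lg}}, whose prior covariance is
#' \eqn{\Sigma_L \otimes G} with
#' \eqn{\Sigma_L = \sigma^2_g \mathbf{1}\mathbf{1}^\top + \Lambda\Lambda^\top + \Psi}.
#' Each EM iteration solves the mixed-model equations once (one dense
#' Cholesky of order p + nL), updates \eqn{\Sigma_L} by maximising the
#' expected complete-data likelihood over \eqn{(\sigma^2_g, \Lambda, \Psi)}
#' (a small bounded quasi-Newton problem), and updates \eqn{\sigma^2_e} with
#' the standard EM-REML residual form. The REML log-likelihood is tracked and
#' is non-decreasing across accepted iterations; variance estimates that hit
#' their lower bound are clamped to zero and flagged. Loadings are
#' sign-anchored so the first location's loading is non-negative.
#'
#' @param pheno data.frame with columns `genotype`, `location`, `yield`, and
#'   (if more than one year) `year`; plot-level data may carry several rows
#'   per genotype x environment and are averaged according to
#'   `opts$blues`.
#' @param grm a `grm` covering every phenotyped genotype (see
#'   [compute_grm()], [identity_grm()]). Must be positive semi-definite to
#'   tolerance; a tiny ridge is added for numerical inversion.
#' @param opts a [fa1_control()].
#' @return an object of class `fa1_fit`; see the fields in the package
#'   vignette. Key components: `mu`, `location_effects`, `ly_effects`,
#'   `env_means`, `sigma2_g`, `loadings`, `psi`, `sigma2_e`, `u_hat`,
#'   `f_hat`, `delta_hat`, `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `boundary`.
#' @seealso [predict.fa1_fit()] for the complete genotype x environment
#'   GBLUP matrix, [fit_check_model()] for the no-GRM check model.
#' @export
fa1_gblup <- function(pheno, grm, opts = fa1_control()) {
  stopifnot(is.data.frame(pheno))
  need <- c("genotype", "location", "yield")
  if (!all(need %in% names(pheno)))
    stop("`pheno` must have columns genotype, location, yield")
  if (!"year" %in% names(pheno)) pheno$year <- "y1"
  if (anyNA(pheno$yield)) stop("missing yields are not allowed")
  gids <- rownames(grm)
  if (!all(pheno$genotype %in% gids))
    stop("phenotyped genotypes absent from the GRM: ",
         paste(utils::head(setdiff(pheno$genotype, gids), 5), collapse = ", "))
  pheno$env <- paste(pheno$location, pheno$year, sep = "_")
  check_connected(pheno$genotype, pheno$env)

  # reduce plot-level data to one record per genotype x environment
  if (is.null(opts$blues)) opts$blues <- "means"
  if (opts$blues == "means") {
    key <- paste(pheno$genotype, pheno$env, sep = "\r")
    agg_y <- tapply(pheno$yield, key, mean)
    w <- as.numeric(tapply(pheno$yield, key, length))
    first <- !duplicated(key)
    dat <- pheno[first, c("genotype", "location", "year", "env")]
    dat <- dat[match(names(agg_y), key[first]), ]
    dat$yield <- as.numeric(agg_y)
    dat$weight <- w
  } else {
    dat <- pheno[, c("genotype", "location", "year", "env", "yield")]
    dat$weight <- if ("weight" %in% names(pheno)) pheno$weight else 1
    if (anyDuplicated(paste(dat$genotype, dat$env)))
      stop("blues = \"none\" requires one record per genotype x environment")
  }

  locs <- sort(unique(dat$location))
  L <- length(locs)
  envs_df <- unique(dat[, c("env", "location", "year")])
  envs_df <- envs_df[order(envs_df$location, envs_df$year), ]
  E <- nrow(envs_df)
  ng <- length(gids)
  N <- nrow(dat)
  gxl <- if (is.null(opts$gxl)) L >= 2 else isTRUE(opts$gxl) && L >= 2

  gi <- match(dat$genotype, gids)
  li <- match(dat$location, locs)
  ei <- match(dat$env, envs_df$env)
  wt <- dat$weight
  y <- dat$yield

  # fixed design: environment cell means (mu + L + L:Y); or location means
  # when L:Y is random
  if (isTRUE(opts$ly_random) && E > L) {
    X <- matrix(0, N, L); X[cbind(seq_len(N), li)] <- 1
    colnames(X) <- locs
  } else {
    opts$ly_random <- FALSE
    X <- matrix(0, N, E); X[cbind(seq_len(N), ei)] <- 1
    colnames(X) <- envs_df$env
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular fixed-effect design")
  if (N <= p) stop("not enough records to estimate residual variance")

  # GRM: PSD check and ridge for inversion
  Gm <- unclass(grm)[gids, gids]
  evG <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  if (min(evG) < -1e-8 * max(abs(evG)))
    stop("GRM is not positive semi-definite beyond tolerance")
  ridge <- max(mean(diag(Gm)) * 1e-8, (1e-8 - min(evG)) * (min(evG) < 1e-8))
  Gb <- Gm + diag(ridge, ng)
  cholG <- chol(Gb)
  Ginv <- chol2inv(cholG)
  logdetG <- 2 * sum(log(diag(cholG)))

  # sufficient statistics that never change
  XtWX <- crossprod(X * wt, X)
  XtWy <- crossprod(X, wt * y)
  yWy <- sum(wt * y^2)
  # random-effect incidence: cell (l, g) index (location-major)
  q <- if (gxl) ng * L else ng
  cell <- if (gxl) (li - 1L) * ng + gi else gi
  ZtWZd <- numeric(q)
  tmp <- tapply(wt, cell, sum); ZtWZd[as.integer(names(tmp))] <- tmp
  ZtWX <- matrix(0, q, p)
  for (j in seq_len(p)) {
    tmp <- tapply(wt * X[, j], cell, sum)
    ZtWX[as.integer(names(tmp)), j] <- tmp
  }
  ZtWy <- numeric(q)
  tmp <- tapply(wt * y, cell, sum); ZtWy[as.integer(names(tmp))] <- tmp
  # optional random L:Y block
  B <- if (opts$ly_random) E else 0L
  if (B) {
    BtWBd <- as.numeric(tapply(wt, ei, sum))
    BtWX <- matrix(0, B, p)
    for (j in seq_len(p)) BtWX[, j] <- tapply(wt * X[, j], ei, sum)
    BtWy <- as.numeric(tapply(wt * y, ei, sum))
    BtWZ <- matrix(0, B, q)
    for (r in seq_len(N)) BtWZ[ei[r], cell[r]] <- BtWZ[ei[r], cell[r]] + wt[r]
  }

  # initial values
  fit0 <- stats::lm.wfit(X, y, wt)
  v0 <- sum(wt * fit0$residuals^2) / max(N - p, 1)
  if (v0 <= max(mean(y^2), 1) * 1e-12) {
    # no residual variation at all: every variance component is zero
    beta0 <- fit0$coefficients
    if (isTRUE(opts$ly_random)) {
      env_means <- stats::setNames(as.numeric(beta0[match(envs_df$location, locs)]),
                                   envs_df$env)
    } else env_means <- stats::setNames(as.numeric(beta0), envs_df$env)
    mu <- mean(env_means)
    loc_eff <- tapply(env_means, envs_df$location, mean) - mu
    ly_eff <- env_means - mu - as.numeric(loc_eff[envs_df$location])
    obs_mask <- matrix(FALSE, ng, E, dimnames = list(gids, envs_df$env))
    obs_mask[cbind(gi, ei)] <- TRUE
    zero <- stats::setNames(rep(0, ng), gids)
    return(structure(list(
      mu = mu, location_effects = stats::setNames(as.numeric(loc_eff), names(loc_eff)),
      ly_effects = stats::setNames(as.numeric(ly_eff), envs_df$env),
      env_means = env_means, sigma2_g = 0,
      loadings = stats::setNames(rep(0, L), locs),
      psi = stats::setNames(rep(0, L), locs), sigma2_e = 0, sigma2_ly = NULL,
      u_hat = zero, f_hat = zero,
      delta_hat = matrix(0, ng, L, dimnames = list(gids, locs)),
      a_hat = matrix(0, ng, L, dimnames = list(gids, locs)),
      loglik = NA_real_, loglik_trace = numeric(0), converged = TRUE, n_iter = 0L,
      boundary = c("sigma2_g", "psi", "sigma2_e"),
      genotype_ids = gids, locations = locs, environments = envs_df,
      observed = obs_mask, gxl = gxl,
      data = data.frame(dat, fitted = env_means[dat$env], residual = 0),
      n_records = N, call = match.call()), class = "fa1_fit"))
  }
  fx <- opts$fix
  sg2 <- if (!is.null(fx$sigma2_g)) fx$sigma2_g else 0.3 * v0
  lam <- if (!is.null(fx$lambda)) rep_len(fx$lambda, L) else rep(sqrt(0.1 * v0), L)
  psi <- if (!is.null(fx$psi)) rep_len(fx$psi, L) else rep(0.15 * v0, L)
  se2 <- if (!is.null(fx$sigma2_e)) fx$sigma2_e else 0.45 * v0
  s_ly <- 0.1 * v0
  psi_floor <- if (!is.null(opts$psi_floor)) opts$psi_floor else v0 * 1e-8
  sg_floor <- v0 * 1e-10
  if (!gxl) { lam <- rep(0, L); psi <- rep(0, L) }
  free_sigma_g <- is.null(fx$sigma2_g)
  free_lambda <- is.null(fx$lambda) && gxl
  free_psi <- is.null(fx$psi) && gxl
  free_se <- is.null(fx$sigma2_e)
  all_fixed <- !free_sigma_g && !free_lambda && !free_psi && !free_se && !B

  sigma_L <- function(sg2, lam, psi) {
    if (gxl) sg2 + tcrossprod(lam) + diag(psi, L) else matrix(sg2, 1, 1)
  }

  # th = c(sg2, lambda (L), psi (L), se2, [s_ly]): evaluate the MME at th.
  # need_inv = TRUE also returns the inverse needed for the EM trace terms.
  th_pack <- function(sg2, lam, psi, se2, s_ly)
    c(sg2, lam, psi, se2, if (B) s_ly)
  mme_eval <- function(th, need_inv = TRUE) {
    sg2 <- th[1]; lam <- th[2:(L + 1)]; psi <- th[(L + 2):(2 * L + 1)]
    se2 <- th[2 * L + 2]; s_ly <- if (B) th[2 * L + 3] else NA
    SigL <- sigma_L(sg2, if (gxl) lam else 0, if (gxl) pmax(psi, psi_floor) else 0)
    cholS <- tryCatch(chol(SigL), error = function(e) NULL)
    if (is.null(cholS)) {
      SigL <- SigL + diag(1e-8 * mean(diag(SigL)), nrow(SigL)); cholS <- chol(SigL)
    }
    Sinv <- chol2inv(cholS)
    logdetS <- 2 * sum(log(diag(cholS)))
    Gpri <- if (gxl) kronecker(Sinv, Ginv) else Ginv / sg2
    dim_all <- p + q + B
    M <- matrix(0, dim_all, dim_all)
    M[1:p, 1:p] <- XtWX
    M[p + 1:q, 1:p] <- ZtWX
    M[1:p, p + 1:q] <- t(ZtWX)
    M[p + 1:q, p + 1:q] <- se2 * Gpri
    diag(M)[p + 1:q] <- diag(M)[p + 1:q] + ZtWZd
    rhs <- c(XtWy, ZtWy)
    if (B) {
      ib <- p + q + 1:B
      M[ib, 1:p] <- BtWX; M[1:p, ib] <- t(BtWX)
      M[ib, p + 1:q] <- BtWZ; M[p + 1:q, ib] <- t(BtWZ)
      M[ib, ib] <- diag(se2 / s_ly, B)
      diag(M)[ib] <- diag(M)[ib] + BtWBd
      rhs <- c(rhs, BtWy)
    }
    cholM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cholM)) {
      diag(M) <- diag(M) * (1 + 1e-10) + max(diag(M)) * 1e-12; cholM <- chol(M)
    }
    Minv <- if (need_inv) chol2inv(cholM) else NULL
    sol <- if (need_inv) Minv %*% rhs else
      backsolve(cholM, backsolve(cholM, rhs, transpose = TRUE))
    beta <- sol[1:p]
    ahat <- sol[p + 1:q]
    bhat <- if (B) sol[p + q + 1:B] else numeric(0)
    yPy <- (yWy - sum(beta * XtWy) - sum(ahat * ZtWy) -
              (if (B) sum(bhat * BtWy) else 0)) / se2
    logdetGbar <- if (gxl) ng * logdetS + L * logdetG else ng * log(sg2) + logdetG
    if (B) logdetGbar <- logdetGbar + B * log(s_ly)
    logdetMt <- 2 * sum(log(diag(cholM))) - dim_all * log(se2)
    ll <- -0.5 * ((N - p) * log(2 * pi) + (N * log(se2) - sum(log(wt))) +
                    logdetGbar + logdetMt + yPy)
    list(ll = ll, beta = beta, ahat = ahat, bhat = bhat, yPy = yPy, Minv = Minv)
  }

  # one generalized-EM parameter update given the current solve
  em_update <- function(th, ev) {
    sg2 <- th[1]; lam <- th[2:(L + 1)]; psi <- th[(L + 2):(2 * L + 1)]
    se2 <- th[2 * L + 2]; s_ly <- if (B) th[2 * L + 3] else NA
    Minv <- ev$Minv
    if (gxl) {
      A <- matrix(ev$ahat, ng, L)
      GiA <- Ginv %*% A
      Tm <- matrix(0, L, L)
      for (l in seq_len(L)) for (m in l:L) {
        blk <- Minv[p + (m - 1L) * ng + 1:ng, p + (l - 1L) * ng + 1:ng]
        Tm[l, m] <- Tm[m, l] <- sum(Ginv * blk)
      }
      S <- crossprod(A, GiA) + se2 * Tm
      S <- (S + t(S)) / 2
      # M-step: minimise ng log|Sigma_L| + tr(Sigma_L^-1 S) over the free parameters
      th0 <- c(sg2, lam, psi)
      freem <- c(free_sigma_g, rep(free_lambda, L), rep(free_psi, L))
      obj <- function(thf) {
        tt <- th0; tt[freem] <- thf
        Sg <- sigma_L(tt[1], tt[2:(L + 1)], pmax(tt[(L + 2):(2 * L + 1)], psi_floor))
        ch <- tryCatch(chol(Sg), error = function(e) NULL)
        if (is.null(ch)) return(1e300)
        ng * 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S)
      }
      if (any(freem)) {
        lower <- c(sg_floor, rep(-Inf, L), rep(psi_floor, L))[freem]
        sc <- pmax(abs(th0), v0 * 1e-3)[freem]
        op <- stats::optim(th0[freem], obj, method = "L-BFGS-B", lower = lower,
                           control = list(maxit = 100, parscale = sc))
        tt <- th0; tt[freem] <- op$par
        sg2 <- tt[1]; lam <- tt[2:(L + 1)]; psi <- pmax(tt[(L + 2):(2 * L + 1)], psi_floor)
      }
    } else {
      Tuu <- sum(Ginv * Minv[p + 1:q, p + 1:q])
      Suu <- sum(ev$ahat * (Ginv %*% ev$ahat)) + se2 * Tuu
      if (free_sigma_g) sg2 <- max(Suu / ng, sg_floor)
    }
    if (B) {
      Cbb <- se2 * sum(diag(Minv)[p + q + 1:B])
      s_ly <- max((sum(ev$bhat^2) + Cbb) / B, v0 * 1e-10)
    }
    if (free_se) se2 <- max(ev$yPy * se2 / (N - p), v0 * 1e-12)
    th_pack(sg2, lam, psi, se2, s_ly)
  }

  # clip a parameter vector back into the feasible region
  th_clip <- function(th) {
    th[1] <- max(th[1], sg_floor)
    th[(L + 2):(2 * L + 1)] <- pmax(th[(L + 2):(2 * L + 1)], psi_floor)
    th[2 * L + 2] <- max(th[2 * L + 2], v0 * 1e-12)
    if (B) th[2 * L + 3] <- max(th[2 * L + 3], v0 * 1e-10)
    th
  }

  th <- th_pack(sg2, lam, psi, se2, s_ly)
  loglik_trace <- numeric(0)
  conv <- FALSE
  iter <- 0L
  th_prev <- NULL
  ev <- NULL
  repeat {
    iter <- iter + 1L
    ev <- mme_eval(th, need_inv = !all_fixed)
    ll <- ev$ll
    loglik_trace <- c(loglik_trace, ll)
    if (opts$verbose)
      cat(sprintf("iter %3d  logLik %.6f  sg2 %.4g  se2 %.4g\n",
                  iter, ll, th[1], th[2 * L + 2]))
    if (all_fixed) { conv <- TRUE; break }

    th_em <- em_update(th, ev)
    rel_par <- max(abs(th_em - th) / (abs(th) + v0 * 1e-6))
    rel_ll <- if (iter > 1) abs(ll - loglik_trace[iter - 1]) / (abs(ll) + 1) else Inf
    if (iter > 1 && rel_ll < opts$tol && rel_par < opts$tol_par) {
      th <- th_em; conv <- TRUE; break
    }
    if (iter >= opts$max_iter) { th <- th_em; break }

    # accelerated step: extrapolate along the EM direction, keep it only if
    # it improves the REML log-likelihood (trace stays monotone)
    th_next <- th_em
    if (!is.null(th_prev)) {
      th_ex <- th_clip(th_em + 3 * (th_em - th))
      if (any(th_ex != th_em)) {
        ll_ex <- mme_eval(th_ex, need_inv = FALSE)$ll
        if (is.finite(ll_ex) && ll_ex > ll) th_next <- th_ex
      }
    }
    th_prev <- th
    th <- th_next
  }
  sg2 <- th[1]; lam <- th[2:(L + 1)]; psi <- th[(L + 2):(2 * L + 1)]
  se2 <- th[2 * L + 2]; if (B) s_ly <- th[2 * L + 3]
  if (!all_fixed) {
    # refresh the solution at the final parameter values so BLUPs, fixed
    # effects and the reported log-likelihood are mutually consistent
    ev <- mme_eval(th, need_inv = FALSE)
    loglik_trace <- c(loglik_trace, ev$ll)
  }
  beta <- ev$beta; ahat <- ev$ahat; bhat <- ev$bhat
  if (!conv && !all_fixed)
    warning(sprintf("EM-REML did not converge in %d iterations (last logLik change %.2e)",
                    iter, if (iter > 1) abs(diff(utils::tail(loglik_trace, 2))) else NA))

  # boundary clamping and sign anchoring
  boundary <- character(0)
  if (gxl) {
    clamped <- psi <= psi_floor * 1.0001
    if (any(clamped)) { psi[clamped] <- 0; boundary <- c(boundary, paste0("psi_", locs[clamped])) }
    nz <- which(abs(lam) > sqrt(v0) * 1e-8)
    if (length(nz) && lam[nz[1]] < 0) lam <- -lam
  }
  if (sg2 <= sg_floor * 1.0001) { sg2 <- 0; boundary <- c(boundary, "sigma2_g") }

  # decompose cell effects into u, f, delta
  if (gxl) {
    SigL <- sigma_L(sg2, lam, psi)
    SigL <- SigL + diag(1e-10 * max(mean(diag(SigL)), 1), L)
    Sinv <- solve(SigL)
    A <- matrix(ahat, ng, L, dimnames = list(gids, locs))
    u_hat <- as.numeric(sg2 * A %*% (Sinv %*% rep(1, L)))
    f_hat <- as.numeric(A %*% (Sinv %*% lam))
    delta_hat <- A - outer(u_hat, rep(1, L)) - outer(f_hat, lam)
  } else {
    u_hat <- ahat
    f_hat <- rep(0, ng)
    delta_hat <- matrix(0, ng, L, dimnames = list(gids, locs))
    A <- matrix(u_hat, ng, L, dimnames = list(gids, locs))
  }
  names(u_hat) <- names(f_hat) <- gids

  # fixed-effect decomposition into mu, L, L:Y on the environment grid
  if (opts$ly_random) {
    loc_means <- stats::setNames(beta, locs)
    env_means <- stats::setNames(as.numeric(loc_means[envs_df$location] + bhat),
                                 envs_df$env)
  } else {
    env_means <- stats::setNames(beta, envs_df$env)
  }
  mu <- mean(env_means)
  loc_eff <- tapply(env_means, envs_df$location, mean) - mu
  ly_eff <- env_means - mu - as.numeric(loc_eff[envs_df$location])

  # observation mask and residuals on the fitted records
  obs_mask <- matrix(FALSE, ng, E, dimnames = list(gids, envs_df$env))
  obs_mask[cbind(gi, ei)] <- TRUE
  fitted_rec <- env_means[dat$env] + A[cbind(gi, li)]
  resid_rec <- y - fitted_rec

  structure(list(
    mu = mu, location_effects = stats::setNames(as.numeric(loc_eff), names(loc_eff)),
    ly_effects = stats::setNames(as.numeric(ly_eff), envs_df$env),
    env_means = env_means,
    sigma2_g = sg2, loadings = stats::setNames(lam, locs),
    psi = stats::setNames(psi, locs), sigma2_e = se2,
    sigma2_ly = if (B) s_ly else NULL,
    u_hat = u_hat, f_hat = f_hat, delta_hat = delta_hat, a_hat = A,
    loglik = loglik_trace[length(loglik_trace)], loglik_trace = loglik_trace,
    converged = conv, n_iter = iter, boundary = boundary,
    genotype_ids = gids, locations = locs, environments = envs_df,
    observed = obs_mask, gxl = gxl,
    data = data.frame(dat, fitted = fitted_rec, residual = resid_rec),
    n_records = N, call = match.call()),
    class = "fa1_fit")
}

#' @export
print.fa1_fit <- function(x, ...) {
  cat("Genomic FA1 multi-environment mixed model (EM-REML)\n")
  cat(sprintf("  %d genotypes, %d locations, %d environments, %d records\n",
              length(x$genotype_ids), length(x$locations),
              nrow(x$environments), x$n_records))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g\n", x$sigma2_g, x$sigma2_e))
  if (x$gxl) {
    cat("  loadings: ", paste(sprintf("%.3g", x$loadings), collapse = ", "), "\n")
    cat("  psi:      ", paste(sprintf("%.3g", x$psi), collapse = ", "), "\n")
  }
  cat(sprintf("  logLik %.3f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$boundary))
    cat("  boundary estimates:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fa1_fit <- function(object, ...) {
  vc <- data.frame(
    component = c("sigma2_g", paste0("lambda[", names(object$loadings), "]"),
                  paste0("psi[", names(object$psi), "]"), "sigma2_e"),
    estimate = c(object$sigma2_g, object$loadings, object$psi, object$sigma2_e),
    row.names = NULL)
  gcov <- object$sigma2_g + tcrossprod(object$loadings) + diag(object$psi, length(object$psi))
  structure(list(fit = object, varcomp = vc,
                 genetic_covariance = gcov,
                 env_means = object$env_means), class = "summary.fa1_fit")
}

#' @export
print.summary.fa1_fit <- function(x, ...) {
  print(x$fit)
  cat("\nVariance components:\n")
  print(x$varcomp, digits = 4)
  cat("\nEnvironment means (mu + L + L:Y):\n")
  print(round(x$env_means, 2))
  invisible(x)
}

#' @export
coef.fa1_fit <- function(object, ...) object$env_means

#' @export
logLik.fa1_fit <- function(object, ...) {
  npar <- 2 + if (object$gxl) 2 * length(object$locations) else 0
  structure(object$loglik, df = npar, class = "logLik")
}

#' @export
residuals.fa1_fit <- function(object, ...) object$data$residual

#' @export
fitted.fa1_fit <- function(object, ...) object$data$fitted

#' @export
plot.fa1_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$loglik_trace, type = "b", xlab = "EM iteration",
       ylab = "REML log-likelihood", main = "Convergence", ...)
  graphics::barplot(x$loadings, main = "FA1 loadings", ylab = expression(lambda[l]),
                    las = 2)
  invisible(x)
}

#' Predict the complete genotype-by-environment GBLUP matrix
#'
#' Returns model predictions for every genotype in every environment of the
#' fit, including combinations never observed (information is borrowed
#' through the genomic relationship matrix and the FA1 loadings). On the
#' default `"yield"` scale a cell is
#' \eqn{\hat\mu_e + \hat u_g + \hat\lambda_l \hat f_g + \hat\delta_{lg}}
#' (environment mean plus genetic effect), the scale on which the
#' check-referenced selection index is defined; `"genetic"` drops the fixed
#' environment mean.
#'
#' @param object an [fa1_gblup()] fit.
#' @param environments environments to predict (default: all in the fit);
#'   unknown environments are an error.
#' @param what `"yield"` or `"genetic"`.
#' @param ... unused.
#' @return a `gblup_matrix`: genotypes x environments numeric matrix with an
#'   `observed_mask` attribute marking cells that had data.
#' @export
predict.fa1_fit <- function(object, environments = NULL, what = c("yield", "genetic"), ...) {
  what <- match.arg(what)
  envs_df <- object$environments
  if (is.null(environments)) environments <- envs_df$env
  unknown <- setdiff(environments, envs_df$env)
  if (length(unknown))
    stop("environments absent from the fit: ", paste(unknown, collapse = ", "))
  sel <- match(environments, envs_df$env)
  li <- match(envs_df$location[sel], object$locations)
  gen <- object$a_hat[, li, drop = FALSE]
  vals <- if (what == "yield") sweep(gen, 2, object$env_means[environments], `+`) else gen
  colnames(vals) <- environments
  gblup_matrix(vals, observed_mask = object$observed[, environments, drop = FALSE])
}

#' Construct a GBLUP matrix
#'
#' @param values genotypes x environments numeric matrix (complete, no
#'   missing cells) with IDs as dimnames.
#' @param observed_mask optional logical matrix of the same shape marking
#'   cells with phenotype records.
#' @return an object of class `gblup_matrix`.
#' @export
gblup_matrix <- function(values, observed_mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values)) stop("GBLUP matrix must be complete (no missing cells)")
  if (is.null(rownames(values))) rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("env", seq_len(ncol(values)))
  if (is.null(observed_mask)) {
    observed_mask <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    stopifnot(identical(dim(observed_mask), dim(values)))
    dimnames(observed_mask) <- dimnames(values)
  }
  structure(values, observed_mask = observed_mask,
            class = c("gblup_matrix", "matrix", "array"))
}

#' @export
print.gblup_matrix <- function(x, ...) {
  msk <- attr(x, "observed_mask")
  cat(sprintf("gblup_matrix: %d genotypes x %d environments (%.1f%% cells observed)\n",
              nrow(x), ncol(x), 100 * mean(msk)))
  invisible(x)
}

#' Write a GBLUP matrix (values + observation mask) as CSV
#' @param gblups a `gblup_matrix`.
#' @param path values CSV path; the mask is written next to it with suffix
#'   `_mask.csv`.
#' @export
write_gblups_csv <- function(gblups, path) {
  df <- data.frame(genotype = rownames(gblups), unclass(gblups), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  msk <- attr(gblups, "observed_mask")
  mdf <- data.frame(genotype = rownames(gblups), msk * 1L, check.names = FALSE)
  utils::write.csv(mdf, sub("\\.csv$", "_mask.csv", path), row.names = FALSE)
  invisible(path)
}

#' Fit the reference-check model and build the check reference
#'
#' Checks carry no marker data, so they are analysed separately with the same
#' FA1 mixed model but an identity relationship matrix in place of the GRM.
#' The check reference is the per-environment, per-maturity-group mean of the
#' checks' predicted yields, the denominator of the selection index.
#'
#' @param pheno_checks plot-level or BLUE-level records for the checks only;
#'   must include a `maturity_group` column.
#' @param opts a [fa1_control()].
#' @return a `check_reference` (see [check_reference()]) with the underlying
#'   `fa1_fit` in attribute `fit`.
#' @export
fit_check_model <- function(pheno_checks, opts = fa1_control()) {
  stopifnot(is.data.frame(pheno_checks))
  if (!"maturity_group" %in% names(pheno_checks))
    stop("`pheno_checks` needs a maturity_group column")
  ids <- unique(pheno_checks$genotype)
  if (length(ids) < 2)
    stop("at least two reference checks are required; the check model cannot ",
         "separate genotype from residual variation with a single check")
  if (!"year" %in% names(pheno_checks)) pheno_checks$year <- "y1"
  env <- paste(pheno_checks$location, pheno_checks$year, sep = "_")
  mgs <- sort(unique(pheno_checks$maturity_group))
  cells <- table(env = env, mg = pheno_checks$maturity_group)
  empty <- which(cells == 0, arr.ind = TRUE)
  if (nrow(empty))
    stop("no check records for environment x maturity group cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = "; "))
  fit <- fa1_gblup(pheno_checks, identity_grm(ids), opts)
  pred <- predict(fit, what = "yield")
  mg_of <- tapply(pheno_checks$maturity_group, pheno_checks$genotype, function(m) m[1])
  out <- expand.grid(env = colnames(pred), maturity_group = mgs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$check_mean <- mapply(function(e, m) {
    mean(pred[names(mg_of)[mg_of == m], e])
  }, out$env, out$maturity_group)
  ref <- check_reference(out)
  attr(ref, "fit") <- fit
  ref
}

#' Construct a check reference
#'
#' The per-environment, per-maturity-group mean yield of the reference
#' checks, used as the denominator of the selection index.
#'
#' @param df data.frame with columns `env`, `maturity_group`, `check_mean`.
#' @return an object of class `check_reference`.
#' @export
check_reference <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("env", "maturity_group", "check_mean") %in% names(df)))
  if (anyDuplicated(paste(df$env, df$maturity_group)))
    stop("duplicate environment x maturity group rows")
  df$env <- as.character(df$env)
  structure(df, class = c("check_reference", "data.frame"))
}

#' @export
print.check_reference <- function(x, ...) {
  cat(sprintf("check_reference: %d environments x %d maturity groups\n",
              length(unique(x$env)), length(unique(x$maturity_group))))
  print.data.frame(utils::head(as.data.frame(x), 12))
  invisible(x)
}
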