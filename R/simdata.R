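#' Configuration for the synthetic breeding-trial generator
#'
#' Defines the population, marker panel, multi-environment trial design and
#' variance structure used by [simulate_markers()] and [simulate_trials()].
#' Defaults emulate a soybean preliminary-yield-trial campaign: ~1,720
#' breeding lines from 172 bi-parental families plus 9 reference checks,
#' ~2,479 post-QC SNPs, and 10 environments (5 locations x 2 years) under
#' sparse testing, with yields generated from
#' \deqn{y_{lyg} = \mu + L_l + (L{:}Y)_{ly} + u_g + w_{lg} + \epsilon_{lyg},}
#' where \eqn{u \sim N(0, \sigma^2_g G)} and the genotype-by-location term
#' follows a factor-analytic structure of order 1,
#' \eqn{w \sim N(0, (\Lambda\Lambda^\top + \Psi) \otimes G)} for the marker
#' lines (checks, which carry no marker data, receive independent latent
#' values with the same marginal variances).
#'
#' Default variance magnitudes are in kg/ha on a ~4,000 kg/ha crop and were
#' chosen so the induced check-referenced selection index is centred near -12
#' with an SD near 7 percentage points, giving roughly a 17/50/33 split of
#' high/moderate/low yield classes under the -5/-15 thresholds. The default
#' per-environment observation probabilities mirror the uneven observed/
#' unobserved pattern of a sparse early-stage campaign.
#'
#' @param n_families number of bi-parental families.
#' @param lines_per_family inbred lines derived per family.
#' @param n_checks number of reference checks (observed in every environment,
#'   no marker data used downstream).
#' @param n_markers SNP panel size.
#' @param n_locations,n_years trial grid; environments are location x year.
#' @param maf_range range of founder minor-allele frequencies, within (0, 0.5].
#' @param sigma2_g additive genomic variance (yield^2 units).
#' @param lambda_loadings per-location FA loadings \eqn{\Lambda} (length
#'   `n_locations`).
#' @param psi_diag per-location specific variances \eqn{\Psi} (length
#'   `n_locations`, non-negative).
#' @param sigma2_e plot-level residual variance.
#' @param mu grand mean yield.
#' @param location_effects fixed per-location shifts (length `n_locations`).
#' @param ly_effects fixed location x year shifts (`n_locations` x `n_years`).
#' @param sparsity per-environment probability that a breeding line is
#'   observed: scalar, or a `n_locations` x `n_years` matrix. Checks are
#'   always observed everywhere and every line is guaranteed at least one
#'   environment.
#' @param missing_rate fraction of marker cells set to missing.
#' @param n_monomorphic number of deliberately invariant marker columns.
#' @param heterozygosity residual heterozygote fraction at loci segregating
#'   within a family; 1/16 matches F4:5-derived lines.
#' @param check_advantage fixed yield advantage of the checks over the line
#'   population mean (kg/ha); places the line MSI distribution below zero as
#'   in an early-stage trial where checks are elite cultivars.
#' @param n_reps plot replicates per genotype x environment (RCBD-style).
#' @param seed integer seed; the generator is byte-reproducible given the
#'   config.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 172, lines_per_family = 10, n_checks = 9,
                       n_markers = 2479, n_locations = 5, n_years = 2,
                       maf_range = c(0.10, 0.50),
                       sigma2_g = 33000,
                       lambda_loadings = c(150, 120, 100, 140, 110),
                       psi_diag = rep(8100, 5),
                       sigma2_e = 160000,
                       mu = 4000,
                       location_effects = c(-300, 150, 0, 250, -100),
                       ly_effects = matrix(c(-150, 100, 200, -120, 80,
                                             60, -90, 140, -60, 30),
                                           nrow = 5, ncol = 2),
                       sparsity = matrix(c(0.57, 0.58, 0.10, 0.50, 0.10,
                                           0.48, 0.48, 0.47, 0.08, 0.05),
                                         nrow = 5, ncol = 2),
                       missing_rate = 0.05, n_monomorphic = 0,
                       heterozygosity = 1 / 16,
                       check_advantage = 570, n_reps = 2, seed = 1) {
  cfg <- list(n_families = n_families, lines_per_family = lines_per_family,
              n_checks = n_checks, n_markers = n_markers,
              n_locations = n_locations, n_years = n_years,
              maf_range = maf_range, sigma2_g = sigma2_g,
              lambda_loadings = lambda_loadings, psi_diag = psi_diag,
              sigma2_e = sigma2_e, mu = mu,
              location_effects = location_effects, ly_effects = ly_effects,
              sparsity = sparsity, missing_rate = missing_rate,
              n_monomorphic = n_monomorphic, heterozygosity = heterozygosity,
              check_advantage = check_advantage, n_reps = n_reps, seed = seed)
  # re-derive defaults that depend on n_locations/n_years when the caller
  # changed the grid but not the per-location vectors
  if (missing(lambda_loadings) && n_locations != 5)
    cfg$lambda_loadings <- rep_len(c(150, 120, 100, 140, 110), n_locations)
  if (missing(psi_diag) && n_locations != 5)
    cfg$psi_diag <- rep(8100, n_locations)
  if (missing(location_effects) && n_locations != 5)
    cfg$location_effects <- rep_len(c(-300, 150, 0, 250, -100), n_locations)
  if (missing(ly_effects) && (n_locations != 5 || n_years != 2))
    cfg$ly_effects <- matrix(rep_len(c(-150, 100, 200, -120, 80, 60, -90, 140,
                                       -60, 30), n_locations * n_years),
                             n_locations, n_years)
  if (missing(sparsity) && (n_locations != 5 || n_years != 2))
    cfg$sparsity <- 0.5
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_families", "lines_per_family", "n_markers",
              "n_locations", "n_years", "n_reps")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) stop("`", nm, "` must be a positive count")
  if (length(cfg$n_checks) != 1 || cfg$n_checks < 0)
    stop("`n_checks` must be a non-negative count")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range >= 1) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("`maf_range` must be an increasing pair within (0, 1)")
  if (cfg$n_monomorphic >= cfg$n_markers)
    stop("`n_monomorphic` must be smaller than `n_markers`")
  if (cfg$sigma2_g < 0 || cfg$sigma2_e < 0 || any(cfg$psi_diag < 0))
    stop("variances must be non-negative")
  if (length(cfg$lambda_loadings) != cfg$n_locations)
    stop("`lambda_loadings` needs one entry per location")
  if (length(cfg$psi_diag) != cfg$n_locations)
    stop("`psi_diag` needs one entry per location")
  if (length(cfg$location_effects) != cfg$n_locations)
    stop("`location_effects` needs one entry per location")
  if (!is.matrix(cfg$ly_effects) || nrow(cfg$ly_effects) != cfg$n_locations ||
      ncol(cfg$ly_effects) != cfg$n_years)
    stop("`ly_effects` must be an n_locations x n_years matrix")
  sp <- cfg$sparsity
  if (is.matrix(sp)) {
    if (nrow(sp) != cfg$n_locations || ncol(sp) != cfg$n_years)
      stop("`sparsity` matrix must be n_locations x n_years")
  } else if (length(sp) != 1) stop("`sparsity` must be a scalar or a matrix")
  if (any(sp < 0) || any(sp > 1)) stop("`sparsity` entries must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)")
  invisible(cfg)
}

#' Simulate a family-structured SNP marker panel
#'
#' Draws two inbred parents per bi-parental family from founder allele
#' frequencies in `maf_range`, then derives `lines_per_family` inbred lines by
#' independent per-marker Mendelian sampling: at loci where the parents carry
#' different alleles a line is heterozygous with probability
#' `heterozygosity` (default 1/16, matching F4:5-derived material) and
#' otherwise fixed for either parental allele with equal probability. Checks
#' are simulated as unrelated inbreds. `n_monomorphic` columns are forced
#' invariant and `missing_rate` of all cells is masked.
#'
#' @param config a [sim_config()].
#' @return a [marker_matrix()] with attributes: `family` (family label per
#'   genotype, `"check"` for checks), `is_check` (logical), and `complete`
#'   (the pre-masking complete code matrix, used by [simulate_trials()] when
#'   missingness was injected).
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_markers
  nf <- config$n_families
  lpf <- config$lines_per_family
  nl <- nf * lpf
  q <- stats::runif(m, config$maf_range[1], config$maf_range[2])  # minor-allele freq
  mono_cols <- if (config$n_monomorphic > 0) seq_len(config$n_monomorphic) else integer(0)
  # parent alleles: 0 = homozygous minor, 2 = homozygous major
  draw_inbred <- function(n) {
    matrix(ifelse(stats::runif(n * m) < rep(q, each = n), 0L, 2L), n, m)
  }
  p1 <- draw_inbred(nf)
  p2 <- draw_inbred(nf)
  # guarantee every non-monomorphic column segregates in at least one family
  same <- p1 == p2
  fixed_cols <- setdiff(which(colSums(!same) == 0), mono_cols)
  for (j in fixed_cols) {
    i <- sample.int(nf, 1)
    p2[i, j] <- 2L - p2[i, j]
  }
  het <- config$heterozygosity
  codes <- matrix(0L, nl + config$n_checks, m)
  for (f in seq_len(nf)) {
    rows <- ((f - 1) * lpf + 1):(f * lpf)
    base <- matrix(rep(p1[f, ], each = lpf), lpf, m)
    seg <- p1[f, ] != p2[f, ]
    if (any(seg)) {
      nseg <- sum(seg)
      u <- matrix(stats::runif(lpf * nseg), lpf, nseg)
      gseg <- matrix(1L, lpf, nseg)           # heterozygote
      gseg[u < (1 - het) / 2] <- 0L
      gseg[u >= (1 - het) / 2 & u < (1 - het)] <- 2L
      base[, seg] <- gseg
    }
    codes[rows, ] <- base
  }
  if (config$n_checks > 0)
    codes[nl + seq_len(config$n_checks), ] <- draw_inbred(config$n_checks)
  if (length(mono_cols)) codes[, mono_cols] <- 2L
  ids <- c(paste0("L", formatC(seq_len(nl), width = 4, flag = "0")),
           if (config$n_checks > 0) paste0("CHK", seq_len(config$n_checks)))
  dimnames(codes) <- list(ids, paste0("M", formatC(seq_len(m), width = 4, flag = "0")))
  complete <- codes
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(codes)) < config$missing_rate
    codes[mask] <- NA_integer_
  }
  meta <- data.frame(chrom = rep_len(1:20, m), pos = seq_len(m) * 1000L)
  out <- marker_matrix(codes, meta = meta)
  attr(out, "family") <- c(rep(paste0("F", seq_len(nf)), each = lpf),
                           rep("check", config$n_checks))
  attr(out, "is_check") <- c(rep(FALSE, nl), rep(TRUE, config$n_checks))
  attr(out, "complete") <- complete
  out
}

#' Simulate sparse multi-environment yield trials
#'
#' Generates plot-level yield records under the genomic FA1 mixed model: for
#' the marker lines, \eqn{u \sim N(0, \sigma^2_g G)},
#' \eqn{f \sim N(0, G)}, \eqn{\delta_{l\cdot} \sim N(0, \psi_l G)} with
#' \eqn{G} computed from the (complete) line markers, so that
#' \eqn{w \sim N(0, (\Lambda\Lambda^\top + \Psi)\otimes G)}. Checks carry no
#' marker information and receive independent latent values with the same
#' marginal variances, plus the fixed `check_advantage`. Records are emitted
#' only for design cells marked observed; checks are observed everywhere and
#' every line in at least one environment.
#'
#' Maturity groups (III/IV/V) are assigned at the family level with
#' early-stage-typical frequencies; checks cycle through all groups so every
#' group has a reference.
#'
#' The RNG is seeded from `config$seed + 1` on entry (a documented offset so
#' marker and trial generation are independently reproducible).
#'
#' @param markers a [marker_matrix()] from [simulate_markers()]; if it
#'   contains missing cells the generator uses its `complete` attribute for
#'   effect generation.
#' @param config the same [sim_config()].
#' @return a `sim_trials` list: `pheno` (tidy data.frame with columns
#'   genotype, location, year, env, replicate, maturity_group, is_check,
#'   yield), and `truth` (per-genotype `true_u`, `true_f`, `true_w` matrix
#'   (genotype x location), `true_msi`, `true_class`, the observation mask
#'   `design`, and the per-environment true check reference).
#' @export
simulate_trials <- function(markers, config) {
  validate_sim_config(config)
  is_check <- attr(markers, "is_check")
  if (is.null(is_check)) is_check <- grepl("^CHK", rownames(markers))
  ng <- nrow(markers)
  if (ng != config$n_families * config$lines_per_family + config$n_checks)
    stop("marker matrix rows do not match the config genotype count")
  if (ncol(markers) != config$n_markers)
    stop("marker matrix columns do not match config$n_markers")
  codes <- if (anyNA(markers)) attr(markers, "complete") else unclass(markers)
  if (is.null(codes) || anyNA(codes))
    stop("complete (no missing) marker codes are required for effect generation")
  set.seed(config$seed + 1L)
  L <- config$n_locations; Y <- config$n_years
  lam <- config$lambda_loadings; psi <- config$psi_diag
  ids <- rownames(markers)
  lines_idx <- which(!is_check); checks_idx <- which(is_check)
  nlines <- length(lines_idx)

  # genomic covariance among lines
  gl <- compute_grm(marker_matrix(codes[lines_idx, , drop = FALSE]))
  Rchol <- chol(unclass(gl) + diag(1e-8 * mean(diag(gl)), nlines))
  draw_g <- function() as.numeric(crossprod(Rchol, stats::rnorm(nlines)))

  u <- f <- numeric(ng)
  delta <- matrix(0, ng, L)
  u[lines_idx] <- sqrt(config$sigma2_g) * draw_g()
  f[lines_idx] <- draw_g()
  for (l in seq_len(L)) delta[lines_idx, l] <- sqrt(psi[l]) * draw_g()
  nchk <- length(checks_idx)
  if (nchk > 0) {
    # checks are elite released cultivars: narrow genetic spread relative to
    # the unselected line population (factor 0.3 on every latent SD)
    u[checks_idx] <- config$check_advantage +
      0.3 * sqrt(config$sigma2_g) * stats::rnorm(nchk)
    f[checks_idx] <- 0.3 * stats::rnorm(nchk)
    for (l in seq_len(L)) delta[checks_idx, l] <- 0.3 * sqrt(psi[l]) * stats::rnorm(nchk)
  }
  w <- outer(f, lam) + delta  # ng x L
  dimnames(w) <- list(ids, paste0("loc", seq_len(L)))

  # maturity groups: family level for lines, cycling for checks
  fam <- attr(markers, "family")
  if (is.null(fam)) fam <- ifelse(is_check, "check", rownames(markers))
  fam_levels <- unique(fam[!is_check])
  fam_mg <- sample(c(3L, 4L, 5L), length(fam_levels), replace = TRUE,
                   prob = c(0.082, 0.863, 0.055))
  mg <- integer(ng)
  mg[!is_check] <- fam_mg[match(fam[!is_check], fam_levels)]
  if (nchk > 0) mg[is_check] <- rep_len(c(3L, 4L, 5L), nchk)

  # sparse design: lines by per-environment Bernoulli, checks everywhere
  sp <- config$sparsity
  spm <- if (is.matrix(sp)) sp else matrix(sp, L, Y)
  design <- array(FALSE, dim = c(ng, L, Y),
                  dimnames = list(ids, paste0("loc", seq_len(L)), paste0("y", seq_len(Y))))
  for (l in seq_len(L)) for (y in seq_len(Y))
    design[lines_idx, l, y] <- stats::runif(nlines) < spm[l, y]
  none <- lines_idx[apply(design[lines_idx, , , drop = FALSE], 1, sum) == 0]
  if (length(none)) {
    cells <- which(spm >= 0, arr.ind = TRUE)
    pr <- spm[cells]; if (all(pr == 0)) pr <- rep(1, length(pr))
    pick <- cells[sample.int(nrow(cells), length(none), replace = TRUE, prob = pr), , drop = FALSE]
    design[cbind(none, pick)] <- TRUE
  }
  if (nchk > 0) design[checks_idx, , ] <- TRUE

  env_name <- function(l, y) sprintf("loc%d_y%d", l, y)
  recs <- vector("list", L * Y)
  k <- 0
  for (l in seq_len(L)) for (y in seq_len(Y)) {
    obs <- which(design[, l, y])
    if (!length(obs)) next
    k <- k + 1
    nrec <- length(obs) * config$n_reps
    gexp <- rep(obs, times = config$n_reps)
    mu_cell <- config$mu + config$location_effects[l] + config$ly_effects[l, y]
    yield <- mu_cell + u[gexp] + w[gexp, l] +
      stats::rnorm(nrec, 0, sqrt(config$sigma2_e))
    recs[[k]] <- data.frame(
      genotype = ids[gexp], location = paste0("loc", l), year = paste0("y", y),
      env = env_name(l, y), replicate = rep(seq_len(config$n_reps), each = length(obs)),
      maturity_group = mg[gexp], is_check = is_check[gexp], yield = yield,
      stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, recs[seq_len(k)])
  rownames(pheno) <- NULL

  # true check reference and true MSI over all environments
  envs <- as.vector(outer(seq_len(L), seq_len(Y), env_name))
  mg_levels <- sort(unique(mg))
  chk_ref <- matrix(NA_real_, length(envs), length(mg_levels),
                    dimnames = list(envs, as.character(mg_levels)))
  total <- matrix(NA_real_, ng, length(envs), dimnames = list(ids, envs))
  for (j in seq_along(envs)) {
    l <- ((j - 1) %% L) + 1
    yv <- ((j - 1) %/% L) + 1
    mu_cell <- config$mu + config$location_effects[l] + config$ly_effects[l, yv]
    total[, j] <- mu_cell + u + w[, l]
    for (gidx in seq_along(mg_levels)) {
      cc <- checks_idx[mg[checks_idx] == mg_levels[gidx]]
      if (length(cc) == 0) cc <- checks_idx  # no check in this group: use all
      if (length(cc)) chk_ref[j, gidx] <- mean(total[cc, j])
    }
  }
  if (nchk > 0) {
    ref_per_g <- chk_ref[, as.character(mg), drop = FALSE]  # E x ng
    true_msi <- colMeans(t(total) / ref_per_g * 100 - 100)
  } else {
    true_msi <- rep(NA_real_, ng)
  }
  names(true_msi) <- ids
  true_class <- if (nchk > 0) assign_class(true_msi) else
    factor(rep(NA, ng), levels = yield_class_levels())

  structure(list(
    pheno = pheno,
    truth = list(true_u = stats::setNames(u, ids), true_f = stats::setNames(f, ids),
                 true_w = w, true_msi = true_msi, true_class = true_class,
                 design = design, check_reference_true = chk_ref,
                 maturity_group = stats::setNames(mg, ids))),
    class = "sim_trials")
}

#' @export
print.sim_trials <- function(x, ...) {
  cat(sprintf("sim_trials: %d records, %d genotypes, %d environments\n",
              nrow(x$pheno), length(unique(x$pheno$genotype)),
              length(unique(x$pheno$env))))
  print(round(100 * prop.table(table(x$truth$true_class)), 1))
  invisible(x)
}

#' Write simulated data to disk
#'
#' Writes the marker matrix as numeric CSV (and VCF when `vcfR` is
#' available), the phenotype table as tidy CSV, and the simulation truth as
#' CSV (intended for tests and diagnostics only).
#'
#' @param markers a [marker_matrix()] from [simulate_markers()].
#' @param trials a `sim_trials` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simdata <- function(markers, trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_markers_csv(markers, file.path(dir, "markers.csv"))
  if (requireNamespace("vcfR", quietly = TRUE))
    write_markers_vcf(markers, file.path(dir, "markers.vcf"))
  utils::write.csv(trials$pheno, file.path(dir, "pheno.csv"), row.names = FALSE)
  tr <- trials$truth
  truth_df <- data.frame(genotype = names(tr$true_u), true_u = tr$true_u,
                         true_f = tr$true_f, true_msi = tr$true_msi,
                         true_class = tr$true_class,
                         maturity_group = tr$maturity_group,
                         stringsAsFactors = FALSE)
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
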