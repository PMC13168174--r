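#' Yield-class thresholds on the MSI scale
#'
#' Default cutoffs follow typical early-stage breeder decision boundaries:
#' high-yielding when MSI >= -5 (about 95% of check performance), moderate
#' when -15 <= MSI < -5, low-yielding when MSI < -15 (about 85% of check
#' performance).
#'
#' @param high_min smallest MSI classified as high-yielding (default -5).
#' @param moderate_min smallest MSI classified as moderate (default -15).
#' @return a `class_thresholds` list.
#' @export
class_thresholds <- function(high_min = -5, moderate_min = -15) {
  if (!is.finite(high_min) || !is.finite(moderate_min) || high_min <= moderate_min)
    stop("`high_min` must be greater than `moderate_min`")
  structure(list(high_min = high_min, moderate_min = moderate_min),
            class = "class_thresholds")
}

#' Yield class order used throughout the package
#'
#' Classes are ordered low < moderate < high; misclassification severity is
#' measured in steps along this order.
#' @return character vector of the three class labels in order.
#' @export
yield_class_levels <- function() c("low", "moderate", "high")

#' Assign three-way yield classes from MSI values
#'
#' Boundaries are exactly: high-yielding when `msi >= high_min`, moderate when
#' `moderate_min <= msi < high_min`, low-yielding when `msi < moderate_min`.
#'
#' @param msi numeric vector of MSI values (finite).
#' @param thresholds a [class_thresholds()].
#' @return factor with levels `low < moderate < high`.
#' @examples
#' assign_class(c(-5, -15, -15.01, 0))  # high, moderate, low, high
#' @export
assign_class <- function(msi, thresholds = class_thresholds()) {
  if (any(!is.finite(msi)))
    stop("non-finite MSI values cannot be classified")
  cls <- ifelse(msi >= thresholds$high_min, "high",
                ifelse(msi >= thresholds$moderate_min, "moderate", "low"))
  factor(cls, levels = yield_class_levels())
}

#' Check-referenced selection index (MSI)
#'
#' For genotype *i*, the MSI is the average over environments of its
#' predicted yield expressed as a percentage-point deviation from the mean
#' yield of the reference checks of the same maturity group:
#' \deqn{\mathrm{MSI}_i = \frac{1}{n}\sum_{j=1}^{n}
#'   \left(\frac{Y_{ij}}{\mathrm{Check}_j} \times 100 - 100\right).}
#' 0 means performance equal to the checks' mean, -5 means 95% of it, +5
#' means 105%. By default the average runs over all environments of the
#' GBLUP matrix — observed and predicted cells alike, which is the point of
#' predicting unobserved combinations; `mode = "observed"` restricts it to
#' cells with phenotype records.
#'
#' @param gblups a [gblup_matrix()] of predicted yields (environment mean +
#'   genetic effect).
#' @param checks a [check_reference()] covering every environment of
#'   `gblups`; check means must be positive.
#' @param mg_map named vector mapping genotype ID to maturity group. If a
#'   genotype's group has no check reference, the nearest group (numeric
#'   distance) is used with a warning.
#' @param thresholds a [class_thresholds()].
#' @param mode average over `"all"` environments (default) or `"observed"`
#'   cells only.
#' @return an `msi_result` data.frame: `genotype`, `msi`, `n_env`,
#'   `yield_class`.
#' @export
compute_msi <- function(gblups, checks, mg_map = NULL,
                        thresholds = class_thresholds(),
                        mode = c("all", "observed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gblups, "gblup_matrix"))
  checks <- if (inherits(checks, "check_reference")) checks else check_reference(checks)
  envs <- colnames(gblups)
  missing_env <- setdiff(envs, checks$env)
  if (length(missing_env))
    stop("check reference missing for environment(s): ",
         paste(missing_env, collapse = ", "))
  bad <- checks$check_mean <= 0 & checks$env %in% envs
  if (any(bad))
    stop("non-positive check mean in environment(s): ",
         paste(unique(checks$env[bad]), collapse = ", "))
  gids <- rownames(gblups)
  mgs_avail <- unique(checks$maturity_group)
  if (is.null(mg_map)) {
    if (length(mgs_avail) > 1)
      stop("`mg_map` is required when the check reference has several maturity groups")
    mg <- rep(mgs_avail, length(gids))
  } else {
    if (!all(gids %in% names(mg_map)))
      stop("`mg_map` missing genotypes: ",
           paste(utils::head(setdiff(gids, names(mg_map)), 5), collapse = ", "))
    mg <- mg_map[gids]
  }
  # map each genotype's group to an available check group
  mg_used <- mg
  unmatched <- !(mg %in% mgs_avail)
  if (any(unmatched)) {
    tgt <- unique(mg[unmatched])
    num_avail <- suppressWarnings(as.numeric(as.character(mgs_avail)))
    for (m in tgt) {
      mn <- suppressWarnings(as.numeric(as.character(m)))
      near <- if (!is.na(mn) && !anyNA(num_avail))
        mgs_avail[which.min(abs(num_avail - mn))] else mgs_avail[1]
      warning(sprintf("no checks of maturity group %s; using group %s as reference", m, near))
      mg_used[mg == m] <- near
    }
  }
  # check mean per (environment, group) on the gblup environment grid
  refmat <- matrix(NA_real_, length(mgs_avail), length(envs),
                   dimnames = list(as.character(mgs_avail), envs))
  sel <- checks$env %in% envs
  refmat[cbind(as.character(checks$maturity_group[sel]), checks$env[sel])] <-
    checks$check_mean[sel]
  ref_per_g <- refmat[as.character(mg_used), , drop = FALSE]
  dev <- unclass(gblups) / ref_per_g * 100 - 100
  if (mode == "observed") {
    msk <- attr(gblups, "observed_mask")
    none <- rowSums(msk) == 0
    if (any(none))
      stop("mode = \"observed\" but genotype(s) without observed cells: ",
           paste(utils::head(gids[none], 5), collapse = ", "))
    msi <- rowSums(dev * msk) / rowSums(msk)
    n_env <- rowSums(msk)
  } else {
    msi <- rowMeans(dev)
    n_env <- rep(ncol(gblups), length(gids))
  }
  out <- data.frame(genotype = gids, msi = as.numeric(msi),
                    n_env = as.integer(n_env),
                    yield_class = assign_class(as.numeric(msi), thresholds),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, thresholds = thresholds, mode = mode,
            class = c("msi_result", "data.frame"))
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("msi_result: %d genotypes (mode = %s)\n", nrow(x), attr(x, "mode")))
  cat(sprintf("  MSI mean %.1f, range [%.1f, %.1f]\n",
              mean(x$msi), min(x$msi), max(x$msi)))
  tab <- table(x$yield_class)
  cat("  classes: ", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Write an MSI table as CSV
#' @param msi an `msi_result`.
#' @param path output file.
#' @export
write_msi_csv <- function(msi, path) {
  utils::write.csv(as.data.frame(msi), path, row.names = FALSE)
  invisible(path)
}
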