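#' Marker quality control
#'
#' Removes monomorphic markers (all non-missing codes identical) and markers
#' with a missing-data fraction at or above `max_missing`. The 20% boundary is
#' inclusive: a marker with exactly 20% missing cells is removed. Genotype
#' rows are never touched.
#'
#' @param markers a [marker_matrix()].
#' @param max_missing markers with missing fraction `>= max_missing` are
#'   dropped; default 0.20.
#' @return the filtered [marker_matrix()], with a `removal_log` attribute: a
#'   `data.frame` of dropped marker IDs and the reason
#'   (`"monomorphic"` / `"missing"`).
#' @export
qc_filter <- function(markers, max_missing = 0.20) {
  markers <- as_marker_matrix(markers)
  if (!(max_missing > 0 && max_missing <= 1)) stop("`max_missing` must be in (0, 1]")
  miss <- colMeans(is.na(markers))
  n_distinct <- apply(markers, 2, function(x) length(unique(x[!is.na(x)])))
  mono <- n_distinct <= 1
  toomiss <- !mono & miss >= max_missing
  log <- data.frame(
    marker_id = c(colnames(markers)[mono], colnames(markers)[toomiss]),
    reason = c(rep("monomorphic", sum(mono)), rep("missing", sum(toomiss))),
    stringsAsFactors = FALSE)
  keep <- !(mono | toomiss)
  if (!any(keep)) stop("QC removed all markers: nothing left to analyse")
  out <- markers[, keep]
  attr(out, "removal_log") <- log
  out
}

#' Write a QC removal log as TSV
#' @param markers a QC-filtered [marker_matrix()] carrying a `removal_log`.
#' @param path output file.
#' @export
write_removal_log <- function(markers, path) {
  log <- attr(markers, "removal_log")
  if (is.null(log)) log <- data.frame(marker_id = character(), reason = character())
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Iterative random-forest imputation of missing marker codes
#'
#' Fills missing genotype calls with an iterative ensemble-of-trees scheme in
#' the style of missForest: cells are first initialised with the per-marker
#' mode, then each marker with missing data is modelled in turn as a
#' categorical response over \{0,1,2\} with all other markers as predictors,
#' visiting markers in order of increasing missingness. Passes repeat until
#' the proportion of imputed cells that change between successive passes is
#' `<= tol`, or `max_iter` passes have run.
#'
#' Observed cells are never altered, and the result is deterministic given
#' `seed`.
#'
#' @param markers a QC-filtered [marker_matrix()]; no marker may be entirely
#'   missing.
#' @param max_iter maximum number of passes over the markers (default 10).
#' @param tol stop when the fraction of imputed cells changing between passes
#'   is at or below this value (default 0, i.e. stop only when no imputed
#'   cell changes).
#' @param seed integer seed for the tree ensembles.
#' @param ntree trees per marker model (default 100).
#' @return a complete [marker_matrix()] with an `impute_iterations` attribute.
#' @export
impute_markers <- function(markers, max_iter = 10, tol = 0, seed = 1, ntree = 100) {
  markers <- as_marker_matrix(markers)
  miss <- is.na(markers)
  if (!any(miss)) return(markers)
  if (any(colMeans(miss) == 1))
    stop("markers entirely missing cannot be imputed: ",
         paste(colnames(markers)[colMeans(miss) == 1], collapse = ", "))
  x <- unclass(markers)
  # initial fill: per-column mode
  for (j in which(colSums(miss) > 0)) {
    obs <- x[!miss[, j], j]
    mode_j <- as.integer(names(which.max(table(obs))))
    x[miss[, j], j] <- mode_j
  }
  ord <- order(colSums(miss))
  ord <- ord[colSums(miss)[ord] > 0]
  set.seed(seed)
  it <- 0L
  repeat {
    it <- it + 1L
    changed <- 0L
    for (j in ord) {
      yj <- factor(x[!miss[, j], j], levels = 0:2)
      if (length(unique(yj)) < 2) next  # nothing to model
      fit <- randomForest::randomForest(
        x = x[!miss[, j], -j, drop = FALSE], y = droplevels(yj), ntree = ntree)
      pred <- as.integer(as.character(
        stats::predict(fit, x[miss[, j], -j, drop = FALSE])))
      changed <- changed + sum(pred != x[miss[, j], j])
      x[miss[, j], j] <- pred
    }
    if (it >= max_iter || changed / sum(miss) <= tol) break
  }
  out <- marker_matrix(x, meta = attr(markers, "meta"))
  attr(out, "impute_iterations") <- it
  out
}

#' Genomic relationship matrix
#'
#' VanRaden's realized additive relationship matrix. With marker codes
#' \eqn{M \in \{0,1,2\}^{n \times m}}, allele frequencies
#' \eqn{p_j = \bar M_{\cdot j} / 2}, and the centered matrix
#' \eqn{Z = M - 2 \mathbf{1} p^\top}, the GRM is
#' \deqn{G = Z Z^\top / \left(2 \sum_j p_j (1 - p_j)\right),}
#' i.e. scaled by the expected marker heterozygosity.
#'
#' @param markers a complete (no missing) [marker_matrix()] with at least one
#'   polymorphic marker.
#' @return a `grm` object: the symmetric \eqn{n \times n} matrix with genotype
#'   IDs on both dimensions and the scaling denominator in attribute `denom`.
#' @examples
#' m <- marker_matrix(matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "m1")))
#' compute_grm(m)  # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(markers) {
  markers <- as_marker_matrix(markers)
  if (anyNA(markers)) stop("marker matrix has missing codes; impute first")
  m <- unclass(markers); storage.mode(m) <- "double"
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: GRM denominator is zero")
  z <- sweep(m, 2, 2 * p, `-`)
  g <- tcrossprod(z) / denom
  g <- (g + t(g)) / 2
  structure(g, denom = denom, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d genotypes, denom = %.4f, mean diag = %.3f\n",
              nrow(x), attr(x, "denom"), mean(diag(x))))
  invisible(x)
}

#' Identity relationship matrix
#'
#' Used for entries without marker data (e.g. reference checks): genotype
#' effects are modelled as unrelated with unit prior variance.
#' @param ids genotype identifiers.
#' @return a `grm` object equal to the identity.
#' @export
identity_grm <- function(ids) {
  g <- diag(length(ids))
  dimnames(g) <- list(ids, ids)
  structure(g, denom = NA_real_, class = c("grm", "matrix", "array"))
}

#' Write a GRM as square CSV with genotype IDs
#' @param grm a `grm`.
#' @param path output file.
#' @export
write_grm_csv <- function(grm, path) {
  df <- data.frame(genotype = rownames(grm), unclass(grm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Principal component analysis of marker codes
#'
#' PCA of the column-centered (not standardized) genotype code matrix, i.e. an
#' eigen-decomposition of the SNP variance-covariance matrix; used to
#' visualize genomic structure and as the advance/discard diversity
#' diagnostic.
#'
#' @param markers a complete [marker_matrix()].
#' @param k number of components to keep; reduced with a warning if it
#'   exceeds the matrix rank.
#' @return a `pca_result`: list with `scores` (n x k, genotype IDs on rows)
#'   and `explained_variance_fraction` (length k, non-increasing).
#' @export
pca_markers <- function(markers, k = 2) {
  markers <- as_marker_matrix(markers)
  if (anyNA(markers)) stop("marker matrix has missing codes; impute first")
  m <- unclass(markers); storage.mode(m) <- "double"
  if (k > min(dim(m))) stop("`k` cannot exceed min(n genotypes, n markers)")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  pos <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  rank <- sum(pos)
  if (k > rank) {
    warning(sprintf("requested k = %d exceeds rank %d; returning %d components",
                    k, rank, rank))
    k <- rank
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev^2
  structure(list(scores = scores,
                 explained_variance_fraction = (ev / sum(ev))[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d genotypes, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}
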