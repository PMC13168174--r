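#' Construct a marker matrix
#'
#' A `marker_matrix` holds biallelic SNP genotypes coded 0 (homozygous minor
#' allele), 1 (heterozygote), 2 (homozygous major allele) or `NA` (missing),
#' with genotype identifiers on rows and marker identifiers on columns.
#'
#' @param codes numeric or integer matrix of genotype codes in
#'   \{0, 1, 2, NA\}. Row names are genotype IDs, column names marker IDs;
#'   both must be unique. Unnamed dimensions are given default IDs.
#' @param meta optional `data.frame` of per-marker metadata (e.g. chromosome,
#'   position) with one row per marker.
#' @return An object of class `marker_matrix`: the integer code matrix with a
#'   `meta` attribute.
#' @examples
#' m <- marker_matrix(matrix(c(0, 2, 1, 2), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("m1", "m2"))))
#' dim(m)
#' @export
marker_matrix <- function(codes, meta = NULL) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("marker codes must be 0, 1, 2 or NA; found other values")
  if (is.null(rownames(codes))) rownames(codes) <- paste0("G", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  if (anyDuplicated(rownames(codes))) stop("duplicate genotype IDs")
  if (anyDuplicated(colnames(codes))) stop("duplicate marker IDs")
  if (!is.null(meta)) {
    if (!is.data.frame(meta) || nrow(meta) != ncol(codes))
      stop("`meta` must be a data.frame with one row per marker")
  }
  structure(codes, meta = meta, class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d genotypes x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# keep class/attributes through subsetting
#' @export
`[.marker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  meta <- attr(x, "meta")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!is.null(meta) && !missing(j)) meta <- meta[j, , drop = FALSE]
    out <- structure(out, meta = meta, class = class(x))
  }
  out
}

as_marker_matrix <- function(x) {
  if (inherits(x, "marker_matrix")) x else marker_matrix(as.matrix(x))
}

#' Read / write marker matrices as numeric CSV
#'
#' The CSV layout is rows = genotypes (first column `genotype`), columns =
#' markers with marker IDs in the header; cells are 0/1/2 codes, empty for
#' missing.
#'
#' @param path file path.
#' @return `read_markers_csv` returns a [marker_matrix()].
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  marker_matrix(m)
}

#' @rdname read_markers_csv
#' @param markers a [marker_matrix()].
#' @export
write_markers_csv <- function(markers, path) {
  df <- data.frame(genotype = rownames(markers),
                   unclass(markers)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write marker matrices as VCF
#'
#' Biallelic sites with a GT field. On reading, genotypes are coded as the
#' count of the ALT allele (0/1/2); set `major_allele = TRUE` to flip each
#' marker so that 2 is the major (most frequent) allele, the convention used
#' for yield-class work in this package. The relationship matrix is invariant
#' to a consistent choice of orientation.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param major_allele flip codes so 2 = homozygous major allele.
#' @return a [marker_matrix()].
#' @export
read_markers_vcf <- function(path, major_allele = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code1 <- gsub("\\|", "/", gt)
  m <- matrix(NA_integer_, nrow(code1), ncol(code1), dimnames = dimnames(code1))
  m[code1 %in% c("0/0")] <- 0L
  m[code1 %in% c("0/1", "1/0")] <- 1L
  m[code1 %in% c("1/1")] <- 2L
  m <- t(m)  # genotypes x markers
  if (major_allele) {
    flip <- colMeans(m, na.rm = TRUE) < 1  # ALT is minor -> already 2=REF=major? count of ALT<1 means ALT minor
    m[, flip] <- 2L - m[, flip]
  }
  meta <- data.frame(chrom = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
                     stringsAsFactors = FALSE)
  marker_matrix(m, meta = meta)
}

#' @rdname read_markers_vcf
#' @param markers a [marker_matrix()]; codes are written as ALT-allele counts.
#' @export
write_markers_vcf <- function(markers, path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("writing VCF requires the 'vcfR' package")
  m <- t(unclass(markers))  # markers x genotypes
  meta <- attr(markers, "meta")
  chrom <- if (!is.null(meta) && "chrom" %in% names(meta)) as.character(meta$chrom) else rep("1", nrow(m))
  pos <- if (!is.null(meta) && "pos" %in% names(meta)) meta$pos else seq_len(nrow(m))
  fix <- cbind(CHROM = chrom, POS = as.character(pos), ID = rownames(m),
               REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".")
  gtchr <- matrix(".\\.", nrow(m), ncol(m))
  gtchr[!is.na(m) & m == 0] <- "0/0"
  gtchr[!is.na(m) & m == 1] <- "0/1"
  gtchr[!is.na(m) & m == 2] <- "1/1"
  gtchr[is.na(m)] <- "./."
  gt <- cbind(FORMAT = "GT", gtchr)
  colnames(gt) <- c("FORMAT", colnames(m))
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  vcfR::write.vcf(v, path)
  invisible(path)
}
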