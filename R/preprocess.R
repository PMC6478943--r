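#' TMM library-size normalization and log2-CPM
#'
#' Normalizes library sizes by the trimmed mean of M-values (via edgeR, the
#' method's reference implementation) and computes log2 counts per million
#' with a prior count of 2 on effective library sizes. The reference sample
#' is the one whose upper-quartile CPM is closest to the mean upper quartile;
#' per-sample factors are the inverse-variance-weighted mean of M-values
#' after trimming the top/bottom 30% by M and 5% by A (genes with a zero
#' count in either sample dropped), rescaled to geometric mean 1.
#'
#' @param counts LesionExperiment of non-negative counts, >= 2 samples.
#' @return list with \code{result} (factors, reference sample, per-sample
#'   M/A values against the reference) and \code{log2cpm} (a
#'   LesionExperiment).
#' @export
tmmNormalize <- function(counts) {
  stopifnot(is(counts, "LesionExperiment"))
  x <- exprValues(counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  if (any(x < 0)) stop("counts must be non-negative")
  lib <- colSums(x)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "))
  if (nrow(x) == 1) {
    warning("single gene: all TMM factors set to 1")
    fac <- stats::setNames(rep(1, ncol(x)), colnames(x))
    ref <- colnames(x)[1]
  } else {
    uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, p = 0.75)
    ref <- colnames(x)[which.min(abs(uq - mean(uq)))]
    fac <- edgeR::calcNormFactors(x, lib.size = lib, method = "TMM",
                                  refColumn = match(ref, colnames(x)))
    names(fac) <- colnames(x)
  }
  cpmRef <- x[, ref] / lib[ref]
  mv <- av <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    cpmJ <- x[, j] / lib[j]
    ok <- cpmJ > 0 & cpmRef > 0
    mv[ok, j] <- log2(cpmJ[ok] / cpmRef[ok])
    av[ok, j] <- 0.5 * log2(cpmJ[ok] * cpmRef[ok])
  }
  lc <- edgeR::cpm(x, lib.size = lib * fac, log = TRUE, prior.count = 2)
  list(result = list(factors = fac, referenceSample = ref,
                     mValues = mv, aValues = av),
       log2cpm = .reValue(counts, lc, scale = "log2cpm"))
}

#' Filter uninformative genes
#'
#' Removes genes whose interquartile range across samples is zero or whose
#' row sum is less than or equal to 1, preserving the order of survivors.
#' By default the filter is evaluated on the matrix as given (the pipeline
#' applies it to normalized log2-CPM values); pass a counts matrix to apply
#' it on the count scale instead.
#'
#' @param expr LesionExperiment on any scale.
#' @return filtered LesionExperiment.
#' @export
filterGenes <- function(expr) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  iqr <- apply(x, 1, stats::IQR)
  keep <- iqr > 0 & rowSums(x) > 1
  if (!any(keep)) stop("gene filter removed every gene")
  .reValue(expr, x[keep, , drop = FALSE])
}

#' Multi-criterion sample outlier screen
#'
#' Flags samples whose |z| exceeds 2 on more than one of three criteria,
#' all computed in a single pass on the full candidate set: (a) mean Pearson
#' correlation with all other samples across the filtered genes, (b) the 1st
#' or 2nd principal component of the expression matrix (the criterion fails
#' if either |z| > 2), and (c) the transcript integrity number (TIN) from
#' sample metadata. A sample is excluded iff at least two criteria fail.
#'
#' @param expr LesionExperiment (gene-filtered); TIN expected in
#'   \code{sampleInfo(expr)$tin}.
#' @param zCut z-score cutoff (default 2).
#' @return data.frame per sample: meanCorrelation, pc1, pc2, tin, their
#'   z-scores, criteriaFailed (comma string), excluded.
#' @export
qcOutlierFilter <- function(expr, zCut = 2) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  n <- ncol(x)
  cc <- stats::cor(x)
  meanCor <- (rowSums(cc) - 1) / (n - 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]; pc2 <- pc$x[, 2]
  md <- sampleInfo(expr)
  tin <- if ("tin" %in% colnames(md)) md$tin else NULL
  z <- function(v) (v - mean(v)) / stats::sd(v)
  zc <- z(meanCor); z1 <- z(pc1); z2 <- z(pc2)
  failCor <- abs(zc) > zCut
  failPc <- abs(z1) > zCut | abs(z2) > zCut
  if (is.null(tin)) {
    warning("TIN missing from metadata: criterion skipped")
    zt <- rep(NA_real_, n); failTin <- rep(FALSE, n)
  } else {
    zt <- z(tin); failTin <- abs(zt) > zCut
  }
  nFail <- failCor + failPc + failTin
  crit <- mapply(function(a, b, c)
    paste(c("correlation", "principal_components", "tin")[c(a, b, c)],
          collapse = ","), failCor, failPc, failTin)
  data.frame(sample = colnames(x), meanCorrelation = meanCor,
             pc1 = pc1, pc2 = pc2, tin = if (is.null(tin)) NA_real_ else tin,
             zCorrelation = zc, zPc1 = z1, zPc2 = z2, zTin = zt,
             criteriaFailed = crit, excluded = nFail > 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact 1-D two-means split
#'
#' Scans every threshold of the sorted values and returns the split that
#' minimizes the within-group sum of squares; deterministic.
#' @keywords internal
.twoMeans1d <- function(v) {
  o <- order(v); s <- v[o]; n <- length(v)
  csum <- cumsum(s); csq <- cumsum(s^2); tot <- csum[n]; totq <- csq[n]
  wss <- vapply(seq_len(n - 1), function(k) {
    (csq[k] - csum[k]^2 / k) +
      ((totq - csq[k]) - (tot - csum[k])^2 / (n - k))
  }, numeric(1))
  k <- which.min(wss)
  high <- logical(n); high[o[(k + 1):n]] <- TRUE
  high
}

#' Sex check against Y-chromosome expression
#'
#' Predicts sex by a two-group (1-D 2-means) split of mean expression over
#' Y-linked genes (defaults to the panel CYorf15A, DDX3Y, KDM5D, RPS4Y1,
#' USP9Y, UTY), calling the higher group male, and flags samples whose
#' prediction disagrees with annotated sex in metadata column \code{sex}.
#'
#' @param expr LesionExperiment; \code{sampleInfo(expr)$sex} required.
#' @param yGenes character, Y-gene IDs to average.
#' @return named logical mismatch flags (NA everywhere, with a warning, if no
#'   listed Y gene is present).
#' @export
sexCheck <- function(expr, yGenes = c("CYorf15A", "DDX3Y", "KDM5D",
                                      "RPS4Y1", "USP9Y", "UTY")) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  present <- intersect(yGenes, rownames(x))
  if (!length(present)) {
    warning("no Y genes in matrix; sex check undetermined")
    return(stats::setNames(rep(NA, ncol(x)), colnames(x)))
  }
  md <- sampleInfo(expr)
  if (!"sex" %in% colnames(md)) stop("annotated sex missing from metadata")
  yMean <- colMeans(x[present, , drop = FALSE])
  high <- .twoMeans1d(yMean)
  predicted <- ifelse(high, "male", "female")
  stats::setNames(predicted != md$sex, colnames(x))
}

#' Residualize expression on nuisance covariates
#'
#' Per-gene ordinary least squares on an intercept plus the named metadata
#' columns (RNA quality, batch, ...); returns the residuals. Character or
#' factor covariates are dummy-coded.
#'
#' @param expr LesionExperiment.
#' @param covariates character, column names of \code{sampleInfo(expr)}.
#' @return LesionExperiment of residuals (scale "residual").
#' @export
residualize <- function(expr, covariates) {
  stopifnot(is(expr, "LesionExperiment"))
  md <- sampleInfo(expr)
  miss <- setdiff(covariates, colnames(md))
  if (length(miss)) stop("covariates not in metadata: ",
                         paste(miss, collapse = ", "))
  df <- md[, covariates, drop = FALSE]
  if (anyNA(df)) stop("covariates contain missing values")
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qx)                                 # n x p orthonormal
  Y <- exprValues(expr)                         # genes x n
  res <- Y - (Y %*% Q) %*% t(Q)
  .reValue(expr, res, scale = "residual")
}
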