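#' Single-sample gene-set variation scores
#'
#' Gene-set activity per sample by the kernel-rank random-walk statistic:
#' (1) each gene's expression is turned into a cumulative-density estimate
#' across samples with a Gaussian kernel of bandwidth sd/4; (2) within each
#' sample, genes are ranked by that estimate (descending) and given the
#' symmetric rank weight |p/2 - rank| (p = gene count); (3) a weighted
#' Kolmogorov-Smirnov random walk over the ranked list steps up by the
#' tau-powered rank weight for in-set genes (normalized) and down by
#' 1/(p - set size) otherwise; (4) the score is the maximum positive
#' deviation plus the minimum negative deviation of the walk
#' (max-difference rule).
#'
#' @param expr LesionExperiment (continuous values); >= 3 samples.
#' @param geneSets named list of gene-ID vectors; sets with < 2 genes
#'   present yield NA scores (marked, not zero).
#' @param tau rank-weight exponent (default 1).
#' @return set-by-sample numeric matrix (NA rows for undefined sets), with
#'   the parameters in attributes.
#' @export
gsvaScores <- function(expr, geneSets, tau = 1) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  p <- nrow(x); n <- ncol(x)
  if (n < 3) stop("need at least 3 samples")
  ## kernel CDF estimate per gene
  z <- matrix(0, p, n, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    h <- stats::sd(x[i, ]) / 4
    if (h == 0) h <- 1e-8
    z[i, ] <- rowMeans(stats::pnorm(outer(x[i, ], x[i, ], "-") / h))
  }
  scores <- matrix(NA_real_, length(geneSets), n,
                   dimnames = list(names(geneSets), colnames(x)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- seq_len(p)
    w <- abs(p / 2 - rk)
    for (s in names(geneSets)) {
      inSet <- rownames(x) %in% geneSets[[s]]
      m <- sum(inSet)
      if (m < 2 || m == p) next
      wt <- w[ord]^tau
      isIn <- inSet[ord]
      up <- ifelse(isIn, wt, 0) / sum(wt[isIn])
      dn <- ifelse(isIn, 0, 1 / (p - m))
      walk <- cumsum(up - dn)
      scores[s, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  attr(scores, "parameters") <- list(kernel = "gaussian", bandwidth = "sd/4",
                                     tau = tau, rule = "max-difference")
  scores
}

#' Empirical-Bayes batch adjustment
#'
#' Removes batch location/scale effects by the parametric empirical-Bayes
#' procedure (ComBat, via sva). Each batch needs >= 2 samples; with a single
#' batch the input is returned unchanged.
#'
#' @param expr LesionExperiment.
#' @param batch batch labels (default: metadata column \code{batch}).
#' @return adjusted LesionExperiment on the same scale.
#' @export
combatAdjust <- function(expr, batch = sampleInfo(expr)$batch) {
  stopifnot(is(expr, "LesionExperiment"))
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(expr)
  if (any(table(batch) < 2))
    stop("every batch needs at least 2 samples")
  adj <- sva::ComBat(exprValues(expr), batch = batch)
  .reValue(expr, adj)
}

#' Whitening transform for exchangeable (compound-symmetric) correlation
#' @keywords internal
.csWhiten <- function(M, subject, rho) {
  subject <- as.factor(subject)
  m <- tabulate(subject)[as.integer(subject)]        # block size per row
  gam <- 1 - sqrt((1 - rho) / (1 + (m - 1) * rho))   # 0 for singletons
  means <- rowsum(M, subject) / tabulate(subject)
  (M - gam * means[as.integer(subject), , drop = FALSE]) / sqrt(1 - rho)
}

#' @keywords internal
.csLogDetV <- function(subject, rho) {
  tab <- table(subject)
  sum((tab - 1) * log(1 - rho) + log(1 + (tab - 1) * rho))
}

#' Repeated-measures association via a consensus-correlation GLS
#'
#' Models each response with fixed effects for a two-level group (plus
#' optional covariates) and an exchangeable within-subject correlation:
#' the intra-subject correlation is REML-profiled per response on a rho
#' grid with quadratic refinement, a consensus rho is formed as
#' tanh(mean(atanh(rho_r))), and every response is then fit by generalized
#' least squares at the consensus rho. With one sample per subject the fit
#' reduces exactly to ordinary least squares. Returns ordinary t-tests on
#' the group coefficient with Benjamini-Hochberg q-values across responses.
#'
#' @param responses response-by-sample numeric matrix (rows = responses,
#'   e.g. module scores; NA rows are dropped from the consensus and carry NA
#'   results).
#' @param group two-level factor (or coercible) per sample.
#' @param subject subject IDs per sample.
#' @param covariates optional data.frame of additional per-sample fixed
#'   effects.
#' @param rhoGrid grid for the REML profile (default seq(-0.2, 0.9, 0.02)).
#' @return data.frame per response: estimate, se, tstat, pvalue, qvalue,
#'   rho (the per-response REML estimate); attributes \code{consensusRho}
#'   and \code{coding} (the contrast direction).
#' @export
mixedAssociation <- function(responses, group, subject, covariates = NULL,
                             rhoGrid = seq(-0.2, 0.9, by = 0.02)) {
  Y <- as.matrix(responses)
  if (is.null(rownames(Y))) rownames(Y) <- paste0("response", seq_len(nrow(Y)))
  n <- ncol(Y)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  subject <- as.character(subject)
  if (length(subject) != n || length(group) != n)
    stop("group/subject length must match the number of samples")
  if (length(unique(subject)) == 1) stop("all samples from one subject")
  df <- data.frame(.group = group)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- stats::model.matrix(~ ., df)
  pcol <- ncol(X)
  keep <- rowSums(is.na(Y)) == 0
  Yk <- Y[keep, , drop = FALSE]
  ## guard rho grid: 1 + (m-1) rho must stay positive
  mMax <- max(table(subject))
  rhoGrid <- rhoGrid[rhoGrid > -1 / (mMax - 1 + 1e-12) + 1e-6 & rhoGrid < 0.999]

  singletons <- all(table(subject) == 1)
  if (singletons || nrow(Yk) == 0) {
    rhoHat <- rep(0, nrow(Yk)); consensus <- 0
  } else {
    ## profile REML criterion on the grid, vectorized over responses
    crit <- matrix(NA_real_, length(rhoGrid), nrow(Yk))
    ldx <- numeric(length(rhoGrid)); ldv <- numeric(length(rhoGrid))
    for (gi in seq_along(rhoGrid)) {
      rho <- rhoGrid[gi]
      Xw <- .csWhiten(X, subject, rho)
      Yw <- .csWhiten(t(Yk), subject, rho)
      qx <- qr(Xw)
      rss <- colSums(qr.resid(qx, Yw)^2)
      ldv[gi] <- .csLogDetV(subject, rho)
      ldx[gi] <- sum(log(abs(diag(qr.R(qx))^2)))
      crit[gi, ] <- -0.5 * (ldv[gi] + ldx[gi] + (n - pcol) * log(rss))
    }
    best <- apply(crit, 2, which.max)
    rhoHat <- vapply(seq_along(best), function(r) {
      i <- best[r]
      if (i == 1 || i == length(rhoGrid)) return(rhoGrid[i])
      ## quadratic refinement around the grid maximum
      y0 <- crit[i - 1, r]; y1 <- crit[i, r]; y2 <- crit[i + 1, r]
      denom <- y0 - 2 * y1 + y2
      if (denom >= 0) return(rhoGrid[i])
      rhoGrid[i] + 0.5 * (y0 - y2) / denom * (rhoGrid[2] - rhoGrid[1])
    }, numeric(1))
    consensus <- tanh(mean(atanh(pmax(pmin(rhoHat, 0.99), -0.99))))
  }
  ## final GLS at the consensus rho, all responses at once
  Xw <- .csWhiten(X, subject, consensus)
  Yw <- .csWhiten(t(Yk), subject, consensus)
  qx <- qr(Xw)
  beta <- qr.coef(qx, Yw)
  rss <- colSums(qr.resid(qx, Yw)^2)
  dfRes <- n - pcol
  XtXinv <- chol2inv(qr.R(qx))
  gIdx <- match(paste0(".group", levels(group)[2]), colnames(X))
  se <- sqrt(XtXinv[gIdx, gIdx] * rss / dfRes)
  est <- beta[gIdx, ]
  tt <- est / se
  pv <- 2 * stats::pt(-abs(tt), dfRes)
  out <- data.frame(response = rownames(Y), estimate = NA_real_,
                    se = NA_real_, tstat = NA_real_, pvalue = NA_real_,
                    qvalue = NA_real_, rho = NA_real_,
                    stringsAsFactors = FALSE)
  out$estimate[keep] <- est; out$se[keep] <- se; out$tstat[keep] <- tt
  out$pvalue[keep] <- pv
  out$qvalue[keep] <- bhFdr(pv)
  out$rho[keep] <- rhoHat
  attr(out, "consensusRho") <- consensus
  attr(out, "coding") <- paste(levels(group)[2], "vs", levels(group)[1])
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (via \code{p.adjust}).
#'
#' @param pvalues numeric in [0, 1].
#' @return q-values, same length and order.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank-based AUC with midrank tie handling
#'
#' Mann-Whitney area under the ROC curve: the probability that a randomly
#' chosen positive scores above a randomly chosen negative, ties counted as
#' half.
#'
#' @param scores numeric scores.
#' @param labels logical (or two-level) positive-class indicator.
#' @return AUC in [0, 1].
#' @export
rankAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Fisher's exact test for r x c tables
#'
#' Exact (hypergeometric/network enumeration) when the table total is at
#' most \code{exactMax}; larger tables fall back to a seeded Monte-Carlo
#' estimate, flagged in the result. Degenerate margins give p = 1.
#'
#' @param tab matrix of non-negative integer counts (>= 2x2).
#' @param exactMax largest total for exact computation (default 500).
#' @param mcReplicates Monte-Carlo draws (default 1e5).
#' @param seed seed for the Monte-Carlo path.
#' @return list: \code{pvalue}, \code{method} ("exact", "monte-carlo" or
#'   "degenerate").
#' @export
fisherExact <- function(tab, exactMax = 500, mcReplicates = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(pvalue = 1, method = "degenerate"))
  if (sum(tab) <= exactMax) {
    list(pvalue = stats::fisher.test(tab)$p.value, method = "exact")
  } else {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE,
                            B = mcReplicates)$p.value
    list(pvalue = p, method = "monte-carlo")
  }
}

#' Over-representation of a gene list in pathway sets
#'
#' One-sided Fisher enrichment of the module genes against each pathway on
#' the 2x2 overlap table within the gene universe, with BH correction across
#' pathways. Pathways with no gene in the universe are skipped and reported.
#'
#' @param genes module gene list (must be within \code{universe}).
#' @param pathways named list of gene sets.
#' @param universe background gene IDs.
#' @return data.frame: pathway, overlap, size, oddsRatio, pvalue, qvalue;
#'   skipped pathways in attribute \code{skipped}.
#' @export
setEnrichment <- function(genes, pathways, universe) {
  if (!all(genes %in% universe)) stop("genes must be a subset of universe")
  genes <- unique(genes); universe <- unique(universe)
  skipped <- character(0)
  rows <- list()
  for (p in names(pathways)) {
    pw <- intersect(pathways[[p]], universe)
    if (!length(pw)) { skipped <- c(skipped, p); next }
    a <- length(intersect(genes, pw))
    b <- length(setdiff(genes, pw))
    c <- length(setdiff(pw, genes))
    d <- length(universe) - a - b - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2),
                             alternative = "greater")
    rows[[p]] <- data.frame(pathway = p, overlap = a, size = length(pw),
                            oddsRatio = unname(ft$estimate),
                            pvalue = ft$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(pathway = character(0), overlap = integer(0),
                      size = integer(0), oddsRatio = numeric(0),
                      pvalue = numeric(0), qvalue = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$qvalue <- bhFdr(out$pvalue)
  }
  attr(out, "skipped") <- skipped
  out
}
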