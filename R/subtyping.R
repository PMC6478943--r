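#' Consensus clustering of samples by subsampled PAM
#'
#' For each k in 2..kMax and each iteration, a fraction of samples is drawn
#' without replacement and partitioned around medoids (PAM, deterministic
#' BUILD + SWAP) on the distance 1 - Pearson correlation between sample
#' profiles over the selected genes; the consensus entry for a pair is its
#' co-clustering count divided by its co-sampling count. The full distance
#' matrix is computed once and subset per iteration. Pairs never co-sampled
#' (possible only for tiny n) are set to 0 and counted.
#'
#' @param expr LesionExperiment (residual scale recommended).
#' @param genes gene IDs to cluster on (default: all).
#' @param kMax largest k (default 10).
#' @param iters subsampling iterations (default 1000).
#' @param subsample subsampled fraction (default 0.8).
#' @param seed RNG seed for the subsampling stream.
#' @param exhaustive if TRUE, enumerate every subsample of size
#'   ceiling(subsample * n) exactly once instead of random draws (feasible
#'   only for small n; makes the consensus matrix deterministic).
#' @return a \linkS4class{ConsensusResult} with consensus matrices, CDF
#'   areas A(k), relative changes Delta(k) and PAC(k); \code{chosenK} unset.
#' @export
consensusCluster <- function(expr, genes = NULL, kMax = 10, iters = 1000,
                             subsample = 0.8, seed = 1L, exhaustive = FALSE) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  n <- ncol(x)
  if (kMax >= n) stop("kMax must be smaller than the number of samples")
  D <- 1 - stats::cor(x)
  m <- ceiling(subsample * n)
  if (exhaustive) {
    subs <- utils::combn(n, m, simplify = FALSE)
  } else {
    set.seed(seed)
    subs <- lapply(seq_len(iters), function(i) sample.int(n, m))
  }
  coSampled <- matrix(0L, n, n)
  for (s in subs) coSampled[s, s] <- coSampled[s, s] + 1L
  neverCo <- sum(coSampled[upper.tri(coSampled)] == 0L)
  if (neverCo > 0)
    warning(neverCo, " sample pair(s) never co-sampled; consensus set to 0")
  consensus <- list()
  for (k in 2:kMax) {
    co <- matrix(0L, n, n)
    for (s in subs) {
      cl <- cluster::pam(stats::as.dist(D[s, s]), k = k, diss = TRUE,
                         cluster.only = TRUE)
      for (g in unique(cl)) {
        idx <- s[cl == g]
        co[idx, idx] <- co[idx, idx] + 1L
      }
    }
    cons <- ifelse(coSampled > 0, co / coSampled, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(x), colnames(x))
    consensus[[as.character(k)]] <- cons
  }
  areas <- vapply(consensus, .cdfArea, numeric(1))
  pac <- vapply(consensus, .pacScore, numeric(1))
  ks <- as.integer(names(consensus))
  delta <- numeric(length(ks)); names(delta) <- names(consensus)
  for (i in seq_along(ks)) {
    delta[i] <- if (ks[i] == 2L) areas[i]
    else if (areas[i - 1] == 0) {
      warning("A(k-1) = 0 at k = ", ks[i], "; Delta undefined, skipped")
      NA_real_
    } else (areas[i] - areas[i - 1]) / areas[i - 1]
  }
  new("ConsensusResult", consensus = consensus, cdfArea = areas,
      delta = delta, pac = pac, chosenK = NA_integer_,
      assignments = integer(0), subtypeNames = character(0),
      provenance = list(kMax = kMax, iters = if (exhaustive) length(subs)
                        else iters, subsample = subsample, seed = seed,
                        exhaustive = exhaustive, distance = "1 - Pearson",
                        algorithm = "PAM (BUILD + SWAP)",
                        neverCoSampledPairs = neverCo))
}

#' Area under the empirical CDF of the upper-triangle consensus entries
#' (step integration over [0, 1])
#' @keywords internal
.cdfArea <- function(M) {
  v <- sort(M[upper.tri(M)])
  xs <- unique(c(v, 1))
  cdf <- stats::ecdf(v)
  sum(diff(c(0, xs)) * cdf(c(0, xs[-length(xs)])))
}

#' Proportion of ambiguous clustering: share of pairs with consensus
#' strictly between the limits
#' @keywords internal
.pacScore <- function(M, lower = 0.1, upper = 0.9) {
  v <- M[upper.tri(M)]
  mean(v > lower & v < upper)
}

#' Choose the number of clusters from consensus CDF areas
#'
#' A(k) is the area under the empirical CDF of the consensus entries;
#' Delta(2) = A(2) and Delta(k) = (A(k) - A(k-1)) / A(k-1) for k > 2. The
#' chosen k is the largest one whose relative area gain is at least
#' \code{delta} and whose proportion of ambiguous clustering (consensus
#' entries between 0.1 and 0.9) is at most \code{pacMax}; the ambiguity
#' guard rejects the spurious area gains produced by splitting a genuine
#' cluster. If no k qualifies, the k with minimal PAC is returned. The rule
#' and parameters are recorded in the result's provenance.
#'
#' @param result a \linkS4class{ConsensusResult} with at least 3 k values.
#' @param delta relative area-gain threshold (default 0.05).
#' @param pacMax ambiguity ceiling (default 0.1; set to 1 for the pure
#'   Delta rule).
#' @return the result with \code{chosenK} set.
#' @export
selectK <- function(result, delta = 0.05, pacMax = 0.1) {
  stopifnot(is(result, "ConsensusResult"))
  if (length(result@consensus) < 3) stop("need at least 3 k values")
  ks <- as.integer(names(result@delta))
  ok <- !is.na(result@delta) & result@delta >= delta & result@pac <= pacMax
  chosen <- if (any(ok)) max(ks[ok]) else ks[which.min(result@pac)]
  result@chosenK <- as.integer(chosen)
  result@provenance <- c(result@provenance,
                         list(selection = list(rule = "delta+pac",
                                               delta = delta,
                                               pacMax = pacMax)))
  result
}

#' Final cluster assignments from the consensus matrix
#'
#' Average-linkage hierarchical clustering of 1 - consensus, cut at the
#' chosen k.
#'
#' @param result a \linkS4class{ConsensusResult}.
#' @param chosenK number of clusters (default: the result's chosenK).
#' @return the result with \code{assignments} filled (named integer).
#' @export
finalizeAssignments <- function(result, chosenK = result@chosenK) {
  stopifnot(is(result, "ConsensusResult"), !is.na(chosenK))
  M <- result@consensus[[as.character(chosenK)]]
  if (is.null(M)) stop("no consensus matrix at k = ", chosenK)
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  cl <- stats::cutree(hc, k = chosenK)
  result@chosenK <- as.integer(chosenK)
  result@assignments <- stats::setNames(as.integer(cl), colnames(M))
  result
}

#' Name clusters by their module activity pattern
#'
#' Runs a one-vs-rest repeated-measures association of each module's
#' per-sample scores against each cluster (subject as random effect where
#' subject IDs are supplied), marks each module up/down/neutral per cluster
#' from the sign of significant (BH FDR < fdr) effects, and matches the
#' resulting direction vectors to an expected subtype pattern. A cluster is
#' given a label when it agrees with the label's non-neutral entries better
#' than any other cluster; clusters matching no label are "unmatched" and
#' ties are reported as ambiguous rather than silently broken.
#'
#' @param result \linkS4class{ConsensusResult} with assignments.
#' @param scores gene-set-by-sample score matrix (e.g. from
#'   \code{\link{gsvaScores}}), columns covering all assigned samples.
#' @param subject optional named subject IDs for the random effect.
#' @param pattern expected subtype-by-module direction matrix; rownames are
#'   the candidate labels (default \code{\link{subtypePattern}()}). Its
#'   columns are matched positionally to the score rows.
#' @param fdr significance level for calling a direction (default 0.05).
#' @return the result with \code{subtypeNames} set; the direction table and
#'   match scores are appended to provenance.
#' @export
annotateSubtypes <- function(result, scores, subject = NULL,
                             pattern = subtypePattern(), fdr = 0.05) {
  stopifnot(is(result, "ConsensusResult"), length(result@assignments) > 0)
  cl <- result@assignments
  sam <- names(cl)
  if (!all(sam %in% colnames(scores)))
    stop("scores missing for some assigned samples")
  scores <- scores[, sam, drop = FALSE]
  nm <- nrow(scores)
  kk <- sort(unique(cl))
  dir <- matrix(0L, length(kk), nm,
                dimnames = list(paste0("cluster", kk), rownames(scores)))
  subj <- if (is.null(subject)) stats::setNames(sam, sam) else subject[sam]
  for (i in seq_along(kk)) {
    grp <- factor(ifelse(cl == kk[i], "in", "out"), levels = c("out", "in"))
    as <- mixedAssociation(scores, grp, subj)
    sig <- as$qvalue < fdr
    dir[i, sig] <- ifelse(as$estimate[sig] > 0, 1L, -1L)
  }
  usePat <- pattern[, seq_len(min(ncol(pattern), nm)), drop = FALSE]
  agree <- matrix(0, length(kk), nrow(usePat),
                  dimnames = list(rownames(dir), rownames(usePat)))
  for (l in rownames(usePat)) {
    nz <- which(usePat[l, ] != 0)
    agree[, l] <- vapply(seq_along(kk), function(i)
      sum(dir[i, nz] == usePat[l, nz]) - sum(dir[i, nz] == -usePat[l, nz]),
      numeric(1))
  }
  labels <- stats::setNames(rep("unmatched", length(kk)), rownames(dir))
  for (l in colnames(agree)) {
    best <- max(agree[, l])
    if (best <= 0) next
    winners <- rownames(agree)[agree[, l] == best]
    if (length(winners) > 1) {
      labels[winners] <- paste0(l, " (ambiguous)")
      warning("label ", l, " matches several clusters: ",
              paste(winners, collapse = ", "))
    } else labels[winners] <- l
  }
  result@subtypeNames <- stats::setNames(labels,
                                         as.character(kk))
  result@provenance <- c(result@provenance,
                         list(directionTable = dir, patternAgreement = agree))
  result
}
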