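#' Soft-threshold selection by the scale-free topology criterion
#'
#' For each candidate power beta the network connectivity
#' \eqn{k_i = \sum_j |r_{ij}|^\beta} is computed (self-correlation excluded)
#' and the scale-free fit is the R-squared of a regression of log10 binned
#' connectivity frequency on log10 mean binned connectivity, signed negative
#' when the slope is positive. The smallest power reaching \code{fitTarget}
#' is returned. When no candidate reaches the target -- typical of
#' block-structured networks, which are not scale-free -- the selection
#' falls back to the sample-size-based default power rather than chasing the
#' spuriously scale-free high-power regime, mirroring standard practice for
#' the method.
#'
#' @param expr LesionExperiment (typically residualized).
#' @param powers candidate powers.
#' @param fitTarget signed R-squared target (default 0.80).
#' @param nBins connectivity histogram bins (default 10).
#' @param minMeanK powers whose mean connectivity falls below this floor are
#'   ineligible (default 2): a network so sparse that the average node is
#'   near-disconnected looks spuriously scale-free.
#' @param defaultPower fallback power; if NULL, set from the sample count
#'   (6 for n >= 40, 7 for 30-39, 8 for 20-29, 9 below 20).
#' @return list: \code{power}, and a data.frame \code{fitTable} with the
#'   signed R-squared and mean connectivity per candidate.
#' @export
pickSoftPower <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                          fitTarget = 0.80, nBins = 10, minMeanK = 2,
                          defaultPower = NULL) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  if (is.null(defaultPower)) {
    n <- ncol(x)
    defaultPower <- if (n >= 40) 6 else if (n >= 30) 7 else if (n >= 20) 8
                    else 9
  }
  if (nrow(x) < 3) {
    warning("fewer than 3 genes: soft-power selection degenerate, ",
            "returning default power ", defaultPower)
    return(list(power = defaultPower, fitTable = NULL))
  }
  r <- abs(stats::cor(t(x)))
  diag(r) <- 0
  fit <- vapply(powers, function(b) {
    k <- rowSums(r^b)
    k <- k[k > 0]
    if (length(k) < 2) return(c(NA_real_, NA_real_))
    br <- seq(min(k), max(k), length.out = nBins + 1)
    bin <- findInterval(k, br, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nBins)
    km <- vapply(seq_len(nBins), function(i) mean(k[bin == i]), numeric(1))
    use <- cnt > 0
    if (sum(use) < 2) return(c(NA_real_, NA_real_))
    lx <- log10(km[use]); ly <- log10(cnt[use] / length(k))
    f <- stats::lm(ly ~ lx)
    r2 <- summary(f)$r.squared
    sl <- stats::coef(f)[2]
    c(if (sl > 0) -r2 else r2, mean(k))
  }, numeric(2))
  tab <- data.frame(power = powers, signedR2 = fit[1, ], meanK = fit[2, ])
  eligible <- !is.na(tab$signedR2) & tab$meanK >= minMeanK
  if (!any(eligible)) {
    warning("no candidate power with a usable connectivity distribution; ",
            "falling back to default power ", defaultPower)
    return(list(power = defaultPower, fitTable = tab))
  }
  ok <- which(eligible & tab$signedR2 >= fitTarget)
  p <- if (length(ok)) powers[min(ok)] else defaultPower
  list(power = p, fitTable = tab)
}

#' Topological overlap from an adjacency matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'       {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_u a_{iu}}; the diagonal is set to 1.
#'
#' @param adjacency symmetric gene-by-gene matrix in [0, 1] (diagonal
#'   ignored and treated as zero).
#' @return symmetric topological-overlap matrix with unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(a) <- 0
  if (any(a < 0 | a > 1)) stop("adjacency values outside [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Sum the internal merge heights and member leaves of each dendrogram node
#' @keywords internal
.treeIndex <- function(hc) {
  n <- length(hc$height) + 1L
  members <- vector("list", n - 1L)
  hsum <- numeric(n - 1L); hcnt <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    ch <- hc$merge[i, ]
    mem <- integer(0); hs <- hc$height[i]; hk <- 1L
    for (c in ch) {
      if (c < 0) mem <- c(mem, -c)
      else {
        mem <- c(mem, members[[c]])
        hs <- hs + hsum[c]; hk <- hk + hcnt[c]
      }
    }
    members[[i]] <- mem; hsum[i] <- hs; hcnt[i] <- hk
  }
  list(members = members, hsum = hsum, hcnt = hcnt)
}

#' Detect co-expression modules by tree cutting of topological overlap
#'
#' Builds an unsigned weighted network (|Pearson r| to the chosen soft
#' power), computes topological overlap, clusters genes by average-linkage
#' on 1 - TOM and cuts the tree: a static cut just below the top plateau of
#' merge heights, with additional descent splitting of branches
#' whose joining height sits well above their internal structure,
#' a branch-quality criterion requiring the branch's mean internal height to
#' sit clearly below the cut (so featureless noise yields no modules), and a
#' core trim dropping loosely attached genes. Modules smaller than
#' \code{minModuleSize} are left unassigned; modules whose eigengenes
#' correlate above \code{1 - mergeCut} are merged iteratively.
#'
#' @param expr LesionExperiment (residual scale recommended).
#' @param power soft threshold; chosen by \code{\link{pickSoftPower}} if NULL.
#' @param tom optional precomputed TOM matrix (rows/cols = genes of expr).
#' @param minModuleSize smallest reported module (default 30).
#' @param mergeCut eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param splitGap a branch is split further while its joining height
#'   exceeds its mean internal merge height by at least this much
#'   (default 0.15).
#' @param minGap minimum clearance between branch scatter and the cut height
#'   for a branch to count as a module (default 0.05).
#' @param plateauFrac fraction of the merge-height range by which the static
#'   cut is forced below the maximum height (default 0.03), so the
#'   featureless top plateau is always separated.
#' @param sourceDataset name recorded in the result.
#' @return a \linkS4class{ModuleSet}; zero modules is a valid outcome.
#' @export
detectModules <- function(expr, power = NULL, tom = NULL,
                          minModuleSize = 30, mergeCut = 0.25,
                          splitGap = 0.15, minGap = 0.05,
                          plateauFrac = 0.03, sourceDataset = "dataset") {
  stopifnot(is(expr, "LesionExperiment"), minModuleSize >= 2)
  x <- exprValues(expr)
  if (is.null(tom)) {
    if (is.null(power)) power <- pickSoftPower(expr)$power
    a <- abs(stats::cor(t(x)))^power
    diag(a) <- 0
    tom <- tomSimilarity(a)
  } else if (is.null(power)) power <- NA_real_
  d <- 1 - tom
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hts <- hc$height
  ## static cut just below the dendrogram's top plateau: featureless joins
  ## and cross-module joins pile up under the maximum merge height
  cutH <- max(hts) - plateauFrac * (max(hts) - min(hts))
  idx <- .treeIndex(hc)
  nNode <- length(hts)

  branches <- list()
  descend <- function(node) {
    if (node < 0) return(invisible(NULL))
    ## core scatter: mean internal merge height of the branch (incl. node)
    scatter <- idx$hsum[node] / idx$hcnt[node]
    if (hts[node] > cutH || hts[node] - scatter >= splitGap) {
      ch <- hc$merge[node, ]
      descend(ch[1]); descend(ch[2])
    } else {
      branches[[length(branches) + 1L]] <<- idx$members[[node]]
    }
  }
  descend(nNode)

  gn <- rownames(x)
  mods <- list()
  for (mem in branches) {
    if (length(mem) < minModuleSize) next
    dd <- d[mem, mem, drop = FALSE]
    scatter <- mean(dd[upper.tri(dd)])
    if (cutH - scatter < minGap) next
    ## core trim: drop genes far from the branch core
    di <- (rowSums(dd)) / (length(mem) - 1)
    thr <- 0.5 * (stats::median(di) + cutH)
    core <- mem[di <= thr]
    if (length(core) < minModuleSize) next
    mods[[length(mods) + 1L]] <- gn[core]
  }
  if (!length(mods)) {
    message("no cluster reached the minimum module size; empty module list")
    return(new("ModuleSet", genes = list(),
               eigengenes = matrix(numeric(0), ncol(x), 0,
                                   dimnames = list(colnames(x), NULL)),
               varExplained = numeric(0),
               sourceDataset = sourceDataset, power = as.numeric(power)))
  }
  ## eigengene merging
  repeat {
    egs <- lapply(mods, function(g) moduleEigengene(expr, g)$eigengene)
    if (length(mods) < 2) break
    E <- do.call(cbind, egs)
    cc <- stats::cor(E); diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - mergeCut) break
    i <- min(top); j <- max(top)
    mods[[i]] <- c(mods[[i]], mods[[j]])
    mods[[j]] <- NULL
  }
  o <- order(lengths(mods), decreasing = TRUE)
  mods <- mods[o]
  names(mods) <- paste0("m", seq_along(mods))
  eg <- lapply(mods, function(g) moduleEigengene(expr, g))
  E <- do.call(cbind, lapply(eg, `[[`, "eigengene"))
  colnames(E) <- names(mods)
  new("ModuleSet", genes = mods, eigengenes = E,
      varExplained = stats::setNames(
        vapply(eg, `[[`, numeric(1), "varExplained"), names(mods)),
      sourceDataset = sourceDataset, power = as.numeric(power))
}

#' Module eigengene (first principal component of z-scored members)
#'
#' Each member gene is standardized across samples; the eigengene is the
#' first principal component over samples, rescaled to unit variance with
#' its sign aligned so it correlates non-negatively with the module's mean
#' expression profile.
#'
#' @param expr LesionExperiment.
#' @param genes gene IDs of the module (all must be present).
#' @return list: \code{eigengene} (named per sample) and \code{varExplained}.
#' @export
moduleEigengene <- function(expr, genes) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) stop("genes absent from matrix: ",
                         paste(miss, collapse = ", "))
  z <- t(scale(t(x[genes, , drop = FALSE])))      # z-score each gene
  if (length(genes) == 1L) {
    e <- drop(z)
    return(list(eigengene = stats::setNames(e / stats::sd(e), colnames(x)),
                varExplained = 1))
  }
  sv <- svd(t(z))                                 # samples x genes
  e <- sv$u[, 1] * sv$d[1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  e <- e / stats::sd(e)
  list(eigengene = stats::setNames(e, colnames(x)), varExplained = ve)
}
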