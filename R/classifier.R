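#' Allocate marker genes to modules inversely to their mean r-squared
#'
#' For every gene in the supplied module gene lists, the squared Pearson
#' correlation to each module eigengene is computed; a gene is retained in
#' its module only when its highest r-squared is to that module's own
#' eigengene. Each module's share of the marker panel is inversely
#' proportional to the mean r-squared of its retained genes (modules whose
#' genes track the eigengene tightly need fewer markers), converted to
#' integer counts by largest-remainder rounding with a floor of one gene per
#' module that retained any; within a module the top-r-squared genes fill
#' its slots.
#'
#' @param expr LesionExperiment the eigengenes were computed in.
#' @param moduleGenes named list, module -> gene IDs.
#' @param eigengenes samples-by-modules matrix (columns matching
#'   \code{names(moduleGenes)}).
#' @param panelSize total markers (default 22).
#' @return list: \code{panel} (ordered gene vector), \code{panelModule}
#'   (module of each panel gene), \code{allocation} (per-module counts),
#'   \code{meanR2}, \code{retained} (per-module retained genes with r2).
#' @export
allocatePanelGenes <- function(expr, moduleGenes, eigengenes,
                               panelSize = 22) {
  stopifnot(is(expr, "LesionExperiment"),
            all(names(moduleGenes) %in% colnames(eigengenes)))
  x <- exprValues(expr)
  mods <- names(moduleGenes)
  retained <- list()
  for (m in mods) {
    g <- intersect(moduleGenes[[m]], rownames(x))
    if (!length(g)) { retained[[m]] <- numeric(0); next }
    r2 <- stats::cor(t(x[g, , drop = FALSE]),
                     eigengenes[colnames(x), mods, drop = FALSE])^2
    own <- r2[, m]
    best <- apply(r2, 1, which.max)
    keep <- mods[best] == m
    retained[[m]] <- sort(own[keep], decreasing = TRUE)
  }
  hasGenes <- lengths(retained) > 0
  if (!any(hasGenes)) stop("no module retained any gene")
  if (any(!hasGenes))
    warning("module(s) with no retained genes allocated 0 markers: ",
            paste(mods[!hasGenes], collapse = ", "))
  active <- mods[hasGenes]
  if (panelSize < length(active))
    stop("panelSize smaller than the number of modules with retained genes")
  meanR2 <- vapply(retained[active], mean, numeric(1))
  nAlloc <- allocateMarkerCounts(meanR2, panelSize)
  nAlloc <- pmin(nAlloc, lengths(retained[active]))
  ideal <- panelSize * (1 / meanR2) / sum(1 / meanR2)
  short <- panelSize - sum(nAlloc)
  while (short > 0) {                 # redistribute if a module ran out
    room <- which(nAlloc < lengths(retained[active]))
    if (!length(room)) break
    give <- room[which.max(ideal[room] - nAlloc[room])]
    nAlloc[give] <- nAlloc[give] + 1
    short <- short - 1
  }
  panel <- character(0); panelModule <- character(0)
  for (m in active) {
    g <- names(retained[[m]])[seq_len(nAlloc[m])]
    panel <- c(panel, g)
    panelModule <- c(panelModule, stats::setNames(rep(m, length(g)), g))
  }
  list(panel = panel, panelModule = panelModule,
       allocation = stats::setNames(as.integer(nAlloc), active),
       meanR2 = meanR2, retained = retained)
}

#' Integer marker counts inversely proportional to module mean r-squared
#'
#' Shares proportional to 1/meanR2 are converted to integers by
#' largest-remainder rounding; every module receives at least one marker
#' (seats taken from the largest allocation when needed). Deterministic
#' tie-breaks follow module order.
#'
#' @param meanR2 named positive numeric, mean r-squared per module.
#' @param panelSize total markers; must be >= length(meanR2).
#' @return named integer allocation summing to \code{panelSize}.
#' @export
allocateMarkerCounts <- function(meanR2, panelSize) {
  stopifnot(all(meanR2 > 0), panelSize >= length(meanR2))
  w <- (1 / meanR2) / sum(1 / meanR2)
  ideal <- panelSize * w
  nAlloc <- floor(ideal)
  rem <- panelSize - sum(nAlloc)
  if (rem > 0) {
    o <- order(ideal - nAlloc, decreasing = TRUE)[seq_len(rem)]
    nAlloc[o] <- nAlloc[o] + 1
  }
  while (any(nAlloc == 0)) {
    z <- which(nAlloc == 0)[1]
    donor <- which.max(nAlloc)
    nAlloc[donor] <- nAlloc[donor] - 1
    nAlloc[z] <- 1
  }
  stats::setNames(as.integer(nAlloc), names(meanR2))
}

#' @keywords internal
.centroidStats <- function(z, labels, epsilon = 1e-6) {
  classes <- sort(unique(labels))
  cent <- do.call(rbind, lapply(classes, function(cl)
    rowMeans(z[, labels == cl, drop = FALSE])))
  dimnames(cent) <- list(classes, rownames(z))
  ssw <- matrix(0, nrow(z), 1)
  for (cl in classes) {
    zc <- z[, labels == cl, drop = FALSE]
    ssw <- ssw + rowSums((zc - cent[cl, ])^2)
  }
  sd <- sqrt(ssw / (ncol(z) - length(classes)))
  if (any(sd < epsilon)) {
    warning("pooled SD floored at ", epsilon, " for ",
            sum(sd < epsilon), " gene(s)")
    sd[sd < epsilon] <- epsilon
  }
  priors <- table(labels)[classes] / length(labels)
  list(centroids = cent, pooledSD = drop(sd),
       priors = stats::setNames(as.numeric(priors), classes))
}

#' @keywords internal
.centroidPredict <- function(z, centroids, pooledSD, priors) {
  classes <- rownames(centroids)
  scores <- vapply(classes, function(cl)
    colSums((z - centroids[cl, ])^2 / pooledSD^2) - 2 * log(priors[cl]),
    numeric(ncol(z)))
  scores <- matrix(scores, ncol = length(classes),
                   dimnames = list(colnames(z), classes))
  idx <- apply(scores, 1, which.min)
  tie <- apply(scores, 1, function(s) sum(s == min(s)) > 1)
  list(labels = stats::setNames(classes[idx], colnames(z)),
       scores = scores, ties = tie)
}

#' Train a nearest-centroid subtype classifier (zero shrinkage)
#'
#' Panel expression is z-scored per gene across the training samples; class
#' centroids are the class means, with a pooled within-class SD per gene and
#' class-frequency priors. The discriminant is the pooled-SD-scaled squared
#' distance minus twice the log prior (the shrunken-centroid form at
#' threshold zero).
#'
#' @param expr training LesionExperiment.
#' @param labels named class labels covering the training samples.
#' @param panel marker genes (e.g. from \code{\link{allocatePanelGenes}}).
#' @param panelModule optional module provenance of the panel genes.
#' @return a \linkS4class{CentroidModel}.
#' @export
trainNearestCentroid <- function(expr, labels, panel,
                                 panelModule = character(0)) {
  stopifnot(is(expr, "LesionExperiment"))
  x <- exprValues(expr)
  miss <- setdiff(panel, rownames(x))
  if (length(miss)) stop("panel genes missing: ", paste(miss, collapse = ", "))
  labels <- labels[colnames(x)]
  if (anyNA(labels)) stop("labels missing for some samples")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 classes with >= 2 samples each")
  xm <- x[panel, , drop = FALSE]
  mu <- rowMeans(xm); sd <- apply(xm, 1, stats::sd)
  z <- (xm - mu) / sd
  st <- .centroidStats(z, labels)
  new("CentroidModel", panel = panel,
      panelModule = if (length(panelModule)) panelModule[panel]
                    else stats::setNames(rep(NA_character_, length(panel)),
                                         panel),
      centroids = st$centroids, pooledSD = st$pooledSD, priors = st$priors,
      trainLabels = stats::setNames(as.character(labels), colnames(x)),
      normalization = list(zMean = mu, zSd = sd, batchAdjusted = FALSE))
}

#' Predict subtypes with joint batch adjustment of train and test
#'
#' The panel expression of the training and test sets is combined; when more
#' than one cohort is present the combined matrix is batch-adjusted by the
#' parametric empirical-Bayes location/scale procedure (cohort as batch) and
#' then z-scored per gene across the combined data. Centroids, pooled SDs
#' and priors are re-estimated from the renormalized training samples using
#' the model's stored labels, and each test sample is assigned the class
#' minimizing the pooled-SD-scaled squared distance minus twice the log
#' prior. Ties are broken by class order and flagged.
#'
#' @param model a \linkS4class{CentroidModel}.
#' @param test,train LesionExperiment with the panel genes present; cohort
#'   is read from metadata column \code{cohort} (test and train fall back to
#'   "test"/"train" when absent).
#' @return list: \code{labels}, \code{scores} (sample-by-class discriminant),
#'   \code{ties}, \code{normalization} record.
#' @export
predictSubtype <- function(model, test, train) {
  stopifnot(is(model, "CentroidModel"),
            is(test, "LesionExperiment"), is(train, "LesionExperiment"))
  missT <- setdiff(model@panel, rownames(exprValues(test)))
  if (length(missT)) stop("panel genes missing in test: ",
                          paste(missT, collapse = ", "))
  xtr <- exprValues(train)[model@panel, , drop = FALSE]
  xte <- exprValues(test)[model@panel, , drop = FALSE]
  cohortOf <- function(le, fallback) {
    md <- sampleInfo(le)
    if ("cohort" %in% colnames(md)) as.character(md$cohort)
    else rep(fallback, ncol(le))
  }
  batch <- c(cohortOf(train, "train"), cohortOf(test, "test"))
  comb <- cbind(xtr, xte)
  colnames(comb) <- make.unique(colnames(comb))
  adjusted <- length(unique(batch)) > 1
  if (adjusted)
    comb <- sva::ComBat(comb, batch = factor(batch))
  z <- (comb - rowMeans(comb)) / apply(comb, 1, stats::sd)
  nTr <- ncol(xtr)
  ztr <- z[, seq_len(nTr), drop = FALSE]
  zte <- z[, nTr + seq_len(ncol(xte)), drop = FALSE]
  colnames(zte) <- colnames(xte)
  st <- .centroidStats(ztr, model@trainLabels[colnames(xtr)])
  pr <- .centroidPredict(zte, st$centroids, st$pooledSD, st$priors)
  if (any(pr$ties))
    warning(sum(pr$ties), " tie(s) broken by class order")
  c(pr, list(normalization = list(batchAdjusted = adjusted,
                                  batches = unique(batch))))
}

#' Train the two-class subtype-presence classifier on a panel subset
#'
#' Collapses the multiclass labels to \code{targetClass} vs the rest and
#' trains a nearest-centroid model on the panel genes whose module
#' provenance falls in \code{modulesSubset} (the compact marker set used to
#' call the Proliferative subtype from airway brushes uses the panel genes of
#' modules 4-7).
#'
#' @param expr training LesionExperiment.
#' @param labels named multiclass labels.
#' @param panel marker genes; \code{panelModule} their module provenance.
#' @param panelModule named character, gene -> module.
#' @param modulesSubset modules whose panel genes form the sub-panel.
#' @param targetClass positive class (default "Proliferative").
#' @return a two-class \linkS4class{CentroidModel}.
#' @export
trainPresenceClassifier <- function(expr, labels, panel, panelModule,
                                    modulesSubset = c("M4", "M5", "M6", "M7"),
                                    targetClass = "Proliferative") {
  sub <- panel[panelModule[panel] %in% modulesSubset]
  if (!length(sub)) stop("sub-panel empty: no panel genes in ",
                         paste(modulesSubset, collapse = ", "))
  bin <- stats::setNames(ifelse(labels == targetClass, targetClass,
                                paste0("not-", targetClass)), names(labels))
  trainNearestCentroid(expr, bin, sub, panelModule)
}

#' Evaluate brush-based presence predictions against matched biopsies
#'
#' A brush's ground truth is positive iff at least one biopsy sharing its
#' subject + procedure key carries the target subtype. Brushes with no
#' matched biopsy are excluded and counted.
#'
#' @param brushPredictions named character predictions per brush (the
#'   positive class as in \code{targetClass}).
#' @param biopsySubtypes named character subtype per biopsy.
#' @param brushKey,biopsyKey named character matching keys (subject +
#'   procedure) for brushes and biopsies.
#' @param targetClass positive class (default "Proliferative").
#' @return list: sensitivity, specificity, confusion (2x2 table),
#'   nUnmatched.
#' @export
evaluateBrushPrediction <- function(brushPredictions, biopsySubtypes,
                                    brushKey, biopsyKey,
                                    targetClass = "Proliferative") {
  brushes <- names(brushPredictions)
  keys <- brushKey[brushes]
  truth <- vapply(keys, function(kk) {
    hits <- biopsySubtypes[biopsyKey == kk]
    if (!length(hits)) NA else any(hits == targetClass)
  }, logical(1))
  unmatched <- is.na(truth)
  truth <- truth[!unmatched]
  pred <- brushPredictions[!unmatched] == targetClass
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                          dimnames = list(truth = c("positive", "negative"),
                                          predicted = c("positive",
                                                        "negative"))),
       nUnmatched = sum(unmatched))
}
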