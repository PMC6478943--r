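# training data with per-module gene-to-eigengene correlations under control
panelFixture <- function(nPerModule = 8, nSamples = 60, nModules = 4,
                         loading = 2, seed = 1) {
  set.seed(seed)
  mods <- list(); rows <- list(); eg <- matrix(0, nSamples, nModules)
  gid <- 0
  for (m in seq_len(nModules)) {
    f <- rnorm(nSamples)
    g <- sprintf("g%03d", gid + seq_len(nPerModule)); gid <- gid + nPerModule
    rows[[m]] <- t(sapply(seq_len(nPerModule), function(i)
      loading * f + rnorm(nSamples)))
    rownames(rows[[m]]) <- g
    mods[[paste0("M", m)]] <- g
    eg[, m] <- scale(f)
  }
  colnames(eg) <- names(mods)
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("s%03d", seq_len(nSamples))
  rownames(eg) <- colnames(x)
  list(le = makeLE(x), modules = mods, eigengenes = eg)
}

test_that("marker counts sum to the panel for arbitrary r-squared draws", {
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    r2 <- runif(k, 0.05, 0.99)
    panel <- sample(k:40, 1)
    n <- allocateMarkerCounts(r2, panel)
    expect_identical(sum(n), as.integer(panel))
    expect_true(all(n >= 1))
  }
})

test_that("equal r-squared gives near-equal allocations; halving one
          doubles its pre-rounding share", {
  n <- allocateMarkerCounts(rep(0.5, 9), 22)
  expect_identical(sum(n), 22L)
  expect_lte(diff(range(n)), 1)
  ## one module at half the (equal) mean r2: its ideal share is exactly
  ## double the others'
  r2 <- c(0.25, rep(0.5, 4))
  w <- (1 / r2) / sum(1 / r2)
  expect_equal(w[1], 2 * w[2], tolerance = 1e-12)
  n2 <- allocateMarkerCounts(r2, 12)
  expect_identical(sum(n2), 12L)
  expect_gt(n2[1], n2[2])
})

test_that("a panel the size of the module count takes each module's best
          gene", {
  fx <- panelFixture(seed = 2)
  alloc <- allocatePanelGenes(fx$le, fx$modules, fx$eigengenes,
                              panelSize = length(fx$modules))
  expect_identical(unname(alloc$allocation),
                   rep(1L, length(fx$modules)))
  x <- exprValues(fx$le)
  for (m in names(fx$modules)) {
    r2 <- sapply(fx$modules[[m]], function(g)
      cor(x[g, ], fx$eigengenes[, m])^2)
    ## brute-force scan: the chosen gene maximizes r2 among genes whose top
    ## module is m
    own <- vapply(fx$modules[[m]], function(g)
      which.max(vapply(colnames(fx$eigengenes), function(mm)
        cor(x[g, ], fx$eigengenes[, mm])^2, numeric(1))), integer(1))
    eligible <- fx$modules[[m]][colnames(fx$eigengenes)[own] == m]
    best <- eligible[which.max(r2[eligible])]
    chosen <- alloc$panel[alloc$panelModule[alloc$panel] == m]
    expect_identical(chosen, best)
  }
  expect_error(allocatePanelGenes(fx$le, fx$modules, fx$eigengenes,
                                  panelSize = 2), "smaller")
})

test_that("nearest-centroid training and the closed-form 1-gene boundary", {
  set.seed(3)
  n <- 40
  x <- matrix(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), 1,
              dimnames = list("g1", sprintf("s%02d", 1:n)))
  labels <- stats::setNames(rep(c("lo", "hi"), each = n / 2), colnames(x))
  le <- makeLE(x)
  model <- trainNearestCentroid(le, labels, "g1")
  ## equal priors, equal SD: the boundary is the centroid midpoint on the
  ## z scale
  mid <- mean(model@centroids[, "g1"])
  z <- (x[1, ] - mean(x[1, ])) / sd(x[1, ])
  pred <- AirwaySubtypes:::.centroidPredict(
    rbind(g1 = z), model@centroids, model@pooledSD, model@priors)$labels
  expected <- ifelse(z > mid, rownames(model@centroids)[which.max(
    model@centroids[, "g1"])], rownames(model@centroids)[which.min(
    model@centroids[, "g1"])])
  expect_identical(unname(pred), unname(expected))
  ## a sample exactly at a centroid belongs to that class
  zc <- rbind(g1 = model@centroids["hi", "g1"])
  colnames(zc) <- "probe"
  expect_identical(unname(AirwaySubtypes:::.centroidPredict(
    zc, model@centroids, model@pooledSD, model@priors)$labels), "hi")
  ## renaming classes renames the model only
  labels2 <- stats::setNames(ifelse(labels == "lo", "A", "B"), names(labels))
  m2 <- trainNearestCentroid(le, labels2, "g1")
  expect_equal(unname(m2@centroids[c("B", "A"), ]),
               unname(model@centroids[c("hi", "lo"), ]))
})

test_that("joint renormalization reproduces resubstitution on a copied test
          set and absorbs cohort shifts", {
  fx <- panelFixture(nPerModule = 6, nSamples = 80, seed = 4)
  x <- exprValues(fx$le)
  ## labels driven by the first module's eigengene quartiles
  lab <- cut(fx$eigengenes[, 1], breaks = quantile(fx$eigengenes[, 1],
                                                   c(0, .25, .5, .75, 1)),
             labels = paste0("c", 1:4), include.lowest = TRUE)
  labels <- stats::setNames(as.character(lab), colnames(x))
  panel <- unlist(fx$modules)
  model <- trainNearestCentroid(fx$le, labels, panel)
  ## direct resubstitution on the training z-scale
  z <- (x[panel, ] - rowMeans(x[panel, ])) / apply(x[panel, ], 1, sd)
  direct <- AirwaySubtypes:::.centroidPredict(
    z, model@centroids, model@pooledSD, model@priors)$labels
  same <- predictSubtype(model, fx$le, fx$le)
  expect_identical(same$labels, direct)
  ## a uniform per-gene shift on a copied cohort is removed by adjustment
  md2 <- data.frame(cohort = rep("other", ncol(x)),
                    row.names = colnames(x))
  shifted <- LesionExperiment(x + 3, md2, scale = scaleTag(fx$le))
  unshifted <- LesionExperiment(x, md2, scale = scaleTag(fx$le))
  trainMd <- LesionExperiment(
    x, data.frame(cohort = rep("train", ncol(x)), row.names = colnames(x)),
    scale = scaleTag(fx$le))
  predShift <- predictSubtype(model, shifted, trainMd)
  predPlain <- predictSubtype(model, unshifted, trainMd)
  ## empirical-Bayes shrinkage leaves a small gene-level residual of the
  ## shift, so agreement is near-perfect rather than exact
  expect_gte(mean(predShift$labels == predPlain$labels), 0.95)
})

test_that("the presence classifier equals the collapsed two-class model and
          swaps centroids under label inversion", {
  fx <- panelFixture(nPerModule = 6, nSamples = 80, seed = 5)
  lab <- ifelse(fx$eigengenes[, 1] > 0, "Proliferative", "other")
  labels <- stats::setNames(lab, colnames(exprValues(fx$le)))
  panel <- unlist(fx$modules)
  panelModule <- stats::setNames(rep(names(fx$modules),
                                     lengths(fx$modules)), panel)
  pm <- trainPresenceClassifier(fx$le, labels, panel, panelModule,
                                modulesSubset = names(fx$modules))
  bin <- stats::setNames(ifelse(labels == "Proliferative", "Proliferative",
                                "not-Proliferative"), names(labels))
  direct <- trainNearestCentroid(fx$le, bin, panel, panelModule)
  expect_equal(pm@centroids, direct@centroids)
  expect_equal(pm@pooledSD, direct@pooledSD)
  ## inverted labels swap the centroid rows
  inv <- stats::setNames(ifelse(bin == "Proliferative", "not-Proliferative",
                                "Proliferative"), names(bin))
  mInv <- trainNearestCentroid(fx$le, inv, panel, panelModule)
  expect_equal(unname(mInv@centroids["Proliferative", ]),
               unname(direct@centroids["not-Proliferative", ]))
  expect_error(trainPresenceClassifier(fx$le, labels, panel, panelModule,
                                       modulesSubset = "M99"), "empty")
})

test_that("brush evaluation counts the confusion table correctly", {
  ## toy: TP 5, FN 8, TN 20, FP 2
  nb <- 35
  pred <- stats::setNames(rep(c("Proliferative", "not", "not",
                                "Proliferative"), c(5, 8, 20, 2)),
                          paste0("b", 1:nb))
  key <- stats::setNames(paste0("k", 1:nb), names(pred))
  truthPos <- rep(c(TRUE, TRUE, FALSE, FALSE), c(5, 8, 20, 2))
  biopsyKey <- key
  names(biopsyKey) <- paste0("bio", 1:nb)
  biopsySub <- stats::setNames(ifelse(truthPos, "Proliferative", "other"),
                               names(biopsyKey))
  names(biopsyKey) <- names(biopsySub)
  ev <- evaluateBrushPrediction(pred, biopsySub,
                                brushKey = key,
                                biopsyKey = stats::setNames(
                                  unname(key), names(biopsySub)))
  expect_equal(ev$sensitivity, 5 / 13)
  expect_equal(ev$specificity, 20 / 22)
  expect_equal(ev$confusion["positive", "positive"], 5)
  ## all-negative predictions: sensitivity 0, specificity 1
  predNeg <- stats::setNames(rep("not", nb), names(pred))
  evNeg <- evaluateBrushPrediction(predNeg, biopsySub,
                                   brushKey = key,
                                   biopsyKey = stats::setNames(
                                     unname(key), names(biopsySub)))
  expect_equal(evNeg$sensitivity, 0)
  expect_equal(evNeg$specificity, 1)
  ## unmatched brushes are excluded and counted
  key2 <- key; key2[1] <- "nowhere"
  ev2 <- evaluateBrushPrediction(pred, biopsySub, brushKey = key2,
                                 biopsyKey = stats::setNames(
                                   unname(key), names(biopsySub)))
  expect_equal(ev2$nUnmatched, 1)
})
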