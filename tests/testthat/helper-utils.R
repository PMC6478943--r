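# shared helpers: small fixtures and independent scoring utilities

jaccardIndex <- function(a, b) length(intersect(a, b)) / length(union(a, b))

adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  N <- choose(sum(tab), 2)
  (sn - sr * sc / N) / (0.5 * (sr + sc) - sr * sc / N)
}

makeLE <- function(values, metadata = NULL, scale = "log2cpm") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  LesionExperiment(values, metadata, scale = scale)
}

# two planted correlated blocks plus noise genes, via a 1-factor model
plantedBlocks <- function(nPerBlock = 50, nNoise = 0, nSamples = 100,
                          withinR = 0.9, seed = 1) {
  set.seed(seed)
  L <- sqrt(withinR / (1 - withinR))   # loading giving cor = L^2/(L^2+1)
  blocks <- list()
  for (b in seq_along(nPerBlock)) {
    f <- rnorm(nSamples)
    blocks[[b]] <- t(sapply(seq_len(nPerBlock[b]), function(i)
      L * f + rnorm(nSamples)))
  }
  x <- do.call(rbind, c(blocks, list(matrix(rnorm(nNoise * nSamples),
                                            nNoise, nSamples))))
  truth <- rep(c(seq_along(nPerBlock), 0L),
               c(nPerBlock, nNoise))
  le <- makeLE(x)
  list(le = le, truth = stats::setNames(truth, rownames(exprValues(le))))
}

# reduced simulation for unit tests that do not need the default study size
smallStudy <- function(seed = 1, ...) {
  simulateLesionStudy(simulationConfig(
    nGenes = 300, nSamples = c(biopsy = 80, brush = 40, tumor = 60,
                               mouse = 30),
    nSharedModules = 3, nPrivateModules = 1, moduleSize = 30,
    subtypeEffect = 0, nSubjects = 20, progressionModuleIndex = 3,
    seed = seed, ...))
}
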