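#' Default subtype-by-module direction pattern
#'
#' Directionality of the nine conserved co-expression modules across the four
#' premalignant-lesion subtypes (+1 up, -1 down, 0 neutral): the Proliferative
#' subtype is up in modules 4, 5 and 7 and down in 6; Inflammatory up in
#' 1, 2, 7, 8 and down in 4, 5, 6; Secretory up in 6, 8 and down in
#' 1, 2, 5, 7; Normal-like up in 1, 6 and down in 8, 9. This pattern drives
#' the simulator's subtype factor shifts and is the default template for
#' naming discovered clusters.
#'
#' @return 4 x 9 integer matrix, rows subtypes, columns modules M1..M9.
#' @export
subtypePattern <- function() {
  p <- matrix(0L, 4, 9,
              dimnames = list(c("Proliferative", "Inflammatory",
                                "Secretory", "Normal-like"),
                              paste0("M", 1:9)))
  p["Proliferative", c(4, 5, 7)] <- 1L; p["Proliferative", 6] <- -1L
  p["Inflammatory", c(1, 2, 7, 8)] <- 1L; p["Inflammatory", c(4, 5, 6)] <- -1L
  p["Secretory", c(6, 8)] <- 1L; p["Secretory", c(1, 2, 5, 7)] <- -1L
  p["Normal-like", c(1, 6)] <- 1L; p["Normal-like", c(8, 9)] <- -1L
  p
}

#' Deterministic per-dataset random seed derived from the master seed
#' @keywords internal
.substreamSeed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 94906249
  as.integer((master %% 94906249) * 17 + h) %% 2147483629L
}

#' Simulation configuration
#'
#' Parameters of the linked four-dataset factor-model simulation. Defaults
#' emulate the structure of the motivating study at desk scale: a biopsy
#' cohort with four module-driven subtypes and repeated biopsies per subject,
#' a matched airway-brush dataset with attenuated subtype signal, a tumor-like
#' and a mouse-like dataset sharing nine modules with the biopsies, plus
#' dataset-private modules, batch and RNA-quality (TIN) covariates, and a
#' progression label tied to one module's activity.
#'
#' On the log2 scale, expression is
#' \deqn{x_{gj} = \mu_g + \sum_m L_{gm} f_{mj} + \beta_g t_j + b_{g,batch(j)}
#'       + u_{subj(j)} + \epsilon_{gj}}
#' with unit-variance baseline factors, so the within-module correlation at
#' neutral settings is \eqn{L^2 / (L^2 + \sigma^2)} (0.8 at the defaults
#' L = 2, \eqn{\sigma} = 1).
#'
#' @param nGenes total genes (shared namespace across datasets).
#' @param nSamples named counts per dataset; names fix the dataset set.
#' @param nSharedModules modules loaded in every dataset (the conserved ones).
#' @param nPrivateModules modules loaded in a single dataset, per dataset.
#' @param moduleSize genes per module.
#' @param loadingStrength factor loading L (log2 units per factor SD).
#' @param noiseSd residual SD sigma.
#' @param nSubtypes number of biopsy subtypes (rows used from \code{pattern}).
#' @param subtypeEffect factor-score shift per pattern unit.
#' @param pattern subtype-by-module direction matrix; default
#'   \code{\link{subtypePattern}()}.
#' @param nSubjects biopsy subjects; each biopsy is assigned a subject so
#'   subjects contribute several biopsies.
#' @param subjectSd SD of the additive, gene-independent subject effect.
#' @param nBatches,batchShiftSd batch count and SD of per-gene batch shifts.
#' @param tinEffect SD of per-gene TIN slopes (TIN is standardized).
#' @param progressionModuleIndex shared module whose factor is depressed in
#'   progressive/persistent biopsies (default 9).
#' @param progressionEffect size of that depression (factor SD units).
#' @param brushAttenuation fraction of the biopsy subtype shift a matched
#'   brush inherits.
#' @param seed master seed; all substreams derive from it.
#' @return object of class \code{SimulationConfig} (a validated list).
#' @export
simulationConfig <- function(nGenes = 800,
                             nSamples = c(biopsy = 160, brush = 80,
                                          tumor = 120, mouse = 40),
                             nSharedModules = 9,
                             nPrivateModules = 2,
                             moduleSize = 40,
                             loadingStrength = 2,
                             noiseSd = 1,
                             nSubtypes = 4,
                             subtypeEffect = 2,
                             pattern = subtypePattern(),
                             nSubjects = 40,
                             subjectSd = 0.5,
                             nBatches = 2,
                             batchShiftSd = 0.3,
                             tinEffect = 0.3,
                             progressionModuleIndex = 9,
                             progressionEffect = 1.5,
                             brushAttenuation = 0.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  nd <- length(nSamples)
  needed <- moduleSize * (nSharedModules + nPrivateModules * nd)
  if (needed > nGenes)
    stop("infeasible configuration: ", needed, " module genes exceed nGenes = ",
         nGenes)
  counts <- c(nGenes, nSamples, nSharedModules, moduleSize, nSubjects, nBatches)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (loadingStrength < 0) stop("loadingStrength must be >= 0")
  if (is.null(names(nSamples)) || !"biopsy" %in% names(nSamples))
    stop("nSamples must be named and include a 'biopsy' dataset")
  if (nSubtypes > nrow(pattern))
    stop("pattern has fewer rows than nSubtypes")
  if (progressionModuleIndex > nSharedModules)
    stop("progressionModuleIndex beyond shared modules")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a linked multi-dataset expression study
#'
#' Generates one \linkS4class{LesionExperiment} per configured dataset on the
#' log2 scale ("residual"-like values before nuisance effects are known) and
#' the ground truth needed for recovery testing. Shared modules are loaded in
#' all datasets, private modules in exactly one. Biopsy subtype labels shift
#' the shared-module factor scores according to the configured pattern; one
#' designated module's factor is additionally depressed in biopsies labelled
#' progressive/persistent; matched brushes inherit an attenuated version of
#' their subject-procedure's biopsy subtype signal.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{datasets} (named list of LesionExperiment, scale
#'   "log2cpm") and \code{truth} (module memberships per dataset, shared
#'   module IDs, subtype and progression labels, factor scores, the pattern,
#'   and per-brush presence truth).
#' @export
simulateLesionStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cf <- config
  dsNames <- names(cf$nSamples)

  ## ---- master stream: gene-level structure shared by all datasets ----
  set.seed(.substreamSeed(cf$seed, "master"))
  genes <- sprintf("G%04d", seq_len(cf$nGenes))
  sharedIds <- paste0("M", seq_len(cf$nSharedModules))
  pool <- sample(genes)                       # random gene placement
  take <- function(n) { g <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; g }
  membership <- list()                        # dataset -> module -> genes
  sharedGenes <- stats::setNames(
    lapply(sharedIds, function(i) take(cf$moduleSize)), sharedIds)
  for (d in dsNames) {
    ids <- sprintf("P%s_%d", d, seq_len(cf$nPrivateModules))
    priv <- stats::setNames(
      lapply(seq_along(ids), function(i) take(cf$moduleSize)), ids)
    membership[[d]] <- c(sharedGenes, priv)
  }
  mu <- stats::setNames(stats::rnorm(cf$nGenes, 6, 1.5), genes)
  betaTin <- stats::setNames(stats::rnorm(cf$nGenes, 0, cf$tinEffect), genes)

  pat <- cf$pattern[seq_len(cf$nSubtypes), seq_len(cf$nSharedModules),
                    drop = FALSE]

  truth <- list(moduleMembership = membership, sharedModuleIds = sharedIds,
                subtypeModulePattern = pat, factorScores = list(),
                subtypeLabels = NULL, progressionLabels = NULL,
                brushPresenceTruth = NULL)
  datasets <- list()
  biopsyMeta <- NULL

  for (d in dsNames) {
    set.seed(.substreamSeed(cf$seed, d))
    n <- cf$nSamples[[d]]
    sid <- sprintf("%s_%03d", d, seq_len(n))
    mods <- membership[[d]]
    nm <- length(mods)
    f <- matrix(stats::rnorm(nm * n), nm, n,
                dimnames = list(names(mods), sid))
    meta <- data.frame(row.names = sid,
                       cohort = d,
                       tissue = d,
                       batch = factor(sample(seq_len(cf$nBatches), n,
                                             replace = TRUE)),
                       tin = stats::rnorm(n, 70, 5),
                       stringsAsFactors = FALSE)
    subjEff <- rep(0, n)

    if (d == "biopsy") {
      meta$subject <- sprintf("subj%02d",
                              sample(seq_len(cf$nSubjects), n, replace = TRUE))
      meta$procedure <- sample(1:3, n, replace = TRUE)
      st <- sample(rownames(pat), n, replace = TRUE)
      meta$subtype <- st
      f[sharedIds, ] <- f[sharedIds, ] +
        cf$subtypeEffect * t(pat[st, , drop = FALSE])
      prog <- sample(c("progressive/persistent", "regressive", "unknown"),
                     n, replace = TRUE, prob = c(0.25, 0.25, 0.5))
      meta$progression <- prog
      pm <- sharedIds[cf$progressionModuleIndex]
      f[pm, prog == "progressive/persistent"] <-
        f[pm, prog == "progressive/persistent"] - cf$progressionEffect
      ue <- stats::rnorm(cf$nSubjects, 0, cf$subjectSd)
      subjEff <- ue[as.integer(sub("subj", "", meta$subject))]
      meta$sex <- sample(c("male", "female"), n, replace = TRUE)
      truth$subtypeLabels <- stats::setNames(st, sid)
      truth$progressionLabels <- stats::setNames(prog, sid)
      biopsyMeta <- meta
    } else if (d == "brush" && !is.null(biopsyMeta)) {
      key <- paste(biopsyMeta$subject, biopsyMeta$procedure)
      pick <- sample(seq_along(key), n, replace = TRUE)
      meta$subject <- biopsyMeta$subject[pick]
      meta$procedure <- biopsyMeta$procedure[pick]
      bkey <- paste(meta$subject, meta$procedure)
      ## field effect: mean subtype pattern over the matched biopsies,
      ## attenuated
      patShift <- vapply(bkey, function(kk) {
        rows <- pat[biopsyMeta$subtype[key == kk], , drop = FALSE]
        colMeans(rows)
      }, numeric(cf$nSharedModules))
      f[sharedIds, ] <- f[sharedIds, ] +
        cf$brushAttenuation * cf$subtypeEffect * patShift
      truth$brushPresenceTruth <- stats::setNames(
        vapply(bkey, function(kk)
          any(biopsyMeta$subtype[key == kk] == "Proliferative"), logical(1)),
        sid)
    }

    L <- matrix(0, cf$nGenes, nm, dimnames = list(genes, names(mods)))
    for (m in names(mods)) L[mods[[m]], m] <- cf$loadingStrength
    tinStd <- (meta$tin - 70) / 5
    bshift <- matrix(stats::rnorm(cf$nGenes * cf$nBatches, 0, cf$batchShiftSd),
                     cf$nGenes, cf$nBatches)
    x <- matrix(mu, cf$nGenes, n) + L %*% f +
      outer(betaTin, tinStd) + bshift[, as.integer(meta$batch)] +
      matrix(subjEff, cf$nGenes, n, byrow = TRUE) +
      matrix(stats::rnorm(cf$nGenes * n, 0, cf$noiseSd), cf$nGenes, n)
    dimnames(x) <- list(genes, sid)
    truth$factorScores[[d]] <- f
    datasets[[d]] <- LesionExperiment(x, meta, scale = "log2cpm")
  }
  list(datasets = datasets, truth = truth)
}

#' Draw negative-binomial counts from a log2-scale expression dataset
#'
#' Count means are proportional to \code{2^value} within each sample, scaled
#' to the sample's library size; the NB size parameter is 1/dispersion, so
#' the variance of a replicated gene is \code{mu * (1 + dispersion * mu)}.
#'
#' @param dataset LesionExperiment on the log2 scale.
#' @param librarySizes positive numeric, recycled across samples.
#' @param dispersion NB dispersion (> 0); small values approach Poisson.
#' @param seed optional seed for reproducible draws.
#' @return LesionExperiment with integer counts (scale "counts").
#' @export
simulateCounts <- function(dataset, librarySizes = 1e6, dispersion = 0.1,
                           seed = NULL) {
  stopifnot(is(dataset, "LesionExperiment"))
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (any(librarySizes <= 0)) stop("librarySizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- exprValues(dataset)
  lib <- rep_len(librarySizes, ncol(x))
  p <- sweep(2^x, 2, colSums(2^x), "/")
  mu <- sweep(p, 2, lib, "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow(x), ncol(x), dimnames = dimnames(x))
  .reValue(dataset, cnt, scale = "counts")
}
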