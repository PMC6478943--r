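#' Pipeline configuration
#'
#' Bundles every stage's parameters with the published defaults: a 0.85
#' conservation threshold, consensus clustering with k up to 10, 1000
#' iterations and 80% subsampling, a 22-gene marker panel, a presence
#' sub-panel drawn from modules 4-7, and an FDR of 0.05 throughout.
#'
#' @param simulation a \code{\link{simulationConfig}} describing the input
#'   study (the pipeline's simulate stage).
#' @param conservationThreshold absolute PC1 correlation threshold.
#' @param kMax,iters,subsample consensus clustering controls.
#' @param consensusSeed seed of the subsampling stream.
#' @param panelSize classifier marker count.
#' @param presenceModules module IDs whose markers form the presence panel.
#' @param fdr significance level for direction calls and associations.
#' @param minModuleSize,mergeCut module-detection controls.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           conservationThreshold = 0.85,
                           kMax = 10, iters = 1000, subsample = 0.8,
                           consensusSeed = simulation$seed,
                           panelSize = 22,
                           presenceModules = c("M4", "M5", "M6", "M7"),
                           fdr = 0.05,
                           minModuleSize = 30, mergeCut = 0.25) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @keywords internal
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Map detected conserved modules onto the planted shared modules
#'
#' Best-Jaccard matching of retained module gene lists against a reference
#' list of module gene sets; used by the simulated pipeline to put detected
#' modules into the canonical M1..M9 numbering the subtype pattern refers
#' to (on real data the analyst numbers the modules).
#'
#' @param filteredGenes named list of retained-module gene lists.
#' @param referenceSets named list of reference module gene sets.
#' @return named character: retained module -> reference module (the best
#'   Jaccard match), with ties and re-uses made unique.
#' @export
matchModulesToReference <- function(filteredGenes, referenceSets) {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  out <- character(0)
  for (m in names(filteredGenes)) {
    js <- vapply(referenceSets, jac, numeric(1), a = filteredGenes[[m]])
    out[m] <- names(referenceSets)[which.max(js)]
  }
  stats::setNames(make.unique(out, sep = "_dup"), names(out))
}

#' Run the end-to-end subtyping pipeline on a simulated study
#'
#' Simulate (or accept) the four linked datasets, residualize each on TIN
#' and batch, detect co-expression modules per dataset, screen biopsy
#' modules for cross-dataset conservation and intersection-filter their
#' genes, consensus-cluster the biopsies over the conserved genes and pick
#' k, score module activity per sample, name the clusters against the
#' expected subtype pattern, build the marker-panel nearest-centroid
#' classifier and the presence classifier, evaluate brush-based presence
#' prediction against matched biopsies, and test module scores for
#' association with lesion progression.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir optional directory; when given, stage artifacts (TSV / GMT
#'   / JSON) and a provenance record are written there.
#' @param datasets optional named list of LesionExperiment to use instead
#'   of simulating (truth-dependent reporting is skipped unless
#'   \code{truth} is also given).
#' @param truth optional simulation truth matching \code{datasets}.
#' @return list with per-stage results and a \code{summary} (module counts,
#'   chosen k, subtype sizes, classifier confusion, brush evaluation,
#'   progression association table) plus a provenance record.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL,
                        datasets = NULL, truth = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(datasets)) {
    sim <- .stage("simulate", simulateLesionStudy(config$simulation))
    datasets <- sim$datasets; truth <- sim$truth
  }
  resid <- .stage("residualize", lapply(datasets, residualize,
                                        covariates = c("tin", "batch")))
  moduleSets <- .stage("modules", {
    ms <- list()
    for (d in names(resid))
      ms[[d]] <- detectModules(resid[[d]], minModuleSize = config$minModuleSize,
                               mergeCut = config$mergeCut, sourceDataset = d)
    ms
  })
  comp <- .stage("compendium", buildCompendium(moduleSets, resid))
  decision <- .stage("conservation", {
    dec <- conservationSelect(comp, threshold = config$conservationThreshold,
                              biopsyDataset = "biopsy")
    if (!length(dec@retained))
      stop("no biopsy module conserved across all datasets (empty result)")
    filterModuleGenes(dec, comp)
  })
  ## canonical module numbering: in simulation mode, match the retained
  ## modules to the planted shared modules so the subtype pattern applies
  genesets <- decision@filteredGenes
  if (!is.null(truth)) {
    mapping <- matchModulesToReference(
      genesets, truth$moduleMembership$biopsy[truth$sharedModuleIds])
    names(genesets) <- mapping[names(genesets)]
    genesets <- genesets[order(names(genesets))]
  }
  clusterGenes <- unique(unlist(genesets))
  biopsy <- resid$biopsy
  cres <- .stage("consensus", {
    r <- consensusCluster(biopsy, genes = clusterGenes, kMax = config$kMax,
                          iters = config$iters, subsample = config$subsample,
                          seed = config$consensusSeed)
    finalizeAssignments(selectK(r))
  })
  scores <- .stage("scores", gsvaScores(biopsy, genesets))
  md <- sampleInfo(biopsy)
  cres <- .stage("annotate",
                 annotateSubtypes(cres, scores,
                                  subject = stats::setNames(md$subject,
                                                            colnames(biopsy)),
                                  fdr = config$fdr))
  subtypeOf <- stats::setNames(
    cres@subtypeNames[as.character(cres@assignments)],
    names(cres@assignments))
  classifier <- .stage("classifier", {
    eig <- vapply(genesets, function(g)
      moduleEigengene(biopsy, g)$eigengene, numeric(ncol(biopsy)))
    rownames(eig) <- colnames(biopsy)
    alloc <- allocatePanelGenes(biopsy, genesets, eig,
                                panelSize = config$panelSize)
    model <- trainNearestCentroid(biopsy, subtypeOf, alloc$panel,
                                  alloc$panelModule)
    resub <- predictSubtype(model, biopsy, biopsy)
    list(allocation = alloc, model = model, resub = resub,
         confusion = table(truth = subtypeOf[names(resub$labels)],
                           predicted = resub$labels),
         accuracy = mean(resub$labels == subtypeOf[names(resub$labels)]))
  })
  brushEval <- NULL
  if ("brush" %in% names(resid) &&
      "Proliferative" %in% cres@subtypeNames) {
    brushEval <- .stage("presence", {
      pm <- trainPresenceClassifier(biopsy, subtypeOf,
                                    classifier$allocation$panel,
                                    classifier$allocation$panelModule,
                                    modulesSubset = config$presenceModules)
      brush <- resid$brush
      pred <- predictSubtype(pm, brush, biopsy)
      bmd <- sampleInfo(brush)
      ev <- evaluateBrushPrediction(
        pred$labels, subtypeOf,
        brushKey = stats::setNames(paste(bmd$subject, bmd$procedure),
                                   colnames(brush)),
        biopsyKey = stats::setNames(paste(md$subject, md$procedure),
                                    colnames(biopsy)))
      c(ev, list(model = pm, predictions = pred$labels))
    })
  }
  progression <- .stage("progression", {
    prog <- md$progression
    use <- !is.na(prog) & prog %in% c("progressive/persistent", "regressive")
    if (sum(use) < 6) NULL else {
      grp <- factor(prog[use], levels = c("regressive",
                                          "progressive/persistent"))
      as <- mixedAssociation(scores[, use, drop = FALSE], grp,
                             md$subject[use])
      as <- as[order(as$qvalue, as$pvalue), ]
      top <- as$response[1]
      list(table = as, topModule = top,
           auc = rankAuc(-scores[top, use], grp == "progressive/persistent"))
    }
  })
  summary <- list(
    moduleCounts = vapply(moduleSets, function(m) length(moduleGenes(m)),
                          integer(1)),
    retainedModules = names(genesets),
    conservedGeneCount = length(clusterGenes),
    chosenK = cres@chosenK,
    subtypeSizes = table(subtypeOf),
    classifierAccuracy = classifier$accuracy,
    confusion = classifier$confusion,
    brushSensitivity = if (!is.null(brushEval)) brushEval$sensitivity,
    brushSpecificity = if (!is.null(brushEval)) brushEval$specificity,
    progressionTop = if (!is.null(progression)) progression$topModule,
    progressionAuc = if (!is.null(progression)) progression$auc)
  provenance <- list(config = config, chosenK = cres@chosenK,
                     selection = cres@provenance$selection,
                     consensus = cres@provenance[c("kMax", "iters",
                                                   "subsample", "seed")])
  out <- list(datasets = datasets, truth = truth, residuals = resid,
              moduleSets = moduleSets, compendium = comp,
              decision = decision, genesets = genesets, consensus = cres,
              scores = scores, subtypes = subtypeOf, classifier = classifier,
              brushEval = brushEval, progression = progression,
              summary = summary, provenance = provenance)
  if (!is.null(outdir)) .writePipelineArtifacts(out, outdir)
  out
}

#' @keywords internal
.writePipelineArtifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(run$residuals))
    writeExpressionTsv(run$residuals[[d]],
                       file.path(outdir, paste0(d, "_residual.tsv")))
  for (d in names(run$moduleSets)) {
    g <- moduleGenes(run$moduleSets[[d]])
    if (length(g))
      utils::write.table(
        data.frame(gene = unlist(g),
                   module = rep(names(g), lengths(g))),
        file.path(outdir, paste0(d, "_modules.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$decision@summedMatrix,
                     file.path(outdir, "conservation_summed.tsv"),
                     sep = "\t", quote = FALSE)
  writeGmt(run$genesets, file.path(outdir, "conserved_modules.gmt"))
  for (k in names(run$consensus@consensus))
    utils::write.table(round(run$consensus@consensus[[k]], 10),
                       file.path(outdir, paste0("consensus_k", k, ".tsv")),
                       sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(sample = names(run$subtypes), subtype = run$subtypes),
    file.path(outdir, "subtypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(set = rownames(run$scores), round(run$scores, 10),
               check.names = FALSE),
    file.path(outdir, "module_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sm <- run$summary
  rec <- list(
    moduleCounts = as.list(sm$moduleCounts),
    retainedModules = sm$retainedModules,
    conservedGeneCount = sm$conservedGeneCount,
    chosenK = sm$chosenK,
    cdfArea = as.list(run$consensus@cdfArea),
    delta = as.list(run$consensus@delta),
    subtypeSizes = as.list(unclass(sm$subtypeSizes)),
    classifierAccuracy = sm$classifierAccuracy,
    panel = run$classifier$allocation$panel,
    brushSensitivity = sm$brushSensitivity,
    brushSpecificity = sm$brushSpecificity,
    progressionTop = sm$progressionTop,
    progressionAuc = sm$progressionAuc,
    seeds = list(master = run$provenance$config$simulation$seed,
                 consensus = run$provenance$consensus$seed))
  jsonlite::write_json(rec, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
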