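#' Build a cross-dataset gene-set compendium with per-dataset PC1 scores
#'
#' Pools the modules detected in every dataset into one compendium of gene
#' sets (IDs prefixed by source dataset) and computes, for each set and each
#' dataset, the first principal component across the z-score-normalized
#' expression of the member genes present in that dataset. Sets with fewer
#' than two member genes in a dataset are marked undefined there (NA
#' column); correlations involving them are treated as sub-threshold.
#'
#' @param moduleSets named list of \linkS4class{ModuleSet} (names = datasets).
#' @param datasets named list of \linkS4class{LesionExperiment}, same names.
#' @return a \linkS4class{ModuleCompendium}.
#' @export
buildCompendium <- function(moduleSets, datasets) {
  stopifnot(identical(sort(names(moduleSets)), sort(names(datasets))))
  geneSets <- list(); src <- character()
  for (d in names(moduleSets)) {
    g <- moduleGenes(moduleSets[[d]])
    if (!length(g)) next
    names(g) <- paste(d, names(g), sep = ".")
    geneSets <- c(geneSets, g)
    src <- c(src, stats::setNames(rep(d, length(g)), names(g)))
  }
  if (!length(geneSets)) stop("no modules supplied")
  pc1 <- list()
  for (d in names(datasets)) {
    x <- exprValues(datasets[[d]])
    M <- matrix(NA_real_, ncol(x), length(geneSets),
                dimnames = list(colnames(x), names(geneSets)))
    for (s in names(geneSets)) {
      pres <- intersect(geneSets[[s]], rownames(x))
      if (length(pres) >= 2)
        M[, s] <- moduleEigengene(datasets[[d]], pres)$eigengene
    }
    pc1[[d]] <- M
  }
  absent <- vapply(names(geneSets), function(s)
    all(vapply(pc1, function(M) all(is.na(M[, s])), logical(1))), logical(1))
  if (any(absent))
    stop("gene set(s) absent from every dataset: ",
         paste(names(geneSets)[absent], collapse = ", "))
  new("ModuleCompendium", geneSets = geneSets, sourceDataset = src, pc1 = pc1)
}

#' Select biopsy modules conserved across all datasets
#'
#' Within each dataset, absolute Pearson correlations between all compendium
#' PC1 vectors are binarized strictly (> threshold is 1, <= threshold is 0;
#' undefined PC1s contribute 0) and the per-dataset binary matrices are
#' summed. Under the default \code{"summed"} rule a biopsy-derived module is
#' retained iff some non-biopsy set reaches the threshold in every dataset
#' (summed entry equal to the number of datasets); the \code{"any-partner"}
#' alternative requires only that each dataset contributes some partner.
#'
#' @param comp a \linkS4class{ModuleCompendium}.
#' @param threshold correlation threshold in (0, 1), default 0.85.
#' @param biopsyDataset name of the biopsy dataset (default "biopsy").
#' @param rule "summed" (same partner across all datasets) or "any-partner".
#' @return a \linkS4class{ConservationDecision} (without filtered genes; see
#'   \code{\link{filterModuleGenes}}).
#' @export
conservationSelect <- function(comp, threshold = 0.85,
                               biopsyDataset = "biopsy",
                               rule = c("summed", "any-partner")) {
  stopifnot(is(comp, "ModuleCompendium"),
            threshold > 0, threshold <= 1)
  rule <- match.arg(rule)
  sets <- names(comp@geneSets)
  nd <- length(comp@pc1)
  biopsySets <- sets[comp@sourceDataset == biopsyDataset]
  if (!length(biopsySets)) stop("no biopsy modules in compendium")
  othersets <- setdiff(sets, biopsySets)
  S <- matrix(0L, length(sets), length(sets), dimnames = list(sets, sets))
  bins <- list()
  for (d in names(comp@pc1)) {
    cc <- suppressWarnings(abs(stats::cor(comp@pc1[[d]])))
    cc[is.na(cc)] <- 0
    B <- (cc > threshold) * 1L
    diag(B) <- 0L
    bins[[d]] <- B
    S <- S + B
  }
  retained <- character(); partners <- list()
  for (b in biopsySets) {
    p <- switch(rule,
      summed = othersets[S[b, othersets] == nd],
      `any-partner` = {
        perDs <- vapply(bins, function(B) any(B[b, othersets] == 1L),
                        logical(1))
        if (all(perDs))
          othersets[Reduce(`|`, lapply(bins, function(B)
            B[b, othersets] == 1L))]
        else character(0)
      })
    if (length(p)) { retained <- c(retained, b); partners[[b]] <- p }
  }
  new("ConservationDecision", summedMatrix = S, retained = retained,
      partners = partners, filteredGenes = list(), threshold = threshold,
      biopsyDataset = biopsyDataset)
}

#' Intersection-filter the genes of retained biopsy modules
#'
#' Each retained module keeps only genes also present in the union of its
#' conserved partner sets; modules left empty are dropped with a warning.
#'
#' @param decision a \linkS4class{ConservationDecision}.
#' @param comp the \linkS4class{ModuleCompendium} it came from.
#' @return the decision with \code{filteredGenes} populated.
#' @export
filterModuleGenes <- function(decision, comp) {
  stopifnot(is(decision, "ConservationDecision"), is(comp, "ModuleCompendium"))
  fg <- list()
  keep <- character()
  for (m in decision@retained) {
    part <- unique(unlist(comp@geneSets[decision@partners[[m]]]))
    g <- intersect(comp@geneSets[[m]], part)
    if (!length(g)) {
      warning("module ", m, " has no genes in any partner set; dropped")
      next
    }
    fg[[m]] <- g
    keep <- c(keep, m)
  }
  decision@filteredGenes <- fg
  decision@retained <- keep
  decision@partners <- decision@partners[keep]
  decision
}
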