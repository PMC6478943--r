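#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.VALID_SCALES <- c("counts", "log2cpm", "residual", "zscore")

#' LesionExperiment: expression matrix plus sample annotation
#'
#' The universal carrier of the pipeline: a gene-by-sample value matrix with
#' aligned per-sample metadata, tagged with the scale the values live on
#' (\code{"counts"}, \code{"log2cpm"}, \code{"residual"} or \code{"zscore"}).
#' Extends \linkS4class{SummarizedExperiment}; sample annotation (subject,
#' tissue, cohort, batch, TIN, histology, progression status, sex, procedure)
#' lives in \code{colData}.
#'
#' @slot scaleTag character(1), one of counts/log2cpm/residual/zscore.
#' @export
setClass("LesionExperiment",
  contains = "SummarizedExperiment",
  representation(scaleTag = "character"))

setValidity("LesionExperiment", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% .VALID_SCALES)
    msg <- c(msg, sprintf("scaleTag must be one of %s",
                          paste(.VALID_SCALES, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample IDs")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and sample IDs are required")
  if (length(msg)) msg else TRUE
})

#' Construct a LesionExperiment
#'
#' @param values numeric gene-by-sample matrix with row and column names.
#' @param metadata data.frame (or DataFrame) of per-sample annotation, rows
#'   aligned with the columns of \code{values}.
#' @param scale scale tag of \code{values}.
#' @return A \linkS4class{LesionExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' le <- LesionExperiment(m, data.frame(tin = rnorm(4, 70)), scale = "log2cpm")
#' @export
LesionExperiment <- function(values, metadata = NULL, scale = "log2cpm") {
  values <- as.matrix(values)
  if (is.null(metadata))
    metadata <- S4Vectors::DataFrame(row.names = colnames(values))
  else {
    metadata <- S4Vectors::DataFrame(metadata)
    rownames(metadata) <- colnames(values)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = metadata)
  new("LesionExperiment", se, scaleTag = scale)
}

#' @rdname LesionExperiment
#' @param x,object a LesionExperiment.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname LesionExperiment
#' @export
sampleInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x), optional = TRUE)

#' @rdname LesionExperiment
#' @export
scaleTag <- function(x) x@scaleTag

#' Replace the assay and/or scale of a LesionExperiment, keeping metadata
#' @keywords internal
.reValue <- function(x, values, scale = scaleTag(x)) {
  LesionExperiment(values,
                   metadata = SummarizedExperiment::colData(x)[colnames(values), ,
                                                               drop = FALSE],
                   scale = scale)
}

setMethod("show", "LesionExperiment", function(object) {
  cat(sprintf("LesionExperiment: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@scaleTag))
  cat("colData:", paste(colnames(SummarizedExperiment::colData(object)),
                        collapse = ", "), "\n")
})

#' ModuleSet: co-expression modules detected in one dataset
#'
#' @slot genes named list of character vectors (module label -> gene IDs).
#' @slot eigengenes samples-by-modules matrix of unit-variance eigengenes
#'   (first principal components), sign-aligned with mean module expression.
#' @slot varExplained named numeric, fraction of module variance on PC1.
#' @slot sourceDataset character(1) dataset name.
#' @slot power numeric(1) soft-threshold used (NA if not applicable).
#' @export
setClass("ModuleSet", representation(
  genes = "list", eigengenes = "matrix", varExplained = "numeric",
  sourceDataset = "character", power = "numeric"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (length(object@genes) &&
      !identical(names(object@genes), colnames(object@eigengenes)))
    msg <- c(msg, "module labels of genes and eigengenes disagree")
  if (anyDuplicated(unlist(object@genes)))
    msg <- c(msg, "a gene is assigned to two modules")
  if (any(lengths(object@genes) == 0L))
    msg <- c(msg, "empty module")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleSet", function(object) {
  cat(sprintf("ModuleSet (%s): %d modules, sizes [%s], power %s\n",
              object@sourceDataset, length(object@genes),
              paste(lengths(object@genes), collapse = ", "),
              format(object@power)))
})

#' @rdname ModuleSet-class
#' @param x a ModuleSet.
#' @export
moduleGenes <- function(x) x@genes

#' @rdname ModuleSet-class
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' ModuleCompendium: pooled gene sets with per-dataset PC1 vectors
#'
#' Gene sets from all datasets' modules combined, each scored by its first
#' principal component within every z-score-normalized dataset where at least
#' two member genes are present (singleton presence is marked undefined).
#'
#' @slot geneSets named list of gene-ID vectors.
#' @slot sourceDataset named character, origin dataset of each set.
#' @slot pc1 named list (per dataset) of samples-by-sets PC1 matrices;
#'   columns of undefined sets are NA.
#' @export
setClass("ModuleCompendium", representation(
  geneSets = "list", sourceDataset = "character", pc1 = "list"))

setMethod("show", "ModuleCompendium", function(object) {
  cat(sprintf("ModuleCompendium: %d gene sets from %d datasets (%s)\n",
              length(object@geneSets), length(object@pc1),
              paste(names(object@pc1), collapse = ", ")))
})

#' ConservationDecision: which biopsy modules are conserved, and their genes
#'
#' @slot summedMatrix set-by-set integer matrix, number of datasets in which
#'   the pair's absolute PC1 correlation exceeded the threshold.
#' @slot retained character, retained biopsy module set IDs.
#' @slot partners named list, retained module -> conserved partner set IDs.
#' @slot filteredGenes named list, retained module -> final gene list.
#' @slot threshold numeric(1) correlation threshold used.
#' @slot biopsyDataset character(1).
#' @export
setClass("ConservationDecision", representation(
  summedMatrix = "matrix", retained = "character", partners = "list",
  filteredGenes = "list", threshold = "numeric", biopsyDataset = "character"))

setMethod("show", "ConservationDecision", function(object) {
  cat(sprintf(
    "ConservationDecision: %d biopsy modules retained (|r| > %.2f in all %s),\n",
    length(object@retained), object@threshold,
    "datasets"))
  if (length(object@filteredGenes))
    cat(sprintf("  %d genes after intersection filtering\n",
                length(unlist(object@filteredGenes))))
})

#' ConsensusResult: consensus matrices, CDF areas and subtype assignments
#'
#' @slot consensus named list (k -> sample-by-sample consensus matrix).
#' @slot cdfArea named numeric A(k).
#' @slot delta named numeric relative change in area.
#' @slot pac named numeric proportion of ambiguous clustering per k.
#' @slot chosenK integer(1) (NA until selected).
#' @slot assignments named integer cluster per sample (length 0 until final).
#' @slot subtypeNames named character cluster -> label.
#' @slot provenance list of the clustering/selection parameters used.
#' @export
setClass("ConsensusResult", representation(
  consensus = "list", cdfArea = "numeric", delta = "numeric", pac = "numeric",
  chosenK = "integer", assignments = "integer", subtypeNames = "character",
  provenance = "list"))

setMethod("show", "ConsensusResult", function(object) {
  ks <- names(object@consensus)
  cat(sprintf("ConsensusResult: k in {%s}", paste(ks, collapse = ",")))
  if (!is.na(object@chosenK)) cat(sprintf(", chosen k = %d", object@chosenK))
  cat("\n")
  if (length(object@assignments))
    cat("  cluster sizes:",
        paste(table(object@assignments), collapse = "/"), "\n")
})

#' CentroidModel: serialized nearest-centroid subtype classifier
#'
#' @slot panel character marker genes (ordered).
#' @slot panelModule named character, module provenance of each panel gene.
#' @slot centroids class-by-gene matrix of class means on the z-scale.
#' @slot pooledSD named numeric pooled within-class SD per gene.
#' @slot priors named numeric class proportions (sum 1).
#' @slot trainLabels named character training labels (per training sample),
#'   kept so the model can be re-estimated on jointly renormalized data.
#' @slot normalization list: z-score parameters and batch-adjustment record.
#' @export
setClass("CentroidModel", representation(
  panel = "character", panelModule = "character", centroids = "matrix",
  pooledSD = "numeric", priors = "numeric", trainLabels = "character",
  normalization = "list"))

setValidity("CentroidModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@centroids))) msg <- c(msg, "non-finite centroids")
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CentroidModel", function(object) {
  cat(sprintf("CentroidModel: %d classes (%s), %d marker genes\n",
              nrow(object@centroids),
              paste(rownames(object@centroids), collapse = ", "),
              length(object@panel)))
})
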