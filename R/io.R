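#' Read / write gene-by-sample expression TSV
#'
#' Plain TSV with genes in rows (first column gene IDs, header row of sample
#' IDs); metadata as a separate TSV with a \code{sample} column.
#'
#' @param file path.
#' @param metadataFile optional per-sample metadata TSV.
#' @param scale scale tag for the returned object.
#' @return a \linkS4class{LesionExperiment}.
#' @export
readExpressionTsv <- function(file, metadataFile = NULL, scale = "log2cpm") {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  md <- NULL
  if (!is.null(metadataFile)) {
    md <- utils::read.delim(metadataFile, stringsAsFactors = FALSE)
    rownames(md) <- md$sample
    md <- md[colnames(m), setdiff(colnames(md), "sample"), drop = FALSE]
  }
  LesionExperiment(m, md, scale = scale)
}

#' @rdname readExpressionTsv
#' @param x LesionExperiment.
#' @export
writeExpressionTsv <- function(x, file, metadataFile = NULL) {
  m <- exprValues(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataFile)) {
    md <- sampleInfo(x)
    md <- data.frame(sample = colnames(m), md, stringsAsFactors = FALSE)
    utils::write.table(md, metadataFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param file path.
#' @return named list of gene-ID vectors.
#' @export
readGmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' @rdname readGmt
#' @param sets named list of gene vectors.
#' @param description description field (recycled).
#' @export
writeGmt <- function(sets, file, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}
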