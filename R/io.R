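#' Read / write tab-delimited tables
#'
#' Thin wrappers fixing the pipeline's table conventions: tab delimiter,
#' UTF-8, header row, '.' decimal separator regardless of locale, and
#' "NA" for missing values.
#'
#' @param path file path.
#' @return \code{readTsv}: a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' @rdname readTsv
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
  old <- options(OutDec = ".")
  on.exit(options(old))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT term map
#'
#' @param path GMT file (term, description, then gene ids, tab-separated).
#' @return named list of gene-id vectors; the description field is kept
#'   as the \code{namespace} attribute when it looks like one.
#' @export
readGmt <- function(path) {
  terms <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(lines, `[`, character(1), 2)
  names(desc) <- vapply(lines, `[`, character(1), 1)
  attr(terms, "namespace") <- desc
  terms
}

#' Write a GMT term map
#'
#' @param terms named list of gene-id vectors.
#' @param namespace optional named character used as the description
#'   field.
#' @param path output file.
#' @export
writeGmt <- function(terms, namespace = NULL, path) {
  if (is.null(namespace))
    namespace <- stats::setNames(rep("na", length(terms)), names(terms))
  lines <- vapply(names(terms), function(tm)
    paste(c(tm, unname(namespace[tm]), terms[[tm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a counts TSV into a SummarizedExperiment
#'
#' @param countsPath TSV with a \code{gene} column then one integer
#'   column per sample.
#' @param lengthsPath TSV with columns gene, length.
#' @param samplesPath TSV with columns sample, condition.
#' @return a \code{SummarizedExperiment} as produced by
#'   [simulateCounts()] (without truth columns).
#' @export
readCounts <- function(countsPath, lengthsPath, samplesPath) {
  cm <- readTsv(countsPath)
  stopifnot("gene" %in% names(cm))
  genes <- cm$gene
  m <- as.matrix(cm[setdiff(names(cm), "gene")])
  rownames(m) <- genes
  len <- readTsv(lengthsPath)
  stopifnot(all(c("gene", "length") %in% names(len)))
  len <- stats::setNames(len$length, len$gene)[genes]
  ss <- readTsv(samplesPath)
  stopifnot(all(c("sample", "condition") %in% names(ss)))
  cond <- stats::setNames(ss$condition, ss$sample)[colnames(m)]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(length = unname(len),
                                   row.names = genes),
    colData = S4Vectors::DataFrame(condition = unname(cond),
                                   row.names = colnames(m)))
}

#' Published seedling-stage comprehensive evaluation table
#'
#' The published comprehensive evaluation of 18 foxtail millet
#' accessions under 0.13, 0.17 and 0.22 mol/L NaCl, bundled as a
#' verification fixture: per-concentration fuzzy scores and ranks plus
#' the total score and rank, exactly as printed (scores to 2 decimals).
#'
#' @return data.frame: code, score_0.13, rank_0.13, score_0.17,
#'   rank_0.17, score_0.22, rank_0.22, total_score, total_rank.
#' @examples
#' ref <- milletScoreTable()
#' ref[ref$total_rank == 1, "code"]  # the most salt-tolerant accession
#' @export
milletScoreTable <- function() {
  readTsv(system.file("extdata", "millet_seedling_scores.tsv",
                      package = "saltScreen", mustWork = TRUE))
}
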