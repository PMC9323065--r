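#' Hypergeometric term enrichment with cluster frequency
#'
#' Upper-tail hypergeometric over-representation of a DEG set in each
#' annotated term: \eqn{p = P(X \ge k)} for \eqn{k} DEGs among the
#' \eqn{K} genes of the term, drawing \eqn{n} database-annotated DEGs
#' from a universe of \eqn{N} database-annotated genes. The universe is
#' the set of genes annotated to the database in question (the union of
#' the supplied term gene sets, unless given explicitly), which is also
#' the denominator convention behind the cluster frequency: the
#' proportion \eqn{k/n} of annotated DEGs falling in the term. BH
#' adjustment is applied within each namespace.
#'
#' @param degSet character vector of DEG identifiers.
#' @param terms named list of term gene-id vectors.
#' @param namespace named character vector (one of BP/CC/MF/pathway per
#'   term); defaults to a single namespace for all terms.
#' @param universe database-annotated gene universe; defaults to the
#'   union of all term gene sets.
#' @param sigCut adjusted-p significance flag cut (default 0.01).
#' @return data.frame sorted by p-value: term, namespace, k, K, n, N,
#'   pvalue, padj, cluster_frequency, significant.
#' @examples
#' terms <- list(T1 = c("a", "b", "c"), T2 = c("d", "e"))
#' enrichTerms(c("a", "b"), terms)
#' @export
enrichTerms <- function(degSet, terms, namespace = NULL, universe = NULL,
                        sigCut = 0.01) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (is.null(universe)) universe <- unique(unlist(terms))
  if (is.null(namespace))
    namespace <- stats::setNames(rep("BP", length(terms)), names(terms))
  if (!length(degSet)) {
    warning("empty DEG set: no enrichment to compute")
    return(data.frame(term = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), padj = numeric(),
                      cluster_frequency = numeric(),
                      significant = logical()))
  }
  N <- length(universe)
  degAnn <- intersect(degSet, universe)
  n <- length(degAnn)
  rows <- lapply(names(terms), function(tm) {
    g <- intersect(terms[[tm]], universe)
    K <- length(g)
    k <- length(intersect(degAnn, g))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, namespace = unname(namespace[tm]),
               k = k, K = K, n = n, N = N, pvalue = p,
               cluster_frequency = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- NA_real_
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$padj[sel] <- stats::p.adjust(res$pvalue[sel], method = "BH")
  }
  res$significant <- res$padj < sigCut
  res <- res[, c("term", "namespace", "k", "K", "n", "N", "pvalue",
                 "padj", "cluster_frequency", "significant")]
  res <- res[order(res$pvalue, res$term), ]
  rownames(res) <- NULL
  res
}

#' Transcription-factor family tallies of a DEG table
#'
#' Counts up- and down-regulated DEGs per TF family. DEGs without a TF
#' annotation are simply not TFs and are ignored; families with no DEG
#' are omitted.
#'
#' @param calls called DEG table from [callDegs()].
#' @param tfAnnotation data.frame with columns \code{gene},
#'   \code{family} (one family per gene).
#' @return data.frame: family, n_up, n_down, n_total, sorted by
#'   descending total.
#' @export
tfTally <- function(calls, tfAnnotation) {
  stopifnot("call" %in% names(calls),
            all(c("gene", "family") %in% names(tfAnnotation)))
  deg <- calls[calls$call != "ns", c("gene", "call")]
  m <- merge(deg, tfAnnotation, by = "gene")
  if (!nrow(m))
    return(data.frame(family = character(), n_up = integer(),
                      n_down = integer(), n_total = integer()))
  tab <- table(m$family, factor(m$call, levels = c("up", "down")))
  res <- data.frame(family = rownames(tab),
                    n_up = as.integer(tab[, "up"]),
                    n_down = as.integer(tab[, "down"]),
                    stringsAsFactors = FALSE)
  res$n_total <- res$n_up + res$n_down
  res <- res[res$n_total > 0, ]
  res <- res[order(-res$n_total, res$family), ]
  rownames(res) <- NULL
  res
}

#' TF families shared between two contrasts
#'
#' @param tallyA,tallyB outputs of [tfTally()].
#' @return character vector of family labels present in both, sorted.
#' @export
tfShared <- function(tallyA, tallyB) {
  sort(intersect(tallyA$family, tallyB$family))
}
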