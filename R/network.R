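#' Build a confidence-thresholded interaction graph
#'
#' Turns a weighted edge list into a simple undirected igraph, keeping
#' edges whose confidence meets the threshold (STRING's "highest
#' confidence" is 0.900). Confidences on STRING's 0-1000 integer scale
#' are auto-detected (any value > 1) and divided by 1000. Self-loops are
#' dropped with a warning; duplicate pairs keep their maximum
#' confidence. Declared nodes with no retained edge stay in the graph as
#' isolated vertices.
#'
#' @param edges data.frame with columns geneA, geneB, confidence.
#' @param threshold minimum confidence to retain an edge (default 0.9).
#' @param nodes optional character vector of vertices to declare even if
#'   isolated after thresholding; defaults to every gene seen in
#'   \code{edges}.
#' @return an \code{igraph} object with edge attribute
#'   \code{confidence}.
#' @export
buildGraph <- function(edges, threshold = 0.9, nodes = NULL) {
  need <- c("geneA", "geneB", "confidence")
  if (!is.data.frame(edges) || !all(need %in% names(edges)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  conf <- as.numeric(edges$confidence)
  if (anyNA(conf) || anyNA(edges$geneA) || anyNA(edges$geneB))
    stop("malformed edge rows (missing gene or confidence)")
  if (any(conf > 1)) conf <- conf / 1000
  if (any(conf < 0 | conf > 1))
    stop("confidences must lie in [0, 1] (or STRING's 0-1000 scale)")
  a <- as.character(edges$geneA); b <- as.character(edges$geneB)
  loop <- a == b
  if (any(loop)) {
    warning("dropped ", sum(loop), " self-loop row(s)")
    a <- a[!loop]; b <- b[!loop]; conf <- conf[!loop]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  # undirected dedup: keep max confidence per unordered pair
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (anyDuplicated(key)) {
    conf <- vapply(split(conf, key), max, numeric(1))
    ab <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    a <- ab[, 1]; b <- ab[, 2]
  }
  keep <- conf >= threshold
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep],
               confidence = conf[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = sort(unique(c(nodes, a[keep], b[keep]))))
  g
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of a simple undirected graph (Bron-Kerbosch with
#' pivoting, via igraph), returned in a deterministic order: members
#' sorted within each clique, cliques sorted lexicographically.
#'
#' @param graph an \code{igraph} object.
#' @param min minimum clique size to report (default 1, so isolated
#'   vertices appear as singleton cliques).
#' @return list of character vectors of vertex names.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' maximalCliques(g)
#' @export
maximalCliques <- function(graph, min = 1) {
  cl <- igraph::max_cliques(graph, min = min)
  cl <- lapply(cl, function(v) sort(names(v)))
  ord <- order(vapply(cl, paste, character(1), collapse = "\r"))
  cl[ord]
}

#' Maximal clique centrality (MCC) hub scores
#'
#' For each node, the sum over all maximal cliques containing it of
#' \eqn{(|C| - 1)!}. Isolated nodes score 0. A node whose largest
#' maximal clique is big dominates: a member of a k-clique alone scores
#' \eqn{(k-1)!}, and each additional maximal clique adds its own
#' factorial term (so a 5-clique member carrying one extra pendant edge
#' scores \eqn{4! + 1! = 25} against \eqn{24} for its clique-only
#' neighbours). Scores are computed in double precision, exact through
#' cliques of 19 nodes (18! < 2^53); larger cliques keep correct hub
#' ordering.
#'
#' @param graph an \code{igraph} object (already thresholded, see
#'   [buildGraph()]).
#' @return data.frame: gene, mcc, rank (descending competition ranks),
#'   sorted by rank then gene.
#' @export
mccScores <- function(graph) {
  cl <- maximalCliques(graph, min = 2)
  genes <- sort(igraph::V(graph)$name)
  mcc <- stats::setNames(numeric(length(genes)), genes)
  for (members in cl)
    mcc[members] <- mcc[members] + factorial(length(members) - 1)
  res <- data.frame(gene = genes, mcc = unname(mcc),
                    stringsAsFactors = FALSE)
  res$rank <- rankScores(res$mcc)
  res <- res[order(res$rank, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Top hub genes and their neighbourhood subnetwork
#'
#' The k highest-MCC genes (ties broken lexicographically by
#' identifier), plus the subgraph induced by the hubs and their direct
#' interactors.
#'
#' @param scores output of [mccScores()].
#' @param graph the graph the scores were computed on.
#' @param k number of hubs (default 10); if larger than the graph, all
#'   nodes are returned with a warning.
#' @return list: \code{hubs} (score table rows of the selected genes)
#'   and \code{subnetwork} (igraph of hubs + neighbours).
#' @export
topHubs <- function(scores, graph, k = 10) {
  if (k > nrow(scores)) {
    warning("k exceeds the number of nodes; returning all")
    k <- nrow(scores)
  }
  ord <- order(-scores$mcc, scores$gene)
  hubs <- scores[ord[seq_len(k)], ]
  rownames(hubs) <- NULL
  nbrs <- unique(unlist(lapply(hubs$gene, function(g)
    names(igraph::neighbors(graph, g)))))
  sub <- igraph::induced_subgraph(graph,
    vids = unique(c(hubs$gene, nbrs)))
  list(hubs = hubs, subnetwork = sub)
}
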