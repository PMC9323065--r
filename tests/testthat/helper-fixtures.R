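# Small configurations and hand-built fixtures shared across tests.

tinyConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nAccessions = 12L, nGenes = 300L,
               ppiNodes = 60L, plantedCliqueSizes = c(6L, 4L),
               backgroundEdgeProb = 0.02)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

# one dish census: cumulative counts over the standard schedule
dish <- function(germinated, sown = 20, days = c(2, 4, 6, 8)) {
  data.frame(day = days, germinated = germinated, sown = sown)
}

# brute-force maximal-clique enumeration over all vertex subsets
bruteMaximalCliques <- function(g) {
  vs <- sort(igraph::V(g)$name)
  adj <- lapply(stats::setNames(vs, vs), function(v)
    names(igraph::neighbors(g, v)))
  isClique <- function(s) all(vapply(seq_along(s), function(i)
    all(s[-i] %in% adj[[s[i]]]), logical(1)))
  out <- list()
  n <- length(vs)
  for (m in seq_len(2^n) - 1L) {
    s <- vs[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0]
    if (!length(s) || !isClique(s)) next
    ext <- setdiff(Reduce(intersect, adj[s]), s)
    if (!length(ext)) out[[length(out) + 1L]] <- sort(s)
  }
  ord <- order(vapply(out, paste, character(1), collapse = "\r"))
  out[ord]
}

bruteMcc <- function(g) {
  cl <- Filter(function(s) length(s) >= 2, bruteMaximalCliques(g))
  vs <- sort(igraph::V(g)$name)
  mcc <- stats::setNames(numeric(length(vs)), vs)
  for (s in cl) mcc[s] <- mcc[s] + factorial(length(s) - 1)
  mcc
}

randomGraph <- function(n, p) {
  vs <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(vs, 2))
  keep <- stats::runif(nrow(pairs)) < p
  igraph::graph_from_data_frame(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
    directed = FALSE, vertices = vs)
}
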