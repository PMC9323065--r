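#' Membership function (min-max rescaling)
#'
#' The fuzzy-mathematics membership value of each observation within one
#' evaluation stratum and index: \eqn{(x - x_{min}) / (x_{max} - x_{min})},
#' so the worst accession maps to 0 and the best to 1. Missing values
#' propagate. A degenerate index (all values equal) is uninformative and
#' maps everything to 0.5 with a warning, rather than forcing extremes.
#'
#' @param values numeric raw index values across accessions (>= 2
#'   non-missing).
#' @return memberships in \[0, 1\], same length and order.
#' @examples
#' membership(c(2, 4, 6))
#' @export
membership <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("membership needs at least 2 non-missing values")
  lo <- min(values[ok]); hi <- max(values[ok])
  if (hi == lo) {
    warning("degenerate index (max = min): memberships set to 0.5")
    return(ifelse(ok, 0.5, NA_real_))
  }
  (values - lo) / (hi - lo)
}

#' Membership matrix over a long trait table
#'
#' Applies [membership()] within every group x index stratum of a long
#' table, appending a \code{membership} column.
#'
#' @param data data.frame with columns accession, group, index, value.
#' @return the input with a \code{membership} column.
#' @export
fuzzyMembership <- function(data) {
  stopifnot(all(c("accession", "group", "index", "value") %in% names(data)))
  data$membership <- NA_real_
  for (g in unique(data$group)) for (j in unique(data$index)) {
    sel <- data$group == g & data$index == j
    if (any(sel)) data$membership[sel] <- membership(data$value[sel])
  }
  data
}

#' Per-group comprehensive score
#'
#' Sums membership values across indices within each group: an accession
#' scoring the maximum of every one of k indices reaches k. Missing
#' memberships are dropped from the sum and flagged; accessions missing
#' every index of a group are excluded from that group.
#'
#' @param memberships output of [fuzzyMembership()].
#' @return data.frame: accession, group, score, n_indices, incomplete.
#' @export
comprehensiveScore <- function(memberships) {
  stopifnot("membership" %in% names(memberships))
  out <- list()
  for (g in unique(memberships$group)) {
    sub <- memberships[memberships$group == g, ]
    nIdx <- length(unique(sub$index))
    for (a in unique(sub$accession)) {
      m <- sub$membership[sub$accession == a]
      if (all(is.na(m))) next   # excluded
      out[[length(out) + 1L]] <- data.frame(
        accession = a, group = g, score = sum(m, na.rm = TRUE),
        n_indices = nIdx, incomplete = anyNA(m),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Total score across groups
#'
#' @param scores output of [comprehensiveScore()]; accessions missing any
#'   group are excluded with a warning.
#' @return data.frame: accession, total_score.
#' @export
totalScore <- function(scores) {
  groups <- unique(scores$group)
  tab <- table(scores$accession)
  full <- names(tab)[tab == length(groups)]
  dropped <- setdiff(names(tab), full)
  if (length(dropped))
    warning("excluded from total (missing groups): ",
            paste(dropped, collapse = ", "))
  sub <- scores[scores$accession %in% full, ]
  agg <- stats::aggregate(score ~ accession, data = sub, FUN = sum)
  names(agg)[2] <- "total_score"
  agg[order(agg$accession), ]
}

#' Descending competition ranks
#'
#' Highest score gets rank 1; tied scores share the smallest rank and the
#' following rank is skipped ("1, 2, 2, 4").
#'
#' @param scores numeric vector.
#' @return integer ranks, same order as the input.
#' @examples
#' rankScores(c(3, 2, 2, 1))
#' @export
rankScores <- function(scores) {
  stopifnot(length(scores) >= 1L)
  as.integer(rank(-scores, ties.method = "min", na.last = "keep"))
}

#' Full fuzzy comprehensive evaluation
#'
#' Membership scoring, per-group comprehensive scores and ranks, and a
#' grand total with its rank: the engine that turns a long relative-trait
#' table into a comprehensive-evaluation score table (one row per
#' accession; one score/rank column pair per stratum, e.g. per NaCl
#' concentration).
#'
#' @param data long data.frame: accession, group, index, value.
#' @return data.frame with columns \code{accession},
#'   \code{score_<group>} and \code{rank_<group>} for each group, and
#'   \code{total_score}, \code{total_rank}. The per-group score sum equals
#'   the total exactly.
#' @examples
#' sim <- simulateGermination(simConfig(seed = 1, nAccessions = 10))
#' rel <- relativeGerminationTraits(germinationTraits(sim$census))
#' head(fuzzyEvaluate(relativeToLong(rel)))
#' @export
fuzzyEvaluate <- function(data) {
  mem <- fuzzyMembership(data)
  sc <- comprehensiveScore(mem)
  tot <- totalScore(sc)
  groups <- unique(sc$group)
  out <- tot
  for (g in groups) {
    sub <- sc[sc$group == g, c("accession", "score")]
    sub$rank <- rankScores(sub$score)
    names(sub) <- c("accession", paste0("score_", g), paste0("rank_", g))
    out <- merge(out, sub, by = "accession", all.x = TRUE)
  }
  out$total_rank <- rankScores(out$total_score)
  cols <- c("accession",
            as.vector(rbind(paste0("score_", groups),
                            paste0("rank_", groups))),
            "total_score", "total_rank")
  out <- out[, cols]
  out[order(out$total_rank, out$accession), ]
}

#' Select extreme accessions from a score table
#'
#' Picks the k best (putative tolerant) and k worst (putative sensitive)
#' accessions by score, breaking ties lexicographically by accession
#' identifier so the selection is deterministic.
#'
#' @param scores named numeric vector (names = accession ids) or the
#'   output of [fuzzyEvaluate()] (its \code{total_score} is used).
#' @param kTop,kBottom set sizes; \code{kTop + kBottom} must not exceed
#'   the number of accessions (overlap is an error).
#' @return list with character vectors \code{tolerant} and
#'   \code{sensitive}.
#' @export
selectExtremes <- function(scores, kTop = 5L, kBottom = 13L) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$total_score, scores$accession)
  stopifnot(!is.null(names(scores)))
  if (kTop + kBottom > length(scores))
    stop("kTop + kBottom exceeds the number of accessions ",
         "(sets would overlap)")
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  list(tolerant = ids[seq_len(kTop)],
       sensitive = if (kBottom > 0) utils::tail(ids, kBottom)
                   else character())
}
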