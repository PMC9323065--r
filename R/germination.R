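#' Germination rate of one dish
#'
#' Final-census proportion germinated: germinated seeds at the last census
#' day divided by seeds sown.
#'
#' @param census data.frame for a single dish with columns \code{day},
#'   \code{germinated}, \code{sown}.
#' @return proportion in \[0, 1\].
#' @export
germinationRate <- function(census) {
  .checkDish(census)
  final <- census[which.max(census$day), ]
  final$germinated / final$sown
}

#' Germination potential of one dish
#'
#' The germination rate on the fourth day, an early-vigour index.
#'
#' @inheritParams germinationRate
#' @param day census day to read (default 4).
#' @return proportion in \[0, 1\].
#' @export
germinationPotential <- function(census, day = 4) {
  .checkDish(census)
  row <- census[census$day == day, ]
  if (nrow(row) != 1L)
    stop("census has no day-", day, " row")
  row$germinated / row$sown
}

#' Germination index of one dish
#'
#' \eqn{GI = \sum_t GR_t / D_t} over the census schedule, where
#' \eqn{GR_t} is the germination rate at census day \eqn{D_t}. By default
#' \eqn{GR_t} is the cumulative germination rate at each census; set
#' \code{method = "interval"} to use the newly-germinated fraction per
#' census instead (both conventions are in use in seed science).
#'
#' @inheritParams germinationRate
#' @param method "cumulative" (default) or "interval".
#' @return non-negative index (dimensionless).
#' @examples
#' dish <- data.frame(day = c(2, 4, 6, 8),
#'                    germinated = c(4, 10, 16, 18), sown = 20)
#' germinationIndex(dish)
#' @export
germinationIndex <- function(census, method = c("cumulative", "interval")) {
  method <- match.arg(method)
  .checkDish(census)
  census <- census[order(census$day), ]
  if (any(census$day <= 0))
    stop("census days must be positive (day 0 would divide by zero)")
  gr <- census$germinated / census$sown
  if (method == "interval") gr <- diff(c(0, gr))
  sum(gr / census$day)
}

.checkDish <- function(census) {
  need <- c("day", "germinated", "sown")
  if (!all(need %in% names(census)))
    stop("dish census needs columns: ", paste(need, collapse = ", "))
  if (any(census$sown <= 0)) stop("'sown' must be positive")
  if (any(census$germinated < 0 | census$germinated > census$sown))
    stop("'germinated' must lie in [0, sown]")
  census <- census[order(census$day), ]
  if (any(duplicated(census$day))) stop("duplicated census day")
  if (is.unsorted(census$germinated))
    stop("cumulative germinated counts must be non-decreasing")
  invisible(census)
}

#' Germination-stage traits per dish
#'
#' Computes GR (final germination rate), GP (day-4 rate), GI (germination
#' index), PL and RL (plumule/radicle length at the final census) for each
#' accession x condition x replicate dish of a census table.
#'
#' @param census data.frame with columns accession, condition, replicate,
#'   day, germinated, sown, plumule_length, radicle_length.
#' @param giMethod passed to [germinationIndex()].
#' @return data.frame: accession, condition, replicate, GR, GP, GI, PL, RL.
#' @export
germinationTraits <- function(census, giMethod = "cumulative") {
  keys <- c("accession", "condition", "replicate")
  stopifnot(all(keys %in% names(census)))
  split_ <- split(census, census[keys], drop = TRUE)
  out <- lapply(split_, function(d) {
    final <- d[which.max(d$day), ]
    data.frame(
      accession = d$accession[1], condition = d$condition[1],
      replicate = d$replicate[1],
      GR = germinationRate(d),
      GP = germinationPotential(d),
      GI = germinationIndex(d, method = giMethod),
      PL = if ("plumule_length" %in% names(d)) final$plumule_length
           else NA_real_,
      RL = if ("radicle_length" %in% names(d)) final$radicle_length
           else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$accession, res$condition, res$replicate), ]
}

#' Relative germination traits (salt / control)
#'
#' For each accession, divides the replicate mean of each germination
#' trait under salt by its replicate mean under control, giving RGR, RGP,
#' RGI, RPL and RRL. Dishes are unpaired, so means are taken before the
#' ratio. A zero control mean yields NA for that trait with a warning.
#'
#' @param traits output of [germinationTraits()] containing both
#'   conditions.
#' @return data.frame: accession, RGR, RGP, RGI, RPL, RRL.
#' @export
relativeGerminationTraits <- function(traits) {
  stopifnot(all(c("control", "salt") %in% traits$condition))
  traitCols <- c(GR = "RGR", GP = "RGP", GI = "RGI", PL = "RPL",
                 RL = "RRL")
  accs <- sort(unique(traits$accession))
  out <- lapply(accs, function(a) {
    sub <- traits[traits$accession == a, ]
    ctl <- sub[sub$condition == "control", ]
    slt <- sub[sub$condition == "salt", ]
    if (!nrow(ctl) || !nrow(slt)) {
      warning("accession ", a, " lacks a condition; skipped")
      return(NULL)
    }
    vals <- vapply(names(traitCols), function(tc) {
      mc <- mean(ctl[[tc]], na.rm = TRUE)
      ms <- mean(slt[[tc]], na.rm = TRUE)
      if (!is.finite(mc) || mc == 0) {
        warning("accession ", a, ": zero/missing control mean for ", tc,
                "; relative trait set to NA")
        return(NA_real_)
      }
      ms / mc
    }, numeric(1))
    data.frame(accession = a, t(vals), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res) <- c("accession", unname(traitCols))
  rownames(res) <- NULL
  res
}

#' Reshape a wide relative-trait table to evaluation-ready long form
#'
#' @param rel wide data.frame with an \code{accession} column and one
#'   column per trait.
#' @param group stratum label attached to every row (germination screens
#'   have a single stratum).
#' @return data.frame: accession, group, index, value — the input shape of
#'   [fuzzyEvaluate()].
#' @export
relativeToLong <- function(rel, group = "germination") {
  traits <- setdiff(names(rel), "accession")
  data.frame(
    accession = rep(rel$accession, times = length(traits)),
    group = group,
    index = rep(traits, each = nrow(rel)),
    value = unlist(rel[traits], use.names = FALSE),
    stringsAsFactors = FALSE)
}
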