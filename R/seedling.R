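#' Growth rate as height gain per day
#'
#' @param heightInitial,heightFinal plant heights (cm) at the start and
#'   end of the stress window.
#' @param duration window length in days (> 0).
#' @return cm/day; negative rates are allowed (shrinking seedlings) but
#'   warned about.
#' @export
growthRate <- function(heightInitial, heightFinal, duration) {
  if (any(duration <= 0)) stop("'duration' must be positive")
  r <- (heightFinal - heightInitial) / duration
  if (any(r < 0, na.rm = TRUE))
    warning("negative growth rate (final height below initial)")
  r
}

#' Total chlorophyll from paired absorbances
#'
#' Arnon-type total chlorophyll from extract absorbances at 663 and
#' 645 nm: \eqn{8.02 \cdot A_{663} + 20.21 \cdot A_{645}} (mg/L). The
#' coefficients are exposed because labs differ in extraction solvent;
#' downstream relative traits are insensitive to the choice as long as it
#' is constant.
#'
#' @param A663,A645 absorbance readings (>= 0).
#' @param coef663,coef645 conversion coefficients.
#' @return chlorophyll concentration, mg/L of extract.
#' @examples
#' chlorophyllTotal(0.5, 0.2)
#' @export
chlorophyllTotal <- function(A663, A645, coef663 = 8.02, coef645 = 20.21) {
  if (any(A663 < 0, na.rm = TRUE) || any(A645 < 0, na.rm = TRUE))
    stop("absorbances must be non-negative")
  coef663 * A663 + coef645 * A645
}

#' Potassium / sodium content ratio
#'
#' Maintenance of leaf K+/Na+ under salt is a classic tolerance
#' indicator. Zero sodium yields NA with a warning rather than Inf.
#'
#' @param K,Na contents (same units, e.g. mg/g DW).
#' @return dimensionless ratio.
#' @export
kNaRatio <- function(K, Na) {
  r <- ifelse(Na > 0, K / Na, NA_real_)
  if (any(Na == 0, na.rm = TRUE))
    warning("Na = 0: K/Na ratio set to NA")
  r
}

#' Derived seedling traits per replicate
#'
#' Adds growth rate, total chlorophyll and the K/Na ratio to a raw
#' seedling table (see [simulateSeedling()] for the expected columns).
#'
#' @param table data.frame with columns accession, concentration,
#'   replicate, biomass, height_initial, height_final, duration, A663,
#'   A645, Na, K.
#' @return the input plus columns growth_rate, chlorophyll, k_na.
#' @export
seedlingTraits <- function(table) {
  need <- c("accession", "concentration", "replicate", "biomass",
            "height_initial", "height_final", "duration", "A663", "A645",
            "Na", "K")
  stopifnot(all(need %in% names(table)))
  table$growth_rate <- growthRate(table$height_initial,
                                  table$height_final, table$duration)
  table$chlorophyll <- chlorophyllTotal(table$A663, table$A645)
  table$k_na <- kNaRatio(table$K, table$Na)
  table
}

#' Relative seedling traits per accession and NaCl concentration
#'
#' For each accession and each salt concentration present, divides the
#' replicate mean of biomass, growth rate, chlorophyll and K/Na under salt
#' by the corresponding control (0 NaCl) mean. Accessions without control
#' rows are excluded with a warning; concentrations missing for an
#' accession are simply absent from the output.
#'
#' @param table raw seedling table; derived traits are computed via
#'   [seedlingTraits()] if absent.
#' @return long data.frame: accession, group (the concentration, as
#'   character), index (relative_biomass, relative_growth_rate,
#'   relative_chlorophyll, relative_k_na), value. Ready for
#'   [fuzzyEvaluate()].
#' @export
relativeSeedlingTraits <- function(table) {
  if (!all(c("growth_rate", "chlorophyll", "k_na") %in% names(table)))
    table <- seedlingTraits(table)
  traits <- c(biomass = "relative_biomass",
              growth_rate = "relative_growth_rate",
              chlorophyll = "relative_chlorophyll",
              k_na = "relative_k_na")
  out <- list()
  for (a in sort(unique(table$accession))) {
    sub <- table[table$accession == a, ]
    ctl <- sub[sub$concentration == 0, ]
    if (!nrow(ctl)) {
      warning("accession ", a, " has no control (0 NaCl) rows; excluded")
      next
    }
    for (cc in sort(setdiff(unique(sub$concentration), 0))) {
      slt <- sub[sub$concentration == cc, ]
      for (tc in names(traits)) {
        mc <- mean(ctl[[tc]], na.rm = TRUE)
        ms <- mean(slt[[tc]], na.rm = TRUE)
        val <- if (is.finite(mc) && mc != 0) ms / mc else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          accession = a, group = format(cc), index = traits[[tc]],
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
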