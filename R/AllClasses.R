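#' @import methods
NULL

#' Simulation configuration
#'
#' An S4 container for every parameter of the synthetic-data generators:
#' germination censuses, seedling traits, negative-binomial count matrices
#' with planted differentially expressed genes, term/TF annotations, and
#' protein-protein interaction graphs with planted cliques. All generators
#' draw their randomness from named substreams of the single \code{seed}
#' slot, so adding a generator never perturbs another's output.
#'
#' @slot seed integer root seed for all substreams.
#' @slot nAccessions number of accessions in the germination screen.
#' @slot tolerantFraction proportion of accessions in the latent
#'   salt-tolerant class.
#' @slot saltLevels NaCl concentrations (mol/L) for the seedling screen.
#' @slot nSeedsPerDish seeds sown per culture dish.
#' @slot censusDays strictly increasing germination census schedule (days).
#' @slot nReplicates dishes (or pots) per accession and condition.
#' @slot nGenes genes in the simulated count matrix.
#' @slot nSamplesPerGroup replicates per condition in each contrast.
#' @slot degFraction proportion of genes receiving a planted expression
#'   shift.
#' @slot lfcEffect planted effect size, log2 units.
#' @slot nbDispersion common negative-binomial dispersion alpha in
#'   \eqn{Var = \mu + \alpha \mu^2}.
#' @slot nTerms number of annotation terms to simulate.
#' @slot genesPerTerm length-2 integer range of term sizes.
#' @slot ppiNodes number of nodes of the simulated interaction graph.
#' @slot plantedCliqueSizes sizes of the high-confidence cliques planted in
#'   the interaction graph.
#' @slot backgroundEdgeProb Erdos-Renyi probability of a low-confidence
#'   background edge.
#'
#' @seealso [simConfig()] for the user-facing constructor with the default
#'   study design (104 accessions, 20 seeds per dish, censuses on days
#'   2/4/6/8, triplicates, NaCl at 0.13/0.17/0.22 mol/L, 3 samples per
#'   group).
#' @export
setClass("SimConfig",
  representation(
    seed               = "integer",
    nAccessions        = "integer",
    tolerantFraction   = "numeric",
    saltLevels         = "numeric",
    nSeedsPerDish      = "integer",
    censusDays         = "integer",
    nReplicates        = "integer",
    nGenes             = "integer",
    nSamplesPerGroup   = "integer",
    degFraction        = "numeric",
    lfcEffect          = "numeric",
    nbDispersion       = "numeric",
    nTerms             = "integer",
    genesPerTerm       = "integer",
    ppiNodes           = "integer",
    plantedCliqueSizes = "integer",
    backgroundEdgeProb = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (!prop(object@tolerantFraction))
    msg <- c(msg, "'tolerantFraction' must be a proportion in [0, 1]")
  if (!prop(object@degFraction))
    msg <- c(msg, "'degFraction' must be a proportion in [0, 1]")
  if (!prop(object@backgroundEdgeProb))
    msg <- c(msg, "'backgroundEdgeProb' must be a proportion in [0, 1]")
  if (any(object@saltLevels <= 0))
    msg <- c(msg, "'saltLevels' must be positive concentrations")
  if (length(object@censusDays) < 1L ||
      any(diff(object@censusDays) <= 0) || any(object@censusDays <= 0))
    msg <- c(msg, "'censusDays' must be strictly increasing positive days")
  if (object@nSeedsPerDish < 1L)
    msg <- c(msg, "'nSeedsPerDish' must be >= 1")
  if (object@nbDispersion < 0)
    msg <- c(msg, "'nbDispersion' must be non-negative")
  if (length(object@genesPerTerm) != 2L ||
      any(object@genesPerTerm < 1L) || diff(object@genesPerTerm) < 0)
    msg <- c(msg, "'genesPerTerm' must be an ascending length-2 range")
  if (any(object@plantedCliqueSizes < 2L))
    msg <- c(msg, "'plantedCliqueSizes' must all be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults reproduce the screening design the pipeline targets: 104
#' accessions germinated as 20-seed dishes in triplicate with censuses on
#' days 2, 4, 6 and 8; seedlings stressed at 0.13, 0.17 and 0.22 mol/L
#' NaCl; RNA-seq contrasts with 3 replicates per condition.
#'
#' @param seed integer root seed.
#' @param nAccessions,tolerantFraction germination-screen population.
#' @param saltLevels NaCl concentrations (mol/L).
#' @param nSeedsPerDish,censusDays,nReplicates germination design.
#' @param nGenes,nSamplesPerGroup,degFraction,lfcEffect,nbDispersion
#'   count-simulation parameters.
#' @param nTerms,genesPerTerm annotation-simulation parameters.
#' @param ppiNodes,plantedCliqueSizes,backgroundEdgeProb interaction-graph
#'   parameters.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 500)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nAccessions = 104L,
                      tolerantFraction = 0.2,
                      saltLevels = c(0.13, 0.17, 0.22),
                      nSeedsPerDish = 20L,
                      censusDays = c(2L, 4L, 6L, 8L),
                      nReplicates = 3L,
                      nGenes = 5000L,
                      nSamplesPerGroup = 3L,
                      degFraction = 0.05,
                      lfcEffect = 2,
                      nbDispersion = 0.05,
                      nTerms = 150L,
                      genesPerTerm = c(10L, 80L),
                      ppiNodes = 300L,
                      plantedCliqueSizes = c(10L, 5L),
                      backgroundEdgeProb = 0.01) {
  new("SimConfig",
    seed               = as.integer(seed),
    nAccessions        = as.integer(nAccessions),
    tolerantFraction   = as.numeric(tolerantFraction),
    saltLevels         = as.numeric(saltLevels),
    nSeedsPerDish      = as.integer(nSeedsPerDish),
    censusDays         = as.integer(censusDays),
    nReplicates        = as.integer(nReplicates),
    nGenes             = as.integer(nGenes),
    nSamplesPerGroup   = as.integer(nSamplesPerGroup),
    degFraction        = as.numeric(degFraction),
    lfcEffect          = as.numeric(lfcEffect),
    nbDispersion       = as.numeric(nbDispersion),
    nTerms             = as.integer(nTerms),
    genesPerTerm       = as.integer(genesPerTerm),
    ppiNodes           = as.integer(ppiNodes),
    plantedCliqueSizes = as.integer(plantedCliqueSizes),
    backgroundEdgeProb = as.numeric(backgroundEdgeProb)
  )
}

#' @describeIn SimConfig-class root seed accessor.
#' @param object a \code{SimConfig}.
#' @export
setGeneric("simSeed", function(object) standardGeneric("simSeed"))

#' @rdname SimConfig-class
#' @export
setMethod("simSeed", "SimConfig", function(object) object@seed)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  seed:              ", object@seed, "\n")
  cat("  germination:       ", object@nAccessions, "accessions x",
      object@nReplicates, "dishes,", object@nSeedsPerDish,
      "seeds, censuses d", paste(object@censusDays, collapse = "/"), "\n")
  cat("  tolerant fraction: ", object@tolerantFraction, "\n")
  cat("  NaCl levels:       ",
      paste(object@saltLevels, collapse = ", "), "mol/L\n")
  cat("  counts:            ", object@nGenes, "genes,",
      object@nSamplesPerGroup, "per group, deg_fraction",
      object@degFraction, ", |lfc|", object@lfcEffect,
      ", alpha", object@nbDispersion, "\n")
  cat("  annotations:       ", object@nTerms, "terms, sizes",
      paste(object@genesPerTerm, collapse = "-"), "\n")
  cat("  ppi:               ", object@ppiNodes, "nodes, cliques",
      paste(object@plantedCliqueSizes, collapse = ","),
      ", background p", object@backgroundEdgeProb, "\n")
  invisible(NULL)
})

# Deterministic per-generator substream: a small hash of the stream name
# folded into the root seed, kept below 2^31 for set.seed().
.substreamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

.withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substreamSeed(seed, stream), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}
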