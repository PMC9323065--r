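#' Run the full screening and transcriptome pipeline
#'
#' Drives every stage end to end on synthetic inputs generated from a
#' [SimConfig-class]: germination screen, fuzzy evaluation and selection
#' of extreme accessions, seedling screen with per-concentration fuzzy
#' scoring (the comprehensive-evaluation table), differential expression
#' for the sensitive and tolerant contrasts with DEG calling and common
#' DEG accounting, term enrichment and TF-family tallies, and MCC
#' hub-gene scoring of a confidence-thresholded interaction graph. All
#' stage outputs are written as TSV under \code{outDir} together with a
#' JSON provenance manifest (package version, seed, thresholds, per-stage
#' row counts). Rerunning with the same configuration rewrites identical
#' files.
#'
#' @param config a [SimConfig-class]; its seed drives every stage.
#' @param outDir output directory, created if needed.
#' @param lfcCut,pCut DEG thresholds (strict \code{|log2fc| > lfcCut},
#'   \code{p < pCut}).
#' @param enrichCut adjusted-p cut for the enrichment significance flag.
#' @param ppiThreshold interaction-confidence threshold.
#' @param kHubs number of hub genes to report.
#' @param kTop,kBottom extreme-accession set sizes for the germination
#'   screen.
#' @param verbose emit one progress line per stage.
#' @return invisibly, a named list with every stage's result and the
#'   manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(simConfig(seed = 1, nAccessions = 30, nGenes = 400,
#'                              ppiNodes = 60), tempfile())
#' res$manifest$stages
#' }
#' @export
runPipeline <- function(config = simConfig(), outDir,
                        lfcCut = 1, pCut = 0.01, enrichCut = 0.01,
                        ppiThreshold = 0.9, kHubs = 10,
                        kTop = 5L, kBottom = 13L, verbose = TRUE) {
  stopifnot(is(config, "SimConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] ", stage), ...)
  p <- function(f) file.path(outDir, f)
  counts <- list()
  res <- list()

  say("simulate", "generating germination screen (",
      config@nAccessions, " accessions)")
  germ <- simulateGermination(config)
  writeTsv(germ$census, p("germination_census.tsv"))
  counts$simulate <- nrow(germ$census)

  say("germscreen", "computing germination traits")
  traits <- germinationTraits(germ$census)
  rel <- relativeGerminationTraits(traits)
  writeTsv(traits, p("germination_traits.tsv"))
  writeTsv(rel, p("germination_relative.tsv"))
  counts$germscreen <- nrow(rel)

  say("evaluate", "fuzzy evaluation of the germination screen")
  germScores <- fuzzyEvaluate(relativeToLong(rel))
  writeTsv(germScores, p("germination_scores.tsv"))
  nAcc <- nrow(germScores)
  kT <- min(kTop, nAcc); kB <- min(kBottom, max(0L, nAcc - kT))
  sel <- selectExtremes(germScores, kTop = kT, kBottom = kB)
  keep <- sort(c(sel$tolerant, sel$sensitive))
  res$germination <- list(scores = germScores, selection = sel,
                          classes = germ$classes)

  say("seedscreen", "seedling screen on ", length(keep), " accessions")
  seedling <- simulateSeedling(config, germ$classes[keep])
  relSeed <- relativeSeedlingTraits(seedling)
  writeTsv(seedling, p("seedling_traits.tsv"))
  writeTsv(relSeed, p("seedling_relative.tsv"))
  seedScores <- fuzzyEvaluate(relSeed)
  writeTsv(seedScores, p("seedling_scores.tsv"))
  counts$seedscreen <- nrow(seedScores)
  res$seedling <- list(traits = seedling, scores = seedScores)

  say("deg", "differential expression, 2 contrasts")
  degRes <- list()
  for (stream in c("sensitive", "tolerant")) {
    se <- simulateCounts(config, stream = stream)
    calls <- callDegs(deTest(se), lfcCut = lfcCut, pCut = pCut)
    fk <- fpkm(SummarizedExperiment::assay(se, "counts"),
               SummarizedExperiment::rowData(se)$length)
    writeTsv(calls, p(sprintf("deg_%s.tsv", stream)))
    writeTsv(cbind(gene = rownames(fk), as.data.frame(fk)),
             p(sprintf("fpkm_%s.tsv", stream)))
    degRes[[stream]] <- list(se = se, calls = calls,
                             summary = degSummary(calls))
  }
  common <- commonDegs(degRes$sensitive$calls, degRes$tolerant$calls)
  summaryTab <- data.frame(
    contrast = c("sensitive", "tolerant"),
    n_up = c(degRes$sensitive$summary["n_up"],
             degRes$tolerant$summary["n_up"]),
    n_down = c(degRes$sensitive$summary["n_down"],
               degRes$tolerant$summary["n_down"]),
    n_deg = c(degRes$sensitive$summary["n_deg"],
              degRes$tolerant$summary["n_deg"]),
    n_common = length(common))
  writeTsv(summaryTab, p("deg_summary.tsv"))
  counts$deg <- sum(summaryTab$n_deg)
  res$deg <- c(degRes, list(common = common, summary = summaryTab))

  say("enrich", "term enrichment and TF tallies")
  se <- degRes$sensitive$se
  ann <- simulateAnnotations(config, rownames(se))
  writeGmt(ann$terms, ann$namespace, p("terms.gmt"))
  writeTsv(ann$tf, p("tf_families.tsv"))
  enrRes <- list(); tfRes <- list()
  for (stream in c("sensitive", "tolerant")) {
    calls <- degRes[[stream]]$calls
    degSet <- calls$gene[calls$call != "ns"]
    enr <- enrichTerms(degSet, ann$terms, ann$namespace,
                       sigCut = enrichCut)
    writeTsv(enr, p(sprintf("enrichment_%s.tsv", stream)))
    tfT <- tfTally(calls, ann$tf)
    writeTsv(tfT, p(sprintf("tf_tally_%s.tsv", stream)))
    enrRes[[stream]] <- enr; tfRes[[stream]] <- tfT
  }
  res$enrichment <- enrRes
  res$tf <- c(tfRes,
              list(shared = tfShared(tfRes$sensitive, tfRes$tolerant)))
  counts$enrich <- sum(vapply(enrRes, nrow, integer(1)))

  say("hub", "interaction network and MCC hubs")
  ppi <- simulatePPI(config, rownames(se))
  writeTsv(ppi$edges, p("ppi_edges.tsv"))
  g <- buildGraph(ppi$edges, threshold = ppiThreshold)
  scores <- mccScores(g)
  hubs <- topHubs(scores, g, k = min(kHubs, nrow(scores)))
  writeTsv(scores, p("mcc_scores.tsv"))
  writeTsv(hubs$hubs, p("hub_genes.tsv"))
  counts$hub <- nrow(hubs$hubs)
  res$network <- list(graph = g, scores = scores, hubs = hubs,
                      planted = ppi$cliques)

  manifest <- list(
    package = "saltScreen",
    version = as.character(utils::packageVersion("saltScreen")),
    seed = config@seed,
    thresholds = list(lfc_cut = lfcCut, p_cut = pCut,
                      enrich_cut = enrichCut,
                      ppi_threshold = ppiThreshold, k_hubs = kHubs,
                      k_top = kT, k_bottom = kB),
    stages = counts)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  say("done", length(counts), " stages complete")
  invisible(res)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML file whose keys mirror the arguments of [simConfig()]
#' (under \code{simulation:}) and [runPipeline()] (under
#' \code{thresholds:}), for use by the command-line driver in
#' \code{inst/scripts}.
#'
#' @param path YAML file.
#' @return list with elements \code{config} (a [SimConfig-class]) and
#'   \code{args} (named list of threshold arguments).
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation %||% list()
  cfg <- do.call(simConfig, sim)
  args <- y$thresholds %||% list()
  list(config = cfg, args = args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
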