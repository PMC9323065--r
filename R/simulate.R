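#' Simulate a germination screen
#'
#' Generates per-dish cumulative germination censuses for every accession
#' under a control and a single NaCl treatment, together with plumule and
#' radicle lengths recorded at the final census. Each dish follows a
#' logistic-in-time germination curve; cumulative counts are drawn by
#' binomial thinning of the not-yet-germinated seeds between censuses, so
#' they are monotone non-decreasing and bounded by the seeds sown. Latent
#' accession classes shift the salt-condition asymptote: tolerant
#' accessions germinate under salt at probabilities close to their control
#' asymptote, sensitive ones far below it.
#'
#' @param config a [SimConfig-class].
#' @param saltAsymptote either \code{NULL} (default: per-accession
#'   asymptote multipliers drawn from \code{saltAsymptoteRange}) or a
#'   single number in \[0, 1\] forcing the salt-condition germination
#'   asymptote for every accession (0 gives no germination under salt).
#' @param saltAsymptoteRange list with elements \code{tolerant} and
#'   \code{sensitive}, each a length-2 range of asymptote multipliers.
#' @param saltDelay length-2 range (days) of the germination-onset delay
#'   under salt; set to \code{c(0, 0)} together with unit asymptote
#'   multipliers for a null (no salt effect) simulation.
#' @return list with elements \code{census} (data.frame: accession,
#'   condition, replicate, day, germinated, sown, plumule_length,
#'   radicle_length — lengths only on final-census rows) and
#'   \code{classes} (named character vector, "tolerant"/"sensitive").
#' @examples
#' sim <- simulateGermination(simConfig(seed = 1, nAccessions = 6))
#' head(sim$census)
#' @export
simulateGermination <- function(config,
                                saltAsymptote = NULL,
                                saltAsymptoteRange = list(
                                  tolerant = c(0.70, 0.95),
                                  sensitive = c(0.20, 0.50)),
                                saltDelay = c(0.5, 1.5)) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .withSubstream(config@seed, "germination", {
    nA <- config@nAccessions
    acc <- sprintf("FM%03d", seq_len(nA))
    nTol <- round(nA * config@tolerantFraction)
    classes <- rep("sensitive", nA)
    classes[sample.int(nA, nTol)] <- "tolerant"
    names(classes) <- acc

    days <- config@censusDays
    sown <- config@nSeedsPerDish

    # control logistic curve per accession
    asymC <- stats::runif(nA, 0.85, 1.00)
    t50C  <- stats::runif(nA, 2.5, 4.5)
    scl   <- stats::runif(nA, 0.8, 1.5)
    mult <- if (!is.null(saltAsymptote)) {
      stopifnot(length(saltAsymptote) == 1L,
                saltAsymptote >= 0, saltAsymptote <= 1)
      rep(saltAsymptote, nA) / pmax(asymC, 1e-12)
    } else {
      lo <- ifelse(classes == "tolerant",
                   saltAsymptoteRange$tolerant[1],
                   saltAsymptoteRange$sensitive[1])
      hi <- ifelse(classes == "tolerant",
                   saltAsymptoteRange$tolerant[2],
                   saltAsymptoteRange$sensitive[2])
      stats::runif(nA, lo, hi)
    }
    asymS <- pmin(asymC * mult, 1)
    t50S  <- t50C + stats::runif(nA, saltDelay[1], saltDelay[2])

    # mean plumule/radicle lengths (mm) at final census
    plC <- stats::runif(nA, 25, 45)
    rlC <- stats::runif(nA, 30, 55)
    lenMult <- pmin(1, mult + stats::runif(nA, -0.05, 0.05))

    logistic <- function(t, asym, t50, s) asym / (1 + exp(-(t - t50) / s))

    rows <- vector("list", nA * 2L * config@nReplicates)
    ri <- 0L
    for (i in seq_len(nA)) {
      for (cond in c("control", "salt")) {
        p <- if (cond == "control")
          logistic(days, asymC[i], t50C[i], scl[i])
        else
          logistic(days, asymS[i], t50S[i], scl[i])
        for (rep_ in seq_len(config@nReplicates)) {
          g <- integer(length(days))
          prev <- 0L; pPrev <- 0
          for (d in seq_along(days)) {
            pd <- min(max(p[d], 0), 1)
            inc <- if (pd <= pPrev || prev >= sown) 0L else
              stats::rbinom(1L, sown - prev, (pd - pPrev) / (1 - pPrev))
            g[d] <- prev + inc
            prev <- g[d]; pPrev <- max(pPrev, pd)
          }
          meanPL <- plC[i] * (if (cond == "salt") lenMult[i] else 1)
          meanRL <- rlC[i] * (if (cond == "salt") lenMult[i] else 1)
          pl <- max(0, stats::rnorm(1, meanPL, 0.1 * plC[i]))
          rl <- max(0, stats::rnorm(1, meanRL, 0.1 * rlC[i]))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            accession = acc[i], condition = cond, replicate = rep_,
            day = days, germinated = g, sown = sown,
            plumule_length = c(rep(NA_real_, length(days) - 1L), pl),
            radicle_length = c(rep(NA_real_, length(days) - 1L), rl),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(census = do.call(rbind, rows), classes = classes)
  })
}

#' Simulate a seedling stress trial
#'
#' For each accession and each NaCl level (plus an unsalted control),
#' generates replicate-level fresh biomass, initial/final plant heights
#' over the stress window, leaf-extract absorbances at 663 and 645 nm, and
#' leaf Na+/K+ contents (mg/g DW). Salt depresses biomass, growth,
#' chlorophyll (through the absorbances) and K+ while raising Na+, with a
#' stronger effect for the sensitive class; effects scale linearly with
#' concentration up to the highest salt level.
#'
#' @param config a [SimConfig-class].
#' @param classes named character vector ("tolerant"/"sensitive") with one
#'   entry per accession to simulate, e.g. from [simulateGermination()].
#' @param saltEffect fractional trait depression at the highest NaCl level
#'   per class; set both to 0 for a null (no-effect) simulation.
#' @param noiseCV between-replicate coefficient of variation.
#' @param duration stress window in days.
#' @return data.frame: accession, concentration (mol/L, 0 = control),
#'   replicate, biomass, height_initial, height_final, duration, A663,
#'   A645, Na, K.
#' @examples
#' cls <- c(FM001 = "tolerant", FM002 = "sensitive")
#' head(simulateSeedling(simConfig(seed = 1), cls))
#' @export
simulateSeedling <- function(config, classes,
                             saltEffect = c(tolerant = 0.25,
                                            sensitive = 0.75),
                             noiseCV = 0.05,
                             duration = 6) {
  stopifnot(is(config, "SimConfig"))
  stopifnot(!is.null(names(classes)),
            all(classes %in% c("tolerant", "sensitive")))
  .withSubstream(config@seed, "seedling", {
    acc <- names(classes)
    concs <- c(0, config@saltLevels)
    top <- max(config@saltLevels)
    noisy <- function(mu) mu * pmax(0.05,
      stats::rnorm(length(mu), 1, noiseCV))

    # per-accession control baselines
    nA <- length(acc)
    base <- data.frame(
      biomass = stats::runif(nA, 1.2, 2.5),       # g FW, 10-seedling sample
      h0      = stats::runif(nA, 8, 12),          # cm at stress onset
      grow    = stats::runif(nA, 0.8, 1.4),       # cm/day
      a663    = stats::runif(nA, 0.45, 0.80),
      na      = stats::runif(nA, 0.8, 1.5),       # mg/g DW
      k       = stats::runif(nA, 25, 40))         # mg/g DW
    a645 <- base$a663 * stats::runif(nA, 0.30, 0.45)

    out <- vector("list", nA * length(concs) * config@nReplicates)
    ri <- 0L
    for (i in seq_len(nA)) {
      eff <- saltEffect[[classes[i]]]
      for (cc in concs) {
        # depression in [0,1]; Na accumulation mirrors it
        dep <- eff * cc / top
        m <- max(0, 1 - dep)
        for (rep_ in seq_len(config@nReplicates)) {
          h0 <- noisy(base$h0[i])
          hf <- h0 + noisy(base$grow[i] * m) * duration
          ri <- ri + 1L
          out[[ri]] <- data.frame(
            accession = acc[i], concentration = cc, replicate = rep_,
            biomass = noisy(base$biomass[i] * m),
            height_initial = h0, height_final = hf, duration = duration,
            A663 = noisy(base$a663[i] * m),
            A645 = noisy(a645[i] * m),
            Na = noisy(base$na[i] * (1 + 6 * dep)),
            K = noisy(base$k[i] * m),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate an RNA-seq count matrix with planted DEGs
#'
#' Draws an integer gene-by-sample matrix for a two-condition contrast
#' (control vs salt, \code{nSamplesPerGroup} replicates each) from a
#' negative-binomial model with per-gene baseline means (log-uniform over
#' \[1, 1000\]) and a single shared dispersion \eqn{\alpha}
#' (\eqn{Var = \mu + \alpha\mu^2}). A \code{degFraction} subset of genes
#' receives a mean shift of \eqn{\pm}\code{lfcEffect} log2 units in the
#' salt condition, half up and half down; gene lengths are uniform on
#' 200-10,000 nt.
#'
#' @param config a [SimConfig-class].
#' @param stream substream label; use different labels (e.g. "sensitive",
#'   "tolerant") to draw independent contrasts from one seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{counts}, rowData columns \code{length}, \code{planted},
#'   \code{direction} ("up"/"down"/"ns", the truth labels), and colData
#'   column \code{condition}.
#' @examples
#' se <- simulateCounts(simConfig(seed = 1, nGenes = 200))
#' table(SummarizedExperiment::rowData(se)$direction)
#' @export
simulateCounts <- function(config, stream = "counts") {
  stopifnot(is(config, "SimConfig"))
  .withSubstream(config@seed, paste0("counts:", stream), {
    nG <- config@nGenes
    n  <- config@nSamplesPerGroup
    genes <- sprintf("G%05d", seq_len(nG))
    mu0 <- 10^stats::runif(nG, 0, 3)
    len <- sample(200:10000, nG, replace = TRUE)

    nDeg <- floor(nG * config@degFraction)
    direction <- rep("ns", nG)
    if (nDeg > 0) {
      idx <- sample.int(nG, nDeg)
      up <- idx[seq_len(ceiling(nDeg / 2))]
      dn <- setdiff(idx, up)
      direction[up] <- "up"
      direction[dn] <- "down"
    }
    shift <- ifelse(direction == "up", 2^config@lfcEffect,
             ifelse(direction == "down", 2^-config@lfcEffect, 1))

    rdraw <- function(mu) {
      if (config@nbDispersion < 1e-8) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config@nbDispersion)
    }
    ctrl <- vapply(seq_len(n), function(j) rdraw(mu0), numeric(nG))
    salt <- vapply(seq_len(n), function(j) rdraw(mu0 * shift), numeric(nG))
    counts <- cbind(ctrl, salt)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes,
      c(paste0("control_", seq_len(n)), paste0("salt_", seq_len(n))))

    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(
        length = len, planted = direction != "ns", direction = direction,
        row.names = genes),
      colData = S4Vectors::DataFrame(
        condition = rep(c("control", "salt"), each = n),
        row.names = colnames(counts)))
  })
}

#' Simulate term and transcription-factor annotations
#'
#' Draws \code{nTerms} term-to-gene-set annotations with sizes uniform in
#' \code{genesPerTerm} and namespaces cycling over BP/CC/MF/pathway, plus a
#' TF table assigning a random subset of genes one of 15 plant TF family
#' labels.
#'
#' @param config a [SimConfig-class].
#' @param geneIds character vector of gene identifiers.
#' @param tfFraction proportion of genes annotated as TFs.
#' @return list with \code{terms} (named list of gene-id vectors),
#'   \code{namespace} (named character, one of BP/CC/MF/pathway per term)
#'   and \code{tf} (data.frame: gene, family).
#' @export
simulateAnnotations <- function(config, geneIds, tfFraction = 0.05) {
  stopifnot(is(config, "SimConfig"), length(geneIds) > 0)
  .withSubstream(config@seed, "annotations", {
    nT <- config@nTerms
    span <- config@genesPerTerm[2] - config@genesPerTerm[1] + 1L
    sizes <- config@genesPerTerm[1] +
      sample.int(span, nT, replace = TRUE) - 1L
    sizes <- pmin(sizes, length(geneIds))
    terms <- lapply(sizes, function(s) sample(geneIds, s))
    names(terms) <- sprintf("TERM%04d", seq_len(nT))
    ns <- rep(c("BP", "CC", "MF", "pathway"), length.out = nT)
    names(ns) <- names(terms)

    fams <- c("bHLH", "WRKY", "AP2/ERF", "MYB-MYC", "HSF", "NAC", "GATA",
              "NF", "bZIP", "C2H2", "MADS", "GRAS", "TCP", "Trihelix",
              "DOF")
    nTf <- max(1L, floor(length(geneIds) * tfFraction))
    tfGenes <- sample(geneIds, nTf)
    tf <- data.frame(gene = tfGenes,
                     family = sample(fams, nTf, replace = TRUE),
                     stringsAsFactors = FALSE)
    list(terms = terms, namespace = ns, tf = tf)
  })
}

#' Simulate a confidence-weighted interaction edge list
#'
#' Plants vertex-disjoint cliques whose edges receive confidence scores
#' drawn uniformly from \[0.9, 1\], then overlays Erdos-Renyi background
#' edges (probability \code{backgroundEdgeProb}) with confidences below
#' 0.9, so that thresholding at the STRING "highest confidence" level of
#' 0.900 recovers exactly the planted cliques when the background is off.
#'
#' @param config a [SimConfig-class].
#' @param geneIds gene identifiers; the graph uses the first
#'   \code{ppiNodes} of them (\code{ppiNodes <= length(geneIds)}).
#' @return list with \code{edges} (data.frame: geneA, geneB, confidence)
#'   and \code{cliques} (list of planted member vectors).
#' @export
simulatePPI <- function(config, geneIds) {
  stopifnot(is(config, "SimConfig"),
            config@ppiNodes <= length(geneIds),
            sum(config@plantedCliqueSizes) <= config@ppiNodes)
  .withSubstream(config@seed, "ppi", {
    nodes <- geneIds[seq_len(config@ppiNodes)]
    pool <- sample(nodes)
    cliques <- list()
    at <- 1L
    for (s in config@plantedCliqueSizes) {
      cliques[[length(cliques) + 1L]] <- sort(pool[at:(at + s - 1L)])
      at <- at + s
    }
    edges <- do.call(rbind, lapply(cliques, function(members) {
      pr <- t(utils::combn(members, 2L))
      data.frame(geneA = pr[, 1], geneB = pr[, 2],
                 confidence = stats::runif(nrow(pr), 0.90, 1.00),
                 stringsAsFactors = FALSE)
    }))
    if (config@backgroundEdgeProb > 0) {
      pr <- t(utils::combn(nodes, 2L))
      keep <- stats::runif(nrow(pr)) < config@backgroundEdgeProb
      bg <- data.frame(geneA = pr[keep, 1], geneB = pr[keep, 2],
                       confidence = stats::runif(sum(keep), 0.30, 0.8999),
                       stringsAsFactors = FALSE)
      # planted edges keep their high confidence on collision
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      bg <- bg[!key(bg$geneA, bg$geneB) %in%
                 key(edges$geneA, edges$geneB), ]
      edges <- rbind(edges, bg)
    }
    rownames(edges) <- NULL
    list(edges = edges, cliques = cliques)
  })
}

#' Write a full synthetic input bundle as delimited text
#'
#' Runs every generator in [SimConfig-class] order and writes the TSV/GMT
#' files the pipeline stages read: germination census, seedling traits
#' (long form), counts plus gene lengths and a sample sheet per contrast,
#' term map (GMT), TF table, and the PPI edge list. Truth labels (classes,
#' planted directions, planted cliques) are written alongside with a
#' \code{truth_} prefix.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory, created if needed.
#' @return invisibly, a named list of the written file paths.
#' @export
writeSimulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- list()

  germ <- simulateGermination(config)
  writeTsv(germ$census, paths$census <- p("germination_census.tsv"))
  writeTsv(data.frame(accession = names(germ$classes),
                      class = unname(germ$classes)),
           paths$truth_classes <- p("truth_classes.tsv"))

  keep <- selectAccessions(germ, config)
  seedling <- simulateSeedling(config, germ$classes[keep])
  long <- stats::reshape(
    seedling, direction = "long",
    varying = list(setdiff(names(seedling),
                           c("accession", "concentration", "replicate"))),
    v.names = "value",
    times = setdiff(names(seedling),
                    c("accession", "concentration", "replicate")),
    timevar = "trait", idvar = c("accession", "concentration", "replicate"))
  rownames(long) <- NULL
  writeTsv(long[, c("accession", "concentration", "replicate", "trait",
                    "value")],
           paths$seedling <- p("seedling_traits.tsv"))

  for (stream in c("sensitive", "tolerant")) {
    se <- simulateCounts(config, stream = stream)
    cm <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
    cm <- cbind(gene = rownames(cm), cm)
    writeTsv(cm, paths[[paste0("counts_", stream)]] <-
               p(sprintf("counts_%s.tsv", stream)))
    rd <- SummarizedExperiment::rowData(se)
    writeTsv(data.frame(gene = rownames(se), length = rd$length),
             paths[[paste0("lengths_", stream)]] <-
               p(sprintf("gene_lengths_%s.tsv", stream)))
    writeTsv(data.frame(sample = colnames(se),
                        condition = se$condition),
             paths[[paste0("samples_", stream)]] <-
               p(sprintf("samples_%s.tsv", stream)))
    writeTsv(data.frame(gene = rownames(se), direction = rd$direction),
             paths[[paste0("truth_deg_", stream)]] <-
               p(sprintf("truth_deg_%s.tsv", stream)))
  }

  se <- simulateCounts(config, stream = "sensitive")
  ann <- simulateAnnotations(config, rownames(se))
  writeGmt(ann$terms, ann$namespace,
           paths$terms <- p("terms.gmt"))
  writeTsv(ann$tf, paths$tf <- p("tf_families.tsv"))

  ppi <- simulatePPI(config, rownames(se))
  writeTsv(ppi$edges, paths$ppi <- p("ppi_edges.tsv"))
  writeTsv(data.frame(
      clique = rep(seq_along(ppi$cliques),
                   lengths(ppi$cliques)),
      gene = unlist(ppi$cliques)),
    paths$truth_cliques <- p("truth_cliques.tsv"))

  invisible(paths)
}

# pick the seedling-stage cohort: top/bottom accessions from the
# germination screen (falls back to all accessions for tiny simulations)
selectAccessions <- function(germ, config, kTop = 5L, kBottom = 13L) {
  if (config@nAccessions <= kTop + kBottom)
    return(names(germ$classes))
  traits <- germinationTraits(germ$census)
  rel <- relativeGerminationTraits(traits)
  st <- fuzzyEvaluate(relativeToLong(rel))
  sel <- selectExtremes(stats::setNames(st$total_score, st$accession),
                        kTop = kTop, kBottom = kBottom)
  sort(c(sel$tolerant, sel$sensitive))
}
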