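#' FPKM standardisation
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \eqn{FPKM_{ij} = c_{ij} \times 10^9 / (L_i N_j)} with \eqn{L_i} the
#' gene length (nt) and \eqn{N_j} the library size. Library sizes default
#' to per-sample total counts as the proxy for mapped reads.
#'
#' @param counts integer gene x sample matrix.
#' @param lengths per-gene transcript lengths, nt (> 0).
#' @param librarySizes per-sample library sizes (> 0); defaults to
#'   \code{colSums(counts)}.
#' @return numeric matrix of FPKM values, same dimensions as
#'   \code{counts}.
#' @examples
#' fpkm(matrix(100), lengths = 1000, librarySizes = 1e6)  # 100
#' @export
fpkm <- function(counts, lengths, librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  stopifnot(length(lengths) == nrow(counts),
            length(librarySizes) == ncol(counts))
  counts * 1e9 / outer(lengths, librarySizes)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: the median across genes of the ratio
#' of each sample's count to the gene's geometric mean over all samples,
#' using only genes expressed in every sample.
#'
#' @param counts integer gene x sample matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene with positive counts in every sample; ",
         "cannot estimate size factors")
  apply(counts, 2, function(cnt)
    exp(stats::median(log(cnt[use]) - logGeo[use])))
}

#' Simplified negative-binomial differential-expression test
#'
#' A transparent count-based test for two-condition contrasts:
#' median-of-ratios size factors, per-condition means of normalised
#' counts, a log2 fold change with pseudocount 1
#' (\code{log2((mTreat + 1) / (mRef + 1))}), and a Wald-type test on the
#' log scale using a single method-of-moments common dispersion
#' (\eqn{Var = \mu + \alpha\mu^2}) and a standard-normal reference
#' (the dispersion is pooled over thousands of genes, so the statistic's
#' variance is effectively known). P-values are floored at
#' 1e-15 and BH-adjusted. This is deliberately simpler than the
#' shrinkage machinery of dedicated DE packages; it exists so the
#' thresholding and bookkeeping stages have a self-contained, calibrated
#' upstream test.
#'
#' @param counts integer gene x sample matrix, or a
#'   \code{SummarizedExperiment} with a \code{counts} assay and a
#'   \code{condition} colData column.
#' @param condition per-sample condition labels (ignored for a
#'   SummarizedExperiment input).
#' @param contrast length-2 character \code{c(treatment, reference)}; the
#'   fold change is treatment over reference.
#' @return data.frame: gene, baseMeanRef, baseMeanTreat, log2fc, pvalue,
#'   padj. All-zero genes get log2fc 0 and p 1.
#' @export
deTest <- function(counts, condition = NULL,
                   contrast = c("salt", "control")) {
  if (is(counts, "SummarizedExperiment")) {
    condition <- counts$condition
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts), length(contrast) == 2L)
  trt <- condition == contrast[1]
  ref <- condition == contrast[2]
  if (sum(trt) < 2L || sum(ref) < 2L)
    stop("each condition needs at least 2 replicates")

  sf <- sizeFactors(counts[, trt | ref, drop = FALSE])
  norm <- sweep(counts[, trt | ref, drop = FALSE], 2, sf, "/")
  trtN <- (condition == contrast[1])[trt | ref]
  a <- norm[, !trtN, drop = FALSE]   # reference
  b <- norm[, trtN, drop = FALSE]    # treatment
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)

  # common dispersion, method of moments on within-condition pooled
  # variance of normalised counts
  s2 <- (apply(a, 1, stats::var) * (nA - 1) +
         apply(b, 1, stats::var) * (nB - 1)) / (nA + nB - 2)
  mu <- (mA * nA + mB * nB) / (nA + nB)
  # trimmed mean rather than median: per-gene moment estimates are
  # right-skewed at few replicates and the median biases alpha low,
  # which makes the test anticonservative
  ok <- mu > 5
  alphaHat <- if (any(ok))
    max(0, mean((s2[ok] - mu[ok]) / mu[ok]^2, trim = 0.05,
                na.rm = TRUE))
  else 0

  log2fc <- log2((mB + 1) / (mA + 1))
  # delta method on log2(mean + 1); Var(mean) under NB(mu, alpha)
  vA <- (mA + alphaHat * mA^2) / nA / ((mA + 1)^2 * log(2)^2)
  vB <- (mB + alphaHat * mB^2) / nB / ((mB + 1)^2 * log(2)^2)
  se <- sqrt(vA + vB)
  w <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(w))
  zero <- mA == 0 & mB == 0
  p[zero] <- 1
  log2fc[zero] <- 0
  p <- pmax(p, 1e-15)

  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(nrow(counts)))
  data.frame(gene = genes, baseMeanRef = mA, baseMeanTreat = mB,
             log2fc = log2fc, pvalue = p,
             padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call DEGs by fold-change and significance filters
#'
#' Applies the strict thresholds \code{|log2fc| > lfcCut} and
#' \code{p < pCut}: a gene at exactly the cut is not called. By default
#' the raw p-value is filtered (the adjusted value is carried along);
#' set \code{useAdjusted = TRUE} to filter on BH-adjusted p instead.
#'
#' @param degTable output of [deTest()].
#' @param lfcCut log2 fold-change cut (default 1).
#' @param pCut significance cut (default 0.01).
#' @param useAdjusted filter on \code{padj} instead of \code{pvalue}.
#' @return the table with a \code{call} column ("up"/"down"/"ns") and a
#'   \code{summary} attribute \code{c(n_up, n_down, n_ns)}.
#' @examples
#' tab <- data.frame(gene = c("a", "b"), log2fc = c(2, -2.5),
#'                   pvalue = c(1e-4, 1e-6), padj = c(1e-3, 1e-5))
#' attr(callDegs(tab), "summary")
#' @export
callDegs <- function(degTable, lfcCut = 1, pCut = 0.01,
                     useAdjusted = FALSE) {
  stopifnot(all(c("gene", "log2fc", "pvalue") %in% names(degTable)))
  p <- if (useAdjusted) degTable$padj else degTable$pvalue
  sig <- p < pCut
  call <- ifelse(sig & degTable$log2fc > lfcCut, "up",
          ifelse(sig & degTable$log2fc < -lfcCut, "down", "ns"))
  degTable$call <- call
  attr(degTable, "summary") <- c(n_up = sum(call == "up"),
                                 n_down = sum(call == "down"),
                                 n_ns = sum(call == "ns"))
  degTable
}

#' Summary counts for a called DEG table
#'
#' @param calls output of [callDegs()].
#' @return named integer vector: n_up, n_down, n_deg (= n_up + n_down),
#'   n_ns.
#' @export
degSummary <- function(calls) {
  s <- table(factor(calls$call, levels = c("up", "down", "ns")))
  c(n_up = unname(s["up"]), n_down = unname(s["down"]),
    n_deg = unname(s["up"] + s["down"]), n_ns = unname(s["ns"]))
}

#' Common DEGs of two contrasts
#'
#' Genes called differentially expressed (up or down) in both contrasts;
#' symmetric in its arguments.
#'
#' @param callsA,callsB called tables from [callDegs()] on the same gene
#'   universe.
#' @return character vector of shared DEG identifiers, sorted.
#' @export
commonDegs <- function(callsA, callsB) {
  degA <- callsA$gene[callsA$call != "ns"]
  degB <- callsB$gene[callsB$call != "ns"]
  sort(intersect(degA, degB))
}
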