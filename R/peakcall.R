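#' Per-probe significance against the array's empirical null
#'
#' The per-array neighborhood model consumes a p-value per probe. When none
#' is supplied externally, this robust upper-tail test is used: each probe's
#' intensity is standardized against the genome-wide median and MAD of the
#' sample (z = (x - median) / (1.4826 * MAD)) and p = 1 - Phi(z). The bulk
#' of probes is unbound background, so the median/MAD pair estimates the
#' null location and scale robustly even with enriched regions present.
#'
#' @param track a [ProbeTrack-class] (>= 10 probes for a stable null).
#' @param condition condition whose replicate-mean signal is tested.
#' @return \code{GRanges} of the probes with metadata column \code{p}.
#' @export
probeSignificance <- function(track, condition = NULL) {
  if (nrow(track) < 10L)
    stop("need >= 10 probes for a stable empirical null")
  x <- conditionMeans(track, condition)
  s <- stats::mad(x)  # includes the 1.4826 consistency constant
  if (s == 0)
    stop("degenerate null (MAD = 0): supply per-probe p-values directly")
  z <- (x - stats::median(x)) / s
  out <- granges(rowRanges(track))
  mcols(out)$p <- stats::pnorm(z, lower.tail = FALSE)
  out
}

#' Call peaks with the per-array neighborhood model
#'
#' Two-step rule. Step 1, probe significance: a probe is significant iff at
#' least one adjacent probe lies within \code{neighborMaxGap} (1000 bp,
#' start-to-start) and the average of the two p-values is strictly below
#' \code{probeAlpha} (0.05). Step 2, peak assembly: maximal runs of
#' significant probes in which consecutive significant probes are at most
#' \code{peakProbeGap} (300 bp) apart become peaks when they contain at
#' least \code{minSigProbes} (4) significant probes. A peak spans from the
#' first significant probe's start through the last significant probe's
#' footprint (start + probe length - 1).
#'
#' @param sig \code{GRanges} of probes with metadata column \code{p}
#'   (from [probeSignificance()] or supplied externally); probe width is
#'   taken as the probe length.
#' @param config a [pipelineConfig()].
#' @return \code{GRanges} of peaks with \code{name}, \code{n_sig} (number
#'   of significant probes) and \code{score} (-log10 mean p over them).
#' @export
callPeaks <- function(sig, config = pipelineConfig()) {
  if (is.null(mcols(sig)$p)) stop("sig must carry a 'p' metadata column")
  p <- mcols(sig)$p
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  emptyPeaks <- function() {
    out <- GRanges()
    mcols(out) <- DataFrame(name = character(), n_sig = integer(),
                            score = numeric())
    out
  }
  if (!length(sig)) return(emptyPeaks())
  chr <- as.character(seqnames(sig))
  res <- list()
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    pos <- start(sig)[i]
    if (is.unsorted(pos, strictly = TRUE)) stop("probes must be sorted")
    pk <- callPeaksChrom(pos, p[i], width(sig)[i][1L], config)
    if (nrow(pk)) res[[cc]] <- cbind(chrom = cc, pk)
  }
  if (!length(res)) return(emptyPeaks())
  tab <- do.call(rbind, unname(res))
  out <- GenomicRanges::sort(GRanges(tab$chrom, IRanges(tab$start, tab$end),
                                     n_sig = tab$n_sig, score = tab$score),
                             ignore.strand = TRUE)
  mcols(out)$name <- paste0("peak_", seq_along(out))
  mcols(out) <- mcols(out)[, c("name", "n_sig", "score"), drop = FALSE]
  out
}

#' Step-1 significant probes under the neighborhood rule
#'
#' The neighborhood predicate on its own: probe i is significant iff an
#' adjacent probe j within \code{neighborMaxGap} gives
#' mean(p_i, p_j) < \code{probeAlpha} (strict). Exposed separately so the
#' rule can be inspected; [callPeaks()] applies it then assembles runs.
#'
#' @inheritParams callPeaks
#' @return logical vector parallel to \code{sig}.
#' @export
significantProbes <- function(sig, config = pipelineConfig()) {
  p <- mcols(sig)$p
  chr <- as.character(seqnames(sig))
  out <- logical(length(sig))
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    out[i] <- neighborhoodSignificant(start(sig)[i], p[i], config)
  }
  out
}

neighborhoodSignificant <- function(pos, p, cfg) {
  n <- length(pos)
  sigf <- logical(n)
  if (n >= 2L) {
    gap <- diff(pos)
    pairOK <- gap <= cfg$neighborMaxGap & (p[-n] + p[-1L]) / 2 < cfg$probeAlpha
    sigf[-n] <- pairOK           # significant via right neighbor
    sigf[-1L] <- sigf[-1L] | pairOK  # or via left neighbor
  }
  sigf
}

## one chromosome; pos strictly increasing
callPeaksChrom <- function(pos, p, probeLen, cfg) {
  si <- which(neighborhoodSignificant(pos, p, cfg))
  if (length(si) < cfg$minSigProbes)
    return(data.frame(start = integer(), end = integer(),
                      n_sig = integer(), score = numeric()))
  runId <- cumsum(c(1L, diff(pos[si]) > cfg$peakProbeGap))
  runs <- split(si, runId)
  runs <- runs[lengths(runs) >= cfg$minSigProbes]
  if (!length(runs))
    return(data.frame(start = integer(), end = integer(),
                      n_sig = integer(), score = numeric()))
  data.frame(
    start = vapply(runs, function(r) pos[r[1L]], integer(1)),
    end = vapply(runs, function(r) pos[r[length(r)]] + probeLen - 1L, numeric(1)),
    n_sig = lengths(runs),
    score = vapply(runs, function(r) -log10(mean(p[r])), numeric(1)),
    row.names = NULL)
}

#' Export peaks as BED6 plus a sidecar TSV
#'
#' BED score is \code{round(1000 * min(1, score/10))}; the sidecar carries
#' \code{n_sig} and the mean p per peak.
#'
#' @param peaks result of [callPeaks()].
#' @param path BED output path; the sidecar is \code{<path>.tsv}.
#' @export
writePeaks <- function(peaks, path) {
  out <- granges(peaks)
  mcols(out)$name <- mcols(peaks)$name
  mcols(out)$score <- round(1000 * pmin(1, mcols(peaks)$score / 10))
  rtracklayer::export(out, path, format = "bed")
  side <- data.frame(name = mcols(peaks)$name, n_sig = mcols(peaks)$n_sig,
                     mean_p = 10^(-mcols(peaks)$score))
  utils::write.table(side, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
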