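#' Pipeline configuration
#'
#' One validated bag of every tunable threshold in the pipeline, with the
#' defaults the analysis was designed around. Distances are in bp;
#' intervals relative to the TSS are strand-oriented (negative = upstream).
#'
#' Key defaults: probes are "significant" when an adjacent probe within
#' \code{neighborMaxGap} (1000 bp) gives an averaged p below
#' \code{probeAlpha} (0.05); peaks need \code{minSigProbes} (4) significant
#' probes no more than \code{peakProbeGap} (300 bp) apart. Promoters are the
#' 200 bp upstream of the TSS; divergent gene pairs allow a TSS gap up to
#' 1000 bp and are "bound" within \code{dpgPeakFlank} (500 bp) downstream of
#' either TSS or between the TSSs; TAD boundaries count hits within
#' \code{tadBoundarySlack} (5 kb). The Pol II paused region is TSS-30..+300,
#' the gene body starts at TSS+1000 (genes under \code{minGeneLen} excluded),
#' meta-profiles use a \code{polIIWindow} of 100 bp over TSS-2000..+5000 and
#' a \code{polIISmooth}ing window of 900 bp; domain profiles use a 10 bp
#' window over boundary +/- 10 kb and center +/- 5 kb. Histone tests use
#' TSS..+2000 (H3K4me3) and TSS+200..+2200 (H3K27me3) with BH FDR at 0.05.
#' Enrichment uses 1000 permutations and a 500 bp overlap slack; motif scans
#' use promoter TSS +/- 500 with p < 0.01 (PWM) and p < 0.001 (consensus);
#' pseudomedian smoothing spans 3 probes.
#'
#' @param ... name = value overrides of any field listed above.
#' @return A classed list (\code{PipelineConfig}).
#' @examples
#' cfg <- pipelineConfig(probeAlpha = 0.01)
#' cfg$probeAlpha
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    neighborMaxGap = 1000L, probeAlpha = 0.05, peakProbeGap = 300L,
    minSigProbes = 4L, overlapSlack = 500L, promoterUpstream = 200L,
    dpgMaxTssGap = 1000L, dpgPeakFlank = 500L, tadBoundarySlack = 5000L,
    boundaryFlank = 10000L, centerFlank = 5000L, domainWindow = 10L,
    pausedRegion = c(-30L, 300L), geneBodyStart = 1000L,
    minGeneLen = 1000L, polIISpan = c(-2000L, 5000L), polIIWindow = 100L,
    polIISmooth = 900L, k4Interval = c(0L, 2000L),
    k27Interval = c(200L, 2200L), fdrAlpha = 0.05, nPerm = 1000L,
    motifPromoterFlank = 500L, pwmP = 0.01, consensusP = 0.001,
    markovOrder = 2L, pseudocount = 0.1, pseudomedianSpan = 3L,
    excludeGenes = character())
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  dists <- c("neighborMaxGap", "peakProbeGap", "overlapSlack",
             "promoterUpstream", "dpgMaxTssGap", "dpgPeakFlank",
             "tadBoundarySlack", "boundaryFlank", "centerFlank",
             "domainWindow", "geneBodyStart", "minGeneLen", "polIIWindow",
             "polIISmooth", "motifPromoterFlank")
  for (d in dists) if (cfg[[d]] < 0) stop(d, " must be >= 0")
  for (pr in c("probeAlpha", "fdrAlpha", "pwmP", "consensusP"))
    if (cfg[[pr]] <= 0 || cfg[[pr]] >= 1) stop(pr, " must be in (0,1)")
  if (cfg$minSigProbes < 1L) stop("minSigProbes must be >= 1")
  if (cfg$pseudomedianSpan %% 2L != 1L) stop("pseudomedianSpan must be odd")
  structure(cfg, class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (n in names(x))
    cat(sprintf("  %-20s %s\n", n, paste(x[[n]], collapse = ", ")))
  invisible(x)
}
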