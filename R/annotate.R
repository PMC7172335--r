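#' Promoter regions of gene models
#'
#' The promoter is the \code{upstream} bp immediately 5' of the TSS:
#' genomic [TSS-upstream, TSS-1] for a \code{+} gene, mirrored to
#' [TSS+1, TSS+upstream] for a \code{-} gene, clipped at position 1.
#'
#' @param genes a [GeneModels-class].
#' @param upstream promoter length in bp (default 200).
#' @return \code{GRanges} parallel to the genes.
#' @export
promoterRegions <- function(genes, upstream = 200L) {
  t <- tss(genes)
  plus <- as.character(strand(t)) == "+"
  s <- ifelse(plus, pmax(1L, start(t) - upstream), start(t) + 1L)
  e <- ifelse(plus, start(t) - 1L, start(t) + upstream)
  out <- GRanges(seqnames(t), IRanges(pmin(s, e), pmax(s, e)), strand = strand(t))
  mcols(out)$gene_id <- mcols(t)$gene_id
  out
}

#' Ranked genomic-feature assignment for peaks
#'
#' Each peak receives exactly one feature by testing in rank order
#' promoter > exon > intron > intergenic: the first rank whose region
#' overlaps the peak by at least 1 bp wins ("intron" = inside a gene span
#' but not matching any promoter or exon; no overlap at all = intergenic).
#'
#' @param peaks \code{GRanges}.
#' @param genes a [GeneModels-class].
#' @param config a [pipelineConfig()] (uses \code{promoterUpstream}).
#' @return factor of feature calls, one per peak.
#' @export
assignFeature <- function(peaks, genes, config = pipelineConfig()) {
  prom <- promoterRegions(genes, config$promoterUpstream)
  exn <- unlist(geneExons(genes))
  body <- geneRanges(genes)
  lv <- c("promoter", "exon", "intron", "intergenic")
  out <- rep("intergenic", length(peaks))
  out[IRanges::overlapsAny(peaks, body, ignore.strand = TRUE)] <- "intron"
  out[IRanges::overlapsAny(peaks, exn, ignore.strand = TRUE)] <- "exon"
  out[IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)] <- "promoter"
  factor(out, levels = lv)
}

#' Signed distance from peak midpoints to the nearest TSS
#'
#' Distance from each peak's midpoint to the closest TSS, signed in that
#' gene's orientation: negative upstream of the TSS, positive downstream.
#' Ties in absolute distance resolve to the leftmost TSS.
#'
#' @param peaks \code{GRanges}.
#' @param genes a [GeneModels-class] (must be non-empty).
#' @return integer vector of signed distances (\code{NA} for peaks on
#'   chromosomes without genes).
#' @export
tssDistance <- function(peaks, genes) {
  if (!length(geneRanges(genes))) stop("empty gene set")
  t <- tss(genes)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  out <- rep(NA_integer_, length(peaks))
  tChr <- as.character(seqnames(t))
  pChr <- as.character(seqnames(peaks))
  for (cc in unique(pChr)) {
    ti <- which(tChr == cc)
    if (!length(ti)) next
    tp <- start(t)[ti]
    o <- order(tp)
    tp <- tp[o]; ti <- ti[o]
    pi <- which(pChr == cc)
    lo <- findInterval(mid[pi], tp)
    cand <- cbind(pmax(lo, 1L), pmin(lo + 1L, length(tp)))
    dlo <- abs(mid[pi] - tp[cand[, 1L]])
    dhi <- abs(mid[pi] - tp[cand[, 2L]])
    pick <- ifelse(dhi < dlo, cand[, 2L], cand[, 1L])
    near <- ti[pick]
    d <- mid[pi] - start(t)[near]
    minus <- as.character(strand(t))[near] == "-"
    out[pi] <- ifelse(minus, -d, d)
  }
  out
}

#' Find divergently paired genes (DPGs)
#'
#' A DPG is a (-, +) gene pair in divergent orientation (bodies pointing
#' away from each other: the minus gene's TSS at or left of the plus
#' gene's TSS) whose TSS gap is at most \code{dpgMaxTssGap} (1000 bp). A
#' gene may belong to several pairs; ids on the exclusion list (e.g.,
#' histone-cluster genes) are skipped.
#'
#' @param genes a [GeneModels-class].
#' @param config a [pipelineConfig()] (\code{dpgMaxTssGap},
#'   \code{excludeGenes}).
#' @return data.frame with \code{gene_minus}, \code{gene_plus},
#'   \code{tss_gap}.
#' @export
findDPGs <- function(genes, config = pipelineConfig()) {
  t <- tss(genes)
  keep <- !(mcols(t)$gene_id %in% config$excludeGenes)
  t <- t[keep]
  isM <- as.character(strand(t)) == "-"
  tm <- t[isM]; tp <- t[!isM]
  if (!length(tm) || !length(tp))
    return(data.frame(gene_minus = character(), gene_plus = character(),
                      tss_gap = integer()))
  win <- GRanges(seqnames(tm),
                 IRanges(start(tm), start(tm) + config$dpgMaxTssGap))
  ov <- findOverlaps(win, granges(tp), ignore.strand = TRUE)
  gm <- mcols(tm)$gene_id[queryHits(ov)]
  gp <- mcols(tp)$gene_id[subjectHits(ov)]
  gap <- start(tp)[subjectHits(ov)] - start(tm)[queryHits(ov)]
  out <- data.frame(gene_minus = gm, gene_plus = gp, tss_gap = gap)
  out[order(out$gene_minus, out$gene_plus), , drop = FALSE]
}

#' Is a divergent pair bound by a peak?
#'
#' A pair counts as bound iff some peak overlaps the union of: 500 bp
#' (\code{dpgPeakFlank}) downstream of the minus gene's TSS, 500 bp
#' downstream of the plus gene's TSS, and the inter-TSS span. For a
#' divergent pair that union is the contiguous interval
#' [TSS- - flank, TSS+ + flank].
#'
#' @param peaks \code{GRanges}.
#' @param pairs data.frame from [findDPGs()].
#' @param genes the [GeneModels-class] the pairs refer to.
#' @param config a [pipelineConfig()] (\code{dpgPeakFlank}).
#' @return logical vector, one per pair.
#' @export
dpgBound <- function(peaks, pairs, genes, config = pipelineConfig()) {
  if (!nrow(pairs)) return(logical())
  t <- tss(genes)
  idx <- stats::setNames(seq_along(t), mcols(t)$gene_id)
  im <- idx[pairs$gene_minus]; ip <- idx[pairs$gene_plus]
  if (anyNA(im) || anyNA(ip)) stop("pair refers to unknown gene id")
  reg <- GRanges(seqnames(t)[im],
                 IRanges(pmax(1L, start(t)[im] - config$dpgPeakFlank),
                         start(t)[ip] + config$dpgPeakFlank))
  IRanges::overlapsAny(reg, peaks, ignore.strand = TRUE)
}

#' Peak presence near boundaries
#'
#' A boundary is hit iff a peak lies within \code{slack} bp of it (the
#' boundary interval expanded symmetrically by \code{slack}, then the
#' >= 1 bp overlap rule).
#'
#' @param peaks,boundaries \code{GRanges}.
#' @param slack expansion in bp (default 5000, the TAD-boundary rule).
#' @return list with logical \code{hit} per boundary and the summary
#'   \code{fraction}.
#' @export
nearBoundary <- function(peaks, boundaries, slack = 5000L) {
  if (slack < 0) stop("slack must be >= 0")
  exp <- GRanges(seqnames(boundaries),
                 IRanges(pmax(1L, start(boundaries) - slack),
                         end(boundaries) + slack))
  hit <- IRanges::overlapsAny(exp, peaks, ignore.strand = TRUE)
  list(hit = hit, fraction = if (length(hit)) mean(hit) else 0)
}

#' Peak binding at the two edges of each domain
#'
#' For each domain interval, tests the two width-1 edge boundaries with
#' [nearBoundary()] and reports whether one or both are hit.
#'
#' @param peaks,domains \code{GRanges}.
#' @param slack expansion in bp.
#' @return data.frame with \code{start_hit}, \code{end_hit}, \code{n_hit}
#'   per domain, plus attributes are left to the caller; fractions are
#'   easily computed from the columns.
#' @export
domainBoundaryBinding <- function(peaks, domains, slack = 5000L) {
  sB <- GRanges(seqnames(domains), IRanges(start(domains), width = 1L))
  eB <- GRanges(seqnames(domains), IRanges(end(domains), width = 1L))
  sh <- nearBoundary(peaks, sB, slack)$hit
  eh <- nearBoundary(peaks, eB, slack)$hit
  data.frame(start_hit = sh, end_hit = eh, n_hit = sh + eh)
}
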