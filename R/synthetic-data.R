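#' Simulate a genome annotation with divergent gene pairs
#'
#' Generates a multi-chromosome genome and a non-overlapping gene
#' annotation on both strands in which a chosen fraction of genes is
#' arranged head-to-head as divergent pairs with a TSS gap drawn uniformly
#' from [50, 1000] bp. Unpaired neighbors are kept at least 1100 bp apart
#' so the planted pairs are exactly the divergent pairs present. Genes get
#' a simple two-exon structure (single exon when short).
#'
#' @param nChrom number of chromosomes.
#' @param chromLen chromosome length in bp.
#' @param nGenes total gene count.
#' @param dpgFraction fraction of genes arranged in divergent pairs.
#' @param geneLenRange min/max gene length in bp.
#' @param seed integer seed (generation is bit-reproducible).
#' @return list: \code{genome} (\code{Seqinfo}), \code{genes}
#'   ([GeneModels-class]), \code{truth} (list with \code{dpgs} data.frame).
#' @export
simulateAnnotation <- function(nChrom = 4L, chromLen = 500000L,
                               nGenes = 200L, dpgFraction = 0.3,
                               geneLenRange = c(1500L, 8000L), seed = 1L) {
  if (dpgFraction < 0 || dpgFraction > 1) stop("dpgFraction must be in [0,1]")
  set.seed(seed)
  nPaired <- 2L * floor(round(nGenes * dpgFraction) / 2)
  nPairs <- nPaired %/% 2L
  nSingle <- nGenes - nPaired
  units <- sample(c(rep("pair", nPairs), rep("single", nSingle)))
  chromNames <- paste0("chr", seq_len(nChrom))
  cursor <- stats::setNames(rep(1L, nChrom), chromNames)
  rows <- list()
  dpgs <- list()
  gi <- 0L
  glen <- function() pick1(seq(geneLenRange[1L], geneLenRange[2L]))
  uc <- 0L
  for (u in units) {
    uc <- uc + 1L
    cc <- chromNames[(uc - 1L) %% nChrom + 1L]
    gap <- pick1(1100:3000)
    s <- cursor[cc] + gap
    if (u == "single") {
      len <- glen()
      if (s + len - 1L > chromLen) stop("infeasible packing: genome too small")
      gi <- gi + 1L
      rows[[gi]] <- data.frame(chrom = cc, start = s, end = s + len - 1L,
                               strand = pick1(c("+", "-")),
                               id = sprintf("g%04d", gi))
      cursor[cc] <- s + len - 1L
    } else {
      lenM <- glen(); lenP <- glen()
      tgap <- pick1(50:1000)
      tssM <- s + lenM - 1L
      tssP <- tssM + tgap
      if (tssP + lenP - 1L > chromLen) stop("infeasible packing: genome too small")
      gi <- gi + 1L
      idM <- sprintf("g%04d", gi)
      rows[[gi]] <- data.frame(chrom = cc, start = s, end = tssM,
                               strand = "-", id = idM)
      gi <- gi + 1L
      idP <- sprintf("g%04d", gi)
      rows[[gi]] <- data.frame(chrom = cc, start = tssP,
                               end = tssP + lenP - 1L, strand = "+", id = idP)
      dpgs[[length(dpgs) + 1L]] <- data.frame(gene_minus = idM,
                                              gene_plus = idP,
                                              tss_gap = tgap)
      cursor[cc] <- tssP + lenP - 1L
    }
  }
  tab <- do.call(rbind, rows)
  g <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand)
  mcols(g)$gene_id <- tab$id
  si <- Seqinfo(seqnames = chromNames,
                seqlengths = rep(as.integer(chromLen), nChrom))
  ## two exons with an intron when the gene is long enough
  exl <- lapply(seq_along(g), function(i) {
    len <- width(g)[i]
    if (len < 600L) return(granges(g[i]))
    e1 <- round(len * 0.3); e2 <- round(len * 0.3)
    GRanges(as.character(seqnames(g)[i]),
            IRanges(c(start(g)[i], end(g)[i] - e2 + 1L),
                    c(start(g)[i] + e1 - 1L, end(g)[i])))
  })
  exl <- GRangesList(exl)
  names(exl) <- tab$id
  genes <- GeneModels(g, exl)
  o <- order(tab$chrom, tab$start)
  genes <- GeneModels(g[o], exl[o])
  dpgs <- if (length(dpgs)) do.call(rbind, dpgs)
          else data.frame(gene_minus = character(), gene_plus = character(),
                          tss_gap = integer())
  list(genome = si, genes = genes, truth = list(dpgs = dpgs))
}

## sample() that never interprets a scalar as 1:n
pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

## TRUE for probes whose start falls inside any of the intervals
probeIn <- function(chrom, start, gr) {
  if (!length(gr)) return(rep(FALSE, length(start)))
  pts <- GRanges(chrom, IRanges(start, width = 1L))
  IRanges::overlapsAny(pts, gr, ignore.strand = TRUE)
}

## non-overlapping random intervals with a minimum separation
placeIntervals <- function(genome, n, widthRange, minSep = 2000L) {
  len <- asSeqlengths(genome)
  chrom <- character(); lo <- integer(); hi <- integer()
  tries <- 0L
  while (length(chrom) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place intervals: genome too small")
    cc <- pick1(names(len))
    w <- pick1(seq(widthRange[1L], widthRange[2L]))
    if (w > len[cc]) next
    s <- sample.int(len[cc] - w + 1L, 1L)
    same <- chrom == cc
    if (any(same & lo - minSep <= s + w - 1L & hi + minSep >= s)) next
    chrom <- c(chrom, cc); lo <- c(lo, s); hi <- c(hi, s + w - 1L)
  }
  GenomicRanges::sort(GRanges(chrom, IRanges(lo, hi)), ignore.strand = TRUE)
}

#' Simulate ChIP-chip probe tracks with known ground truth
#'
#' Builds a regular probe grid (default spacing 33 bp, emulating a
#' high-density tiling design) and three marks over it:
#' \describe{
#'   \item{factor}{Gaussian background of sd \code{noiseSd} plus a boxcar
#'     of height \code{peakSnr * noiseSd} over \code{nPeaks} planted,
#'     well-separated peaks (the TF ChIP signal the peak caller targets).}
#'   \item{k27}{broad-domain mark: a plateau of height
#'     \code{domainPlateau} over \code{nDomains} planted domains,
#'     multiplied by \code{domainDepletion} in the mutant condition.}
#'   \item{polii}{TSS-anchored polymerase signal: a paused-region spike
#'     (TSS-30..+300) of height \code{pausedHeight} and a gene-body
#'     plateau (TSS+1000..TES) of height \code{bodyHeight}. Genes are
#'     split between two mutant regimes: regime 1 scales spike and body
#'     by \code{regime1Scale}; regime 2 raises the spike and lowers the
#'     body per \code{regime2Scale}.}
#' }
#'
#' @param genome \code{Seqinfo} or named chromosome lengths.
#' @param genes a [GeneModels-class] (for the Pol II mark).
#' @param spacing probe spacing in bp.
#' @param probeLength probe length in bp.
#' @param nPeaks,peakWidth,peakSnr planted factor peaks.
#' @param nDomains,domainWidthRange,domainPlateau,domainDepletion planted
#'   broad domains.
#' @param pausedHeight,bodyHeight,regime1Scale,regime2Scale Pol II shape;
#'   each scale is c(paused multiplier, body multiplier) for the mutant.
#' @param noiseSd background noise sd.
#' @param marks which marks to generate (subset of factor, k27, polii);
#'   earlier marks' draws are unaffected by dropping later ones.
#' @param seed integer seed.
#' @return list: \code{tracks} (list of [ProbeTrack-class]: factor, k27,
#'   polii), \code{truth} (peaks GRanges, domains GRanges with a
#'   \code{depletion} column, regimes data.frame).
#' @export
simulateChipTracks <- function(genome, genes = NULL, spacing = 33L,
                               probeLength = 50L, nPeaks = 150L,
                               peakWidth = 300L, peakSnr = 4,
                               nDomains = 10L,
                               domainWidthRange = c(10000L, 30000L),
                               domainPlateau = 2, domainDepletion = 0.5,
                               pausedHeight = 4, bodyHeight = 1,
                               regime1Scale = c(0.5, 0.5),
                               regime2Scale = c(1.5, 0.5),
                               noiseSd = 0.3,
                               marks = c("factor", "k27", "polii"),
                               seed = 1L) {
  marks <- match.arg(marks, several.ok = TRUE)
  if (spacing <= 0) stop("spacing must be > 0")
  if (peakSnr < 0) stop("peakSnr must be >= 0")
  if (domainDepletion <= 0 || domainDepletion > 1)
    stop("domainDepletion must be in (0, 1]")
  len <- asSeqlengths(genome)
  if (spacing > max(len)) stop("spacing exceeds the genome length")
  set.seed(seed)
  starts <- lapply(names(len), function(cc)
    seq.int(1L, max(1L, len[[cc]] - probeLength + 1L), by = spacing))
  chrom <- rep(names(len), lengths(starts))
  pos <- unlist(starts, use.names = FALSE)
  nP <- length(pos)
  noise <- function() stats::rnorm(nP, 0, noiseSd)

  factorTrack <- NULL
  peaks <- GRanges()
  if ("factor" %in% marks) {
    peaks <- placeIntervals(genome, nPeaks, c(peakWidth, peakWidth))
    mcols(peaks)$name <- paste0("true_peak_", seq_along(peaks))
    inPeak <- probeIn(chrom, pos, peaks)
    factorTrack <- ProbeTrack(chrom, pos,
                              noise() + peakSnr * noiseSd * inPeak,
                              probeLength = probeLength, condition = "chip",
                              seqinfo = genome)
  }

  k27 <- NULL
  domains <- GRanges()
  if ("k27" %in% marks) {
    domains <- placeIntervals(genome, nDomains, domainWidthRange,
                              minSep = 5000L)
    mcols(domains)$name <- paste0("domain_", seq_along(domains))
    mcols(domains)$depletion <- domainDepletion
    inDom <- probeIn(chrom, pos, domains)
    k27 <- ProbeTrack(chrom, pos,
                      cbind(noise() + domainPlateau * inDom,
                            noise() + domainPlateau * domainDepletion * inDom),
                      probeLength = probeLength,
                      condition = c("control", "mutant"), seqinfo = genome)
  }

  polii <- NULL
  regimes <- data.frame(gene_id = character(), regime = integer())
  if ("polii" %in% marks && !is.null(genes) && length(genes)) {
    t0 <- tss(genes); t1 <- tes(genes)
    paused <- relRegion(t0, t1, c(-30L, 300L))
    body <- relRegion(t0, t1, NULL, bodyStart = 1000L)
    bodyOK <- !mcols(body)$empty & width(geneRanges(genes)) > 1000L
    nG <- length(genes)
    regime <- sample(rep_len(c(1L, 2L), nG))
    regimes <- data.frame(gene_id = geneIds(genes), regime = regime)
    scPaused <- ifelse(regime == 1L, regime1Scale[1L], regime2Scale[1L])
    scBody <- ifelse(regime == 1L, regime1Scale[2L], regime2Scale[2L])
    pts <- GRanges(chrom, IRanges(pos, width = 1L))
    addRegion <- function(reg, keep, hCtrl, hMut) {
      ov <- findOverlaps(reg[keep], pts, ignore.strand = TRUE)
      gI <- which(keep)[queryHits(ov)]
      pI <- subjectHits(ov)
      dc <- rowsum(rep(hCtrl, length(pI)), pI)
      dm <- rowsum(hMut[gI], pI)
      i <- as.integer(rownames(dc))
      list(i = i, ctrl = dc[, 1L], mut = dm[, 1L])
    }
    ctrl <- numeric(nP); mut <- numeric(nP)
    aP <- addRegion(paused, rep(TRUE, nG), pausedHeight,
                    pausedHeight * scPaused)
    ctrl[aP$i] <- ctrl[aP$i] + aP$ctrl; mut[aP$i] <- mut[aP$i] + aP$mut
    if (any(bodyOK)) {
      aB <- addRegion(body, bodyOK, bodyHeight, bodyHeight * scBody)
      ctrl[aB$i] <- ctrl[aB$i] + aB$ctrl; mut[aB$i] <- mut[aB$i] + aB$mut
    }
    polii <- ProbeTrack(chrom, pos, cbind(ctrl + noise(), mut + noise()),
                        probeLength = probeLength,
                        condition = c("control", "mutant"), seqinfo = genome)
  }
  list(tracks = list(factor = factorTrack, k27 = k27, polii = polii),
       truth = list(peaks = peaks, domains = domains, regimes = regimes))
}

#' Simulate promoter-window sequences with planted motifs
#'
#' I.i.d. background sequence of the given GC content, one window of
#' 2*flank+1 bp per gene; a \code{plantRate} fraction of windows receives
#' one exact-consensus motif instance (each degenerate position realized
#' uniformly among its admitted bases) at a recorded position and strand.
#'
#' @param genes a [GeneModels-class] (window per gene, named by id).
#' @param motif IUPAC consensus to plant (default YAACKG).
#' @param plantRate fraction of windows with a planted instance.
#' @param gc background GC proportion.
#' @param flank promoter half-window in bp.
#' @param seed integer seed.
#' @return list: \code{seqs} (\code{DNAStringSet}), \code{truth}
#'   (data.frame gene_id, pos, strand, site).
#' @export
simulateSequences <- function(genes, motif = "YAACKG", plantRate = 0.5,
                              gc = 0.4, flank = 500L, seed = 1L) {
  if (plantRate < 0 || plantRate > 1) stop("plantRate must be in [0,1]")
  codes <- strsplit(toupper(motif), "")[[1]]
  if (!all(codes %in% names(IUPAC))) stop("invalid IUPAC code in motif")
  wlen <- 2L * flank + 1L
  if (length(codes) > wlen) stop("motif longer than the promoter window")
  set.seed(seed)
  ids <- geneIds(genes)
  nW <- length(ids)
  pBase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mat <- matrix(sample(BASES, nW * wlen, replace = TRUE, prob = pBase),
                nrow = nW)
  planted <- sort(sample.int(nW, round(plantRate * nW)))
  truth <- data.frame(gene_id = character(), pos = integer(),
                      strand = character(), site = character())
  for (i in planted) {
    inst <- vapply(codes, function(cd) sample(IUPAC[[cd]], 1L), character(1))
    strandI <- sample(c("+", "-"), 1L)
    put <- if (strandI == "+") inst else rev(c(A = "T", C = "G", G = "C",
                                               T = "A")[inst])
    p <- sample.int(wlen - length(codes) + 1L, 1L)
    mat[i, p:(p + length(codes) - 1L)] <- put
    truth <- rbind(truth, data.frame(gene_id = ids[i], pos = p,
                                     strand = strandI,
                                     site = paste(inst, collapse = "")))
  }
  seqs <- Biostrings::DNAStringSet(apply(mat, 1L, paste, collapse = ""))
  names(seqs) <- ids
  list(seqs = seqs, truth = truth)
}
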