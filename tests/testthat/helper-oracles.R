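## Independent brute-force oracles, written as direct transcriptions of the
## rules; deliberately naive so they share no code path with the package.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## peak caller: per-probe neighborhood test, then explicit maximal-run
## enumeration (one chromosome)
oracleCallPeaks <- function(pos, p, probeLen, alpha = 0.05,
                            neighborGap = 1000, runGap = 300, minSig = 4) {
  n <- length(pos)
  sig <- logical(n)
  for (i in seq_len(n)) {
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > n) next
      if (abs(pos[j] - pos[i]) <= neighborGap &&
          (p[i] + p[j]) / 2 < alpha) sig[i] <- TRUE
    }
  }
  S <- which(sig)
  peaks <- list()
  k <- 1L
  while (k <= length(S)) {
    run <- S[k]
    while (k < length(S) && pos[S[k + 1L]] - pos[S[k]] <= runGap) {
      k <- k + 1L
      run <- c(run, S[k])
    }
    if (length(run) >= minSig)
      peaks[[length(peaks) + 1L]] <-
        data.frame(start = pos[run[1L]],
                   end = pos[run[length(run)]] + probeLen - 1,
                   n_sig = length(run), score = -log10(mean(p[run])))
    k <- k + 1L
  }
  if (!length(peaks))
    return(data.frame(start = integer(), end = integer(),
                      n_sig = integer(), score = numeric()))
  do.call(rbind, peaks)
}

## ranked feature call by looping over every gene
oracleAssignFeature <- function(pkStart, pkEnd, genes, chrom, upstream = 200) {
  g <- geneRanges(genes)
  ex <- geneExons(genes)
  ov <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  inProm <- inExon <- inGene <- FALSE
  for (i in seq_along(g)) {
    if (as.character(seqnames(g))[i] != chrom) next
    gs <- start(g)[i]; ge <- end(g)[i]
    minus <- as.character(strand(g))[i] == "-"
    tssP <- if (minus) ge else gs
    ps <- if (minus) tssP + 1 else max(1, tssP - upstream)
    pe <- if (minus) tssP + upstream else tssP - 1
    if (ps <= pe && ov(pkStart, pkEnd, ps, pe)) inProm <- TRUE
    e <- ex[[i]]
    for (k in seq_along(e))
      if (ov(pkStart, pkEnd, start(e)[k], end(e)[k])) inExon <- TRUE
    if (ov(pkStart, pkEnd, gs, ge)) inGene <- TRUE
  }
  if (inProm) "promoter" else if (inExon) "exon"
  else if (inGene) "intron" else "intergenic"
}

## signed TSS distance by scanning every TSS
oracleTssDistance <- function(mid, genes, chrom) {
  g <- geneRanges(genes)
  best <- NA_integer_
  for (i in seq_along(g)) {
    if (as.character(seqnames(g))[i] != chrom) next
    minus <- as.character(strand(g))[i] == "-"
    tssP <- if (minus) end(g)[i] else start(g)[i]
    d <- if (minus) tssP - mid else mid - tssP
    if (is.na(best) || abs(d) < abs(best)) best <- d
  }
  best
}

## DPGs by looping over all ordered gene pairs
oracleDPGs <- function(genes, maxGap = 1000) {
  g <- geneRanges(genes)
  ids <- geneIds(genes)
  out <- list()
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (as.character(strand(g))[i] != "-" ||
        as.character(strand(g))[j] != "+") next
    if (as.character(seqnames(g))[i] != as.character(seqnames(g))[j]) next
    tm <- end(g)[i]; tp <- start(g)[j]
    gap <- tp - tm
    if (gap >= 0 && gap <= maxGap)
      out[[length(out) + 1L]] <- data.frame(gene_minus = ids[i],
                                            gene_plus = ids[j],
                                            tss_gap = gap)
  }
  if (!length(out))
    return(data.frame(gene_minus = character(), gene_plus = character(),
                      tss_gap = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_minus, res$gene_plus), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## overlap count by double loop
oracleOverlapCount <- function(a, b, slack = 0) {
  n <- 0L
  for (i in seq_along(a)) {
    hit <- FALSE
    for (j in seq_along(b)) {
      if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
      if (start(a)[i] <= end(b)[j] + slack &&
          start(b)[j] - slack <= end(a)[i]) hit <- TRUE
    }
    n <- n + hit
  }
  n
}

## Fisher two-sided p by enumerating all tables with the observed margins
oracleFisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
  probTab <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (min(b, cc, d) < 0) return(NA_real_)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(N, c1))
  }
  pv <- vapply(0:min(r1, c1), probTab, numeric(1))
  pv <- pv[!is.na(pv)]
  pObs <- probTab(m[1, 1])
  sum(pv[pv <= pObs * (1 + 1e-7)])
}

## hypergeometric upper tail by summing point masses
oracleHyper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## pseudomedian of one window by listing every Walsh average
oracleWalsh <- function(v) {
  w <- c()
  for (i in seq_along(v)) for (j in i:length(v)) w <- c(w, (v[i] + v[j]) / 2)
  median(w)
}

## windowed profile value by direct per-position recomputation
oracleProfilePoint <- function(relPos, vals, p, window, stat = "mean") {
  h <- window / 2
  inWin <- relPos >= ceiling(p - h) & relPos <= ceiling(p + h) - 1
  if (!any(inWin)) return(NA_real_)
  if (stat == "mean") mean(vals[inWin]) else median(vals[inWin])
}

## quick single-sample track on one chromosome
makeTrack <- function(pos, vals, chrom = "chr1", probeLength = 50,
                      condition = "chip", seqinfo = NULL) {
  ProbeTrack(rep(chrom, length(pos)), pos, vals, probeLength = probeLength,
             condition = condition, seqinfo = seqinfo)
}

## two-condition track from explicit value vectors
makeTrack2 <- function(pos, ctrl, mut, chrom = "chr1", probeLength = 50) {
  ProbeTrack(rep(chrom, length(pos)), pos, cbind(ctrl, mut),
             probeLength = probeLength, condition = c("control", "mutant"))
}

## minimal GeneModels from vectors
makeGenes <- function(chrom, start, end, strand, ids = NULL) {
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(g)$gene_id <- if (is.null(ids)) sprintf("g%03d", seq_along(g)) else ids
  GeneModels(g)
}
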