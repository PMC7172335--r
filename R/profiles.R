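#' Anchors for meta-profiles
#'
#' \code{boundaryAnchors()} returns width-1 anchors at both edges of each
#' domain; end-edge anchors are put on the minus strand so that, with
#' \code{flip = TRUE} in [anchoredProfile()], positive relative positions
#' always point into the domain. \code{centerAnchors()} returns the domain
#' midpoints (unstranded).
#'
#' @param domains \code{GRanges}.
#' @return \code{GRanges} of width 1 with an \code{anchor_id} column.
#' @export
boundaryAnchors <- function(domains) {
  ids <- if (!is.null(mcols(domains)$name)) as.character(mcols(domains)$name)
         else paste0("domain_", seq_along(domains))
  s <- GRanges(seqnames(domains), IRanges(start(domains), width = 1L), strand = "+")
  e <- GRanges(seqnames(domains), IRanges(end(domains), width = 1L), strand = "-")
  mcols(s)$anchor_id <- paste0(ids, ".start")
  mcols(e)$anchor_id <- paste0(ids, ".end")
  c(s, e)
}

#' @rdname boundaryAnchors
#' @export
centerAnchors <- function(domains) {
  ids <- if (!is.null(mcols(domains)$name)) as.character(mcols(domains)$name)
         else paste0("domain_", seq_along(domains))
  mid <- floor((start(domains) + end(domains)) / 2)
  out <- GRanges(seqnames(domains), IRanges(mid, width = 1L), strand = "*")
  mcols(out)$anchor_id <- ids
  out
}

#' Anchored sliding-window meta-profile
#'
#' For each anchor, probe signals within \code{span} of the anchor are
#' placed at anchor-relative coordinates (reflected when \code{flip} and
#' the anchor is on the minus strand, so minus-strand genes and domain
#' end-boundaries read in the same orientation as plus-strand ones). The
#' per-entity value at relative position p is \code{stat} over all probes
#' whose start falls in the centered window [p - window/2, p + window/2)
#' stepping 1 bp; the aggregate applies the same \code{stat} across
#' entities per position, ignoring empty windows (never zero-filling).
#'
#' @param track a [ProbeTrack-class].
#' @param anchors width-1 \code{GRanges} (e.g. [tss()], [boundaryAnchors()],
#'   [centerAnchors()]); an \code{anchor_id} or \code{gene_id} column names
#'   the entities.
#' @param span integer c(upstream, downstream) relative span in bp, e.g.
#'   \code{c(-10000, 10000)}.
#' @param window window length in bp.
#' @param stat \code{"mean"} or \code{"median"}.
#' @param flip reflect minus-strand anchors (default TRUE).
#' @param condition which condition of the track to profile.
#' @return A [ProfileMatrix-class].
#' @export
anchoredProfile <- function(track, anchors, span = c(-10000L, 10000L),
                            window = 10L, stat = c("mean", "median"),
                            flip = TRUE, condition = NULL) {
  stat <- match.arg(stat)
  if (span[1L] > span[2L]) stop("span must be (lo, hi) with lo <= hi")
  if (window < 1L) stop("window must be >= 1")
  if (!length(anchors)) stop("anchors must be non-empty")
  vals <- conditionMeans(track, condition)
  pPos <- start(rowRanges(track))
  pChr <- as.character(seqnames(rowRanges(track)))
  ids <- if (!is.null(mcols(anchors)$anchor_id)) as.character(mcols(anchors)$anchor_id)
         else if (!is.null(mcols(anchors)$gene_id)) as.character(mcols(anchors)$gene_id)
         else paste0("anchor_", seq_along(anchors))
  grid <- seq.int(span[1L], span[2L])
  h <- window / 2
  M <- matrix(NA_real_, nrow = length(anchors), ncol = length(grid),
              dimnames = list(ids, NULL))
  aChr <- as.character(seqnames(anchors))
  aPos <- start(anchors)
  aFlip <- flip & as.character(strand(anchors)) == "-"
  lo <- as.integer(ceiling(grid - h))
  hi <- as.integer(ceiling(grid + h) - 1)
  for (i in seq_along(anchors)) {
    sel <- which(pChr == aChr[i])
    if (!length(sel)) next
    rel <- if (aFlip[i]) aPos[i] - pPos[sel] else pPos[sel] - aPos[i]
    keep <- rel >= span[1L] - window & rel <= span[2L] + window
    if (!any(keep)) next
    rel <- rel[keep]
    v <- vals[sel][keep]
    o <- order(rel)
    rel <- rel[o]; v <- v[o]
    Fhi <- findInterval(hi, rel)
    Flo <- findInterval(lo - 1L, rel)
    cnt <- Fhi - Flo
    if (stat == "mean") {
      cs <- c(0, cumsum(v))
      row <- (cs[Fhi + 1L] - cs[Flo + 1L]) / cnt
      row[cnt == 0L] <- NA_real_
      M[i, ] <- row
    } else {
      nz <- which(cnt > 0L)
      row <- rep(NA_real_, length(grid))
      row[nz] <- vapply(nz, function(j)
        stats::median(v[(Flo[j] + 1L):Fhi[j]]), numeric(1))
      M[i, ] <- row
    }
  }
  aggFun <- if (stat == "mean") function(x) mean(x, na.rm = TRUE)
            else function(x) stats::median(x, na.rm = TRUE)
  agg <- apply(M, 2L, function(col) if (all(is.na(col))) NA_real_ else aggFun(col))
  new("ProfileMatrix", positions = as.integer(grid), values = M,
      aggregate = as.numeric(agg), entityIds = ids, stat = stat,
      window = as.integer(window))
}

#' @describeIn anchoredProfile accessors for the aggregate curve and the
#'   relative positions.
#' @param x a \code{ProfileMatrix}.
#' @export
profileAggregate <- function(x) x@aggregate

#' @rdname anchoredProfile
#' @export
profilePositions <- function(x) x@positions

#' @rdname anchoredProfile
#' @export
profileValues <- function(x) x@values

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@values), "entities x",
      length(object@positions), "positions (",
      min(object@positions), "..", max(object@positions), "bp ), window",
      object@window, "bp,", object@stat, "\n")
})

#' Pooled-probe signal test inside domains
#'
#' Pools every probe value falling inside any domain, separately for the
#' two conditions, and compares them with a two-sample t test (Welch by
#' default; set \code{var.equal = TRUE} for the pooled-variance variant).
#'
#' @param track a [ProbeTrack-class] carrying both conditions.
#' @param domains \code{GRanges}.
#' @param control,mutant condition labels.
#' @param var.equal passed to [stats::t.test()].
#' @return list with \code{mean_ctrl}, \code{mean_mut}, \code{t}, \code{p},
#'   \code{df}, \code{n}.
#' @export
domainSignalTest <- function(track, domains, control = "control",
                             mutant = "mutant", var.equal = FALSE) {
  inDom <- IRanges::overlapsAny(rowRanges(track), domains, ignore.strand = TRUE)
  if (sum(inDom) < 2L) stop("insufficient data: < 2 probes inside the domains")
  xc <- conditionMeans(track, control)[inDom]
  xm <- conditionMeans(track, mutant)[inDom]
  if (identical(xc, xm))
    return(list(mean_ctrl = mean(xc), mean_mut = mean(xm), t = 0, p = 1,
                df = NA_real_, n = sum(inDom)))
  if (stats::sd(xc) == 0 && stats::sd(xm) == 0)  # noiseless shift
    return(list(mean_ctrl = mean(xc), mean_mut = mean(xm),
                t = sign(mean(xc) - mean(xm)) * Inf, p = 0,
                df = NA_real_, n = sum(inDom)))
  tt <- stats::t.test(xc, xm, var.equal = var.equal)
  list(mean_ctrl = mean(xc), mean_mut = mean(xm),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = sum(inDom))
}

## strand-oriented interval relative to the TSS, in genome coordinates;
## rel = c(lo, hi) with negative = upstream. "body" = TSS+bodyStart .. TES.
relRegion <- function(tssGr, tesGr, rel, bodyStart = NULL) {
  plus <- as.character(strand(tssGr)) == "+"
  tp <- start(tssGr)
  if (is.null(bodyStart)) {
    s <- ifelse(plus, tp + rel[1L], tp - rel[2L])
    e <- ifelse(plus, tp + rel[2L], tp - rel[1L])
  } else {
    te <- start(tesGr)
    s <- ifelse(plus, tp + bodyStart, te)
    e <- ifelse(plus, te, tp - bodyStart)
  }
  bad <- s > e
  out <- GRanges(seqnames(tssGr), IRanges(pmax(1L, pmin(s, e)), pmax(s, e, 1L)))
  mcols(out)$empty <- bad
  out
}

#' Classify RNA Pol II response at paused regions
#'
#' Per gene of length >= \code{minGeneLen} (1000 bp) with probes in the
#' paused region (TSS-30 .. TSS+300, strand-oriented) in both conditions:
#' category 1 if the mutant's median paused signal is lower than the
#' control's (reduced recruitment), category 2 if higher (paused
#' accumulation); exact ties and genes failing the preconditions are
#' excluded with a reason. Gene-body medians (TSS+1000 .. TES) are reported
#' alongside.
#'
#' @param track Pol II [ProbeTrack-class] with both conditions.
#' @param genes a [GeneModels-class].
#' @param control,mutant condition labels.
#' @param config a [pipelineConfig()].
#' @return data.frame: \code{gene_id}, \code{category} (1/2/excluded),
#'   \code{reason}, paused and body medians per condition.
#' @export
classifyPolII <- function(track, genes, control = "control",
                          mutant = "mutant", config = pipelineConfig()) {
  t0 <- tss(genes); t1 <- tes(genes)
  g <- geneRanges(genes)
  paused <- relRegion(t0, t1, config$pausedRegion)
  body <- relRegion(t0, t1, NULL, bodyStart = config$geneBodyStart)
  bodyEmpty <- mcols(body)$empty | width(g) <= config$geneBodyStart
  xc <- conditionMeans(track, control)
  xm <- conditionMeans(track, mutant)
  probes <- rowRanges(track)
  ovP <- findOverlaps(paused, probes, ignore.strand = TRUE)
  ovB <- findOverlaps(body, probes, ignore.strand = TRUE)
  pl <- split(subjectHits(ovP), factor(queryHits(ovP), levels = seq_along(g)))
  bl <- split(subjectHits(ovB), factor(queryHits(ovB), levels = seq_along(g)))
  n <- length(g)
  out <- data.frame(gene_id = geneIds(genes),
                    category = rep("excluded", n), reason = rep("", n),
                    paused_ctrl = NA_real_, paused_mut = NA_real_,
                    body_ctrl = NA_real_, body_mut = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (width(g)[i] < config$minGeneLen) {
      out$reason[i] <- "short_gene"; next
    }
    pi <- pl[[i]]
    if (!length(pi)) { out$reason[i] <- "no_paused_probes"; next }
    out$paused_ctrl[i] <- stats::median(xc[pi])
    out$paused_mut[i] <- stats::median(xm[pi])
    bi <- if (bodyEmpty[i]) integer() else bl[[i]]
    if (length(bi)) {
      out$body_ctrl[i] <- stats::median(xc[bi])
      out$body_mut[i] <- stats::median(xm[bi])
    }
    if (out$paused_mut[i] < out$paused_ctrl[i]) out$category[i] <- "1"
    else if (out$paused_mut[i] > out$paused_ctrl[i]) out$category[i] <- "2"
    else out$reason[i] <- "tie"
  }
  out$category <- factor(out$category, levels = c("1", "2", "excluded"))
  out
}

#' Per-gene two-condition tests over a TSS-anchored region
#'
#' For every gene, compares the two conditions' probe values in a
#' strand-oriented region with a Mann-Whitney U test or a t test (Welch),
#' then adjusts over all tested genes with Benjamini-Hochberg.
#' Named regions: \code{"paused"} (TSS-30..+300), \code{"body"}
#' (TSS+1000..TES), \code{"k4"} (TSS..+2000), \code{"k27"}
#' (TSS+200..+2200); or a custom \code{c(lo, hi)} relative to the TSS.
#'
#' @param track [ProbeTrack-class] with both conditions.
#' @param genes a [GeneModels-class].
#' @param region region name or numeric \code{c(lo, hi)}.
#' @param test \code{"mannwhitney"} or \code{"ttest"}.
#' @param control,mutant condition labels.
#' @param fdr apply BH adjustment (default TRUE).
#' @param config a [pipelineConfig()].
#' @return data.frame: \code{gene_id}, \code{stat}, \code{p}, \code{q},
#'   \code{direction} (up/down, sign of mutant - control mean),
#'   \code{n_probes}, \code{skipped}, \code{reason}.
#' @export
regionTest <- function(track, genes, region = "k27",
                       test = c("mannwhitney", "ttest"),
                       control = "control", mutant = "mutant",
                       fdr = TRUE, config = pipelineConfig()) {
  test <- match.arg(test)
  t0 <- tss(genes); t1 <- tes(genes)
  reg <- if (is.numeric(region)) relRegion(t0, t1, region)
    else switch(region,
      paused = relRegion(t0, t1, config$pausedRegion),
      body = relRegion(t0, t1, NULL, bodyStart = config$geneBodyStart),
      k4 = relRegion(t0, t1, config$k4Interval),
      k27 = relRegion(t0, t1, config$k27Interval),
      stop("unknown region: ", region))
  xc <- conditionMeans(track, control)
  xm <- conditionMeans(track, mutant)
  ov <- findOverlaps(reg, rowRanges(track), ignore.strand = TRUE)
  idx <- split(subjectHits(ov), factor(queryHits(ov),
                                       levels = seq_along(reg)))
  if (!is.null(mcols(reg)$empty)) idx[mcols(reg)$empty] <- list(integer())
  minN <- if (test == "ttest") 2L else 1L
  n <- length(reg)
  out <- data.frame(gene_id = geneIds(genes), stat = NA_real_, p = NA_real_,
                    q = NA_real_, direction = NA_character_,
                    n_probes = lengths(idx), skipped = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ii <- idx[[i]]
    if (length(ii) < minN) {
      out$skipped[i] <- TRUE
      out$reason[i] <- if (length(ii)) "too_few_probes" else "no_probes"
      next
    }
    a <- xc[ii]; b <- xm[ii]
    if (test == "ttest") {
      if (isTRUE(all.equal(stats::sd(c(a, b)), 0)) || identical(a, b)) {
        out$stat[i] <- 0; out$p[i] <- 1
      } else {
        tt <- stats::t.test(b, a)
        out$stat[i] <- unname(tt$statistic); out$p[i] <- tt$p.value
      }
    } else {
      wt <- suppressWarnings(stats::wilcox.test(b, a))
      out$stat[i] <- unname(wt$statistic)
      out$p[i] <- if (is.nan(wt$p.value)) 1 else wt$p.value
    }
    d <- mean(b) - mean(a)
    out$direction[i] <- if (d > 0) "up" else if (d < 0) "down" else NA_character_
  }
  tested <- !out$skipped
  out$q[tested] <- if (fdr) stats::p.adjust(out$p[tested], "BH") else out$p[tested]
  out
}

#' Smooth an aggregate profile curve
#'
#' Centered moving average of the given window length (bp, one point per
#' bp), with windows shrinking at the edges so curve length is preserved;
#' \code{NA} points are ignored within each window.
#'
#' @param y numeric curve.
#' @param window window length in points (bp).
#' @return numeric, same length as \code{y}.
#' @export
smoothProfile <- function(y, window = 900L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(y)
  if (!n) return(y)
  hl <- (window - 1L) %/% 2L
  hr <- window %/% 2L
  ok <- !is.na(y)
  y0 <- ifelse(ok, y, 0)
  cs <- c(0, cumsum(y0))
  cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl); hi <- pmin(n, i + hr)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Categorize expression fold changes
#'
#' none below 2-fold; moderate 2- to 5-fold; high above 5- up to 10-fold;
#' maximal above 10-fold.
#'
#' @param fold positive fold changes (mutant/control).
#' @return factor with levels none, moderate, high, maximal.
#' @export
foldCategory <- function(fold) {
  if (any(!is.finite(fold) | fold <= 0)) stop("fold must be positive")
  ## bands are closed on the right: 5 is still moderate, 10 still high
  lv <- c("none", "moderate", "high", "maximal")
  out <- ifelse(fold < 2, "none",
         ifelse(fold <= 5, "moderate",
         ifelse(fold <= 10, "high", "maximal")))
  factor(out, levels = lv)
}

#' Joint chromatin-change class from H3K27me3 and H3K4me3 tests
#'
#' K27 "depleted" iff q < alpha and direction down; K4 "enriched" iff
#' q < alpha and direction up; the class is the three-way combination
#' (any other significant change maps to unchanged).
#'
#' @param k27,k4 [regionTest()] results for the same genes.
#' @param alpha significance level on q.
#' @return data.frame with \code{gene_id} and \code{class}.
#' @export
chromatinChangeClass <- function(k27, k4, alpha = 0.05) {
  if (!identical(sort(k27$gene_id), sort(k4$gene_id)))
    stop("k27 and k4 results must cover the same genes")
  k4 <- k4[match(k27$gene_id, k4$gene_id), , drop = FALSE]
  dep <- !is.na(k27$q) & k27$q < alpha & k27$direction %in% "down"
  enr <- !is.na(k4$q) & k4$q < alpha & k4$direction %in% "up"
  cls <- ifelse(dep & enr, "both",
         ifelse(dep, "K27depletedOnly",
         ifelse(enr, "K4enrichedOnly", "unchanged")))
  data.frame(gene_id = k27$gene_id,
             class = factor(cls, levels = c("K27depletedOnly",
                                            "K4enrichedOnly", "both",
                                            "unchanged")))
}
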