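#' Count query intervals overlapping a subject set
#'
#' Number of intervals in \code{a} with >= 1 bp overlap with some interval
#' of \code{b} after expanding \code{b} by \code{slack} on both sides
#' (the "within +/- slack" rule); each \code{a} interval counts at most
#' once.
#'
#' @param a,b \code{GRanges}.
#' @param slack expansion of \code{b} in bp.
#' @return integer count.
#' @export
overlapCount <- function(a, b, slack = 0L) {
  if (!length(a) || !length(b)) return(0L)
  bExp <- GRanges(seqnames(b),
                  IRanges(pmax(1L, start(b) - slack), end(b) + slack))
  sum(IRanges::overlapsAny(granges(a), bExp, ignore.strand = TRUE))
}

#' Shuffle intervals preserving count, size, and chromosome
#'
#' Each interval is independently re-placed uniformly on its own
#' chromosome, keeping its length and staying entirely within bounds.
#' Shuffled intervals may overlap one another.
#'
#' @param a \code{GRanges}.
#' @param genome \code{Seqinfo} or named vector of chromosome lengths.
#' @param seed optional integer seed (RNG untouched when \code{NULL}).
#' @return \code{GRanges} parallel to \code{a} (metadata kept).
#' @export
shuffleIntervals <- function(a, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- asSeqlengths(genome)
  chr <- as.character(seqnames(a))
  if (!all(chr %in% names(len))) stop("interval chromosome absent from genome")
  L <- len[chr]
  w <- width(a)
  if (any(w > L)) stop("interval longer than its chromosome")
  newStart <- floor(stats::runif(length(a)) * (L - w + 1)) + 1L
  out <- GRanges(chr, IRanges(as.integer(newStart), width = w),
                 strand = strand(a))
  mcols(out) <- mcols(a)
  out
}

#' Permutation enrichment of interval overlaps
#'
#' Observed overlap of \code{a} with \code{b} (after \code{slack}
#' expansion of \code{b}) compared against a null built by re-placing the
#' \code{a} intervals uniformly on their own chromosomes \code{nPerm}
#' times (count, size, and chromosome preserved). Significance is a z-test
#' of the observed count against the permuted distribution
#' (z = (obs - mean) / sd, sd with the n-1 denominator); fold enrichment
#' is observed/mean.
#'
#' @param a,b \code{GRanges}.
#' @param genome \code{Seqinfo} or named chromosome lengths.
#' @param nPerm number of permutations (>= 30 for the z approximation).
#' @param slack expansion of \code{b} in bp.
#' @param seed optional integer seed.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return An [EnrichmentResult-class].
#' @export
permutationEnrichment <- function(a, b, genome, nPerm = 1000L, slack = 0L,
                                  seed = NULL,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (nPerm < 30L) warning("nPerm < 30: z approximation is unreliable")
  if (!is.null(seed)) set.seed(seed)
  len <- asSeqlengths(genome)
  aChr <- as.character(seqnames(a))
  if (!all(aChr %in% names(len))) stop("interval chromosome absent from genome")
  w <- width(a)
  L <- len[aChr]
  if (any(w > L)) stop("interval longer than its chromosome")
  ## merged slack-expanded b per chromosome, for O(log n) membership tests
  bChr <- as.character(seqnames(b))
  merged <- lapply(split(seq_along(b), factor(bChr, levels = names(len))),
                   function(i) {
                     if (!length(i)) return(NULL)
                     r <- IRanges::reduce(IRanges(pmax(1L, start(b)[i] - slack),
                                                  end(b)[i] + slack))
                     list(s = start(r), e = end(r))
                   })
  countHits <- function(starts) {
    ends <- starts + w - 1
    tot <- 0L
    for (cc in names(len)) {
      m <- merged[[cc]]
      if (is.null(m)) next
      sel <- aChr == cc
      if (!any(sel)) next
      idx <- findInterval(ends[sel], m$s)
      tot <- tot + sum(idx >= 1L & m$e[pmax(idx, 1L)] >= starts[sel])
    }
    tot
  }
  obs <- countHits(start(a))
  null <- vapply(seq_len(nPerm), function(i)
    countHits(floor(stats::runif(length(a)) * (L - w + 1)) + 1L), integer(1))
  m <- mean(null)
  s <- stats::sd(null)
  degen <- s == 0
  z <- if (degen) NA_real_ else (obs - m) / s
  p <- if (degen) NA_real_ else switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  fold <- if (m > 0) obs / m else NA_real_
  new("EnrichmentResult", observed = as.numeric(obs), nPerm = as.integer(nPerm),
      permMean = m, permSd = s, z = z, p = p, fold = fold,
      alternative = alternative, degenerate = degen,
      permCounts = as.numeric(null))
}

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", object@observed, "observed vs",
      sprintf("%.2f +/- %.2f", object@permMean, object@permSd),
      "over", object@nPerm, "permutations\n")
  if (object@degenerate) {
    cat("  degenerate null (sd = 0); p undefined\n")
  } else {
    cat(sprintf("  z = %.3f, p = %.3g (%s), fold = %.2f\n",
                object@z, object@p, object@alternative, object@fold))
  }
})

#' @describeIn permutationEnrichment one-row data.frame summary of an
#'   \code{EnrichmentResult} (observed, perm_mean, perm_sd, z, p, fold).
#' @param x an \code{EnrichmentResult}.
#' @export
enrichmentSummary <- function(x) {
  data.frame(observed = x@observed, n_perm = x@nPerm, perm_mean = x@permMean,
             perm_sd = x@permSd, z = x@z, p = x@p, fold = x@fold,
             degenerate = x@degenerate)
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p by summing the probabilities of all tables with the fixed
#' margins whose probability does not exceed the observed table's.
#'
#' @param x 2x2 matrix of non-negative counts.
#' @return p-value.
#' @export
fisherExactP <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == 2L) || any(x < 0)) stop("x must be a 2x2 table of counts")
  stats::fisher.test(x)$p.value
}

#' Hypergeometric upper-tail test
#'
#' p = P(X >= k) with X hypergeometric: draw \code{n} from a universe of
#' \code{N} containing \code{K} successes.
#'
#' @param k observed successes in the draw.
#' @param K successes in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return p-value.
#' @export
hypergeomP <- function(k, K, n, N) {
  if (N < K || N < n || k > min(K, n) || any(c(k, K, n, N) < 0))
    stop("inconsistent hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
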