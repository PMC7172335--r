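## median of all Walsh averages (x_i + x_j)/2, i <= j (one-sample
## Hodges-Lehmann pseudomedian)
walshMedian <- function(v) {
  n <- length(v)
  if (n == 1L) return(v)
  s <- outer(v, v, "+") / 2
  stats::median(s[upper.tri(s, diag = TRUE)])
}

#' Pseudomedian smoothing of probe signal
#'
#' Robust track smoothing for visualization/export: each probe's value is
#' replaced by the Hodges-Lehmann pseudomedian of the window of
#' \code{span} probes centered on it (the median of all Walsh averages
#' (x_i + x_j)/2 over window pairs i <= j, including i = j). Windows
#' shrink at chromosome ends; positions are unchanged; every sample is
#' smoothed independently. Span is counted in probes, not bp.
#'
#' @param track a [ProbeTrack-class].
#' @param span odd window size in probes (default 3).
#' @return A smoothed [ProbeTrack-class].
#' @export
pseudomedianSmooth <- function(track, span = 3L) {
  if (span < 1L || span %% 2L != 1L) stop("span must be odd and >= 1")
  if (span == 1L) return(track)
  h <- (span - 1L) %/% 2L
  x <- intensity(track)
  chr <- as.character(seqnames(rowRanges(track)))
  out <- x
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    n <- length(i)
    for (s in seq_len(ncol(x))) {
      v <- x[i, s]
      out[i, s] <- vapply(seq_len(n), function(k)
        walshMedian(v[max(1L, k - h):min(n, k + h)]), numeric(1))
    }
  }
  sm <- track
  SummarizedExperiment::assay(sm, "intensity") <- out
  sm
}
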