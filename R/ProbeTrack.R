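#' Construct a ProbeTrack
#'
#' @param chrom character vector of chromosome names, one per probe.
#' @param start integer vector of probe start positions (1-based).
#' @param intensity numeric matrix (probes x samples) of log2 signal, or a
#'   vector for a single sample.
#' @param probeLength constant probe length in bp (default 50, the oligo
#'   length of the tiling design emulated here; 60 for long-oligo arrays).
#' @param condition character vector, one per sample.
#' @param replicate integer vector, one per sample.
#' @param seqinfo optional \code{Seqinfo} (or named vector of chromosome
#'   lengths) attaching a genome to the track.
#' @return A [ProbeTrack-class] with probes sorted by (chromosome, start).
#' @examples
#' pt <- ProbeTrack(rep("chr1", 5), c(1, 34, 67, 100, 133),
#'                  rnorm(5), condition = "control")
#' probeLength(pt)
#' @export
ProbeTrack <- function(chrom, start, intensity, probeLength = 50L,
                       condition = "sample", replicate = 1L,
                       seqinfo = NULL) {
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1L)
  chrom <- rep_len(chrom, length(start))
  stopifnot(nrow(intensity) == length(start))
  nS <- ncol(intensity)
  condition <- rep_len(condition, nS)
  replicate <- rep_len(replicate, nS)
  si <- asSeqinfo(seqinfo)
  gr <- GRanges(chrom, IRanges(as.integer(start), width = as.integer(probeLength)))
  if (!is.null(si)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
  }
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  intensity <- intensity[o, , drop = FALSE]
  colnames(intensity) <- paste(condition, replicate, sep = ".")
  se <- SummarizedExperiment(
    assays = list(intensity = intensity), rowRanges = gr,
    colData = DataFrame(condition = condition, replicate = replicate,
                        row.names = colnames(intensity)))
  new("ProbeTrack", se)
}

asSeqinfo <- function(x) {
  if (is.null(x)) return(NULL)
  if (is(x, "Seqinfo")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x <= 0) || anyDuplicated(names(x)) || any(!nzchar(names(x))))
      stop("chromosome lengths must be positive with unique non-empty names")
    return(Seqinfo(seqnames = names(x), seqlengths = as.integer(x)))
  }
  stop("seqinfo must be a Seqinfo object or a named length vector")
}

asSeqlengths <- function(x) {
  si <- asSeqinfo(x)
  stats::setNames(as.numeric(seqlengths(si)), seqlevels(si))
}

#' @describeIn ProbeTrack constant probe length in bp.
#' @param x,object a \code{ProbeTrack}.
#' @export
probeLength <- function(x) {
  if (!length(rowRanges(x))) return(NA_integer_)
  width(rowRanges(x))[1L]
}

#' @describeIn ProbeTrack the probe-by-sample intensity matrix.
#' @export
intensity <- function(x) assay(x, "intensity")

#' Per-probe mean intensity for one condition
#'
#' Collapses replicate samples of \code{condition} to one value per probe
#' (the replicate mean), the representation downstream stages consume.
#'
#' @param x a [ProbeTrack-class].
#' @param condition condition label; if \code{NULL} and the track has a
#'   single condition, that one is used.
#' @return numeric vector, one value per probe.
#' @export
conditionMeans <- function(x, condition = NULL) {
  cond <- colData(x)$condition
  if (is.null(condition)) {
    u <- unique(cond)
    if (length(u) != 1L)
      stop("track has conditions ", paste(u, collapse = ", "),
           "; pick one explicitly")
    condition <- u
  }
  sel <- which(cond == condition)
  if (!length(sel)) stop("no samples with condition '", condition, "'")
  rowMeans(intensity(x)[, sel, drop = FALSE])
}

setMethod("show", "ProbeTrack", function(object) {
  cat("ProbeTrack with", nrow(object), "probes (length",
      probeLength(object), "bp) on",
      length(unique(as.character(seqnames(rowRanges(object))))),
      "chromosome(s)\n")
  cd <- colData(object)
  cat("samples:", paste(sprintf("%s (rep %s)", cd$condition, cd$replicate),
                        collapse = ", "), "\n")
})

## subsetting keeps class via SummarizedExperiment's methods
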