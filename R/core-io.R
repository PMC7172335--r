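#' Read genomic intervals (BED or interval-GFF)
#'
#' BED is 0-based half-open on disk, GFF 1-based inclusive; both are
#' converted exactly once, at this boundary, to the package-internal GRanges
#' convention (1-based closed).
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"gff"} (generic one-interval-per-line
#'   GFF with the score column carrying the interval score).
#' @param seqinfo optional genome (\code{Seqinfo} or named lengths) to attach
#'   and validate against.
#' @return sorted \code{GRanges} (name/score kept when present).
#' @export
readIntervals <- function(path, format = c("bed", "gff"), seqinfo = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff")
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (format == "gff") {
    keep <- intersect(c("score", "ID", "Name"), colnames(mcols(gr)))
    mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
    nmcol <- intersect(c("Name", "ID"), keep)
    if (length(nmcol)) {
      mcols(gr)$name <- as.character(mcols(gr)[[nmcol[1L]]])
      mcols(gr) <- mcols(gr)[, intersect(c("name", "score"), colnames(mcols(gr))),
                             drop = FALSE]
    }
  }
  si <- asSeqinfo(seqinfo)
  if (!is.null(si)) {
    if (!all(seqlevels(gr) %in% seqlevels(si)))
      stop("interval chromosome(s) absent from the genome index")
    if (any(end(gr) > seqlengths(si)[as.character(seqnames(gr))]))
      stop("interval(s) extend past the chromosome end")
    GenomeInfoDb::seqlevels(gr) <- seqlevels(si)
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
  }
  gr
}

#' Write intervals as BED
#'
#' @param gr \code{GRanges} (name/score metadata columns used when present).
#' @param path output file.
#' @export
writeIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts gene / mRNA / exon features; exons are attached to their gene
#' through the Parent chain (one transcript model per gene id).
#'
#' @param path GFF3 file.
#' @return A [GeneModels-class].
#' @export
readGenes <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  if (any(is.na(gid) | !nzchar(gid))) stop("gene feature without ID")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("gene without strand")
  ## resolve exon Parent -> gene id, through mRNA when present
  toGene <- stats::setNames(gid, gid)
  mrna <- gff[type == "mRNA"]
  if (length(mrna)) {
    mid <- as.character(mrna$ID)
    mpar <- vapply(mrna$Parent, function(p) as.character(p)[1L], character(1))
    toGene <- c(toGene, stats::setNames(mpar, mid))
  }
  exons <- gff[type == "exon"]
  exGene <- if (length(exons)) {
    par <- vapply(exons$Parent, function(p) as.character(p)[1L], character(1))
    unname(toGene[par])
  } else character()
  if (length(exGene) && anyNA(exGene)) stop("exon with unresolvable Parent")
  g <- granges(genes)
  mcols(g)$gene_id <- gid
  exl <- methods::as(GenomicRanges::sort(split(granges(exons), factor(exGene, levels = gid))),
                     "GRangesList")
  ## genes without exon rows default to a single full-span exon
  empty <- lengths(exl) == 0L
  if (any(empty))
    exl[empty] <- methods::as(granges(g)[empty], "GRangesList")
  GeneModels(g, exl)
}

#' Write gene models as GFF3
#'
#' @param x a [GeneModels-class].
#' @param path output file.
#' @export
writeGenes <- function(x, path) {
  g <- geneRanges(x)
  ex <- geneExons(x)
  ids <- geneIds(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(g)) {
    writeLines(sprintf("%s\ttileChIP\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(seqnames(g)[i]), start(g)[i], end(g)[i],
                       as.character(strand(g)[i]), ids[i]), con)
    e <- ex[[i]]
    if (length(e))
      writeLines(sprintf("%s\ttileChIP\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         as.character(seqnames(e)), start(e), end(e),
                         as.character(strand(g)[i]), ids[i], seq_along(e),
                         ids[i]), con)
  }
  invisible(path)
}

#' Read probe-level signal (wiggle or probe-GFF)
#'
#' @param path file path.
#' @param format \code{"wiggle"} (fixedStep or variableStep) or
#'   \code{"probe-gff"} (one probe per line, score column = intensity).
#' @param condition,replicate sample labels for the single sample read.
#' @param probeLength probe length in bp; defaults to the span/width found
#'   in the file.
#' @param seqinfo optional genome to attach.
#' @return A single-sample [ProbeTrack-class].
#' @export
readSignal <- function(path, format = c("wiggle", "probe-gff"),
                       condition = "sample", replicate = 1L,
                       probeLength = NULL, seqinfo = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "wiggle") "wig" else "gff")
  if (is.null(mcols(gr)$score) || anyNA(mcols(gr)$score))
    stop("missing value token in ", path)
  byChr <- split(start(gr), as.character(seqnames(gr)))
  if (!all(vapply(byChr, function(s) all(diff(s) > 0), logical(1))))
    stop("probe positions must be strictly increasing per chromosome")
  if (is.null(probeLength)) probeLength <- width(gr)[1L]
  ProbeTrack(as.character(seqnames(gr)), start(gr),
             as.numeric(mcols(gr)$score), probeLength = probeLength,
             condition = condition, replicate = replicate, seqinfo = seqinfo)
}

#' Write one sample of a ProbeTrack as UCSC wiggle
#'
#' Positions are emitted 1-based (variableStep). The span is the probe
#' length, shrunk to the smallest probe gap when probes overlap on the
#' array (wiggle forbids overlapping spans); probe length itself is a
#' track property, re-suppliable to [readSignal()].
#'
#' @param track a [ProbeTrack-class].
#' @param path output file.
#' @param condition which condition to write (replicate mean); default the
#'   track's only condition.
#' @export
writeSignal <- function(track, path, condition = NULL) {
  if (!nrow(track)) {
    writeLines("track type=wiggle_0", path)
    return(invisible(path))
  }
  rr <- rowRanges(track)
  gaps <- unlist(lapply(split(start(rr), as.character(seqnames(rr))), diff),
                 use.names = FALSE)
  span <- min(probeLength(track), if (length(gaps)) min(gaps) else Inf)
  gr <- GRanges(seqnames(rr), IRanges(start(rr), width = span))
  mcols(gr)$score <- conditionMeans(track, condition)
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}
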