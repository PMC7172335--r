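#' Construct GeneModels
#'
#' @param genes \code{GRanges} of gene spans with a \code{gene_id} metadata
#'   column and strand \code{+} or \code{-}.
#' @param exons optional \code{GRangesList} of exons parallel to
#'   \code{genes} (named by gene id). Defaults to single-exon genes
#'   covering the whole span.
#' @return A [GeneModels-class].
#' @export
GeneModels <- function(genes, exons = NULL) {
  ids <- as.character(mcols(genes)$gene_id)
  if (is.null(exons)) {
    exons <- methods::as(granges(genes), "GRangesList")
    names(exons) <- ids
  }
  new("GeneModels", genes = genes, exons = exons)
}

#' @describeIn GeneModels gene spans as a \code{GRanges}.
#' @param x a \code{GeneModels}.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModels exons as a \code{GRangesList} named by gene id.
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneModels character vector of gene ids.
#' @export
geneIds <- function(x) as.character(mcols(x@genes)$gene_id)

#' Transcription start / end sites
#'
#' \code{tss()} returns width-1 anchors at each gene's transcription start
#' site (leftmost base of a \code{+} gene, rightmost of a \code{-} gene),
#' keeping gene strand and id; \code{tes()} the opposite end.
#'
#' @param x a [GeneModels-class].
#' @return \code{GRanges} of width 1, parallel to the genes.
#' @export
tss <- function(x) {
  g <- geneRanges(x)
  pos <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
  out <- GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g))
  mcols(out)$gene_id <- geneIds(x)
  out
}

#' @rdname tss
#' @export
tes <- function(x) {
  g <- geneRanges(x)
  pos <- ifelse(as.character(strand(g)) == "+", end(g), start(g))
  out <- GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g))
  mcols(out)$gene_id <- geneIds(x)
  out
}

setMethod("show", "GeneModels", function(object) {
  g <- geneRanges(object)
  cat("GeneModels with", length(g), "genes on",
      length(unique(as.character(seqnames(g)))), "chromosome(s);",
      sum(as.character(strand(g)) == "+"), "plus /",
      sum(as.character(strand(g)) == "-"), "minus strand\n")
})

setMethod("length", "GeneModels", function(x) length(x@genes))
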