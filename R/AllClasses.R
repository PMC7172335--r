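#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#'   findOverlaps countOverlaps granges sort
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo seqnames<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#' @importFrom stats mad median pnorm p.adjust t.test wilcox.test fisher.test
#'   phyper runif rnorm sd setNames aggregate
#' @importFrom utils head tail
NULL

#' ProbeTrack: probe-level tiling-array signal
#'
#' A \code{ProbeTrack} stores the per-probe log2 signal of one tiling-array
#' mark across one or more samples. It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are probes (a sorted
#' \code{GRanges} of constant width, the probe length), columns are samples
#' with \code{condition} and \code{replicate} in \code{colData}, and the
#' single assay \code{"intensity"} holds one finite value per probe per
#' sample.
#'
#' Probe identity is (chromosome, start); all distance rules in the package
#' (neighbor gaps, run gaps) are measured start-to-start.
#'
#' @seealso [ProbeTrack()] the constructor, [probeLength()], [intensity()],
#'   [conditionMeans()]
#' @export
setClass("ProbeTrack", contains = "RangedSummarizedExperiment")

setValidity("ProbeTrack", function(object) {
  msg <- character()
  rr <- rowRanges(object)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (length(rr)) {
    if (length(unique(width(rr))) != 1L)
      msg <- c(msg, "probe length (range width) must be constant")
    byChr <- split(start(rr), as.character(seqnames(rr)))
    if (!all(vapply(byChr, function(s) all(diff(s) > 0), logical(1))))
      msg <- c(msg, "probe starts must be strictly increasing per chromosome")
    if (!all(is.finite(assay(object, "intensity"))))
      msg <- c(msg, "intensities must be finite")
  }
  cd <- colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'condition' and 'replicate'")
  if (length(msg)) msg else TRUE
})

#' GeneModels: strand-aware gene annotation
#'
#' Holds one transcript model per gene id: a \code{GRanges} of gene spans
#' (with a \code{gene_id} metadata column and strand in \code{+/-}) and a
#' parallel \code{GRangesList} of sorted, non-overlapping exons contained in
#' each span. The TSS of a \code{+} gene is its leftmost base, of a \code{-}
#' gene its rightmost base; the TES is the opposite end.
#'
#' @seealso [GeneModels()], [geneRanges()], [geneExons()], [tss()], [tes()]
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- character()
  g <- object@genes
  if (is.null(mcols(g)$gene_id))
    msg <- c(msg, "genes must carry a gene_id metadata column")
  else {
    ids <- mcols(g)$gene_id
    if (anyDuplicated(ids)) msg <- c(msg, "gene ids must be unique")
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "every gene must be stranded (+ or -)")
    if (!identical(names(object@exons), as.character(ids)))
      msg <- c(msg, "exons must be named by gene_id, in gene order")
    ok <- vapply(seq_along(g), function(i) {
      ex <- object@exons[[i]]
      if (!length(ex)) return(TRUE)
      all(start(ex) >= start(g)[i]) && all(end(ex) <= end(g)[i]) &&
        all(diff(start(ex)) > 0) &&
        (length(ex) < 2L || all(start(ex)[-1] > end(ex)[-length(ex)]))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "exons must be sorted, non-overlapping, inside the gene span")
  }
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: observed overlap against a permutation null
#'
#' Result of [permutationEnrichment()]: the observed overlap count, the
#' permutation null (mean, sd with the n-1 denominator, and the raw null
#' counts), the z statistic, its normal-tail p-value, and the fold
#' enrichment observed/mean. When the null is degenerate (sd = 0) the
#' p-value is \code{NA} and \code{degenerate} is \code{TRUE}.
#'
#' @export
setClass("EnrichmentResult",
         representation(observed = "numeric", nPerm = "integer",
                        permMean = "numeric", permSd = "numeric",
                        z = "numeric", p = "numeric", fold = "numeric",
                        alternative = "character", degenerate = "logical",
                        permCounts = "numeric"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
  if (!is.na(object@permSd) && object@permSd < 0) msg <- c(msg, "permSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ProfileMatrix: anchor-relative windowed signal
#'
#' Result of [anchoredProfile()]: \code{positions} are strictly increasing
#' anchor-relative base positions, \code{values} is an entity-by-position
#' matrix of windowed statistics (\code{NA} where an entity has no probe in
#' the window), and \code{aggregate} is the cross-entity summary per
#' position (empty windows ignored, never zero-filled).
#'
#' @export
setClass("ProfileMatrix",
         representation(positions = "integer", values = "matrix",
                        aggregate = "numeric", entityIds = "character",
                        stat = "character", window = "integer"))

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (length(object@positions) && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@aggregate) != length(object@positions))
    msg <- c(msg, "aggregate length must equal positions length")
  if (ncol(object@values) != length(object@positions))
    msg <- c(msg, "values must have one column per position")
  if (nrow(object@values) != length(object@entityIds))
    msg <- c(msg, "values must have one row per entity")
  if (length(msg)) msg else TRUE
})

#' MarkovBackground: sequence background model
#'
#' An order-k Markov model of nucleotide composition: the order-0 marginal
#' over A/C/G/T plus, for k > 0, a 4^k-by-4 matrix of conditional
#' probabilities P(base | preceding k-mer). Every conditional distribution
#' sums to one; with a positive pseudocount every probability is positive.
#'
#' @seealso [fitBackground()]
#' @export
setClass("MarkovBackground",
         representation(order = "integer", marginal = "numeric",
                        transitions = "matrix", pseudocount = "numeric"))

setValidity("MarkovBackground", function(object) {
  msg <- character()
  if (object@order < 0L) msg <- c(msg, "order must be >= 0")
  if (!isTRUE(all.equal(sum(object@marginal), 1, tolerance = 1e-9)))
    msg <- c(msg, "marginal must sum to 1")
  if (!identical(names(object@marginal), c("A", "C", "G", "T")))
    msg <- c(msg, "marginal must be named A,C,G,T")
  if (object@order > 0L) {
    if (nrow(object@transitions) != 4L^object@order)
      msg <- c(msg, "transitions must have 4^order rows")
    s <- rowSums(object@transitions)
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "each conditional distribution must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
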