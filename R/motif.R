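IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

BASES <- c("A", "C", "G", "T")

#' Fit a Markov background model to sequences
#'
#' Counts (k+1)-mers over the literal text of the sequences (add
#' \code{bothStrands = TRUE} to augment with the reverse complement),
#' applies a pseudocount per transition, and normalizes per context.
#' The order-0 marginal is fitted alongside and is what position-level
#' match probabilities use.
#'
#' @param seqs \code{DNAStringSet} (or character vector).
#' @param order model order k >= 0.
#' @param pseudocount added to every transition count (default 0.1).
#' @param bothStrands augment counts with the reverse complement.
#' @return A [MarkovBackground-class].
#' @export
fitBackground <- function(seqs, order = 2L, pseudocount = 0.1,
                          bothStrands = FALSE) {
  if (order < 0L) stop("order must be >= 0")
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (bothStrands) seqs <- c(seqs, Biostrings::reverseComplement(seqs))
  totLen <- sum(Biostrings::width(seqs))
  if (totLen <= 4^(order + 1))
    warning("fewer bases than 4^(order+1); estimates will be noisy")
  m1 <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = 1L))[BASES]
  marginal <- (m1 + pseudocount) / sum(m1 + pseudocount)
  trans <- matrix(numeric(), 0L, 4L)
  if (order > 0L) {
    km <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = order + 1L))
    ctx <- substr(names(km), 1L, order)
    last <- substr(names(km), order + 1L, order + 1L)
    cnt <- matrix(0, nrow = 4^order, ncol = 4L,
                  dimnames = list(sort(unique(ctx)), BASES))
    cnt[cbind(ctx, last)] <- km
    cnt <- cnt + pseudocount
    trans <- cnt / rowSums(cnt)
  }
  new("MarkovBackground", order = as.integer(order), marginal = marginal,
      transitions = trans, pseudocount = pseudocount)
}

setMethod("show", "MarkovBackground", function(object) {
  cat("MarkovBackground of order", object@order,
      sprintf("(pseudocount %.3g); marginal A/C/G/T = %s\n",
              object@pseudocount,
              paste(sprintf("%.3f", object@marginal), collapse = "/")))
})

## reverse-complemented PWM (rows reversed, A<->T, C<->G columns swapped)
reverseComplementPwm <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- BASES
  out
}

validatePwm <- function(pwm) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4L) stop("pwm must have 4 columns (A,C,G,T)")
  if (is.null(colnames(pwm))) colnames(pwm) <- BASES
  pwm <- pwm[, BASES, drop = FALSE]
  if (any(abs(rowSums(pwm) - 1) > 1e-9)) stop("pwm rows must sum to 1")
  pwm
}

## exact null distribution of the lattice-discretized log-odds score of a
## random order-0 background word, by dynamic programming over the score
## lattice. dmat is the 4 x L matrix of per-position lattice scores
## (integers; -Inf where the PWM cell is zero). Returns p(latticeSum) =
## P(random word's lattice score >= latticeSum).
pwmScoreSurvival <- function(dmat, bg0) {
  L <- ncol(dmat)
  dead <- 0        # mass of words containing a -Inf position
  offset <- 0L     # lattice index of prob[1]
  prob <- 1
  for (i in seq_len(L)) {
    di <- dmat[, i]
    f <- which(is.finite(di))
    if (length(f) < 4L) dead <- dead + sum(bg0[-f]) * sum(prob)
    if (!length(f)) { prob <- numeric(); offset <- 0L; break }
    lo <- offset + min(di[f]); hi <- offset + length(prob) - 1L + max(di[f])
    newProb <- numeric(hi - lo + 1L)
    for (b in f) {
      sh <- offset + di[b] - lo
      idx <- seq_along(prob) + sh
      newProb[idx] <- newProb[idx] + prob * bg0[b]
    }
    prob <- newProb
    offset <- as.integer(lo)
  }
  surv <- rev(cumsum(rev(prob)))
  tot <- sum(prob) + dead
  function(latticeSum) {
    k <- latticeSum - offset + 1L
    out <- numeric(length(k))
    out[k <= 0] <- tot
    inRange <- k > 0 & k <= length(surv)
    out[inRange] <- surv[k[inRange]]
    out
  }
}

## lattice score of every window of one strand; -Inf where the window
## crosses a zero PWM cell or a non-ACGT base
scanOneStrand <- function(seqChars, dmat, L) {
  n <- length(seqChars)
  if (n < L) return(numeric())
  idx <- match(seqChars, BASES)
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    bi <- idx[i:(i + nw - 1L)]
    v <- dmat[bi, i]
    v[is.na(bi)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Scan sequences with a PWM against a Markov background
#'
#' Both strands are scanned with the log-odds score
#' sum(log2(pwm[i, base] / bg0(base))) where bg0 is the background's
#' order-0 marginal. The p-value of a score is the exact probability of an
#' equal-or-better score at a random background position, computed by
#' dynamic programming over a discretized score lattice (default
#' granularity 1e-3 bits). Zero PWM cells score -Inf and can never be
#' hits.
#'
#' @param seqs \code{DNAStringSet} (names become sequence ids).
#' @param pwm L x 4 probability matrix (columns A,C,G,T; rows sum to 1).
#' @param bg a [MarkovBackground-class] (its order-0 marginal is the null).
#' @param pThresh report hits with p strictly below this (default 0.01).
#' @param granularity score lattice step in bits.
#' @return data.frame: \code{seq}, \code{start} (1-based on the forward
#'   strand), \code{strand}, \code{score} (bits), \code{p}; sorted by
#'   sequence then position.
#' @export
scanPwm <- function(seqs, pwm, bg, pThresh = 0.01, granularity = 1e-3) {
  pwm <- validatePwm(pwm)
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  L <- nrow(pwm)
  if (L > min(Biostrings::width(seqs)))
    stop("pwm longer than the shortest sequence")
  bg0 <- bg@marginal
  smat <- t(log2(pwm / matrix(bg0, nrow = L, ncol = 4L, byrow = TRUE)))  # 4 x L
  rownames(smat) <- BASES
  dmat <- round(smat / granularity)  # scores live on the lattice throughout
  pfun <- pwmScoreSurvival(dmat, bg0)
  smatRC <- t(log2(reverseComplementPwm(pwm) /
                     matrix(bg0, nrow = L, ncol = 4L, byrow = TRUE)))
  rownames(smatRC) <- BASES
  dmatRC <- round(smatRC / granularity)
  pfunRC <- pwmScoreSurvival(dmatRC, bg0)  # null differs if bg0 asymmetric
  res <- list()
  for (s in seq_along(seqs)) {
    ch <- strsplit(as.character(seqs[[s]]), "")[[1]]
    for (str in c("+", "-")) {
      sc <- scanOneStrand(ch, if (str == "+") dmat else dmatRC, L)
      ok <- which(is.finite(sc))
      if (!length(ok)) next
      pv <- if (str == "+") pfun(sc[ok]) else pfunRC(sc[ok])
      hit <- pv < pThresh
      if (any(hit))
        res[[length(res) + 1L]] <- data.frame(
          seq = names(seqs)[s], start = ok[hit], strand = str,
          score = sc[ok][hit] * granularity, p = pv[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(seq = character(), start = integer(),
                      strand = character(), score = numeric(), p = numeric()))
  out <- do.call(rbind, res)
  out[order(match(out$seq, names(seqs)), out$start, out$strand), ,
      drop = FALSE]
}

#' Scan sequences for an IUPAC consensus motif
#'
#' The consensus is treated as a 0/1 acceptance matrix: a window is a hit
#' iff every position's base is admitted. The motif's p-value is the
#' probability that a random background word matches (product of the
#' admitted bases' order-0 marginals per position); hits are reported only
#' when that probability is strictly below \code{pThresh}. Both strands
#' are scanned.
#'
#' @param seqs \code{DNAStringSet}.
#' @param consensus IUPAC string, e.g. \code{"YAACKG"}.
#' @param bg a [MarkovBackground-class].
#' @param pThresh motif-probability threshold (default 0.001).
#' @return data.frame as in [scanPwm()] (score is NA; p is the match
#'   probability, identical for all hits).
#' @export
scanConsensus <- function(seqs, consensus, bg, pThresh = 0.001) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  codes <- strsplit(toupper(consensus), "")[[1]]
  if (!all(codes %in% names(IUPAC))) stop("invalid IUPAC code in consensus")
  pMatch <- prod(vapply(codes, function(cd) sum(bg@marginal[IUPAC[[cd]]]),
                        numeric(1)))
  empty <- data.frame(seq = character(), start = integer(),
                      strand = character(), score = numeric(), p = numeric())
  if (pMatch >= pThresh) return(empty)
  pat <- Biostrings::DNAString(consensus)
  res <- list()
  for (str in c("+", "-")) {
    p <- if (str == "+") pat else Biostrings::reverseComplement(pat)
    mt <- Biostrings::vmatchPattern(p, seqs, fixed = FALSE)
    for (s in seq_along(seqs)) {
      st <- Biostrings::startIndex(mt)[[s]]
      if (!is.null(st) && length(st))
        res[[length(res) + 1L]] <- data.frame(
          seq = names(seqs)[s], start = st, strand = str,
          score = NA_real_, p = pMatch, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(match(out$seq, names(seqs)), out$start, out$strand), ,
      drop = FALSE]
}

#' Extract strand-oriented promoter windows
#'
#' The window TSS +/- \code{flank}, reverse-complemented for minus-strand
#' genes so every window reads 5' to 3' in gene orientation; truncated at
#' chromosome edges.
#'
#' @param genes a [GeneModels-class].
#' @param genome named \code{DNAStringSet} of chromosome sequences.
#' @param flank half-window in bp (default 500).
#' @return \code{DNAStringSet} named by gene id.
#' @export
promoterWindows <- function(genes, genome, flank = 500L) {
  t <- tss(genes)
  chr <- as.character(seqnames(t))
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss)) stop("chromosome(s) missing from genome: ",
                         paste(miss, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  s <- pmax(1L, start(t) - flank)
  e <- pmin(lens[chr], start(t) + flank)
  out <- Biostrings::DNAStringSet(lapply(seq_along(t), function(i)
    Biostrings::subseq(genome[[chr[i]]], s[i], e[i])))
  minus <- as.character(strand(t)) == "-"
  out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- mcols(t)$gene_id
  out
}
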