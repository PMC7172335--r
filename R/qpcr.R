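#' Delta-delta-Ct fold quantification
#'
#' Standard ddCt with amplification efficiency 2. Technical replicates
#' (repeated rows per (target, sample, biorep)) are averaged first, then
#' biological replicates:
#' ddCt = (Ct_target - Ct_reference)_sample - (Ct_target - Ct_reference)_calibrator
#' and fold = 2^(-ddCt). For ChIP-qPCR the "reference" is a control region
#' and the fold is enrichment of the region of interest over it; for
#' qRT-PCR the reference is a housekeeping gene (e.g. rp49) and the fold is
#' expression relative to the calibrator condition.
#'
#' Per-biological-replicate folds use each biorep's sample-side dCt against
#' the calibrator-side mean dCt; significance is a two-sided unpaired t
#' test of the sample-side per-biorep folds against the calibrator-side
#' ones.
#'
#' @param ct data.frame with columns \code{target}, \code{sample},
#'   \code{biorep}, \code{ct} (technical replicates as repeated rows).
#' @param target,reference target and reference (normalizer) labels.
#' @param sample,calibrator sample and calibrator condition labels.
#' @return list: \code{fold}, \code{ddct}, \code{rep_folds}, \code{sem},
#'   \code{p} (NA with < 2 bioreps on either side).
#' @export
ddctFold <- function(ct, target, reference, sample, calibrator) {
  need <- c("target", "sample", "biorep", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("Ct values must be finite")
  cell <- function(tg, sm) {
    rows <- ct[ct$target == tg & ct$sample == sm, , drop = FALSE]
    if (!nrow(rows)) stop("missing Ct data for (", tg, ", ", sm, ")")
    techMeans <- tapply(rows$ct, rows$biorep, mean)
    techMeans  # named by biorep
  }
  tS <- cell(target, sample);     rS <- cell(reference, sample)
  tC <- cell(target, calibrator); rC <- cell(reference, calibrator)
  dctS <- mean(tS) - mean(rS)
  dctC <- mean(tC) - mean(rC)
  ddct <- dctS - dctC
  fold <- 2^(-ddct)
  ## per-biorep folds on each side, against the calibrator-side mean dCt
  perRep <- function(tv, rv) {
    common <- intersect(names(tv), names(rv))
    2^(-((tv[common] - rv[common]) - dctC))
  }
  fS <- perRep(tS, rS)
  fC <- perRep(tC, rC)
  sem <- if (length(fS) > 1L) stats::sd(fS) / sqrt(length(fS)) else NA_real_
  p <- if (length(fS) > 1L && length(fC) > 1L)
    tryCatch(stats::t.test(fS, fC)$p.value,
             error = function(e) NA_real_)  # constant replicate folds
  else NA_real_
  list(fold = fold, ddct = ddct, rep_folds = fS, sem = sem, p = p)
}
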