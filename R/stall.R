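#' Kolmogorov-Smirnov stall score between two normalized profiles
#'
#' The score is the maximum absolute difference between the cumulative sums
#' of the two normalized per-codon densities -- the K-S distance between the
#' two read distributions along the transcript. A rate-limiting pause
#' redistributes ribosomes upstream of the pause site, producing a large
#' cumulative difference peaking near the stall, whereas a pure change in
#' initiation rescales the profile and leaves the distribution unchanged.
#' A pointwise variant (max |difference| of the densities themselves) is
#' available via \code{cumulative = FALSE}.
#'
#' @param normA,normB numeric vectors of equal length, each summing to 1.
#' @param cumulative compare cumulative distributions (default) or raw
#'   normalized densities.
#' @return list with \code{ks_stat} in [0, 1] and \code{argmax_codon}, the
#'   0-based codon of maximal cumulative difference.
#' @export
ksStatistic <- function(normA, normB, cumulative = TRUE) {
  if (length(normA) != length(normB))
    stop("profiles must have equal length")
  if (abs(sum(normA) - 1) > 1e-6 || abs(sum(normB) - 1) > 1e-6)
    stop("profiles must each sum to 1 (use normalizeProfile)")
  diffs <- if (cumulative) abs(cumsum(normA) - cumsum(normB))
           else abs(normA - normB)
  i <- which.max(diffs)
  list(ks_stat = min(diffs[i], 1), argmax_codon = i - 1L)
}

#' Assign a K-S statistic to the high / medium / low group
#'
#' Groups follow the published cutoffs: high for scores above 0.3, low for
#' scores below 0.15, medium between them with both boundaries inclusive
#' to medium.
#'
#' @param ksStat numeric vector of K-S scores in [0, 1].
#' @return character vector of group labels.
#' @export
classifyKs <- function(ksStat) {
  if (any(is.na(ksStat)) || any(ksStat < 0) || any(ksStat > 1))
    stop("K-S statistic must lie in [0, 1]")
  ifelse(ksStat > 0.3, "high", ifelse(ksStat < 0.15, "low", "medium"))
}

#' Score paired control/mutant profiles transcript by transcript
#'
#' Applies the full detector to matched profile lists: joint filtering,
#' LOWESS smoothing of raw counts, sum normalization, the cumulative K-S
#' statistic and the three-group classification.
#'
#' @param control,mutant named lists of \linkS4class{RiboProfile}.
#' @param span LOWESS span.
#' @param minCodons,minMeanDensity retention filters
#'   (\code{\link{filterTranscripts}}).
#' @return data.frame with columns \code{transcript_id}, \code{n_codons},
#'   \code{mean_density_control}, \code{mean_density_mutant},
#'   \code{ks_stat}, \code{argmax_codon}, \code{group}.
#' @export
ksTable <- function(control, mutant, span = 0.1, minCodons = 100,
                    minMeanDensity = 0.5) {
  flt <- filterTranscripts(control, mutant, minCodons, minMeanDensity)
  ids <- names(flt$control)
  rows <- lapply(ids, function(id) {
    a <- smoothedProfile(flt$control[[id]], span = span)
    b <- smoothedProfile(flt$mutant[[id]], span = span)
    ks <- ksStatistic(normalizedDensity(a), normalizedDensity(b))
    data.frame(
      transcript_id = id,
      n_codons = nCodons(flt$control[[id]]),
      mean_density_control = mean(footprintCounts(flt$control[[id]])),
      mean_density_mutant = mean(footprintCounts(flt$mutant[[id]])),
      ks_stat = ks$ks_stat,
      argmax_codon = ks$argmax_codon,
      group = classifyKs(ks$ks_stat),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(transcript_id = character(), n_codons = integer(),
                  mean_density_control = numeric(),
                  mean_density_mutant = numeric(), ks_stat = numeric(),
                  argmax_codon = integer(), group = character(),
                  stringsAsFactors = FALSE)
  attr(out, "filter_report") <- flt$report
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric tail summation: the probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (standard two-sided convention). The degenerate
#' all-zero table has p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return two-sided p-value in (0, 1].
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Target-set enrichment across K-S groups
#'
#' For each K-S group, the fold enrichment is the fraction of all scored
#' targets falling in the group divided by the fraction of all scored
#' nontargets falling in the group, with a two-sided Fisher's exact test on
#' the corresponding 2x2 table (in group vs not, target vs nontarget).
#' Transcripts absent from \code{ksResults} never enter the totals.
#'
#' @param ksResults data.frame from \code{\link{ksTable}} (needs columns
#'   \code{transcript_id}, \code{group}).
#' @param targetIds character vector of target transcript identifiers.
#' @return data.frame, one row per group, with count columns,
#'   \code{fold_enrichment} (+Inf with \code{fold_undefined = TRUE} when no
#'   nontarget falls in the group) and \code{fisher_p}.
#' @export
enrichTargets <- function(ksResults, targetIds) {
  isTarget <- ksResults$transcript_id %in% targetIds
  nT <- sum(isTarget); nN <- sum(!isTarget)
  if (nT == 0 || nN == 0)
    stop("need at least one target and one nontarget among scored transcripts")
  groups <- c("high", "medium", "low")
  rows <- lapply(groups, function(g) {
    inG <- ksResults$group == g
    a <- sum(isTarget & inG); b <- nT - a
    c_ <- sum(!isTarget & inG); d <- nN - c_
    fold <- if (c_ == 0) {
      if (a == 0) NaN else Inf
    } else (a / nT) / (c_ / nN)
    data.frame(group = g,
               n_targets_in = a, n_targets_total = nT,
               n_nontargets_in = c_, n_nontargets_total = nN,
               fold_enrichment = fold,
               fold_undefined = c_ == 0,
               fisher_p = fisherExact2x2(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
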