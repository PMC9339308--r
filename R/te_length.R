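#' Transcripts-per-million from raw counts
#'
#' \code{tpm_i = 1e6 * (c_i / L_i) / sum_j (c_j / L_j)}.
#'
#' @param counts non-negative read counts per transcript.
#' @param lengths strictly positive effective lengths (nt).
#' @return numeric vector summing to 1e6.
#' @export
computeTpm <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths must have the same length")
  if (any(lengths <= 0)) stop("effective lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot <= 0) stop("total count is zero; TPM undefined")
  1e6 * rate / tot
}

#' Pick the representative isoform of each gene
#'
#' The highest-expressed transcript isoform (by RNA TPM) represents its
#' gene; ties are broken by the longest CDS, then by lexicographically
#' smallest transcript id.
#'
#' @param records data.frame with columns \code{gene_id},
#'   \code{transcript_id}, \code{rna_tpm} and optionally \code{cds_len_nt}
#'   (taken as 0 when absent).
#' @return data.frame, one row per gene: the selected record.
#' @export
selectRepresentativeIsoform <- function(records) {
  need <- c("gene_id", "transcript_id", "rna_tpm")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  cds <- if ("cds_len_nt" %in% names(records)) records$cds_len_nt else 0
  ord <- order(records$gene_id, -records$rna_tpm, -cds, records$transcript_id)
  sorted <- records[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.lengthFeatures <- c("cds_len_nt", "utr5_len_nt", "utr3_len_nt",
                     "intron_len_total_nt")

#' Length summaries for a gene set vs the expressed background
#'
#' Medians and means of CDS, 5' UTR, 3' UTR and summed-intron lengths for a
#' gene set against the full background of expressed transcripts (the set is
#' typically a subset of the background, as in set-vs-all box plots), with a
#' Mann-Whitney U test per feature. Records are expected to have passed the
#' TPM >= 2 expression filter upstream.
#'
#' @param records background data.frame with \code{gene_id} and the length
#'   columns \code{cds_len_nt}, \code{utr5_len_nt}, \code{utr3_len_nt},
#'   \code{intron_len_total_nt} (missing columns are skipped).
#' @param geneSet character vector of gene ids forming the set.
#' @return data.frame, one row per feature: set/background median and mean,
#'   \code{median_ratio} (set/background) and \code{p_value}.
#' @export
lengthSummary <- function(records, geneSet) {
  inSet <- records$gene_id %in% geneSet
  if (!any(inSet)) stop("gene set is empty after matching against records")
  feats <- intersect(.lengthFeatures, names(records))
  rows <- lapply(feats, function(f) {
    s <- records[[f]][inSet]; b <- records[[f]]
    p <- suppressWarnings(stats::wilcox.test(s, b)$p.value)
    data.frame(feature = f,
               set_median = stats::median(s), set_mean = mean(s),
               background_median = stats::median(b),
               background_mean = mean(b),
               median_ratio = stats::median(s) / stats::median(b),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.motifAlphabet <- c("A", "C", "G", "U", "W", "K", "Y")

.toDna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Count occurrences of a degenerate RNA motif
#'
#' Counts all (overlapping) positions where an IUPAC motif over
#' \{A, C, G, U, W, K, Y\} matches the sequence (W = A/U, K = G/U,
#' Y = C/U). Sequences may be RNA or DNA spelling (U and T equivalent);
#' N in the sequence never matches.
#'
#' @param seq single character string over \{A, C, G, U/T, N\}.
#' @param motif IUPAC pattern string.
#' @return list with \code{count} and \code{density} (matches per kb of
#'   sequence).
#' @export
motifScan <- function(seq, motif) {
  if (length(seq) != 1L || !nzchar(seq)) stop("seq must be one non-empty string")
  if (length(motif) != 1L || !nzchar(motif)) stop("motif must be non-empty")
  motChars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motChars %in% .motifAlphabet))
    stop("motif alphabet restricted to ", paste(.motifAlphabet, collapse = ""))
  seqU <- toupper(seq)
  if (grepl("[^ACGUTN]", .toDna(seqU)))
    stop("sequence may only contain A, C, G, U/T, N")
  subject <- Biostrings::DNAString(.toDna(seqU))
  pattern <- Biostrings::DNAString(.toDna(paste(motChars, collapse = "")))
  # fixed = "subject": IUPAC codes in the pattern are interpreted, letters in
  # the subject are literal, so subject N matches nothing in ACGT-space
  count <- Biostrings::countPattern(pattern, subject, fixed = "subject")
  list(count = count, density = count / (nchar(seq) / 1000))
}

#' Motif density for many sequences
#'
#' @param seqs character vector of sequences.
#' @param motif IUPAC pattern (see \code{\link{motifScan}}).
#' @return numeric vector of per-kb densities.
#' @export
motifDensity <- function(seqs, motif) {
  vapply(seqs, function(s) motifScan(s, motif)$density, numeric(1),
         USE.NAMES = FALSE)
}

#' Length-matched motif enrichment test
#'
#' Tests whether a motif is denser in a set of (typically translationally
#' downregulated) transcripts than in unaffected transcripts of similar
#' length. The background transcript lengths define quantile bins; within
#' each bin the motif densities of set vs background members are compared
#' with a one-sided Mann-Whitney test, bin p-values are pooled by Fisher's
#' method, and the verdict is "enriched" when the pooled p falls below
#' \code{alpha}. Optionally the identical procedure runs for a panel of
#' random 4-mers as negative controls.
#'
#' @param downSeqs,backgroundSeqs character vectors of transcript sequences.
#' @param motif IUPAC pattern.
#' @param nBins number of background length-quantile bins (default 5).
#' @param alpha significance level for the pooled verdict.
#' @param minBinSize bins with fewer members than this in either set are
#'   dropped with a warning.
#' @param nControls number of random 4-mer negative controls (0 disables).
#' @param controlSeed seed for the control panel.
#' @return list: \code{per_bin} data.frame (bin ranges, sizes, p-values),
#'   \code{pooled_p}, \code{enriched}, and \code{controls} data.frame
#'   (motif, pooled_p, enriched) when controls were requested.
#' @export
lengthMatchedMotifTest <- function(downSeqs, backgroundSeqs, motif,
                                   nBins = 5, alpha = 0.05, minBinSize = 3,
                                   nControls = 0, controlSeed = 1L) {
  if (length(downSeqs) == 0 || length(backgroundSeqs) == 0)
    stop("both sequence sets must be non-empty")
  runOne <- function(mot) {
    dDens <- motifDensity(downSeqs, mot)
    bDens <- motifDensity(backgroundSeqs, mot)
    dLen <- nchar(downSeqs); bLen <- nchar(backgroundSeqs)
    edges <- unique(stats::quantile(bLen, probs = seq(0, 1, length.out = nBins + 1)))
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    dBin <- cut(dLen, edges); bBin <- cut(bLen, edges)
    rows <- lapply(levels(bBin), function(lv) {
      ds <- dDens[dBin == lv]; bs <- bDens[bBin == lv]
      if (length(ds) < minBinSize || length(bs) < minBinSize)
        return(data.frame(bin = lv, n_down = length(ds), n_bg = length(bs),
                          p_value = NA_real_, stringsAsFactors = FALSE))
      p <- suppressWarnings(
        stats::wilcox.test(ds, bs, alternative = "greater")$p.value)
      data.frame(bin = lv, n_down = length(ds), n_bg = length(bs),
                 p_value = p, stringsAsFactors = FALSE)
    })
    perBin <- do.call(rbind, rows)
    dropped <- sum(is.na(perBin$p_value))
    if (dropped > 0)
      warning(dropped, " length bin(s) dropped (fewer than ", minBinSize,
              " members)")
    ps <- perBin$p_value[!is.na(perBin$p_value)]
    if (length(ps) == 0) stop("no length bin had enough members to test")
    ps <- pmax(ps, 1e-300)
    stat <- -2 * sum(log(ps))
    pooled <- stats::pchisq(stat, df = 2 * length(ps), lower.tail = FALSE)
    list(per_bin = perBin, pooled_p = pooled, enriched = pooled < alpha)
  }
  main <- runOne(motif)
  controls <- NULL
  if (nControls > 0) {
    kmers <- withr::with_seed(controlSeed, vapply(seq_len(nControls),
      function(i) paste(sample(c("A", "C", "G", "U"), 4, replace = TRUE),
                        collapse = ""), character(1)))
    controls <- do.call(rbind, lapply(kmers, function(km) {
      r <- suppressWarnings(runOne(km))
      data.frame(motif = km, pooled_p = r$pooled_p, enriched = r$enriched,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_bin = main$per_bin, pooled_p = main$pooled_p,
       enriched = main$enriched, controls = controls)
}

#' Chi-squared comparison of two proportions
#'
#' Pearson chi-squared test on the 2x2 table of successes/failures, without
#' continuity correction, 1 degree of freedom.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
proportionTest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group totals must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0)
    stop("successes must lie in [0, n]")
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (k1 / n1 == k2 / n2) return(list(statistic = 0, p_value = 1))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Translation efficiency with the expression filter
#'
#' TE is the ratio of ribosome-footprint TPM to mRNA TPM for the same
#' transcript. Transcripts below the mRNA expression floor (TPM < 2 by
#' default) are too noisy to ratio and get NA.
#'
#' @param rnaTpm,riboTpm non-negative TPM vectors of equal length.
#' @param minRnaTpm expression floor below which TE is undefined.
#' @return numeric vector of TE values (NA where filtered).
#' @export
translationEfficiency <- function(rnaTpm, riboTpm, minRnaTpm = 2) {
  if (length(rnaTpm) != length(riboTpm))
    stop("rnaTpm and riboTpm must have the same length")
  if (any(rnaTpm < 0, na.rm = TRUE) || any(riboTpm < 0, na.rm = TRUE))
    stop("TPM values must be non-negative")
  ifelse(!is.na(rnaTpm) & rnaTpm >= minRnaTpm, riboTpm / rnaTpm, NA_real_)
}
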