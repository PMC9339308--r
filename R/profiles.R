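#' Read a transcript-space footprint table
#'
#' Expected TSV columns: \code{transcript_id}, \code{five_prime_pos}
#' (0-based position of the read 5' end within the transcript),
#' \code{read_length} (nt) and optionally \code{count} (collapsed
#' duplicates; defaults to 1). Malformed rows (missing/negative fields) are
#' dropped with one warning carrying the row count.
#'
#' @param path TSV file path.
#' @return data.frame of well-formed reads; attribute \code{"n_bad_rows"}
#'   counts dropped rows.
#' @export
readFootprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "five_prime_pos", "read_length")
  if (!all(need %in% names(df)))
    stop("footprint table must have columns: ", paste(need, collapse = ", "))
  if (!"count" %in% names(df)) df$count <- 1L
  bad <- is.na(df$transcript_id) | is.na(df$five_prime_pos) |
    is.na(df$read_length) | is.na(df$count) |
    df$five_prime_pos < 0 | df$read_length <= 0 | df$count < 0
  if (any(bad))
    warning(sum(bad), " malformed footprint row(s) skipped")
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_bad_rows") <- sum(bad)
  out
}

#' Read a per-codon count table into RiboProfile objects
#'
#' Expected TSV columns: \code{transcript_id}, \code{codon_index} (0-based),
#' \code{count}. Codons absent from the table are taken as zero up to the
#' largest index seen per transcript (or to the annotated length when
#' \code{annotation} is supplied).
#'
#' @param path TSV file path.
#' @param annotation optional annotation data.frame from
#'   \code{\link{readAnnotation}} fixing each transcript's codon count.
#' @return named list of \linkS4class{RiboProfile}.
#' @export
readCodonCounts <- function(path, annotation = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "codon_index", "count")
  if (!all(need %in% names(df)))
    stop("codon count table must have columns: ", paste(need, collapse = ", "))
  bad <- is.na(df$transcript_id) | is.na(df$codon_index) | is.na(df$count) |
    df$codon_index < 0 | df$count < 0
  if (any(bad)) warning(sum(bad), " malformed count row(s) skipped")
  df <- df[!bad, , drop = FALSE]
  ids <- unique(df$transcript_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$transcript_id == id, ]
    n <- if (!is.null(annotation) && id %in% annotation$transcript_id)
      annotation$n_codons[match(id, annotation$transcript_id)]
    else max(sub$codon_index) + 1L
    counts <- integer(n)
    keep <- sub$codon_index < n
    counts[sub$codon_index[keep] + 1L] <-
      counts[sub$codon_index[keep] + 1L] + as.integer(sub$count[keep])
    new("RiboProfile", transcriptId = id, counts = counts)
  })
  names(out) <- ids
  out
}

#' Read a transcript annotation (flat TSV or transcript-space GTF)
#'
#' Two formats are accepted. A flat TSV with columns \code{transcript_id},
#' \code{utr5_len}, \code{cds_len} (nt) and optionally \code{utr3_len},
#' \code{intron_len_total}, \code{gene_id}. Or a GTF whose coordinates are
#' transcript-relative (seqname = transcript id, 1-based inclusive per the
#' GTF standard, converted to 0-based internally); CDS features define the
#' coding span and optional \code{five_prime_utr}/\code{three_prime_utr}
#' features the UTRs.
#'
#' @param path annotation file; format chosen by extension
#'   (\code{.gtf}/\code{.gff}* vs anything else).
#' @return data.frame with columns \code{transcript_id}, \code{cds_start}
#'   (0-based nt of the first CDS base), \code{cds_len}, \code{n_codons},
#'   and UTR/intron lengths where available.
#' @export
readAnnotation <- function(path) {
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    cds <- gr[gr$type == "CDS"]
    if (length(cds) == 0) stop("annotation contains no CDS features")
    ids <- as.character(GenomicRanges::seqnames(cds))
    starts <- GenomicRanges::start(cds)
    widths <- GenomicRanges::width(cds)
    agg <- data.frame(transcript_id = ids, start = starts, width = widths)
    cdsStart <- tapply(agg$start, agg$transcript_id, min) - 1L  # to 0-based
    cdsLen <- tapply(agg$width, agg$transcript_id, sum)
    out <- data.frame(transcript_id = names(cdsStart),
                      cds_start = as.integer(cdsStart),
                      cds_len = as.integer(cdsLen),
                      stringsAsFactors = FALSE)
    utr5 <- gr[gr$type == "five_prime_utr"]
    if (length(utr5)) {
      u <- tapply(GenomicRanges::width(utr5),
                  as.character(GenomicRanges::seqnames(utr5)), sum)
      out$utr5_len <- as.integer(u[out$transcript_id])
    }
    utr3 <- gr[gr$type == "three_prime_utr"]
    if (length(utr3)) {
      u <- tapply(GenomicRanges::width(utr3),
                  as.character(GenomicRanges::seqnames(utr3)), sum)
      out$utr3_len <- as.integer(u[out$transcript_id])
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "utr5_len", "cds_len")
    if (!all(need %in% names(df)))
      stop("flat annotation must have columns: ", paste(need, collapse = ", "))
    out <- df
    out$cds_start <- as.integer(df$utr5_len)
  }
  if (any(out$cds_len %% 3 != 0))
    warning("CDS length not a multiple of 3 for some transcripts; ",
            "codon count floored")
  out$n_codons <- as.integer(out$cds_len %/% 3)
  out
}

#' Estimate 3'-end P-site offsets per read length
#'
#' For footprints of each read length, the offset is the modal distance from
#' the read 3' end to the first base of the start codon, computed over
#' start-codon-proximal reads (reads covering the first CDS base). This is a
#' simplified re-implementation of the usual P-site calibration: initiating
#' ribosomes have their P-site on the start codon, so the modal 3'-end
#' distance recovers the length-specific offset.
#'
#' @param reads footprint data.frame as from \code{\link{readFootprints}}.
#' @param annotation data.frame from \code{\link{readAnnotation}}.
#' @param minSupport minimum (weighted) number of proximal reads a length
#'   needs to receive an offset; lengths below it are dropped.
#' @return data.frame with columns \code{read_length}, \code{offset_3prime},
#'   \code{support}.
#' @export
estimateOffsets <- function(reads, annotation, minSupport = 5) {
  m <- match(reads$transcript_id, annotation$transcript_id)
  keep <- !is.na(m)
  reads <- reads[keep, , drop = FALSE]
  cdsStart <- annotation$cds_start[m[keep]]
  threePrime <- reads$five_prime_pos + reads$read_length - 1L
  d <- threePrime - cdsStart
  prox <- d >= 0 & d <= reads$read_length - 1L  # read spans first CDS base
  if (!any(prox)) stop("no CDS-overlapping reads; cannot estimate offsets")
  sub <- data.frame(len = reads$read_length[prox], d = d[prox],
                    w = reads$count[prox])
  res <- lapply(split(sub, sub$len), function(s) {
    h <- tapply(s$w, s$d, sum)
    data.frame(read_length = s$len[1],
               offset_3prime = as.integer(names(h)[which.max(h)]),
               support = sum(s$w))
  })
  out <- do.call(rbind, res)
  out <- out[out$support >= minSupport, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("no read length reaches the support threshold")
  if (any(out$offset_3prime < 0 | out$offset_3prime >= out$read_length))
    warning("estimated offset outside [0, read_length) for some lengths")
  out
}

#' Map footprints to P-site codons
#'
#' Each read's P-site base is its 3' end minus the length-specific offset;
#' the codon index is \code{floor((psite - cds_start)/3)}. Reads whose
#' length has no offset, or whose codon falls outside \code{[0, n_codons)},
#' are dropped and tallied in the discard log.
#'
#' @param reads footprint data.frame (see \code{\link{readFootprints}}).
#' @param offsets offset table from \code{\link{estimateOffsets}} (or read
#'   from a TSV with columns \code{read_length}, \code{offset_3prime}).
#' @param annotation data.frame from \code{\link{readAnnotation}}.
#' @return list with \code{profiles} (named list of
#'   \linkS4class{RiboProfile}, one per annotated transcript with reads),
#'   \code{discarded} (named counts by reason) and \code{nAssigned}.
#' @export
assignPsites <- function(reads, offsets, annotation) {
  discard <- c(unknown_transcript = 0, unknown_length = 0, outside_cds = 0)
  m <- match(reads$transcript_id, annotation$transcript_id)
  discard["unknown_transcript"] <- sum(reads$count[is.na(m)])
  keep <- !is.na(m)
  reads <- reads[keep, , drop = FALSE]; m <- m[keep]
  om <- match(reads$read_length, offsets$read_length)
  discard["unknown_length"] <- sum(reads$count[is.na(om)])
  keep <- !is.na(om)
  reads <- reads[keep, , drop = FALSE]; m <- m[keep]; om <- om[keep]
  psite <- reads$five_prime_pos + reads$read_length - 1L -
    offsets$offset_3prime[om]
  codon <- floor((psite - annotation$cds_start[m]) / 3)
  inCds <- codon >= 0 & codon < annotation$n_codons[m]
  discard["outside_cds"] <- sum(reads$count[!inCds])
  reads <- reads[inCds, , drop = FALSE]
  m <- m[inCds]; codon <- codon[inCds]
  ids <- unique(reads$transcript_id)
  profiles <- lapply(ids, function(id) {
    sel <- reads$transcript_id == id
    n <- annotation$n_codons[match(id, annotation$transcript_id)]
    counts <- integer(n)
    tab <- tapply(reads$count[sel], codon[sel], sum)
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    new("RiboProfile", transcriptId = id, counts = counts)
  })
  names(profiles) <- ids
  list(profiles = profiles, discarded = discard,
       nAssigned = sum(reads$count))
}

#' Jointly filter paired control/mutant profiles
#'
#' A transcript is retained only when its CDS exceeds \code{minCodons}
#' codons and its mean read density exceeds \code{minMeanDensity} reads per
#' codon in \emph{both} conditions (both inequalities strict). The K-S
#' comparison is only meaningful when both profiles are adequately covered,
#' so the density filter is applied jointly across conditions.
#'
#' @param control,mutant named lists of \linkS4class{RiboProfile}; only
#'   transcripts present in both are considered.
#' @param minCodons,minMeanDensity strict lower bounds (defaults 100 codons,
#'   0.5 reads/codon).
#' @return list with filtered \code{control} and \code{mutant} lists plus a
#'   \code{report} data.frame of rejections (\code{transcript_id},
#'   \code{reason}).
#' @export
filterTranscripts <- function(control, mutant, minCodons = 100,
                              minMeanDensity = 0.5) {
  ids <- intersect(names(control), names(mutant))
  reasons <- character(0); rejIds <- character(0)
  keep <- character(0)
  for (id in ids) {
    nc <- nCodons(control[[id]])
    if (nc != nCodons(mutant[[id]])) {
      rejIds <- c(rejIds, id); reasons <- c(reasons, "length_mismatch")
      next
    }
    if (nc <= minCodons) {
      rejIds <- c(rejIds, id); reasons <- c(reasons, "short_cds")
      next
    }
    dc <- mean(footprintCounts(control[[id]]))
    dm <- mean(footprintCounts(mutant[[id]]))
    if (dc <= minMeanDensity || dm <= minMeanDensity) {
      rejIds <- c(rejIds, id); reasons <- c(reasons, "low_density")
      next
    }
    keep <- c(keep, id)
  }
  list(control = control[keep], mutant = mutant[keep],
       report = data.frame(transcript_id = rejIds, reason = reasons,
                           stringsAsFactors = FALSE))
}

#' LOWESS-smooth a per-codon count vector
#'
#' Locally weighted linear regression with tricube weights over the
#' \code{ceiling(span * n)} nearest codons, zero robustifying iterations,
#' evaluated at every codon; negative fitted values are clamped to zero.
#' Degenerate local fits (all weight on one codon) fall back to the
#' weighted mean.
#'
#' @param counts numeric vector (>= 3 codons).
#' @param span fraction of the transcript in each local window, in (0, 1].
#' @return numeric vector of non-negative smoothed values.
#' @export
smoothProfile <- function(counts, span = 0.1) {
  n <- length(counts)
  if (n < 3) stop("need at least 3 codons to smooth")
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must lie in (0, 1]")
  k <- ceiling(span * n)
  if (span * n < 2) stop("span * n must be at least 2 points")
  x <- seq_len(n) - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    dmax <- d[idx[k]]
    w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
    sw <- sum(w)
    xs <- x[idx]; ys <- counts[idx]
    sx <- sum(w * xs); sy <- sum(w * ys)
    sxx <- sum(w * xs * xs); sxy <- sum(w * xs * ys)
    denom <- sw * sxx - sx * sx
    out[i] <- if (denom <= .Machine$double.eps * sw * sxx + 1e-300 ||
                  sw == 0) {
      if (sw > 0) sy / sw else counts[i]
    } else {
      b <- (sw * sxy - sx * sy) / denom
      a <- (sy - b * sx) / sw
      a + b * x[i]
    }
  }
  pmax(out, 0)
}

#' Sum-normalize a density vector
#'
#' @param density non-negative numeric vector with positive sum.
#' @return vector scaled to sum to 1.
#' @export
normalizeProfile <- function(density) {
  if (any(density < 0)) stop("density must be non-negative")
  tot <- sum(density)
  if (tot <= 0) stop("cannot normalize an all-zero density")
  density / tot
}

#' Smooth and normalize a footprint profile
#'
#' Convenience constructor chaining \code{\link{smoothProfile}} and
#' \code{\link{normalizeProfile}} in the pipeline's stated order
#' (smoothing of raw counts first, then normalization).
#'
#' @param profile a \linkS4class{RiboProfile}.
#' @param span LOWESS span.
#' @return a \linkS4class{SmoothedProfile}.
#' @export
smoothedProfile <- function(profile, span = 0.1) {
  stopifnot(is(profile, "RiboProfile"))
  dens <- smoothProfile(as.numeric(footprintCounts(profile)), span = span)
  new("SmoothedProfile", transcriptId = transcriptId(profile),
      density = dens, normalized = normalizeProfile(dens))
}
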