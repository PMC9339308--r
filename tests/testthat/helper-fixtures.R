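# Shared fixture builders; everything is generated in code at test time.

# A RiboProfile from a plain count vector.
rp <- function(counts, id = "tx") {
  new("RiboProfile", transcriptId = id, counts = as.integer(counts))
}

# Random footprint table for n transcripts whose reads are constructed so
# that each read length has a known, fixed 3'-offset to the P-site.
makeSyntheticReads <- function(annotation, offsetsByLength, nReads = 300,
                               seed = 1) {
  withr::with_seed(seed, {
    lens <- as.integer(names(offsetsByLength))
    rows <- lapply(seq_len(nReads), function(i) {
      a <- annotation[sample(nrow(annotation), 1), ]
      L <- sample(lens, 1)
      off <- offsetsByLength[[as.character(L)]]
      codon <- sample(0:(a$n_codons - 1), 1)
      frame <- sample(0:2, 1)
      psite <- a$cds_start + 3 * codon + frame
      threePrime <- psite + off
      fivePrime <- threePrime - L + 1
      if (fivePrime < 0) return(NULL)
      data.frame(transcript_id = a$transcript_id, five_prime_pos = fivePrime,
                 read_length = L, count = sample(1:3, 1),
                 true_codon = codon, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

toyAnnotation <- function() {
  data.frame(transcript_id = c("txA", "txB"),
             cds_start = c(60L, 30L),
             cds_len = c(450L, 360L),
             n_codons = c(150L, 120L),
             stringsAsFactors = FALSE)
}

# Independent per-point weighted-least-squares LOWESS oracle: a literal
# translation of the definition using lm() at every codon.
lowessOracle <- function(y, span) {
  n <- length(y)
  k <- ceiling(span * n)
  x <- seq_len(n) - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    dmax <- max(d[idx])
    w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
    fit <- stats::lm(y[idx] ~ x[idx], weights = w)
    out[i] <- unname(fit$coefficients[1] + fit$coefficients[2] * x[i])
  }
  pmax(out, 0)
}

# Brute-force K-S oracle: explicit loop over every codon position.
ksOracle <- function(a, b) {
  ca <- cumsum(a); cb <- cumsum(b)
  best <- -1; arg <- NA
  for (i in seq_along(a)) {
    d <- abs(ca[i] - cb[i])
    if (d > best) { best <- d; arg <- i - 1L }
  }
  list(ks_stat = best, argmax_codon = arg)
}

# Brute-force degenerate-motif counter over expanded IUPAC sets.
motifOracle <- function(seq, motif) {
  expand <- list(A = "A", C = "C", G = "G", U = "U",
                 W = c("A", "U"), K = c("G", "U"), Y = c("C", "U"))
  s <- chartr("T", "U", toupper(seq))
  m <- strsplit(toupper(motif), "")[[1]]
  n <- nchar(s); L <- length(m)
  if (n < L) return(0)
  count <- 0
  for (i in seq_len(n - L + 1)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      ch <- substr(s, i + j - 1, i + j - 1)
      if (!(ch %in% expand[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1
  }
  count
}

# Random RNA string.
randomRna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = ""))
}
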