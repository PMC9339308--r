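test_that("offset estimation recovers constructed 3' offsets", {
  ann <- toyAnnotation()
  # all 28-mers placed with 3' ends 15 nt past the first CDS base,
  # all 29-mers 14 nt past it
  reads <- rbind(
    data.frame(transcript_id = "txA", five_prime_pos = 60 + 15 - 27,
               read_length = 28, count = 20),
    data.frame(transcript_id = "txB", five_prime_pos = 30 + 14 - 28,
               read_length = 29, count = 12))
  off <- estimateOffsets(reads, ann, minSupport = 5)
  expect_equal(off$offset_3prime[off$read_length == 28], 15)
  expect_equal(off$offset_3prime[off$read_length == 29], 14)
  # support threshold drops sparse lengths
  reads2 <- rbind(reads, data.frame(transcript_id = "txA",
                                    five_prime_pos = 60 + 16 - 29,
                                    read_length = 30, count = 2))
  off2 <- estimateOffsets(reads2, ann, minSupport = 5)
  expect_false(30 %in% off2$read_length)
  # no start-proximal reads at all
  far <- data.frame(transcript_id = "txA", five_prime_pos = 300,
                    read_length = 28, count = 5)
  expect_error(estimateOffsets(far, ann), "CDS-overlapping")
})

test_that("offset mode equals a brute-force histogram over random reads", {
  ann <- toyAnnotation()
  offsets <- list(`28` = 15, `29` = 14)
  reads <- makeSyntheticReads(ann, offsets, nReads = 400, seed = 21)
  # keep only start-proximal reads and tally the 3'-start distance directly
  cds <- ann$cds_start[match(reads$transcript_id, ann$transcript_id)]
  d <- reads$five_prime_pos + reads$read_length - 1 - cds
  prox <- d >= 0 & d <= reads$read_length - 1
  est <- estimateOffsets(reads, ann, minSupport = 1)
  for (L in c(28, 29)) {
    sel <- prox & reads$read_length == L
    h <- tapply(reads$count[sel], d[sel], sum)
    expect_equal(est$offset_3prime[est$read_length == L],
                 as.integer(names(h)[which.max(h)]))
  }
})

test_that("P-site assignment matches a per-read loop and conserves reads", {
  ann <- toyAnnotation()
  offsets <- list(`28` = 15, `29` = 14)
  reads <- makeSyntheticReads(ann, offsets, nReads = 250, seed = 8)
  offTab <- data.frame(read_length = c(28L, 29L), offset_3prime = c(15L, 14L))
  res <- assignPsites(reads, offTab, ann)
  # independent oracle: loop over individual reads
  for (id in names(res$profiles)) {
    n <- ann$n_codons[ann$transcript_id == id]
    oracle <- integer(n)
    for (r in seq_len(nrow(reads))) {
      if (reads$transcript_id[r] != id) next
      off <- offTab$offset_3prime[offTab$read_length == reads$read_length[r]]
      ps <- reads$five_prime_pos[r] + reads$read_length[r] - 1 - off
      cd <- floor((ps - ann$cds_start[ann$transcript_id == id]) / 3)
      if (cd >= 0 && cd < n)
        oracle[cd + 1] <- oracle[cd + 1] + reads$count[r]
    }
    expect_identical(footprintCounts(res$profiles[[id]]), oracle)
  }
  # construction also tells us the true codon of every kept read
  expect_equal(res$nAssigned + sum(res$discarded), sum(reads$count))
  # a single worked example: 3' end 17 nt past the start codon, offset 15
  one <- data.frame(transcript_id = "txA", five_prime_pos = 60 + 17 - 27,
                    read_length = 28, count = 1)
  prof <- assignPsites(one, offTab, ann)$profiles$txA
  expect_equal(which(footprintCounts(prof) == 1) - 1, 0)  # codon 0
  # unlisted read length goes to the discard log
  unk <- data.frame(transcript_id = "txA", five_prime_pos = 100,
                    read_length = 31, count = 2)
  res2 <- assignPsites(unk, offTab, ann)
  expect_equal(unname(res2$discarded["unknown_length"]), 2)
  expect_equal(res2$nAssigned, 0)
})

test_that("retention filters are strict and joint across conditions", {
  ok <- rp(rep(1L, 101), "keep")       # 101 codons, density 1
  short <- rp(rep(9L, 100), "short")   # exactly 100 codons: rejected
  ctrl <- list(keep = ok, short = short,
               sparse = rp(c(rep(1L, 60), rep(0L, 60)), "sparse"),
               border = rp(rep(c(1L, 0L), 60), "border"))
  mut <- list(keep = rp(rep(2L, 101), "keep"), short = short,
              sparse = rp(rep(1L, 120), "sparse"),
              border = rp(rep(c(0L, 1L), 60), "border"))
  flt <- filterTranscripts(ctrl, mut)
  expect_identical(names(flt$control), "keep")
  rep_ <- flt$report
  expect_identical(rep_$reason[rep_$transcript_id == "short"], "short_cds")
  # density 0.5 exactly (border) and one-condition failure (sparse): rejected
  expect_identical(rep_$reason[rep_$transcript_id == "border"], "low_density")
  expect_identical(rep_$reason[rep_$transcript_id == "sparse"], "low_density")
})

test_that("LOWESS smoothing is exact on lines and matches a per-point WLS fit", {
  x <- 0:149
  line <- 2 + 0.5 * x
  expect_lt(max(abs(smoothProfile(line, 0.2) - line)), 1e-6)
  expect_equal(smoothProfile(rep(3, 120), 0.1), rep(3, 120))
  y <- withr::with_seed(13, rpois(200, lambda = 5))
  expect_lt(max(abs(smoothProfile(y, 0.1) - lowessOracle(y, 0.1))), 1e-8)
  expect_lt(max(abs(smoothProfile(y, 0.3) - lowessOracle(y, 0.3))), 1e-8)
  expect_error(smoothProfile(c(1, 2), 0.5), "at least 3")
  expect_error(smoothProfile(rep(1, 10), 0.1), "at least 2 points")
  expect_error(smoothProfile(rep(1, 10), 1.2), "span")
})

test_that("smoothing roughly conserves total signal at small spans", {
  y <- withr::with_seed(29, rpois(300, lambda = 3))
  s <- smoothProfile(y, 0.1)
  expect_lt(abs(sum(s) - sum(y)) / sum(y), 0.1)
})

test_that("normalization closes to one and is scale invariant", {
  expect_equal(normalizeProfile(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  v <- withr::with_seed(3, runif(50))
  expect_equal(sum(normalizeProfile(v)), 1, tolerance = 1e-9)
  expect_equal(normalizeProfile(10 * v), normalizeProfile(v))
  expect_error(normalizeProfile(rep(0, 5)), "all-zero")
  expect_error(normalizeProfile(c(-1, 2)), "non-negative")
})

test_that("count tables and annotations round-trip through files", {
  dir <- withr::local_tempdir()
  ann <- toyAnnotation()
  prof <- list(txA = rp(withr::with_seed(2, rpois(150, 2)), "txA"))
  df <- data.frame(transcript_id = "txA", codon_index = 0:149,
                   count = footprintCounts(prof$txA))
  f <- file.path(dir, "counts.tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readCodonCounts(f)
  expect_identical(footprintCounts(back$txA), footprintCounts(prof$txA))
  # flat annotation TSV
  af <- file.path(dir, "ann.tsv")
  write.table(data.frame(transcript_id = "txA", utr5_len = 60, cds_len = 450),
              af, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- readAnnotation(af)
  expect_equal(a$cds_start, 60)
  expect_equal(a$n_codons, 150)
  # transcript-space GTF (1-based inclusive) converts to the same model
  gf <- file.path(dir, "ann.gtf")
  writeLines(paste(c("txA", "test", "CDS", "61", "510", ".", "+", "0",
                     'transcript_id "txA"; gene_id "gA";'),
                   collapse = "\t"), gf)
  g <- readAnnotation(gf)
  expect_equal(g$cds_start, 60)
  expect_equal(g$n_codons, 150)
})
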