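test_that("Hoogsteen triplet rules match the published pairing table", {
  expect_true(hoogsteenMatch("U", "A", "pyrimidine"))
  expect_true(hoogsteenMatch("C", "G", "pyrimidine"))
  expect_false(hoogsteenMatch("C", "A", "pyrimidine"))
  expect_true(hoogsteenMatch("G", "G", "purine"))
  expect_true(hoogsteenMatch("A", "A", "purine"))
  expect_false(hoogsteenMatch("U", "A", "purine"))
  expect_true(hoogsteenMatch("U", "A", "mixed"))
  expect_true(hoogsteenMatch("G", "G", "mixed"))
  expect_false(hoogsteenMatch("C", "G", "mixed"))
  ## T behaves as U; N never matches
  expect_true(hoogsteenMatch("T", "A", "pyrimidine"))
  for (m in c("pyrimidine", "purine", "mixed")) {
    expect_false(hoogsteenMatch("N", "A", m))
    expect_false(hoogsteenMatch("U", "N", m))
  }
})

test_that("canonical GA-tract fixtures obey the four search constraints", {
  p <- triplexParams()
  ## perfect 16-mer pyrimidine match (GA purine strand, CU TFO)
  m <- findTriplexes("CUCUCUCUCUCUCUCU", "GAGAGAGAGAGAGAGA", p)
  expect_identical(nrow(m), 1L)
  expect_identical(m$length, 16L)
  expect_identical(m$errors, 0L)
  expect_identical(m$motif, "pyrimidine")
  expect_identical(m$orientation, "parallel")
  expect_equal(m$guanine_fraction, 0.5)
  expect_equal(m$score, 16)
  ## a perfect 14-mer is below the minimum length
  m14 <- findTriplexes("CUCUCUCUCUCUCU", "GAGAGAGAGAGAGA", p)
  expect_identical(nrow(m14), 0L)
  ## guanine content bound: a pure A tract has guanine fraction 0 < 0.20
  expect_identical(nrow(findTriplexes(strrep("U", 15), strrep("A", 15), p)), 0L)
  ## ...but passes when the guanine constraint is lifted
  p0 <- triplexParams(minGuanine = 0, motifs = "pyrimidine")
  expect_identical(nrow(findTriplexes(strrep("U", 15), strrep("A", 15), p0)), 1L)
})

test_that("error-rate and consecutive-error bounds are strict at the boundary", {
  p <- triplexParams()
  tract <- strrep("GA", 10)                       # 20 nt purine strand
  tfo <- strsplit(chartr("GA", "CT", tract), "")[[1]]
  ## 15-mer with 3 errors = 20% fails the strict bound; 2 errors passes
  t3 <- tfo[1:15]; t3[c(3, 8, 13)] <- "G"
  m3 <- findTriplexes(paste(t3, collapse = ""), substr(tract, 1, 15), p)
  expect_false(any(m3$length >= 15 & m3$errors >= 3))
  expect_identical(nrow(m3), 0L)
  t2 <- tfo[1:15]; t2[c(3, 13)] <- "G"
  m2 <- findTriplexes(paste(t2, collapse = ""), substr(tract, 1, 15), p)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$errors, 2L)
  expect_true(m2$errors / m2$length < 0.2)
  ## a centred run of 4 mismatches cannot be spanned by one match
  tr30 <- strrep("GA", 15)
  tf30 <- strsplit(chartr("GA", "CT", tr30), "")[[1]]
  tf30[14:17] <- "G"
  mRun <- findTriplexes(paste(tf30, collapse = ""), tr30, p)
  expect_true(all(mRun$errors <= 3))
  for (k in seq_len(nrow(mRun)))
    expect_false(mRun$tfo_start[k] <= 14 && mRun$tfo_end[k] >= 17)
  ## 3 consecutive errors are allowed when the rate permits
  tf21 <- strsplit(chartr("GA", "CT", strrep("GA", 12)), "")[[1]]
  tf21[11:13] <- "G"
  mCons <- findTriplexes(paste(tf21, collapse = ""), strrep("GA", 12),
                         triplexParams(maxErrorRate = 0.3))
  expect_true(any(mCons$errors == 3 & mCons$length == 24))
})

test_that("matches equal the brute-force enumerator on random and planted pairs", {
  set.seed(500)
  p <- triplexParams()
  for (i in 1:15) {
    rna <- randSeq(150); dna <- randSeq(150)
    expect_identical(triplexKeys(findTriplexes(rna, dna, p)),
                     triplexKeys(oracleTriplex(rna, dna, p)))
  }
  for (i in 1:10) {
    tract <- paste(sample(c("G", "A"), 40, TRUE), collapse = "")
    tf <- strsplit(chartr("GA", "CT", tract), "")[[1]]
    nerr <- sample(0:5, 1)
    if (nerr > 0) tf[sample(40, nerr)] <- sample(c("A", "G", "C", "T"), 1)
    rna <- paste0(randSeq(30), paste(tf, collapse = ""), randSeq(30))
    dna <- paste0(randSeq(40), tract, randSeq(40))
    expect_identical(triplexKeys(findTriplexes(rna, dna, p)),
                     triplexKeys(oracleTriplex(rna, dna, p)))
  }
})

test_that("reported error positions re-verify under the Hoogsteen rule", {
  set.seed(81)
  p <- triplexParams()
  tract <- paste(sample(c("G", "A"), 60, TRUE), collapse = "")
  tf <- strsplit(chartr("GA", "CT", tract), "")[[1]]
  tf[sample(60, 6)] <- "G"
  rna <- paste0(randSeq(20), paste(tf, collapse = ""), randSeq(20))
  dna <- paste0(randSeq(30), tract, randSeq(30))
  m <- findTriplexes(rna, dna, p)
  expect_gt(nrow(m), 0)
  rnaV <- strsplit(chartr("U", "T", rna), "")[[1]]
  dnaV <- strsplit(dna, "")[[1]]
  for (k in seq_len(nrow(m))) {
    if (m$orientation[k] != "parallel" || m$tts_strand[k] != "+") next
    tfo <- rnaV[m$tfo_start[k]:m$tfo_end[k]]
    tts <- dnaV[m$tts_start[k]:m$tts_end[k]]
    ok <- hoogsteenMatch(tfo, tts, m$motif[k])
    errAt <- if (nzchar(m$error_positions[k]))
      as.integer(strsplit(m$error_positions[k], ",")[[1]]) else integer(0)
    expect_identical(which(!ok), errAt)
    expect_identical(length(errAt), m$errors[k])
  }
})

test_that("matches on a sequence map onto its reverse complement with strands swapped", {
  set.seed(92)
  p <- triplexParams()
  tract <- paste(sample(c("G", "A"), 30, TRUE), collapse = "")
  rna <- paste0(randSeq(20), chartr("GA", "CT", tract), randSeq(20))
  dna <- paste0(randSeq(40), tract, randSeq(40))
  n <- nchar(dna)
  a <- findTriplexes(rna, dna, p)
  b <- findTriplexes(rna, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dna))), p)
  expect_identical(nrow(a), nrow(b))
  ## coordinates mirror: start' = n - end + 1; purine strand flips
  bk <- paste(b$tfo_start, b$tfo_end, n - b$tts_end + 1, n - b$tts_start + 1,
              b$motif, b$orientation, chartr("+-", "-+", b$tts_strand))
  ak <- paste(a$tfo_start, a$tfo_end, a$tts_start, a$tts_end,
              a$motif, a$orientation, a$tts_strand)
  expect_setequal(ak, bk)
})

test_that("TTS clusters merge by overlap and report GA fractions", {
  matches <- data.frame(tts_start = c(100, 110, 400), tts_end = c(120, 130, 420),
                        tts_strand = "+")
  dna <- Biostrings::DNAString(paste0(strrep("C", 99), strrep("GA", 16),
                                      strrep("T", 269), strrep("G", 21),
                                      strrep("C", 50)))
  cl <- clusterTts(matches, dna, gap = 0, minMembers = 2)
  expect_identical(cl$start, c(100L, 400L))
  expect_identical(cl$end, c(130L, 420L))
  expect_identical(cl$n_members, c(2L, 1L))
  expect_identical(cl$high_frequency, c(TRUE, FALSE))
  expect_equal(cl$ga_fraction[1], 1)
  ## single match forms its own cluster
  one <- clusterTts(matches[3, ], dna)
  expect_identical(one$n_members, 1L)
  expect_identical(nrow(clusterTts(matches[0, ], dna)), 0L)
})

test_that("locus scans lift coordinates to genome space and annotate features", {
  cfg <- simulationConfig(seed = 19)
  st <- simulateStudy(cfg)
  tri <- st$truth$triplex
  expect_false(is.null(tri))
  host <- st$reference[tri$host_transcript]
  sp <- txSpan(host)
  locus <- GRanges(tri$scaffold,
                   IRanges(GenomicRanges::start(sp) - 500,
                           GenomicRanges::end(sp) + 500))
  lseq <- extractTxSeqs(st$novel[tri$lncrna_id], st$genome)[[1]]
  m <- scanLncrnaVsLocus(lseq, st$genome, locus, st$reference,
                         unname(geneIds(st$reference)[tri$host_transcript]))
  hit <- m[m$tts_genomic_start <= tri$tract_end &
             m$tts_genomic_end >= tri$tract_start, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$feature == "intron1"))
  ## lifted coordinates round-trip through BED unchanged
  gr <- GRanges(m$scaffold, IRanges(m$tts_genomic_start, m$tts_genomic_end))
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- rtracklayer::import(f)
  expect_identical(GenomicRanges::start(back), m$tts_genomic_start)
  expect_identical(GenomicRanges::end(back), m$tts_genomic_end)
  ## a locus outside the scaffold errors
  expect_error(scanLncrnaVsLocus(lseq, st$genome,
                                 GRanges(tri$scaffold, IRanges(1, 1e9)),
                                 st$reference, "gM001"), "outside")
})

test_that("an impure tract is not matched over its full length under the error bound", {
  cfg <- simulationConfig(seed = 23, tractPurity = 0.5)
  ga <- simulateGenomeAnnotation(cfg)
  nv <- simulateNovelTranscripts(ga, cfg)
  uId <- nv$truth$transcript_id[nv$truth$true_class == "u"][1]
  tri <- plantTriplex(nv$genome, ga$reference, nv$novel, uId, cfg)
  lseq <- extractTxSeqs(nv$novel[uId], tri$genome)[[1]]
  host <- ga$reference[tri$truth$host_transcript]
  sp <- txSpan(host)
  locus <- GRanges(tri$truth$scaffold,
                   IRanges(GenomicRanges::start(sp), GenomicRanges::end(sp)))
  m <- scanLncrnaVsLocus(lseq, tri$genome, locus, ga$reference,
                         unname(geneIds(ga$reference)[tri$truth$host_transcript]))
  full <- m[m$tts_genomic_start <= tri$truth$tract_start &
              m$tts_genomic_end >= tri$truth$tract_end, ]
  expect_identical(nrow(full), 0L)
})
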