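smallCfg <- function(seed = 1, ...) {
  simulationConfig(seed = seed, nScaffolds = 2, scaffoldLength = 200000,
                   nRefMrna = 14, nRefLncrna = 8,
                   nNovel = c(i = 3, y = 2, p = 3, u = 4), nDecoy = 3, ...)
}

test_that("the genome and annotation generators are deterministic under seed", {
  a <- simulateGenomeAnnotation(smallCfg(seed = 4))
  b <- simulateGenomeAnnotation(smallCfg(seed = 4))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGtf(a$reference, f1); writeGtf(b$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## a different seed changes the genome
  c <- simulateGenomeAnnotation(smallCfg(seed = 5))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("reference annotation honours the configured composition", {
  ga <- simulateGenomeAnnotation(smallCfg(seed = 2))
  bt <- txBiotype(ga$reference)
  expect_identical(sum(bt == "mRNA"), 14L)
  expect_identical(sum(bt == "lncRNA"), 8L)
  ## all reference lncRNAs are spliced (>= 2 exons)
  expect_true(all(lengths(txExons(ga$reference))[bt == "lncRNA"] >= 2))
  ## no lncRNAs when none are requested
  ga0 <- simulateGenomeAnnotation(
    simulationConfig(seed = 2, nScaffolds = 2, scaffoldLength = 200000,
                     nRefMrna = 10, nRefLncrna = 0,
                     nNovel = c(i = 1, y = 0, p = 1, u = 1), nDecoy = 0))
  expect_false(any(txBiotype(ga0$reference) == "lncRNA"))
})

test_that("generated mRNAs carry long codon-biased ORFs readable from the genome", {
  ga <- simulateGenomeAnnotation(smallCfg(seed = 3))
  seqs <- extractTxSeqs(ga$reference, ga$genome)
  bt <- txBiotype(ga$reference)
  for (id in names(bt)[bt == "mRNA"]) {
    orf <- longestOrf(seqs[[id]])
    expect_gte(orf$length_nt, 300)
    expect_true(orf$has_stop)
  }
  ## reference lncRNAs have no 100-codon ORF by construction
  for (id in names(bt)[bt == "lncRNA"]) {
    o <- findOrfs(seqs[[id]])
    o <- o[o$has_stop, , drop = FALSE]
    if (nrow(o)) expect_lt(max(o$length_nt) / 3 - 1, 100)
  }
})

test_that("planted novel transcripts are recovered with their intended class codes", {
  cfg <- smallCfg(seed = 6)
  ga <- simulateGenomeAnnotation(cfg)
  nv <- simulateNovelTranscripts(ga, cfg)
  got <- assignClassCode(nv$novel, ga$reference)
  truth <- nv$truth
  planted <- truth$true_class %in% c("i", "y", "p", "u")
  expect_identical(unname(got[truth$transcript_id[planted]]),
                   truth$true_class[planted])
  ## decoys never land in a kept class
  expect_false(any(got[truth$transcript_id[!planted]] %in% c("i", "y", "p", "u")))
  ## zero requested novels produce an empty set
  cfg0 <- simulationConfig(seed = 6, nScaffolds = 2, scaffoldLength = 200000,
                           nRefMrna = 10, nRefLncrna = 2,
                           nNovel = c(i = 0, y = 0, p = 0, u = 0), nDecoy = 0)
  ga0 <- simulateGenomeAnnotation(cfg0)
  nv0 <- simulateNovelTranscripts(ga0, cfg0)
  expect_identical(length(nv0$novel), 0L)
})

test_that("count simulation is deterministic and respects planted fold changes", {
  cfg <- smallCfg(seed = 9)
  means <- stats::setNames(rep(c(100, 500), 10), sprintf("g%02d", 1:20))
  lfc <- c(rep(0, 10), rep(2, 5), rep(-2, 5))
  a <- simulateCounts(means, lfc, 0.1, cfg, seed = 77)
  b <- simulateCounts(means, lfc, 0.1, cfg, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(dim(a$counts), c(20L, 32L))
  mated <- a$sampleSheet$group == "mated"
  ratio <- rowMeans(a$counts[, mated]) / rowMeans(a$counts[, !mated])
  expect_equal(mean(log2(ratio[11:15])), 2, tolerance = 0.5)
  expect_equal(mean(log2(ratio[16:20])), -2, tolerance = 0.5)
  expect_error(simulateCounts(c(g = -1), 0, 0.1, cfg), "positive")
})

test_that("null genes show no systematic group difference", {
  cfg <- smallCfg()
  means <- stats::setNames(exp(runif(60, log(50), log(800))), sprintf("g%02d", 1:60))
  frac <- replicate(8, {
    s <- sample.int(1e6, 1)
    sim <- simulateCounts(means, rep(0, 60), 0.1, cfg, seed = s)
    ## technical runs share a biological replicate's latent expression, so
    ## the unit of replication is the biological replicate mean
    repId <- paste(sim$sampleSheet$group, sim$sampleSheet$biological_replicate)
    repMeans <- sapply(unique(repId), function(r)
      rowMeans(sim$counts[, repId == r, drop = FALSE]))
    mated <- startsWith(colnames(repMeans), "mated")
    m1 <- rowMeans(repMeans[, mated]); m0 <- rowMeans(repMeans[, !mated])
    v <- apply(repMeans[, mated], 1, var) / 4 +
      apply(repMeans[, !mated], 1, var) / 4
    mean(abs(m1 - m0) < 3 * sqrt(v))
  })
  expect_gte(mean(frac), 0.95)
})

test_that("the dispersion parameter controls the variance/mean ratio", {
  cfg <- smallCfg()
  means <- stats::setNames(rep(200, 200), sprintf("g%03d", 1:200))
  ## Poisson limit: alpha below the threshold collapses the Gamma layer
  simP <- simulateCounts(means, rep(0, 200), 1e-6, cfg, seed = 5)
  virgin <- simP$sampleSheet$group == "virgin"
  ## compare within a single library-size stratum: rescale by column sums
  k <- t(t(simP$counts[, virgin]) / colSums(simP$counts[, virgin])) * 200 * 200
  vm <- apply(k, 1, var) / rowMeans(k)
  expect_lt(median(vm), 1.5)
  ## strong overdispersion pushes the ratio far above 1
  simN <- simulateCounts(means, rep(0, 200), 0.3, cfg, seed = 5)
  kN <- t(t(simN$counts[, virgin]) / colSums(simN$counts[, virgin])) * 200 * 200
  vmN <- apply(kN, 1, var) / rowMeans(kN)
  expect_gt(median(vmN), 5)
})

test_that("the copula plant induces the targeted rank correlation", {
  cfg <- smallCfg()
  means <- stats::setNames(rep(400, 6), c("L1", "L2", "L3", "M1", "M2", "M3"))
  rhos <- replicate(10, {
    s <- sample.int(1e6, 1)
    sim <- simulateCounts(means, rep(0, 6), 0.1, cfg,
                          pairs = data.frame(a = "L1", b = "M1", rho = 0.95,
                                             group = "both"), seed = s)
    cor(sim$counts["L1", ], sim$counts["M1", ], method = "spearman")
  })
  expect_gt(median(rhos), 0.8)
})

test_that("the triplex plant writes a recoverable tract and matching TFO", {
  cfg <- smallCfg(seed = 13)
  ga <- simulateGenomeAnnotation(cfg)
  nv <- simulateNovelTranscripts(ga, cfg)
  uId <- nv$truth$transcript_id[nv$truth$true_class == "u"][1]
  tri <- plantTriplex(nv$genome, ga$reference, nv$novel, uId, cfg)
  tr <- tri$truth
  ## the tract is pure purine at purity 1
  tract <- Biostrings::subseq(tri$genome[[tr$scaffold]], tr$tract_start, tr$tract_end)
  freq <- Biostrings::alphabetFrequency(tract)
  expect_identical(sum(freq[c("G", "A")]), as.integer(cfg$tractLength))
  ## the planted TFO matches the tract under the pyrimidine motif
  lseq <- extractTxSeqs(nv$novel[uId], tri$genome)[[1]]
  tfo <- strsplit(substr(as.character(lseq), tr$tfo_start, tr$tfo_end), "")[[1]]
  expect_true(all(hoogsteenMatch(tfo, strsplit(as.character(tract), "")[[1]],
                                 "pyrimidine")))
  ## determinism of the plant coordinates
  tri2 <- plantTriplex(nv$genome, ga$reference, nv$novel, uId, cfg)
  expect_identical(tri$truth, tri2$truth)
})

test_that("the assembled study is reproducible end to end", {
  cfg <- smallCfg(seed = 21)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$expression, s2$truth$expression)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudy(s1, d1); writeStudy(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})
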