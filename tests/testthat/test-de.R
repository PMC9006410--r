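test_that("TPM normalisation follows the rate/sum definition", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- computeTpm(m, c(1000, 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
  ## symmetry: equal counts and lengths split evenly
  m2 <- matrix(c(7, 7), 2, 1)
  expect_equal(unname(computeTpm(m2, c(500, 500))[, 1]), c(5e5, 5e5))
  ## columns sum to 1e6; all-zero columns stay zero
  set.seed(3)
  m3 <- matrix(rpois(60, 20), 10, 6)
  m3[, 4] <- 0
  tpm3 <- computeTpm(m3, runif(10, 200, 2000))
  expect_equal(unname(colSums(tpm3)), c(1e6, 1e6, 1e6, 0, 1e6, 1e6),
               tolerance = 1e-6)
  expect_error(computeTpm(m3, rep(0, 10)), "positive")
})

test_that("the prefilter keeps genes expressed in at least 3 samples of one group", {
  groups <- rep(c("virgin", "mated"), each = 4)
  counts <- rbind(
    allzero  = rep(0, 8),
    mated3   = c(0, 0, 0, 0, 5, 3, 8, 0),
    twoEach  = c(4, 2, 0, 0, 0, 0, 1, 9),
    allon    = rep(10, 8))
  keep <- prefilterGenes(counts, groups)
  expect_identical(unname(keep), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(prefilterGenes(counts, rep("virgin", 8)), "two groups")
})

test_that("median-of-ratios size factors match hand computations", {
  m <- matrix(c(4, 9, 25, 4, 9, 25), 3, 2)
  expect_equal(unname(computeSizeFactors(m)), c(1, 1))
  ## second sample at double depth
  m2 <- matrix(c(10, 20, 40, 20, 40, 80), 3, 2)
  expect_equal(unname(computeSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  ## invariance to gene order
  set.seed(8)
  m3 <- matrix(rpois(40, 50) + 1, 10, 4)
  p <- sample(10)
  expect_equal(computeSizeFactors(m3), computeSizeFactors(m3[p, ]))
  expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)), "prefilter")
})

test_that("moment dispersion recovers the Poisson and NB regimes", {
  set.seed(42)
  n <- 16
  groups <- rep(c("virgin", "mated"), each = n)
  ## Poisson counts: dispersion estimates collapse toward the floor
  pois <- matrix(rpois(500 * 2 * n, lambda = rep(exp(runif(500, 3, 6)), 2 * n)),
                 nrow = 500)
  sf <- rep(1, 2 * n)
  aP <- estimateDispersion(pois, sf, groups)
  expect_lte(median(aP), 0.01)
  ## NB alpha = 0.2 is recovered within a factor ~2
  mu <- exp(runif(500, 3, 6))
  nb <- matrix(rnbinom(500 * 2 * n, mu = rep(mu, 2 * n), size = 1 / 0.2),
               nrow = 500)
  aN <- estimateDispersion(nb, sf, groups)
  expect_gt(median(aN), 0.1)
  expect_lt(median(aN), 0.4)
  ## constant gene hits the floor
  cst <- rbind(rep(5, 2 * n), pois[1:20, ])
  expect_equal(unname(estimateDispersion(cst, sf, groups)[1]), 1e-8)
})

test_that("the NB Wald test estimates planted fold changes and is antisymmetric", {
  set.seed(99)
  n <- 16
  groups <- rep(c("virgin", "mated"), each = n)
  G <- 150
  mu <- rep(100, G)
  counts <- cbind(
    matrix(rnbinom(G * n, mu = mu, size = 1 / 0.05), G, n),
    matrix(rnbinom(G * n, mu = 4 * mu, size = 1 / 0.05), G, n))
  sf <- rep(1, 2 * n)
  disp <- rep(0.05, G)
  res <- nbWaldTest(counts, sf, disp, groups)
  expect_true(all(res$converged))
  expect_equal(mean(res$log2FC), 2, tolerance = 0.1)
  expect_true(all(abs(res$log2FC - 2) < 1))
  ## swapping group labels negates the estimate exactly
  res2 <- nbWaldTest(counts, sf, disp, rev(groups))
  expect_equal(res2$log2FC, -res$log2FC, tolerance = 1e-9)
  ## null genes give approximately uniform p-values
  null <- matrix(rnbinom(800 * 2 * n, mu = 200, size = 1 / 0.1), 800, 2 * n)
  resN <- nbWaldTest(null, sf, rep(0.1, 800), groups)
  ks <- suppressWarnings(stats::ks.test(resN$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NB Wald agrees with an independent fixed-dispersion likelihood fit", {
  set.seed(7)
  n <- 8
  groups <- rep(c("virgin", "mated"), each = n)
  sf <- runif(2 * n, 0.8, 1.2)
  y <- rnbinom(2 * n, mu = 150 * sf * rep(c(1, 3), each = n), size = 1 / 0.1)
  counts <- matrix(y, 1)
  res <- nbWaldTest(counts, sf, 0.1, groups)
  ## direct likelihood maximisation as the oracle
  nll <- function(b) -sum(dnbinom(y, mu = exp(b[1] + b[2] * (groups == "mated") +
                                                log(sf)), size = 1 / 0.1, log = TRUE))
  opt <- optim(c(5, 1), nll, method = "BFGS")
  expect_equal(res$log2FC, opt$par[2] / log(2), tolerance = 1e-4)
})

test_that("BH adjustment matches hand computation and propagates NA", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.42), 0.42)
  p <- c(0.04, NA, 0.001)
  adj <- bhAdjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], stats::p.adjust(p, "BH")[c(1, 3)])
  expect_error(bhAdjust(c(0.5, 1.2)), "outside")
  ## BH is monotone in p and preserves gene order
  set.seed(2)
  q <- runif(50)
  expect_true(all(diff(bhAdjust(q)[order(q)]) >= -1e-15))
})

test_that("DE calls use an inclusive fold-change and strict FDR bound", {
  expect_identical(callDE(1.0, 0.005), "up_in_mated")
  expect_identical(callDE(2.5, 0.01), "ns")
  expect_identical(callDE(-3, 1e-6), "up_in_virgin")
  expect_identical(callDE(0.99, 1e-6), "ns")
  expect_identical(callDE(NA, 0.001), "ns")
})

test_that("replicate-averaged z-score clustering separates the two states", {
  set.seed(55)
  nBio <- 4; nTech <- 4
  sheet <- expand.grid(technical_run = 1:nTech, biological_replicate = 1:nBio,
                       group = c("virgin", "mated"), stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_b%d_t%d", sheet$group,
                             sheet$biological_replicate, sheet$technical_run)
  G <- 30
  base <- matrix(rnorm(G * nrow(sheet), 50, 5), G,
                 dimnames = list(sprintf("g%02d", 1:G), sheet$sample_id))
  base[, sheet$group == "mated"] <- base[, sheet$group == "mated"] + 40
  cl <- clusterDEGenes(base, rownames(base), sheet)
  ## z-rows are centred and unit-scale (population sd)
  expect_equal(unname(rowMeans(cl$z)), rep(0, G), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowMeans(cl$z^2))), rep(1, G), tolerance = 1e-9)
  ## the top split of the sample dendrogram is the group partition
  top <- stats::cutree(cl$sampleHclust, k = 2)
  grp <- sub("_[0-9]+$", "", names(top))
  expect_identical(length(unique(paste(top, grp))), 2L)
  ## technical runs were averaged: one column per biological replicate
  expect_identical(ncol(cl$z), 8L)
  expect_error(clusterDEGenes(base, "g01", sheet), "at least 2")
})

test_that("duplicated biological replicates cluster at distance zero", {
  sheet <- data.frame(sample_id = c("a", "b"), group = "virgin",
                      biological_replicate = 1:2, technical_run = 1)
  tpm <- matrix(c(1, 5, 1, 5), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  cl <- suppressWarnings(clusterDEGenes(tpm, c("g1", "g2"), sheet))
  expect_equal(cl$sampleHclust$height, 0)
})

test_that("the full DE analysis flags planted changes on a small experiment", {
  set.seed(10)
  n <- 16
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:(2 * n)),
                      group = rep(c("virgin", "mated"), each = n),
                      biological_replicate = rep(rep(1:4, each = 4), 2),
                      technical_run = rep(1:4, 2 * 4))
  G <- 400
  mu <- exp(runif(G, 4, 6))
  lfc <- c(rep(2, 20), rep(-2, 20), rep(0, G - 40))
  counts <- sapply(seq_len(2 * n), function(j) {
    m <- if (sheet$group[j] == "mated") mu * 2^lfc else mu
    rnbinom(G, mu = m, size = 1 / 0.05)
  })
  rownames(counts) <- sprintf("g%03d", 1:G)
  colnames(counts) <- sheet$sample_id
  se <- makeCountExperiment(counts, sheet, setNames(rep(1000, G), rownames(counts)))
  res <- runDEAnalysis(se)
  expect_identical(nrow(res), as.integer(G))
  planted <- res$flag[1:40]
  expect_gte(mean(planted == c(rep("up_in_mated", 20), rep("up_in_virgin", 20))),
             0.9)
  expect_lte(mean(res$flag[41:G] != "ns"), 0.02)
})

test_that("size factors and Wald estimates agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(404)
  n <- 8
  G <- 120
  groups <- rep(c("virgin", "mated"), each = n)
  mu <- exp(runif(G, 4, 7))
  lfc <- sample(c(-1.5, 0, 0, 1.5), G, replace = TRUE)
  depth <- runif(2 * n, 0.6, 1.6)
  counts <- sapply(seq_len(2 * n), function(j) {
    m <- depth[j] * mu * if (groups[j] == "mated") 2^lfc else 1
    rnbinom(G, mu = m, size = 1 / 0.1)
  })
  dimnames(counts) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(2 * n)))
  counts <- counts[rowSums(counts > 0) == ncol(counts), ]
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, data.frame(condition = factor(groups, c("virgin", "mated"))),
      ~condition)
    dds <- DESeq2::estimateSizeFactors(dds)
  })
  sf <- computeSizeFactors(counts)
  expect_equal(unname(sf), unname(DESeq2::sizeFactors(dds)), tolerance = 1e-8)
  ## same fixed dispersion on both sides isolates the Wald fit itself
  suppressMessages({
    DESeq2::dispersions(dds) <- rep(0.1, nrow(counts))
    dds <- DESeq2::nbinomWaldTest(dds)
    ref <- DESeq2::results(dds)
  })
  mine <- nbWaldTest(counts, sf, rep(0.1, nrow(counts)), groups)
  expect_equal(mine$log2FC, ref$log2FoldChange, tolerance = 1e-3)
  expect_equal(mine$se, ref$lfcSE, tolerance = 1e-2)
  expect_gt(cor(-log10(mine$pvalue), -log10(ref$pvalue)), 0.999)
})
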