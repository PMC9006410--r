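#' Transcripts-per-million normalisation
#'
#' Per sample: \code{rate_i = count_i / length_i};
#' \code{TPM_i = rate_i / sum(rate) * 1e6}, so non-degenerate columns sum
#' to one million. All-zero columns stay all-zero.
#'
#' @param counts Non-negative matrix (features x samples).
#' @param lengths Positive effective lengths in nt (spliced transcript
#'   length), one per feature.
#' @return Matrix of TPM values, same dimnames as \code{counts}.
#' @export
computeTpm <- function(counts, lengths) {
  lengths <- rep_len(lengths, nrow(counts))
  if (any(lengths <= 0)) stop("lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero column stays zero
  sweep(rate, 2, tot, "/") * 1e6
}

#' Prefilter weakly observed genes
#'
#' Keeps a gene iff it has nonzero counts in at least \code{minNonzero}
#' samples of at least one group (the "expressed somewhere" reading of a
#' zero-count prefilter).
#'
#' @param counts Count matrix.
#' @param groups Character/factor of group labels per sample (column).
#' @param minNonzero Minimum nonzero samples within a group (default 3).
#' @return Logical vector per gene (TRUE = kept), named by feature.
#' @export
prefilterGenes <- function(counts, groups, minNonzero = 3) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("two groups required")
  keep <- Reduce(`|`, lapply(unique(groups), function(g) {
    rowSums(counts[, groups == g, drop = FALSE] > 0) >= minNonzero
  }))
  stats::setNames(keep, rownames(counts))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of its
#' count to the gene's geometric mean across samples.
#'
#' @param counts Count matrix.
#' @return Named numeric of per-sample size factors.
#' @export
computeSizeFactors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene with nonzero counts in all samples; prefilter the matrix first")
  lc <- log(counts[ok, , drop = FALSE])
  gm <- rowMeans(lc)
  stats::setNames(exp(apply(lc - gm, 2, stats::median)), colnames(counts))
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per gene, on normalised counts: the within-group pooled variance and
#' overall mean give a raw NB dispersion
#' \code{alpha = max((s2 - mu) / mu^2, 1e-8)}; raw values are then shrunk
#' halfway (in log space) toward a log-linear mean-dispersion trend fitted
#' by least squares.
#'
#' @param counts Count matrix.
#' @param sizeFactors Per-sample size factors.
#' @param groups Group labels per sample.
#' @return Named numeric of per-gene dispersions (floored at 1e-8).
#' @export
estimateDispersion <- function(counts, sizeFactors, groups) {
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("need at least 2 samples per group")
  k <- sweep(counts, 2, sizeFactors, "/")
  mu <- rowMeans(k)
  ## pooled within-group variance (group effect removed)
  ss <- 0; df <- 0
  for (g in unique(groups)) {
    kg <- k[, groups == g, drop = FALSE]
    m <- rowMeans(kg)
    ss <- ss + rowSums((kg - m)^2)
    df <- df + ncol(kg) - 1L
  }
  s2 <- ss / df
  raw <- pmax((s2 - mu) / mu^2, 1e-8)
  fitIdx <- raw > 1e-8 & mu > 0
  alpha <- raw
  if (sum(fitIdx) >= 10) {
    fit <- stats::lm.fit(cbind(1, log(mu[fitIdx])), log(raw[fitIdx]))
    trend <- exp(cbind(1, log(pmax(mu, 1e-8))) %*% fit$coefficients)
    alpha <- exp((log(raw) + log(pmax(trend[, 1], 1e-8))) / 2)
  }
  stats::setNames(pmax(alpha, 1e-8), rownames(counts))
}

#' Negative-binomial Wald test for a two-group design
#'
#' Per gene, fits the NB log-link model
#' \code{log mu = log s_j + b0 + b1 * [mated]} by iteratively reweighted
#' least squares with the gene's dispersion held fixed, and tests
#' \code{b1 = 0} with a two-sided Wald statistic. The IRLS loop is
#' vectorised across genes (all genes share the design); convergence is
#' declared when the largest coefficient change drops below 1e-8, within
#' 100 iterations. Non-converged genes get \code{NA} p-values and are
#' flagged.
#'
#' @param counts Count matrix.
#' @param sizeFactors Per-sample size factors.
#' @param dispersions Per-gene NB dispersions.
#' @param groups Group labels per sample; the coefficient is
#'   \code{refGroup[2]} versus \code{refGroup[1]}.
#' @param refGroup Length-2 character giving (baseline, contrast); default
#'   \code{c("virgin", "mated")} so log2FC is mated vs virgin.
#' @return data.frame per gene: \code{baseMean}, \code{log2FC}, \code{se}
#'   (on the log2 scale), \code{stat}, \code{pvalue}, \code{converged}.
#' @export
nbWaldTest <- function(counts, sizeFactors, dispersions, groups,
                       refGroup = c("virgin", "mated")) {
  groups <- as.character(groups)
  stopifnot(all(groups %in% refGroup), length(sizeFactors) == ncol(counts))
  x <- as.numeric(groups == refGroup[2])
  G <- nrow(counts)
  s <- matrix(sizeFactors, G, ncol(counts), byrow = TRUE)
  k <- counts
  alpha <- rep_len(dispersions, G)
  ## initialise from normalised group means
  kn <- counts / s
  m0 <- rowMeans(kn[, x == 0, drop = FALSE]) + 0.1
  m1 <- rowMeans(kn[, x == 1, drop = FALSE]) + 0.1
  b0 <- log(m0)
  b1 <- log(m1) - log(m0)
  conv <- rep(FALSE, G)
  for (it in seq_len(100)) {
    eta <- outer(b0, rep(1, ncol(counts))) + outer(b1, x) + log(s)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - log(s)) + (k - mu) / mu
    S11 <- rowSums(w)
    S1x <- rowSums(w * rep(x, each = G))
    Sxx <- S1x  # x is 0/1 so x^2 = x
    S1z <- rowSums(w * z)
    Sxz <- rowSums(w * z * rep(x, each = G))
    det <- S11 * Sxx - S1x^2
    det[det <= 0] <- NA
    b1New <- (S11 * Sxz - S1x * S1z) / det
    b0New <- (S1z - S1x * b1New) / S11
    delta <- pmax(abs(b1New - b1), abs(b0New - b0))
    upd <- !conv & is.finite(delta)
    b0[upd] <- b0New[upd]; b1[upd] <- b1New[upd]
    newConv <- upd & delta < 1e-8
    conv <- conv | newConv
    if (all(conv | !is.finite(delta))) break
  }
  eta <- outer(b0, rep(1, ncol(counts))) + outer(b1, x) + log(s)
  mu <- exp(pmin(pmax(eta, -30), 30))
  w <- mu / (1 + alpha * mu)
  S11 <- rowSums(w); S1x <- rowSums(w * rep(x, each = G))
  det <- S11 * S1x - S1x^2
  seB1 <- sqrt(S11 / det)
  stat <- b1 / seB1
  p <- 2 * stats::pnorm(-abs(stat))
  p[!conv] <- NA
  data.frame(baseMean = rowMeans(counts / s),
             log2FC = b1 / log(2), se = seB1 / log(2),
             stat = stat, pvalue = p, converged = conv,
             row.names = rownames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with cumulative-minimum monotonisation (the standard
#' \code{p.adjust} procedure); NA p-values propagate.
#'
#' @param pvalues Numeric in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(pvalues) {
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression
#'
#' \code{up_in_mated} when \code{log2FC >= lfcMin} and \code{fdr < fdrMax};
#' \code{up_in_virgin} when \code{log2FC <= -lfcMin} and
#' \code{fdr < fdrMax}; \code{ns} otherwise. The fold-change bound is
#' inclusive and the FDR bound strict.
#'
#' @param log2FC,fdr Numeric vectors (NA treated as not significant).
#' @param lfcMin Minimum |log2FC| (default 1, i.e. two-fold).
#' @param fdrMax FDR threshold (default 0.01).
#' @return Character vector of flags.
#' @export
callDE <- function(log2FC, fdr, lfcMin = 1.0, fdrMax = 0.01) {
  sig <- !is.na(fdr) & !is.na(log2FC) & fdr < fdrMax
  ifelse(sig & log2FC >= lfcMin, "up_in_mated",
         ifelse(sig & log2FC <= -lfcMin, "up_in_virgin", "ns"))
}

#' Full differential-expression analysis of a count experiment
#'
#' Prefilter, median-of-ratios size factors, moment dispersion with trend
#' shrinkage, NB Wald test, BH adjustment and DE calls, with technical
#' runs treated as samples (the testing convention for a
#' biological x technical replicate design).
#'
#' @param se A \code{SummarizedExperiment} from [makeCountExperiment()].
#' @param lfcMin,fdrMax Call thresholds (defaults 1 and 0.01).
#' @param minNonzero Prefilter threshold (default 3).
#' @return data.frame of [nbWaldTest()] results plus \code{fdr},
#'   \code{flag} and \code{kept} (prefilter verdict) for every input gene.
#' @export
runDEAnalysis <- function(se, lfcMin = 1.0, fdrMax = 0.01, minNonzero = 3) {
  counts <- SummarizedExperiment::assay(se, "counts")
  groups <- SummarizedExperiment::colData(se)$group
  keep <- prefilterGenes(counts, groups, minNonzero)
  kc <- counts[keep, , drop = FALSE]
  sf <- computeSizeFactors(kc)
  disp <- estimateDispersion(kc, sf, groups)
  res <- nbWaldTest(kc, sf, disp, groups)
  res$fdr <- bhAdjust(res$pvalue)
  res$flag <- callDE(res$log2FC, res$fdr, lfcMin, fdrMax)
  out <- data.frame(baseMean = NA_real_, log2FC = NA_real_, se = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, converged = NA,
                    fdr = NA_real_, flag = "ns", kept = keep,
                    row.names = rownames(counts))
  out[rownames(res), colnames(res)] <- res
  out
}

#' Hierarchically cluster DE genes on replicate-averaged z-scores
#'
#' Technical runs are averaged per biological replicate; each gene's
#' averaged profile is z-transformed (population standard deviation);
#' genes and samples are clustered by average-linkage agglomeration on
#' Euclidean distances. Zero-variance genes get a zero z-row and are
#' flagged.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param deGenes Ids of the DE genes to cluster (at least 2).
#' @param sampleSheet data.frame with \code{sample_id}, \code{group},
#'   \code{biological_replicate} matching the TPM columns.
#' @return List with \code{z} (z-score matrix), \code{geneOrder},
#'   \code{sampleOrder}, \code{geneHclust}, \code{sampleHclust},
#'   \code{flatGenes} (zero-variance gene ids).
#' @export
clusterDEGenes <- function(tpm, deGenes, sampleSheet) {
  deGenes <- intersect(deGenes, rownames(tpm))
  if (length(deGenes) < 2) stop("need at least 2 DE genes to cluster")
  idx <- match(colnames(tpm), sampleSheet$sample_id)
  rep_id <- paste(sampleSheet$group[idx], sampleSheet$biological_replicate[idx],
                  sep = "_")
  reps <- unique(rep_id)
  avg <- vapply(reps, function(r)
    rowMeans(tpm[deGenes, rep_id == r, drop = FALSE]), numeric(length(deGenes)))
  rownames(avg) <- deGenes
  mu <- rowMeans(avg)
  sdp <- sqrt(rowMeans((avg - mu)^2))
  flat <- sdp == 0
  z <- (avg - mu) / ifelse(sdp == 0, 1, sdp)
  z[flat, ] <- 0
  gh <- stats::hclust(stats::dist(z), method = "average")
  sh <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, geneOrder = rownames(z)[gh$order],
       sampleOrder = colnames(z)[sh$order],
       geneHclust = gh, sampleHclust = sh,
       flatGenes = deGenes[flat])
}
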