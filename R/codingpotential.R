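## Fickett TESTCODE lookup tables (position and composition parameters of
## the published method). Thresholds are scanned in decreasing order; the
## probability of the first threshold not exceeding the observed value is
## weighted and summed over the eight base statistics.
.fickett <- local({
  posPara <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  cntPara <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  posProb <- rbind(
    A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
    C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
    G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.66, 0.71, 0.32, 0.23),
    T = c(0.51, 0.60, 0.69, 0.64, 0.62, 0.67, 0.58, 0.48, 0.39, 0.24))
  cntProb <- rbind(
    A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
    C = c(0.50, 0.63, 0.59, 0.50, 0.41, 0.30, 0.33, 0.29, 0.25, 0.26),
    G = c(0.21, 0.40, 0.58, 0.61, 0.42, 0.33, 0.30, 0.41, 0.29, 0.17),
    T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.34, 0.20, 0.21, 0.20, 0.32))
  posWeight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cntWeight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  list(posPara = posPara, cntPara = cntPara, posProb = posProb,
       cntProb = cntProb, posWeight = posWeight, cntWeight = cntWeight)
})

.asDnaChar <- function(seq) {
  if (is(seq, "XString") || is(seq, "XStringSet")) seq <- as.character(seq)
  toupper(chartr("Uu", "Tt", seq))
}

#' Find open reading frames on the sense strand
#'
#' Scans the three sense-strand frames; an ORF runs from an ATG to the
#' first in-frame stop codon (stop included). An ATG with no downstream
#' in-frame stop yields an ORF running to the last complete codon with
#' \code{has_stop = FALSE}. T and U are treated identically.
#'
#' @param seq A single DNA/RNA sequence (character or \code{XString}).
#' @return A data.frame with one row per ORF: \code{start}, \code{end}
#'   (1-based closed, on the transcript), \code{frame} (0/1/2),
#'   \code{has_start}, \code{has_stop}, \code{length_nt}; zero rows when
#'   no ATG exists.
#' @seealso [longestOrf()]
#' @export
findOrfs <- function(seq) {
  s <- .asDnaChar(seq)
  n <- nchar(s)
  out <- list()
  if (n >= 3) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (fr in 0:2) {
      if (fr + 3L > n) next
      starts <- seq.int(fr + 1L, n - 2L, by = 3L)
      cod <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
      atg <- which(cod == "ATG")
      if (!length(atg)) next
      stp <- which(cod %in% c("TAA", "TAG", "TGA"))
      nxt <- stp[findInterval(atg, stp) + 1L]  # first in-frame stop after the ATG
      hasStop <- !is.na(nxt)
      endCodon <- ifelse(hasStop, nxt, length(cod))
      out[[length(out) + 1L]] <- data.frame(
        start = starts[atg], end = starts[endCodon] + 2L, frame = fr,
        has_start = TRUE, has_stop = hasStop,
        length_nt = starts[endCodon] + 2L - starts[atg] + 1L)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      has_start = logical(0), has_stop = logical(0),
                      length_nt = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' @rdname findOrfs
#' @return \code{longestOrf}: the single longest ORF (ties broken by
#'   smallest start), or \code{NULL} when the sequence has none.
#' @export
longestOrf <- function(seq) {
  orfs <- findOrfs(seq)
  if (!nrow(orfs)) return(NULL)
  orfs[order(-orfs$length_nt, orfs$start)[1L], , drop = FALSE]
}

#' Fickett TESTCODE statistic
#'
#' Combines base-position periodicity (max positional count over the three
#' codon phases divided by min + 1) and base composition through the
#' published lookup tables; the eight converted values are weighted and
#' summed. Identical for T and U alphabets; ambiguous bases are ignored.
#'
#' @param seq A single DNA/RNA sequence of length at least 2.
#' @return The TESTCODE score (higher = more coding-like).
#' @export
fickettScore <- function(seq) {
  s <- .asDnaChar(seq)
  if (nchar(s) < 2) stop("sequence shorter than 2 nt")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  phase <- (seq_along(ch) - 1L) %% 3L
  tb <- .fickett
  score <- 0
  tot <- sum(ch %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(phase[ch == b] + 1L, nbins = 3L)
    posVal <- max(cnt) / (min(cnt) + 1)
    cntVal <- if (tot > 0) sum(cnt) / tot else 0
    iPos <- which(posVal >= tb$posPara)[1L]
    iCnt <- which(cntVal >= tb$cntPara)[1L]
    score <- score + tb$posProb[b, iPos] * tb$posWeight[[b]] +
      tb$cntProb[b, iCnt] * tb$cntWeight[[b]]
  }
  unname(score)
}

.hexamerNames <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

.hexamerCounts <- function(seqs, step) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(.asDnaChar(seqs))
  f <- Biostrings::oligonucleotideFrequency(seqs, width = 6, step = step)
  if (is.matrix(f)) colSums(f) else f
}

#' Build a hexamer usage-bias table
#'
#' Per-hexamer log-ratio \code{log(f_coding / f_noncoding)} with additive
#' smoothing, where coding frequencies come from in-frame (step 3)
#' hexamers of training ORF sequences and noncoding frequencies from
#' step-1 hexamers of noncoding sequences.
#'
#' @param codingSeqs ORF sequences of the coding training set
#'   (\code{DNAStringSet} or character, frame 0).
#' @param noncodingSeqs Noncoding training sequences.
#' @param pseudocount Additive smoothing constant (default 1).
#' @return Named numeric of length 4096.
#' @export
buildHexamerTable <- function(codingSeqs, noncodingSeqs, pseudocount = 1) {
  if (!length(codingSeqs) || !length(noncodingSeqs))
    stop("empty hexamer training set")
  cc <- .hexamerCounts(codingSeqs, step = 3)
  nc <- .hexamerCounts(noncodingSeqs, step = 1)
  nm <- .hexamerNames()
  cc <- cc[nm]; nc <- nc[nm]
  fc <- (cc + pseudocount) / sum(cc + pseudocount)
  fn <- (nc + pseudocount) / sum(nc + pseudocount)
  stats::setNames(log(fc / fn), nm)
}

#' Hexamer bias score of an ORF
#'
#' Mean log-ratio over the in-frame (step 3) hexamers of the sequence;
#' sequences shorter than 6 nt score 0. Hexamers containing ambiguous
#' bases are skipped.
#'
#' @param orfSeq A single sequence read in frame 0.
#' @param table Hexamer table from [buildHexamerTable()].
#' @return Mean log-ratio (0 when no scorable hexamer).
#' @export
hexamerScore <- function(orfSeq, table) {
  s <- .asDnaChar(orfSeq)
  if (nchar(s) < 6) return(0)
  starts <- seq.int(1L, nchar(s) - 5L, by = 3L)
  hx <- substring(s, starts, starts + 5L)
  v <- table[hx]
  v <- v[!is.na(v)]
  if (!length(v)) return(0) else mean(v)
}

#' Compute the four coding-potential features
#'
#' Per transcript: longest-ORF length (nt), ORF coverage (ORF length /
#' transcript length), Fickett TESTCODE score and hexamer bias score. The
#' hexamer score is computed on the longest ORF when one exists, otherwise
#' on the whole sequence in frame 0.
#'
#' @param seqs \code{DNAStringSet}/\code{RNAStringSet} or character vector,
#'   named by transcript.
#' @param hexTable Hexamer table from [buildHexamerTable()].
#' @return data.frame with columns \code{orf_length}, \code{orf_coverage},
#'   \code{fickett}, \code{hexamer}; rownames are transcript ids.
#' @export
codingFeatures <- function(seqs, hexTable) {
  sc <- .asDnaChar(seqs)
  res <- t(vapply(seq_along(sc), function(k) {
    s <- sc[[k]]
    orf <- longestOrf(s)
    if (is.null(orf)) {
      c(0, 0, fickettScore(s), hexamerScore(s, hexTable))
    } else {
      oseq <- substr(s, orf$start, orf$end)
      c(orf$length_nt, orf$length_nt / nchar(s), fickettScore(s),
        hexamerScore(oseq, hexTable))
    }
  }, numeric(4)))
  out <- as.data.frame(res)
  colnames(out) <- c("orf_length", "orf_coverage", "fickett", "hexamer")
  rownames(out) <- if (!is.null(names(seqs))) names(seqs) else NULL
  out
}

## IRLS logistic fit on a design matrix (intercept included in X).
.irlsLogistic <- function(X, y, ridge = 0, tol = 1e-8, maxit = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    A <- XtW %*% X + diag(ridge, p)
    if (ridge > 0) A[1, 1] <- A[1, 1] - ridge  # intercept unpenalised
    betaNew <- drop(solve(A, XtW %*% z))
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (!all(is.finite(beta))) break
    if (delta < tol) { conv <- TRUE; break }
  }
  list(beta = beta, converged = conv, iterations = it)
}

#' Train a CPAT-style coding-probability model
#'
#' Fits a logistic regression of the coding label on the four
#' [codingFeatures()] by iteratively reweighted least squares
#' (standardised internally; convergence when the largest coefficient
#' change drops below 1e-8, at most 100 iterations), then calibrates the
#' probability cutoff by accuracy maximisation ([calibrateCutoff()]).
#' Under perfect separation (diverging coefficients) the fit falls back to
#' a small ridge penalty (1e-4 on standardised features) and the model is
#' flagged.
#'
#' @param features data.frame from [codingFeatures()] (rows = training
#'   transcripts).
#' @param labels Logical (or 0/1): \code{TRUE} for coding.
#' @param hexTable The hexamer table the features were computed with
#'   (stored in the model for later scoring).
#' @return A [CodingModel-class].
#' @export
trainCodingModel <- function(features, labels, hexTable) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both labels must be present")
  if (length(y) < 20) stop("need at least 20 training transcripts")
  F <- as.matrix(features[, c("orf_length", "orf_coverage", "fickett", "hexamer")])
  ctr <- colMeans(F)
  scl <- apply(F, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(F, 2, ctr), 2, scl, "/")
  X <- cbind(1, Z)
  fit <- .irlsLogistic(X, y)
  separated <- !fit$converged || max(abs(fit$beta)) > 15 ||
    !all(is.finite(fit$beta))
  if (separated) fit <- .irlsLogistic(X, y, ridge = 1e-4)
  bz <- fit$beta
  slopes <- bz[-1] / scl
  intercept <- bz[1] - sum(bz[-1] * ctr / scl)
  prob <- 1 / (1 + exp(-drop(X %*% bz)))
  cal <- calibrateCutoff(prob, y == 1)
  new("CodingModel",
      coefficients = stats::setNames(c(intercept, slopes),
        c("(Intercept)", colnames(F))),
      center = ctr, scale = scl, hexamerTable = hexTable,
      cutoff = cal$cutoff, roc = cal$roc, auc = cal$auc,
      accuracy = cal$accuracy,
      metadata = list(n_coding = sum(y == 1), n_noncoding = sum(y == 0),
                      converged = fit$converged,
                      iterations = fit$iterations,
                      ridge_fallback = separated))
}

#' Predict coding probability
#'
#' @param object A [CodingModel-class].
#' @param features data.frame of [codingFeatures()] rows.
#' @return Numeric probabilities in \[0, 1\].
#' @rdname codingProbability
#' @export
setMethod("codingProbability", "CodingModel", function(object, features) {
  F <- as.matrix(features[, c("orf_length", "orf_coverage", "fickett", "hexamer")])
  eta <- drop(cbind(1, F) %*% object@coefficients)
  1 / (1 + exp(-eta))
})

setMethod("show", "CodingModel", function(object) {
  cat("CodingModel (logistic, 4 features)\n")
  cat("  cutoff:", format(object@cutoff, digits = 4),
      " accuracy:", format(object@accuracy, digits = 4),
      " AUC:", format(object@auc, digits = 4), "\n")
  cat("  training: coding =", object@metadata$n_coding,
      ", noncoding =", object@metadata$n_noncoding,
      if (isTRUE(object@metadata$ridge_fallback)) "(ridge fallback)" else "",
      "\n")
})

#' Calibrate a coding-probability cutoff by accuracy maximisation
#'
#' Every observed score is evaluated as a threshold under the rule
#' "coding if probability >= t"; the accuracy-maximising threshold is
#' returned (ties broken by the smallest threshold) together with ROC
#' points and the trapezoid AUC.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Logical, \code{TRUE} = coding.
#' @return List with \code{cutoff}, \code{accuracy}, \code{roc}
#'   (data.frame threshold/fpr/tpr), \code{auc}.
#' @export
calibrateCutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("both classes required for calibration")
  thr <- sort(unique(scores))
  nPos <- sum(labels); nNeg <- sum(!labels)
  stats <- vapply(thr, function(t) {
    call <- scores >= t
    c(acc = mean(call == labels),
      tpr = sum(call & labels) / nPos,
      fpr = sum(call & !labels) / nNeg)
  }, numeric(3))
  best <- which.max(stats["acc", ])  # first max = smallest threshold
  roc <- data.frame(threshold = c(-Inf, thr, Inf),
                    fpr = c(1, stats["fpr", ], 0),
                    tpr = c(1, stats["tpr", ], 0))
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]; yv <- roc$tpr[ord]
  auc <- sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
  list(cutoff = thr[best], accuracy = unname(stats["acc", best]),
       roc = roc, auc = auc)
}

#' ORF-size and homology discard step
#'
#' Candidates that already scored below the coding-probability cutoff are
#' discarded when they still contain a long complete ORF (peptide of at
#' least \code{maxOrfAa} codons, stop codon excluded; inclusive bound) or
#' appear in a precomputed homology-hit table.
#'
#' @param ids Candidate transcript ids.
#' @param seqs Sequences covering \code{ids}.
#' @param maxOrfAa Peptide-length threshold in codons (default 100).
#' @param hits Optional data.frame with a \code{transcript_id} column of
#'   homology hits (e.g. precomputed BLASTP results).
#' @return data.frame with \code{transcript_id}, \code{orf_aa},
#'   \code{homology_hit}, \code{verdict}, \code{reason}.
#' @export
orfHomologyFilter <- function(ids, seqs, maxOrfAa = 100, hits = NULL) {
  hitIds <- if (is.null(hits)) character(0) else as.character(hits$transcript_id)
  aa <- vapply(ids, function(id) {
    orfs <- findOrfs(seqs[[id]])
    orfs <- orfs[orfs$has_stop, , drop = FALSE]
    if (!nrow(orfs)) 0L else as.integer(max(orfs$length_nt) / 3L - 1L)
  }, integer(1))
  inHits <- ids %in% hitIds
  longOrf <- aa >= maxOrfAa
  reason <- ifelse(inHits, "homology", ifelse(longOrf, "orf", ""))
  data.frame(transcript_id = ids, orf_aa = aa, homology_hit = inHits,
             verdict = ifelse(longOrf | inHits, "discarded", "kept"),
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}
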