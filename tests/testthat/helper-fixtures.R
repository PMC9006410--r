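## Builders and independent oracles shared across the suite. The oracles
## deliberately use naive loop-based logic, independent of the package
## implementations they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## build a TranscriptSet from a list of exon coordinate matrices
## (2 columns: start, end; 1-based closed), one per transcript
makeTs <- function(exons, scaffold = "scf1", strand = "+", ids = NULL,
                   biotype = "novel", geneId = NULL) {
  n <- length(exons)
  strand <- rep_len(strand, n)
  scaffold <- rep_len(scaffold, n)
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(n))
  grl <- GRangesList(lapply(seq_len(n), function(k) {
    m <- exons[[k]]
    GRanges(scaffold[k], IRanges(m[, 1], m[, 2]),
            strand = chartr(".", "*", strand[k]))
  }))
  names(grl) <- ids
  TranscriptSet(grl, geneId = geneId, biotype = biotype)
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## ---- class-code oracle: all-pairs interval checks with plain arithmetic
oracleClassCode <- function(qExons, qStrand, refList, window = 2000) {
  ## qExons: matrix (start, end); refList: list of list(exons, strand)
  qs <- min(qExons[, 1]); qe <- max(qExons[, 2])
  evalStrand <- function(strandQ) {
    ## '='
    for (r in refList) {
      if (nrow(r$exons) == nrow(qExons) &&
          all(r$exons == qExons) &&
          (r$strand == strandQ || r$strand == "*" || strandQ == "*")) {
        return("=")
      }
    }
    ## 'o'
    for (r in refList) for (i in seq_len(nrow(r$exons)))
      for (j in seq_len(nrow(qExons)))
        if (qExons[j, 1] <= r$exons[i, 2] && qExons[j, 2] >= r$exons[i, 1])
          return("o")
    ## 'i'
    for (r in refList) {
      if (nrow(r$exons) < 2) next
      for (i in seq_len(nrow(r$exons) - 1)) {
        is <- r$exons[i, 2] + 1; ie <- r$exons[i + 1, 1] - 1
        if (qs >= is && qe <= ie) return("i")
      }
    }
    ## 'y'
    if (nrow(qExons) >= 2) {
      for (i in seq_len(nrow(qExons) - 1)) {
        is <- qExons[i, 2] + 1; ie <- qExons[i + 1, 1] - 1
        for (r in refList) {
          rs <- min(r$exons[, 1]); re <- max(r$exons[, 2])
          if (rs >= is && re <= ie) return("y")
        }
      }
    }
    ## 'p' (strand-aware downstream)
    for (r in refList) {
      rs <- min(r$exons[, 1]); re <- max(r$exons[, 2])
      if (r$strand == "+" && strandQ %in% c("+", "*")) {
        d <- qs - re
        if (d >= 1 && d <= window) return("p")
      }
      if (r$strand == "-" && strandQ %in% c("-", "*")) {
        d <- rs - qe
        if (d >= 1 && d <= window) return("p")
      }
    }
    "u"
  }
  evalStrand(qStrand)
}

## ---- brute-force ORF scanner: walk codons from every ATG
oracleOrfScan <- function(seq) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  res <- list()
  for (start in seq_len(max(n - 2, 0))) {
    if (paste0(ch[start], ch[start + 1], ch[start + 2]) != "ATG") next
    pos <- start
    end <- NA
    while (pos + 2 <= n) {
      cod <- paste0(ch[pos], ch[pos + 1], ch[pos + 2])
      if (cod %in% c("TAA", "TAG", "TGA")) { end <- pos + 2; break }
      pos <- pos + 3
    }
    hasStop <- !is.na(end)
    if (!hasStop) end <- start + 3 * ((n - start + 1) %/% 3) - 1
    res[[length(res) + 1]] <- data.frame(
      start = start, end = end, frame = (start - 1) %% 3,
      has_start = TRUE, has_stop = hasStop, length_nt = end - start + 1)
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      has_start = logical(0), has_stop = logical(0),
                      length_nt = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

## ---- hand-written Fickett table lookup (independent transcription)
oracleFickett <- function(seq) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  ch <- strsplit(seq, "")[[1]]
  positionProb <- list(
    A = c(0.36, 0.50, 0.54, 0.57, 0.58, 0.48, 0.52, 0.57, 0.55, 0.51),
    C = c(0.38, 0.51, 0.56, 0.60, 0.60, 0.52, 0.49, 0.55, 0.44, 0.29),
    G = c(0.23, 0.32, 0.71, 0.66, 0.62, 0.61, 0.65, 0.74, 0.67, 0.62),
    T = c(0.24, 0.39, 0.48, 0.58, 0.67, 0.62, 0.64, 0.69, 0.60, 0.51))
  contentProb <- list(
    A = c(0.19, 0.38, 0.45, 0.45, 0.48, 0.52, 0.58, 0.58, 0.55, 0.40),
    C = c(0.26, 0.25, 0.29, 0.33, 0.30, 0.41, 0.50, 0.59, 0.63, 0.50),
    G = c(0.17, 0.29, 0.41, 0.30, 0.33, 0.42, 0.61, 0.58, 0.40, 0.21),
    T = c(0.32, 0.20, 0.21, 0.20, 0.34, 0.48, 0.53, 0.56, 0.49, 0.30))
  positionWeight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  contentWeight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ## thresholds here ascend; the tables above are stored low-to-high
  posThresh <- c(0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)
  cntThresh <- c(0, 0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33)
  total <- sum(ch %in% c("A", "C", "G", "T"))
  s <- 0
  for (b in c("A", "C", "G", "T")) {
    c1 <- sum(ch[seq(1, length(ch), 3)] == b)
    c2 <- sum(ch[seq(2, length(ch), 3)] == b)
    c3 <- if (length(ch) >= 3) sum(ch[seq(3, length(ch), 3)] == b) else 0
    posVal <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    cntVal <- if (total > 0) (c1 + c2 + c3) / total else 0
    ip <- max(which(posVal >= posThresh))
    ic <- max(which(cntVal >= cntThresh))
    s <- s + positionProb[[b]][ip] * positionWeight[b] +
      contentProb[[b]][ic] * contentWeight[b]
  }
  unname(s)
}

## ---- naive Spearman: explicit average ranks + Pearson formula
oracleSpearman <- function(x, y) {
  ## average rank = (number smaller) + (1 + number equal) / 2
  avgRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## ---- triplex oracle: per-diagonal enumeration of every window with
## vectorised constraint checks (independent of the C++ scan kernel)
oracleTriplex <- function(rna, dna, params) {
  rna <- toupper(chartr("U", "T", rna)); dna <- toupper(dna)
  m <- nchar(rna); n <- nchar(dna)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  pairOk <- function(r, d, motif) {
    if (motif == "pyrimidine") (r == "T" & d == "A") | (r == "C" & d == "G")
    else if (motif == "purine") (r == "A" & d == "A") | (r == "G" & d == "G")
    else (r == "T" & d == "A") | (r == "G" & d == "G")
  }
  minLen <- params$minLength
  maxErr <- params$maxErrorRate
  minG <- params$minGuanine
  runLen <- params$maxConsecutive + 1
  minMatch <- ceiling(minLen * (1 - maxErr))
  rows <- list()
  seen <- character(0)
  purvs <- list("+" = strsplit(dna, "")[[1]],
                "-" = strsplit(rc(dna), "")[[1]])
  qvs <- list(parallel = strsplit(rna, "")[[1]],
              antiparallel = rev(strsplit(rna, "")[[1]]))
  ## precompute, per (i, j) cell of the m x n alignment matrix, its
  ## diagonal membership (column-major order is increasing i in a diagonal)
  cellI <- rep(seq_len(m), n)
  cellJ <- rep(seq_len(n), each = m)
  byDiag <- split(seq_len(m * n), cellJ - cellI)
  byDiag <- byDiag[vapply(byDiag, length, 1L) >= minLen]
  jByDiag <- lapply(byDiag, function(ix) cellJ[ix])
  for (motif in params$motifs) {
    orients <- switch(motif, pyrimidine = "parallel", purine = "antiparallel",
                      mixed = c("parallel", "antiparallel"))
    for (strand in c("+", "-")) {
      purv <- purvs[[strand]]
      purG <- purv == "G"; purGA <- purv %in% c("G", "A")
      for (ori in orients) {
        qv <- qvs[[ori]]
        Mv <- pairOk(qv[cellI], purv[cellJ], motif)
        for (dn in names(byDiag)) {
          d <- as.integer(dn)
          ix <- byDiag[[dn]]
          L <- length(ix)
          i0 <- max(1, 1 - d)
          match <- Mv[ix]
          if (sum(match) < minMatch) next
          jj <- jByDiag[[dn]]
          ## start of each run of (maxConsecutive+1) errors
          runIdx <- integer(0)
          if (L >= runLen) {
            cs <- c(0, cumsum(!match))
            a <- 1:(L - runLen + 1)
            runIdx <- a[(cs[a + runLen] - cs[a]) == runLen]
          }
          ## quick reject: the widest stretch free of a full error run
          ## bounds every candidate window
          if (length(runIdx)) {
            widest <- max(runIdx[1] + runLen - 2,
                          L - runIdx[length(runIdx)],
                          if (length(runIdx) > 1) max(diff(runIdx)) + runLen - 2 else 0)
            if (widest < minLen) next
          }
          nextRun <- if (length(runIdx)) {
            k <- findInterval((1:L) - 1L, runIdx) + 1L
            k[k > length(runIdx)] <- length(runIdx) + 1L
            c(c(runIdx, Inf)[k], Inf)
          } else rep(Inf, L + 1)
          ok <- function(s, e) {
            if (s < 1 || e > L) return(FALSE)
            len <- e - s + 1
            if (len < minLen) return(FALSE)
            if ((err[e + 1] - err[s]) / len >= maxErr) return(FALSE)
            if (nextRun[s] + runLen - 1 <= e) return(FALSE)
            if ((gg[e + 1] - gg[s]) / len < minG) return(FALSE)
            TRUE
          }
          ## windows containing a full error run can never validate, so the
          ## enumeration over e may stop just before the next run ends
          eCapAll <- nextRun[1:L] + runLen - 2
          eCapAll[eCapAll > L] <- L
          sCand <- which(eCapAll - (1:L) + 1 >= minLen)
          if (!length(sCand)) next
          err <- cumsum(c(0, !match))
          gg <- cumsum(c(0, purG[jj]))
          for (s in sCand) {
          eCap <- eCapAll[s]
          for (e in (s + minLen - 1):eCap) {
            if (!ok(s, e)) next
            if (ok(s - 1, e) || ok(s, e + 1)) next
            qs <- i0 + s - 1; qe <- i0 + e - 1
            ps <- qs + d; pe <- qe + d
            if (ori == "parallel") { tfs <- qs; tfe <- qe }
            else { tfs <- m - qe + 1; tfe <- m - qs + 1 }
            if (strand == "+") { tts <- ps; tte <- pe }
            else { tts <- n - pe + 1; tte <- n - ps + 1 }
            key <- paste(tfs, tfe, tts, tte, motif, ori)
            if (key %in% seen) next
            seen <- c(seen, key)
            rows[[length(rows) + 1]] <- data.frame(
              tfo_start = tfs, tfo_end = tfe, tts_start = tts, tts_end = tte,
              tts_strand = strand, motif = motif, orientation = ori,
              length = e - s + 1, errors = err[e + 1] - err[s],
              stringsAsFactors = FALSE)
          }
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(tfo_start = integer(0), tfo_end = integer(0),
                      tts_start = integer(0), tts_end = integer(0),
                      tts_strand = character(0), motif = character(0),
                      orientation = character(0), length = integer(0),
                      errors = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$tts_start, out$tts_end, out$tfo_start, out$motif,
            out$orientation), , drop = FALSE]
}

## canonical key set for comparing triplex outputs
triplexKeys <- function(df) {
  sort(paste(df$tfo_start, df$tfo_end, df$tts_start, df$tts_end,
             df$motif, df$orientation))
}
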