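#' Assign gffcompare-style class codes to assembled transcripts
#'
#' Compares each query transcript against a reference annotation and
#' assigns a single-letter relationship code, by precedence:
#' \describe{
#'   \item{\code{=}}{exon chain identical to a reference transcript
#'     (strand-compatible);}
#'   \item{\code{o}}{any query exon overlaps any reference exon (either
#'     strand) without an exact match;}
#'   \item{\code{i}}{the query lies entirely within a single reference
#'     intron;}
#'   \item{\code{y}}{a full reference transcript lies within a query
#'     intron;}
#'   \item{\code{p}}{no exonic overlap and the query starts within
#'     \code{runonWindow} bp downstream of a reference transcript end
#'     (strand-aware), i.e. a possible run-on fragment;}
#'   \item{\code{u}}{none of the above (intergenic/unknown).}
#' }
#' Exonic overlap always disqualifies a candidate (precedence of \code{o}
#' over \code{i}/\code{y}/\code{p}), so only transcripts from non-coding
#' loci survive the downstream filter. Codes \code{i} and \code{y} ignore
#' strand by default (\code{strandAwareIntron = FALSE}); unstranded
#' queries are evaluated on both strands and receive the most
#' "overlapping" code under the precedence above.
#'
#' @param query,reference [TranscriptSet-class] objects sharing a scaffold
#'   namespace.
#' @param runonWindow Downstream window for code \code{p}, in bp
#'   (default 2000, the gffcompare convention).
#' @param strandAwareIntron If \code{TRUE}, codes \code{i}/\code{y}
#'   require matching strand.
#' @return Named character vector of class codes, one per query.
#' @export
assignClassCode <- function(query, reference, runonWindow = 2000,
                            strandAwareIntron = FALSE) {
  stopifnot(is(query, "TranscriptSet"), is(reference, "TranscriptSet"))
  if (any(lengths(txExons(query)) == 0L)) stop("query transcript with no exons")
  nq <- length(query)
  if (nq == 0L) return(stats::setNames(character(0), character(0)))
  qex <- txExons(query); rex <- txExons(reference)
  qspan <- txSpan(query)
  qstr <- as.character(GenomicRanges::strand(qspan))
  qstr[qstr == "."] <- "*"
  codes <- rep("u", nq)

  if (length(reference)) {
    rspan <- txSpan(reference)
    rstr <- as.character(GenomicRanges::strand(rspan))
    rflat <- unlist(rex, use.names = FALSE)
    qflat <- unlist(qex, use.names = FALSE)
    qidx <- rep(seq_len(nq), lengths(qex))

    ## '=': identical exon chain, strand-compatible
    sig <- function(grl) {
      scf <- as.character(GenomicRanges::seqnames(unlist(range(grl), use.names = FALSE)))
      coo <- vapply(seq_along(grl), function(k)
        paste(GenomicRanges::start(grl[[k]]), GenomicRanges::end(grl[[k]]),
              sep = "-", collapse = ","), character(1))
      paste(scf, coo, sep = ":")
    }
    qsig <- sig(qex); rsig <- sig(rex)
    eqchain <- qsig %in% rsig &
      vapply(seq_len(nq), function(k) {
        hit <- which(rsig == qsig[k])
        any(rstr[hit] == qstr[k] | qstr[k] == "*" | rstr[hit] == "*")
      }, logical(1))

    ## 'o': exonic overlap on either strand
    ohit <- GenomicRanges::countOverlaps(qflat, rflat, ignore.strand = TRUE) > 0L
    isO <- as.logical(tapply(ohit, qidx, any))

    ## reference introns / query introns
    intronsOf <- function(grl, spans, strands) {
      multi <- which(lengths(grl) > 1L)
      if (!length(multi)) return(list(gr = GRanges(), of = integer(0)))
      g <- lapply(multi, function(k) {
        e <- grl[[k]]
        GRanges(GenomicRanges::seqnames(e)[1],
                IRanges(GenomicRanges::end(e)[-length(e)] + 1L,
                        GenomicRanges::start(e)[-1L] - 1L),
                strand = strands[k])
      })
      gr <- unlist(GRangesList(unname(g)), use.names = FALSE)
      list(gr = gr, of = rep(unname(multi), lengths(grl)[multi] - 1L))
    }
    rin <- intronsOf(rex, rspan, rstr)
    isI <- rep(FALSE, nq)
    if (length(rin$gr)) {
      isI <- IRanges::overlapsAny(qspan, rin$gr, type = "within",
                                        ignore.strand = !strandAwareIntron)
    }
    qin <- intronsOf(qex, qspan, qstr)
    isY <- rep(FALSE, nq)
    if (length(qin$gr)) {
      hits <- GenomicRanges::findOverlaps(rspan, qin$gr, type = "within",
                                          ignore.strand = !strandAwareIntron)
      isY[unique(qin$of[S4Vectors::subjectHits(hits)])] <- TRUE
    }

    ## 'p': query start within runonWindow downstream of a reference end
    qs <- GenomicRanges::start(qspan); qe <- GenomicRanges::end(qspan)
    rs <- GenomicRanges::start(rspan); re <- GenomicRanges::end(rspan)
    qscf <- as.character(GenomicRanges::seqnames(qspan))
    rscf <- as.character(GenomicRanges::seqnames(rspan))
    winPlus <- GRanges(rscf[rstr == "+"],
                       IRanges(re[rstr == "+"] + 1L, re[rstr == "+"] + runonWindow))
    winMinus <- GRanges(rscf[rstr == "-"],
                        IRanges(pmax(1L, rs[rstr == "-"] - runonWindow),
                                rs[rstr == "-"] - 1L))
    ptPlus <- GRanges(qscf, IRanges(qs, qs))
    ptMinus <- GRanges(qscf, IRanges(qe, qe))
    isP <- (qstr %in% c("+", "*") &
              IRanges::overlapsAny(ptPlus, winPlus, ignore.strand = TRUE)) |
           (qstr %in% c("-", "*") &
              IRanges::overlapsAny(ptMinus, winMinus, ignore.strand = TRUE))

    codes[isP] <- "p"
    codes[isY] <- "y"
    codes[isI] <- "i"
    codes[isO] <- "o"
    codes[eqchain] <- "="
  }
  stats::setNames(codes, txIds(query))
}

#' Filter assembled transcripts to lncRNA candidates
#'
#' Applies the candidate filter: keep class codes \code{i}, \code{y},
#' \code{p}, \code{u} with spliced (exonic) length of at least
#' \code{minLength} nt (inclusive). Each transcript receives a verdict and
#' a machine-readable rejection reason (\code{"class_code"} before
#' \code{"length"} when both fail).
#'
#' @param novel,reference [TranscriptSet-class] objects.
#' @param minLength Minimum spliced length in nt (default 200).
#' @param keptCodes Class codes retained (default \code{i,y,p,u}).
#' @param ... Passed to [assignClassCode()].
#' @return A data.frame with columns \code{transcript_id},
#'   \code{class_code}, \code{spliced_length}, \code{verdict}
#'   (\code{"kept"}/\code{"rejected"}), \code{reason}.
#' @export
filterCandidates <- function(novel, reference, minLength = 200,
                             keptCodes = c("i", "y", "p", "u"), ...) {
  code <- assignClassCode(novel, reference, ...)
  len <- splicedLength(novel)
  okCode <- code %in% keptCodes
  okLen <- len >= minLength
  reason <- ifelse(!okCode, "class_code", ifelse(!okLen, "length", ""))
  data.frame(transcript_id = txIds(novel),
             class_code = unname(code),
             spliced_length = unname(len),
             verdict = ifelse(okCode & okLen, "kept", "rejected"),
             reason = unname(reason),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Characterise transcript groups and compare them pairwise
#'
#' Summarises spliced length, exon count, GC content and (optionally)
#' expression on the log10(TPM + 1) scale per named transcript group, and
#' compares every metric between group pairs with a two-sided
#' Mann-Whitney U test (exact enumeration when both groups have at most 8
#' members and no ties, tie-corrected normal approximation otherwise).
#'
#' @param groups Named list of [TranscriptSet-class] objects (e.g. known
#'   mRNA, known lncRNA, novel lncRNA).
#' @param seqs \code{DNAStringSet} of spliced transcript sequences covering
#'   all group members.
#' @param tpm Optional named numeric of mean TPM per transcript.
#' @return List with \code{values} (per-transcript metric table),
#'   \code{summary} (per-group medians) and \code{tests} (pairwise
#'   Mann-Whitney p-values per metric).
#' @export
characterizeTranscripts <- function(groups, seqs, tpm = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty transcript group")
  vals <- do.call(rbind, lapply(names(groups), function(g) {
    ts <- groups[[g]]
    ids <- txIds(ts)
    miss <- setdiff(ids, names(seqs))
    if (length(miss)) stop("sequences missing for: ", paste(miss, collapse = ", "))
    data.frame(group = g, transcript_id = ids,
               length = unname(splicedLength(ts)),
               exons = unname(lengths(txExons(ts))),
               gc = gcContent(seqs[ids]),
               log10_tpm1 = if (is.null(tpm)) NA_real_ else
                 log10(unname(tpm[ids]) + 1),
               stringsAsFactors = FALSE)
  }))
  metrics <- c("length", "exons", "gc",
               if (!is.null(tpm)) "log10_tpm1")
  summ <- do.call(rbind, lapply(split(vals, vals$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               t(vapply(metrics, function(m) stats::median(d[[m]]), 0)))
  }))
  gn <- names(groups)
  pairs <- if (length(gn) > 1) utils::combn(gn, 2, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- vals[[m]][vals$group == pr[1]]
      y <- vals[[m]][vals$group == pr[2]]
      data.frame(metric = m, group1 = pr[1], group2 = pr[2],
                 p = mannWhitneyP(x, y), stringsAsFactors = FALSE)
    }))
  }))
  list(values = vals, summary = summ, tests = tests)
}

#' Two-sided Mann-Whitney U p-value
#'
#' Exact when both samples have at most 8 observations and no ties;
#' otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param x,y Numeric vectors.
#' @return Two-sided p-value.
#' @export
mannWhitneyP <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
  if (is.na(p)) 1 else p  # fully tied samples: no separation
}
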