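#' Triplex search parameters
#'
#' Constraints for RNA:DNA:DNA triplex prediction: minimum TFO/TTS length,
#' strict maximum error rate, maximum run of consecutive errors, minimum
#' guanine fraction of the TTS purine strand (inclusive), and the searched
#' Hoogsteen motifs. Defaults follow the convention of constraining the
#' error rate below 20\%, at most 3 consecutive errors, a minimum pair
#' length of 15 nt and at least 20\% guanine in the target site.
#'
#' @param minLength Minimum match length in nt (default 15).
#' @param maxErrorRate Strict upper bound on errors/length (default 0.20;
#'   a 15-mer thus admits at most 2 errors).
#' @param maxConsecutive Maximum run of consecutive errors (default 3).
#' @param minGuanine Minimum guanine fraction of the TTS purine strand,
#'   inclusive (default 0.20).
#' @param motifs Subset of \code{c("pyrimidine", "purine", "mixed")}.
#' @return A validated list of class \code{"TriplexParams"}.
#' @export
triplexParams <- function(minLength = 15, maxErrorRate = 0.20,
                          maxConsecutive = 3, minGuanine = 0.20,
                          motifs = c("pyrimidine", "purine", "mixed")) {
  stopifnot(minLength >= 5, maxErrorRate > 0, maxErrorRate < 1,
            maxConsecutive >= 0, minGuanine >= 0, minGuanine <= 1)
  motifs <- match.arg(motifs, several.ok = TRUE)
  structure(list(minLength = as.integer(minLength),
                 maxErrorRate = maxErrorRate,
                 maxConsecutive = as.integer(maxConsecutive),
                 minGuanine = minGuanine, motifs = motifs),
            class = "TriplexParams")
}

#' Hoogsteen triplet match rule
#'
#' Pyrimidine motif accepts U.A and C.G; purine motif A.A and G.G; mixed
#' motif U.A and G.G. T on the RNA side is treated as U; N never matches.
#'
#' @param tfoBase Single RNA base of the third strand.
#' @param purineBase Single DNA base on the purine strand of the duplex.
#' @param motif One of \code{"pyrimidine"}, \code{"purine"},
#'   \code{"mixed"}.
#' @return Logical.
#' @export
hoogsteenMatch <- function(tfoBase, purineBase, motif) {
  motif <- match.arg(motif, c("pyrimidine", "purine", "mixed"))
  r <- chartr("Uu", "Tt", toupper(tfoBase))
  d <- toupper(purineBase)
  switch(motif,
    pyrimidine = (r == "T" & d == "A") | (r == "C" & d == "G"),
    purine     = (r == "A" & d == "A") | (r == "G" & d == "G"),
    mixed      = (r == "T" & d == "A") | (r == "G" & d == "G"))
}

#' Predict RNA:DNA:DNA triplexes between an RNA and a duplex DNA
#'
#' Both DNA strands are considered as candidate purine strands. The
#' pyrimidine motif is searched parallel (TFO 5'-3' along the purine
#' strand 5'-3'), the purine motif antiparallel, and the mixed motif in
#' both orientations. Every reported match is a maximal ungapped segment:
#' it satisfies all constraints in \code{params} and cannot be extended by
#' one base on either side without violating one. Matches are
#' deduplicated by (TFO, TTS, motif, orientation). Coordinates are 1-based
#' closed; \code{tts_strand} names the purine strand relative to the input
#' DNA.
#'
#' @param rna RNA sequence (character, \code{RNAString} or
#'   \code{DNAString}; T and U equivalent).
#' @param dna Duplex DNA sequence (given as its plus strand).
#' @param params A [triplexParams()] object.
#' @return data.frame of matches: \code{tfo_start}, \code{tfo_end},
#'   \code{tts_start}, \code{tts_end}, \code{tts_strand}, \code{motif},
#'   \code{orientation}, \code{length}, \code{errors}, \code{score}
#'   (length - errors), \code{guanine_fraction}, \code{ga_fraction},
#'   \code{error_positions} (comma-separated 1-based offsets within the
#'   match).
#' @export
findTriplexes <- function(rna, dna, params = triplexParams()) {
  stopifnot(inherits(params, "TriplexParams"))
  rna <- as.character(rna); dna <- as.character(dna)
  if (nchar(rna) < params$minLength)
    return(.emptyTriplexDf())
  res <- .triplexScanCpp(rna, dna, params$minLength, params$maxErrorRate,
                         params$maxConsecutive, params$minGuanine,
                         params$motifs)
  if (!length(res) || !nrow(as.data.frame(res))) return(.emptyTriplexDf())
  df <- as.data.frame(res, stringsAsFactors = FALSE)
  df <- df[order(df$tts_start, df$tts_end, df$tfo_start, df$motif,
                 df$orientation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.emptyTriplexDf <- function() {
  data.frame(tfo_start = integer(0), tfo_end = integer(0),
             tts_start = integer(0), tts_end = integer(0),
             tts_strand = character(0), motif = character(0),
             orientation = character(0), length = integer(0),
             errors = integer(0), score = numeric(0),
             guanine_fraction = numeric(0), ga_fraction = numeric(0),
             error_positions = character(0), stringsAsFactors = FALSE)
}

#' Scan a lncRNA against a genomic locus
#'
#' Runs [findTriplexes()] on a genome slice, lifts TTS coordinates to
#' genome space and annotates each match with the transcript feature it
#' falls in (exon k, intron k, or flank) for a chosen gene.
#'
#' @param lncrnaSeq The lncRNA sequence.
#' @param genome \code{DNAStringSet} named by scaffold.
#' @param locus \code{GRanges} of length 1: the scanned genomic window.
#' @param annotation [TranscriptSet-class] used for feature annotation.
#' @param geneId Gene whose exon/intron structure labels the matches
#'   (first transcript of the gene is used).
#' @param params A [triplexParams()] object.
#' @return data.frame of matches with additional \code{scaffold},
#'   \code{tts_genomic_start}, \code{tts_genomic_end}, \code{feature}
#'   columns.
#' @export
scanLncrnaVsLocus <- function(lncrnaSeq, genome, locus, annotation, geneId,
                              params = triplexParams()) {
  stopifnot(is(locus, "GRanges"), length(locus) == 1)
  scf <- as.character(GenomicRanges::seqnames(locus))
  if (!scf %in% names(genome)) stop("locus scaffold absent from genome")
  if (GenomicRanges::start(locus) < 1 ||
      GenomicRanges::end(locus) > length(genome[[scf]]))
    stop("locus outside scaffold bounds")
  dna <- Biostrings::subseq(genome[[scf]], GenomicRanges::start(locus),
                            GenomicRanges::end(locus))
  df <- findTriplexes(lncrnaSeq, dna, params)
  off <- GenomicRanges::start(locus) - 1L
  df$scaffold <- rep(scf, nrow(df))
  df$tts_genomic_start <- df$tts_start + off
  df$tts_genomic_end <- df$tts_end + off
  df$feature <- rep(NA_character_, nrow(df))
  tx <- annotation[txIds(annotation)[geneIds(annotation) == geneId][1]]
  if (length(tx) == 1 && nrow(df)) {
    ex <- txExons(tx)[[1]]
    neg <- as.character(GenomicRanges::strand(ex))[1] == "-"
    ne <- length(ex)
    exn <- if (neg) rev(seq_len(ne)) else seq_len(ne)  # transcript order
    mid <- floor((df$tts_genomic_start + df$tts_genomic_end) / 2)
    for (k in seq_len(nrow(df))) {
      p <- mid[k]
      hitEx <- which(p >= GenomicRanges::start(ex) & p <= GenomicRanges::end(ex))
      if (length(hitEx)) { df$feature[k] <- paste0("exon", exn[hitEx[1]]); next }
      if (ne > 1) {
        ints <- cbind(GenomicRanges::end(ex)[-ne] + 1L,
                      GenomicRanges::start(ex)[-1L] - 1L)
        hitIn <- which(p >= ints[, 1] & p <= ints[, 2])
        if (length(hitIn)) {
          intn <- if (neg) rev(seq_len(ne - 1L)) else seq_len(ne - 1L)
          df$feature[k] <- paste0("intron", intn[hitIn[1]])
          next
        }
      }
      df$feature[k] <- "flank"
    }
  }
  df
}

#' Cluster triplex target sites
#'
#' Merges TTS intervals that overlap or lie within \code{gap} bp of each
#' other, counts member matches per cluster, and reports the GA fraction
#' of the merged interval on its majority purine strand. Clusters with at
#' least \code{minMembers} members are flagged high-frequency.
#'
#' @param matches data.frame from [findTriplexes()] or
#'   [scanLncrnaVsLocus()] (genomic coordinates used when present).
#' @param dna The sequence the TTS coordinates refer to (\code{DNAString}
#'   or single-sequence \code{DNAStringSet}); for genomic matches, the
#'   scaffold sequence.
#' @param gap Maximum gap between merged intervals (default 0 = merge
#'   overlapping or adjacent).
#' @param minMembers Member count for the \code{high_frequency} flag
#'   (default 10).
#' @return data.frame with \code{start}, \code{end}, \code{n_members},
#'   \code{ga_fraction}, \code{high_frequency}.
#' @export
clusterTts <- function(matches, dna, gap = 0, minMembers = 10) {
  if (is(dna, "DNAStringSet")) dna <- dna[[1]]
  if (!nrow(matches))
    return(data.frame(start = integer(0), end = integer(0),
                      n_members = integer(0), ga_fraction = numeric(0),
                      high_frequency = logical(0)))
  st <- if ("tts_genomic_start" %in% colnames(matches))
    matches$tts_genomic_start else matches$tts_start
  en <- if ("tts_genomic_end" %in% colnames(matches))
    matches$tts_genomic_end else matches$tts_end
  ir <- IRanges(st, en)
  red <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  ov <- IRanges::findOverlaps(ir, red)
  memb <- tabulate(S4Vectors::subjectHits(ov), nbins = length(red))
  ga <- vapply(seq_along(red), function(k) {
    s <- Biostrings::subseq(dna, IRanges::start(red)[k], IRanges::end(red)[k])
    idx <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]
    strands <- matches$tts_strand[idx]
    if (sum(strands == "-") > sum(strands == "+"))
      s <- Biostrings::reverseComplement(s)
    f <- Biostrings::alphabetFrequency(s)
    unname((f[["G"]] + f[["A"]]) / length(s))
  }, numeric(1))
  data.frame(start = IRanges::start(red), end = IRanges::end(red),
             n_members = memb, ga_fraction = ga,
             high_frequency = memb >= minMembers)
}
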