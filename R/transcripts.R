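#' Accessors for TranscriptSet objects
#'
#' @param x A [TranscriptSet-class].
#' @return \code{txIds}, \code{geneIds}, \code{txBiotype}: character
#'   vectors; \code{txExons}: the exon \code{GRangesList}; \code{txSpan}:
#'   a \code{GRanges} of genomic spans (one per transcript);
#'   \code{splicedLength}: integer exonic (spliced) lengths in nt.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txIds", "TranscriptSet", function(x) names(x@exons))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) {
  stats::setNames(x@txData$gene_id, names(x@exons))
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txBiotype", "TranscriptSet", function(x) {
  stats::setNames(x@txData$biotype, names(x@exons))
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txSpan", "TranscriptSet", function(x) {
  unlist(range(x@exons), use.names = TRUE)
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("splicedLength", "TranscriptSet", function(x) {
  stats::setNames(sum(GenomicRanges::width(x@exons)), names(x@exons))
})

#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @export
setMethod("names", "TranscriptSet", function(x) names(x@exons))

#' @param i Transcript ids, indices or a logical vector.
#' @rdname TranscriptSet-accessors
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  initialize(x, exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' Combine TranscriptSet objects
#' @param x,... TranscriptSet objects with disjoint transcript ids.
#' @export
setMethod("c", "TranscriptSet", function(x, ...) {
  args <- c(list(x), list(...))
  ex <- do.call(c, lapply(args, txExons))
  td <- do.call(rbind, lapply(args, function(a) a@txData))
  new("TranscriptSet", exons = ex, txData = td)
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
  if (length(object)) {
    bt <- table(object@txData$biotype)
    cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
    cat("  scaffolds:", length(unique(as.character(GenomicRanges::seqnames(
      unlist(range(object@exons), use.names = FALSE))))), "\n")
    cat("  spliced length: median",
        stats::median(splicedLength(object)), "nt\n")
  }
})

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in transcript order; minus-strand
#' transcripts are reverse-complemented. Unstranded ("." ) transcripts are
#' returned in plus-strand orientation.
#'
#' @param ts A [TranscriptSet-class].
#' @param genome A \link[Biostrings]{DNAStringSet} named by scaffold.
#' @return A \code{DNAStringSet} named by transcript id.
#' @export
extractTxSeqs <- function(ts, genome) {
  stopifnot(is(ts, "TranscriptSet"), is(genome, "DNAStringSet"))
  ex <- txExons(ts)
  scf <- as.character(unlist(GenomicRanges::seqnames(ex), use.names = FALSE))
  flat <- unlist(ex, use.names = FALSE)
  miss <- setdiff(unique(scf), names(genome))
  if (length(miss))
    stop("scaffolds absent from genome: ", paste(miss, collapse = ", "))
  pieces <- Biostrings::subseq(genome[scf],
                               start = GenomicRanges::start(flat),
                               end = GenomicRanges::end(flat))
  grp <- rep(seq_along(ex), lengths(ex))
  seqs <- Biostrings::DNAStringSet(vapply(
    split(as.character(pieces), grp),
    paste0, character(1), collapse = ""))
  names(seqs) <- names(ex)
  neg <- as.character(GenomicRanges::strand(
    unlist(range(ex), use.names = FALSE))) == "-"
  if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  seqs
}

#' GC content of sequences, ignoring N
#'
#' Fraction of G+C among unambiguous bases; N (and other ambiguity codes)
#' are excluded from both numerator and denominator.
#'
#' @param seqs A \code{DNAStringSet}, \code{RNAStringSet} or character
#'   vector.
#' @return Numeric vector in \[0, 1\] (NaN for sequences with no
#'   unambiguous base).
#' @examples
#' gcContent(c("GGCC", "ATAT", "ACGNT"))
#' @export
gcContent <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(chartr("Uu", "Tt", seqs))
  f <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  unname(rowSums(f[, c("C", "G"), drop = FALSE]) / acgt)
}
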