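#' Read transcript models from a GTF file
#'
#' Parses exon features (1-based closed coordinates, GTF convention) and
#' groups them into a [TranscriptSet-class] by \code{transcript_id}. Lines
#' are validated before import; a malformed line (wrong column count,
#' non-numeric or inverted coordinates) raises an error naming the line
#' number.
#'
#' @param path Path to a tab-delimited GTF file.
#' @param biotype Default biotype for transcripts lacking a
#'   \code{transcript_biotype} attribute.
#' @return A [TranscriptSet-class].
#' @seealso [writeGtf()]
#' @export
readGtf <- function(path, biotype = "novel") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  for (ln in which(keep)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                   ln, length(f)))
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en))
      stop(sprintf("GTF parse error at line %d: non-numeric coordinates", ln))
    if (en < st)
      stop(sprintf("GTF parse error at line %d: end (%d) < start (%d)", ln, en, st))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(TranscriptSet(GRangesList()))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF exon features must carry a transcript_id attribute")
  gid <- if (is.null(gr$gene_id)) gr$transcript_id else gr$gene_id
  bt <- if (is.null(gr$transcript_biotype)) rep(biotype, length(gr)) else
    ifelse(is.na(gr$transcript_biotype), biotype, gr$transcript_biotype)
  ids <- unique(gr$transcript_id)
  first <- match(ids, gr$transcript_id)
  gr2 <- GRanges(GenomicRanges::seqnames(gr), IRanges::ranges(gr),
                 strand = GenomicRanges::strand(gr), transcript_id = gr$transcript_id)
  TranscriptSet(gr2, geneId = gid[first], biotype = bt[first])
}

#' Write transcript models to a GTF file
#'
#' Emits one exon feature per exon (sorted by start within transcript) with
#' \code{transcript_id}, \code{gene_id} and \code{transcript_biotype}
#' attributes, such that [readGtf()] reproduces the input.
#'
#' @param ts A [TranscriptSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGtf <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  ex <- txExons(ts)
  flat <- unlist(ex, use.names = FALSE)
  n <- rep(seq_along(ex), lengths(ex))
  if (length(flat)) {
    flat$source <- "lncScout"
    flat$type <- "exon"
    flat$transcript_id <- names(ex)[n]
    flat$gene_id <- unname(geneIds(ts))[n]
    flat$transcript_biotype <- unname(txBiotype(ts))[n]
  }
  rtracklayer::export(flat, path, format = "gtf")
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around \pkg{Biostrings} readers that enforce unique,
#' non-empty records.
#'
#' @param path FASTA path.
#' @param type \code{"DNA"} or \code{"RNA"}.
#' @return \code{readFasta}: a \code{DNAStringSet} or \code{RNAStringSet}.
#' @export
readFasta <- function(path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  seqs <- if (type == "DNA") Biostrings::readDNAStringSet(path)
          else Biostrings::readRNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L)) stop("empty FASTA record")
  seqs
}

#' @param seqs An \code{XStringSet} named by identifier.
#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence identifiers")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Rows are genes/transcripts, columns are samples (header row of sample
#' ids, first column feature ids). Counts must be non-negative integers.
#'
#' @param path TSV path.
#' @return An integer matrix with feature rownames and sample colnames.
#' @export
readCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate feature identifiers in count table")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @param counts Matrix written with feature ids in a leading
#'   \code{feature_id} column.
#' @rdname readCountsTsv
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns \code{sample_id}, \code{group} (one of
#' \code{"virgin"}, \code{"mated"}), \code{biological_replicate},
#' \code{technical_run}.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
readSampleSheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "biological_replicate", "technical_run")
  miss <- setdiff(need, colnames(ss))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(ss$group), c("virgin", "mated"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ss
}

#' Write genomic intervals as BED6
#'
#' Emits the standard 0-based half-open BED convention (a 1-based closed
#' \code{GRanges} range \[s, e\] prints as start \code{s-1}, end \code{e}).
#'
#' @param gr A \code{GRanges}; optional \code{name} and \code{score}
#'   metadata columns populate BED fields 4-5.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Assemble counts, sample sheet and lengths into a SummarizedExperiment
#'
#' @param counts Integer matrix (features x samples).
#' @param sampleSheet data.frame as from [readSampleSheet()]; rows are
#'   matched to count columns by \code{sample_id}.
#' @param lengths Named numeric of effective (spliced) lengths in nt.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}.
#' @export
makeCountExperiment <- function(counts, sampleSheet, lengths) {
  idx <- match(colnames(counts), sampleSheet$sample_id)
  if (anyNA(idx)) stop("count columns missing from sample sheet")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop("every feature needs a positive length")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sampleSheet[idx, , drop = FALSE],
                        row.names = colnames(counts)),
    rowData = DataFrame(length = unname(lengths), row.names = rownames(counts)))
}
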