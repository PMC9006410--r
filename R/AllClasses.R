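#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
#' @useDynLib lncScout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TranscriptSet: exon-structured transcript models
#'
#' A container for stranded, exon-structured transcript models on genomic
#' scaffolds: the unit that is classified against a reference annotation,
#' scored for coding potential and quantified. Exons are held as a
#' \link[GenomicRanges]{GRangesList} (one element per transcript, 1-based
#' closed coordinates, sorted by start) and per-transcript metadata
#' (gene id, biotype) as a \link[S4Vectors]{DataFrame}.
#'
#' @slot exons A \code{GRangesList}, one element per transcript, named by
#'   transcript id. Each element lies on a single scaffold and strand and
#'   its ranges are sorted and separated by at least 1 bp (introns).
#' @slot txData A \code{DataFrame} with columns \code{gene_id} and
#'   \code{biotype} (one of \code{"mRNA"}, \code{"lncRNA"},
#'   \code{"novel"}), one row per transcript.
#'
#' @seealso [TranscriptSet()], [readGtf()], [splicedLength()]
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("txData must have one row per transcript")
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("transcript ids must be unique and non-empty")
  if (!identical(rownames(td), names(ex)))
    return("txData rownames must match exon list names")
  if (!all(c("gene_id", "biotype") %in% colnames(td)))
    return("txData must carry gene_id and biotype columns")
  if (!all(td$biotype %in% c("mRNA", "lncRNA", "novel")))
    return("biotype must be one of mRNA, lncRNA, novel")
  if (length(ex)) {
    nseq <- lengths(unique(S4Vectors::runValue(GenomicRanges::seqnames(ex))))
    nstr <- lengths(unique(S4Vectors::runValue(GenomicRanges::strand(ex))))
    if (any(nseq != 1L) || any(nstr != 1L))
      return("each transcript must lie on one scaffold and one strand")
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    for (k in which(lengths(ex) > 1L)) {
      s <- st[[k]]; e <- en[[k]]
      if (is.unsorted(s, strictly = TRUE))
        return(sprintf("exons of '%s' are not sorted by start", names(ex)[k]))
      if (any(s[-1L] <= e[-length(e)] + 1L))
        return(sprintf("exons of '%s' overlap or touch (no intron)", names(ex)[k]))
    }
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons A \code{GRangesList} of exons, named by transcript id, or a
#'   \code{GRanges} with a \code{transcript_id} metadata column. Exons are
#'   sorted by start within each transcript.
#' @param geneId Character vector of gene ids, one per transcript (recycled
#'   from transcript ids when missing).
#' @param biotype Character vector of biotypes (\code{"mRNA"},
#'   \code{"lncRNA"} or \code{"novel"}), one per transcript or length 1.
#' @return A [TranscriptSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("scf1", IRanges::IRanges(c(1, 201), c(100, 300)),
#'   strand = "+", transcript_id = "t1")
#' ts <- TranscriptSet(gr, geneId = "g1", biotype = "mRNA")
#' splicedLength(ts)
#' @export
TranscriptSet <- function(exons, geneId = NULL, biotype = "novel") {
  if (is(exons, "GRanges")) {
    if (is.null(exons$transcript_id))
      stop("GRanges input needs a transcript_id metadata column")
    ids <- unique(exons$transcript_id)
    exons <- GenomicRanges::split(exons, factor(exons$transcript_id, levels = ids))
  }
  exons <- methods::as(exons, "GRangesList")
  mcols(exons@unlistData) <- NULL
  exons <- GenomicRanges::sort(exons)
  n <- length(exons)
  if (n == 0L) names(exons) <- character(0)
  if (is.null(geneId)) geneId <- names(exons)
  geneId <- rep_len(as.character(geneId), n)
  biotype <- rep_len(as.character(biotype), n)
  td <- DataFrame(gene_id = geneId, biotype = biotype,
                  row.names = names(exons))
  new("TranscriptSet", exons = exons, txData = td)
}

#' CodingModel: a CPAT-style coding-probability model
#'
#' Logistic-regression model over four sequence features (ORF length, ORF
#' coverage, Fickett TESTCODE score, hexamer usage bias) with its hexamer
#' log-ratio table, calibrated probability cutoff and ROC.
#'
#' @slot coefficients Named numeric of length 5 (intercept + 4 features),
#'   on the original feature scale.
#' @slot center,scale Numeric length-4 standardisation constants used
#'   during fitting.
#' @slot hexamerTable Named numeric of length 4096: per-hexamer
#'   log(f_coding / f_noncoding) with additive smoothing.
#' @slot cutoff Calibrated coding-probability cutoff in (0, 1).
#' @slot roc A data.frame of ROC points (threshold, fpr, tpr).
#' @slot auc Trapezoid area under the ROC curve.
#' @slot accuracy Accuracy at the calibrated cutoff.
#' @slot metadata List of training metadata (n per class, convergence,
#'   ridge fallback flag).
#' @exportClass CodingModel
setClass("CodingModel",
  representation(coefficients = "numeric", center = "numeric",
                 scale = "numeric", hexamerTable = "numeric",
                 cutoff = "numeric", roc = "data.frame", auc = "numeric",
                 accuracy = "numeric", metadata = "list"))

setValidity("CodingModel", function(object) {
  if (length(object@coefficients) != 5L)
    return("coefficients must be intercept + 4 features")
  if (length(object@hexamerTable) != 4096L ||
      any(!is.finite(object@hexamerTable)))
    return("hexamerTable must hold 4096 finite log-ratios")
  if (length(object@cutoff) == 1L &&
      (object@cutoff <= 0 || object@cutoff >= 1))
    return("cutoff must lie in (0, 1)")
  TRUE
})
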