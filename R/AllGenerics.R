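#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txBiotype", function(x) standardGeneric("txBiotype"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txSpan", function(x) standardGeneric("txSpan"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("splicedLength", function(x) standardGeneric("splicedLength"))

#' @rdname codingProbability
#' @export
setGeneric("codingProbability", function(object, ...)
  standardGeneric("codingProbability"))
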