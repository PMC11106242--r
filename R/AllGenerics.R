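#' Accessors for the core classes
#'
#' Small accessor generics so slots are never touched directly by user code.
#'
#' @param x a \linkS4class{TranscriptModel}, \linkS4class{AnalysisWindow} or
#'   \linkS4class{FoldResult}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @rdname accessors
#' @export
setGeneric("windowSeq", function(x) standardGeneric("windowSeq"))
#' @rdname accessors
#' @export
setGeneric("utrLen", function(x) standardGeneric("utrLen"))
#' @rdname accessors
#' @export
setGeneric("cdsLen", function(x) standardGeneric("cdsLen"))
#' @rdname accessors
#' @export
setGeneric("frameAnchor", function(x) standardGeneric("frameAnchor"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))
#' @rdname accessors
#' @export
setGeneric("foldEngine", function(x) standardGeneric("foldEngine"))

#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("transcriptId", "AnalysisWindow", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("geneSymbol", "TranscriptModel", function(x) x@geneSymbol)
#' @rdname accessors
#' @export
setMethod("geneSymbol", "AnalysisWindow", function(x) x@geneSymbol)
#' @rdname accessors
#' @export
setMethod("windowSeq", "AnalysisWindow", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("utrLen", "AnalysisWindow", function(x) x@utrLen)
#' @rdname accessors
#' @export
setMethod("cdsLen", "AnalysisWindow", function(x) x@cdsLen)
#' @rdname accessors
#' @export
setMethod("frameAnchor", "AnalysisWindow", function(x) x@frameAnchor)
#' @rdname accessors
#' @export
setMethod("dotBracket", "FoldResult", function(x) x@db)
#' @rdname accessors
#' @export
setMethod("mfe", "FoldResult", function(x) x@mfe)
#' @rdname accessors
#' @export
setMethod("foldEngine", "FoldResult", function(x) x@engine)
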