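#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib m6adscan, .registration = TRUE
NULL

#' TranscriptModel: exon/CDS block structure of one mRNA
#'
#' Strand-aware model of a single transcript on a genome.  All coordinates
#' are 1-based inclusive genomic positions (the native convention of
#' \pkg{IRanges}, which backs every interval operation in the package);
#' BED12 half-open input and VCF positions are converted on read so a single
#' convention holds internally.
#'
#' @slot transcriptId character transcript identifier (e.g. RefSeq accession).
#' @slot geneSymbol character gene symbol (may equal the transcript id when
#'   the BED name field carries no symbol).
#' @slot chrom character chromosome/sequence name.
#' @slot strand character, \code{"+"} or \code{"-"}.
#' @slot txStart,txEnd integer transcript span (1-based inclusive).
#' @slot cdsStart,cdsEnd integer CDS span (1-based inclusive).
#' @slot blocks \link[IRanges]{IRanges} of exon blocks, non-overlapping and
#'   sorted in ascending genomic order.
#' @export
setClass("TranscriptModel",
    representation(
        transcriptId = "character",
        geneSymbol   = "character",
        chrom        = "character",
        strand       = "character",
        txStart      = "integer",
        txEnd        = "integer",
        cdsStart     = "integer",
        cdsEnd       = "integer",
        blocks       = "IRanges"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character()
    b <- object@blocks
    if (length(b) < 1L) msg <- c(msg, "transcript must have at least one exon block")
    if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
    if (length(b) > 1L) {
        st <- IRanges::start(b)
        if (is.unsorted(st, strictly = TRUE))
            msg <- c(msg, "blocks must be sorted ascending by genomic coordinate")
        if (any(IRanges::start(b)[-1L] <= IRanges::end(b)[-length(b)]))
            msg <- c(msg, "blocks must be non-overlapping")
    }
    if (object@cdsStart > object@cdsEnd)
        msg <- c(msg, "empty CDS (non-coding transcripts are rejected on read)")
    if (object@cdsStart < object@txStart || object@cdsEnd > object@txEnd)
        msg <- c(msg, "CDS outside transcript bounds")
    if (any(IRanges::start(b) < object@txStart) || any(IRanges::end(b) > object@txEnd))
        msg <- c(msg, "exon block outside transcript bounds")
    if (length(msg) == 0L) {
        cds <- IRanges::IRanges(object@cdsStart, object@cdsEnd)
        if (sum(IRanges::width(IRanges::intersect(b, cds))) == 0L)
            msg <- c(msg, "no exon block intersects the CDS")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel", object@transcriptId,
        sprintf("(%s)", object@geneSymbol), "\n")
    cat("  ", object@chrom, ":", object@txStart, "-", object@txEnd,
        " (", object@strand, "), ", length(object@blocks), " exon(s), CDS ",
        object@cdsStart, "-", object@cdsEnd, "\n", sep = "")
})

#' AnalysisWindow: spliced CDS-terminal + 3'UTR analysis window
#'
#' The (at most 250 nt) spliced sequence analysed per transcript: the tail of
#' the coding sequence restricted to the last two CDS exons, ending at and
#' including the stop codon, followed by the first (at most 100) nt of the
#' spliced 3'UTR.  \code{w2g} maps every window position (1-based, transcript
#' orientation) to its 1-based genomic position; for minus-strand transcripts
#' the window sequence is the reverse complement of the genomic text.
#'
#' @slot transcriptId,geneSymbol,chrom,strand transcript annotation carried over.
#' @slot seq character DNA sequence of the window (uppercase ACGT/N).
#' @slot utrLen integer number of 3'UTR nucleotides included (<= 100 by default).
#' @slot cdsLen integer number of CDS nucleotides included; window length is
#'   \code{cdsLen + utrLen}.
#' @slot frameAnchor integer 1-based window index of the first base of the
#'   stop codon (\code{cdsLen - 2}).
#' @slot w2g integer vector, genomic position of each window position.
#' @slot upstreamContext character 0-2 nt of spliced CDS immediately upstream
#'   of the window, kept so the leading partial codon can be classified.
#' @export
setClass("AnalysisWindow",
    representation(
        transcriptId    = "character",
        geneSymbol      = "character",
        chrom           = "character",
        strand          = "character",
        seq             = "character",
        utrLen          = "integer",
        cdsLen          = "integer",
        frameAnchor     = "integer",
        w2g             = "integer",
        upstreamContext = "character"
    )
)

setValidity("AnalysisWindow", function(object) {
    msg <- character()
    n <- nchar(object@seq)
    if (n != object@cdsLen + object@utrLen)
        msg <- c(msg, "window length must equal cdsLen + utrLen")
    if (object@cdsLen < 3L) msg <- c(msg, "cdsLen must cover at least the stop codon")
    if (object@frameAnchor != object@cdsLen - 2L)
        msg <- c(msg, "frameAnchor must be cdsLen - 2 (1-based)")
    if (length(object@w2g) != n)
        msg <- c(msg, "w2g must have one genomic position per window base")
    if (anyDuplicated(object@w2g)) msg <- c(msg, "w2g positions must be unique")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AnalysisWindow", function(object) {
    cat("AnalysisWindow for", object@transcriptId,
        sprintf("(%s, %s strand)", object@chrom, object@strand), "\n")
    cat("  length:", nchar(object@seq), "nt =", object@cdsLen, "CDS +",
        object@utrLen, "UTR; stop codon at", object@frameAnchor, "\n")
    s <- object@seq
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat("  seq:", s, "\n")
})

#' FoldResult: one minimum-free-energy secondary structure
#'
#' Dot-bracket structure and MFE for one sequence, with the engine and
#' constraint set that produced it.  Sequences are rendered as RNA on output
#' even though the package works in a DNA alphabet internally.
#'
#' @slot seq character the folded sequence, rendered as RNA.
#' @slot db character dot-bracket string, same length as \code{seq}.
#' @slot mfe numeric minimum free energy, kcal/mol.
#' @slot engine character engine tag ("builtin" or "vienna").
#' @slot noLonelyPairs logical whether isolated base pairs were forbidden.
#' @export
setClass("FoldResult",
    representation(
        seq           = "character",
        db            = "character",
        mfe           = "numeric",
        engine        = "character",
        noLonelyPairs = "logical"
    )
)

setValidity("FoldResult", function(object) {
    if (nchar(object@seq) != nchar(object@db))
        return("sequence and dot-bracket must have equal length")
    if (grepl("[^().]", object@db))
        return("dot-bracket may only contain '(', ')' and '.'")
    TRUE
})

setMethod("show", "FoldResult", function(object) {
    cat(object@seq, "\n")
    cat(sprintf("%s (%6.2f)\n", object@db, object@mfe))
    cat("engine:", object@engine,
        if (object@noLonelyPairs) "[no lonely pairs]" else "", "\n")
})
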