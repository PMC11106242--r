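# Apply a variant to the analysis window, classify its coding consequence
# and enforce the rejection filters (nonsense / frameshift / stop-loss /
# DRACH-overlapping variants are dropped).

#' Place a variant into an analysis window
#'
#' Maps the genomic REF span into window coordinates (reverse-complementing
#' the alleles for minus-strand transcripts), verifies the REF allele
#' against the window sequence and rejects spans that cross an exon
#' junction (their window image is not contiguous).
#'
#' @param window an \linkS4class{AnalysisWindow}.
#' @param pos 1-based genomic position of the variant (VCF convention).
#' @param ref,alt VCF alleles (genomic strand).
#' @return list with wStart, wEnd (1-based inclusive window span of the
#'   replaced bases), refW, altW (window-strand alleles).
#' @export
variantInWindow <- function(window, pos, ref, alt) {
    ref <- normalizeDna(ref); alt <- normalizeDna(alt)
    gSpan <- seq.int(pos, pos + nchar(ref) - 1L)
    w <- genomicToWindow(window, gSpan)
    if (all(is.na(w))) reject("variant span outside window exonic span")
    if (anyNA(w)) reject("junction-spanning allele")
    w <- sort(w)
    if (length(w) > 1L && any(diff(w) != 1L))
        reject("junction-spanning allele")
    if (window@strand == "-") { refW <- revComp(ref); altW <- revComp(alt) }
    else { refW <- ref; altW <- alt }
    have <- substr(window@seq, w[1L], w[length(w)])
    if (have != refW)
        stop("allele/genome disagreement at ", window@chrom, ":", pos,
             " (expected ", refW, ", window has ", have, ")")
    list(wStart = w[1L], wEnd = w[length(w)], refW = refW, altW = altW)
}

#' Apply a placed variant to the window sequence
#'
#' @param window an \linkS4class{AnalysisWindow}.
#' @param viw placement from \code{\link{variantInWindow}}.
#' @return the alternate window sequence (length changes only for indels).
#' @export
applyVariant <- function(window, viw) {
    paste0(substr(window@seq, 1L, viw$wStart - 1L), viw$altW,
           substr(window@seq, viw$wEnd + 1L, nchar(window@seq)))
}

#' Classify the coding consequence of a placed variant
#'
#' Classes: \code{utr} (replaced span entirely 3' of the stop codon),
#' \code{frameshift} (indel with length difference not divisible by 3),
#' \code{stop_loss} (the terminal stop codon becomes a sense codon),
#' \code{nonsense} (a new in-frame stop appears upstream of the terminal
#' stop), \code{synonymous} / \code{missense} for substitutions, and
#' \code{inframe_indel}.  The reading frame is anchored at the stop codon;
#' the window's 0-2 nt of upstream CDS context completes the leading
#' partial codon so every CDS position is classifiable.
#'
#' @param window an \linkS4class{AnalysisWindow}.
#' @param viw placement from \code{\link{variantInWindow}}.
#' @return character class label.
#' @export
classifyVariant <- function(window, viw) {
    cdsN <- window@cdsLen
    if (viw$wStart > cdsN) return("utr")
    lenDiff <- nchar(viw$altW) - nchar(viw$refW)
    if (lenDiff %% 3L != 0L) return("frameshift")

    # full in-frame CDS text = upstream context + window CDS portion,
    # trimmed at the 5' end to a codon boundary (frame anchored at the stop)
    ctx <- window@upstreamContext
    refCds <- paste0(ctx, substr(window@seq, 1L, cdsN))
    altWin <- applyVariant(window, viw)
    altCds <- paste0(ctx, substr(altWin, 1L, cdsN + lenDiff))
    trim <- nchar(refCds) %% 3L
    refCds <- substr(refCds, trim + 1L, nchar(refCds))
    altCds <- substr(altCds, trim + 1L, nchar(altCds))

    refAA <- translateDna(refCds)
    altAA <- translateDna(altCds)
    refStop <- substr(refAA, nchar(refAA), nchar(refAA)) == "*"
    altStop <- substr(altAA, nchar(altAA), nchar(altAA)) == "*"
    altBody <- substr(altAA, 1L, nchar(altAA) - 1L)
    if (refStop && !altStop) return("stop_loss")
    if (grepl("*", altBody, fixed = TRUE)) return("nonsense")
    if (lenDiff != 0L) return("inframe_indel")
    if (refAA == altAA) "synonymous" else "missense"
}

#' Keep/reject decision for a placed, classified variant
#'
#' Rejects variants whose class is nonsense, frameshift or stop_loss, and
#' variants whose replaced span overlaps any DRACH motif in the
#' \emph{reference} window (the filter is evaluated against the reference
#' motif set only; a motif gained in the alternate sequence at the variant
#' site does not reject the record but is flagged in the output).
#'
#' @param viw placement from \code{\link{variantInWindow}}.
#' @param class class label from \code{\link{classifyVariant}}.
#' @param drachRef \code{\link{scanDrach}} table of the reference window.
#' @return list(keep = logical, reason = character or NA).
#' @export
filterVariant <- function(viw, class, drachRef) {
    if (class %in% c("nonsense", "frameshift", "stop_loss"))
        return(list(keep = FALSE, reason = class))
    if (variantOverlapsDrach(drachRef, viw$wStart, viw$wEnd))
        return(list(keep = FALSE, reason = "overlaps DRACH"))
    list(keep = TRUE, reason = NA_character_)
}
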