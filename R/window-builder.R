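# Build the <=250-nt spliced analysis window (CDS tail restricted to the
# last two coding exons + head of the 3'UTR) and the genomic<->window maps.

#' CDS exon intervals of a transcript
#'
#' Exon blocks intersected with the CDS span, in ascending genomic order;
#' empty intersections are dropped.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @return an \link[IRanges]{IRanges} of CDS exon intervals.
#' @export
cdsExons <- function(tx) {
    cds <- IRanges::IRanges(tx@cdsStart, tx@cdsEnd)
    out <- IRanges::intersect(tx@blocks, cds)
    if (length(out) == 0L)
        stop("no exon block overlaps the CDS of ", tx@transcriptId)
    out
}

# Per-base genomic positions of a set of intervals, in transcript
# orientation (reversed for minus strand).
splicedPositions <- function(ranges, strand) {
    pos <- unlist(lapply(seq_along(ranges), function(i)
        seq.int(IRanges::start(ranges)[i], IRanges::end(ranges)[i])),
        use.names = FALSE)
    if (strand == "-") rev(pos) else pos
}

# Transcript-orientation base at each genomic position (complemented on
# the minus strand).
basesAt <- function(genome, chrom, positions, strand) {
    if (!chrom %in% names(genome))
        stop("chromosome not in genome: ", chrom)
    chromSeq <- genome[[chrom]]
    if (any(positions < 1L) || any(positions > length(chromSeq)))
        stop("position outside chromosome ", chrom)
    txt <- vapply(positions, function(p)
        as.character(Biostrings::subseq(chromSeq, p, p)), character(1L))
    if (strand == "-") txt <- unname(REVCOMP[txt])
    paste(txt, collapse = "")
}

#' Build the analysis window for one transcript
#'
#' The window is the tail of the spliced coding sequence restricted to the
#' last two CDS exons, ending at and including the stop codon, followed by
#' the first \code{min(utrCap, available)} nt of the spliced 3'UTR.  The
#' CDS tail takes whatever the UTR leaves free up to the total cap:
#' \code{cdsLen = min(maxWindow - utrLen, length of last two CDS exons)}.
#'
#' Transcripts whose CDS does not end in a stop codon are rejected (classed
#' condition, reason \code{"no terminal stop"}), as are windows shorter
#' than 9 nt.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param genome a \link[Biostrings]{DNAStringSet} covering the transcript.
#' @param maxWindow total window cap in nt (default 250).
#' @param utrCap 3'UTR cap in nt (default 100).
#' @return an \linkS4class{AnalysisWindow}.
#' @export
buildWindow <- function(tx, genome, maxWindow = 250L, utrCap = 100L) {
    stopifnot(maxWindow > 0L, utrCap >= 0L, utrCap <= maxWindow)
    cds <- cdsExons(tx)
    cdsPos <- splicedPositions(cds, tx@strand)          # transcript orientation
    cdsSeq <- basesAt(genome, tx@chrom, cdsPos, tx@strand)

    if (nchar(cdsSeq) < 3L || !isStopCodon(substr(cdsSeq, nchar(cdsSeq) - 2L,
                                                  nchar(cdsSeq)))) {
        warning("transcript ", tx@transcriptId, " rejected: no terminal stop")
        reject("no terminal stop")
    }

    # 3'UTR: exonic positions downstream of the CDS in transcript orientation
    utrRanges <- if (tx@strand == "+") {
        IRanges::intersect(tx@blocks, IRanges::IRanges(tx@cdsEnd + 1L, tx@txEnd))
    } else {
        IRanges::intersect(tx@blocks, IRanges::IRanges(tx@txStart, tx@cdsStart - 1L))
    }
    utrPos <- if (length(utrRanges)) splicedPositions(utrRanges, tx@strand)
              else integer()
    utrLen <- min(utrCap, length(utrPos))
    utrPos <- utrPos[seq_len(utrLen)]

    # CDS tail limited to the last two CDS exons (transcript orientation)
    nExon <- length(cds)
    lastTwo <- if (tx@strand == "+") {
        cds[max(1L, nExon - 1L):nExon]
    } else {
        cds[1L:min(2L, nExon)]
    }
    lastTwoLen <- sum(IRanges::width(lastTwo))
    if (lastTwoLen < 9L) reject("CDS tail shorter than 9 nt")
    cdsLen <- min(maxWindow - utrLen, lastTwoLen, length(cdsPos))
    if (cdsLen < 3L) reject("window shorter than minimal CDS tail")
    keep <- seq.int(length(cdsPos) - cdsLen + 1L, length(cdsPos))
    wPos <- c(cdsPos[keep], utrPos)
    if (length(wPos) < 9L) reject("window shorter than 9 nt")

    wSeq <- paste0(substr(cdsSeq, length(cdsPos) - cdsLen + 1L, length(cdsPos)),
                   if (utrLen) basesAt(genome, tx@chrom, utrPos, tx@strand)
                   else "")
    upstream <- substr(cdsSeq, max(1L, length(cdsPos) - cdsLen - 1L),
                       length(cdsPos) - cdsLen)

    new("AnalysisWindow",
        transcriptId = tx@transcriptId, geneSymbol = tx@geneSymbol,
        chrom = tx@chrom, strand = tx@strand,
        seq = wSeq, utrLen = as.integer(utrLen), cdsLen = as.integer(cdsLen),
        frameAnchor = as.integer(cdsLen - 2L),
        w2g = as.integer(wPos), upstreamContext = upstream)
}

#' Map a genomic position into the window
#'
#' @param window an \linkS4class{AnalysisWindow}.
#' @param gpos 1-based genomic position(s).
#' @return 1-based window index, or NA for intronic/outside positions.
#' @export
genomicToWindow <- function(window, gpos) {
    match(as.integer(gpos), window@w2g)
}

#' Map a window index back to its genomic position
#'
#' @param window an \linkS4class{AnalysisWindow}.
#' @param widx 1-based window index/indices.
#' @return 1-based genomic position(s).
#' @export
windowToGenomic <- function(window, widx) {
    window@w2g[widx]
}

#' Spliced sequence of a transcript's terminal exons
#'
#' Concatenated sequence (transcript orientation) of the last \code{n}
#' exons, including any UTR they contain -- the region scanned in the
#' terminal-exon DRACH census.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param n number of terminal exons (default 2).
#' @return character sequence.
#' @export
lastExonsSeq <- function(tx, genome, n = 2L) {
    blocks <- tx@blocks
    nEx <- length(blocks)
    keep <- if (tx@strand == "+") blocks[max(1L, nEx - n + 1L):nEx]
            else blocks[1L:min(n, nEx)]
    basesAt(genome, tx@chrom, splicedPositions(keep, tx@strand), tx@strand)
}
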