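# DRACH-site accessibility: pairing profiles, non-overlapping segment
# counters and reference-vs-alternate structure diffs.

# Segment layout within the 5-mer motif (offsets relative to the D base),
# in scoring priority order: longer segments first, 5' before 3' at equal
# length.  The full DRACH consumes everything; DRAC is preferred over RACH
# at the 4-mer tie (documented tie-break).
SEGMENTS <- list(
    DRACH = 0:4,
    DRAC  = 0:3,
    RACH  = 1:4,
    DRA   = 0:2,
    RAC   = 1:3,
    ACH   = 2:4
)

#' Pairing profile and free/paired label of one DRACH site
#'
#' Reads the five motif positions straight off the dot-bracket of a folded
#' window and labels the site \code{"free"} if 3 or more of the 5
#' nucleotides are unpaired, \code{"paired"} if 3 or more are paired
#' (exactly one label applies by pigeonhole).
#'
#' @param foldResult a \linkS4class{FoldResult} for the window.
#' @param siteStart 1-based position of the D base in the folded sequence.
#' @return list with \code{paired} (logical length 5) and \code{label}.
#' @export
siteProfile <- function(foldResult, siteStart) {
    db <- dotBracket(foldResult)
    if (siteStart < 1L || siteStart + 4L > nchar(db))
        stop("DRACH site extends beyond the folded sequence")
    flags <- substring(db, siteStart:(siteStart + 4L),
                       siteStart:(siteStart + 4L)) != "."
    list(paired = flags, label = if (sum(flags) >= 3L) "paired" else "free")
}

# Score one site's 5 pairing flags with the non-overlapping counter scheme.
# A segment scores "free" when all its positions are unpaired (or "paired"
# when all are paired) and none of its positions has been consumed by an
# earlier-scored segment; scoring consumes the positions.
scoreSiteSegments <- function(flags) {
    counters <- integer(12L)
    names(counters) <- c(paste0("free_", names(SEGMENTS)),
                         paste0("paired_", names(SEGMENTS)))
    consumed <- rep(FALSE, 5L)
    for (segName in names(SEGMENTS)) {
        pos <- SEGMENTS[[segName]] + 1L
        if (any(consumed[pos])) next
        f <- flags[pos]
        if (all(!f)) {
            counters[paste0("free_", segName)] <- 1L
            consumed[pos] <- TRUE
        } else if (all(f)) {
            counters[paste0("paired_", segName)] <- 1L
            consumed[pos] <- TRUE
        }
    }
    counters
}

#' Non-overlapping free/paired segment counters over all DRACH sites
#'
#' For each site the motif sub-segments DRA, RAC, ACH, DRAC, RACH and DRACH
#' are examined in priority order (longer first, 5' before 3' at equal
#' length).  A segment is counted \emph{free} when every one of its
#' positions is unpaired, \emph{paired} when every position is paired, and
#' a counted segment consumes its positions so no shorter segment can reuse
#' them -- e.g. a free DRAC increments the free-DRAC counter but the same
#' site is not additionally counted for free DRA or RAC.
#'
#' @param foldResult a \linkS4class{FoldResult}.
#' @param sites data.frame from \code{\link{scanDrach}} on the same sequence.
#' @return named integer vector of 12 counters
#'   (\code{free_DRA} ... \code{paired_DRACH}), summed over sites.
#' @export
segmentCounters <- function(foldResult, sites) {
    total <- scoreSiteSegments(rep(FALSE, 5L))
    total[] <- 0L
    if (nrow(sites) == 0L) return(total)
    for (s in sites$start) {
        prof <- siteProfile(foldResult, s)
        total <- total + scoreSiteSegments(prof$paired)
    }
    total
}

#' Diff reference and alternate structures at the DRACH level
#'
#' Matches DRACH sites between the reference and alternate windows by
#' coordinate (offset-adjusted downstream of an indel), labels each matched
#' site in both structures with the 3-of-5 rule and reports transitions
#' (\code{paired->free}, \code{free->paired} or \code{none}).  DeltaMFE is
#' the difference between the absolute values of the two MFEs,
#' \code{|mfe_ref| - |mfe_alt|}; a positive value means the variant
#' destabilizes the fold.
#'
#' @param refFold,altFold \linkS4class{FoldResult}s folded with the same
#'   engine and constraints.
#' @param refSites,altSites \code{\link{scanDrach}} tables for the two
#'   sequences.
#' @param variantSpan optional integer c(wStart, wEnd) of the replaced span
#'   in the reference window plus \code{lenDiff = nchar(alt) - nchar(ref)};
#'   give as list(wStart=, wEnd=, lenDiff=) for indel offset mapping.
#' @return list with \code{transitions} data.frame (refIndex, refStart,
#'   altStart, labelRef, labelAlt, transition) and \code{deltaMfe}.
#' @export
diffStructures <- function(refFold, refSites, altFold, altSites,
                           variantSpan = NULL) {
    if (foldEngine(refFold) != foldEngine(altFold) ||
        refFold@noLonelyPairs != altFold@noLonelyPairs)
        stop("reference and alternate must be folded with the same engine and constraints")
    shift <- function(pos) {
        if (is.null(variantSpan) || variantSpan$lenDiff == 0L) return(pos)
        ifelse(pos > variantSpan$wEnd, pos + variantSpan$lenDiff, pos)
    }
    trans <- data.frame(refIndex = integer(), refStart = integer(),
                        altStart = integer(), labelRef = character(),
                        labelAlt = character(), transition = character(),
                        stringsAsFactors = FALSE)
    for (k in seq_len(nrow(refSites))) {
        rs <- refSites$start[k]
        # sites overlapping the variant span itself are not matched
        if (!is.null(variantSpan) &&
            rs <= variantSpan$wEnd && rs + 4L >= variantSpan$wStart) next
        as_ <- shift(rs)
        if (!as_ %in% altSites$start) next
        lr <- siteProfile(refFold, rs)$label
        la <- siteProfile(altFold, as_)$label
        tr <- if (lr == la) "none" else paste0(lr, "->", la)
        trans <- rbind(trans, data.frame(
            refIndex = refSites$index[k], refStart = rs, altStart = as_,
            labelRef = lr, labelAlt = la, transition = tr,
            stringsAsFactors = FALSE))
    }
    list(transitions = trans, deltaMfe = abs(mfe(refFold)) - abs(mfe(altFold)))
}
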