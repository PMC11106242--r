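#' Scan a sequence for DRACH motifs
#'
#' Enumerates every occurrence of the m6A consensus motif DRACH
#' (D = A/G/T, R = A/G, then the methylatable A, then C, H = A/C/T; DNA
#' regex \code{[AGT][AG]AC[ACT]}).  Overlapping occurrences are all
#' reported -- polymethylated regions pack several sites into a ~20-25 nt
#' stretch, so a first-match-only scan would silently miss sites.  N bases
#' never match.
#'
#' @param seq uppercase DNA (or RNA) string.
#' @return data.frame with columns \code{index} (ordinal, 5' to 3',
#'   1-based), \code{start} (1-based position of the D base) and
#'   \code{seq5} (the 5-mer).  Zero-row data.frame when nothing matches.
#' @examples
#' scanDrach("AGGACTTTTT")
#' @export
scanDrach <- function(seq) {
    seq <- normalizeDna(seq)
    # lookahead so overlapping matches are all reported
    hits <- gregexpr("(?=[AGT][AG]AC[ACT])", seq, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) {
        return(data.frame(index = integer(), start = integer(),
                          seq5 = character(), stringsAsFactors = FALSE))
    }
    starts <- as.integer(hits)
    data.frame(
        index = seq_along(starts),
        start = starts,
        seq5  = substring(seq, starts, starts + 4L),
        stringsAsFactors = FALSE
    )
}

#' Does a variant span overlap any DRACH motif?
#'
#' @param sites data.frame from \code{\link{scanDrach}}.
#' @param wStart,wEnd 1-based inclusive window span of the replaced bases.
#' @return TRUE iff the span intersects any 5-mer motif span.
#' @export
variantOverlapsDrach <- function(sites, wStart, wEnd) {
    if (nrow(sites) == 0L) return(FALSE)
    any(wStart <= sites$start + 4L & wEnd >= sites$start)
}
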