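# Independent oracles used across the suite.  These deliberately do not
# share code with the package implementation paths they check.

# -- exhaustive folding oracle --------------------------------------------
# Enumerates every nested structure (canonical pairs, hairpin >= 3),
# filters lonely pairs when requested, and scores with the same documented
# energy model (pair stabilities + helix initiation penalty).
pairEnergyOracle <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) -3
    else if (p %in% c("AU", "UA")) -2
    else if (p %in% c("GU", "UG")) -1
    else NA_real_
}

enumerateStructures <- function(chars) {
    n <- length(chars)
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (j - i < 4) return(list(list()))
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        out <- rec(i, j - 1)
        for (k in i:(j - 4)) {
            if (is.na(pairEnergyOracle(chars[k], chars[j]))) next
            left <- if (k > i) rec(i, k - 1) else list(list())
            right <- rec(k + 1, j - 1)
            for (L in left) for (R in right)
                out[[length(out) + 1L]] <- c(L, R, list(c(k, j)))
        }
        memo[[key]] <- out
        out
    }
    rec(1, n)
}

oracleFold <- function(seq, noLonelyPairs = TRUE) {
    chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
    best <- 0; bestPairs <- list()
    for (st in enumerateStructures(chars)) {
        if (length(st)) {
            partner <- rep(NA_integer_, length(chars))
            for (p in st) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
            if (noLonelyPairs) {
                lonely <- FALSE
                for (p in st) {
                    i <- p[1]; j <- p[2]
                    inner <- !is.na(partner[i + 1]) && partner[i + 1] == j - 1
                    outer <- i > 1 && j < length(chars) &&
                        !is.na(partner[i - 1]) && partner[i - 1] == j + 1
                    if (!inner && !outer) { lonely <- TRUE; break }
                }
                if (lonely) next
            }
        }
        keys <- vapply(st, function(p) paste(p[1], p[2]), "")
        nHelix <- sum(!vapply(st, function(p) paste(p[1] - 1, p[2] + 1), "")
                      %in% keys)
        e <- sum(vapply(st, function(p)
            pairEnergyOracle(chars[p[1]], chars[p[2]]), 0)) + 4 * nHelix
        if (e < best) { best <- e; bestPairs <- st }
    }
    list(mfe = best, pairs = bestPairs)
}

# -- naive DRACH oracle ----------------------------------------------------
naiveDrachScan <- function(seq) {
    chars <- strsplit(seq, "")[[1L]]
    hits <- integer()
    for (i in seq_len(max(0L, length(chars) - 4L))) {
        w <- chars[i:(i + 4L)]
        if (w[1] %in% c("A", "G", "T") && w[2] %in% c("A", "G") &&
            w[3] == "A" && w[4] == "C" && w[5] %in% c("A", "C", "T"))
            hits <- c(hits, i)
    }
    hits
}

# -- recursive segment-counter oracle -------------------------------------
# Literal rule application over the ordered segment list, with an explicit
# consumed-position set; structured differently from the implementation.
oracleSegmentCounters <- function(flags) {
    segs <- list(DRACH = 1:5, DRAC = 1:4, RACH = 2:5,
                 DRA = 1:3, RAC = 2:4, ACH = 3:5)
    out <- integer(12)
    names(out) <- c(paste0("free_", names(segs)), paste0("paired_", names(segs)))
    step <- function(remaining, consumed) {
        if (length(remaining) == 0L) return(invisible(NULL))
        nm <- remaining[1L]
        pos <- segs[[nm]]
        if (length(intersect(pos, consumed)) == 0L) {
            if (all(flags[pos])) {
                out[paste0("paired_", nm)] <<- out[paste0("paired_", nm)] + 1L
                consumed <- union(consumed, pos)
            } else if (all(!flags[pos])) {
                out[paste0("free_", nm)] <<- out[paste0("free_", nm)] + 1L
                consumed <- union(consumed, pos)
            }
        }
        step(remaining[-1L], consumed)
    }
    step(names(segs), integer())
    out
}

# maximal stacked helix length through the pair at position i
helixRunAt <- function(partner, i) {
    if (is.na(partner[i])) return(0L)
    lo <- min(i, partner[i]); hi <- max(i, partner[i])
    n <- 1L; a <- lo; b <- hi
    while (a + 1 <= length(partner) && !is.na(partner[a + 1]) &&
           partner[a + 1] == b - 1) { a <- a + 1; b <- b - 1; n <- n + 1L }
    a <- lo; b <- hi
    while (a - 1 >= 1 && !is.na(partner[a - 1]) &&
           partner[a - 1] == b + 1) { a <- a - 1; b <- b + 1; n <- n + 1L }
    n
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")
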