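#' Fold a window sequence to its minimum-free-energy structure
#'
#' Computes a single MFE secondary structure (dot-bracket plus free energy)
#' for a sequence of 9-250 nt under the constraint set used throughout the
#' package: canonical pairs only (AU, GC, GU), hairpin loops of at least
#' three unpaired nucleotides and -- by default -- no isolated base pairs
#' (no helix of length one).
#'
#' Two engines satisfy the same contract:
#' \describe{
#'   \item{\code{"vienna"}}{adapter around the \code{RNAfold} executable
#'     (ViennaRNA), run with \code{--noLP} when \code{noLonelyPairs} is TRUE.
#'     This is the production engine with the full nearest-neighbor energy
#'     model.}
#'   \item{\code{"builtin"}}{an exact dynamic program compiled into the
#'     package, using a documented simplified energy model (per-pair
#'     stabilities GC -3, AU -2, GU -1 kcal/mol).  It is deterministic,
#'     dependency-free, and agrees with exhaustive enumeration of all legal
#'     structures for short sequences; intended for tests and offline use.}
#' }
#' Energies and structures from different engines are never mixed in one
#' result table; every \linkS4class{FoldResult} carries its engine tag.
#'
#' T is folded as U and the result sequence is rendered as RNA.  N never
#' pairs; sequences with more than 10\% N are rejected.
#'
#' @param seq character DNA or RNA sequence, 9-250 nt, alphabet ACGTUN.
#' @param engine \code{"builtin"} or \code{"vienna"}.
#' @param noLonelyPairs logical, forbid helices of length 1 (default TRUE).
#' @return a \linkS4class{FoldResult}.
#' @examples
#' fold("GGGGAAAACCCC", engine = "builtin")
#' @export
fold <- function(seq, engine = c("builtin", "vienna"), noLonelyPairs = TRUE) {
    engine <- match.arg(engine)
    seq <- normalizeDna(seq)
    n <- nchar(seq)
    if (n < 9L || n > 250L)
        stop("sequence length must be between 9 and 250 nt, got ", n)
    if (grepl("[^ACGTN]", seq))
        stop("sequence contains characters outside {A,C,G,T,U,N}")
    nN <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE)))
    if (nN > 0.10 * n)
        reject("window rejected: more than 10%% ambiguous (N) bases")
    rna <- chartr("T", "U", seq)
    if (engine == "vienna") {
        res <- viennaFold(rna, noLonelyPairs)
    } else {
        raw <- .builtin_fold_cpp(rna, noLonelyPairs)
        res <- list(db = raw$db, mfe = raw$mfe)
    }
    out <- new("FoldResult", seq = rna, db = res$db, mfe = res$mfe,
               engine = engine, noLonelyPairs = noLonelyPairs)
    stopifnot(validateStructure(rna, res$db, noLonelyPairs))
    out
}

#' Which folding engines are available?
#'
#' @return named logical vector for engines "builtin" and "vienna".
#' @export
foldEngines <- function() {
    c(builtin = TRUE, vienna = nzchar(Sys.which("RNAfold")))
}

viennaFold <- function(rna, noLonelyPairs) {
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe))
        stop("RNAfold executable not found on PATH; use engine = \"builtin\" instead")
    args <- c("--noPS")
    if (noLonelyPairs) args <- c(args, "--noLP")
    out <- suppressWarnings(system2(exe, args, input = rna, stdout = TRUE))
    if (length(out) < 2L)
        stop("unexpected RNAfold output: ", paste(out, collapse = " | "))
    line <- out[2L]
    m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1L]]
    if (length(m) != 3L)
        stop("could not parse RNAfold structure line: ", line)
    list(db = m[2L], mfe = as.numeric(m[3L]))
}

#' Parse a dot-bracket string into a pairing table
#'
#' @param db dot-bracket string over \code{(}, \code{)}, \code{.}.
#' @return integer vector of partner indices (1-based), NA where unpaired.
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(db) {
    chars <- strsplit(db, "", fixed = TRUE)[[1L]]
    if (length(chars) && any(!chars %in% c("(", ")", ".")))
        stop("dot-bracket may only contain '(', ')' and '.'")
    partner <- rep(NA_integer_, length(chars))
    stack <- integer()
    for (i in seq_along(chars)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (length(stack) == 0L) stop("unbalanced dot-bracket: unmatched ')'")
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            partner[i] <- j
            partner[j] <- i
        }
    }
    if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
    partner
}

renderDotBracket <- function(partner) {
    out <- rep(".", length(partner))
    paired <- which(!is.na(partner))
    out[paired[partner[paired] > paired]] <- "("
    out[paired[partner[paired] < paired]] <- ")"
    paste(out, collapse = "")
}

#' Validate a secondary structure against the folding constraints
#'
#' Checks that the dot-bracket is balanced, every pair is AU, GC or GU,
#' hairpin loops have at least 3 unpaired nt and, when \code{noLonelyPairs},
#' that no helix has length 1.
#'
#' @param seq sequence (DNA or RNA alphabet).
#' @param db dot-bracket of the same length.
#' @param noLonelyPairs logical.
#' @return TRUE or FALSE.
#' @export
validateStructure <- function(seq, db, noLonelyPairs = TRUE) {
    seq <- normalizeDna(seq)
    if (nchar(seq) != nchar(db)) return(FALSE)
    partner <- tryCatch(parseDotBracket(db), error = function(e) NULL)
    if (is.null(partner)) return(FALSE)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    ok_pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
    for (i in which(!is.na(partner))) {
        j <- partner[i]
        if (j <= i) next
        if (!paste0(chars[i], chars[j]) %in% ok_pairs) return(FALSE)
        if (j - i - 1L < 3L) return(FALSE)  # hairpin >= 3 for innermost pairs
        if (noLonelyPairs) {
            inner <- !is.na(partner[i + 1L]) && partner[i + 1L] == j - 1L
            outer <- i > 1L && j < length(partner) &&
                !is.na(partner[i - 1L]) && partner[i - 1L] == j + 1L
            if (!inner && !outer) return(FALSE)
        }
    }
    TRUE
}
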