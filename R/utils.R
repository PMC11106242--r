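# Internal helpers shared across modules.

# Classed rejection condition: stages signal these for records that are
# dropped with a reason (distinct from programming errors, which remain
# plain errors).  The pipeline catches them and books the reason.
reject <- function(reason, ...) {
    stop(structure(
        class = c("m6adscan_reject", "error", "condition"),
        list(message = sprintf(reason, ...), call = sys.call(-1),
             reason = sprintf(reason, ...))
    ))
}

isReject <- function(e) inherits(e, "m6adscan_reject")

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", U = "A")

revComp <- function(seq) {
    if (nchar(seq) == 0L) return("")
    chars <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
    out <- REVCOMP[chars]
    if (anyNA(out)) stop("cannot reverse-complement non-ACGTN sequence")
    paste(out, collapse = "")
}

# Standard genetic code on the DNA alphabet.
GENETIC_CODE_DNA <- Biostrings::GENETIC_CODE
names(GENETIC_CODE_DNA) <- chartr("U", "T", names(Biostrings::GENETIC_CODE))

translateDna <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return("")
    codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- GENETIC_CODE_DNA[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

isStopCodon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

normalizeDna <- function(seq) chartr("u", "T", chartr("U", "T", toupper(seq)))
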