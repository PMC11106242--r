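# Readers and writers for the four standard inputs (genome FASTA, BED12
# transcripts, VCF variants, m6A-site TSV) and the candidate output table.

#' Read a genome FASTA file
#'
#' Sequences are uppercased and U is converted to T so one internal DNA
#' alphabet holds throughout (the folding module renders U again on output).
#'
#' @param path path to a FASTA file.
#' @return a \link[Biostrings]{DNAStringSet}, one entry per header.
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    # read as BStringSet first so RNA input (U) can be normalized
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    nm <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(nm))
        stop("duplicate sequence names in FASTA: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    seqs <- vapply(as.character(raw), normalizeDna, character(1L),
                   USE.NAMES = FALSE)
    if (any(nchar(seqs) == 0L)) stop("empty sequence record in FASTA")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- nm
    out
}

#' Read transcript models from a BED12 file (UCSC RefSeq dialect)
#'
#' Parsing is delegated to \code{\link[rtracklayer]{import}}; block offsets
#' (relative to chromStart) become absolute genomic exon intervals and
#' thickStart/thickEnd become the CDS span.  Non-coding entries
#' (thickStart == thickEnd) are rejected with reason \code{"no CDS"} rather
#' than raising an error; structurally invalid entries (CDS outside the
#' transcript, malformed blocks) raise errors.
#'
#' The BED name field may be either \code{transcriptId} or
#' \code{transcriptId|geneSymbol}.
#'
#' @param path path to a 12-column BED file.
#' @return list of \linkS4class{TranscriptModel}; rejected records are
#'   available in \code{attr(, "rejected")} (data.frame name/reason).
#' @export
readTranscriptsBed12 <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks))
        stop("expected 12-column BED (with block structure): ", path)
    out <- list()
    rejected <- data.frame(name = character(), reason = character(),
                           stringsAsFactors = FALSE)
    for (i in seq_along(gr)) {
        nm <- gr$name[i]
        parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
        txId <- parts[1L]
        gene <- if (length(parts) >= 2L) parts[2L] else parts[1L]
        thick <- gr$thick[i]
        if (IRanges::width(thick) == 0L) {
            rejected <- rbind(rejected, data.frame(
                name = nm, reason = "no CDS", stringsAsFactors = FALSE))
            next
        }
        blocks <- IRanges::shift(gr$blocks[[i]],
                                 GenomicRanges::start(gr)[i] - 1L)
        tm <- new("TranscriptModel",
                  transcriptId = txId, geneSymbol = gene,
                  chrom  = as.character(GenomicRanges::seqnames(gr)[i]),
                  strand = as.character(GenomicRanges::strand(gr)[i]),
                  txStart = GenomicRanges::start(gr)[i],
                  txEnd   = GenomicRanges::end(gr)[i],
                  cdsStart = IRanges::start(thick),
                  cdsEnd   = IRanges::end(thick),
                  blocks = blocks)
        out[[txId]] <- tm
    }
    attr(out, "rejected") <- rejected
    out
}

#' Read variant records from a VCF file
#'
#' Minimal ClinVar-style subset: CHROM, POS, ID, REF, ALT.  Multi-allelic
#' records are split into one record per ALT allele.  Symbolic or breakend
#' alleles are rejected with reason \code{"unsupported allele"}.  REF
#' agreement with the genome is checked later, at the window stage, where
#' chrom/pos context is reported.
#'
#' @param path path to a VCF (v4.x) file.
#' @return data.frame with columns variantId, chrom, pos (1-based), ref,
#'   alt; rejected alleles in \code{attr(, "rejected")}.
#' @export
readVariants <- function(path) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
    ids0 <- names(SummarizedExperiment::rowRanges(vcf))
    nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (is.null(ids0)) ids0 <- paste0("var", seq_along(nAlt))
    # multi-allelic records keep their id plus an allele ordinal
    ids <- unlist(lapply(seq_along(ids0), function(i)
        if (nAlt[i] > 1L) paste0(ids0[i], "_", seq_len(nAlt[i])) else ids0[i]),
        use.names = FALSE)
    alt <- as.character(rr$ALT)
    ref <- as.character(rr$REF)
    ok <- !grepl("[^ACGTN]", alt) & nzchar(alt) & !grepl("[^ACGTN]", ref)
    rejected <- data.frame(variantId = ids[!ok],
                           reason = rep("unsupported allele", sum(!ok)),
                           stringsAsFactors = FALSE)
    out <- data.frame(
        variantId = ids[ok],
        chrom = as.character(GenomicRanges::seqnames(rr))[ok],
        pos = GenomicRanges::start(rr)[ok],
        ref = ref[ok],
        alt = alt[ok],
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "rejected") <- rejected
    out
}

#' Read validated m6A site records
#'
#' Primary dialect: a tab-delimited file with columns site_id, chrom, pos
#' (1-based position of the methylated adenosine), strand, transcript_id
#' (optional, may be empty).  As an alternate dialect a VCF whose INFO
#' field carries \code{M6A_POS=<pos>} (and optionally
#' \code{M6A_STRAND=<+/->}) is accepted.
#'
#' @param path path to the site file.
#' @return data.frame with columns siteId, chrom, pos, strand, transcriptId.
#' @export
readM6aSites <- function(path) {
    if (!file.exists(path)) stop("m6A site file not found: ", path)
    first <- readLines(path, n = 1L)
    if (startsWith(first, "##fileformat=VCF")) {
        vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
        rr <- SummarizedExperiment::rowRanges(vcf)
        info <- VariantAnnotation::info(vcf)
        if (!"M6A_POS" %in% colnames(info))
            stop("VCF m6A dialect requires INFO key M6A_POS")
        strand <- if ("M6A_STRAND" %in% colnames(info))
            as.character(unlist(info$M6A_STRAND)) else rep("+", length(rr))
        out <- data.frame(
            siteId = names(rr),
            chrom = as.character(GenomicRanges::seqnames(rr)),
            pos = as.integer(unlist(info$M6A_POS)),
            strand = strand,
            transcriptId = NA_character_,
            stringsAsFactors = FALSE
        )
    } else {
        tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
        need <- c("site_id", "chrom", "pos", "strand")
        if (!all(need %in% names(tab)))
            stop("m6A TSV must have columns: ",
                 paste(c(need, "transcript_id (optional)"), collapse = ", "))
        out <- data.frame(
            siteId = tab$site_id,
            chrom = tab$chrom,
            pos = as.integer(tab$pos),
            strand = tab$strand,
            transcriptId = if ("transcript_id" %in% names(tab))
                ifelse(nzchar(tab$transcript_id), tab$transcript_id,
                       NA_character_) else NA_character_,
            stringsAsFactors = FALSE
        )
    }
    if (any(is.na(out$pos)) || any(out$pos < 1L))
        stop("m6A site positions must be 1-based integers >= 1")
    if (!all(out$strand %in% c("+", "-")))
        stop("m6A site strand must be '+' or '-'")
    rownames(out) <- NULL
    out
}

#' Join variants to m6A sites through shared transcripts
#'
#' Produces one (variant, m6A site, transcript) pair for every combination
#' where variant and site fall on the same transcript: both positions lie
#' within the transcript's exon blocks (a site carrying an explicit
#' transcript_id is restricted to that transcript) and the site strand
#' matches the transcript strand.  Pairs whose site later falls outside the
#' analysis window are dropped at the window stage, not here.
#'
#' @param variants data.frame from \code{\link{readVariants}}.
#' @param sites data.frame from \code{\link{readM6aSites}}.
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @return data.frame with one row per pair: variantId, siteId,
#'   transcriptId plus the variant and site coordinates.
#' @export
joinVariantsToSites <- function(variants, sites, transcripts) {
    rows <- list()
    for (tx in transcripts) {
        inBlocks <- function(chrom, pos) {
            chrom == tx@chrom &
                IRanges::countOverlaps(
                    IRanges::IRanges(pos, pos), tx@blocks) > 0L
        }
        vHit <- which(inBlocks(variants$chrom, variants$pos))
        if (length(vHit) == 0L) next
        sOk <- sites$strand == tx@strand &
            (is.na(sites$transcriptId) | sites$transcriptId == tx@transcriptId) &
            inBlocks(sites$chrom, sites$pos)
        sHit <- which(sOk)
        if (length(sHit) == 0L) next
        grid <- expand.grid(v = vHit, s = sHit)
        rows[[length(rows) + 1L]] <- data.frame(
            variantId = variants$variantId[grid$v],
            siteId = sites$siteId[grid$s],
            transcriptId = tx@transcriptId,
            chrom = tx@chrom,
            variantPos = variants$pos[grid$v],
            ref = variants$ref[grid$v],
            alt = variants$alt[grid$v],
            sitePos = sites$pos[grid$s],
            stringsAsFactors = FALSE
        )
    }
    if (length(rows) == 0L) {
        return(data.frame(variantId = character(), siteId = character(),
                          transcriptId = character(), chrom = character(),
                          variantPos = integer(), ref = character(),
                          alt = character(), sitePos = integer(),
                          stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Output table schema (order matters; serialization is covered by a
# round-trip test).
CANDIDATE_COLUMNS <- c(
    "variant_id", "chrom", "genomic_pos", "strand", "gene_symbol",
    "transcript_id", "m6a_site_pos", "mfe_ref", "mfe_alt", "delta_mfe",
    "synonymous_flag", "variant_class", "n_drach_ref", "n_drach_alt",
    paste0("free_", c("DRA", "RAC", "ACH", "DRAC", "RACH", "DRACH"), "_ref"),
    paste0("paired_", c("DRA", "RAC", "ACH", "DRAC", "RACH", "DRACH"), "_ref"),
    paste0("free_", c("DRA", "RAC", "ACH", "DRAC", "RACH", "DRACH"), "_alt"),
    paste0("paired_", c("DRA", "RAC", "ACH", "DRAC", "RACH", "DRACH"), "_alt"),
    "gained_motif_at_variant", "transitions"
)

#' Write the candidate output table
#'
#' Tab-separated, one row per candidate record, fixed column schema.  An
#' optional JSON dump additionally carries the dot-bracket structures and
#' the engine tag.
#'
#' @param records data.frame of candidate records (from
#'   \code{\link{runPipeline}}).
#' @param path output TSV path.
#' @param jsonPath optional path for a JSON dump including dot-brackets.
#' @return invisibly, the written data.frame.
#' @export
writeCandidateTable <- function(records, path, jsonPath = NULL) {
    tab <- records[, CANDIDATE_COLUMNS, drop = FALSE]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    if (!is.null(jsonPath)) {
        jsonlite::write_json(records, jsonPath, auto_unbox = FALSE,
                             digits = NA, na = "null")
    }
    invisible(tab)
}

#' Read back a candidate table written by \code{\link{writeCandidateTable}}
#'
#' @param path TSV path.
#' @return data.frame with the candidate schema.
#' @export
readCandidateTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(m6a_site_pos = "character",
                                            transitions = "character"))
    tab$transitions[is.na(tab$transitions)] <- ""
    tab
}
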