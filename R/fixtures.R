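# Self-contained synthetic fixture bundle: toy genome + BED12 transcripts +
# VCF variants + m6A sites + machine-readable truth manifest.
#
# The structured loci are hand-designed cassettes whose fold behaviour is
# analytic (mutually exclusive helix families; see the methods vignette);
# seeded randomness is confined to filler that cannot change the planted
# truths (intergenic DNA, introns, and the filter-matrix transcript's
# backbone, which is guarded against accidental DRACH collisions).
#
# The EPRS1-like, VHL-like and TSC2-like loci are SYNTHETIC stand-ins for
# the corresponding published worked examples; they are engineered to carry
# the documented features (a 5-bp stem with four sequential G-C pairs whose
# central C is the variant, 55 nt from the last exon-exon junction; a
# variant freeing two DRACH sites and burying a third; a variant freeing
# three sites), not real human sequence.

A_ <- function(n) strrep("A", n)

# ---- frozen cassette arms (verified against both folding engines) -------
SWITCH_P   <- "GCGGCGGGGGA"          # anchor arm (6 bp) + stem arm GGGGA
SWITCH_Q   <- "TCCCCACGCCGC"         # stem arm TCCCC (variant = 3rd C) + bulge + anchor
SWITCH_R   <- "TGACTCTGACT"          # two DRACH motifs, junction after base 5
SWITCH_X   <- "AGTCAGGGTCA"          # anti-R with one wobble
VHL_P      <- "GGTGTTTGGGGGA"        # anchor arm (8 bp) + stem arm
VHL_Q      <- "TCCCCAACAAACACC"      # stem + 2-nt bulge + anchor arm carrying AAACA
VHL_X      <- "AGTCAGAGTCA"          # full Watson-Crick anti-R
TSC2_P     <- "GGCGGCGGCGGGGGGA"     # anchor arm (11 bp) + stem arm
TSC2_Q     <- "TCCCCACCGCCGCCGCC"
TSC2_R     <- "TGACTCTGACTCTGACT"    # three DRACH motifs
TSC2_X     <- "GGTCAGAGTCAGAGTCA"

SENSE_CODONS <- setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))

randomDna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = "")
randomCodons <- function(nCodons) paste(sample(SENSE_CODONS, nCodons,
                                               replace = TRUE), collapse = "")

# independent inline motif scan, used only as a generation guard
drachStarts <- function(s) {
    h <- gregexpr("(?=[AGT][AG]AC[ACT])", s, perl = TRUE)[[1L]]
    if (h[1L] == -1L) integer() else as.integer(h)
}

# ---- locus assembly ------------------------------------------------------
# A locus spec: exon sequences in transcript orientation, CDS = spliced
# prefix of length cdsLen, plus transcript-coordinate variants and sites.
assembleLocus <- function(spec, intronLens) {
    exLens <- nchar(spec$exons)
    nEx <- length(exLens)
    introns <- vapply(intronLens, randomDna, character(1L))
    pieces <- character(0L)
    for (i in seq_len(nEx)) {
        pieces <- c(pieces, spec$exons[i])
        if (i < nEx) pieces <- c(pieces, introns[i])
    }
    unspliced <- paste(pieces, collapse = "")
    Lu <- nchar(unspliced)
    # unspliced offset of each exon start (transcript orientation)
    exU <- integer(nEx); off <- 0L
    for (i in seq_len(nEx)) {
        exU[i] <- off + 1L
        off <- off + exLens[i] + if (i < nEx) nchar(introns[i]) else 0L
    }
    cumSpliced <- cumsum(c(0L, exLens))
    t2u <- function(t) {
        k <- findInterval(t - 1L, cumSpliced, rightmost.closed = FALSE)
        exU[k] + (t - cumSpliced[k] - 1L)
    }
    list(spec = spec, unspliced = unspliced, Lu = Lu, exLens = exLens,
         exU = exU, t2u = t2u,
         genomicText = if (spec$strand == "+") unspliced else revComp(unspliced))
}

# 1-based genomic position (within chromosome) of spliced transcript pos t
locusG <- function(loc, start1, t) {
    u <- loc$t2u(t)
    if (loc$spec$strand == "+") start1 + u - 1L
    else start1 + (loc$Lu - u + 1L) - 1L
}

bedLine <- function(loc, start1) {
    spec <- loc$spec
    start0 <- start1 - 1L
    nEx <- length(loc$exLens)
    exStartsU <- loc$exU; exEndsU <- loc$exU + loc$exLens - 1L
    if (spec$strand == "+") {
        bStarts <- exStartsU - 1L
        bSizes <- loc$exLens
    } else {
        bStarts <- rev(loc$Lu - exEndsU)
        bSizes <- rev(loc$exLens)
    }
    cdsG <- sort(c(locusG(loc, start1, 1L), locusG(loc, start1, spec$cdsLen)))
    paste(spec$chrom, start0, start0 + loc$Lu,
          paste0(spec$txId, "|", spec$gene), 0L, spec$strand,
          cdsG[1L] - 1L, cdsG[2L], 0L, nEx,
          paste0(paste(bSizes, collapse = ","), ","),
          paste0(paste(bStarts, collapse = ","), ","),
          sep = "\t")
}

# ---- the individual loci -------------------------------------------------

switchLocus <- function() {
    exon1 <- paste0("ATG", A_(9))                          # 12 nt CDS
    exonA <- paste0(A_(4), SWITCH_P, A_(4), substr(SWITCH_R, 1, 5))   # 24
    exonBc <- paste0(substr(SWITCH_R, 6, 11), A_(46), SWITCH_Q, A_(5), "TAA")
    utr <- paste0(A_(6), "AAACA", A_(5), SWITCH_X, A_(6))  # 33 nt 3'UTR
    cdsLen <- nchar(exon1) + nchar(exonA) + nchar(exonBc)
    stopifnot(cdsLen %% 3L == 0L)
    exons <- c(exon1, exonA, paste0(exonBc, utr))
    # transcript coordinates (spliced)
    offA <- nchar(exon1); offB <- offA + nchar(exonA)
    varT <- offB + 6L + 46L + 3L                           # central stem C
    tx <- paste(exons, collapse = "")
    stopifnot(substr(tx, varT, varT) == "C",
              varT - offB == 55L,                          # junction offset
              substr(translateDna(substr(tx, 1, cdsLen)), 1, 1) == "M")
    aa <- translateDna(substr(tx, 1, cdsLen))
    stopifnot(!grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
              substr(aa, nchar(aa), nchar(aa)) == "*")
    sites <- c(offA + 20L + 2L,                            # A of DRACH 1 (exon 2)
               offB + 2L + 2L,                             # A of DRACH 2 (exon 3)
               offB + nchar(exonBc) + 6L + 3L)             # A of UTR AAACA
    list(chrom = "chrS", txId = "SYNEPRS1L.1", gene = "SYNEPRS1L",
         strand = "+", exons = exons, cdsLen = cdsLen,
         variants = list(list(id = "var_switch", t = varT, ref = "C",
                              alt = "A", class = "missense", keep = TRUE,
                              reason = NA_character_)),
         siteT = sites, siteIds = c("m6a_S1", "m6a_S2", "m6a_S3"),
         expectedTransitions = c(m6a_S1 = "free->paired",
                                 m6a_S2 = "free->paired",
                                 m6a_S3 = "none"))
}

vhlLocus <- function() {
    exon1 <- paste0("ATG", A_(10))                         # 13 nt CDS
    exonA <- paste0(A_(4), VHL_P, A_(4), substr(SWITCH_R, 1, 5))      # 26
    # reference allele A sits in the stem (broken); ALT C completes it
    qBroken <- VHL_Q
    substr(qBroken, 3, 3) <- "A"
    exonBc <- paste0(substr(SWITCH_R, 6, 11), A_(40), qBroken, A_(5), "TAA")
    utr <- paste0(A_(6), VHL_X, A_(6))
    cdsLen <- nchar(exon1) + nchar(exonA) + nchar(exonBc)
    stopifnot(cdsLen %% 3L == 0L)
    exons <- c(exon1, exonA, paste0(exonBc, utr))
    offA <- nchar(exon1); offB <- offA + nchar(exonA)
    varT <- offB + 6L + 40L + 3L
    tx <- paste(exons, collapse = "")
    stopifnot(substr(tx, varT, varT) == "A")
    aa <- translateDna(substr(tx, 1, cdsLen))
    stopifnot(!grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
              substr(aa, nchar(aa), nchar(aa)) == "*")
    sites <- c(offA + 24L,                                 # A of DRACH 1 (exon 2)
               offB + 4L,                                  # A of DRACH 2
               offB + 46L + 11L)                           # A of AAACA in anchor arm
    list(chrom = "chrV", txId = "SYNVHLL.1", gene = "SYNVHLL",
         strand = "+", exons = exons, cdsLen = cdsLen,
         variants = list(list(id = "var_vhl", t = varT, ref = "A",
                              alt = "C", class = "missense", keep = TRUE,
                              reason = NA_character_)),
         siteT = sites, siteIds = c("m6a_V1", "m6a_V2", "m6a_V3"),
         expectedTransitions = c(m6a_V1 = "paired->free",
                                 m6a_V2 = "paired->free",
                                 m6a_V3 = "free->paired"))
}

tsc2Locus <- function() {
    exon1 <- paste0("ATG", A_(10))                         # 13 nt CDS
    exonA <- paste0(A_(4), TSC2_P, A_(4), substr(TSC2_R, 1, 6))       # 30
    qBroken <- TSC2_Q
    substr(qBroken, 3, 3) <- "A"
    exonBc <- paste0(substr(TSC2_R, 7, 17), A_(40), qBroken, A_(6), "TAA")
    utr <- paste0(A_(6), TSC2_X, A_(6))
    cdsLen <- nchar(exon1) + nchar(exonA) + nchar(exonBc)
    stopifnot(cdsLen %% 3L == 0L)
    exons <- c(exon1, exonA, paste0(exonBc, utr))
    offA <- nchar(exon1); offB <- offA + nchar(exonA)
    varT <- offB + 11L + 40L + 3L
    tx <- paste(exons, collapse = "")
    stopifnot(substr(tx, varT, varT) == "A")
    aa <- translateDna(substr(tx, 1, cdsLen))
    stopifnot(!grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
              substr(aa, nchar(aa), nchar(aa)) == "*")
    # motif starts: R3[1] at exon-2 offset 25; R3[7], R3[13] at exon-3
    # offsets 1 and 7; methylated A = motif position 3
    sites <- c(offA + 27L, offB + 3L, offB + 9L)
    list(chrom = "chrT", txId = "SYNTSC2L.1", gene = "SYNTSC2L",
         strand = "-", exons = exons, cdsLen = cdsLen,
         variants = list(list(id = "var_tsc2", t = varT, ref = "A",
                              alt = "C", class = "missense", keep = TRUE,
                              reason = NA_character_)),
         siteT = sites, siteIds = c("m6a_T1", "m6a_T2", "m6a_T3"),
         expectedTransitions = c(m6a_T1 = "paired->free",
                                 m6a_T2 = "paired->free",
                                 m6a_T3 = "paired->free"))
}

censusLocus <- function() {
    cluster <- "GGACTAGGACTAGGACT"                         # 3 motifs, no extras
    single <- paste0(A_(3), "AAACA", A_(3))                # exactly one motif
    exon1 <- paste0("ATG", A_(9))
    exonP <- paste0(A_(3), cluster, A_(4), single, A_(3))          # 38 nt
    exonLc <- paste0(A_(4), cluster, A_(4), single, A_(1), "TAA")  # 40 nt
    utr <- paste0(A_(4), cluster, A_(3), single, A_(3), single, A_(3))
    cdsLen <- nchar(exon1) + nchar(exonP) + nchar(exonLc)
    stopifnot(cdsLen %% 3L == 0L)
    exons <- c(exon1, exonP, paste0(exonLc, utr))
    tx <- paste(exons, collapse = "")
    aa <- translateDna(substr(tx, 1, cdsLen))
    stopifnot(!grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
              substr(aa, nchar(aa), nchar(aa)) == "*")
    terminalTwo <- paste0(exonP, exonLc, utr)
    stopifnot(length(drachStarts(terminalTwo)) == 13L)
    offP <- nchar(exon1); offL <- offP + nchar(exonP)
    sites <- c(offP + 6L,                                  # cluster 1, first motif A
               offL + 7L,                                  # cluster 2
               offL + nchar(exonLc) + 7L)                  # cluster 3 (3'UTR)
    list(chrom = "chrC", txId = "SYNCENS.1", gene = "SYNCENS",
         strand = "+", exons = exons, cdsLen = cdsLen,
         variants = list(),
         siteT = sites, siteIds = c("m6a_C1", "m6a_C2", "m6a_C3"),
         expectedTransitions = NULL,
         censusCount = 13L)
}

nostopLocus <- function() {
    exon1 <- paste0("ATG", A_(9))
    exonL <- paste0(A_(12), "GGACT", A_(10), "AAA")        # CDS without stop codon
    cdsLen <- nchar(exon1) + nchar(exonL)
    exons <- c(exon1, paste0(exonL, A_(10)))
    list(chrom = "chrN", txId = "SYNNOSTOP.1", gene = "SYNNOSTOP",
         strand = "+", exons = exons, cdsLen = cdsLen,
         variants = list(list(id = "var_nostop", t = nchar(exon1) + 3L,
                              ref = "A", alt = "G", class = NA_character_,
                              keep = FALSE, reason = "no terminal stop")),
         siteT = nchar(exon1) + 12L + 2L, siteIds = "m6a_N1",
         expectedTransitions = NULL)
}

# Filter-matrix transcript: random sense-codon backbone with planted codons
# and one planted DRACH; eight variant classes.  Regenerated (with a rolled
# sub-seed) until no accidental DRACH motif touches a planted variant span.
filterLocus <- function() {
    exALen <- 201L; exBCdsLen <- 81L; utrLen <- 500L
    for (attempt in 1:100) {
        exonA <- randomCodons(exALen %/% 3L)
        bCodons <- strsplit(randomCodons(exBCdsLen %/% 3L), "")[[1L]]
        exonBc <- paste(bCodons, collapse = "")
        # plant codons at exon-B CDS offsets (all codon-aligned, b %% 3 == 1)
        substr(exonBc, 10, 12)  <- "CCT"   # synonymous target (T->A at 12)
        substr(exonBc, 16, 18)  <- "CCT"   # missense target (C->A at 16)
        substr(exonBc, 22, 24)  <- "TGC"   # nonsense target (C->A at 24)
        substr(exonBc, 31, 36)  <- "GGACTA" # DRACH + safe 3rd base; m6A at 33
        substr(exonBc, 79, 81)  <- "TAA"   # the stop codon
        utr <- randomDna(utrLen)
        tx1 <- paste0(exonA, exonBc)
        if (grepl("\\*", substr(translateDna(tx1), 1,
                                nchar(tx1) %/% 3L - 1L))) next
        # UTR variant position (within the first 100 UTR nt)
        utrVarT <- 50L
        win <- paste0(substr(exonA, exALen - 68L, exALen), exonBc,
                      substr(utr, 1, 100L))
        # guard: no accidental motif overlapping a planted variant span
        hits <- drachStarts(win)
        planted <- 69L + 31L                               # the planted motif
        varWin <- 69L + c(12L, 16L, 24L, 33L, 45L, 46L, 79L) # CDS spans
        varWin <- c(varWin, 69L + exBCdsLen + utrVarT)
        badHit <- FALSE
        for (h in setdiff(hits, planted))
            if (any(varWin >= h & varWin <= h + 4L)) { badHit <- TRUE; break }
        if (badHit) next
        cdsLen <- exALen + exBCdsLen
        exons <- c(exonA, paste0(exonBc, utr))
        offB <- exALen
        utrBase <- substr(utr, utrVarT, utrVarT)
        variants <- list(
            list(id = "var_syn", t = offB + 12L, ref = "T", alt = "A",
                 class = "synonymous", keep = TRUE, reason = NA_character_),
            list(id = "var_mis", t = offB + 16L, ref = "C", alt = "A",
                 class = "missense", keep = TRUE, reason = NA_character_),
            list(id = "var_non", t = offB + 24L, ref = "C", alt = "A",
                 class = "nonsense", keep = FALSE, reason = "nonsense"),
            list(id = "var_fs", t = offB + 45L, del = 1L,
                 class = "frameshift", keep = FALSE, reason = "frameshift"),
            list(id = "var_stoploss", t = offB + 79L, ref = "T", alt = "C",
                 class = "stop_loss", keep = FALSE, reason = "stop_loss"),
            list(id = "var_drach", t = offB + 33L, ref = "A", alt = "G",
                 class = "synonymous", keep = FALSE, reason = "overlaps DRACH"),
            list(id = "var_utr", t = cdsLen + utrVarT, ref = utrBase,
                 alt = if (utrBase == "A") "C" else "A",
                 class = "utr", keep = TRUE, reason = NA_character_),
            list(id = "var_junction", t = exALen, junction = TRUE,
                 class = NA_character_, keep = FALSE,
                 reason = "junction-spanning allele")
        )
        return(list(chrom = "chrF", txId = "SYNFILT.1", gene = "SYNFILT",
                    strand = "+", exons = exons, cdsLen = cdsLen,
                    variants = variants,
                    siteT = c(offB + 33L, cdsLen + 200L),
                    siteIds = c("m6a_F1", "m6a_F2_outside"),
                    expectedTransitions = NULL))
    }
    stop("could not generate a clean filter locus in 100 attempts")
}

#' Generate the synthetic fixture bundle
#'
#' Writes a deterministic, fully self-contained input set -- toy genome
#' (FASTA), transcript models (BED12), variants (VCF), validated m6A sites
#' (TSV) -- plus a truth manifest (JSON) holding the planted expectations:
#' per-variant class and filter verdict, per-site accessibility transitions
#' of the three structure-switch loci, the DRACH census of the census
#' locus's terminal two exons, and the expected pipeline summary counts.
#'
#' Six transcripts are planted: an EPRS1-like structure-switch locus (5-bp
#' stem with four sequential G-C pairs whose central C is the variant, 55 nt
#' downstream of the last exon-exon junction; the variant buries two distal
#' DRACH sites), a VHL-like locus (variant frees two sites and buries a
#' third), a minus-strand TSC2-like locus (variant frees three sites), a
#' census locus with exactly 13 DRACH motifs in its terminal two exons in
#' three polymethylated clusters plus singles, a filter-matrix transcript
#' carrying all eight variant classes, and a transcript lacking a terminal
#' stop codon.  All named loci are synthetic stand-ins, not real human
#' sequence.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the same seed reproduces the bundle
#'   byte-for-byte.
#' @return invisibly, the manifest list.
#' @export
makeFixtures <- function(dir, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
    loci <- list(switchLocus(), vhlLocus(), tsc2Locus(), censusLocus(),
                 filterLocus(), nostopLocus())
    pad <- 20L
    fastaLines <- character()
    bedLines <- character()
    vcfRows <- character()
    siteRows <- "site_id\tchrom\tpos\tstrand\ttranscript_id"
    manifestVariants <- list()
    transitions <- list()

    for (spec in loci) {
        nEx <- length(spec$exons)
        loc <- assembleLocus(spec, intronLens = rep(30L, nEx - 1L))
        start1 <- pad + 1L
        chromSeq <- paste0(randomDna(pad), loc$genomicText, randomDna(pad))
        fastaLines <- c(fastaLines, paste0(">", spec$chrom), chromSeq)
        bedLines <- c(bedLines, bedLine(loc, start1))

        for (v in spec$variants) {
            if (!is.null(v$junction)) {
                # deletion spanning the end of the penultimate exon into the intron
                gpos <- locusG(loc, start1, v$t)
                ref <- substr(chromSeq, gpos, gpos + 1L)
                alt <- substr(chromSeq, gpos, gpos)
            } else if (!is.null(v$del)) {
                gpos <- locusG(loc, start1, v$t)
                ref <- substr(chromSeq, gpos, gpos + v$del)
                alt <- substr(chromSeq, gpos, gpos)
            } else if (spec$strand == "+") {
                gpos <- locusG(loc, start1, v$t)
                ref <- v$ref; alt <- v$alt
            } else {
                gpos <- locusG(loc, start1, v$t)
                ref <- revComp(v$ref); alt <- revComp(v$alt)
            }
            stopifnot(substr(chromSeq, gpos, gpos + nchar(ref) - 1L) == ref)
            vcfRows <- c(vcfRows, paste(spec$chrom, gpos, v$id, ref, alt,
                                        ".", ".", ".", sep = "\t"))
            manifestVariants[[v$id]] <- list(
                variant_id = v$id, transcript_id = spec$txId,
                class = v$class, keep = v$keep, reason = v$reason)
        }
        for (i in seq_along(spec$siteT)) {
            gpos <- locusG(loc, start1, spec$siteT[i])
            siteRows <- c(siteRows, paste(spec$siteIds[i], spec$chrom, gpos,
                                          spec$strand, spec$txId, sep = "\t"))
        }
        if (!is.null(spec$expectedTransitions))
            transitions[[spec$txId]] <- as.list(spec$expectedTransitions)
    }

    writeLines(fastaLines, file.path(dir, "genome.fa"))
    writeLines(bedLines, file.path(dir, "tx.bed"))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##contig=<ID=", vapply(loci, `[[`, "", "chrom"), ">"),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", sep = "\t"),
                 vcfRows), file.path(dir, "variants.vcf"))
    writeLines(siteRows, file.path(dir, "m6a.tsv"))

    manifest <- list(
        seed = as.integer(seed),
        variants = manifestVariants,
        site_transitions = transitions,
        switch_geometry = list(transcript_id = "SYNEPRS1L.1",
                               junction_offset = 55L, stem_len = 5L,
                               stem_gc_pairs = 4L),
        census = list(transcript_id = "SYNCENS.1",
                      n_drach_terminal_two_exons = 13L),
        summary = list(
            n_pairs = 26L, n_kept_pairs = 12L, n_rejected_pairs = 14L,
            n_records = 6L, n_genes = 4L, n_distinct_variants = 6L,
            rejected_by_reason = list(
                `site outside window` = 8L, nonsense = 1L, frameshift = 1L,
                stop_loss = 1L, `overlaps DRACH` = 1L,
                `junction-spanning allele` = 1L, `no terminal stop` = 1L))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
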