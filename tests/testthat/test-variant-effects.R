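# A small hand-built window: 15 nt CDS (incl. stop) + 6 nt UTR.
# CDS codons: ATG CCT TGC TAA  (M P C *)
mkWindow <- function(strand = "+") {
    seq <- "ATGCCTTGCTAA"                 # 12 nt CDS ending in stop
    utr <- "ACACAC"
    w2g <- if (strand == "+") 101:118 else rev(101:118)
    new("AnalysisWindow", transcriptId = "TX", geneSymbol = "TX",
        chrom = "c1", strand = strand, seq = paste0(seq, utr),
        utrLen = 6L, cdsLen = 12L, frameAnchor = 10L,
        w2g = as.integer(w2g), upstreamContext = "")
}

test_that("variant placement verifies the REF allele against the window", {
    w <- mkWindow()
    v <- variantInWindow(w, 104L, "C", "A")      # window index 4
    expect_equal(v$wStart, 4L)
    expect_equal(v$refW, "C")
    alt <- applyVariant(w, v)
    expect_equal(substr(alt, 4, 4), "A")
    expect_equal(nchar(alt), nchar(windowSeq(w)))
    # everything else untouched
    expect_equal(strsplit(alt, "")[[1]][-4], strsplit(windowSeq(w), "")[[1]][-4])

    expect_error(variantInWindow(w, 104L, "G", "A"), "disagreement")
    expect_error(variantInWindow(w, 300L, "C", "A"), class = "m6adscan_reject")
})

test_that("minus-strand alleles are reverse-complemented into the window", {
    w <- mkWindow("-")
    # genomic position 115 is window index 4 (C); VCF alleles are genomic
    v <- variantInWindow(w, 115L, "G", "T")
    expect_equal(v$wStart, 4L)
    expect_equal(v$refW, "C")
    expect_equal(v$altW, "A")
})

test_that("in-frame deletions shorten the alternate window by their length", {
    w <- mkWindow()
    v <- variantInWindow(w, 103L, "GCCT", "G")   # in-frame 3-nt deletion
    alt <- applyVariant(w, v)
    expect_equal(nchar(alt), nchar(windowSeq(w)) - 3L)
    expect_equal(classifyVariant(w, v), "inframe_indel")
})

test_that("coding consequences follow the genetic code anchored at the stop", {
    w <- mkWindow()
    # CCT -> ACT: Pro -> Thr missense
    expect_equal(classifyVariant(w, variantInWindow(w, 104L, "C", "A")),
                 "missense")
    # CCT -> CCA: synonymous
    expect_equal(classifyVariant(w, variantInWindow(w, 106L, "T", "A")),
                 "synonymous")
    # TGC -> TGA: new in-frame stop upstream of the anchor
    expect_equal(classifyVariant(w, variantInWindow(w, 109L, "C", "A")),
                 "nonsense")
    # TAA -> CAA at the frame anchor: stop loss
    expect_equal(classifyVariant(w, variantInWindow(w, 110L, "T", "C")),
                 "stop_loss")
    # TAA -> TGA: stop retained, synonymous
    expect_equal(classifyVariant(w, variantInWindow(w, 111L, "A", "G")),
                 "synonymous")
    # UTR substitution
    expect_equal(classifyVariant(w, variantInWindow(w, 114L, "C", "G")),
                 "utr")
    # 1-nt deletion: frameshift
    expect_equal(classifyVariant(w, variantInWindow(w, 105L, "CT", "C")),
                 "frameshift")
})

test_that("classification is strand-symmetric", {
    wp <- mkWindow("+"); wm <- mkWindow("-")
    # the same window-space change expressed through both strands
    cases <- list(
        list(p = c(104L, "C", "A"), m = c(115L, "G", "T")),
        list(p = c(106L, "T", "A"), m = c(113L, "A", "T")),
        list(p = c(109L, "C", "A"), m = c(110L, "G", "T")))
    for (cs in cases) {
        clsP <- classifyVariant(wp, variantInWindow(
            wp, as.integer(cs$p[1]), cs$p[2], cs$p[3]))
        clsM <- classifyVariant(wm, variantInWindow(
            wm, as.integer(cs$m[1]), cs$m[2], cs$m[3]))
        expect_equal(clsP, clsM)
    }
})

test_that("rejection filters drop the documented classes and DRACH overlaps", {
    w <- mkWindow()
    drach <- scanDrach(windowSeq(w))
    keepCase <- variantInWindow(w, 104L, "C", "A")
    expect_true(filterVariant(keepCase, "missense", drach)$keep)
    expect_true(filterVariant(keepCase, "synonymous", drach)$keep)
    expect_true(filterVariant(keepCase, "utr", drach)$keep)
    for (cls in c("nonsense", "frameshift", "stop_loss")) {
        verdict <- filterVariant(keepCase, cls, drach)
        expect_false(verdict$keep)
        expect_equal(verdict$reason, cls)
    }
    # a variant sitting on a reference DRACH motif is rejected
    sites <- data.frame(index = 1L, start = 3L, seq5 = "GGACT")
    hit <- list(wStart = 5L, wEnd = 5L, refW = "C", altW = "A")
    verdict <- filterVariant(hit, "synonymous", sites)
    expect_false(verdict$keep)
    expect_equal(verdict$reason, "overlaps DRACH")
})

test_that("no kept variant yields a premature stop in the alternate window", {
    res <- pipelineResult("builtin")
    fx <- fixtureBundle()
    for (i in seq_len(nrow(res$records))) {
        r <- res$records[i, ]
        w <- buildWindow(fx$transcripts[[r$transcript_id]], fx$genome)
        v <- fx$variants[fx$variants$variantId == r$variant_id, ]
        viw <- variantInWindow(w, v$pos, v$ref, v$alt)
        alt <- applyVariant(w, viw)
        lenDiff <- nchar(viw$altW) - nchar(viw$refW)
        cds <- paste0(w@upstreamContext, substr(alt, 1, cdsLen(w) + lenDiff))
        cds <- substr(cds, nchar(cds) %% 3L + 1L, nchar(cds))
        aa <- m6adscan:::translateDna(cds)
        expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)),
                     info = r$variant_id)
    }
})
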