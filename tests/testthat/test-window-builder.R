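mkTx <- function(blocks, cds, strand = "+", chrom = "c1", id = "T1") {
    new("TranscriptModel", transcriptId = id, geneSymbol = id,
        chrom = chrom, strand = strand,
        txStart = as.integer(min(IRanges::start(blocks))),
        txEnd = as.integer(max(IRanges::end(blocks))),
        cdsStart = as.integer(cds[1L]), cdsEnd = as.integer(cds[2L]),
        blocks = blocks)
}

test_that("cdsExons intersects blocks with the CDS span", {
    # 0-based half-open blocks [(0,100),(200,300)], CDS [50,250)
    tx <- mkTx(IRanges::IRanges(c(1, 201), c(100, 300)), c(51, 250))
    got <- cdsExons(tx)
    expect_equal(IRanges::start(got), c(51L, 201L))
    expect_equal(IRanges::end(got), c(100L, 250L))

    # single-exon CDS
    tx2 <- mkTx(IRanges::IRanges(1, 300), c(31, 120))
    expect_equal(length(cdsExons(tx2)), 1L)
})

test_that("half-open CDS boundary semantics match a per-base oracle", {
    blocks <- IRanges::IRanges(c(1, 151), c(100, 260))
    tx <- mkTx(blocks, c(81, 151))  # CDS boundary exactly at a block edge
    got <- cdsExons(tx)
    perBase <- integer()
    for (b in seq_len(2)) {
        for (p in IRanges::start(blocks)[b]:IRanges::end(blocks)[b])
            if (p >= 81 && p <= 151) perBase <- c(perBase, p)
    }
    expanded <- unlist(lapply(seq_along(got), function(i)
        IRanges::start(got)[i]:IRanges::end(got)[i]))
    expect_equal(expanded, perBase)
})

test_that("window caps follow the UTR-first rule (250 = 150 CDS + 100 UTR)", {
    fx <- fixtureBundle()
    w <- buildWindow(fx$transcripts[["SYNFILT.1"]], fx$genome)
    expect_equal(utrLen(w), 100L)
    expect_equal(cdsLen(w), 150L)
    expect_equal(nchar(windowSeq(w)), 250L)
    expect_equal(frameAnchor(w), 148L)
    # short 3'UTR: everything available is taken, CDS may exceed 150
    w2 <- buildWindow(fx$transcripts[["SYNEPRS1L.1"]], fx$genome)
    expect_lt(utrLen(w2), 100L)
    expect_equal(nchar(windowSeq(w2)), cdsLen(w2) + utrLen(w2))
    # the CDS portion ends with a stop codon at the frame anchor
    stop2 <- substr(windowSeq(w2), frameAnchor(w2), frameAnchor(w2) + 2L)
    expect_true(stop2 %in% c("TAA", "TAG", "TGA"))
})

test_that("window sequence equals per-base genome lookups on both strands", {
    fx <- fixtureBundle()
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (id in c("SYNEPRS1L.1", "SYNTSC2L.1")) {
        w <- buildWindow(fx$transcripts[[id]], fx$genome)
        chromSeq <- as.character(fx$genome[[w@chrom]])
        expected <- vapply(w@w2g, function(g) {
            b <- substr(chromSeq, g, g)
            if (w@strand == "-") comp[[b]] else b
        }, character(1L))
        expect_equal(strsplit(windowSeq(w), "")[[1L]], unname(expected),
                     info = id)
    }
})

test_that("genomic-window maps are mutual inverses and strictly monotone", {
    fx <- fixtureBundle()
    w <- buildWindow(fx$transcripts[["SYNTSC2L.1"]], fx$genome)
    n <- nchar(windowSeq(w))
    expect_equal(genomicToWindow(w, windowToGenomic(w, seq_len(n))), seq_len(n))
    # minus strand: genomic positions strictly decreasing along the window
    expect_true(all(diff(w@w2g) < 0))
    wp <- buildWindow(fx$transcripts[["SYNEPRS1L.1"]], fx$genome)
    expect_true(all(diff(wp@w2g) > 0))
})

test_that("intronic positions do not map into the window", {
    fx <- fixtureBundle()
    tx <- fx$transcripts[["SYNEPRS1L.1"]]
    w <- buildWindow(tx, fx$genome)
    intronic <- IRanges::end(tx@blocks)[2L] + 5L
    expect_true(is.na(genomicToWindow(w, intronic)))
})

test_that("the planted variant sits 55 nt downstream of the last junction", {
    fx <- fixtureBundle()
    tx <- fx$transcripts[["SYNEPRS1L.1"]]
    w <- buildWindow(tx, fx$genome)
    v <- fx$variants[fx$variants$variantId == "var_switch", ]
    junctionIdx <- genomicToWindow(w, IRanges::end(tx@blocks)[2L])
    expect_equal(genomicToWindow(w, v$pos), junctionIdx + 55L)
})

test_that("transcripts without a terminal stop codon are rejected", {
    fx <- fixtureBundle()
    expect_warning(
        expect_error(buildWindow(fx$transcripts[["SYNNOSTOP.1"]], fx$genome),
                     class = "m6adscan_reject"),
        "no terminal stop")
})

test_that("every fixture window translates to a single terminal stop", {
    fx <- fixtureBundle()
    for (id in c("SYNEPRS1L.1", "SYNVHLL.1", "SYNTSC2L.1", "SYNFILT.1")) {
        w <- buildWindow(fx$transcripts[[id]], fx$genome)
        cds <- paste0(w@upstreamContext, substr(windowSeq(w), 1, cdsLen(w)))
        cds <- substr(cds, nchar(cds) %% 3L + 1L, nchar(cds))
        aa <- m6adscan:::translateDna(cds)
        expect_equal(substr(aa, nchar(aa), nchar(aa)), "*", info = id)
        expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)), info = id)
    }
})
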