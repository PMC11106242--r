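mkFold <- function(seq, db, mfeVal = -10, engine = "builtin") {
    new("FoldResult", seq = chartr("T", "U", seq), db = db, mfe = mfeVal,
        engine = engine, noLonelyPairs = TRUE)
}

test_that("site labels follow the 3-of-5 rule and partition every site", {
    f <- mkFold("AAGGACTAAAA", "(((((......")
    prof <- siteProfile(f, 3L)
    expect_equal(prof$label, "paired")          # 3 of 5 paired

    # all 32 pairing patterns: exactly one label, by pigeonhole
    for (bits in 0:31) {
        flags <- as.logical(bitwAnd(bits, 2^(0:4)))
        db <- paste(ifelse(flags, "(", "."), collapse = "")
        fr <- mkFold("GGACT", db)
        prof <- siteProfile(fr, 1L)
        expect_equal(prof$label,
                     if (sum(flags) >= 3) "paired" else "free")
    }
})

test_that("non-overlapping segment counters match the recursive oracle", {
    for (bits in 0:31) {
        flags <- as.logical(bitwAnd(bits, 2^(0:4)))
        db <- paste(ifelse(flags, "(", "."), collapse = "")
        fr <- mkFold("GGACT", db)
        sites <- data.frame(index = 1L, start = 1L, seq5 = "GGACT")
        got <- segmentCounters(fr, sites)
        expect_equal(got[sort(names(got))],
                     oracleSegmentCounters(flags)[sort(names(got))],
                     info = db)
    }
})

test_that("counter priority follows documented worked cases", {
    sites <- data.frame(index = 1L, start = 1L, seq5 = "GGACT")
    # fully paired motif: paired_DRACH only
    full <- segmentCounters(mkFold("GGACT", "((((("), sites)
    expect_equal(unname(full["paired_DRACH"]), 1L)
    expect_equal(sum(full), 1L)
    # D unpaired, RACH paired: paired_RACH only (leftover D supports nothing)
    part <- segmentCounters(mkFold("GGACT", ".(((("), sites)
    expect_equal(unname(part["paired_RACH"]), 1L)
    expect_equal(sum(part), 1L)
    # alternating: no homogeneous segment at all
    alt <- segmentCounters(mkFold("GGACT", "(.(.("), sites)
    expect_equal(sum(alt), 0L)
    # a free DRAC consumes its positions: no free_DRA / free_RAC double count
    drac <- segmentCounters(mkFold("GGACT", "....("), sites)
    expect_equal(unname(drac["free_DRAC"]), 1L)
    expect_equal(sum(drac), 1L)
})

test_that("counters are additive over sites and bounded by motif length", {
    set.seed(31)
    for (i in 1:20) {
        s <- paste0("CC", paste(sample(c("GGACT", "AAACA", "TGACT"),
                                       3, replace = TRUE), collapse = "CC"))
        f <- fold(paste0(s, "AAAA"), engine = "builtin")
        sites <- scanDrach(f@seq)
        if (nrow(sites) == 0) next
        counters <- segmentCounters(f, sites)
        segLen <- c(DRA = 3, RAC = 3, ACH = 3, DRAC = 4, RACH = 4, DRACH = 5)
        weighted <- sum(counters * segLen[sub("^(free|paired)_", "",
                                              names(counters))])
        expect_lte(weighted, 5L * nrow(sites))
    }
})

test_that("structure diff reports transitions and the absolute-value deltaMFE", {
    seqc <- "AAGGACTAAAAAAGTCCAA"
    f1 <- mkFold(seqc, "..(((((......)))))." , -10)
    f2 <- mkFold(seqc, "...................", -7.5)
    sites <- scanDrach(seqc)
    d <- diffStructures(f1, sites, f2, sites)
    expect_equal(d$deltaMfe, 2.5)
    expect_equal(d$transitions$transition[d$transitions$refStart == 3],
                 "paired->free")

    # identity diff: all transitions none, delta zero
    dId <- diffStructures(f1, sites, f1, sites)
    expect_true(all(dId$transitions$transition == "none"))
    expect_equal(dId$deltaMfe, 0)

    # engines must match
    f3 <- mkFold(seqc, "...................", -7.5, engine = "vienna")
    expect_error(diffStructures(f1, sites, f3, sites), "same engine")
})

test_that("indel offset mapping matches sites downstream of the variant", {
    refSeq <- "AAGGACTAAAAAAAAGGACTAAA"     # motifs at 3 and 16
    altSeq <- "AAGGACTAAAAAGGACTAAA"        # 3-nt deletion at position 9
    refSites <- scanDrach(refSeq)
    altSites <- scanDrach(altSeq)
    fr <- mkFold(refSeq, strrep(".", nchar(refSeq)), 0)
    fa <- mkFold(altSeq, strrep(".", nchar(altSeq)), 0)
    d <- diffStructures(fr, refSites, fa, altSites,
                        list(wStart = 9L, wEnd = 11L, lenDiff = -3L))
    expect_equal(nrow(d$transitions), 2L)
    expect_equal(d$transitions$altStart, c(3L, 13L))
})
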