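# End-to-end orchestration: windows -> variant placement -> filters ->
# folding -> DRACH accessibility scoring -> candidate table.

#' Pipeline configuration
#'
#' @param maxWindow total analysis-window cap in nt (default 250).
#' @param utrCap 3'UTR nucleotides included after the stop codon (default 100).
#' @param cdsSoftCap nominal CDS tail length when the full UTR is available
#'   (default 150 = maxWindow - utrCap); informational, the binding
#'   constraint is \code{maxWindow - utrLen}.
#' @param engine folding engine, \code{"builtin"} or \code{"vienna"}.
#' @param noLonelyPairs forbid isolated base pairs (default TRUE).
#' @param explodeSites one output row per (variant, transcript, m6A site)
#'   triple instead of one per (variant, transcript) with a site list.
#' @param sortKey output order: \code{"transitions"} (number of altered
#'   sites desc, then |deltaMFE| desc) or \code{"none"} (input order).
#' @return validated config list.
#' @export
runConfig <- function(maxWindow = 250L, utrCap = 100L, cdsSoftCap = 150L,
                      engine = c("builtin", "vienna"), noLonelyPairs = TRUE,
                      explodeSites = FALSE, sortKey = c("transitions", "none")) {
    engine <- match.arg(engine)
    sortKey <- match.arg(sortKey)
    stopifnot(maxWindow > 0L, utrCap >= 0L, utrCap <= maxWindow,
              cdsSoftCap > 0L)
    list(maxWindow = as.integer(maxWindow), utrCap = as.integer(utrCap),
         cdsSoftCap = as.integer(cdsSoftCap), engine = engine,
         noLonelyPairs = isTRUE(noLonelyPairs),
         explodeSites = isTRUE(explodeSites), sortKey = sortKey)
}

transitionTokens <- function(transitions) {
    hit <- transitions$transition != "none"
    if (!any(hit)) return("")
    paste(sprintf("%d:%s", transitions$refIndex[hit],
                  transitions$transition[hit]), collapse = ";")
}

#' Run the full variant / m6A-accessibility scan
#'
#' For every variant joined to a validated m6A site on a shared transcript,
#' and whose site falls inside the transcript's analysis window: builds the
#' window, places and classifies the variant, applies the rejection filters
#' (nonsense, frameshift, stop-loss, DRACH-overlap, junction-spanning),
#' folds reference and alternate windows with the configured engine, scores
#' DRACH segment pairing and site transitions, and emits one candidate
#' record per kept (variant, transcript) pair (sites joined into a list
#' column, or exploded with \code{explodeSites}).
#'
#' @param genome \link[Biostrings]{DNAStringSet} from \code{\link{readGenome}}.
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @param variants data.frame from \code{\link{readVariants}}.
#' @param m6aSites data.frame from \code{\link{readM6aSites}}.
#' @param config list from \code{\link{runConfig}}.
#' @return list with \code{records} (data.frame, candidate schema),
#'   \code{rejects} (data.frame variantId/transcriptId/reason) and
#'   \code{summary} (named list of counts).
#' @export
runPipeline <- function(genome, transcripts, variants, m6aSites,
                        config = runConfig()) {
    pairs <- joinVariantsToSites(variants, m6aSites, transcripts)
    if (length(transcripts) == 0L || nrow(variants) == 0L)
        warning("no transcripts or no variants; output table is empty")

    rejects <- data.frame(variantId = character(), transcriptId = character(),
                          reason = character(), stringsAsFactors = FALSE)
    addReject <- function(vid, tid, reason, n = 1L) {
        rejects <<- rbind(rejects, data.frame(
            variantId = rep(vid, n), transcriptId = rep(tid, n),
            reason = rep(reason, n), stringsAsFactors = FALSE))
    }

    windows <- list()   # per-transcript cache (incl. fold of the reference)
    getWindowBundle <- function(tid) {
        if (!is.null(windows[[tid]])) return(windows[[tid]])
        tx <- transcripts[[tid]]
        bundle <- tryCatch({
            w <- buildWindow(tx, genome, config$maxWindow, config$utrCap)
            fr <- fold(w@seq, engine = config$engine,
                       noLonelyPairs = config$noLonelyPairs)
            list(window = w, foldRef = fr, drachRef = scanDrach(w@seq),
                 reason = NA_character_)
        }, m6adscan_reject = function(e) list(reason = conditionMessage(e)))
        windows[[tid]] <<- bundle
        bundle
    }

    rows <- list()
    if (nrow(pairs)) {
        key <- paste(pairs$variantId, pairs$transcriptId, sep = "\r")
        for (grp in split(seq_len(nrow(pairs)), key)) {
            p1 <- pairs[grp[1L], ]
            nSites <- length(grp)
            bundle <- getWindowBundle(p1$transcriptId)
            if (!is.na(bundle$reason)) {
                addReject(p1$variantId, p1$transcriptId, bundle$reason, nSites)
                next
            }
            w <- bundle$window
            siteIdx <- genomicToWindow(w, pairs$sitePos[grp])
            inWin <- !is.na(siteIdx)
            if (any(!inWin))
                addReject(p1$variantId, p1$transcriptId, "site outside window",
                          sum(!inWin))
            if (!any(inWin)) next
            grp <- grp[inWin]

            res <- tryCatch({
                viw <- variantInWindow(w, p1$variantPos, p1$ref, p1$alt)
                cls <- classifyVariant(w, viw)
                verdict <- filterVariant(viw, cls, bundle$drachRef)
                if (!verdict$keep) {
                    addReject(p1$variantId, p1$transcriptId, verdict$reason,
                              length(grp))
                    NULL
                } else {
                    list(viw = viw, cls = cls)
                }
            }, m6adscan_reject = function(e) {
                addReject(p1$variantId, p1$transcriptId, e$reason, length(grp))
                NULL
            })
            if (is.null(res)) next

            viw <- res$viw
            altSeq <- applyVariant(w, viw)
            foldAlt <- fold(altSeq, engine = config$engine,
                            noLonelyPairs = config$noLonelyPairs)
            drachAlt <- scanDrach(altSeq)
            lenDiff <- nchar(viw$altW) - nchar(viw$refW)
            span <- list(wStart = viw$wStart, wEnd = viw$wEnd,
                         lenDiff = lenDiff)
            diff <- diffStructures(bundle$foldRef, bundle$drachRef,
                                   foldAlt, drachAlt, span)
            cRef <- segmentCounters(bundle$foldRef, bundle$drachRef)
            cAlt <- segmentCounters(foldAlt, drachAlt)
            gained <- variantOverlapsDrach(drachAlt, viw$wStart,
                                           viw$wEnd + lenDiff)

            base <- data.frame(
                variant_id = p1$variantId, chrom = w@chrom,
                genomic_pos = p1$variantPos, strand = w@strand,
                gene_symbol = w@geneSymbol, transcript_id = w@transcriptId,
                m6a_site_pos = paste(sort(pairs$sitePos[grp]), collapse = ";"),
                mfe_ref = mfe(bundle$foldRef), mfe_alt = mfe(foldAlt),
                delta_mfe = round(diff$deltaMfe, 2L),
                synonymous_flag = res$cls == "synonymous",
                variant_class = res$cls,
                n_drach_ref = nrow(bundle$drachRef),
                n_drach_alt = nrow(drachAlt),
                stringsAsFactors = FALSE
            )
            for (nm in names(cRef)) {
                parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
                base[[paste0(parts[1L], "_", parts[2L], "_ref")]] <- cRef[[nm]]
            }
            for (nm in names(cAlt)) {
                parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
                base[[paste0(parts[1L], "_", parts[2L], "_alt")]] <- cAlt[[nm]]
            }
            base$gained_motif_at_variant <- gained
            base$transitions <- transitionTokens(diff$transitions)
            base$db_ref <- dotBracket(bundle$foldRef)
            base$db_alt <- dotBracket(foldAlt)
            base$engine <- foldEngine(foldAlt)
            base$n_transitions <- sum(diff$transitions$transition != "none")
            if (config$explodeSites) {
                siteRows <- lapply(sort(pairs$sitePos[grp]), function(sp) {
                    r <- base; r$m6a_site_pos <- as.character(sp); r
                })
                rows <- c(rows, siteRows)
            } else {
                rows[[length(rows) + 1L]] <- base
            }
        }
    }

    records <- if (length(rows)) do.call(rbind, rows) else emptyRecords()
    if (config$sortKey == "transitions" && nrow(records)) {
        ord <- order(-records$n_transitions, -abs(records$delta_mfe),
                     records$variant_id, records$transcript_id)
        records <- records[ord, , drop = FALSE]
        rownames(records) <- NULL
    }

    nKeptPairs <- nrow(pairs) - nrow(rejects)
    summary <- list(
        n_pairs = nrow(pairs),
        n_kept_pairs = nKeptPairs,
        n_rejected_pairs = nrow(rejects),
        rejected_by_reason = if (nrow(rejects))
            as.list(table(rejects$reason)) else list(),
        n_records = nrow(records),
        n_genes = length(unique(records$gene_symbol)),
        n_distinct_variants = length(unique(records$variant_id))
    )
    stopifnot(summary$n_pairs == summary$n_kept_pairs + summary$n_rejected_pairs)
    list(records = records, rejects = rejects, summary = summary)
}

emptyRecords <- function() {
    cols <- c(CANDIDATE_COLUMNS, "db_ref", "db_alt", "engine", "n_transitions")
    out <- lapply(cols, function(x) character())
    names(out) <- cols
    out$genomic_pos <- integer(); out$mfe_ref <- numeric()
    out$mfe_alt <- numeric(); out$delta_mfe <- numeric()
    out$synonymous_flag <- logical(); out$gained_motif_at_variant <- logical()
    out$n_drach_ref <- integer(); out$n_drach_alt <- integer()
    out$n_transitions <- integer()
    for (nm in grep("^(free|paired)_", cols, value = TRUE))
        out[[nm]] <- integer()
    as.data.frame(out, stringsAsFactors = FALSE)
}
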