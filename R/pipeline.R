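#' Read and validate a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{organism}, \code{temperature},
#' \code{treatment}, \code{replicate} and \code{path} (alignment SAM/BAM or
#' pileup TSV per sample). The combination (organism, temperature,
#' treatment, replicate) must be unique and treatments must be one of
#' untreated, NaBH4, CMCT, CMCT_control.
#'
#' @param path Sample sheet path.
#' @return A data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "organism", "temperature", "treatment",
              "replicate")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$treatment),
                   c("untreated", "NaBH4", "CMCT", "CMCT_control"))
    if (length(bad))
        stop("unknown treatment(s): ", paste(bad, collapse = ", "))
    key <- paste(df$organism, df$temperature, df$treatment, df$replicate)
    if (anyDuplicated(key))
        stop("duplicate (organism, temperature, treatment, replicate) rows")
    df
}

## control library paired with each treatment
.controlOf <- c(NaBH4 = "untreated", CMCT = "CMCT_control")

.loadSamplePileups <- function(samples, clusters, min_mapq = 0L) {
    out <- list()
    for (s in seq_len(nrow(samples))) {
        p <- samples$path[s]
        out[[samples$sample_id[s]]] <-
            if (tolower(tools::file_ext(p)) %in% c("sam", "bam"))
                countFromAlignments(p, clusters, min_mapq = min_mapq)
            else readPileupTsv(p)
    }
    out
}

.poolTreatment <- function(samples, pileups, org, temp, trt) {
    sel <- samples$organism == org & samples$temperature == temp &
        samples$treatment == trt
    ids <- samples$sample_id[sel]
    if (!length(ids)) return(NULL)
    cluster_ids <- unique(unlist(lapply(pileups[ids], names)))
    out <- list()
    for (cid in cluster_ids)
        out[[cid]] <- poolPileups(lapply(pileups[ids],
                                         function(x) x[[cid]]))
    out
}

#' Run the full modification-profiling pipeline
#'
#' Orchestrates the analysis per (organism, temperature) group: pools
#' replicates, calls treatment-enriched RT-stop sites per treatment/control
#' pair (NaBH4 vs untreated; CMCT vs its buffer control), classifies
#' passing calls against the known-site catalog, profiles misincorporation
#' signatures on the pooled untreated libraries, and builds the summary
#' table of TP calls per condition.
#'
#' @param samples Sample sheet data.frame (see \code{\link{readSampleSheet}});
#'   needs a \code{path} column unless \code{pileups} is supplied.
#' @param clusters A \code{TRNAClusterSet} with Sprinzl maps.
#' @param pileups Optional preloaded pileups: named list (by sample id) of
#'   named lists of \code{PileupMatrix}.
#' @param catalog Known-site catalog (default \code{\link{defaultCatalog}}).
#' @param params Enrichment thresholds (\code{\link{enrichmentParams}}).
#' @param min_coverage,min_mismatch_fraction Mismatch-profiler gates.
#' @param min_mapq MAPQ threshold when counting from alignments.
#' @param out_dir Optional output directory for TSVs and run metadata.
#' @return List with \code{calls} (classified passing calls),
#'   \code{enrichment} (all tested positions, all treatments),
#'   \code{mismatches} (signature records) and \code{summary} (TP table).
#' @export
runProfile <- function(samples, clusters, pileups = NULL,
                       catalog = defaultCatalog(),
                       params = enrichmentParams(),
                       min_coverage = 10, min_mismatch_fraction = 0.10,
                       min_mapq = 0L, out_dir = NULL) {
    if (is.character(samples)) samples <- readSampleSheet(samples)
    if (is.null(pileups))
        pileups <- .loadSamplePileups(samples, clusters, min_mapq)

    groups <- unique(samples[, c("organism", "temperature")])
    all_records <- list(); all_calls <- list(); all_mm <- list()
    for (g in seq_len(nrow(groups))) {
        org <- groups$organism[g]; temp <- groups$temperature[g]
        gsel <- samples$organism == org & samples$temperature == temp
        trts <- unique(samples$treatment[gsel])
        for (trt in intersect(names(.controlOf), trts)) {
            ctrl <- .controlOf[[trt]]
            if (!ctrl %in% trts)
                stop(sprintf("group %s/%dC has %s libraries but no %s control",
                             org, temp, trt, ctrl))
            treated <- .poolTreatment(samples, pileups, org, temp, trt)
            control <- .poolTreatment(samples, pileups, org, temp, ctrl)
            rec <- callSites(treated, control, clusters, params = params)
            if (nrow(rec) == 0L) next
            rec$treatment <- trt
            rec$organism <- org
            rec$temperature <- temp
            all_records[[length(all_records) + 1L]] <- rec
            passed <- rec[rec$pass, , drop = FALSE]
            if (nrow(passed)) {
                cls <- classifyCalls(passed, trt, catalog)
                all_calls[[length(all_calls) + 1L]] <- cls
            }
        }
        if ("untreated" %in% trts) {
            unt <- .poolTreatment(samples, pileups, org, temp, "untreated")
            for (cid in names(unt)) {
                mm <- profileMismatches(unt[[cid]], clusters,
                                        min_coverage = min_coverage,
                                        min_mismatch_fraction =
                                            min_mismatch_fraction)
                if (nrow(mm) == 0L) next
                mm <- assignSignature(mm)
                mm$organism <- org
                mm$temperature <- temp
                all_mm[[length(all_mm) + 1L]] <- mm
            }
        }
    }
    enrichment <- if (length(all_records)) do.call(rbind, all_records)
                  else DataFrame()
    calls <- if (length(all_calls)) do.call(rbind, all_calls)
             else DataFrame()
    mismatches <- if (length(all_mm)) do.call(rbind, all_mm)
                  else DataFrame()
    summary <- if (nrow(calls)) summarizeCounts(calls)
               else data.frame(site = character(0))

    res <- list(calls = calls, enrichment = enrichment,
                mismatches = mismatches, summary = summary)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (nm in c("calls", "enrichment", "mismatches"))
            utils::write.table(as.data.frame(res[[nm]]),
                               file.path(out_dir, paste0(nm, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(res$summary,
                           file.path(out_dir, "summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        meta <- list(package = "tRNAstopR",
                     version = as.character(utils::packageVersion("tRNAstopR")),
                     thresholds = unclass(params),
                     min_coverage = min_coverage,
                     min_mismatch_fraction = min_mismatch_fraction,
                     replicate_handling = "raw counts pooled before testing",
                     stop_offset = "mod_index = stop_index - 1")
        jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    res
}
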