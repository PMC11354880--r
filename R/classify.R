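#' Default known-site catalog
#'
#' The shipped catalog of tRNA positions where the profiled modifications
#' are documented in bacteria, used to classify enriched RT-stop calls:
#' \itemize{
#'   \item NaBH4 treatment: dihydrouridine (D) at U positions 16, 17, 20,
#'     20a, 20b, 21 and 47; m7G at G46; s4U at U8.
#'   \item CMCT treatment: pseudouridine (Psi) at U positions 13, 31, 32,
#'     38, 39, 40, 55, 60 and 65.
#'   \item CMCT calls at U54 are ambiguous: only m5U (ribothymidine) is
#'     documented there in bacteria, and CMCT is not established to detect
#'     it, so such calls cannot be attributed to Psi.
#' }
#' U positions are matched against reference base T (DNA alphabet). The
#' catalog is an editable table so newly validated sites (the workflow that
#' promoted s4U8 and Psi60 after mass-spectrometry confirmation) can be
#' added by the user.
#'
#' @return A data.frame with columns \code{treatment}, \code{modification},
#'   \code{label}, \code{ref_base}, \code{class} (\code{TP} or
#'   \code{ambiguous}).
#' @export
defaultCatalog <- function() {
    rbind(
        data.frame(treatment = "NaBH4", modification = "D",
                   label = c("16", "17", "20", "20a", "20b", "21", "47"),
                   ref_base = "T", class = "TP"),
        data.frame(treatment = "NaBH4", modification = "m7G",
                   label = "46", ref_base = "G", class = "TP"),
        data.frame(treatment = "NaBH4", modification = "s4U",
                   label = "8", ref_base = "T", class = "TP"),
        data.frame(treatment = "CMCT", modification = "Psi",
                   label = c("13", "31", "32", "38", "39", "40", "55",
                             "60", "65"),
                   ref_base = "T", class = "TP"),
        data.frame(treatment = "CMCT", modification = "m5U",
                   label = "54", ref_base = "T", class = "ambiguous"))
}

#' Read / write a known-site catalog
#'
#' TSV with columns \code{treatment}, \code{modification}, \code{label},
#' \code{ref_base}, \code{class}.
#'
#' @param path File path.
#' @return \code{readCatalog}: the catalog data.frame.
#' @export
readCatalog <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    need <- c("treatment", "modification", "label", "ref_base", "class")
    if (!all(need %in% names(df)))
        stop("catalog must have columns ", paste(need, collapse = ", "))
    df[, need]
}

#' @rdname readCatalog
#' @param catalog Catalog data.frame.
#' @export
writeCatalog <- function(catalog, path) {
    utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## treatment-appropriate target bases: both treatments target U (read as T);
## G is a valid target only under NaBH4 (m7G depurination)
.targetBases <- function(treatment) {
    switch(treatment,
           NaBH4 = c("T", "G"),
           CMCT = "T",
           stop(sprintf("no classification rules for treatment '%s'",
                        treatment)))
}

#' Classify enriched RT-stop calls against the known-site catalog
#'
#' Each passing enrichment record receives exactly one status:
#' \itemize{
#'   \item \code{TP_known}: the (Sprinzl label, reference base) pair matches
#'     a catalog entry for the treatment; the modification is assigned.
#'   \item \code{ambiguous_m5U}: CMCT call at U54, where only m5U is
#'     documented in bacteria.
#'   \item \code{type1_FP}: the reference base is a valid target of the
#'     treatment (U; additionally G under NaBH4) but the position is not in
#'     the catalog -- a stop at a position with no previously known
#'     modification.
#'   \item \code{type2_FP}: the reference base cannot be targeted by the
#'     treatment (C/A under NaBH4; C/A/G under CMCT).
#'   \item \code{shadow}: a would-be FP at position 45 in a cluster that
#'     also carries a TP m7G46 call; such stops occur only when m7G46 is
#'     present and are tallied separately.
#' }
#'
#' @param records \code{DataFrame} of passing enrichment records
#'   (\code{\link{callSites}} rows with \code{pass == TRUE}).
#' @param treatment \code{"NaBH4"} or \code{"CMCT"}.
#' @param catalog Catalog data.frame (default \code{\link{defaultCatalog}}).
#' @return The records with \code{modification} and \code{status} columns.
#' @export
classifyCalls <- function(records, treatment, catalog = defaultCatalog()) {
    if (nrow(records) == 0L) {
        records$modification <- character(0)
        records$status <- character(0)
        return(records)
    }
    if (any(is.na(records$sprinzl_label)))
        stop("records with unassigned Sprinzl labels cannot be classified")
    cat_t <- catalog[catalog$treatment == treatment & catalog$class == "TP", ]
    amb_t <- catalog[catalog$treatment == treatment &
                     catalog$class == "ambiguous", ]
    targets <- .targetBases(treatment)

    n <- nrow(records)
    modification <- rep(NA_character_, n)
    status <- character(n)
    key <- paste(records$sprinzl_label, records$ref_base)
    tp_key <- paste(cat_t$label, cat_t$ref_base)
    amb_key <- paste(amb_t$label, amb_t$ref_base)
    hit <- match(key, tp_key)
    for (i in seq_len(n)) {
        if (!is.na(hit[i])) {
            status[i] <- "TP_known"
            modification[i] <- cat_t$modification[hit[i]]
        } else if (key[i] %in% amb_key) {
            status[i] <- "ambiguous_m5U"
        } else if (records$ref_base[i] %in% targets) {
            status[i] <- "type1_FP"
        } else {
            status[i] <- "type2_FP"
        }
    }
    ## shadow sites: FP at 45 next to a TP m7G46 in the same cluster
    m7g_clusters <- unique(records$cluster_id[status == "TP_known" &
                                              !is.na(modification) &
                                              modification == "m7G" &
                                              records$sprinzl_label == "46"])
    shadow <- records$sprinzl_label == "45" &
        status %in% c("type1_FP", "type2_FP") &
        records$cluster_id %in% m7g_clusters
    status[shadow] <- "shadow"

    records$modification <- modification
    records$status <- status
    records
}

#' Summarize TP calls per modification position and sample condition
#'
#' Produces the per-condition overview: rows are modification + Sprinzl
#' label (e.g. \code{s4U8}, \code{D17}, \code{Psi55}), columns are
#' (organism, temperature) conditions, and each cell counts the distinct
#' tRNA clusters carrying a TP call -- replicate or duplicate calls of the
#' same cluster count once. Absent entries render as \code{"-"}.
#'
#' @param calls Classified call table (rbind of \code{\link{classifyCalls}}
#'   outputs) with added \code{organism} and \code{temperature} columns.
#' @return A data.frame of character cells, one column per condition.
#' @export
summarizeCounts <- function(calls) {
    calls <- as.data.frame(calls)
    tp <- calls[calls$status == "TP_known", , drop = FALSE]
    if (nrow(tp) == 0L)
        return(data.frame(site = character(0)))
    tp$site <- paste0(tp$modification, tp$sprinzl_label)
    tp$condition <- paste0(tp$organism, "_", tp$temperature, "C")
    combos <- unique(tp[, c("site", "condition", "cluster_id")])
    tab <- table(combos$site, combos$condition)
    out <- as.data.frame.matrix(tab)
    out[] <- lapply(out, function(col) ifelse(col == 0, "-",
                                              as.character(col)))
    cbind(site = rownames(out), out, row.names = NULL)
}

#' Compare two modification callsets
#'
#' Set algebra over callset keys (conventionally isoacceptor family +
#' anticodon + Sprinzl label + modification, counted uniquely), as used to
#' compare against an independent caller's output.
#'
#' @param a,b Character vectors of callset keys.
#' @return List with sizes \code{n_both}, \code{n_only_a}, \code{n_only_b}
#'   and the membership vectors \code{both}, \code{only_a}, \code{only_b}.
#' @examples
#' compareCallsets(c("x", "y"), c("y", "z"))
#' @export
compareCallsets <- function(a, b) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    both <- intersect(a, b)
    only_a <- setdiff(a, b)
    only_b <- setdiff(b, a)
    list(n_both = length(both), n_only_a = length(only_a),
         n_only_b = length(only_b),
         both = both, only_a = only_a, only_b = only_b)
}
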