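#' Parameters of the RT-stop enrichment test
#'
#' Bundles the thresholds of the site-calling chain. Defaults follow the
#' method's published operating point: FDR-adjusted p below 0.01, log2 fold
#' change above 1, at least 20 pooled RT-stops, and at least 2 percent of
#' covering reads stopping.
#'
#' @param fdr FDR threshold on BH-adjusted p-values (calls require
#'   \code{qvalue < fdr}).
#' @param min_log2fc Log2 fold-change threshold (calls require
#'   \code{log2fc > min_log2fc}).
#' @param min_stops Minimum pooled treated RT-stop count (\code{>=}).
#' @param min_stop_percent Minimum percentage of covering treated reads
#'   that stop at the position (\code{>=}).
#' @param alpha Pseudocount added symmetrically in the fold change.
#' @param literal_eq3 Debug flag: use the literal \code{1 - pmf(k)} reading
#'   of the published p-value formula instead of the upper-tail survival
#'   function (see \code{\link{poissonSfPvalue}}).
#' @return A named list of class \code{enrichment_params}.
#' @export
enrichmentParams <- function(fdr = 0.01, min_log2fc = 1, min_stops = 20,
                             min_stop_percent = 2, alpha = 1,
                             literal_eq3 = FALSE) {
    stopifnot(fdr > 0, fdr <= 1, min_stops >= 0, min_stop_percent >= 0,
              min_stop_percent <= 100, alpha > 0)
    structure(list(fdr = fdr, min_log2fc = min_log2fc,
                   min_stops = min_stops,
                   min_stop_percent = min_stop_percent, alpha = alpha,
                   literal_eq3 = literal_eq3),
              class = "enrichment_params")
}

#' Per-cluster scaling ratio gamma
#'
#' Ratio of reads assigned to the cluster in the treated library to reads
#' assigned in the control library; the control stop counts are multiplied
#' by gamma to put them on the treated library's scale. Computed per
#' cluster, so differences in cluster expression do not leak between tRNAs.
#'
#' @param treated,control \code{PileupMatrix} objects for the same cluster.
#' @return The scaling ratio, or \code{NA} (with a warning) when the
#'   control cluster has zero reads.
#' @export
clusterGamma <- function(treated, control) {
    stopifnot(is(treated, "PileupMatrix"), is(control, "PileupMatrix"))
    if (!identical(treated@cluster_id, control@cluster_id))
        stop("treated and control pileups belong to different clusters")
    nplus <- assignedReads(treated)
    nminus <- assignedReads(control)
    if (nminus == 0L) {
        warning(sprintf("cluster '%s': zero control reads, gamma undefined",
                        treated@cluster_id))
        return(NA_real_)
    }
    nplus / nminus
}

#' Pseudocounted treated/control fold change
#'
#' \code{FC = (stop_plus + alpha) / (gamma * stop_minus + alpha)} with the
#' pseudocount \code{alpha} (default 1) applied symmetrically to handle
#' zero counts; \code{gamma} scales only the control side.
#'
#' @param stop_plus Treated RT-stop count(s).
#' @param stop_minus Control RT-stop count(s).
#' @param gamma Cluster scaling ratio.
#' @param alpha Pseudocount (default 1).
#' @return Fold change(s), strictly positive.
#' @examples
#' foldChange(39, 0, 1)   # 40: zero control stops
#' foldChange(10, 5, 2)   # 1:  stop_plus equals gamma * stop_minus
#' @export
foldChange <- function(stop_plus, stop_minus, gamma, alpha = 1) {
    stopifnot(all(stop_plus >= 0), all(stop_minus >= 0), all(gamma > 0),
              alpha > 0)
    (stop_plus + alpha) / (gamma * stop_minus + alpha)
}

#' Upper-tail Poisson p-value for an RT-stop count
#'
#' Probability of observing \code{k} or more read 5' ends under the
#' background Poisson process with rate \code{lam} (the gamma-scaled
#' control stop count at the same position): \code{P(X >= k) =
#' 1 - CDF(k - 1; lam)}, computed via the numerically stable survival
#' function. \code{k = 0} gives 1 (the whole support).
#'
#' With \code{literal = TRUE} the function instead returns
#' \code{1 - pmf(k; lam)}, a debug rendering of the point-mass complement
#' that is not a tail probability; it is provided only for comparison.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lam Background rate(s), non-negative.
#' @param literal Use the point-mass complement instead of the tail.
#' @return P-value(s) in [0, 1].
#' @export
poissonSfPvalue <- function(k, lam, literal = FALSE) {
    if (any(lam < 0)) stop("lam must be non-negative")
    if (any(k < 0)) stop("k must be non-negative")
    if (literal)
        return(1 - stats::dpois(k, lam))
    stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment, capped at 1, preserving the input order.
#' Applied jointly over all tested positions of a treated/control pair.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Apply the noise filters to an enrichment table
#'
#' Sets the four pass flags and the overall \code{pass} column: a site
#' passes iff \code{qvalue < fdr}, \code{log2fc > min_log2fc},
#' \code{stop_plus >= min_stops} and \code{stop_percent >=
#' min_stop_percent}.
#'
#' @param records \code{DataFrame} as produced by \code{\link{callSites}}.
#' @param params An \code{\link{enrichmentParams}} list.
#' @return The table with \code{pass_fdr}, \code{pass_fc},
#'   \code{pass_count}, \code{pass_percent} and \code{pass} columns set.
#' @export
applyNoiseFilters <- function(records, params = enrichmentParams()) {
    records$pass_fdr <- records$qvalue < params$fdr
    records$pass_fc <- records$log2fc > params$min_log2fc
    records$pass_count <- records$stop_plus >= params$min_stops
    records$pass_percent <- records$stop_percent >= params$min_stop_percent
    records$pass <- records$pass_fdr & records$pass_fc &
        records$pass_count & records$pass_percent
    records
}

#' Call treatment-enriched RT-stop sites
#'
#' For every cluster position covered in both conditions this computes the
#' per-cluster scaling ratio gamma, the pseudocounted fold change, the
#' upper-tail Poisson p-value against the gamma-scaled control background,
#' BH-adjusted q-values across all tested positions, the noise-filter
#' flags, and shifts the stop position to the modification position: the
#' reverse transcriptase mostly terminates one position 3' of the modified
#' nucleotide (the template is read 3' to 5'), so \code{mod_index =
#' stop_index - 1}. Stops at index 0 have no upstream base and yield no
#' candidate.
#'
#' @param treated,control Named lists of \code{PileupMatrix} pooled over
#'   replicates, keyed by cluster id; clusters present in only one
#'   condition are skipped with a warning, as are clusters with zero
#'   control reads.
#' @param clusters A \code{TRNAClusterSet} with Sprinzl maps (labels are
#'   reported as \code{NA} where unassigned).
#' @param params An \code{\link{enrichmentParams}} list.
#' @param all_sites Keep non-passing rows (default TRUE; filter on the
#'   \code{pass} column for the callset).
#' @return A \code{DataFrame}, one row per tested position, with the raw
#'   and scaled counts, gamma, lambda, fold change, p/q-values, stop
#'   percentage and filter flags.
#' @export
callSites <- function(treated, control, clusters,
                      params = enrichmentParams(), all_sites = TRUE) {
    common <- intersect(names(treated), names(control))
    only <- c(setdiff(names(treated), names(control)),
              setdiff(names(control), names(treated)))
    if (length(only))
        warning("clusters present in only one condition skipped: ",
                paste(only, collapse = ", "))
    rows <- list()
    for (id in common) {
        tp <- treated[[id]]; cp <- control[[id]]
        gamma <- suppressWarnings(clusterGamma(tp, cp))
        if (is.na(gamma)) {
            warning(sprintf("cluster '%s': zero control reads, skipped", id))
            next
        }
        L <- nchar(tp@ref)
        if (L < 2L) next
        idx <- 2:L                       # 1-based; stop_index0 = idx - 1 >= 1
        covered <- tp@coverage[idx] > 0L & cp@coverage[idx] > 0L
        idx <- idx[covered]
        if (!length(idx)) next
        sp <- sprinzlMap(clusters, id)
        refchars <- strsplit(tp@ref, "")[[1]]
        stop_plus <- tp@stop5[idx]
        stop_minus <- cp@stop5[idx]
        ## the pseudocount enters the test consistently on both sides:
        ## k includes it and so does the background rate, which keeps
        ## zero-count control positions from degenerating (a rate of
        ## exactly 0 would make any treated stop infinitely significant)
        lam <- pmax(gamma * stop_minus + params$alpha, 1e-9)
        fc <- foldChange(stop_plus, stop_minus, gamma, params$alpha)
        rows[[id]] <- DataFrame(
            cluster_id = id,
            stop_index = idx - 1L,
            mod_index = idx - 2L,
            sprinzl_label = if (is.null(sp)) NA_character_ else sp[idx - 1L],
            ref_base = refchars[idx - 1L],
            stop_plus = stop_plus,
            stop_minus = stop_minus,
            gamma = gamma,
            lam = lam,
            fc = fc,
            log2fc = log2(fc),
            pvalue = poissonSfPvalue(stop_plus + params$alpha, lam,
                                     literal = params$literal_eq3),
            stop_percent = 100 * stop_plus / tp@coverage[idx])
    }
    if (!length(rows)) {
        warning("no testable positions")
        return(DataFrame())
    }
    res <- do.call(rbind, unname(rows))
    res$qvalue <- bhAdjust(res$pvalue)
    res$n_stops_total <- res$stop_plus
    res <- applyNoiseFilters(res, params)
    if (!all_sites)
        res <- res[res$pass, , drop = FALSE]
    res
}
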