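#' Profile base-misincorporation sites in an untreated library
#'
#' Some modifications need no chemical treatment to be seen: they leave a
#' mismatch signature in the untreated mapping profile (inosine 34 reads as
#' G at a genomic A; m1A22 reads as G or T; m1G37 accumulates mixed
#' mismatches). This profiler emits one record per position whose coverage
#' is at least \code{min_coverage} and whose mismatch fraction is at least
#' \code{min_mismatch_fraction}; positions below either gate are
#' suppressed. Per-base fractions are relative to the confident aligned
#' base calls at the position, and a one-sided binomial test against a 1
#' percent sequencing-error rate is reported alongside to flag mismatch
#' excess beyond noise.
#'
#' @param p A \code{PileupMatrix} (untreated sample, replicates pooled).
#' @param clusters A \code{TRNAClusterSet} supplying Sprinzl labels.
#' @param min_coverage Minimum read coverage (default 10).
#' @param min_mismatch_fraction Minimum mismatch fraction (default 0.10).
#' @return A \code{DataFrame} with columns \code{cluster_id},
#'   \code{index0}, \code{sprinzl_label}, \code{ref_base}, \code{coverage},
#'   \code{fA}, \code{fC}, \code{fG}, \code{fT}, \code{mismatch_fraction},
#'   \code{binom_p} and \code{signature} (initially \code{unassigned}).
#' @export
profileMismatches <- function(p, clusters, min_coverage = 10,
                              min_mismatch_fraction = 0.10) {
    stopifnot(is(p, "PileupMatrix"))
    L <- nchar(p@ref)
    refchars <- strsplit(p@ref, "")[[1]]
    sp <- sprinzlMap(clusters, p@cluster_id)
    n <- rowSums(p@baseCounts)
    frac <- p@baseCounts / pmax(n, 1L)
    ref_idx <- cbind(seq_len(L), match(refchars, c("A", "C", "G", "T")))
    fref <- frac[ref_idx]
    fref[is.na(fref)] <- 0           # ambiguous reference base
    mismatch <- ifelse(n > 0, 1 - fref, 0)
    mis_n <- n - p@baseCounts[ref_idx]

    keep <- p@coverage >= min_coverage & mismatch >= min_mismatch_fraction &
        n > 0
    if (!any(keep))
        return(DataFrame())
    idx <- which(keep)
    DataFrame(
        cluster_id = p@cluster_id,
        index0 = idx - 1L,
        sprinzl_label = if (is.null(sp)) NA_character_ else sp[idx],
        ref_base = refchars[idx],
        coverage = p@coverage[idx],
        fA = frac[idx, "A"], fC = frac[idx, "C"],
        fG = frac[idx, "G"], fT = frac[idx, "T"],
        mismatch_fraction = mismatch[idx],
        binom_p = stats::pbinom(mis_n[idx] - 1L, n[idx], 0.01,
                                lower.tail = FALSE),
        signature = "unassigned")
}

#' Assign misincorporation signatures to mismatch records
#'
#' Applies the catalog of mismatch-visible modifications:
#' \itemize{
#'   \item \code{inosine_A34}: Sprinzl 34, genomic A, G fraction above 0.99
#'     (enzymatic A-to-I editing; inosine pairs with C so it reads as G);
#'   \item \code{m1A22}: Sprinzl 22, genomic A, with G and T dominating the
#'     mismatching calls;
#'   \item \code{m1G37}: Sprinzl 37, genomic G, any mismatch accumulation
#'     above the profiler threshold.
#' }
#' Everything else stays \code{unassigned}.
#'
#' @param records \code{DataFrame} from \code{\link{profileMismatches}}.
#' @return The records with the \code{signature} column filled in.
#' @export
assignSignature <- function(records) {
    if (nrow(records) == 0L) return(records)
    sig <- rep("unassigned", nrow(records))
    lab <- records$sprinzl_label
    refb <- records$ref_base

    ino <- !is.na(lab) & lab == "34" & refb == "A" & records$fG > 0.99
    sig[ino] <- "inosine_A34"

    gt_dominant <- (records$fG + records$fT) >
        0.5 * records$mismatch_fraction
    m1a <- !is.na(lab) & lab == "22" & refb == "A" & gt_dominant & !ino
    sig[m1a] <- "m1A22"

    m1g <- !is.na(lab) & lab == "37" & refb == "G"
    sig[m1g] <- "m1G37"

    records$signature <- sig
    records
}
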