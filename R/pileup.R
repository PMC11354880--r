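#' Normalized per-position stop and coverage tracks
#'
#' Library-size scaled (and possibly replicate-averaged) real-valued tracks,
#' used for visualization and QC. The enrichment test itself consumes raw
#' pooled counts (its gamma scaling performs the between-sample
#' normalization; applying both would double-correct).
#'
#' @slot cluster_id Cluster identifier.
#' @slot stop Numeric per-position scaled RT-stop track.
#' @slot coverage Numeric per-position scaled coverage track.
#' @export
setClass("NormalizedProfile",
    representation(cluster_id = "character", stop = "numeric",
                   coverage = "numeric"))

setValidity("NormalizedProfile", function(object) {
    if (length(object@stop) != length(object@coverage))
        return("stop and coverage tracks must have equal length")
    if (any(object@stop < 0) || any(object@coverage < 0))
        return("tracks must be non-negative")
    TRUE
})

.ensureBam <- function(file) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "sam") {
        dest <- tempfile(fileext = ".bam")
        Rsamtools::asBam(file, sub("\\.bam$", "", dest),
                         overwrite = TRUE, indexDestination = TRUE)
        dest
    } else {
        if (!file.exists(paste0(file, ".bai")))
            Rsamtools::indexBam(file)
        file
    }
}

#' Count coverage, RT-stops and base composition from alignments
#'
#' Converts single-end alignments against the cluster FASTA into one
#' \code{\link{PileupMatrix}} per cluster. For each primary, non-supplementary
#' alignment with \code{MAPQ >= min_mapq}: the read's reference-leftmost
#' aligned index increments \code{stop5} (the reverse transcriptase runs
#' 3' to 5' on the template, so the cDNA's last synthesized base -- the
#' read 5' end -- marks the arrest position), every reference index the
#' alignment spans (including deletions) increments \code{coverage}, and
#' aligned base calls with Phred quality >= 20 increment \code{baseCounts}.
#' Soft-clipped bases are ignored throughout; the clip boundary defines the
#' 5'-most aligned index.
#'
#' @param file SAM or BAM path; reference names must be cluster ids.
#' @param clusters A \code{TRNAClusterSet} the alignments were made against.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return Named list of \code{PileupMatrix}, one per cluster (clusters
#'   without reads get zero counts). An alignment file without usable reads
#'   returns an empty list with a warning.
#' @export
countFromAlignments <- function(file, clusters, min_mapq = 0L) {
    bam <- .ensureBam(file)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq",
                                     mapqFilter = min_mapq)
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    if (length(gal) == 0L) {
        warning("no usable alignments in ", file)
        return(stats::setNames(list(), character(0)))
    }
    refs <- as.character(GenomicAlignments::seqnames(gal))
    unknown <- setdiff(unique(refs), clusterIds(clusters))
    if (length(unknown))
        stop("alignment references not in the cluster set: ",
             paste(unknown, collapse = ", "))
    total <- length(gal)

    cov <- GenomicAlignments::coverage(gal)  # includes deletion ops
    starts0 <- GenomicAlignments::start(gal) - 1L

    pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                                 min_base_quality = 20L,
                                 min_mapq = as.integer(min_mapq),
                                 min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = TRUE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    pup <- Rsamtools::pileup(bam,
                             scanBamParam = Rsamtools::ScanBamParam(flag = flag),
                             pileupParam = pp)

    out <- list()
    widths <- Biostrings::width(clusterSequences(clusters))
    names(widths) <- clusterIds(clusters)
    for (id in clusterIds(clusters)) {
        L <- widths[[id]]
        coverage <- if (id %in% names(cov)) {
            v <- as.integer(cov[[id]])
            c(v, integer(max(0L, L - length(v))))[seq_len(L)]
        } else integer(L)
        stop5 <- integer(L)
        sel <- refs == id
        if (any(sel)) {
            t5 <- table(starts0[sel])
            idx <- as.integer(names(t5)) + 1L
            stop5[idx] <- as.integer(t5)
        }
        bc <- matrix(0L, nrow = L, ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
        psel <- pup$seqnames == id & pup$nucleotide %in% c("A", "C", "G", "T")
        if (any(psel)) {
            sub <- pup[psel, , drop = FALSE]
            ij <- cbind(sub$pos,
                        match(as.character(sub$nucleotide),
                              c("A", "C", "G", "T")))
            bc[ij] <- bc[ij] + as.integer(sub$count)
        }
        out[[id]] <- newPileupMatrix(
            id, as.character(clusterSequences(clusters)[[id]]),
            coverage, stop5, bc, totalMappedReads = total)
    }
    out
}

#' Write pileup matrices to TSV
#'
#' One row per cluster position with columns \code{cluster_id},
#' \code{index0}, \code{ref_base}, \code{coverage}, \code{stop5},
#' \code{nA}, \code{nC}, \code{nG}, \code{nT}. The sample's total mapped
#' read count is stored in a \code{#total_mapped_reads=} header comment so
#' the round trip is lossless.
#'
#' @param pileups Named list of \code{PileupMatrix} (one sample).
#' @param path Output TSV path.
#' @export
writePileupTsv <- function(pileups, path) {
    total <- if (length(pileups)) pileups[[1]]@totalMappedReads else 0
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#total_mapped_reads=%.10g", total), con)
    writeLines(paste(c("cluster_id", "index0", "ref_base", "coverage",
                       "stop5", "nA", "nC", "nG", "nT"), collapse = "\t"),
               con)
    for (p in pileups) {
        L <- nchar(p@ref)
        df <- data.frame(cluster_id = p@cluster_id, index0 = seq_len(L) - 1L,
                         ref_base = strsplit(p@ref, "")[[1]],
                         coverage = p@coverage, stop5 = p@stop5,
                         nA = p@baseCounts[, "A"], nC = p@baseCounts[, "C"],
                         nG = p@baseCounts[, "G"], nT = p@baseCounts[, "T"])
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read pileup matrices from TSV
#'
#' Inverse of \code{\link{writePileupTsv}}. Count invariants (non-negative,
#' \code{stop5 <= coverage}) are validated and violations raise an error.
#'
#' @param path TSV path.
#' @return Named list of \code{PileupMatrix}.
#' @export
readPileupTsv <- function(path) {
    first <- readLines(path, n = 1L)
    total <- 0
    if (grepl("^#total_mapped_reads=", first))
        total <- as.numeric(sub("^#total_mapped_reads=", "", first))
    df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                            colClasses = c("character", "integer", "character",
                                           "integer", "integer", "integer",
                                           "integer", "integer", "integer"))
    if (nrow(df) == 0L)
        return(stats::setNames(list(), character(0)))
    out <- list()
    for (id in unique(df$cluster_id)) {
        sub <- df[df$cluster_id == id, ]
        sub <- sub[order(sub$index0), ]
        if (!identical(sub$index0, seq_len(nrow(sub)) - 1L))
            stop(sprintf("pileup TSV for '%s': index0 not contiguous from 0", id))
        if (any(sub$coverage < 0) || any(sub$stop5 < 0))
            stop(sprintf("pileup TSV for '%s': negative counts", id))
        if (any(sub$stop5 > sub$coverage))
            stop(sprintf("pileup TSV for '%s': stop5 exceeds coverage", id))
        out[[id]] <- newPileupMatrix(
            id, paste(sub$ref_base, collapse = ""), sub$coverage, sub$stop5,
            cbind(A = sub$nA, C = sub$nC, G = sub$nG, T = sub$nT),
            totalMappedReads = total)
    }
    out
}

#' Library-size normalization of one pileup
#'
#' Scales the stop and coverage tracks to a common library size:
#' each track is multiplied by \code{scale_to / totalMappedReads}.
#'
#' @param p A \code{PileupMatrix}.
#' @param scale_to Target library size (default 1e6, i.e. counts per
#'   million mapped reads).
#' @return A \code{\link{NormalizedProfile}}.
#' @export
normalizeLibrary <- function(p, scale_to = 1e6) {
    stopifnot(is(p, "PileupMatrix"))
    if (p@totalMappedReads <= 0)
        stop("cannot normalize a sample with zero total mapped reads")
    f <- scale_to / p@totalMappedReads
    new("NormalizedProfile", cluster_id = p@cluster_id,
        stop = p@stop5 * f, coverage = p@coverage * f)
}

#' Position-wise mean of replicate profiles
#'
#' @param profiles List of \code{NormalizedProfile} for the same cluster.
#' @return A \code{NormalizedProfile} of position-wise arithmetic means.
#' @export
replicateMean <- function(profiles) {
    stopifnot(length(profiles) >= 1L)
    id <- profiles[[1]]@cluster_id
    L <- length(profiles[[1]]@stop)
    for (p in profiles) {
        if (!identical(p@cluster_id, id))
            stop("replicate profiles belong to different clusters")
        if (length(p@stop) != L)
            stop("replicate profiles have different lengths")
    }
    new("NormalizedProfile", cluster_id = id,
        stop = Reduce(`+`, lapply(profiles, slot, "stop")) / length(profiles),
        coverage = Reduce(`+`, lapply(profiles, slot, "coverage")) /
            length(profiles))
}

#' Pool raw counts across replicate pileups
#'
#' Sums coverage, stop and base counts position-wise; total mapped reads are
#' summed as well. The enrichment test consumes pooled raw counts.
#'
#' @param pileups List of \code{PileupMatrix} for the same cluster.
#' @return A pooled \code{PileupMatrix}.
#' @export
poolPileups <- function(pileups) {
    stopifnot(length(pileups) >= 1L)
    p1 <- pileups[[1]]
    for (p in pileups[-1]) {
        if (!identical(p@cluster_id, p1@cluster_id) ||
            !identical(p@ref, p1@ref))
            stop("cannot pool pileups of different clusters")
    }
    newPileupMatrix(
        p1@cluster_id, p1@ref,
        Reduce(`+`, lapply(pileups, slot, "coverage")),
        Reduce(`+`, lapply(pileups, slot, "stop5")),
        Reduce(`+`, lapply(pileups, slot, "baseCounts")),
        totalMappedReads = sum(vapply(pileups, slot, 0, "totalMappedReads")))
}
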