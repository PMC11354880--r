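#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet
NULL

#' Set of identical-sequence tRNA clusters
#'
#' A \code{TRNAClusterSet} groups tRNA genes whose mature sequences are
#' identical into clusters, each with one representative sequence, an optional
#' dot-bracket secondary structure and an optional Sprinzl coordinate map.
#' Clustering identical sequences sidesteps the multi-mapping problem created
#' by the multi-copy nature of tRNA genes: each cluster is one mapping
#' reference.
#'
#' @slot sequences A \code{DNAStringSet} of representative mature sequences,
#'   one per cluster, named by \code{cluster_id}.
#' @slot members Named list; for each cluster the character vector of member
#'   \code{gene_id}s.
#' @slot isotype Named character vector of amino-acid isotypes per cluster.
#' @slot anticodon Named character vector of anticodons (DNA alphabet).
#' @slot structure Named character vector of dot-bracket structures
#'   (\code{NA} where no member carried one).
#' @slot sprinzl Named list of Sprinzl label vectors (character, one label
#'   per 0-based sequence index); \code{NULL} entries mean unassigned.
#'
#' @seealso \code{\link{buildClusters}}, \code{\link{assignSprinzl}}
#' @export
setClass("TRNAClusterSet",
    representation(
        sequences = "DNAStringSet",
        members = "list",
        isotype = "character",
        anticodon = "character",
        structure = "character",
        sprinzl = "list"
    )
)

setValidity("TRNAClusterSet", function(object) {
    ids <- names(object@sequences)
    if (is.null(ids) || anyDuplicated(ids))
        return("cluster ids must be unique, non-NULL names on 'sequences'")
    for (slotnm in c("members", "isotype", "anticodon", "structure", "sprinzl")) {
        x <- slot(object, slotnm)
        if (!identical(names(x), ids))
            return(sprintf("names of '%s' must match cluster ids", slotnm))
    }
    widths <- Biostrings::width(object@sequences)
    for (i in seq_along(ids)) {
        sp <- object@sprinzl[[i]]
        if (!is.null(sp) && length(sp) != widths[i])
            return(sprintf("sprinzl map of '%s' has length %d, sequence %d",
                           ids[i], length(sp), widths[i]))
    }
    TRUE
})

#' Per-cluster pileup of coverage, RT-stop 5' ends and base composition
#'
#' A \code{PileupMatrix} holds, for one tRNA cluster in one sequencing
#' library, the per-position read coverage, the counts of read 5' ends
#' (RT-stop signal: the reverse transcriptase falls off so the cDNA 3' end,
#' i.e. the read's reference-leftmost aligned base, marks the arrest), and
#' aligned base counts used for misincorporation profiling.
#'
#' @slot cluster_id Cluster identifier.
#' @slot ref Reference (mature tRNA) sequence of the cluster, DNA alphabet.
#' @slot coverage Integer vector, reads overlapping each 0-based index.
#' @slot stop5 Integer vector, reads whose 5'-most aligned index equals i.
#' @slot baseCounts Integer matrix L x 4 with columns A, C, G, T.
#' @slot totalMappedReads Total mapped reads in the sample (all clusters),
#'   used for library-size normalization.
#'
#' @export
setClass("PileupMatrix",
    representation(
        cluster_id = "character",
        ref = "character",
        coverage = "integer",
        stop5 = "integer",
        baseCounts = "matrix",
        totalMappedReads = "numeric"
    )
)

setValidity("PileupMatrix", function(object) {
    L <- nchar(object@ref)
    if (length(object@coverage) != L || length(object@stop5) != L)
        return("coverage and stop5 must have one entry per reference position")
    if (!identical(colnames(object@baseCounts), c("A", "C", "G", "T")))
        return("baseCounts must have columns A, C, G, T")
    if (nrow(object@baseCounts) != L)
        return("baseCounts must have one row per reference position")
    if (any(object@coverage < 0) || any(object@stop5 < 0) ||
        any(object@baseCounts < 0))
        return("counts must be non-negative")
    if (any(object@stop5 > object@coverage))
        return("stop5 cannot exceed coverage")
    if (any(rowSums(object@baseCounts) > object@coverage))
        return("per-position base counts cannot exceed coverage")
    TRUE
})

#' @describeIn TRNAClusterSet Number of clusters.
#' @param x,object A \code{TRNAClusterSet}.
#' @export
setMethod("length", "TRNAClusterSet", function(x) length(x@sequences))

#' Cluster identifiers
#' @param x A \code{TRNAClusterSet}.
#' @return Character vector of cluster ids.
#' @export
clusterIds <- function(x) names(x@sequences)

#' Representative cluster sequences
#' @param x A \code{TRNAClusterSet}.
#' @return \code{DNAStringSet} named by cluster id.
#' @export
clusterSequences <- function(x) x@sequences

#' Member gene ids per cluster
#' @param x A \code{TRNAClusterSet}.
#' @return Named list of character vectors.
#' @export
clusterMembers <- function(x) x@members

#' Sprinzl label vector of one cluster
#' @param x A \code{TRNAClusterSet}.
#' @param cluster_id Cluster identifier.
#' @return Character vector of labels, or \code{NULL} if unassigned.
#' @export
sprinzlMap <- function(x, cluster_id) x@sprinzl[[cluster_id]]

setMethod("show", "TRNAClusterSet", function(object) {
    n <- length(object)
    cat("TRNAClusterSet with", n, "cluster(s)\n")
    if (n > 0L) {
        nmem <- lengths(object@members)
        assigned <- sum(!vapply(object@sprinzl, is.null, logical(1)))
        cat("  genes:", sum(nmem), "| length range:",
            paste(range(Biostrings::width(object@sequences)), collapse = "-"),
            "nt | Sprinzl maps assigned:", assigned, "/", n, "\n")
        head_ids <- utils::head(clusterIds(object), 5L)
        cat("  ids:", paste(head_ids, collapse = ", "),
            if (n > 5L) "..." else "", "\n")
    }
})

setMethod("show", "PileupMatrix", function(object) {
    L <- nchar(object@ref)
    cat("PileupMatrix for cluster", object@cluster_id, "(", L, "nt )\n")
    cat("  assigned reads:", sum(object@stop5),
        "| max coverage:", if (L) max(object@coverage) else 0L,
        "| sample total mapped:", object@totalMappedReads, "\n")
})

## internal constructor used across modules
newPileupMatrix <- function(cluster_id, ref, coverage, stop5, baseCounts,
                            totalMappedReads = sum(stop5)) {
    new("PileupMatrix",
        cluster_id = as.character(cluster_id),
        ref = toupper(as.character(ref)),
        coverage = as.integer(coverage),
        stop5 = as.integer(stop5),
        baseCounts = matrix(as.integer(baseCounts),
                            ncol = 4L,
                            dimnames = list(NULL, c("A", "C", "G", "T"))),
        totalMappedReads = as.numeric(totalMappedReads))
}

#' Number of reads assigned to a cluster pileup
#'
#' Each assigned read contributes exactly one 5' end, so the cluster read
#' count is the sum of the RT-stop track.
#' @param p A \code{PileupMatrix}.
#' @return Integer count.
#' @export
assignedReads <- function(p) {
    stopifnot(is(p, "PileupMatrix"))
    sum(p@stop5)
}
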