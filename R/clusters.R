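#' Build identical-sequence tRNA clusters
#'
#' Partitions tRNA genes by exact mature-sequence identity. tRNA genes occur
#' in many identical copies; mapping reads against one representative per
#' cluster avoids multi-mapping ambiguity, and downstream statistics are
#' computed per cluster.
#'
#' Cluster ids are \code{<isotype>-<anticodon>-<serial>} and the ordering is
#' deterministic: clusters are sorted by isotype, anticodon, then sequence.
#' If members of one cluster disagree on the isotype annotation the majority
#' isotype is kept (alphabetical tie-break) and a warning is emitted.
#'
#' @param genes A \code{DataFrame} as returned by \code{\link{parseTrnascan}}.
#' @return A \code{\link{TRNAClusterSet}}.
#' @examples
#' genes <- S4Vectors::DataFrame(
#'     gene_id = c("g1", "g2", "g3"),
#'     isotype = c("Gly", "Gly", "Ala"),
#'     anticodon = c("GCC", "GCC", "AGC"),
#'     mature_sequence = c("ACGT", "ACGT", "GGGG"),
#'     structure = NA_character_)
#' buildClusters(genes)
#' @export
buildClusters <- function(genes) {
    if (nrow(genes) == 0L)
        stop("no genes to cluster")
    seqs <- as.character(genes$mature_sequence)
    groups <- split(seq_len(nrow(genes)), seqs)

    info <- lapply(groups, function(idx) {
        iso <- as.character(genes$isotype[idx])
        tab <- sort(table(iso), decreasing = TRUE)
        if (length(tab) > 1L)
            warning(sprintf("isotype conflict within an identical-sequence cluster (%s); keeping majority '%s'",
                            paste(names(tab), collapse = "/"), names(tab)[1]))
        ac <- as.character(genes$anticodon[idx])
        actab <- sort(table(ac), decreasing = TRUE)
        str <- as.character(genes$structure[idx])
        str <- str[!is.na(str)]
        list(idx = idx, isotype = names(tab)[1], anticodon = names(actab)[1],
             structure = if (length(str)) str[1] else NA_character_,
             sequence = seqs[idx[1]])
    })
    ord <- order(vapply(info, `[[`, "", "isotype"),
                 vapply(info, `[[`, "", "anticodon"),
                 vapply(info, `[[`, "", "sequence"))
    info <- info[ord]
    key <- paste(vapply(info, `[[`, "", "isotype"),
                 vapply(info, `[[`, "", "anticodon"), sep = "-")
    serial <- stats::ave(seq_along(key), key, FUN = seq_along)
    ids <- paste(key, serial, sep = "-")

    sequences <- DNAStringSet(vapply(info, `[[`, "", "sequence"))
    names(sequences) <- ids
    members <- lapply(info, function(x) as.character(genes$gene_id[x$idx]))
    names(members) <- ids
    isotype <- vapply(info, `[[`, "", "isotype")
    anticodon <- vapply(info, `[[`, "", "anticodon")
    structure <- vapply(info, `[[`, "", "structure")
    names(isotype) <- names(anticodon) <- names(structure) <- ids
    sprinzl <- rep(list(NULL), length(ids))
    names(sprinzl) <- ids
    new("TRNAClusterSet", sequences = sequences, members = members,
        isotype = isotype, anticodon = anticodon, structure = structure,
        sprinzl = sprinzl)
}

#' Write cluster representatives to FASTA
#'
#' The record id is the cluster id; isotype, anticodon, member gene ids and
#' the dot-bracket structure are carried in the description so that
#' \code{\link{readClusterFasta}} reproduces the full object (Sprinzl maps
#' travel separately, see \code{\link{writeSprinzlTsv}}).
#'
#' @param clusters A \code{TRNAClusterSet}.
#' @param path Output FASTA path.
#' @export
writeClusterFasta <- function(clusters, path) {
    ids <- clusterIds(clusters)
    desc <- sprintf("%s isotype=%s anticodon=%s members=%s structure=%s",
                    ids, clusters@isotype, clusters@anticodon,
                    vapply(clusters@members, paste, "", collapse = ","),
                    ifelse(is.na(clusters@structure), ".",
                           clusters@structure))
    x <- clusterSequences(clusters)
    names(x) <- desc
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a cluster FASTA written by \code{writeClusterFasta}
#'
#' @param path FASTA path.
#' @param sprinzl_tsv Optional path of the matching Sprinzl map TSV.
#' @return A \code{TRNAClusterSet}.
#' @export
readClusterFasta <- function(path, sprinzl_tsv = NULL) {
    x <- Biostrings::readDNAStringSet(path)
    full <- names(x)
    ids <- sub("\\s.*$", "", full)
    grab <- function(key) {
        m <- regmatches(full, regexec(paste0(key, "=(\\S+)"), full))
        vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
    }
    isotype <- grab("isotype")
    anticodon <- grab("anticodon")
    structure <- grab("structure")
    structure[structure == "."] <- NA_character_
    members <- strsplit(grab("members"), ",", fixed = TRUE)
    names(x) <- ids
    names(members) <- names(isotype) <- names(anticodon) <-
        names(structure) <- ids
    sprinzl <- rep(list(NULL), length(ids))
    names(sprinzl) <- ids
    obj <- new("TRNAClusterSet", sequences = x, members = members,
               isotype = isotype, anticodon = anticodon,
               structure = structure, sprinzl = sprinzl)
    if (!is.null(sprinzl_tsv))
        obj <- readSprinzlTsv(sprinzl_tsv, obj)
    obj
}

#' Write Sprinzl coordinate maps to TSV
#'
#' One row per cluster position: \code{cluster_id}, \code{index0} (0-based
#' raw index, kept for traceability), \code{label} (Sprinzl label), and
#' \code{base}.
#'
#' @param clusters A \code{TRNAClusterSet} with assigned maps.
#' @param path Output TSV path.
#' @export
writeSprinzlTsv <- function(clusters, path) {
    rows <- lapply(clusterIds(clusters), function(id) {
        sp <- sprinzlMap(clusters, id)
        if (is.null(sp)) return(NULL)
        seq <- as.character(clusterSequences(clusters)[[id]])
        data.frame(cluster_id = id, index0 = seq_along(sp) - 1L,
                   label = sp,
                   base = strsplit(seq, "")[[1]],
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(cluster_id = character(), index0 = integer(),
                         label = character(), base = character())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read Sprinzl maps from TSV into a cluster set
#'
#' @param path TSV written by \code{\link{writeSprinzlTsv}}.
#' @param clusters A \code{TRNAClusterSet} whose ids/lengths must match.
#' @return The cluster set with \code{sprinzl} maps filled in.
#' @export
readSprinzlTsv <- function(path, clusters) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer",
                                           "character", "character"))
    for (id in unique(df$cluster_id)) {
        if (!id %in% clusterIds(clusters))
            stop(sprintf("Sprinzl map for unknown cluster '%s'", id))
        sub <- df[df$cluster_id == id, ]
        sub <- sub[order(sub$index0), ]
        L <- Biostrings::width(clusterSequences(clusters)[id])
        if (nrow(sub) != L)
            stop(sprintf("Sprinzl map for '%s' has %d rows, sequence length %d",
                         id, nrow(sub), L))
        clusters@sprinzl[[id]] <- sub$label
    }
    validObject(clusters)
    clusters
}
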