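#' Parse tRNAscan-SE v2.0 tabular output into a gene table
#'
#' Reads the tab-separated hit table produced by tRNAscan-SE (with or without
#' its three-line header block) and returns one row per non-pseudogene tRNA
#' gene with its mature (intron-removed, sense-strand) sequence.
#'
#' Coordinates in the file are 1-based inclusive with Begin > End on the
#' minus strand; they are converted to 0-based half-open sense coordinates.
#' Intron spans are excised from the mature sequence. Records flagged as
#' pseudogenes (isotype \code{Pseudo} or a Note containing \code{pseudo})
#' are dropped.
#'
#' @param path Path to the tRNAscan-SE tabular output.
#' @param genome Optional \code{DNAStringSet} or FASTA path with the contigs
#'   named in the table. Required unless \code{structures} supplies sequences
#'   for every gene.
#' @param structures Optional path to the tRNAscan-SE secondary-structure
#'   output (\code{-f}); supplies dot-bracket structures (and sequences when
#'   no genome is given), matched by gene id.
#' @return A \code{DataFrame} with columns \code{gene_id}, \code{isotype},
#'   \code{anticodon}, \code{mature_sequence}, \code{structure},
#'   \code{contig}, \code{start}, \code{end}, \code{strand}, \code{score}.
#' @examples
#' tab <- tempfile(fileext = ".out")
#' writeLines(paste("chr1", "1", "10", "85", "Gly", "GCC", "0", "0", "80.0",
#'                  sep = "\t"), tab)
#' genome <- Biostrings::DNAStringSet(c(chr1 = paste(
#'     rep("ACGT", 30), collapse = "")))
#' parseTrnascan(tab, genome)
#' @export
parseTrnascan <- function(path, genome = NULL, structures = NULL) {
    lines <- readLines(path)
    struct <- if (!is.null(structures)) readTrnascanStructure(structures)
              else list()
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    if (!is.null(genome))
        names(genome) <- sub("\\s.*$", "", names(genome))

    is_header <- grepl("^(Sequence|Name|-+\\t)", lines) |
        grepl("^-+", lines) | !nzchar(trimws(lines))
    keep <- which(!is_header)

    rows <- vector("list", length(keep))
    for (k in seq_along(keep)) {
        lineno <- keep[k]
        f <- trimws(strsplit(lines[lineno], "\t")[[1]])
        if (length(f) < 9L)
            stop(sprintf("malformed tRNAscan-SE row at line %d: expected >= 9 tab-separated fields, got %d",
                         lineno, length(f)))
        begin <- suppressWarnings(as.integer(f[3]))
        end <- suppressWarnings(as.integer(f[4]))
        ib <- suppressWarnings(as.integer(f[7]))
        ie <- suppressWarnings(as.integer(f[8]))
        score <- suppressWarnings(as.numeric(f[9]))
        if (anyNA(c(begin, end, ib, ie, score)))
            stop(sprintf("malformed tRNAscan-SE row at line %d: non-numeric coordinate or score",
                         lineno))
        note <- if (length(f) >= 10L) f[10] else ""
        rows[[k]] <- list(contig = f[1], serial = f[2], begin = begin,
                          end = end, isotype = f[5], anticodon = toupper(f[6]),
                          intron_begin = ib, intron_end = ie, score = score,
                          note = note, lineno = lineno)
    }

    out <- list()
    for (r in rows) {
        if (grepl("pseudo", r$note, ignore.case = TRUE) ||
            r$isotype %in% c("Pseudo", "pseudo"))
            next
        gene_id <- paste0(r$contig, ".trna", r$serial)
        strand <- if (r$begin <= r$end) "+" else "-"
        start0 <- min(r$begin, r$end) - 1L
        end0 <- max(r$begin, r$end)

        seq <- NA_character_
        if (!is.null(genome)) {
            if (!r$contig %in% names(genome))
                stop(sprintf("contig '%s' (line %d) not found in genome",
                             r$contig, r$lineno))
            clen <- Biostrings::width(genome[r$contig])
            if (end0 > clen)
                stop(sprintf("gene %s (line %d): end %d exceeds contig length %d",
                             gene_id, r$lineno, end0, clen))
            g <- Biostrings::subseq(genome[[r$contig]], start0 + 1L, end0)
            if (strand == "-")
                g <- Biostrings::reverseComplement(g)
            seq <- as.character(g)
            if (r$intron_begin > 0L && r$intron_end > 0L) {
                rel1 <- abs(r$intron_begin - r$begin) + 1L
                rel2 <- abs(r$intron_end - r$begin) + 1L
                seq <- paste0(substr(seq, 1L, min(rel1, rel2) - 1L),
                              substr(seq, max(rel1, rel2) + 1L, nchar(seq)))
            }
        } else if (!is.null(struct[[gene_id]]$seq)) {
            seq <- struct[[gene_id]]$seq
        } else {
            stop(sprintf("no genome given and no sequence for gene %s in structure file",
                         gene_id))
        }
        seq <- toupper(chartr("u", "t", seq))
        if (nchar(seq) < 55L || nchar(seq) > 120L)
            warning(sprintf("gene %s has unusual mature length %d nt (canonical 55-120)",
                            gene_id, nchar(seq)))
        str <- struct[[gene_id]]$str
        out[[length(out) + 1L]] <- DataFrame(
            gene_id = gene_id, isotype = r$isotype, anticodon = r$anticodon,
            mature_sequence = seq,
            structure = if (is.null(str)) NA_character_ else str,
            contig = r$contig, start = start0, end = end0, strand = strand,
            score = r$score)
    }
    if (!length(out))
        return(DataFrame(gene_id = character(), isotype = character(),
                         anticodon = character(),
                         mature_sequence = character(),
                         structure = character(), contig = character(),
                         start = integer(), end = integer(),
                         strand = character(), score = numeric()))
    do.call(rbind, out)
}

#' Read a tRNAscan-SE secondary-structure file
#'
#' Parses the \code{-f} output of tRNAscan-SE into per-gene sequence and
#' dot-bracket structure. tRNAscan's \code{>}/\code{<} pairing notation is
#' converted to \code{(}/\code{)}.
#'
#' @param path Path to the structure file.
#' @return Named list (by gene id) of lists with elements \code{seq} and
#'   \code{str}.
#' @export
readTrnascanStructure <- function(path) {
    lines <- readLines(path)
    out <- list()
    cur <- NULL
    for (ln in lines) {
        m <- regmatches(ln, regexec("^(\\S+)\\s+\\(\\d+-\\d+\\)", ln))[[1]]
        if (length(m)) {
            cur <- m[2]
            out[[cur]] <- list(seq = NULL, str = NULL)
        } else if (!is.null(cur) && grepl("^Seq:", ln)) {
            out[[cur]]$seq <- trimws(sub("^Seq:", "", ln))
        } else if (!is.null(cur) && grepl("^Str:", ln)) {
            s <- trimws(sub("^Str:", "", ln))
            out[[cur]]$str <- chartr("><", "()", s)
        }
    }
    out
}
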