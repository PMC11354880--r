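## Hand-annotated cloverleaf fixtures and a small SAM writer, all built in
## code at test time.

## canonical 76-nt tRNA: 7 bp acceptor stem, 2-nt linker, 4 bp D stem with
## an 8-nt D loop, 5 bp anticodon stem with 7-nt loop, 5-nt variable loop,
## 5 bp T stem with 7-nt loop, discriminator + CCA
canonicalCloverleaf <- function(anticodon = "GCC") {
    acc5 <- "GCGGCGG"; dstem5 <- "GCAT"; acstem5 <- "CTGGA"
    tstem5 <- "CGTGG"
    rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x),
                                         "")[[1]]), collapse = "")
    sequence <- paste0(acc5, "TA", dstem5, "AGTTGGTA", rc(dstem5), "G",
                       acstem5, "TT", anticodon, "AT", rc(acstem5),
                       "AGGTC", tstem5, "TTCGAAT", rc(tstem5), rc(acc5),
                       "ACCA")
    structure <- paste0("(((((((..((((........)))).(((((.......)))))",
                        ".....(((((.......))))))))))))....")
    labels <- c(as.character(1:9),            # acceptor 5' + linker
                as.character(10:13),          # D stem 5'
                as.character(14:21),          # 8-nt D loop
                as.character(22:25), "26",    # D stem 3' + linker
                as.character(27:31),          # AC stem 5'
                as.character(32:38),          # AC loop (34-36 anticodon)
                as.character(39:43),          # AC stem 3'
                as.character(44:48),          # variable loop
                as.character(49:53),          # T stem 5'
                as.character(54:60),          # T loop
                as.character(61:65),          # T stem 3'
                as.character(66:72),          # acceptor 3'
                as.character(73:76))          # discriminator + CCA
    stopifnot(nchar(sequence) == 76L, nchar(structure) == 76L,
              length(labels) == 76L)
    list(sequence = sequence, structure = structure, labels = labels)
}

## 78-nt variant with a 10-nt D loop carrying the 20a/20b insertions
cloverleaf20ab <- function(anticodon = "ACG") {
    cl <- canonicalCloverleaf(anticodon)
    ## D loop becomes 14,15,16,17,18,19,20,20a,20b,21
    sequence <- paste0(substr(cl$sequence, 1, 13), "AGTTGGTTTA",
                       substr(cl$sequence, 22, 76))
    structure <- paste0(substr(cl$structure, 1, 13), "..........",
                        substr(cl$structure, 22, 76))
    labels <- c(cl$labels[1:20], "20a", "20b", cl$labels[21:76])
    stopifnot(nchar(sequence) == 78L, length(labels) == 78L)
    list(sequence = sequence, structure = structure, labels = labels)
}

## minimal TRNAClusterSet around explicit sequences/structures
makeClusterSet <- function(fixtures, ids = names(fixtures),
                           isotype = NULL, anticodon = NULL) {
    genes <- do.call(rbind, lapply(seq_along(fixtures), function(i) {
        S4Vectors::DataFrame(
            gene_id = paste0("g", i),
            isotype = if (is.null(isotype)) paste0("Iso", i) else isotype[i],
            anticodon = if (is.null(anticodon)) "GCC" else anticodon[i],
            mature_sequence = fixtures[[i]]$sequence,
            structure = fixtures[[i]]$structure)
    }))
    buildClusters(genes)
}

## write a SAM file from a reads table; qualities default to Phred 40
writeTestSam <- function(path, ref_lengths, reads) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)))
    lines <- vapply(seq_len(nrow(reads)), function(i) {
        r <- reads[i, ]
        qual <- if (!is.null(reads$qual)) r$qual
                else strrep("I", nchar(r$seq))
        paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
              r$seq, qual, sep = "\t")
    }, "")
    writeLines(c(hdr, lines), path)
    path
}

## independent per-read CIGAR walker used as the counting oracle: returns
## coverage/stop5/baseCounts built by re-walking each alignment
oraclePileup <- function(reads, L, min_mapq = 0L) {
    coverage <- integer(L); stop5 <- integer(L)
    bc <- matrix(0L, nrow = L, ncol = 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_len(nrow(reads))) {
        r <- reads[i, ]
        if (bitwAnd(r$flag, 256L) > 0L || bitwAnd(r$flag, 2048L) > 0L ||
            bitwAnd(r$flag, 4L) > 0L || r$mapq < min_mapq)
            next
        ops <- regmatches(r$cigar, gregexpr("[0-9]+[MIDNSHP=X]", r$cigar))[[1]]
        refpos <- r$pos           # 1-based
        qpos <- 1L
        first <- TRUE
        for (op in ops) {
            n <- as.integer(sub("[A-Z=]", "", op))
            type <- sub("[0-9]+", "", op)
            if (type %in% c("M", "=", "X")) {
                if (first) { stop5[refpos] <- stop5[refpos] + 1L; first <- FALSE }
                for (k in seq_len(n)) {
                    coverage[refpos] <- coverage[refpos] + 1L
                    b <- substr(r$seq, qpos, qpos)
                    bc[refpos, b] <- bc[refpos, b] + 1L
                    refpos <- refpos + 1L; qpos <- qpos + 1L
                }
            } else if (type == "D") {
                if (first) { stop5[refpos] <- stop5[refpos] + 1L; first <- FALSE }
                coverage[refpos:(refpos + n - 1L)] <-
                    coverage[refpos:(refpos + n - 1L)] + 1L
                refpos <- refpos + n
            } else if (type %in% c("I", "S")) {
                qpos <- qpos + n
            } else if (type == "N") {
                refpos <- refpos + n
            }
        }
    }
    list(coverage = coverage, stop5 = stop5, baseCounts = bc)
}

## build a PileupMatrix directly from count vectors (ref defaults to all A)
makePileup <- function(cluster_id, stop5, coverage,
                       ref = strrep("A", length(stop5)),
                       baseCounts = NULL, total = sum(stop5)) {
    L <- length(stop5)
    if (is.null(baseCounts)) {
        baseCounts <- matrix(0L, L, 4L,
                             dimnames = list(NULL, c("A", "C", "G", "T")))
        refchars <- strsplit(ref, "")[[1]]
        baseCounts[cbind(seq_len(L),
                         match(refchars, c("A", "C", "G", "T")))] <- coverage
    }
    new("PileupMatrix", cluster_id = cluster_id, ref = ref,
        coverage = as.integer(coverage), stop5 = as.integer(stop5),
        baseCounts = matrix(as.integer(baseCounts), ncol = 4L,
                            dimnames = list(NULL, c("A", "C", "G", "T"))),
        totalMappedReads = as.numeric(total))
}
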