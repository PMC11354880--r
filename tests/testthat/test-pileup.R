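## a 100-nt single-cluster reference for alignment-counting tests
.samClusterSet <- function(len = 100L) {
    seqs <- Biostrings::DNAStringSet(
        setNames(paste(rep("ACGT", len / 4), collapse = ""), "clu1"))
    members <- setNames(list("g1"), "clu1")
    iso <- setNames("Gly", "clu1"); ac <- setNames("GCC", "clu1")
    str <- setNames(NA_character_, "clu1")
    sprinzl <- setNames(list(NULL), "clu1")
    new("TRNAClusterSet", sequences = seqs, members = members,
        isotype = iso, anticodon = ac, structure = str, sprinzl = sprinzl)
}

.refSubstr <- function(cs, from, to)
    substr(as.character(clusterSequences(cs)[["clu1"]]), from, to)

test_that("single reads update stop5 and coverage at aligned indices", {
    cs <- .samClusterSet()
    sam <- tempfile(fileext = ".sam")
    ## one read aligned at reference indices 10-70 (0-based)
    reads <- data.frame(qname = "r1", flag = 0L, rname = "clu1",
                        pos = 11L, mapq = 60L, cigar = "61M",
                        seq = .refSubstr(cs, 11, 71))
    writeTestSam(sam, c(clu1 = 100L), reads)
    p <- countFromAlignments(sam, cs)[["clu1"]]
    expect_equal(p@stop5[11], 1L)                 # 0-based index 10
    expect_equal(sum(p@stop5), 1L)
    expect_equal(p@coverage[11:71], rep(1L, 61))
    expect_equal(sum(p@coverage), 61L)
})

test_that("deletions add coverage but no base counts; additivity holds", {
    cs <- .samClusterSet()
    sam <- tempfile(fileext = ".sam")
    ## r1 spans indices 25-35 with a deletion over 0-based index 30
    reads <- data.frame(
        qname = c("r1", "r2", "r3"), flag = 0L, rname = "clu1",
        pos = c(26L, 11L, 12L), mapq = 60L,
        cigar = c("5M1D5M", "20M", "19M"),
        seq = c(paste0(.refSubstr(cs, 26, 30), .refSubstr(cs, 32, 36)),
                .refSubstr(cs, 11, 30), .refSubstr(cs, 12, 30)))
    writeTestSam(sam, c(clu1 = 100L), reads)
    p <- countFromAlignments(sam, cs)[["clu1"]]
    expect_equal(p@coverage[31], 1L)              # deletion covered
    expect_equal(sum(p@baseCounts[31, ]), 0L)     # but no base call
    expect_equal(p@stop5[11:12], c(1L, 1L))       # leftmost indices 10, 11
    expect_equal(sum(p@stop5), 3L)
})

test_that("soft clips, secondary alignments and MAPQ are handled", {
    cs <- .samClusterSet()
    sam <- tempfile(fileext = ".sam")
    reads <- data.frame(
        qname = c("r1", "r2", "r3"), rname = "clu1",
        flag = c(0L, 256L, 0L),
        pos = c(21L, 31L, 41L), mapq = c(60L, 60L, 5L),
        cigar = c("4S10M", "10M", "10M"),
        seq = c(paste0("TTTT", .refSubstr(cs, 21, 30)),
                .refSubstr(cs, 31, 40), .refSubstr(cs, 41, 50)))
    writeTestSam(sam, c(clu1 = 100L), reads)
    p <- countFromAlignments(sam, cs, min_mapq = 10L)[["clu1"]]
    ## clip boundary (not the clipped bases) defines the 5'-most index
    expect_equal(p@stop5[21], 1L)
    expect_equal(sum(p@stop5), 1L)                # secondary + low MAPQ gone
    expect_equal(sum(p@coverage), 10L)
})

test_that("alignment counting matches a brute-force CIGAR walker", {
    cs <- .samClusterSet()
    set.seed(7)
    n <- 60L
    pos <- sample(1:60, n, replace = TRUE)
    len <- sample(15:35, n, replace = TRUE)
    cigar <- sprintf("%dM", len)
    ## sprinkle a few deletions and soft clips
    del <- sample(n, 8L)
    cigar[del] <- sprintf("%dM2D%dM", len[del] %/% 2,
                          len[del] - len[del] %/% 2)
    seqs <- vapply(seq_len(n), function(i) {
        if (i %in% del)
            paste0(.refSubstr(cs, pos[i], pos[i] + len[i] %/% 2 - 1),
                   .refSubstr(cs, pos[i] + len[i] %/% 2 + 2,
                              pos[i] + len[i] + 1))
        else .refSubstr(cs, pos[i], pos[i] + len[i] - 1)
    }, "")
    reads <- data.frame(qname = paste0("r", seq_len(n)), flag = 0L,
                        rname = "clu1", pos = pos, mapq = 60L,
                        cigar = cigar, seq = seqs)
    sam <- tempfile(fileext = ".sam")
    writeTestSam(sam, c(clu1 = 100L), reads)
    p <- countFromAlignments(sam, cs)[["clu1"]]
    oracle <- oraclePileup(reads, 100L)
    expect_equal(p@coverage, oracle$coverage)
    expect_equal(p@stop5, oracle$stop5)
    expect_equal(unname(p@baseCounts), unname(oracle$baseCounts))
    ## conservation: every assigned read contributes exactly one 5' end
    expect_equal(sum(p@stop5), n)
})

test_that("alignments to unknown references error; empty files warn", {
    cs <- .samClusterSet()
    sam <- tempfile(fileext = ".sam")
    reads <- data.frame(qname = "r1", flag = 0L, rname = "cluX",
                        pos = 1L, mapq = 60L, cigar = "10M",
                        seq = strrep("A", 10))
    writeTestSam(sam, c(cluX = 100L), reads)
    expect_error(countFromAlignments(sam, cs), "cluX")

    writeTestSam(sam, c(clu1 = 100L),
                 data.frame(qname = character(), flag = integer(),
                            rname = character(), pos = integer(),
                            mapq = integer(), cigar = character(),
                            seq = character()))
    expect_warning(res <- countFromAlignments(sam, cs), "no usable")
    expect_length(res, 0L)
})

test_that("pileup TSVs round-trip losslessly and validate invariants", {
    set.seed(11)
    mk <- function(id) {
        cov <- as.integer(rpois(40, 50))
        stop5 <- pmin(as.integer(rpois(40, 3)), cov)
        makePileup(id, stop5, cov,
                   ref = paste(sample(c("A", "C", "G", "T"), 40,
                                      replace = TRUE), collapse = ""),
                   total = 12345)
    }
    pileups <- list(c1 = mk("c1"), c2 = mk("c2"))
    tsv <- tempfile(fileext = ".tsv")
    writePileupTsv(pileups, tsv)
    back <- readPileupTsv(tsv)
    expect_equal(names(back), names(pileups))
    for (id in names(pileups)) {
        expect_equal(back[[id]]@coverage, pileups[[id]]@coverage)
        expect_equal(back[[id]]@stop5, pileups[[id]]@stop5)
        expect_equal(back[[id]]@baseCounts, pileups[[id]]@baseCounts)
        expect_equal(back[[id]]@ref, pileups[[id]]@ref)
        expect_equal(back[[id]]@totalMappedReads, 12345)
    }

    ## corrupt: stop5 > coverage
    lines <- readLines(tsv)
    parts <- strsplit(lines[3], "\t")[[1]]
    parts[5] <- as.character(as.integer(parts[4]) + 1L)
    lines[3] <- paste(parts, collapse = "\t")
    writeLines(lines, tsv)
    expect_error(readPileupTsv(tsv), "exceeds coverage")

    ## header only -> empty map
    writeLines(c("#total_mapped_reads=0",
                 paste(c("cluster_id", "index0", "ref_base", "coverage",
                         "stop5", "nA", "nC", "nG", "nT"),
                       collapse = "\t")), tsv)
    expect_length(readPileupTsv(tsv), 0L)
})

test_that("library scaling is linear and preserves stop/coverage ratios", {
    p <- makePileup("c1", stop5 = c(40L, 10L, 0L),
                    coverage = c(100L, 50L, 20L), ref = "AAA",
                    total = 2e6)
    np <- normalizeLibrary(p, scale_to = 1e6)
    expect_equal(np@stop[1], 20)
    ## total equals scale_to -> identity
    p2 <- makePileup("c1", c(40L, 10L, 0L), c(100L, 50L, 20L), ref = "AAA",
                     total = 1e6)
    expect_equal(normalizeLibrary(p2, 1e6)@stop, c(40, 10, 0))
    ## ratios unchanged by scaling
    expect_equal(np@stop / np@coverage, p@stop5 / p@coverage)
    p3 <- makePileup("c1", c(0L, 0L, 0L), c(0L, 0L, 0L), ref = "AAA",
                     total = 0)
    expect_error(normalizeLibrary(p3), "zero total")
})

test_that("replicate means are position-wise and order-invariant", {
    mk <- function(v) new("NormalizedProfile", cluster_id = "c1",
                          stop = v, coverage = v * 2)
    reps <- list(mk(c(10, 0)), mk(c(20, 3)), mk(c(30, 6)))
    m <- replicateMean(reps)
    expect_equal(m@stop, c(20, 3))
    expect_equal(replicateMean(reps[1])@stop, c(10, 0))    # identity
    expect_equal(replicateMean(rev(reps))@stop, m@stop)    # commutative
    bad <- list(mk(c(1, 2)), new("NormalizedProfile", cluster_id = "c1",
                                 stop = c(1, 2, 3), coverage = c(1, 2, 3)))
    expect_error(replicateMean(bad), "length")
})

test_that("scaling then averaging is linear on random tracks", {
    set.seed(3)
    tracks <- replicate(3, rpois(20, 30), simplify = FALSE)
    totals <- c(1e5, 2e5, 4e5)
    ps <- Map(function(tr, tot)
        makePileup("c1", tr, tr + 5L, total = tot), tracks, totals)
    m <- replicateMean(lapply(ps, normalizeLibrary, scale_to = 1e6))
    manual <- Reduce(`+`, Map(function(tr, tot) tr * 1e6 / tot,
                              tracks, totals)) / 3
    expect_equal(m@stop, manual)
})

test_that("pooling sums raw counts and totals across replicates", {
    a <- makePileup("c1", c(1L, 2L), c(5L, 5L), ref = "AC", total = 100)
    b <- makePileup("c1", c(3L, 0L), c(7L, 4L), ref = "AC", total = 200)
    pool <- poolPileups(list(a, b))
    expect_equal(pool@stop5, c(4L, 2L))
    expect_equal(pool@coverage, c(12L, 9L))
    expect_equal(pool@totalMappedReads, 300)
    c2 <- makePileup("c2", c(1L, 1L), c(2L, 2L), ref = "AC")
    expect_error(poolPileups(list(a, c2)), "different clusters")
})
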