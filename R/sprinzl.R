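## Structure-guided Sprinzl numbering.
##
## Standard tRNA positions are labeled 1-76 with insertions 17a, 20a, 20b in
## the D-loop and e-labels in long variable arms, so that, e.g., "position 34"
## is the anticodon wobble base in every tRNA regardless of its actual length.
## The assignment here segments the dot-bracket structure into the four
## cloverleaf arms and fills each segment with its canonical label run.

.pairTable <- function(db) {
    chars <- strsplit(db, "")[[1]]
    pt <- rep(NA_integer_, length(chars))
    stack <- integer(0)
    for (i in seq_along(chars)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (!length(stack))
                stop("unbalanced dot-bracket structure")
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pt[i] <- j
            pt[j] <- i
        } else if (chars[i] != ".") {
            stop(sprintf("unexpected character '%s' in dot-bracket structure",
                         chars[i]))
        }
    }
    if (length(stack))
        stop("unbalanced dot-bracket structure")
    pt
}

## count consecutive stacked pairs of the helix opening at (i, j)
.helixLength <- function(pt, i, j) {
    s <- 0L
    while (i + s <= length(pt) && j - s >= 1L &&
           !is.na(pt[i + s]) && pt[i + s] == j - s)
        s <- s + 1L
    s
}

.cloverleafError <- function(msg) {
    stop(sprintf(paste0("%s; structure cannot be decomposed into a four-arm ",
                        "cloverleaf -- consider supplying a Sprinzl map ",
                        "override"), msg), call. = FALSE)
}

## labels for a D-loop of n residues: core 14,15,18,19,20,21 always present,
## extras admitted in priority order 16, 17, 20a, 20b, 17a and placed 5'->3'
.dLoopLabels <- function(n) {
    if (n < 6L || n > 11L)
        .cloverleafError(sprintf("D-loop length %d outside supported 6-11", n))
    extras <- n - 6L
    pri <- c("16", "17", "20a", "20b", "17a")[seq_len(extras)]
    slot1 <- intersect(c("16", "17", "17a"), pri)
    slot2 <- intersect(c("20a", "20b"), pri)
    c("14", "15", slot1, "18", "19", "20", slot2, "21")
}

## labels for the variable region between the anticodon and T arms; short
## loops drop 47 first (then 46, 45, 44), long variable arms (class II) get
## e-labels between 47 and 48
.variableLabels <- function(n) {
    if (n == 0L) return(character(0))
    if (n <= 5L) {
        full <- c("44", "45", "46", "47", "48")
        drop_order <- c("47", "46", "45", "44")
        setdiff(full, drop_order[seq_len(5L - n)])
    } else {
        c("44", "45", "46", "47", paste0("e", seq_len(n - 5L)), "48")
    }
}

#' Assign Sprinzl labels from a dot-bracket structure
#'
#' Segments a cloverleaf secondary structure into acceptor stem, D arm,
#' anticodon arm, variable region and T arm, and returns one canonical
#' (Sprinzl) label per sequence position: acceptor 5' arm \code{1-7},
#' linker \code{8-9}, D arm \code{10-25} (with insertions \code{17a},
#' \code{20a}, \code{20b}), \code{26}, anticodon arm \code{27-43} with the
#' anticodon at \code{34-36}, variable region \code{44-48} (plus
#' \code{e}-labels for long variable arms), T arm \code{49-65} with the
#' canonical T-loop starting at \code{54}, and 3' acceptor side
#' \code{66-76}.
#'
#' @param structure Dot-bracket string (one \code{(}/\code{)} pair per base
#'   pair).
#' @param sequence Optional sequence (same length) used only for the
#'   anticodon sanity check.
#' @param anticodon Optional anticodon (DNA alphabet); if given together
#'   with \code{sequence}, a warning is raised when the bases labeled
#'   \code{34-36} differ.
#' @return Character vector of labels, one per 0-based sequence index.
#' @examples
#' db <- paste0("(((((((..((((........)))).(((((.......))))).....",
#'              "(((((.......)))))))))))).")
#' # not a real tRNA; see tests for canonical 76-nt fixtures
#' @export
sprinzlFromStructure <- function(structure, sequence = NULL,
                                 anticodon = NULL) {
    L <- nchar(structure)
    if (L < 55L)
        stop(sprintf("structure length %d below the minimal tRNA length 55", L))
    if (!is.null(sequence) && nchar(sequence) != L)
        stop("sequence and structure lengths differ")
    pt <- .pairTable(structure)

    paired <- which(!is.na(pt))
    if (!length(paired)) .cloverleafError("no base pairs")
    i0 <- paired[1]
    if (i0 != 1L)
        .cloverleafError(sprintf("5' end is unpaired up to position %d", i0 - 1L))
    j0 <- pt[i0]
    s_acc <- .helixLength(pt, i0, j0)
    if (s_acc < 5L || s_acc > 8L)
        .cloverleafError(sprintf("acceptor stem of %d bp outside 5-8", s_acc))
    a5_end <- i0 + s_acc - 1L        # innermost 5' acceptor position
    a3_start <- pt[a5_end]           # innermost 3' acceptor position

    ## walk the multiloop between the acceptor stem halves, collecting
    ## alternating unpaired runs and hairpin arms
    segs <- list()
    i <- a5_end + 1L
    while (i < a3_start) {
        if (is.na(pt[i])) {
            j <- i
            while (j + 1L < a3_start && is.na(pt[j + 1L])) j <- j + 1L
            segs[[length(segs) + 1L]] <- list(type = "loop", from = i, to = j)
            i <- j + 1L
        } else {
            if (pt[i] < i) .cloverleafError("crossing base pairs in multiloop")
            segs[[length(segs) + 1L]] <- list(type = "arm", from = i,
                                              to = pt[i])
            i <- pt[i] + 1L
        }
    }
    arms <- Filter(function(s) s$type == "arm", segs)
    if (!length(arms) %in% c(3L, 4L))
        .cloverleafError(sprintf("found %d hairpin arms in the multiloop",
                                 length(arms)))
    armD <- arms[[1]]; armAC <- arms[[2]]
    armT <- arms[[length(arms)]]

    labelArm <- function(arm, loop_fun, stem5_labels, stem3_labels,
                         what, loop_len_fixed = NA) {
        s <- .helixLength(pt, arm$from, arm$to)
        loop_from <- arm$from + s; loop_to <- arm$to - s
        if (loop_from > loop_to)
            .cloverleafError(sprintf("%s arm has no loop", what))
        if (any(!is.na(pt[loop_from:loop_to])))
            .cloverleafError(sprintf("%s loop contains base pairs", what))
        n <- loop_to - loop_from + 1L
        if (!is.na(loop_len_fixed) && n != loop_len_fixed)
            .cloverleafError(sprintf("%s loop has %d nt, expected %d",
                                     what, n, loop_len_fixed))
        list(stem = s, loop_labels = loop_fun(n))
    }

    ## D arm: stem canonically 3-4 bp, labels ...13 / 22...
    sD <- .helixLength(pt, armD$from, armD$to)
    if (sD < 3L || sD > 5L)
        .cloverleafError(sprintf("D stem of %d bp outside 3-5", sD))
    d <- labelArm(armD, .dLoopLabels, NULL, NULL, "D")
    d_stem5 <- as.character((14L - sD):13L)
    d_stem3 <- as.character(22L:(21L + sD))

    ## anticodon arm: loop must be exactly 7 so the anticodon sits at 34-36
    sAC <- .helixLength(pt, armAC$from, armAC$to)
    if (sAC < 3L || sAC > 6L)
        .cloverleafError(sprintf("anticodon stem of %d bp outside 3-6", sAC))
    ac <- labelArm(armAC, function(n) as.character(32L:38L), NULL, NULL,
                   "anticodon", loop_len_fixed = 7L)
    ac_stem5 <- as.character((32L - sAC):31L)
    ac_stem3 <- as.character(39L:(38L + sAC))

    ## T arm: loop must be exactly 7 (canonical T-loop, 54-60)
    sT <- .helixLength(pt, armT$from, armT$to)
    if (sT < 3L || sT > 6L)
        .cloverleafError(sprintf("T stem of %d bp outside 3-6", sT))
    tt <- labelArm(armT, function(n) as.character(54L:60L), NULL, NULL,
                   "T", loop_len_fixed = 7L)
    t_stem5 <- as.character((54L - sT):53L)
    t_stem3 <- as.character(61L:(60L + sT))

    ## linkers
    n8 <- armD$from - (a5_end + 1L)
    if (n8 < 1L || n8 > 2L)
        .cloverleafError(sprintf("%d nt between acceptor and D stems (expected 1-2)",
                                 n8))
    link89 <- as.character(7L + seq_len(n8))
    n26 <- armAC$from - (armD$to + 1L)
    if (n26 > 1L)
        .cloverleafError(sprintf("%d nt between D and anticodon arms (expected 0-1)",
                                 n26))
    link26 <- if (n26 == 1L) "26" else character(0)
    n_var <- armT$from - (armAC$to + 1L)
    varlab <- .variableLabels(n_var)
    if (armT$to != a3_start - 1L)
        .cloverleafError("unpaired residues between the T arm and the acceptor stem")

    ## 3' acceptor arm + discriminator/CCA tail
    acc3 <- as.character((73L - s_acc):72L)
    n_tail <- L - (a3_start + s_acc - 1L)
    if (n_tail < 1L || n_tail > 4L)
        .cloverleafError(sprintf("3' tail of %d nt after the acceptor stem (expected 1-4)",
                                 n_tail))
    tail_lab <- as.character(72L + seq_len(n_tail))

    labels <- c(as.character((8L - s_acc):7L),   # acceptor 5'
                link89,
                d_stem5, d$loop_labels, d_stem3,
                link26,
                ac_stem5, ac$loop_labels, ac_stem3,
                varlab,
                t_stem5, tt$loop_labels, t_stem3,
                acc3, tail_lab)
    if (length(labels) != L)
        .cloverleafError(sprintf("internal labeling mismatch (%d labels for %d nt)",
                                 length(labels), L))

    if (!is.null(sequence) && !is.null(anticodon)) {
        obs <- paste(strsplit(toupper(chartr("U", "T", sequence)), "")[[1]][
            labels %in% c("34", "35", "36")], collapse = "")
        exp <- toupper(chartr("U", "T", anticodon))
        if (!identical(obs, exp))
            warning(sprintf("bases at Sprinzl 34-36 are %s, annotated anticodon is %s",
                            obs, exp))
    }
    labels
}

#' Assign Sprinzl coordinate maps to all clusters
#'
#' Runs \code{\link{sprinzlFromStructure}} on each cluster's dot-bracket
#' structure. A user-supplied map (named list of label vectors, one entry
#' per cluster id) overrides the structure-guided assignment and is returned
#' unchanged after a length check, which covers tRNAs whose structure does
#' not segment cleanly.
#'
#' @param clusters A \code{TRNAClusterSet}.
#' @param override Named list of label vectors keyed by cluster id.
#' @return The cluster set with \code{sprinzl} maps filled in.
#' @export
assignSprinzl <- function(clusters, override = list()) {
    for (id in clusterIds(clusters)) {
        if (!is.null(override[[id]])) {
            sp <- as.character(override[[id]])
            L <- Biostrings::width(clusterSequences(clusters)[id])
            if (length(sp) != L)
                stop(sprintf("override map for '%s' has length %d, sequence %d",
                             id, length(sp), L))
            clusters@sprinzl[[id]] <- sp
            next
        }
        db <- clusters@structure[[id]]
        if (is.na(db))
            stop(sprintf("cluster '%s' has no secondary structure; supply an override map",
                         id))
        seq <- as.character(clusterSequences(clusters)[[id]])
        clusters@sprinzl[[id]] <- sprinzlFromStructure(
            db, sequence = seq, anticodon = clusters@anticodon[[id]])
    }
    validObject(clusters)
    clusters
}
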