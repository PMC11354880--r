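#' Configuration of a synthetic treated/control tRNA-seq experiment
#'
#' Defines the study conditions the simulator emulates: a multi-replicate
#' experiment with four treatments (untreated, NaBH4, CMCT, CMCT buffer
#' control), a background termination process with a linear 3' bias (the
#' reverse transcriptase terminates prematurely more often towards the 3'
#' range), and planted position-specific stop enhancement at
#' treatment-matched modification sites.
#'
#' @param n_clusters Number of tRNA clusters (default 20).
#' @param depth Mean reads per cluster per sample (Poisson; default 2000).
#' @param background Per-position background stop probability
#'   (default 0.002).
#' @param bias Linear 3' bias factor: the background stop probability at
#'   position i is \code{background * (1 + bias * i/(L-1))}; 0 switches the
#'   bias off (default 1).
#' @param stop_prob Stop probability at the position one nt 3' of a planted
#'   modification in the matching treatment (default 0.2).
#' @param replicates Biological replicates per treatment (default 3).
#' @param treatments Treatments to emit.
#' @param planted Optional data.frame overriding the default planted sites
#'   (columns \code{cluster_id}, \code{sprinzl_label}, \code{modification},
#'   \code{treatment}, and optionally \code{stop_prob}); by default two
#'   sites per cluster are planted, one per treatment, cycling through the
#'   catalog positions.
#' @param sites_per_cluster Planted sites per cluster per treatment under
#'   the default scheme (default 1, i.e. 2 sites per cluster).
#' @param miscall Optional data.frame of base-miscall sites (columns
#'   \code{cluster_id}, \code{index0}, \code{target_base}, \code{fraction})
#'   applied to every sample.
#' @param organism,temperature Sample-sheet metadata.
#' @param seed Random seed; a fixed seed gives identical output.
#' @return A named list of class \code{sim_config}.
#' @export
simConfig <- function(n_clusters = 20, depth = 2000, background = 0.002,
                      bias = 1, stop_prob = 0.2, replicates = 3,
                      treatments = c("untreated", "NaBH4", "CMCT",
                                     "CMCT_control"),
                      planted = NULL, sites_per_cluster = 1,
                      miscall = NULL, organism = "SimBacillus",
                      temperature = 30, seed = 1) {
    stopifnot(n_clusters >= 1, depth > 0, background >= 0, background <= 1,
              stop_prob >= 0, stop_prob <= 1, replicates >= 1)
    structure(list(n_clusters = n_clusters, depth = depth,
                   background = background, bias = bias,
                   stop_prob = stop_prob, replicates = replicates,
                   treatments = treatments, planted = planted,
                   sites_per_cluster = sites_per_cluster,
                   miscall = miscall, organism = organism,
                   temperature = temperature, seed = seed),
              class = "sim_config")
}

## anticodon table the generator cycles through (isotype, anticodon)
.simIsotypes <- data.frame(
    isotype = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                "Thr", "Trp", "Tyr", "Val"),
    anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC", "GCC",
                  "GTG", "GAT", "TAG", "TTT", "CAT", "GAA", "TGG", "TGA",
                  "TGT", "CCA", "TGT", "TAC"),
    stringsAsFactors = FALSE)

.randBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.revcomp <- function(x) rev(chartr("ACGT", "TGCA", x))

## build one canonical cloverleaf with catalog positions held at their
## canonical bases so that modifications can be planted there
.simCloverleaf <- function(anticodon, d_loop_len = 8L, var_len = 5L) {
    acc5 <- .randBases(7L)
    dstem5 <- .randBases(4L)
    acstem5 <- .randBases(5L)
    tstem5 <- .randBases(5L)

    dl <- .dLoopLabels(d_loop_len)
    dloop <- vapply(dl, function(lab) switch(lab,
        "14" = "A", "18" = "G", "19" = "G",
        "15" = .randBases(1L),
        "T"), "")                        # 16/17/17a/20/20a/20b/21 -> T
    vl <- .variableLabels(var_len)
    vloop <- vapply(vl, function(lab) switch(lab,
        "46" = "G", "47" = "T", "48" = "C", .randBases(1L)), "")
    ac <- strsplit(anticodon, "")[[1]]
    acloop <- c("T", "T", ac, "A", "T")  # 32,33,34-36,37,38
    tloop <- c("T", "T", "C", "G", "A", "A", "T")  # 54..60

    seqv <- c(acc5, c("T", "A"),                     # 8, 9
              dstem5, dloop, .revcomp(dstem5), "G",  # 26
              acstem5, acloop, .revcomp(acstem5),
              vloop,
              tstem5, tloop, .revcomp(tstem5),
              .revcomp(acc5), "A", "C", "C", "A")
    str <- c(rep("(", 7L), "..",
             rep("(", 4L), strrep(".", d_loop_len), rep(")", 4L), ".",
             rep("(", 5L), ".......", rep(")", 5L),
             strrep(".", var_len),
             rep("(", 5L), ".......", rep(")", 5L),
             rep(")", 7L), "....")
    list(sequence = paste(seqv, collapse = ""),
         structure = paste(str, collapse = ""))
}

## default planted-site scheme: cycle catalog loop positions per treatment
.defaultPlanted <- function(clusters, stop_prob, sites_per_cluster) {
    nabh4 <- data.frame(
        label = c("8", "16", "17", "20", "46", "47", "21"),
        modification = c("s4U", "D", "D", "D", "m7G", "D", "D"))
    cmct <- data.frame(
        label = c("32", "38", "55", "60"),
        modification = "Psi")
    ids <- clusterIds(clusters)
    rows <- list()
    k1 <- 0L; k2 <- 0L
    for (id in ids) {
        for (s in seq_len(sites_per_cluster)) {
            k1 <- k1 + 1L
            i <- (k1 - 1L) %% nrow(nabh4) + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                cluster_id = id, sprinzl_label = nabh4$label[i],
                modification = nabh4$modification[i], treatment = "NaBH4")
            k2 <- k2 + 1L
            j <- (k2 - 1L) %% nrow(cmct) + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                cluster_id = id, sprinzl_label = cmct$label[j],
                modification = cmct$modification[j], treatment = "CMCT")
        }
    }
    out <- do.call(rbind, rows)
    out$stop_prob <- stop_prob
    out
}

#' Simulate a treated/control tRNA-seq experiment
#'
#' Generates canonical cloverleaf tRNA clusters, plants modification sites,
#' and simulates, for each sample, read 3' starts at the cluster 3' end
#' with a sequential-survival termination process toward the 5' end: at
#' each position the read survives with probability \code{1 - p_stop};
#' \code{p_stop} is the 3'-biased background everywhere except one position
#' 3' of each planted site in the matching treatment, where it is elevated
#' to the planted stop probability. This matches the physics of reverse
#' transcription (the template is read 3' to 5') and automatically yields
#' the coverage drop 5' of strong stops. Base miscalls are applied at the
#' configured sites. Output is in the exact containers the rest of the
#' package consumes.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return List with \code{clusters} (a \code{TRNAClusterSet} with Sprinzl
#'   maps), \code{pileups} (named by sample id, each a named list of
#'   \code{PileupMatrix}), \code{samples} (sample sheet data.frame),
#'   \code{truth} (planted sites with 0-based \code{index0} of the
#'   modified base) and \code{config}.
#' @export
simulateExperiment <- function(cfg = simConfig()) {
    set.seed(cfg$seed)
    iso <- .simIsotypes[rep(seq_len(nrow(.simIsotypes)),
                            length.out = cfg$n_clusters), ]
    genes <- do.call(rbind, lapply(seq_len(cfg$n_clusters), function(i) {
        cl <- .simCloverleaf(iso$anticodon[i],
                             d_loop_len = 8L + (i - 1L) %% 3L)
        DataFrame(gene_id = sprintf("simgene%03d", i),
                  isotype = iso$isotype[i], anticodon = iso$anticodon[i],
                  mature_sequence = cl$sequence, structure = cl$structure)
    }))
    clusters <- assignSprinzl(buildClusters(genes))

    planted <- cfg$planted
    if (is.null(planted) && cfg$stop_prob > 0)
        planted <- .defaultPlanted(clusters, cfg$stop_prob,
                                   cfg$sites_per_cluster)
    if (is.null(planted))
        planted <- data.frame(cluster_id = character(),
                              sprinzl_label = character(),
                              modification = character(),
                              treatment = character(),
                              stop_prob = numeric())
    if (is.null(planted$stop_prob) && nrow(planted))
        planted$stop_prob <- cfg$stop_prob

    ## resolve planted labels to 0-based indices
    planted$index0 <- rep(NA_integer_, nrow(planted))
    for (r in seq_len(nrow(planted))) {
        id <- planted$cluster_id[r]
        sp <- sprinzlMap(clusters, id)
        if (is.null(sp))
            stop(sprintf("planted site in cluster '%s' without Sprinzl map", id))
        hit <- which(sp == planted$sprinzl_label[r])
        if (length(hit) != 1L)
            stop(sprintf("planted label '%s' absent from cluster '%s'",
                         planted$sprinzl_label[r], id))
        planted$index0[r] <- hit - 1L
    }

    samples <- expand.grid(replicate = seq_len(cfg$replicates),
                           treatment = cfg$treatments,
                           stringsAsFactors = FALSE)
    samples$organism <- cfg$organism
    samples$temperature <- cfg$temperature
    samples$sample_id <- sprintf("%s_%dC_%s_rep%d", samples$organism,
                                 samples$temperature, samples$treatment,
                                 samples$replicate)
    samples <- samples[, c("sample_id", "organism", "temperature",
                           "treatment", "replicate")]

    ids <- clusterIds(clusters)
    seqs <- as.character(clusterSequences(clusters))
    pileups <- list()
    for (s in seq_len(nrow(samples))) {
        trt <- samples$treatment[s]
        smp <- list()
        for (id in ids) {
            L <- nchar(seqs[[id]])
            p_stop <- cfg$background *
                (1 + cfg$bias * (seq_len(L) - 1L) / (L - 1L))
            act <- planted[planted$cluster_id == id &
                           planted$treatment == trt, , drop = FALSE]
            if (nrow(act)) {
                stop_idx <- act$index0 + 1L          # one position 3' of mod
                p_stop[stop_idx + 1L] <- act$stop_prob
            }
            depth <- stats::rpois(1L, cfg$depth)
            stop5 <- integer(L)
            remaining <- depth
            for (i in L:2) {                          # RT walks 3' -> 5'
                k <- stats::rbinom(1L, remaining, p_stop[i])
                stop5[i] <- k
                remaining <- remaining - k
            }
            stop5[1L] <- stop5[1L] + remaining        # full-length reads
            ## a read covers its stop index through the 3' end, so position
            ## j is covered by every read stopping at i <= j
            coverage <- cumsum(stop5)
            refchars <- strsplit(seqs[[id]], "")[[1]]
            bc <- matrix(0L, nrow = L, ncol = 4L,
                         dimnames = list(NULL, c("A", "C", "G", "T")))
            bc[cbind(seq_len(L),
                     match(refchars, c("A", "C", "G", "T")))] <- coverage
            mc <- cfg$miscall
            if (!is.null(mc)) {
                mc <- mc[mc$cluster_id == id, , drop = FALSE]
                for (r in seq_len(nrow(mc))) {
                    i <- mc$index0[r] + 1L
                    nmis <- stats::rbinom(1L, coverage[i], mc$fraction[r])
                    bc[i, refchars[i]] <- coverage[i] - nmis
                    bc[i, mc$target_base[r]] <- nmis
                }
            }
            smp[[id]] <- newPileupMatrix(id, seqs[[id]], coverage, stop5,
                                         bc, totalMappedReads = NA_real_)
        }
        total <- sum(vapply(smp, assignedReads, 0L))
        for (id in ids) smp[[id]]@totalMappedReads <- total
        pileups[[samples$sample_id[s]]] <- smp
    }

    truth <- DataFrame(cluster_id = planted$cluster_id,
                       index0 = planted$index0,
                       sprinzl_label = planted$sprinzl_label,
                       modification = planted$modification,
                       treatment = planted$treatment,
                       stop_prob = planted$stop_prob)
    list(clusters = clusters, pileups = pileups, samples = samples,
         truth = truth, config = cfg)
}

#' Write a simulated experiment to disk
#'
#' Emits the exact formats the rest of the package consumes: one pileup TSV
#' per sample, the cluster FASTA, the Sprinzl map TSV, a sample sheet TSV
#' (with a \code{path} column pointing at the pileups) and the truth TSV.
#'
#' @param sim Result of \code{\link{simulateExperiment}}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeClusterFasta(sim$clusters, file.path(dir, "clusters.fa"))
    writeSprinzlTsv(sim$clusters, file.path(dir, "sprinzl.tsv"))
    sheet <- sim$samples
    sheet$path <- file.path(dir, paste0(sheet$sample_id, ".pileup.tsv"))
    for (s in seq_len(nrow(sheet)))
        writePileupTsv(sim$pileups[[sheet$sample_id[s]]], sheet$path[s])
    utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sim$truth),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Evaluate a callset against planted truth
#'
#' A planted site counts as recovered when a passing call reports the same
#' cluster, modified-base index and treatment. Sensitivity is the recovered
#' fraction of planted sites; the observed FDR is the fraction of passing
#' calls that match no planted site. With no passing calls the FDR is
#' reported as 0 with \code{no_calls = TRUE}.
#'
#' @param calls Call table (rows of \code{\link{callSites}} output,
#'   optionally classified) with a \code{treatment} column and
#'   \code{pass} flags.
#' @param truth Truth table from \code{\link{simulateExperiment}}.
#' @return List with \code{sensitivity}, \code{fdr}, \code{n_planted},
#'   \code{n_calls}, \code{n_matched}, \code{no_calls} and a
#'   \code{per_modification} data.frame.
#' @export
evaluateAgainstTruth <- function(calls, truth) {
    calls <- as.data.frame(calls)
    truth <- as.data.frame(truth)
    if (nrow(calls) && !is.null(calls$pass))
        calls <- calls[calls$pass, , drop = FALSE]
    key <- function(df, idx_col)
        paste(df$cluster_id, df[[idx_col]], df$treatment, sep = "|")
    tkey <- key(truth, "index0")
    ckey <- if (nrow(calls)) key(calls, "mod_index") else character(0)
    matched <- tkey %in% ckey
    fp <- sum(!(ckey %in% tkey))
    per_mod <- if (nrow(truth)) {
        agg <- stats::aggregate(matched, by = list(modification =
                                                   truth$modification), FUN = mean)
        names(agg)[2] <- "sensitivity"
        agg
    } else data.frame(modification = character(), sensitivity = numeric())
    list(sensitivity = if (nrow(truth)) mean(matched) else NA_real_,
         fdr = if (length(ckey)) fp / length(ckey) else 0,
         n_planted = nrow(truth),
         n_calls = length(ckey),
         n_matched = sum(matched),
         no_calls = length(ckey) == 0L,
         per_modification = per_mod)
}
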