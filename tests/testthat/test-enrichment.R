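## independent oracles -------------------------------------------------------

## upper-tail Poisson probability by direct pmf summation (truncated far
## beyond the mass)
bruteForcePoissonTail <- function(k, lam, kmax = 500L) {
    if (k == 0L) return(1)
    i <- k:kmax
    sum(exp(-lam + i * log(lam) - lgamma(i + 1)))
}

## step-up BH by its definition: q_(i) = min_{j >= i} m * p_(j) / j
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
}

test_that("cluster gamma is the treated/control read ratio", {
    t2000 <- makePileup("c1", stop5 = c(1500L, 500L), coverage = c(2000L, 500L))
    c1000 <- makePileup("c1", stop5 = c(700L, 300L), coverage = c(1000L, 300L))
    expect_equal(clusterGamma(t2000, c1000), 2)
    expect_equal(clusterGamma(c1000, c1000), 1)
    czero <- makePileup("c1", stop5 = c(0L, 0L), coverage = c(0L, 0L))
    expect_warning(g <- clusterGamma(t2000, czero), "zero control")
    expect_true(is.na(g))
})

test_that("fold change honours the pseudocount contract", {
    expect_equal(foldChange(39, 0, 1), 40)       # zero-count behaviour
    expect_equal(foldChange(10, 5, 2), 1)        # stop_plus == gamma*stop_minus
    expect_equal(foldChange(7, 7, 1), 1)         # fixed point
    ## alpha = 1, stop_minus = 0: FC = stop_plus + 1 for any gamma
    for (g in c(0.1, 1, 3.7))
        expect_equal(foldChange(12, 0, g), 13)
})

test_that("fold change is monotone in each argument", {
    sp <- 0:30
    fc <- foldChange(sp, 5, 1.3)
    expect_true(all(diff(fc) > 0))               # increasing in stop_plus
    sm <- 0:30
    fc2 <- foldChange(10, sm, 1.3)
    expect_true(all(diff(fc2) < 0))              # decreasing in stop_minus
    g <- seq(0.2, 5, by = 0.2)
    fc3 <- foldChange(10, 5, g)
    expect_true(all(diff(fc3) < 0))              # decreasing in gamma
})

test_that("Poisson survival p-values match closed forms and brute force", {
    expect_equal(poissonSfPvalue(0, 5), 1)       # whole support
    expect_equal(poissonSfPvalue(1, 1), 1 - exp(-1), tolerance = 1e-12)
    expect_equal(poissonSfPvalue(10, 2),
                 bruteForcePoissonTail(10L, 2), tolerance = 1e-12)
    expect_error(poissonSfPvalue(1, -1), "non-negative")
    ## the printed point-mass complement is available behind the debug flag
    expect_equal(poissonSfPvalue(3, 2, literal = TRUE), 1 - dpois(3, 2))
})

test_that("BH adjustment matches its step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)             # single p unchanged
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(5)
    for (i in 1:20) {
        p <- runif(sample(2:50, 1))
        expect_equal(bhAdjust(p), bruteForceBH(p))
    }
})

## helper: treated/control pair with one strongly enriched stop position
.enrichedPair <- function(stop_plus = 200L, cov_plus = 1000L,
                          stop_minus = 2L, cov_minus = 1000L,
                          stop_index0 = 20L, L = 60L) {
    sp <- integer(L); sp[stop_index0 + 1L] <- stop_plus
    sp[1L] <- cov_plus - stop_plus                 # rest full length
    cm <- integer(L); cm[stop_index0 + 1L] <- stop_minus
    cm[1L] <- cov_minus - stop_minus
    list(treated = list(c1 = makePileup("c1", sp, cumsum(sp))),
         control = list(c1 = makePileup("c1", cm, cumsum(cm))))
}

.simpleClusters <- function(L = 60L) {
    seqs <- Biostrings::DNAStringSet(setNames(strrep("A", L), "c1"))
    new("TRNAClusterSet", sequences = seqs,
        members = setNames(list("g1"), "c1"),
        isotype = setNames("Gly", "c1"),
        anticodon = setNames("GCC", "c1"),
        structure = setNames(NA_character_, "c1"),
        sprinzl = setNames(list(NULL), "c1"))
}

test_that("a strongly enriched position passes every gate, shifted one 5'", {
    pair <- .enrichedPair()
    res <- callSites(pair$treated, pair$control, .simpleClusters())
    hit <- res[res$stop_index == 20L, ]
    expect_equal(nrow(hit), 1L)
    expect_true(hit$pass)
    expect_equal(hit$mod_index, 19L)              # one position upstream
    expect_equal(hit$gamma, 1)
    q_oracle <- bruteForceBH(res$pvalue)[which(res$stop_index == 20L)]
    expect_equal(hit$qvalue, q_oracle)
})

test_that("count and percentage gates reject boundary sites", {
    ## 19 treated stops (all else passing): below the >= 20 count gate
    pair <- .enrichedPair(stop_plus = 19L, cov_plus = 400L)
    res <- callSites(pair$treated, pair$control, .simpleClusters())
    hit <- res[res$stop_index == 20L, ]
    expect_false(hit$pass)
    expect_false(hit$pass_count)
    expect_true(hit$pass_fdr && hit$pass_fc && hit$pass_percent)

    ## stop percentage 1.9 (all else passing): below the >= 2 percent gate
    pair <- .enrichedPair(stop_plus = 19000L, cov_plus = 1000000L,
                          stop_minus = 20L, cov_minus = 1000000L)
    res <- callSites(pair$treated, pair$control, .simpleClusters())
    hit <- res[res$stop_index == 20L, ]
    expect_equal(hit$stop_percent, 1.9)
    expect_false(hit$pass_percent)
    expect_false(hit$pass)
})

test_that("doubling both libraries leaves FC fixed and sharpens p-values", {
    pair1 <- .enrichedPair(stop_plus = 50L, stop_minus = 10L)
    pair2 <- .enrichedPair(stop_plus = 100L, cov_plus = 2000L,
                           stop_minus = 20L, cov_minus = 2000L)
    r1 <- callSites(pair1$treated, pair1$control, .simpleClusters())
    r2 <- callSites(pair2$treated, pair2$control, .simpleClusters())
    h1 <- r1[r1$stop_index == 20L, ]; h2 <- r2[r2$stop_index == 20L, ]
    expect_equal(h1$gamma, h2$gamma)              # gamma compensates
    ## exactly scale-free up to the pseudocount: exact with a negligible
    ## alpha, within a few percent at the default alpha = 1
    expect_equal(foldChange(100, 20, h2$gamma, alpha = 1e-9),
                 foldChange(50, 10, h1$gamma, alpha = 1e-9))
    expect_equal(h1$fc, h2$fc, tolerance = 0.05)
    expect_lte(h2$pvalue, h1$pvalue)              # enrichment sharpens
})

test_that("clusters missing a condition or control reads are skipped", {
    pair <- .enrichedPair()
    treated <- pair$treated
    treated$c2 <- treated$c1
    expect_warning(callSites(treated, pair$control, .simpleClusters()),
                   "only one condition")
    control0 <- list(c1 = makePileup("c1", integer(60), integer(60)))
    expect_warning(
        expect_warning(res <- callSites(pair$treated, control0,
                                        .simpleClusters()),
                       "zero control"),
        "no testable")
    expect_equal(nrow(res), 0L)
})

test_that("a pure-null comparison keeps the q < 0.01 fraction at nominal level", {
    ## treated and control drawn from the same stop process,
    ## 3 replicates, 120 clusters of 60 nt
    set.seed(2024)
    n_clu <- 120L; L <- 60L
    mkSample <- function() {
        lapply(setNames(seq_len(n_clu), paste0("c", seq_len(n_clu))),
               function(i) {
            sp <- rbinom(L, 40L, 0.01)
            sp[1L] <- sp[1L] + 500L
            makePileup(paste0("c", i), sp, cumsum(sp))
        })
    }
    pool3 <- function() {
        reps <- replicate(3, mkSample(), simplify = FALSE)
        lapply(setNames(names(reps[[1]]), names(reps[[1]])), function(id)
            poolPileups(lapply(reps, `[[`, id)))
    }
    seqs <- Biostrings::DNAStringSet(
        setNames(rep(strrep("A", L), n_clu), paste0("c", seq_len(n_clu))))
    ids <- names(seqs)
    cs <- new("TRNAClusterSet", sequences = seqs,
              members = setNames(as.list(ids), ids),
              isotype = setNames(rep("Gly", n_clu), ids),
              anticodon = setNames(rep("GCC", n_clu), ids),
              structure = setNames(rep(NA_character_, n_clu), ids),
              sprinzl = setNames(rep(list(NULL), n_clu), ids))
    res <- callSites(pool3(), pool3(), cs)
    expect_lte(mean(res$qvalue < 0.01), 0.01 + 0.01)  # Monte-Carlo slack
})
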