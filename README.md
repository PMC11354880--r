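# tRNAstopR

Treatment-based profiling of tRNA modifications from small-RNA sequencing,
at single-nucleotide resolution.

Several tRNA modifications become visible in sequencing data only after a
chemical treatment that makes them block reverse transcription (RT):
sodium borohydride (NaBH4) converts dihydrouridine (D) and
7-methylguanosine (m7G) — and, in practice, 4-thiouridine (s4U) at
position 8 — into RT blocks, and CMCT forms adducts on pseudouridine (Ψ).
Because the RT copies the template 3'→5' and falls off just before the
lesion, a blocked modification shows up as an excess of read 5' ends one
nucleotide 3' of the modified base in the treated library relative to its
control. Other modifications (inosine 34, m1A22, m1G37) need no treatment
and are read directly as base-misincorporation accumulations in untreated
libraries.

The package is aimed at groups running treated/control bacterial tRNA-seq
experiments (microbial physiology, RNA modification biology, thermal
adaptation studies) who need a reproducible path from alignments or
pileups to a per-position, per-condition modification table.

## The statistic at the core

For each tRNA cluster (genes with identical mature sequence, used as one
mapping reference) the control is scaled by the per-cluster read ratio
γ = ΣReads⁺ / ΣReads⁻. At each position n+1, with treated stop count
Stop⁺ and control stop count Stop⁻:

* fold change: FC = (Stop⁺ + α) / (γ·Stop⁻ + α), pseudocount α = 1;
* p-value: upper tail P(X ≥ Stop⁺ + α) for X ~ Poisson(γ·Stop⁻ + α);
* Benjamini–Hochberg FDR across all positions of the treated/control pair.

A site is called when q < 0.01, log₂FC > 1, Stop⁺ ≥ 20 and at least 2% of
the covering treated reads stop there; the call is reported at the
modified base, one position 5' of the stop (`mod_index = stop_index − 1`),
in Sprinzl numbering (1–76 with 17a/20a/20b and e-label insertions,
assigned structure-guided from the cloverleaf). Calls are classified
against an editable catalog of documented bacterial positions into
TP / type-I FP / type-II FP / ambiguous(m5U54) / shadow(G45).

## Worked example

A fully synthetic experiment — 6 clusters, 3 replicates of all four
treatments, one NaBH4-type and one CMCT-type site planted per cluster —
analyzed end to end:

```r
library(tRNAstopR)

sim <- simulateExperiment(simConfig(n_clusters = 6, depth = 1500, seed = 11))
res <- runProfile(sim$samples, sim$clusters, pileups = sim$pileups)

calls <- as.data.frame(res$calls)
calls[1:4, c("cluster_id", "sprinzl_label", "ref_base", "treatment",
             "stop_plus", "log2fc", "qvalue", "stop_percent",
             "status", "modification")]
#>   cluster_id sprinzl_label ref_base treatment stop_plus log2fc qvalue
#> 1  Ala-AGC-1             8        T     NaBH4       713   7.13      0
#> 2  Arg-ACG-1            16        T     NaBH4       754   6.98      0
#> 3  Asn-GTT-1            17        T     NaBH4       763   7.96      0
#> 4  Asp-GTC-1            20        T     NaBH4       754   5.86      0
#>   stop_percent   status modification
#> 1         19.2 TP_known          s4U
#> 2         20.5 TP_known            D
#> 3         20.2 TP_known            D
#> 4         19.9 TP_known            D
```

Each row is one called site: ~750 of ~3700 pooled treated reads (about
20%) stop one position 3' of the planted base, the fold change over the
γ-scaled control is 2⁶–2⁸, and the BH-adjusted p-value is numerically
zero. The summary counts distinct modified clusters per condition:

```r
res$summary
#>     site SimBacillus_30C
#> 1    D16               1
#> 2    D17               1
#> 3    D20               1
#> 4    D47               1
#> 5  m7G46               1
#> 6  Psi32               2
#> 7  Psi38               2
#> 8  Psi55               1
#> 9  Psi60               1
#> 10  s4U8               1

evaluateAgainstTruth(calls, sim$truth)[c("sensitivity", "fdr")]
#> $sensitivity
#> [1] 1
#> $fdr
#> [1] 0
```

Real data enter through `parseTrnascan()` + `buildClusters()` +
`assignSprinzl()` for the references, and `countFromAlignments()`
(SAM/BAM) or `readPileupTsv()` per sample, wired together by a sample
sheet (`runProfile()`). A thin command-line front end is installed at
`inst/scripts/trnastop.R`.

## Methods

See the vignette (`vignettes/tRNAstopR-methods.Rmd`) for the model, the
pseudocount and offset conventions, the Sprinzl labeling rules, what the
simulator does and does not emulate, and known limitations.
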