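---
title: "Profiling tRNA modifications from RT-stop and misincorporation signatures"
author: "tRNAstopR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tRNA modifications from RT-stop and misincorporation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAstopR)
```

# The measurement

Many tRNA modifications block or derail reverse transcription (RT). When a
small-RNA library is built by priming cDNA synthesis from the tRNA 3' end,
the RT walks the template 3' to 5' and, upon hitting a blocking lesion,
falls off: the read's 5' end piles up one nucleotide 3' of the modified
base. Two chemical treatments convert otherwise silent modifications into
such blocks:

* **NaBH4** (sodium borohydride) opens the saturated ring of dihydrouridine
  (D) and depurinates 7-methylguanosine (m7G); in this assay it also
  reveals 4-thiouridine (s4U) at position 8.
* **CMCT** (a carbodiimide) forms adducts on pseudouridine (Psi) that block
  RT; its no-reagent buffer control is the matching baseline.

A third class of modifications needs no treatment at all: inosine 34, m1A22
and m1G37 misincorporate bases at high rates and are read directly from the
mismatch composition of the untreated libraries.

Because tRNA genes occur in many identical copies, reads are assigned to
*clusters* of genes with identical mature sequence, and every position is
reported in Sprinzl numbering (1-76 with insertions 17a/20a/20b and
e-labels), so that "position 34" means the anticodon wobble base in every
tRNA regardless of its length.

# The enrichment test

For each cluster the control library is put on the treated library's scale
by the per-cluster ratio

$$\gamma = \frac{\sum \text{reads}^{+}_{\text{cluster}}}
                {\sum \text{reads}^{-}_{\text{cluster}}},$$

estimated per cluster so that expression differences between tRNAs do not
leak into the test. At every position $n+1$ with coverage in both
conditions, with treated stop count $\mathrm{Stop}^{+}$ and control stop
count $\mathrm{Stop}^{-}$, the effect size is the pseudocounted fold change

$$\mathrm{FC} = \frac{\mathrm{Stop}^{+} + \alpha}
                     {\gamma\,\mathrm{Stop}^{-} + \alpha},
  \qquad \alpha = 1,$$

and the significance is the upper tail of a Poisson background model,

$$p = P(X \ge \mathrm{Stop}^{+} + \alpha), \qquad
  X \sim \mathrm{Poisson}(\lambda), \quad
  \lambda = \gamma\,\mathrm{Stop}^{-} + \alpha .$$

The pseudocount enters both sides of the test consistently. This matters:
with a raw $\lambda = \gamma\,\mathrm{Stop}^{-}$, any position whose
control happens to draw zero stops would make a single treated stop
arbitrarily significant, and the null calibration collapses. With
$\alpha$ on both sides the package's pure-null simulations hold the
fraction of positions at $q < 0.01$ at or below the nominal level. A
`literal_eq3` debug flag exposes the point-mass complement
$1 - \mathrm{pmf}(k)$ for comparison; it is not a tail probability and is
never used for calling.

P-values are adjusted by Benjamini-Hochberg jointly over all positions of
a treated/control pair. A site is called when all four gates hold:

| gate | default | meaning |
|------|---------|---------|
| `fdr` | $q < 0.01$ | BH-adjusted significance |
| `min_log2fc` | $\log_2 \mathrm{FC} > 1$ | effect size (FC > 2) |
| `min_stops` | $\mathrm{Stop}^{+} \ge 20$ | guards low-coverage ratio blow-ups |
| `min_stop_percent` | $\ge 2\%$ of covering reads stop | treatment stops are proportionally strong |

The count and percentage gates exist because low coverage overestimates
ratios: a handful of stops over ten reads can produce a large fold change
that no one should believe. Replicates are pooled (raw counts summed)
before testing; the library-size normalization
(`normalizeLibrary`/`replicateMean`) is used for visualization and QC
only, because the test's $\gamma$ already performs between-sample
normalization and applying both would double-correct.

Finally the call is shifted one position 5': `mod_index = stop_index - 1`,
because the arrest occurs just before the RT would copy the modified base.
Stops at index 0 (full-length cDNAs) have no upstream base and are never
candidates.

# Classification

Passing calls are compared with an editable catalog of documented
bacterial positions: D at U16/17/20/20a/20b/21/47, m7G at G46 and s4U at
U8 for NaBH4; Psi at U13/31/32/38/39/40/55/60/65 for CMCT. Calls at
positions with a treatment-appropriate base (U for both; G only under
NaBH4, because only m7G makes G a target) but outside the catalog are
type I false positives; calls at bases the treatment cannot touch are
type II. CMCT calls at U54 are flagged ambiguous because only
ribothymidine (m5U) is documented there in bacteria and CMCT is not an
established probe for it. Stops at G45 adjacent to a called m7G46 in the
same cluster are flagged `shadow` and tallied separately: they track the
m7G46 lesion, not an independent modification. The catalog is a plain TSV
so that sites validated later (the s4U8 and Psi60 route: RT signal first,
mass-spectrometry confirmation second) can be promoted to TP without code
changes.

# Sprinzl assignment

The package assigns Sprinzl labels from the dot-bracket secondary
structure rather than by database alignment, removing the external
dependency while keeping the label vocabulary. The structure is segmented
into the four cloverleaf arms (acceptor stem; D, anticodon and T
hairpins; the variable region between the anticodon and T arms), and each
segment is filled with its canonical label run. Conventions for the
regions whose length varies, chosen once and applied deterministically:

* D-loop: the six core labels 14, 15, 18, 19, 20, 21 are always present;
  additional residues are admitted in the priority order 16, 17, 20a,
  20b, 17a and placed in 5' to 3' order. An 8-nt loop is therefore
  14-21, a 10-nt loop gains 20a/20b, an 11-nt loop also 17a.
* Variable region: up to five residues take 44-48, dropping 47 first
  (then 46, 45, 44) when shorter; longer (class II) arms are labeled
  44-47, e1..eN, 48, whether or not they pair internally.
* Anticodon and T loops must be exactly 7 nt so that the anticodon sits
  at 34-36 and the T-loop starts at 54; structures violating this (or
  any other segmentation assumption) raise an error suggesting a
  user-supplied map, which `assignSprinzl(override = )` accepts and
  passes through unchanged after a length check.

# The synthetic experiment

`simulateExperiment()` emulates the study design: three biological
replicates of four treatments, reads per cluster drawn from a Poisson
(default mean 2000, a realistic per-cluster depth for a multiplexed MiSeq
tRNA run), and a *sequential-survival* termination model: each read
starts at the 3' end and survives each position with probability
$1 - p_{stop}$. This matches the physical RT process and automatically
produces the coverage drop 5' of strong stops. The background stop
probability is 0.002 per position with a linear 3' bias (doubling toward
the 3' end by default), reflecting the RT's tendency to terminate
prematurely in the 3' range; planted sites elevate $p_{stop}$ to 0.2 at
the position one nucleotide 3' of the modified base, in the matching
treatment only. Default study conditions: 20 clusters, 40 planted sites
(one NaBH4-type and one CMCT-type per cluster, cycling through the
catalog positions), base-miscall sites only where configured.

What the simulation does *not* emulate: sequencing errors beyond
configured miscall sites, alignment ambiguity (pileups are generated
directly, so multi-mapping and clipping artifacts never occur), RT
fall-off that depends on RNA structure rather than position, partial
modification stoichiometry varying across replicates, and adapter or
quality artifacts. Passing recovery tests therefore demonstrate the
statistical chain end to end -- counting, gamma scaling, testing,
filtering, offset shift, classification -- but not robustness to mapping
noise in real libraries; for that, the SAM/BAM counting path is tested
separately against a per-read re-walking oracle.

# Numerical choices and degenerate inputs

* Poisson tails use the survival function (`lower.tail = FALSE`), stable
  for large counts; the brute-force pmf summation agrees to a relative
  error below 1e-9 over the tested grid.
* $\lambda$ is floored at 1e-9 purely defensively; with the pseudocount
  it is always at least $\alpha$.
* Clusters with zero control reads have undefined $\gamma$ and are
  skipped with a warning rather than guessed at.
* Pileup invariants (stop5 never exceeding coverage, non-negative
  counts) are enforced by class validity and at TSV read time.
* Base calls with Phred quality below 20 are excluded from the mismatch
  composition when counting from BAM, mirroring a confidence gate of the
  kind variant callers apply; the mismatch profiler additionally reports
  a one-sided binomial test against a 1% error rate.
* All internal indices are 0-based half-open; reported tables carry both
  the raw index (`index0`, for traceability) and the Sprinzl label.
* Sequences are held in the DNA alphabet (T, not U) because alignments
  and pileups live in DNA space; catalog "U" positions match reference T.

# Test problem sizes

The shipped test-suite simulations use 6-20 clusters at depths 200-2000
and the null calibration uses 120 clusters of 60 nt and 20 seeded
repetitions of the full default design; these sizes give stable Monte
Carlo behaviour for the asserted bounds while keeping the suite quick to
run. The binomial-sampling test of mismatch-fraction recovery plants
fractions in 0.05-0.15 at coverage 1000, the regime the signatures
occupy, where the 0.03 tolerance band is more than 2.6 standard
deviations wide.

# Known limitations

* Classification is catalog-driven: genuinely novel sites land in the
  type I FP bin until promoted, so the method cannot discover
  modifications at unexpected positions without external validation.
* The Poisson model assumes no substantial overdispersion between pooled
  replicates; strongly inconsistent replicates would need a
  negative-binomial extension, which is deliberately out of scope.
* Structure-guided Sprinzl assignment requires a clean four-arm
  cloverleaf; unusual tRNAs need a user-supplied map.
* The stop-percent denominator is the treated coverage at the stop
  position; for positions close to the 5' end of heavily stopped
  clusters this denominator is itself reduced by upstream terminations.
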