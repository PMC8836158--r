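---
title: "Methods: integrating multi-factor differential binding with differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating multi-factor differential binding with differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbind)
```

# The analysis crossbind implements

crossbind integrates ChIP-seq differential binding for several
transcription factors with RNA-seq differential expression. The motivating
setting is hepatic gene regulation under a xenobiotic agonist of the aryl
hydrocarbon receptor (AhR): AhR is cytosolic until ligand binding, so its
genomic enrichment relative to an IgG/input control is one-sided, whereas
constitutive factors such as COUP-TFII and HNF4A show both gains and
losses of binding after treatment. The package takes peak tables with
treated and control signal, a gene annotation, per-gene fold-change tables
with a posterior probability of differential expression, and gene-set
collections, and produces gene-level co-binding patterns, their
over-representation in gene sets of interest, functional enrichment,
preranked GSEA and known-motif enrichment.

The pipeline stages and their statistical content are:

1. **Differential peak enrichment.** Per peak,
   $\mathrm{FC} = (t + c_0) / (c + c_0)$ with treated signal $t$, control
   signal $c$ and pseudocount $c_0$ (default 1, which also bounds the
   fold-change when the control is zero). A peak is *increased* when
   $\mathrm{FC} \ge 1.5$, *decreased* when $\mathrm{FC} \le 0.6$,
   *no change* otherwise; both boundaries are inclusive. The thresholds
   are reciprocal 1.5-fold cutoffs (1/1.5 rounded to 0.6), which makes
   them deliberately asymmetric on the log2 scale
   ($+0.585$ vs $-0.737$).
2. **Region classification and gene assignment.** A peak is anchored at
   its center, $\lfloor (start + end)/2 \rfloor$; one anchor everywhere
   keeps region calls, gene assignment and distance histograms composable.
   A peak is *intragenic* when its center falls in the window from 10 kb
   upstream of any gene's TSS (strand-aware, since "upstream" is a
   strand-relative notion) to the end of its transcribed region, else
   *intergenic*. Among genes whose window contains the center, the
   assigned gene minimizes |center − TSS|; exact ties resolve to the
   lexicographically smaller gene identifier so the assignment is
   deterministic.
3. **DEG calling.** A gene/condition record is differentially expressed
   when its fold-change passes the same 1.5/0.6 thresholds *and* its
   posterior probability P1(t) is at least 0.8 (non-strict: the published
   rule does not say otherwise, and a non-strict reading matches the
   inclusive fold-change boundaries). P1(t) is consumed from the input
   table, never recomputed.
4. **Gene-level binding patterns.** Per gene and factor, the direction is
   the differential status of the intragenic peak with the largest
   |log2 FC|; exact magnitude ties resolve to *increased*. The source
   analyses report one direction per factor per gene without stating an
   aggregation rule, so a deterministic one is required; taking the
   strongest peak is the least surprising choice and is monotone in
   effect size. Unbound factors are recorded separately in the table and
   collapsed into *no change* for over-representation, because the tested
   pattern space ranges over increase/decrease/no-change; the
   `collapse_unbound = FALSE` mode keeps unbound as its own level.
5. **Over-representation.** For a pattern (or gene set) with $K$ carriers
   in a reference universe of size $N$, observing $k$ carriers in a target
   of size $n$ is scored by the one-sided Fisher's exact test
   $p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, computed
   exactly via the hypergeometric tail. FDR correction is
   Benjamini–Hochberg (the procedure is fixed because the source says
   only "FDR correction"). The co-regulation rule counts a gene as
   affected when at least one member factor of its bound combination has
   a differentially enriched peak.
6. **Preranked GSEA.** Genes are ranked by decreasing log2 fold-change;
   the running sum gains $|s_i|^w / \sum_{hits} |s|^w$ at members and
   loses $1/(N - N_h)$ at non-members; the enrichment score is the signed
   extreme deviation ($w = 1$ by default, matching the weighted statistic
   of GSEA v4, which the workflow this package systematizes used with its
   defaults; $w = 0$ recovers the Kolmogorov–Smirnov form). Because only
   a preranked list exists, the null is gene-label permutation: member
   positions are redrawn uniformly, preserving set size. NES divides ES
   by the mean |null ES| of matching sign; the nominal p is the fraction
   of same-sign null ES at least as extreme; the FDR q compares the
   pooled sign-normalized null with the observed NES distribution,
   stratified by sign and made monotone in |NES|. 1000 permutations by
   default; the seed is a required argument, never taken from the clock.
7. **Motif enrichment.** Position weight matrices are scored as summed
   log2 odds against background base frequencies; `N` bases contribute
   zero; both strands are scanned; a sequence is a hit when any window
   reaches the threshold, by default 80% of the motif's maximal score
   (common practice; the upstream tooling does not publish its
   threshold). Enrichment of hit frequency in target versus background
   sequences uses the same Fisher implementation as stage 5,
   sequence-level rather than hit-level because the figures this mirrors
   report "% of sequences possessing" a motif. Background sequences are
   user-supplied (typically non-differential peaks from the same run);
   GC-matched resampling is a known omission of this version.

## Coordinate conventions

Internally every interval is 0-based half-open and every anchor (TSS, TES,
peak center) a 0-based position; GTF input converts at the boundary
(1-based inclusive to 0-based half-open) and BED input is already in the
internal convention. One convention everywhere prevents off-by-one drift
between stages. On the `+` strand the TSS is `start` and the TES is
`end − 1`; on `-` the TSS is `end − 1` and the upstream window extends to
the right.

## Tie and edge-case policy

* Fold-changes of zero-signal peaks are defined through the pseudocount;
  negative signals are an error, not clamped.
* Status boundaries are inclusive on both sides.
* Closest-gene ties: lexicographically smaller `gene_id`.
* Direction ties at equal |log2 FC|: `increased`.
* ES magnitude ties between the positive and negative extreme: the
  positive deviation wins, with a 1e-12 tolerance because the running
  sum's rational steps make exact floating-point ties common.
* Ranking-score ties keep stable input order and are reported.
* Center-distance ties between an upstream and downstream neighbor take
  the downstream (positive) distance.
* Genes absent from an expression table at some condition are not
  differentially expressed there, not an error.
* Peaks on chromosomes missing from the annotation are kept, classified
  intergenic, and reported once per file.

# The synthetic-data generator

Every stage is exercised end-to-end on generated data with planted ground
truth; `simulation_config()` fixes the study conditions and one seed
governs every draw (per-stage seeds are small fixed offsets of it), so
artifacts are byte-identical across runs.

The defaults emulate the headline structure of the motivating study:
three factors with intragenic binding fractions 0.574 (AhR-like), 0.815
(COUP-TFII-like) and 0.764 (HNF4A-like); median log2 fold-changes +0.99,
−0.30 and +0.13; zero control signal for the AhR-like factor (its
fold-change distribution is truncated at zero, so no peak can classify as
decreased); 5000 peaks per factor; 1500 genes on three 30-Mb chromosomes;
an eight-dose expression design (0.01–30, log-spaced) whose headline
condition carries the full planted effect; a 30% DEG fraction; and a
planted coupling in which genes bound with the pattern (AhR increased,
COUP-TFII decreased, HNF4A increased) are repressed with mean log2 FC
−1.5 — the package's analogue of the repression-with-co-binding signal
the integration is designed to detect.

Generator design notes:

* **Signals invert the fold-change exactly.** Control signal is drawn
  (uniform 10–100, or zero for the AhR-like factor) and the treated
  signal is constructed as $(c + c_0)\,2^{\mathrm{lfc}} - c_0$, so the
  pipeline's fold-change recovers the planted log2 FC to machine
  precision and median recovery is limited only by sampling noise.
* **Intragenic placement is exact by construction.** A peak center is
  planted inside a uniformly chosen gene's window with the target
  probability, and intergenic centers are rejection-sampled against all
  windows, so the realized fraction differs from the target only by
  binomial noise (sd ≈ 0.006 at 5000 peaks).
* **P1(t) is phenomenological.** The posterior is modeled as
  `plogis(10 (|lfc| − 0.3))` plus Gaussian noise (sd 0.02), clamped to
  [0, 1]. The upstream quantity is consumed, never defined, by the
  analyses this package implements; only its thresholding behavior at
  0.8 matters, and the logistic model makes that behavior a smooth,
  controllable function of effect size.
* **Random DEGs respect the asymmetric thresholds.** Induced genes need
  |log2 FC| ≥ 0.585 but repressed genes need ≥ 0.737, so the generator
  draws the excess magnitude above the side-specific minimum
  (exponential, rate 1/0.6). An early symmetric draft systematically
  undershot the target DEG fraction by the mass between the two cutoffs.
* **Pattern–expression coupling is planted at the gene level**, not
  mechanistically: the artifact tests the inference machinery, not
  biology.
* **What the generator does not emulate:** read-level noise, chromatin
  signal shapes, GC composition, correlated peak widths, overlapping
  genes, orthologue mapping. Passing recovery tests therefore
  demonstrates the correctness of the inference machinery under the
  planted model, not performance on real libraries.

`simulate_pattern_table()` and `sample_enriched_target()` bypass the peak
layer and plant binding patterns directly at configured frequencies and
target enrichment odds — the fast route for power and calibration studies
of the over-representation stage.

# Verification design and problem sizes

The test suite verifies each statistic against an independent oracle and
each generator parameter by round trip:

* Fisher tail vs brute-force `choose()` enumeration for every table with
  universe ≤ 30, plus random spot checks.
* Enrichment score vs an explicit position-by-position running-sum loop
  on 1000 random lists of up to 50 genes, and against the weighted
  statistic of the independent fgsea implementation (magnitudes always;
  signs except on exact magnitude ties, where conventions differ).
* Overlap counting vs all-pairs interval intersection on random peak
  sets.
* Planted-pattern recovery: a pattern planted at odds ratio 8 in a
  150-gene target within a 3000-gene reference must be the top-ranked
  pattern at q < 0.05 in at least 95 of 100 seeded replicates.
* Emulation round trip at 5000 peaks per factor: intragenic fractions
  within ±0.03 and median log2 FC within ±0.05 of the planted values.
* Determinism: regenerated artifacts and repeated GSEA runs are
  byte-identical per seed.

**Null calibration and discreteness.** Under no planted association,
pattern-ORA p-values should be uniform (Kolmogorov–Smirnov over 1000
replicates). Exact tests on discrete counts are conservative:
$P(p \le t) \le t$ with a deficiency of about half the maximal
hypergeometric pmf. The calibration study is therefore sized so that this
deficiency is far below what the KS test can resolve: a universe of
20000 genes, a target of 10000, and pattern frequencies of 0.3–0.4 give
the overlap count a standard deviation near 33, a p-value grid step near
0.012, and a deficiency near 0.006 against a KS resolution of 0.0515 —
at a smaller target size (a few hundred genes) the same uniformity check
fails purely through discretization bias, not through any defect of the
test. GSEA calibration uses 100 random 50-gene sets on a 1000-gene list
with 200 permutations and checks that |NES| centers at 1 and nominal
p-values are uniform.

Problem sizes throughout (demo: 800 genes, 2000 peaks per factor;
recovery: 3000-gene references; calibration: as above) were chosen once
as the smallest sizes at which the binomial/KS tolerances above are
meaningful, and the methods scale linearly in peaks and genes.

# Parameters that matter

| Parameter | Default | Units | Where | Why |
|---|---|---|---|---|
| `fc_up`, `fc_down` | 1.5, 0.6 | linear FC | peaks, DEGs | reciprocal 1.5-fold cutoffs, inclusive |
| `p1t_min` | 0.8 | probability | DEGs | published posterior cutoff, non-strict |
| `upstream_bp` | 10000 | bp | region class | intragenic = 10 kb upstream of TSS to TES |
| `pseudocount` | 1 | signal units | fold-change | bounds FC at zero control |
| `weight` | 1 | — | GSEA | weighted running-sum exponent |
| `n_permutations` | 1000 | — | GSEA | permutation-null resolution |
| `threshold_frac` | 0.8 | fraction of max score | motifs | common log-odds cutoff |
| `max_distance`, `bin_width` | 10000, 1000 | bp | overlap histograms | clamp and bin for center distances |

# Known limitations

* The ORA reference universe is the caller's choice (all DEGs at the
  tested condition in the workflow this mirrors); whether genes with no
  detected binding belong in it is analysis-dependent, and both modes
  are supported via `collapse_unbound` and the choice of
  `reference_genes`.
* Motif backgrounds are user-supplied; no GC matching.
* The GSEA nominal p is a plain same-sign permutation fraction and can
  be zero at finite permutation counts; the q-value, not the nominal p,
  is the calibrated quantity.
* Genome-scale results from the motivating study (absolute peak totals,
  specific ORA p-values, NES values) depend on its deposited datasets
  and are out of scope; the package's claims are about the machinery,
  verified on planted ground truth.
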