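---
title: "Models and methods behind acceptorscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acceptorscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`acceptorscape` characterises the architecture of 3' splice sites (3'ss)
for groups of internal exons — typically a splicing-factor-activated
set, a repressed set, and a large control set. The quantities it
computes are the ones this field uses to describe an acceptor region:

* the **AG-dinucleotide exclusion zone (AGEZ)** — the AG-free stretch
  upstream of the 3'ss AG within which the branch point must sit;
* **polypyrimidine tract (PPT)** composition metrics, including the
  G-rich versus C-rich backgrounds that distinguish bipartite tracts;
* PWM-scored **branch-point (BP) candidates** and the distance of the
  best candidate to the 3'ss;
* **probability-unpaired (PU)** profiles — a partition-function measure
  of RNA single-strandedness around both splice sites;
* positional nucleotide composition with Bayesian credible intervals,
  k-mer enrichment, and the group statistics (Wilcoxon–Mann–Whitney,
  correlation, chi-squared, BH-FDR).

All positions use signed splice-site frames with **no position 0**: in
the acceptor frame, −1 is the G of the intron-terminal AG and +1 the
first exon base; in the donor frame, −1 is the last exon base and +1
the G of the intron-initial GU/GC.

# The folding model and PU values

PU of a span is the Boltzmann-ensemble probability that every base of
the span is unpaired:

$$\mathrm{PU}(i..j) = \frac{Z_{i..j\ \text{unpaired}}}{Z},$$

computed by McCaskill-style inside recursions over nested secondary
structures, with the constrained numerator obtained by excluding the
span's bases from pairing. The energy model is deliberately small: one
energy per canonical pair type (defaults GC −3.0, AU −2.0, GU −1.0
kcal/mol), a stacking bonus (−1.0) when two pairs are immediately
nested, a minimum hairpin loop of 3 nt, and kT = 0.6156 kcal/mol
(37 °C). Recursions run on per-nucleotide rescaled long-double arrays,
so partition functions up to several hundred nt neither overflow nor
underflow, and Z is reported in log space. Base-pair probabilities come
from the matching outside pass and satisfy, for every base,
unpaired + Σ pair probabilities = 1 to better than 1e−9 (this is
tested against exhaustive structure enumeration).

Positional PU values follow the pentamer convention: the PU of the
pentamer centred at a position is computed inside three symmetric
sequence contexts of 10, 20 and 30 nt on each side (truncated at
sequence ends), and the arithmetic mean of the three is assigned to the
centre position. Whether the average is arithmetic, and whether
boundary pentamers are truncated or dropped, is not externally fixed;
we chose arithmetic means and truncation, because truncation lets
regulated exons with short available flanks contribute to the profile
rather than vanishing from it.

**What the absolute numbers mean.** This model has no loop-entropy
penalties, so absolute PU values are compressed relative to
full-parameter folding engines (random intron-like background sits
near PU ≈ 0.01–0.05 here, versus ≈ 0.3 under Turner-parameter models).
All analyses in the package therefore compare PU **within a run** —
group versus group, real versus shuffled — where the monotone mapping
between models is irrelevant. An external folding engine can be
substituted wherever a `(sequence, span) -> PU` adapter fits. One
physically interesting consequence at this energy scale: a planted
hairpin *lowers* PU at its stem positions but *raises* it at the loop,
and can raise the window mean; tests therefore assert the per-position
form of the hairpin effect.

# Shuffled controls

Background sequences preserve local composition exactly: each unmasked
flank segment is shuffled by the Euler-path (Altschul–Erickson)
construction on the dinucleotide multigraph, implemented with uniform
arborescence sampling so every valid rearrangement is equally likely —
a property verified by exhaustive enumeration on short strings.
Mono- and dinucleotide counts and segment endpoints are conserved
exactly, never approximately. The default mask preserves the splice
sites and the last/first 10 intronic nt; the exon body is never
shuffled. Upstream and downstream flanks are shuffled independently
(a documented choice; whether the original procedure shuffled them
jointly is not stated anywhere we could anchor to, and independence
preserves per-flank composition).

# AGEZ, branch points, splice-site strength

The AGEZ scanner reports the number of nucleotides strictly between
the G of the nearest upstream AG (G at position ≤ −3) and the A of the
3'ss AG. When no upstream AG exists within the flank the value is
**censored** at flank length − 2; group summaries default to clamping
censored values (matching a fixed-window analysis), and callers can
drop them instead — the choice matters only for extreme flank lengths.

Branch points are scored by a configurable PWM with a designated
branch-A column (default: a smoothed heptamer matrix around UACUAAC,
branch A at column 6, matching the synthetic generator's planting
distribution; published matrices can be supplied instead). Every
A-anchored window in the search range (default −9 down to
−min(100, flank)) is scored; ties break towards the 3'ss-proximal
candidate, the deterministic convention under which proximal branch
points dominate control exons. Splice-site strength is PWM log-odds
over windows straddling the splice sites (defaults: 20 intronic + 3
exonic nt at the acceptor, 6 + 3 at the donor), with PWMs estimated
from the run's own control set — scores are comparable within a run,
which is how they are used.

# Composition statistics

Per-letter credible intervals use the Beta marginal of a symmetric
Jeffreys-style Dirichlet posterior, Beta(c + 1/2, n − c + 1/2),
equal-tailed at 95%. The exact flavour of "Bayesian interval" is a
convention choice; this one is calibrated (93–97% coverage at n = 100
in the Monte-Carlo check) and configurable. Information content is
2 − H (bits) against an equiprobable background with no small-sample
correction — the intervals carry the uncertainty.

Positional enrichment of a letter compares two groups per position
(Fisher where any expected count < 5, otherwise the two-proportion
z-test), BH-adjusted across positions. The op reports the significant
positions, the longest contiguous significant run, **and the detected
enrichment region** — the span from first to last significant
position. The region, not the significant set, is the window estimate:
a tract with alternating-U structure is significant at alternating
positions by construction, while the biological statement being made
is about a region's extent.

The Wilcoxon–Mann–Whitney implementation reports U with mid-rank ties
and uses the exact distribution when n1·n2 ≤ 400 with no ties,
otherwise the tie-corrected normal approximation with continuity
correction, tagging which path was taken. k-mer enrichment counts
per-sequence presence by default (occurrence counting is length-biased;
a flag restores it) and tests all 4^k k-mers by Fisher with BH.

# The synthetic study generator

The generator is first-class, tested code: it emits exon groups in
which **every analysed feature is planted and literally verifiable on
the emitted strings** (truth-table claims are re-checked by independent
string scans in the tests). Defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| group sizes | 120 / 20 / 500 | activated / repressed / control |
| flank, exon | 150 / 80 nt | context geometry |
| background | A .27, C .21, G .21, U .31 | intron-like composition |
| AGEZ | Gamma(3), control mean 37 nt | activated mean ×1.51 |
| BP distance | N(52, 8) vs N(25, 6) | planted heptamer UACUAAC |
| U window | −18..−50, +0.25 U | bipartite, alternation ×0.75 |
| coupling | log2fold = −27·PU(−4..−100) + N(0, 0.35) | activated exons |

The bipartite U window alternates high/low U positions and tilts the
non-U background C-rich in the 3'-proximal half and G-rich in the
distal half, mimicking bipartite PPTs. Repressed exons get U→G mass
transfer in the same window. AGEZ enforcement redraws AG-forming bases
inside the zone sequentially (position-wise resampling, not post-hoc
editing), which keeps composition near background but — as in real
acceptors — makes long AGEZs mildly A/G-depleted overall; the
localisation check in the acceptance suite accounts for this real
secondary effect.

The coupling slope is in log2-fold units per PU unit; its magnitude
reflects the compressed PU scale of the folding model (PU summaries
vary with sd ≈ 0.008 across exons), and targets a population
correlation near −0.5 at n = 120 — deliberately stronger than
correlations reported for real exon sets, to make recovery decisively
testable; this is a testability choice, not a claim about real data.
Two calibration trade-offs are worth recording: a coupling far weaker
than this plants no recoverable signal at all, and a coupling far
stronger (r ≈ −0.8) leaks any chance sample-correlation between
upstream and downstream PU summaries into the downstream
discriminant check (r_down ≈ r_up · r_up,down), degrading its
calibration. The default sits between those regimes.

**What the generator does not emulate:** real intron length variation,
splice-site strength heterogeneity, transposed-element-derived tracts,
correlated k-mer structure beyond the planted motifs, or read-level
noise in exon-usage estimates. Passing recovery tests demonstrates the
pipeline's internal correctness on data with known truth, not the
effect sizes of any real dataset.

# Pipeline determinism and problem sizes

`run_profile` writes a deterministic report bundle: fixed column
orders, `%.10g` numeric formatting, LF newlines, JSON without
timestamps, and a provenance block whose config hash covers scientific
parameters only (never run-local paths). Two runs with the same seed
are byte-identical; this is asserted file-by-file (md5) in the tests.
The shuffled-background PU profile subsamples (default 3 shuffles per
exon, 50 exons per group) — an unbiased estimator of the background
mean; full 100-shuffle backgrounds remain available via configuration.

The test suite runs folding oracles at enumerable lengths (≤ 14 nt,
against brute-force structure enumeration), the shuffle invariants at
1,000 random sequences, WMW against full permutation enumeration for
all n1, n2 ≤ 8, CI coverage on 2,000 simulated columns, and the
end-to-end recovery on the default 120/500 study; the determinism
check uses a 40-exon study so that two full bundles fit comfortably in
a desk-scale run.

# Known limitations

* Absolute PU values are model-dependent (see above); only
  within-run contrasts are meaningful.
* The branch-point scorer is a PWM, not a trained classifier; its
  scores rank candidates within a run and recover planted consensus
  sites, but are not calibrated probabilities.
* The downstream-correlation discriminant in the recovery suite is a
  single-draw null check at α = 0.05 and is expected to fail for
  roughly one seed in twenty by construction.
* `select_control_exons` trusts the annotation's principal-isoform
  flags; principality is never inferred.
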