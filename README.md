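# acceptorscape

Analysis of 3′ splice-site (3′ss) architecture for groups of internal
exons — e.g. a splicing-factor-activated set, a repressed set and a
control set. Exons activated by polypyrimidine-tract-binding factors
tend to differ from controls in a coordinated way upstream of their
acceptors: longer AG-dinucleotide exclusion zones (AGEZ), more distant
branch points (BP), U-rich tracts, and greater RNA single-strandedness
across the branch-site region. `acceptorscape` computes all of these
quantities from genome sequence and exon tables, compares groups with
the field's standard statistics, and ships a synthetic-study generator
that plants every feature so the whole pipeline is testable against a
known truth table.

What it computes, per exon and per group:

* **AGEZ length** — nucleotides strictly between the G of the nearest
  upstream AG (position ≤ −3) and the A of the 3′ss AG, with explicit
  censoring when no upstream AG is in the flank;
* **PPT metrics** — U/pyrimidine fractions, longest runs, G-rich vs
  C-rich non-U backgrounds (bipartite tracts);
* **branch-point candidates** — PWM log-odds over every A-anchored
  window in the search region; best-BP-to-3′ss distance with a
  3′ss-proximal tie-break;
* **PU values** — probability that a pentamer is unpaired under the
  Boltzmann ensemble of nested secondary structures,
  `PU(i..j) = Z_constrained / Z`, averaged over 10/20/30-nt symmetric
  contexts and assigned to the pentamer centre; positional profiles in
  the acceptor (−100..+10) and donor (−10..+100) frames, against
  dinucleotide-preserving shuffled backgrounds (Euler-path /
  Altschul–Erickson construction, splice sites and terminal 10
  intronic nt masked);
* **group statistics** — Wilcoxon–Mann–Whitney (exact when
  n1·n2 ≤ 400 and tie-free), Pearson/Spearman correlation of PU
  summaries with exon-usage log2fold values, Pearson χ², BH-FDR,
  positional composition with Jeffreys-style Beta credible intervals,
  and k-mer enrichment scans.

All analysis positions use signed splice-site frames with no position
0 (acceptor: −1 = G of the 3′ss AG, +1 = first exon base; donor: −1 =
last exon base, +1 = G of the 5′ss GU/GC).

## Worked example

Generate a small synthetic study (30 activated vs 60 control exons,
planted AGEZ ratio 1.51, branch points at ~52 vs ~25 nt, U-rich window
−18..−50, negative PU–log2fold coupling) and analyse it:

```r
library(acceptorscape)

spec  <- synthetic_spec(n_activated = 30, n_repressed = 0,
                        n_control = 60, seed = 42)
study <- generate_study(spec)
study
#> SyntheticStudy: 90 contexts (activated=30, control=60)

cfg   <- run_config(contexts = study$contexts, seed = 42, outdir = "report")
feats <- exon_feature_table(study$contexts, cfg)
aggregate(cbind(agez_len, best_bp_distance, pu_bp_window) ~ group,
          feats, mean)
#>       group agez_len best_bp_distance pu_bp_window
#> 1 activated     55.1             54.1       0.0212
#> 2   control     38.3             24.2       0.0155

act <- feats$group == "activated"; ctl <- feats$group == "control"
mann_whitney_u(feats$agez_len[act], feats$agez_len[ctl])
#> GroupComparison [normal-approx]: statistic U = 1213.5, p = 0.007363
mann_whitney_u(feats$best_bp_distance[act], feats$best_bp_distance[ctl])
#> GroupComparison [normal-approx]: statistic U = 1800, p = 1.305e-14
correlation(feats$pu_up[act], feats$log2fold[act])
#> GroupComparison [pearson]: statistic r = -0.456604, p = 0.0112
```

Reading the output: the activated group's mean AGEZ is 55.1 nt versus
38.3 for controls (ratio ≈ 1.44, drawn around the planted 1.51); best
branch points sit ~54 vs ~24 nt upstream of the 3′ss; the branch-site
window (−18..−40) is more single-stranded for activated exons (PU
0.021 vs 0.016 — absolute PU values are compressed under the
simplified energy model and are meaningful as within-run contrasts);
and exon-usage log2fold values correlate negatively with upstream PU
(r = −0.46), i.e. exons with more accessible acceptor regions lose
more inclusion when their activator is depleted. At this small n the
PU group test is underpowered (p ≈ 0.15); the full-size study (120 vs
500) separates the groups at p < 0.001.

`run_profile(cfg)` runs the whole pipeline (features → composition →
PU profiles with shuffled backgrounds → k-mer scan → statistics) and
writes a byte-deterministic report bundle (`features.tsv`,
`composition.tsv`, `pu_profile.tsv`, `kmers.tsv`, `stats.json`,
`provenance.json`, `run.log`).

Real data enter through `read_exon_table()` (BED6+ or TSV, 0-based
half-open) plus a genome FASTA via `extract_contexts()`, through the
structured-header context FASTA dialect
(`>exon_id|group|log2fold|up_len|exon_len|down_len`, sequence =
upstream+exon+downstream), or via `select_control_exons()` applied to
an annotation (internal exons of the longest principal isoform, length
> 60 nt, flanking introns > 400 nt, AG..GU/GC boundaries).

A thin command-line wrapper with `simulate`, `run` and `shuffle`
subcommands is installed at `inst/scripts/acceptorscape.R`.

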