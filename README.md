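# rediaDOL

Division-of-labor (DOL) pattern assessment for trematode redia colonies.

Redia-producing trematodes proliferate clonally inside snail hosts, and in
many marine species the clone splits into castes: large *reproductive*
rediae packed with embryos, and small, active *soldier* rediae with
relatively enormous muscular pharynges that attack co-infecting
trematodes. Evidence for (or against) this division of labor in a sampled
colony is a battery of per-colony patterns, not one statistic. `rediaDOL`
implements that battery for researchers working from photo-based
morphometric tables, presence scores, movement trials, attack trials and
COI barcodes — and ships a ground-truthed synthetic colony generator so
every stage can be validated without any field data.

## What it computes

For each colony (all rediae from one infected snail):

- **Morphometrics** — cylindrical body volume `V = pi (w/2)^2 L`,
  spherical pharynx volume `v = (4/3) pi (d/2)^3`, relative pharynx size
  `v / V`, and standard linear size `V^(1/3)` (all from micrometre
  measurements).
- **Size designation** — Shapiro–Wilk on log volumes, then an explicit
  histogram-trough rule on the default-binned `log10` histogram for
  bimodality (code `Y` / `N*` / `N`); bimodal colonies split small/large
  at the trough, others fall back to quartiles (small ≤ Q1 < intermediate
  < Q3 ≤ large, interpolated quantiles).
- **Pattern battery** — coded per-colony results in the field's summary
  vocabulary: Reproduction (max embryo score of the five smallest rediae,
  `Y`/`Y?`/`U`/`N`), Morphology (anterior + posterior appendage scores,
  one-tailed rank-sum, `Y`/`O`/`N`), Pharynx (one-tailed rank-sum on
  relative pharynx size, small > large, `Y`/`N`/`NA`), %Small,
  Distribution (per-section Clopper–Pearson intervals on the proportion
  of small rediae, `Y`/`O`/`N`/`NA`), Activity (two-tailed rank-sum on
  relative 2-s distance, `S`/`NS`/`NA`), Attacks (`Y`/`N`/`NA`), plus a
  Tukey-fence (`Q3 + 1.5 IQR`) screen for large-pharynx subpopulations.
  Rank-sum p-values are exact (full enumeration, ties handled by midrank
  permutation) whenever the combined sample is ≤ 12, and tie- and
  continuity-corrected normal approximations otherwise. `alpha = 0.05`
  throughout, with no multiple-testing adjustment.
- **COI species** — percent-identity matrix (built-in Needleman–Wunsch
  aligner or pre-aligned FASTA), single-linkage clustering at ≥ 95%
  identity into putative "COI species".
- **Reporting** — per-colony coded rows, per-(species × medium) and
  overall aggregate count strings ("4Y", "1Y/2N*", ...), TSV and JSON
  output.

## Worked example

```r
library(rediaDOL)

sim <- simulate_colony(colony_sim_config(n_rediae = 120,
                                         medium = "saline", seed = 42))
a <- assess_dol(sim$colony)
print(a)
#> Division-of-labor assessment: colony SIM1 (saline)
#>   120 rediae: 21 small / 0 intermediate / 99 large (histogram_trough)
#> [volume] Y
#> [reproduction] Y
#> [morphology] N
#> [pharynx] Y (p = 5.152e-09)
#> [pct_small] 18%
#> [distribution] Y
#> [activity] NS (p = 0.162)
#> [attacks] N
#> [large_pharynx] not_flagged
```

Reading the codes: the colony's log-volume distribution is bimodal
(`volume Y`), so rediae were split at the histogram trough — 21 small,
99 large, 18% small. The small rediae have significantly larger pharynges
relative to their bodies (`pharynx Y`, one-tailed rank-sum p ≈ 5e-9) and
sit disproportionately in the snail's head/foot (`distribution Y`), both
soldier-consistent. But embryos are clearly visible in the smallest five
rediae (`reproduction Y`), appendage scores do not differ (`morphology
N`), relative movement does not differ (`activity NS`) and small rediae
did not out-attack large ones (`attacks N`) — the typical freshwater
profile: no dedicated non-reproductive soldier caste despite the pharynx
signal.

Colony tables can also be read from CSV (`read_measurements()`,
`read_scores()`, `read_activity()`, `read_attacks()`, `attach_tables()`),
and batches summarized with `summarize_colonies()` /
`aggregate_summaries()` / `write_report()`. COI FASTA files are clustered
with `cluster_coi(path, threshold = 95)`.

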