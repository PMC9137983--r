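# pocketcons

Combined evolutionary-conservation and druggability analysis of protein
binding pockets, as an open, fully tested R pipeline.

Broad-spectrum antibacterial target validation asks three questions about a
candidate pocket: can a small molecule bind it at all (*ligandability*),
can a drug-like molecule bind it (*druggability*), and is it conserved
across pathogens so an inhibitor keeps working and resistance has little
room (*evolutionary conservation*)? pocketcons answers all three from
standard inputs — PDB structures, FASTA/Clustal alignments, Newick trees —
and classifies each detected pocket with a combined filter.

## What it computes

* **Conservation** — BLOSUM62 pairwise distances, a neighbor-joining tree,
  tree-weighted (Gerstein–Sonnhammer–Chothia) sum-of-pairs column scores
  standardised to mean 0 / sd 1, binned into nine grades (9 = most
  conserved; "conserved" = grades 8–9), and projected onto structure
  residues by global sequence alignment.
* **Pockets** — grid-based site-point detection (vdW exclusion, 4 Å
  proximity, ray-cast burial ≥ 0.5 over 110 rays), connected-component
  sites (≥ 15 points, ≤ 10 sites), a descriptor block (volume, exposure,
  enclosure, contact, phobic/philic, balance, donor/acceptor, charged
  fraction) and the published druggability equations

      SiteScore = 0.0733·√min(n,100) + 0.6688·e − 0.20·min(p, 1)
      DScore    = 0.094 ·√min(n,100) + 0.60 ·e − 0.324·p

  with the 0.8 ligandable/druggable threshold (the reference
  submicromolar-site profile scores 1.0547 / 1.084).
* **Hotspots** — the canonical 16-probe fragment library mapped over the
  surface, consensus clusters ranked by total nonbonded contacts, and
  top-3 binding-site prediction with 4 Å lining extraction.
* **Assessment** — orthosteric/cofactor/other typing, SiteScore×DScore
  quadrants, the combined filter (scores ≥ 0.8, then conserved fraction
  ≥ 0.5; charged fraction > 26.3% flags a hard-to-drug site),
  conservation summaries over secondary structure, exact Mann–Whitney
  group comparisons, and inhibitor TPSA / donor–acceptor comparison.
* **Synthetic data** — generators for cavity-bearing structures (controlled
  radius, mouth opening, lining polarity), conformational ensembles with
  planted families, alignments evolved along a known tree with slow/fast
  site-rate classes, and candidate-site tables, so every stage is testable
  with known ground truth.

Everything is tibble-first: results are data frames that pipe into dplyr,
have `tidy()`/`glance()` methods, and plot with `autoplot()` /
`plot_quadrants()` / `plot_conservation_summary()`.

## Worked example

Generate a structure with a planted, ligand-marked 4 Å cavity, then run the
whole pipeline at a 0.8 Å test grid:

```r
library(pocketcons)

cfg <- pipeline_config(
  structure = structure_spec(shell_radius = 12, cavity_radius = 4,
                             mouth_fraction = 0.1, residue_count = 40,
                             plant_ligand = TRUE, seed = 5),
  spacing = 0.8, seed = 11)
report <- run_pipeline(cfg)
report
#> <assessment_report>
#>   sites detected: 1
#>   retained by combined filter: 1
#>   probe consensus clusters: 68

glance(report)
#> # A tibble: 1 × 4
#>   n_sites n_clusters n_retained pct_conserved
#>     <int>      <int>      <int>         <dbl>
#> 1       1         68          1          61.4

tidy(report)[, c("site_id", "site_type", "n_points", "enclosure",
                 "site_score", "d_score", "conserved_fraction",
                 "quadrant", "retained")]
#>   site_id   site_type n_points enclosure site_score d_score
#> 1 site_01 orthosteric      447    0.7647      1.047   1.079
#>   conserved_fraction quadrant retained
#> 1             0.5467       UR     TRUE
```

Reading the output: the detector found one pocket — the engineered cavity —
whose lining touches the planted ligand (`orthosteric`). Its enclosure
(0.76) and moderate polarity put both scores above the 0.8 threshold
(upper-right quadrant: ligandable *and* druggable), 55% of its lining
residues carry conservation grade 8–9 (the alignment was evolved with a
70/30 slow/fast site mix), so the site passes the combined filter and is
retained. `write_report(report, "out/")` emits the per-site CSV, grades
TSV, cluster CSV, retained list and JSON summary/manifest; a rerun with
the same configuration is byte-identical.

Individual stages are exported too: `load_structure()`, `find_sites()`,
`score_conservation() |> assign_grades()`, `map_probes() |>
cluster_poses() |> predict_binding_sites()`, `compare_groups()`, and the
generators `generate_structure()`, `generate_ensemble()`,
`evolve_alignment()`, `make_candidate_sites()`.

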