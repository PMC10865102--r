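# congenerGap

Closest-congener distance statistics and threshold-based MOTU evaluation
for curated DNA barcode libraries.

## What this is for

Large barcode releases for speciose taxa (the motivating case: Western
Palearctic weevils, ~658 nt CO1 barcodes with morphologically validated
identifications) support two practical questions:

1. **How close is the genetically nearest congener of each well-founded
   species?**  For a reference species *r* with records \(R\) and a congener
   *c* with records \(C\), the species-to-species distance is
   \(d(r,c) = \min_{i \in R, j \in C} p(i,j)\), where \(p\) is the
   uncorrected p-distance under pairwise deletion (sites with gaps, `N` or
   IUPAC ambiguities in either sequence are excluded for that pair).  The
   closest congener is \(\arg\min_c d(r,c)\) over the same genus, and per
   genus × distribution group (ISL / C1 ≤ 50 km / C2 / C3, with
   subfamily-specific cutoffs) the tables report
   \(\min_r d(r, c^*(r))\) and \(\operatorname{mean}_r d(r, c^*(r))\) in
   percent.  These morphologically calibrated values tell a taxonomist how
   small an interspecific distance can legitimately get in that group.
2. **How well can any single distance threshold delimit species?**
   Records are partitioned into MOTUs by single linkage at threshold *t*
   (connected components of the graph with edges \(p \le t\)); a
   morphospecies counts as correct only if its record set equals exactly
   one MOTU.  A threshold sweep reports wrongly assigned taxa and sequences
   per threshold and the best achievable error.

Around this core: parsing of structured FASTA labels
(`Genus_epithet[_subepithet|_cf|_sp]_specimenID[_accession]`), per-species
annotation tables (confidence groups 1/2/3, island flag, range in km),
pseudogene (NUMT) screening via in-frame stop codons under the invertebrate
mitochondrial code, leave-one-out sensitivity of all statistics, and a
seeded simulator that generates genus-structured libraries with known
expected divergences so every stage is testable offline.

## Worked example

```r
library(congenerGap)

ds  <- simulate_dataset(sim_config(seed = 1, n_genera = 40))
dm  <- distance_matrix(ds$alignment)
rows <- congener_stat_table(dm, ds$alignment$identity, ds$annotations)
head(genus_distribution_table(rows))
#>     genus distribution_group min_of_min avg_of_min n_reference_species
#> 1  Genusa                 C2       15.5       15.5                   1
#> 2 Genusaa                 C2       15.5       15.5                   2
#> 3 Genusab                 C2       13.2       13.2                   1
#> 4 Genusac                 C1       13.8       13.8                   1
#> 5 Genusac                ISL       13.2       13.8                   3
#> 6 Genusad                 C1       13.5       13.5                   1
```

Each row is one genus × distribution-group cell: `min_of_min` is the
smallest closest-congener distance (percent) among the cell's reference
species, `avg_of_min` the mean, `n_reference_species` how many group-1
species the cell aggregates.  With the simulator's defaults (per-lineage
divergence 0.08 from the genus ancestor) congeners sit near the closed-form
expectation of 15.1%, which is what the recovery tests assert.

The numbered drivers under `analysis/` run the full narrative —
`01_simulate.R` (library generation), `02_qc_screen.R` (NUMT flags and
length accounting), `03_distances.R` (distance matrix, intra/inter split),
`04_congener_stats.R` (the tables above + leave-one-out), and
`05_threshold_sweep.R` (MOTU concordance across thresholds) — writing
their tables under `results/`.

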