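---
title: "Closest-congener distances and threshold-based MOTU evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closest-congener distances and threshold-based MOTU evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congenerGap)
```

## The problem

A DNA barcode library for a speciose beetle group (here: Western Palearctic
weevils, Curculionoidea) pairs a ~658 nt fragment of the mitochondrial CO1
gene with a morphologically validated species identity for every voucher
specimen.  Two recurring questions in alpha-taxonomy are served by such a
library: *how far away is the genetically nearest congener of a given
species* (so that a newly sequenced specimen showing a smaller distance
should raise suspicion of a synonym rather than a new species), and *can any
single genetic distance threshold delimit species concordantly with
morphology* (it usually cannot; the error of the best achievable threshold
is worth quantifying).  This package implements the full analysis path for
both questions, plus the data screening around it, plus a seeded simulator
so the whole path is testable without the original specimen data.

## Distance model

All distances are uncorrected p-distances: the fraction of differing
nucleotide positions among pairwise-comparable sites.  Sites at which either
sequence carries an alignment gap, an `N`, or any IUPAC ambiguity code are
excluded for that pair (*pairwise deletion*).  Ambiguity codes are treated
as missing rather than as partial matches: a conservative policy that keeps
each pair's distance independent of every other record.  No model correction
(JC69/K2P) is applied in the statistics path — the reported quantities are
meant to be read directly against barcode practice, which reports percent
p-distance.  With pairwise deletion the p-distance is not a metric; nothing
downstream assumes the triangle inequality.

Distances are reported in percent to one decimal, rounding half **up**
(0.0225 becomes 2.3), matching how distance tables are conventionally
printed; internal computation always keeps full precision.

## Closest-congener statistics

Species are curated into three confidence groups: group 1 ("good species",
morphologically uncontroversial) are the **reference species**; group 2
species are usable as congeners only (their own distances are never
tabulated); group 3 (species complexes, candidate species) is excluded.
The distance between two species is the **minimum** p-distance over all
cross-species record pairs — the single closest pair, not a centroid —
because the practical question is how small an interspecific distance can
get, and a conservative lower envelope is the useful calibration.

For each reference species the closest congener is the same-genus species
(reference or group 2) attaining the smallest such distance; ties are kept
and the lexicographically first is displayed.  Congener scope is the genus
exactly as annotated; a genus alias map lets curators pool genera they treat
as one complex.  Per genus and geographic **distribution group** the minimum
and the arithmetic mean of these per-species minima are tabulated.
Distribution groups: `ISL` for island taxa regardless of extent, otherwise
`C1` for ranges up to 50 km, `C2` up to an upper cutoff, `C3` beyond it; the
cutoff is 500 km for Cryptorhynchinae and 2000 km for Apioninae and
Ceutorhynchinae.  "Up to" includes the endpoint: `C1` = (0, 50],
`C2` = (50, U], `C3` = (U, ∞) — the natural reading of interval labels that
meet at their boundary.

Sampling depth matters: removing a species can only *remove* candidate
congeners, so every remaining minimum can only grow.  `leave_one_out()`
makes this undersampling sensitivity explicit by recomputing all statistics
without one species and reporting every reference species whose closest
congener or distance changed; the monotonicity is asserted by the test
suite.

## MOTU partitioning and concordance

`single_linkage_partition()` groups records into molecular operational
taxonomic units (MOTUs) as the connected components of the graph whose edges
are record pairs with distance at or below a threshold — the connectivity
rule all barcode-gap partitioners share.  The probability machinery of any
specific partitioning programme (recursive split probabilities, partition
scores) is deliberately out of scope; externally produced partitions can be
read from a record/MOTU table and scored by the same evaluator.

A morphospecies counts as **correctly assigned** only when its record set
equals exactly one MOTU — neither split across MOTUs nor lumped with
another species.  This one-to-one criterion is the weakest definition under
which both a wrong-taxon count and a wrong-sequence count are well defined.
By default the wrong-sequence count includes every record of a wrongly
assigned morphospecies; a stricter "misplaced-only" variant (records outside
their species' plurality MOTU) is available behind `seq_count =
"misplaced"`, since published evaluations do not always state which
bookkeeping they use.  Wrong-sequence percentages are rounded to whole
percent.  `threshold_sweep()` evaluates a threshold grid and reports the
argmin by either measure, quantifying the best any single threshold could
do.

## The synthetic library

The generator emulates the statistical structure the analysis relies on,
one seeded RNG stream end to end (same seed, byte-identical FASTA):

* **Sequences.** Per genus an ancestral 658 nt haplotype is drawn codon-wise
  from the 62 non-stop codons of the invertebrate mitochondrial code.  Each
  species substitutes every site independently with probability
  `inter_divergence` (default 0.08); each specimen does the same against its
  species haplotype with `intra_divergence` (default 0.01).  A substituting
  base is drawn uniformly from the three alternatives, so the expected
  p-distance between two sequences diverged at rate *q* from a common
  ancestor has the closed form `2q(1−q) + (2/3)q²` — which is what the
  oracle and recovery tests check against.  Mutations creating an in-frame
  stop are reverted (purifying selection); the resulting downward bias on
  realised divergence is far below the binomial noise the tests allow.
  There is no coalescent structure and no indel evolution; gaps and `N`s can
  be injected at configurable per-site rates (default 0) purely to exercise
  the pairwise-deletion policy.
* **Sampling depth.** A species is a singleton with probability 0.43;
  otherwise its specimen count is `2 + NB(size 1, mean 2)`.  These defaults
  reproduce the internally consistent trio of published composition numbers
  for the weevil release this analysis is designed around — about 43% of
  species sampled once, about 16% of *sequences* being singletons, and a
  mean of ~2.7 specimens per species.  A species-level median of six
  specimens cannot coexist with 43% singleton species, so the median is the
  one composition statistic the defaults do not chase; the summary reports
  it for whatever data it is given.
* **Annotations.** Genera rotate through the three supported subfamilies;
  confidence groups are drawn with probabilities (0.65, 0.20, 0.15), island
  status with probability 0.4 (island faunas are heavily sampled in this
  kind of release), and continental range extents from a log-normal
  (meanlog log 150 km, sdlog 1.2), spreading species across all four
  distribution groups.
* **Planted gap.** `make_gap_scenario()` rejection-samples datasets until
  every intraspecific distance is ≤ 2% and every interspecific distance is
  ≥ 8% — verified by direct scan, not assumed — so a 5% threshold must
  recover the species exactly.  It validates the sweep machinery, not any
  claim about real data.

What passing these tests shows — and what it does not: the simulator's
independent-sites model produces much cleaner barcoding gaps than real
libraries, where introgression, incomplete lineage sorting and uneven
sampling blur the intra/inter separation.  Green tests therefore certify
the *computations* (distances, minima, aggregation, partitioning,
bookkeeping), not the biological claim that a given real genus has a gap.

## Numerical and design choices

* Degenerate inputs: a record pair with zero comparable sites is an error
  surfaced to the caller; species without any same-genus congener are
  omitted from the tables and listed in an attribute; an all-group-3
  annotation table yields an empty reference set with a warning.
* Stop-codon calls on ambiguous codons require *every* resolution to be a
  stop (`TAR` is a stop, `TAN` is not), so base-calling uncertainty alone
  never flags a pseudogene.  Incomplete terminal codons are ignored.  QC
  flags and never deletes: exclusion is a curator decision.  The reading
  frame is a dataset property passed by the caller (primer-trimmed barcodes
  do not advertise their frame).
* Ties for the closest congener are broken lexicographically for display
  only; all tied congeners stay in the output.
* Problem sizes in the tests and acceptance script (40 genera, ~600
  sequences; 25 two-species genera for recovery) are chosen so each check
  has enough resolution for its 3-SE band while the whole suite stays quick
  to run routinely.

## Known limitations

The analysis takes the curated annotations as given: no automatic
confidence-group inference, no range estimation from occurrence data, no
endosymbiont screening (which needs external sequence databases).  The
concordance evaluator scores any partition it is handed but does not search
for partitions beyond the single-threshold sweep.
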