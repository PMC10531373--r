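# np10

Proteomic evaluation of genome annotation accuracy.

## The problem

Bottom-up proteomics identifies peptides from tandem mass spectra and infers
proteins from the predicted protein database of a genome annotation. Because
every identification depends on that database, a fixed high-quality MS/MS
data set can be turned into a measuring instrument for the annotation
itself: search the same spectra against two annotation releases and the
differences reflect the databases. A fragmented annotation — one that splits
true genes across multiple *partial* coding sequences — can even inflate the
number of identified proteins, so identification counts alone are a poor
quality signal. What fragmentation cannot produce is large proteins carrying
many peptides.

**NP10** is a summary statistic built on that observation: take the table of
identified proteins, find the top decile by peptides-per-protein (nearest-rank
90th percentile threshold *t*, membership inclusive, so every protein with
*c*ᵢ ≥ *t* is selected), and report the **median molecular weight (kDa) of
those proteins**. As partial sequences are merged into complete genes across
releases, peptide evidence concentrates onto longer sequences and NP10 rises;
the improvement is reported as a percent change.

The package is for researchers evaluating de novo genome assemblies and
re-annotations — particularly of non-model organisms — who have proteomic
search results (or want to study the metric itself). It provides:

* `np10()`, `decile_threshold()`, `median_mw()`, `percent_change()` — the
  statistic and its arithmetic;
* `read_protein_fasta()`, `average_mass()` — protein databases and average
  molecular masses;
* `read_protein_table()`, `read_peptide_table()`, `compute_coverage()`,
  `parsimony_group()` — identification tables, sequence coverage, simplified
  parsimony grouping;
* `compare_annotations()` with `read_change_map()` — cross-release
  comparison: NP10 change, peptide gain/loss attributed to annotation change
  categories (identical / minor / major / new / deprecated / other), and the
  partial-protein improvement quadrant analysis;
* `simulation_config()`, `generate_proteome()`, `fragment_annotation()`,
  `tryptic_digest()`, `simulate_identifications()`, `simulate_bundle()` — a
  synthetic proteome and identification simulator, so the entire pipeline
  runs and is tested without any mass spectrometry data;
* tidyverse-style surfaces throughout: tibbles in and out, `tidy()` /
  `glance()` on result objects, `autoplot()` / `plot_partial_quadrants()`
  for the standard figures, and a command-line front end
  (`inst/cli/np10.R`).

## Worked example

The statistic on a toy table where protein *i* has *i* peptides and weighs
10 *i* kDa:

```r
library(np10)
tab <- tibble::tibble(
  accession = sprintf("P%02d", 1:10),
  n_peptides = 1:10, n_unique_peptides = 1:10,
  coverage_pct = 50, mw_kda = 10 * (1:10)
)
np10(tab)
#> NP10 summary (total peptide counts, top 10%)
#>   proteins:            10
#>   decile threshold:    >= 9 peptides
#>   proteins at/above:   2
#>   NP10:                95.00 kDa
#>   median MW (all):     55.00 kDa
```

The threshold is the 9th of 10 sorted counts (nearest-rank 90th percentile),
the top set is the two proteins with ≥ 9 peptides (90 and 100 kDa), and NP10
is their median, 95 kDa.

A full simulated annotation comparison — a 300-protein proteome, a degraded
release with 30% of proteins truncated to partial fragments, one detection
pattern searched against both:

```r
cfg <- simulation_config(n_proteins = 300, fragment_fraction = 0.3,
                         detection_prob = 0.3, seed = 42)
b <- simulate_bundle(cfg)
compare_annotations(b$set_old, b$set_new, b$change_map, b$partial_flags)
#> <annotation_comparison> fragmented -> complete
#>   NP10: 88.44 -> 94.13 kDa (+6.4%)
#>   median MW: 31.90 -> 38.22 kDa (+19.8%)
#>   peptides: 8208 old, 9806 new, 8097 overlap (111 lost, 1709 gained)
#>   formerly partial proteins matched: 90 (median MW fold change 2.25)
```

Restoring the truncated proteins raises NP10 by 6.4% and roughly doubles the
median molecular weight of the formerly partial proteins, while most peptides
are found with both databases — the same qualitative pattern seen when real
re-annotations are compared. `write_comparison_report()` serialises the full
report (JSON plus per-section TSVs); the same pipeline is available from a
shell via `Rscript inst/cli/np10.R {compute,compare,simulate,digest,mw} ...`.

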