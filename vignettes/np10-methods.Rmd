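---
title: "Benchmarking genome annotation accuracy with proteomics: the NP10 statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genome annotation accuracy with proteomics: the NP10 statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(np10)
```

## The problem

Bottom-up proteomics infers proteins by matching tandem mass spectra against
the predicted protein database of a genome annotation. That dependency can be
turned around: holding one high-quality MS/MS data set fixed and varying the
database, differences in the identification results measure the database, not
the instrument. A poorly assembled or annotated genome splits true
protein-coding genes across multiple *partial* coding sequences — database
fragmentation. Searching against a fragmented database still yields many
protein identifications (often *more*, since one gene contributes several
entries), so raw identification counts are a misleading quality signal. What
fragmentation cannot fake is *large proteins carrying a lot of peptide
evidence*: when partial sequences are merged into complete ones, the peptides
that previously scattered over fragments concentrate onto longer sequences.

## The NP10 statistic

NP10 captures that signal in two steps. Given a table of identified proteins
with their peptides-per-protein counts $c_i$ and molecular weights $w_i$
(kDa):

1. **Stratify.** Compute the top-decile threshold $t$ on the counts — the
   nearest-rank (type 1) 90th percentile: sort the $c_i$ ascending and take
   the value at 1-based index $\lceil 0.9\,n \rceil$. Select every protein
   with $c_i \ge t$.
2. **Summarise.** NP10 is the median of $w_i$ over the selected proteins.

```{r ladder}
tab <- tibble::tibble(
  accession = sprintf("P%02d", 1:10),
  n_peptides = 1:10, n_unique_peptides = 1:10,
  coverage_pct = 50, mw_kda = 10 * (1:10)
)
np10(tab)
```

A fragmented annotation depresses NP10 (the best-evidenced proteins are
truncated); merging partials into complete sequences raises it. The
improvement between two releases is reported as a percent change,
`percent_change(old, new)`, rounded only for display.

### Design choices in the definition

* **Quantile definition.** Nearest-rank was chosen because peptide counts
  are small integers: the threshold is then always a count value actually
  present in the data, and the two-step reading — find a count, then take
  every protein *with at least* that many peptides — needs no interpolation.
  `decile_threshold()` agrees with `quantile(x, 0.9, type = 1)`.
* **Inclusive ties.** Every protein whose count equals the threshold is in
  the top set. With heavy ties the top set can exceed 10% of proteins; this
  is deliberate, since excluding an arbitrary subset of tied proteins would
  make the statistic order-dependent. Consequently
  $n_{\mathrm{top}}/n \ge 0.1 - 1/n$ always holds.
* **Total versus unique peptide counts.** Shared peptides are real evidence
  for a long, correctly merged sequence, so the default ranks proteins on
  *total* distinct peptide groups. Strict-parsimony users can rank on unique
  counts with `use_unique = TRUE`; both modes are first-class and the choice
  is recorded in the result object.
* **Median convention.** Even-sized sets use the midpoint of the two central
  values (`stats::median`).
* **Generalisation.** The quantile level is exposed as `p` (default 0.9)
  for exploration, but only the top decile is given a name.

## Molecular weight

`average_mass()` sums standard *average* residue masses plus one water
(18.0153 Da). Average rather than monoisotopic masses are used because the
quantity of interest is whole-protein size, not precursor mass; the
difference is below 0.1% and cannot reorder a decile. Selenocysteine
(150.0379) and pyrrolysine (237.3018) are included; the ambiguity codes B and
Z take the mean of their two candidate residues and X a conventional 110.0 Da
mean residue mass, so predicted proteomes containing ambiguous residues are
processed rather than rejected (a warning counts affected records). Reported
kDa values are `mass_da / 1000`, rendered at two decimals in text output.

## Identification tables, coverage and parsimony

Protein and peptide identification results enter as plain TSV tables
(`read_protein_table()`, `read_peptide_table()`) shaped like filtered
search-engine exports. Peptide identity is the bare sequence string —
modifications must be stripped upstream, and I/L are *not* collapsed, the
conservative default in the absence of a stated rule. When both tables are
supplied, disagreements between the reported peptides-per-protein and a
recount from the peptide table are warnings, not errors: real exports embed
inference logic this package does not replicate.

`compute_coverage()` is the share of residue positions covered by at least
one occurrence of at least one peptide; all substring occurrences count,
including overlapping ones. `parsimony_group()` is a deliberately simple
greedy set cover (ties to the lexicographically smallest accession) that
reproduces the *law of parsimony* idea — report the fewest proteins that
explain all peptides — without claiming equivalence to any commercial
grouping engine; greedy set cover can exceed the optimum on adversarial
inputs, which the test suite documents by brute-force comparison on small
instances.

## Comparing two annotation releases

`compare_annotations()` takes identification sets from searching the same
data against an old and a new release plus a change map — rows of
(old accession, new accession, category) with the standard release-comparison
categories *identical, minor, major, new, deprecated, other*.

* **Peptide attribution.** Peptides are split into overlap / lost (old only)
  / gained (new only); the conservation identities
  `overlap + lost = |old|` and `overlap + gained = |new|` are revalidated
  before any report is written. Each lost peptide is attributed via the
  categories of its *old* parents, each gained peptide via its *new*
  parents. A peptide whose parents span several categories counts once
  toward each per-category tally, while the headline lost/gained numbers
  are deduplicated peptide counts — so tallies may sum to more than the
  headline, and both are reported. Parents absent from the map go to an
  explicit `unmapped` category rather than being dropped.
* **Partial-protein improvement.** For proteins flagged partial in the old
  release and identified there, counterparts in the new release are found
  through `minor`/`major`/`other` map rows. One-to-many mappings resolve to
  the identified new protein with the most unique peptides (ties: larger
  MW, then lexicographic accession), and the resolutions are reported.
  Matched pairs are classified by the signs of (change in MW, change in unique
  peptides) into four quadrants; a delta of exactly zero is counted
  on-axis, separately, because quadrant membership of boundary points is
  otherwise arbitrary. The summary reports the quadrant counts, the median
  change in unique peptides and the fold change of median MW
  (median new MW / median old MW over matched pairs), which is exactly 1 on
  identical inputs.

## The simulator

Because real search results require raw data and commercial search engines,
the package ships a generative model of the *setting*, not of mass
spectrometry:

* **Proteome.** `generate_proteome()` draws i.i.d. residues from a fixed
  Swiss-Prot-like composition with log-normal lengths (median 350 residues,
  log-sd 0.6, floor 50) — a realistic size distribution for a vertebrate
  proteome at the scale used here.
* **Fragmentation.** `fragment_annotation()` truncates a seeded random
  fraction of proteins to one contiguous fragment covering a uniform 30–70%
  of the residues, flags them partial, and emits the corresponding change
  map (truncated records `major`, untouched `identical`). Multi-fragment
  splitting is not modelled; one fragment per protein is the minimal
  mechanism that produces the phenomenon of interest.
* **Detection.** `simulate_identifications()` digests every database protein
  with the classic trypsin rule — cleave after K/R except before P, up to 2
  missed cleavages, 6–144 residue window — and detects each distinct peptide
  sequence with one Bernoulli draw at `detection_prob`. The draw is keyed to
  the peptide *sequence* (a seeded hash mapped to a uniform variate), so the
  same peptide is detected or missed consistently when the two databases are
  searched: this emulates one fixed MS/MS data set measured once, and it is
  why simulated cross-release peptide overlap is high, as in real
  re-annotation comparisons. Detected peptides are assigned to every
  protein whose in-silico digest yields them — the way a search engine
  assigns shared peptides — and identified proteins get recomputed counts,
  positional coverage and MW.

The whole simulation is a pure function of its `simulation_config()`,
including the seed.

**What the simulator does not model:** protein abundance and peptide
flyability (detection is i.i.d.), modifications, spectral quality and FDR,
isoforms and homologous gene families (so shared-peptide structure is much
sparser than in a real proteome), and multi-fragment or mis-assembled gene
models. Passing simulation-based tests therefore demonstrates that the
statistics behave correctly under controlled database fragmentation — not
that any particular real annotation will show a particular NP10 value.

## Numerical and scale choices

Degenerate inputs are defined, not special-cased: uniform peptide counts make
the top set the whole table, so NP10 equals the overall median MW; a
single-protein table yields its own MW; empty tables are errors. JSON output
is written at full precision; text reports render kDa at two decimals and
percent changes at one.

The test suite exercises the NP10 oracle equivalence on 1000 random tables up
to n = 500, digestion combinatorics on 200 random sequences, peptide
conservation on 100 simulated release pairs (25 proteins each), and the
fragmentation-direction demonstration on 20 replicates of 1000-protein
proteomes at fragment fractions 0.1/0.3/0.5 — sizes chosen so the full suite
runs in a few minutes while keeping the binomial and median statistics
well-resolved.

## Limitations

NP10 is a coarse, relative measure: it compares releases searched with the
same data and the same filters, and says nothing in absolute terms about a
single search. It inherits every bias of the underlying identification
pipeline (protease choice, length window, FDR filtering), and the package
deliberately consumes already-filtered tables rather than re-implementing any
of that machinery.
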