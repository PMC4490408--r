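---
title: "Methods: cell-surface glycoproteomics and time-course marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-surface glycoproteomics and time-course marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscMarker)
```

## The problem

Cell-surface capture (CSC) glycoproteomics enriches N-glycosylated surface
peptides: surface glycans are oxidized and biotinylated on live cells,
captured on streptavidin, and released with PNGase F, which converts each
formerly glycosylated asparagine to aspartate (a +0.984 Da deamidation).
Sampling a reprogramming time course this way yields, per time point and
technical replicate, a table of peptide-spectrum matches (PSMs). The
analytical task `cscMarker` addresses is to go from those PSM tables to a
ranked list of candidate surface markers that separate a transgene-dependent
pluripotent end state (F-class, reached under sustained high OKMS induction
with doxycycline, "DOX-high") from both the somatic starting state (MEF) and
the transgene-independent ESC-like state.

## Glycopeptide qualification

A PSM qualifies as a genuine N-glycopeptide when three rules hold, applied
in a fixed order so rejection reasons are deterministic:

1. **Sequon**: the peptide carries the consensus motif N-x-S/T with x any
   residue except proline. Because proteolysis can cut inside a sequon, a
   peptide *ending* in N, or in N-x with x ≠ P, carries at least the start
   of a sequon and is accepted by default
   (`filter_config(allow_truncated_sequon = FALSE)` gives the strict
   full-motif reading).
2. **Deamidation**: a deamidation modification must sit on a sequon
   asparagine — the PNGase-F scar that distinguishes a formerly
   glycosylated site from a merely sequon-containing peptide. The delta
   used for mass arithmetic is the chemical value +0.98402 Da; deamidated
   asparagine then weighs exactly as aspartate (within 1e-4 Da), which is
   the identity the test suite asserts. Input tables may label the
   modification with the commonly printed rounded deltas (0.984, 0.986);
   labels, not deltas, identify it. Whether the original workflow demanded
   the deamidation on the sequon asparagine specifically or anywhere in
   the peptide is not stated; the default is the sequon-specific reading,
   switchable with `deamidation_on_sequon = FALSE`.
3. **Mass**: the observed neutral monoisotopic mass must agree with the
   theoretical modified mass within 20 ppm (`ppm_tolerance`, the
   accurate-mass gate of the original Orbitrap workflow).

Identification confidence is consumed, not computed: the upstream search
engine's validator supplies a per-PSM probability, and the reader drops
records below 0.98. The published description is ambiguous about whether
98% is a per-PSM probability or a set-level rate (a 2% false-positive
rate); the reader treats it as per-PSM and documents that choice.

## Proteoform groups

Isoforms of one gene share most of their sequence, so peptides from shared
regions cannot be attributed to a single isoform. Accessions sharing a
(gene, primary ID) key in the isoform index are therefore collapsed into
one *proteoform group* quantified collectively. A peptide hitting several
groups is counted in each — the collective reading; no parsimony or razor
assignment is attempted, since the published tallies are per group. A
`cross_gene = "exclude"` switch drops cross-group peptides instead. When
the index does not designate a primary ID, the lexicographically smallest
member accession is used, for determinism.

## Spectral-count quantification

Counts are tallied per group, replicate and sample, then depth-normalized
through the factor `sqrt(400 / T_r)`, where `T_r` is the replicate's total
count and 400 the reference total. The square root deliberately corrects
only half the (log) depth difference: a fixed protein amount was injected
per run, so totals are *expected* to be similar, and a full proportional
correction would erase genuinely different totals. The published sentence
reads "dividing each by the square root of (400 over the total)", which
taken literally *amplifies* deep replicates — the opposite of its stated
purpose. Both readings ship: `rationale` mode (multiply by the factor; the
default) and `literal` mode (divide); the mode used is stamped in the
matrix metadata and neither is asserted to be the published intent.

Technical replicates (three per point) are then averaged with **absence
as zero**: the denominator is the designed replicate count, not the
observed one, since a missing spectral count in a replicate is evidence of
absence, not missing data.

## Marker discovery

All downstream analysis runs on the averaged matrix after `log2(x + 1)`;
counts share a scale, so unit-variance scaling is off by default
(`scale. = TRUE` exposes it).

- **PCA** treats time points as observations and groups as variables
  (`stats::prcomp`, column-centred).
- **K-means** (`stats::kmeans`, best of 25 restarts, fixed seed) clusters
  per-group z-scored trajectories, so shape, not abundance, drives
  membership. K defaults to 10: the published analysis reports *finding*
  two F-class clusters but not the K used, so K is kept comfortably above
  the number of archetypal shapes and exposed as a parameter.
- **Cluster selection** keeps clusters whose mean standardized trajectory
  rises from the day-0 point to the first post-induction point and peaks
  at an F-class end-state sample. The F-class end state is resolved as
  the late DOXH plateau (day ≥ 18); by then the F-class phenotype is
  established, and tying selection to a single terminal column would make
  the rule needlessly fragile at spectral-count depths.
- **Ranking**: for each contrast (F-class vs ESC, F-class vs MEF) the
  separating component is the PC with the largest centroid gap between
  the two states' scores, measured in raw score units. Scores already
  carry each component's variance; dividing the gap by the per-component
  score s.d. would inflate trailing components whose variance is numerical
  noise, and in sparse-count data those components occasionally win such a
  standardized comparison. A group's contribution on a component is
  |loading| / max |loading| on that component, and its marker score is the
  minimum of its two contributions — a candidate must separate the F-class
  state from *both* references (`method = "max"` and `"product"` are
  offered). "Contribution to the principal components" has no published
  numerical definition; absolute-loading normalization is this package's
  definition. Only groups in selected clusters are ranked; ties break by
  primary ID. The published shortlist was additionally filtered by
  antibody availability, which is not computable — an allow-list filter
  on the ranking serves that role.

Fold-change statistics use pseudocounted ratios `(late + c)/(early + c)`
with c = 0.5 (spectral counts are small integers), flagged up at ratio
≥ θ and down at ≤ 1/θ, θ = 2 by default. The down-then-up overlap
statistic is the percentage of late-upregulated groups (e.g. day 18 to the
final iPSC state) that were already ≥ θ-fold down between days 0 and 2; it
errors, rather than returning a number, when nothing is late-upregulated.
Category dispersion tabulates detected groups (count > 0) into functional
categories per time point and averages the per-category s.d. of those
percentages. Validation panels use the delta-delta-Ct closed form
`2^(-ΔΔCt)` against a reference gene and calibrator sample, and
hierarchical clustering fixed to Euclidean distance with average linkage
(the documented defaults of the common clustergram tools), both
configurable.

## The synthetic generator

Because the deposited data require a download, every stage is exercised
against a seeded generator with planted ground truth
(`simulate_timecourse()`, `simulate_counts()`, `simulate_psm_table()`).
It emulates:

- the three-arm, 30-day sampling design: MEF at day 0, DOX-high sampled
  through day 30, a DOX-low arm branching after day 14 and a
  DOX-withdrawn arm after day 18 (both converging to ESC-like levels),
  plus ESC and secondary-iPSC reference points — 12 distinct days, three
  technical replicates per point;
- five trajectory archetypes with mixture 0.3/0.1/0.1/0.2/0.3:
  *early_down* (high in MEF, ≥ 2-fold down by day 2, recovering in the
  pluripotent end states), *fclass_up* (rising after induction to a
  plateau over days 18–30 under DOX-high, falling back in the withdrawal
  arms, low in ESC/iPSC), *esc_like*, *transient* (mid-course bump), and
  *flat*. One fclass_up group is planted as the marker with its elevation
  scaled 8-fold (`marker_effect`); at `marker_effect = 1` it is exactly
  its archetype, the null case the tests assert;
- group-level lognormal abundance scatter (sdlog 0.3) and mild per-point
  lognormal jitter (sdlog 0.2); per-replicate depths lognormal around 400
  (sdlog 0.3) — 400 both matches the normalization reference, making the
  reference an interpretable identity case, and gives realistically sparse
  counts (mean < 1 per group per replicate at 500 groups);
- counts drawn Poisson around depth × relative abundance — spectral
  counts are small and no dispersion information is published; a
  negative-binomial option with configurable size is available;
- PSM-level structure: 1–3 tryptic peptides per group, each with one full
  sequon (one group carries a C-terminally truncated sequon), sequon-free
  decoy peptides receiving 20% of records, deamidation on the sequon
  asparagine, observed masses within ±10 ppm with a labelled +50 ppm
  spike, a labelled sub-threshold-confidence spike, and ~10% of groups
  carrying two isoform accessions so grouping genuinely collapses
  isoforms. Every qualification edge case (proline-containing NPS motif,
  truncated sequon, off-tolerance mass, low confidence) occurs in every
  default fixture.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data — includes chimeric/mis-assigned spectra,
peptide-specific detectability (ionization efficiency, missed cleavages),
shared peptides between unrelated genes, batch drift between replicates,
and any glycan-level structure. It provides planted *truth* for pipeline
logic, not a biophysical simulation of an Orbitrap run.

## Numerical and design choices

- All randomness flows from explicit integer seeds through named
  arguments; the count stream uses `seed + 1` and the peptide stream
  `seed + 2`, so abundance, counts and fixtures are independently
  reproducible. Identical configs give byte-identical pipeline outputs.
- Zero-variance trajectories z-score to zero rather than NaN;
  zero-total replicate columns pass through normalization unchanged with
  a warning; a constant matrix is a PCA error; an empty late-upregulated
  set is an overlap error; K outside [2, n groups] is a clustering error.
- Rejection reasons are assigned in rule order (sequon → deamidation →
  mass), so a record failing several rules reports the first.
- Problem sizes in the test suite: filter and overlap oracles run at the
  stated scales (1,000 and 100 random cases); marker recovery and PCA
  divergence run the full study conditions (500 groups, 20 seeds) at the
  count level, where a run takes a fraction of a second; the PSM-level
  end-to-end reconciliation runs at 120 groups over 5 seeds, sizes chosen
  to keep the default suite brisk while leaving the count-level checks at
  full scale.

## Known limitations

- Spectral counts at depth 400 over 500 groups are very sparse; two-fold
  calls on single groups are noisy, and the overlap statistic inherits
  that noise. The ranking, which pools evidence across components and
  clusters, is much more stable (the planted marker is recovered top-3 in
  ≥ 18/20 seeded runs at default conditions).
- Relative (compositional) normalization means large coordinated shifts
  in true abundance dilute apparent fold changes; this is intrinsic to
  spectral counting with fixed injection amounts, and the square-root
  normalization deliberately does not attempt to undo it.
- Protein inference is deliberately naive (collective groups, no
  parsimony); protein-level FDR control is out of scope, as the upstream
  validator owns identification error rates.
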