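---
title: "Methods: coverage-based miRNA precursor analysis in isomiRscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based miRNA precursor analysis in isomiRscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

isomiRscope analyzes human small-RNA sequencing studies *after* read
preprocessing and genome alignment: its inputs are miRDeep2-style `arf`
alignment files (13 tab-separated columns, 1-based inclusive
coordinates, per-base match/mismatch edit string), miRBase-dialect GFF3
annotation of hairpin precursors and mature arms, a per-sample totals
table, and a two-class design. Everything downstream happens in
*precursor coordinates*: each alignment overlapping a hairpin is mapped
into 1..L positions along the hairpin's 5′→3′ orientation (on minus
strand precursors the genomic end maps to position 1), and the central
object is the per-precursor coverage matrix `raw[s, p]` counting the
reads of sample `s` that cover position `p`.

Conventions worth stating once:

- `arf` and GFF3 coordinates are both treated as 1-based inclusive,
  their native conventions; all user-facing positions are reported
  1-based.
- Alignments on the strand opposite a precursor are ignored (miRNAs are
  strand-specific); partially overlapping alignments contribute their
  overlapping bases; an alignment overlapping k precursors counts once
  in each — no fractional multi-mapping weights, so counts stay
  reproducible integers. Identical reads are not collapsed: whatever
  collapsing the upstream aligner did is respected as-is.
- RPM normalization is `raw * 1e6 / totals[s]`, where the totals may be
  raw run totals or genome-mapped totals (both modes are supported; a
  "none" mode leaves counts untouched). Which totals to use is a study
  design decision, not something the package can infer.
- Arm labels (5p/3p) come from the mature name suffix when present;
  otherwise the arm whose midpoint lies in the strand-aware 5′ half of
  the hairpin is called 5p. miRBase v20-era names are inconsistent
  enough that the fallback is required.
- Hairpin *sequences* are not part of the GFF/mature.fa inputs, so the
  readers accept an optional hairpin FASTA. Without it, sequence-bearing
  outputs degrade: pileups print `#` placeholders and window motifs are
  reported as missing.

# Statistical model

All tests compare the two cohorts on a per-sample summary statistic and
are two-sided.

**Feature statistic.** For a precursor, a mature arm, a novel-arm
region, or a single base, the per-sample statistic is the mean per-base
RPM over the feature's positions. One coherent statistic across all
resolutions keeps precursor-, arm- and base-level results directly
comparable; no read-to-arm assignment rule is needed.

**Tests.** `t_test` is the Welch unequal-variance t test — cohort sizes
in real biomarker studies are rarely balanced, so the equal-variance
form is never used. `wilcoxon` is the Mann–Whitney rank-sum test. When
`choose(n, n1) <= 20000` (which covers all group-size pairs up to 8 per
group) the p-value is computed by exact enumeration of the rank-sum
permutation distribution on midranks, so it is exact under ties too;
larger cohorts use the normal approximation with tie correction and
continuity correction. The two-sided exact p is the fraction of
assignments whose rank sum deviates from its permutation mean at least
as much as the observed one.

**Degenerate inputs.** Identical cohorts (as multisets) return p = 1
with a `degenerate` flag; cohorts that are each constant but different
return p = 0 with the flag (the Welch statistic is undefined there);
all-zero positions return p = 1 with direction "none".

**Fold changes.** `FC = (mean_case + 0.01) / (mean_control + 0.01)` in
RPM units. The 0.01 RPM pseudocount keeps fold changes finite and
positive for features absent in one cohort while being negligible
(≤1%) for any feature expressed above 1 RPM. Swapping the cohort labels
maps FC to 1/FC and leaves every p-value unchanged — this antisymmetry
is enforced by tests.

**Multiple testing.** Raw p-values are the primary output, matching how
this class of per-miRNA screening results is conventionally reported; a
Benjamini–Hochberg column is emitted alongside but never used to filter
or gate anything.

**Arm ratio.** For two-arm precursors the statistic is the *quotient*
`FC(5p) / FC(3p)`. A difference and a quotient are both defensible
readings of "difference between the arms"; the quotient is implemented
because the natural calibration — both arms moving together giving a
value of 1 — only holds for the quotient. Single-arm precursors are
omitted.

# isomiR window analysis

For each annotated arm and each of its ends, the window is the `w`
precursor positions immediately *outside* the arm (towards the hairpin
5′ end at the arm's 5′ end, towards the hairpin 3′ end at its 3′ end).
A (sample, position) cell is covered when it has at least one raw read
— a raw-count threshold keeps the definition independent of the
normalization mode. The cohort percentage is 100 times the cohort mean
of per-sample covered fractions; at `w = 1` this reduces exactly to the
percentage of samples showing any templated end extension. The
case/control quotient of the two percentages is the reported effect
measure, with the case cohort always in the numerator; the quotient is
invariant under common rescaling of both percentages, which is why it
stays stable across window sizes while the percentages themselves decay.

Boundary handling: a window truncated by the precursor edge uses the
number of in-precursor window positions as its denominator (so
percentages stay on the 0–100 scale); a window entirely outside the
precursor is dropped. Typical working window sizes are 2–4 bases;
`w = 0` is rejected. The `w` bases outside each end are also reported
as a sequence motif when the hairpin sequence is available, truncated at
the precursor boundary. Only outward windows are computed: truncation
isomiRs (reads ending *inside* the annotated arm) are a different
phenomenon and out of scope.

# Novel mature arms

Precursors with a single annotated arm are scanned for read support at
an unannotated arm position. The detector is deliberately
coverage-driven, not structure-driven: the maximal contiguous run of
positions whose pooled (all-sample) mean raw coverage is ≥1 read,
restricted to the region outside the annotated arm plus a 5 nt guard
band on each side. The guard band prevents templated end extensions of
the known arm from seeding a spurious candidate. Runs of 16–30 nt — the
plausible mature-arm length range — are reported with their mean read
count, cohort fold change and p-value on the per-sample mean RPM over
the region; longer or shorter runs are not mature-arm-like and yield no
call. Ties between equally long runs go to the run with higher pooled
coverage. RNA secondary-structure prediction would be an alternative way
to propose the second arm's position, but it would add a folding
dependency without changing what the data can support: read clusters.

# Aggregation across studies

With aggregation enabled, a study contributes one anonymized row per
analyzed feature — finding type, miRNA name, direction, significant
yes/no — under an opaque study hash (md5 of the parameter echo). No
sample identifiers, class labels or per-sample values ever enter the
store, which is a plain append-only text file with a versioned header.
The hash acts as an idempotency key: re-recording the same study is
rejected, so frequencies never double-count. A miRNA counts as
"analyzed" in a study when it had nonzero coverage in at least one
sample; this defines the denominator of the reported frequency. Window
findings need a significance rule the upstream analyses do not provide:
a window finding is recorded significant when the cohort percentages
differ by at least 20 points — a deliberately conservative cut for a
screening-level store. A finding significant in a large fraction of
unrelated stored studies is more plausibly a recurrent platform artifact
than a trait-specific signal; the frequency query exists to surface
exactly that.

# Reporting

Every analysis writes a tab-delimited table; every figure has a TSV (or,
for pileups, plain-text) twin holding exactly the plotted numbers, so no
result exists only as pixels. Manhattan plots place each miRNA at its
precursor's annotated start position with chromosomes concatenated in
karyotype order (1–22, X, Y) and show −log10 p, capped at 320 where
p-values underflow to zero. Per-base bar plots color up-regulation in
cases red and down-regulation green. Pileups print, per sample with at
least one mapped read, the precursor base wherever that sample covers
the position — cases above the sequence line, controls below, annotated
arm spans marked. The `arf` edit string only distinguishes match from
mismatch, so pileups render the reference base rather than inventing
per-base allele calls. The bundle is a gzip-compressed tar with a
sorted manifest, built with R's internal tar so no external archiver is
needed.

# The study simulator

`simulateStudy` generates a complete synthetic study — random genome,
miRBase-style GFF3/FASTA annotation, per-sample `arf` files, totals and
design tables, and a truth table — from a single seed; identical seed
and configuration give byte-identical files.

What it emulates, and how:

- **Counts.** Per sample and arm, read counts are negative binomial
  with `var = mu + disp * mu^2` (dispersion default 0.2): human cohort
  miRNA counts are overdispersed, and Poisson noise would make recovery
  tests unrealistically easy. Case means scale by the configured
  per-arm fold change.
- **Library size.** Per-sample size factors are log-normal (sd 0.1 by
  default); totals and expected counts scale together, so RPM
  normalization must remove the factor — a real check that
  normalization is wired correctly.
- **End extensions.** Extension is modeled as a *per-sample trait*:
  `round(p * n)` samples per cohort carry the isoform, and within a
  carrier a fixed fraction (default 0.3) of the arm's reads is extended
  by the carrier's extension length. Cohort-level window percentages
  are what the analysis estimates, so the simulator controls them
  exactly rather than letting a per-read coin flip saturate every
  sample's window at realistic depths. Extension lengths follow a
  truncated geometric profile (decay 0.5) allocated by stratified
  inverse-CDF across carriers, which makes the expected percentages
  decay with window size while the cohort quotient stays constant — the
  qualitative signature the window analysis is designed around.
  `truthWindowPct` computes the implied expected percentages for any w.
- **Novel arms.** Single-arm precursors can carry a spiked unannotated
  arm (26 nt by default) at its own fold change.
- **Geometry.** Precursors alternate strands so coordinate reflection is
  exercised end-to-end; reads are genome-templated, perfectly matching,
  and span exactly their arm (plus any extension). arf cannot represent
  non-templated additions, so none are simulated.

What it does **not** emulate: sequencing errors and mismatch patterns,
non-templated 3′ additions, read-start jitter, multi-mapping across
precursor families, adapter artifacts, and GC- or length-dependent
biases. Passing recovery tests therefore demonstrates that the
estimators measure what they claim on clean overdispersed data — not
that real studies are free of the alignment artifacts the pileup
visualizations exist to catch.

# Benchmark configurations and problem sizes

Two presets (`exampleStudyConfig`) define the package's benchmark
conditions:

- **recovery**: 10 + 10 samples, depth 200 reads/arm, 20 precursors of
  length 80 — ten two-arm precursors with 5p fold change 2.0 and 3p
  fold change 1.0 (three of them also carry a 3-base end shift present
  in 90% of cases and no controls), six single-arm precursors with a
  spiked 26 nt novel arm at 1.6×, four clean single-arm precursors for
  specificity.
- **window**: 20 + 20 samples, depth 100, two two-arm precursors (one
  per strand) with extension carrier fractions 0.6 (case) vs 0.3
  (control), maximum extension 4 nt.

At these depths a single arm's fold-change estimate carries roughly 20%
sampling error (NB dispersion 0.2, cohort means of 10), so recovery is
assessed in aggregate — the mean estimate across same-truth arms,
pooled over three replicate simulations in the test suite — rather than
arm-by-arm, where a tight band would be a coin flip by construction.
Per-arm errors remain available via `truthCompare`. The law-of-
large-numbers depth check pools 600 sample-arm draws at depth 1000 for
the same reason. These sizes keep the full test suite in the minutes
range while leaving 2.5–4 standard errors of margin on every asserted
band.

# Known limitations

- Two-group designs only: no pairing, covariates, or multi-group
  comparisons.
- Per-base tests are computed independently per position; spatial
  correlation along the hairpin is not modeled, which is why the
  arm-level "at least `minSigPositions` significant positions" rule
  (default 15, about two-thirds of a mature arm) exists as a blunt but
  transparent aggregation.
- The novel-arm detector reports at most one candidate region per
  precursor (the maximal run).
- The window quotient is undefined when the control percentage is zero
  and is reported as missing rather than infinite.
- BAM/SAM input is out of scope by design; alignment and preprocessing
  belong to the upstream aligner.
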