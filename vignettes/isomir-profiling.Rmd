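---
title: "IsomiR profiling and transmural differential abundance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsomiR profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRseq)
```

## The problem

Mature miRNAs are excised from hairpin precursors by Drosha and Dicer, and
neither cut is perfectly precise; post-cleavage trimming and non-templated
tailing (mostly adenylation and uridylation) further diversify the 3' end.
The result is that a single miRNA locus is observed in sequencing data as a
family of isomiRs around the canonical miRBase sequence. Profiling that
family matters for two reasons: 5' variants shift the seed (nucleotides
2–8) and hence the target spectrum, and assay chemistries anchored to a
specific end can badly under-report a miRNA whose dominant isomiR differs
there. `isomiRseq` implements a complete profiling pass — grouping,
classification, quantification, two-condition testing — together with a
simulator that provides per-read ground truth.

## Grouping model

A read r is matched to a canonical mature m by ungapped placements indexed
by end offsets (d5, d3), positive when the read extends beyond the
canonical end, with the length constraint |r| = |m| + d5 + d3. Placements
are admissible when |d5| ≤ 3, |d3| ≤ 3 and the number of mismatches over
the overlapping positions is ≤ 2. Extension nucleotides are *not*
mismatches at grouping time; whether they match the hairpin is a separate
classification question. Among admissible placements the minimiser of
(mismatches, |d5| + |d3|) wins; residual ties prefer smaller |d5|, then the
negative d5. Across matures, ties break by fewest mismatches, smallest
total offset, then lexicographically smallest mature id, so annotation is a
pure function of the input set (order independence is tested).

Two readings of the tolerance phrase "3 additions or deletions from either
end" are possible: a per-end limit or a total across both ends. We use the
per-end limit, because observed isomiR tables combine 5' and 3' changes in
a single sequence (e.g. types coded `Sub/Sup`), which a 3-total budget
would often exclude. Gapped alignment is deliberately not offered: the
variation being modelled is end-offset plus substitution, and allowing
indels would blur the (d5, d3) coordinates the rest of the analysis is
built on.

Reads are annotated against the study-species tier first; only unmatched
reads fall through to the other-species tier (candidate novel orthologs).
This ordering is asymmetric on purpose: a read compatible with both tiers
is evidence for the already-annotated species, not for a new ortholog.

## IsomiR classification

For each grouped read the extensions are compared with the flanking
hairpin sequence from the mature's placement:

* a 5' extension is *templated* when every extension nucleotide equals the
  corresponding upstream hairpin nucleotide;
* on the 3' side, the maximal suffix of the extension that disagrees with
  the hairpin is the non-templated addition (NTA). A templated nucleotide
  sitting 3' of a non-templated one is counted as part of the tail —
  tails are added sequentially after cleavage, so once a non-templated
  position occurs, downstream agreement with the hairpin is coincidence.

The taxonomy code is derived from the ground-truth fields (d5, d3,
templating, substitutions), never the other way round: `M` for the exact
mature, `Sub`/`Sup`/`Sub/Sup` for end deviations, `P` when both ends
deviate and every extension nucleotide is templated (the read is then a
shifted window of the precursor), `V` appended when any non-templated or
substituted nucleotide exists, and `*` inserted after the leading letter
for star-strand matures. The `P`/`PV` semantics are a declared
reconstruction of type codes seen in published isomiR tables; the fields
themselves are unambiguous. 5' non-templated additions are reported via
the templating flag but get no dedicated code letter — they are rare and a
code for them would never be exercised.

Consensus sequences take the count-weighted majority nucleotide at each
position of the union alignment span (negative indices for 5' extensions),
with ties resolved to the canonical (mature or hairpin-template)
nucleotide, so a consensus never drifts from the reference without a
strict majority. Per-position variant reports flag positions where a
single alternative nucleotide reaches a configurable fraction (default
0.2) of covering reads — high-frequency internal variants are the
signature of an unannotated paralog or an editing site, and 0.2 is low
enough to catch either while ignoring sequencing noise at realistic error
rates.

## Quantification

Counts are aggregated at three levels: exact mature (only d5 = d3 = 0,
zero-mismatch reads, but the feature exists as soon as any read groups to
the mature — a locus whose reads are all shifted shows an informative
zero), grouped on mature, and unique sequence. RPMM normalises to each
library's total annotated reads (both tiers); the per-library RPMM sums to
10⁶ at the unique level by construction, and this identity is tested. A
switch allows all kept reads as denominator instead; with it, RPMM depends
on how much unannotatable material a library carries, which is sometimes
wanted as a library-quality-sensitive measure, but the annotated
denominator is the default because the downstream proportions test uses
annotated totals.

Reportability requires ≥ 10 raw reads in at least one library. The
differential filters evaluate "detected in either layer" on
condition-level aggregates instead: summed raw reads (mature levels,
threshold 10) or condition mean RPMM (unique level, threshold 100). The
published wording does not disambiguate per-library from per-condition
evaluation; condition sums are used in the tables' own terms ("detected in
either layer") and the choice only affects borderline features.

## The differential test

Fold changes are computed from condition means of RPMM with the signed
convention fold = b/a if b ≥ a else −(a/b), so |fold| ≥ 1 always and the
sign carries direction. Report rounding is 2 decimals, half away from
zero; this convention is fixed so that round trips against printed tables
are well defined. One zero mean yields signed infinity (direction known,
magnitude not); both-zero features are dropped as untestable.

The proportions test is a weighted beta-binomial t-test in the spirit of
Baggerly's SAGE test, which the original analysis names without formulas;
the exact estimator here is therefore declared, not inferred. Per library
i, the feature proportion is p_i = x_i / n_i with n_i the annotated total.
Within each group the estimate is p̂ = Σw_i p_i / Σw_i with weights w_i =
1 / (p̂(1−p̂)/n_i + τ²), where τ² is a DerSimonian–Laird-type moment
estimate of between-library overdispersion, iterated to convergence and
floored at zero; Var(p̂) = 1/Σw_i. The statistic (p̂_A − p̂_B) /
√(Var_A + Var_B) is referred to a t distribution with (total libraries −
2) degrees of freedom — the natural residual count for two estimated group
means. With 3 + 3 libraries this df = 4 reference is deliberately
heavy-tailed: it is what keeps the test honest at tiny replication. Under
a beta-binomial null matching the declared model the test is calibrated
(rejection near 5% at α = 0.05, tested on 2,000 draws); under a pure
binomial null the τ² floor makes it conservative, never anticonservative.
Benjamini–Hochberg FDR across testable features accompanies the raw
p-values.

Degenerate inputs: groups need ≥ 2 libraries; all-zero totals are an
error; zero pooled variance with zero difference returns p = 1, with a
nonzero difference a p at the numerical floor.

## The simulator

`simulate_reference()` builds random hairpins with matures embedded at
fixed 5p/3p positions (3-nt flanks), optionally with star strands and two
planted fixture genes: a 5p-mature/3p-star pair and a paralog pair whose
matures differ at exactly position 17 (G/A) — the situation where an
internal "variant" at fixed fraction is really a second locus.
`simulate_library()` draws reads miRNA by miRNA from a log-normal
abundance model (stars downscaled ×0.05), applies sampled end offsets
(5': 90% canonical, ±1 at 8%, ±2 at 2%; 3': 40% canonical with symmetric
decay to ±3), an optional non-templated A/U tail (probability 0.15,
continuation 0.3), planted substitutions, per-nucleotide sequencing error,
and an optional adapter. Default depth is 50,000 reads per library, three
libraries per condition, two conditions, with per-miRNA condition
gradients.

The offset and tail defaults are chosen to reproduce the qualitative
shape of real cardiac libraries — 3' variability far exceeding 5'
variability — and are repository defaults, not estimates of any dataset.
Two constructions keep the truth table exactly recoverable: the first
nucleotide of every tail is forced to disagree with the hairpin flank
(otherwise the classifier would, correctly, call it templated), and tails
are only added on top of non-negative templated offsets with total 3'
deviation ≤ 3 (so no read is pushed outside the grouping tolerance).
Consequently, at zero sequencing error the pipeline recovers mature, d5,
d3, NTA and substitutions for 100% of reads, and this identity is a test,
not an aspiration. The paralog fixture is opt-in because a read from
paralog A carrying the planted substitution *is* paralog B's exact
sequence; grouping rightly prefers the exact assignment, which no truth
table labelled "A + substitution" can match.

What the simulator does not model: RNA-ligase/adapter sequence bias
(known to skew real libraries, with no published model to copy), quality
score structure, indels, and cross-mapping between genuinely homologous
families beyond the planted paralog pair. Passing tests on simulated data
therefore validate the algorithmic contracts, not the biases of any
particular library preparation.

## Problem sizes and numerical conventions

The test suite runs the truth-recovery check at the simulator's default
scale (5 hairpins, 3 + 3 libraries, 50,000 reads each, once at zero error
and once at 0.1%), the grouping oracle on 1,000 random read/mature pairs
against an independent brute-force enumerator, and the calibration study
at 2,000 null and 200 alternative draws; everything completes in well
under a minute on one core. Printed-table round trips check the seven
externally anchored rows exactly at 2 decimals and all remaining rows at
±0.03 — printed means are themselves rounded to 2 decimals, which for
large-magnitude folds (e.g. a 63-fold row) propagates to more than ±0.01
of fold.

Other fixed conventions: DNA alphabet internally (U→T on input, since
reads arrive as cDNA); 0-based half-open hairpin coordinates; a mature
occurring twice in a hairpin is placed leftmost with a warning; matures
found in several hairpins (multi-copy genes reported as `//`-joined
names) are one feature with multiple placements, the first deciding the
arm; reads containing N are dropped (tolerances are defined over ACGT);
the analysis length window defaults to 13–30 nt, encoding "longer than
12 nt" at the lower end and miRNA-sized material at the upper.

## Limitations

* The taxonomy code letters beyond (d5, d3, templating, substitutions)
  are a reconstruction; downstream work should consume the fields.
* The test's df and weighting scheme are declared choices; other
  beta-binomial formulations (e.g. likelihood-ratio on counts) would give
  slightly different p-values at this replication level.
* No between-sample normalisation beyond RPMM is provided (no TMM or
  quantile); RPMM is compositional, so strong single-feature gradients
  compress the apparent folds of everything else — visible even in the
  README's worked example.
* Multi-mapping reads are assigned to exactly one mature by the
  deterministic tie-break; an expectation-splitting assigner is out of
  scope.
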