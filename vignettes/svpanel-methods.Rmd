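---
title: "Methods: ensemble SV integration and cohort panel QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SV integration and cohort panel QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpanel)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, the numerical conventions, and
the design decisions taken where more than one reasonable choice
existed. The companion README shows a worked end-to-end example.

## Coordinate and genotype conventions

All internal coordinates are 0-based half-open `[start, end)`; VCF
input/output converts at the boundary (`pos = start + 1`), and BED is
consumed natively. A single arithmetic convention keeps every overlap
computation branch-free. Insertions carry a point coordinate
(`end == start`) plus a separate length field; reciprocal overlap is
undefined for insertions by construction, and their concordance is a
breakpoint-distance rule instead.

Genotypes live in paired integer allele matrices `(h1, h2)`. Missing is
`h1 = h2 = NA`; a haploid call (male non-PAR X) is `h1` set with
`h2 = NA`. Missing is never conflated with homozygous reference, and
haploid calls are first-class throughout the trio logic. In phased
truth panels the child convention is `h1` = paternal, `h2` = maternal,
which is what the parental flip rate is measured against.

When multiallelic rows are split (`split_multiallelics`), genotypes are
recoded against the retained alternate allele and INDELs are
left-normalised by shared-base trimming only — no reference FASTA is
consulted. Records that share a start position after splitting are
*not* given artificial coordinate shifts; instead a reversible key map
ties every output record to its source row and allele index. Mutating
coordinates would silently corrupt downstream overlap math, and a key
map is exactly invertible.

## Ensemble SV integration

**Concordance.** Two non-insertion records of the same type are
concordant when their reciprocal overlap — the minimum of
`overlap/len_A` and `overlap/len_B`, i.e. both fractions must meet the
cutoff (bedtools `-r` semantics) — reaches 50% for large pairs and 10%
for small ones. The published rule speaks of SVs "larger than 5 kb" and
"under 5 kb", leaving exactly 5 kb unassigned; this package assigns a
*pair* to the large class when its larger member exceeds 5,000 bp, so a
record of exactly 5 kb falls under the permissive 10% rule. Insertions
are concordant when their insertion points lie within 100 bp (closed
bound).

**Clustering** is single linkage over the concordance graph, per
chromosome and SV type, with records first put into canonical
(chrom, start, end, id) order so the result is invariant to input file
order. Candidate pairs come from an interval index rather than all
pairs; the test suite checks equality with a brute-force all-pairs
implementation.

**Boost model.** Each SV × carrier-genome gets a score in [0, 1] from a
per-SV-class supervised model over eight features: local depth ratio,
1-kb flank depth, pair-end count within 150 bp, split-read count within
100 bp of a breakpoint, log10 size, cohort allele fraction, genomic
context class, and the fraction of offspring carrying the SV de novo
among trios where it is observed. The default scorer is
gradient-boosted trees (xgboost, `nrounds = 60`, `max_depth = 3`,
`eta = 0.3`, single thread for determinism); a logistic-regression
fallback is selectable where a dependency-light scorer is preferred.
The published model's exact hyper-parameters are not recoverable, only
the procedure; the scorer is therefore pluggable and its settings are
arguments.

Training labels come from trio structure plus orthogonal support:
positives are uni-parentally inherited, shared across callers, and
carry both support flags; negatives appear de novo in offspring, were
discovered by a single caller, and carry neither flag. Everything else
is unlabelled. On synthetic data the support flags are supplied by the
generator's injection log, standing in for the long-read and assembly
evidence a real study would use (the stand-in is exact rather than
noisy, which makes the labels slightly cleaner than real orthogonal
support would be).

**Threshold selection.** The decision threshold is the smallest value
`t` whose estimated FDR among validation records scoring strictly above
`t` is below the 5% target; with no labels the published constant 0.448
is used, with a strict `>` at the boundary. Two estimator choices
matter and are deliberate:

* the estimate is computed at *call level* — one score per record, the
  mean over its carriers — because per-genome rows let a common true SV
  with hundreds of carriers swamp the estimate and drive the selected
  threshold to zero;
* inside the full pipeline the estimate is the upper bound of a
  Clopper–Pearson 95% interval on the false fraction
  (`conf_level = 0.95`), so the target is met with confidence rather
  than only in expectation. The bare `select_threshold()` operation
  defaults to the point estimate, which is the textbook rule and the
  right behaviour on small validation sets (an upper confidence bound
  can never reach 5% with fewer than ~60 validation records).

**Retention and final records.** Loci found by two or more callers are
retained outright. A caller-specific locus survives only if fewer than
48% (strict) of examined samples fail the boost model; "examined" is
interpreted as samples carrying a non-reference genotype, an
interpretation recorded here because the alternative (all genotyped
samples) would dilute the rule with irrelevant hom-ref samples. Within
a retained locus the per-sample winner has the most split reads, ties
broken by boost score; the locus winner is the record winning the most
samples, ties by carrier support then lexicographic id (determinism).
For shared insertion loci an optionally designated higher-precision
caller's record is kept instead. mCNV, CPX and CTX records pass through
unscored with `FILTER = Manual_LQ`; automated depth-profile review is
out of scope.

## Panel filtering

A site is retained iff all of: `FILTER = PASS`; genotype missingness
`< 0.05`; HWE exact p `> 1e-10` in at least one super-population;
Mendelian error rate `≤ 0.05`; minor allele count `≥ 2` (singletons
carry no phasing information). Inequalities are exactly as printed —
three strict, one non-strict — and verdicts are computed independently
then conjoined, so the retained set does not depend on evaluation
order; the *reported* first-failing criterion follows the order above.
A second MAC pass (`recheck_mac`) exists for use after phasing-side
edits.

The HWE exact test is the two-sided conditional test: given the sample
size and minor-allele count, sum the probabilities of all heterozygote
counts whose conditional probability does not exceed the observed
one (no mid-p correction, matching the standard reference
implementation). The enumeration runs in normalized probability space
with an additive `1e-12` guard at the ≤ comparison to absorb floating
noise. Monomorphic sites return p = 1 by convention. The chi-square
variant returns p = 1 with a warning when any expected cell is zero.
Both tests are exposed because the small-variant cascade uses the exact
test while the insertion-pipeline filter historically used chi-square;
`apply_panel_filters(hwe_test =)` selects between them.

Male chromosome-X correction converts male diploid genotypes to haploid
outside the pseudoautosomal regions ("0|1", "1|0", "1|1" → "1";
"0|0" → "0"), leaves PAR regions diploid and females untouched, and is
idempotent. GRCh38 PAR coordinates ship as the default and are
overridable.

## Trio metrics

Mendelian consistency uses explicit allele-multiset logic: a diploid
child must draw one allele from each parent's allele set; a haploid
child (male non-PAR X) must draw its single allele from the mother; a
haploid father contributes his single allele to diploid daughters.
Trios with any missing member are excluded from that site's
denominator — "complete trio calls" — and a site with zero complete
trios reports `NA`, a distinct state that passes through filters with a
warning rather than masquerading as 0.

The de novo rate is `1 − inheritance rate` by definition (inheritance =
fraction of the child's non-reference variants non-reference in ≥1
parent). Parental transmission counts only informative sites —
heterozygous in exactly one parent, absent in the other — where
Mendelian segregation predicts 50% transmission. Singleton profiles
count cohort-AC-1 alleles per sample over *all* samples (related
included); allele frequencies used elsewhere for binning are a separate
per-site statistic. Duo children are excluded from the child stratum
and reported separately.

## Phasing accuracy

SER walks consecutive assessed heterozygous sites (het and phased in
both panels) per chromosome and counts junctions where the relative
orientation changes. A single-site flip therefore contributes two
switches — the plain junction-count convention; no flip correction is
applied to SER because dedicated flip-rate metrics exist. Samples with
fewer than two assessed sites report `NA`, never 0. SER is invariant
under globally swapping either panel's haplotypes. MAF stratification
bins junctions by their right-hand site with default edges
{0.001, 0.01, 0.1, 0.5}.

The SV flip rate compares the cis/trans relationship of each assessed
SV with its nearest phased heterozygous flanking SNV on each side
(default search window 50 kb) between test and truth. The pairing rule
is a documented package choice: when both flanks exist and disagree
with each other, the nearer flank decides. Assessment is restricted to
SVs exactly matching the truth set per type (identical interval for
deletions — the 100% reciprocal-overlap case — and identical breakpoint
for insertions); the assessed fraction is reported alongside the rate.

The parental flip rate assesses child-heterozygous sites with
unambiguous trio phase: sites where child, father and mother are all
heterozygous are excluded, as are de novo sites and sites where neither
parent could consistently have donated the alternate allele. One
haplotype-to-parent orientation is chosen per chromosome per child by
majority vote, so a single upstream switch error cannot masquerade as a
long run of flips.

## Imputation evaluation

Dosage is `p_het + 2·p_homalt`. The info score is the IMPUTE-style
variance ratio `1 − Σ(fᵢ − eᵢ²) / (2Nθ(1−θ))` with
`eᵢ = p_het + 2 p_homalt`, `fᵢ = p_het + 4 p_homalt`,
`θ = Σeᵢ/(2N)`; monomorphic sites (θ ∈ {0, 1}) return 1 by convention.
The named software's formula is not printed in its documentation of
record, so the formula identity is stated here and cross-checked in the
tests against an independent per-sample variance enumeration.
Probability triples are validated to sum to 1 within `1e-6`.

Hard calls take the arg-max class when the maximum probability reaches
0.90 (0.90 itself is a call, not missing); ties at the maximum are set
missing with a warning (impossible above threshold 0.5, handled
defensively). Discordance is `1 − matches / non-missing calls` per
sample, optionally restricted to sites shared between the panels under
comparison. Dosage r² is the squared Pearson correlation; the default
aggregation computes one r² per sample within each reference-panel AF
bin and averages over samples, excluding undefined (zero-variance)
sample-bins from the mean and reporting how many were excluded;
site-wise aggregation is available via `by = "site"`. Variant counting
by info cutoff uses strict `>` at {0.4, 0.8} and the imputed-set MAF
with bins {<0.5%, 0.5–5%, ≥5%}; counts are nested across cutoffs by
construction.

## Truth-set construction

Genotyper A contributes calls with genotype quality ≥ 200; genotyper B
contributes PASS sites; agreement (unordered genotypes) yields the
integrated call, anything else is missing, and sites missing across all
samples are dropped. When one genotyper lacks a site entirely the
integrated genotype is missing (intersection semantics) — the
alternative of admitting single-source genotypes is not taken, because
a truth set should only contain doubly-supported calls. Site matching
uses closed ±50 bp start windows (match iff `|Δstart| ≤ 100`, a
convention stated explicitly because half-open window arithmetic could
give 99 or 101) and a shorter/longer length ratio ≥ 0.80, reduced to
one-to-one pairs greedily by smallest start distance, ties by larger
length ratio — a truth set must not double-count. Finalisation drops
monomorphic sites and sites with HWE exact p < 1e-10. Genotype
concordance divides correct genotypes by all non-missing validation
genotypes (a missing test call counts against concordance);
non-reference precision divides correct het + hom-alt calls by all
non-reference calls the test set makes.

## Benchmarking

Small-variant matching requires identical (chrom, pos, ref, alt) after
splitting and left-normalisation, plus identical unordered genotypes in
genotype-aware mode; full local-haplotype reconciliation (as done by
dedicated benchmarking engines) is out of scope and noted. All counts
are restricted to variants falling entirely within the confidence
regions. Easy/difficult stratification classifies an SNV by its single
base and any length-bearing variant overlapping ≥1 difficult base —
including border-spanning variants — as difficult. Summary calculators
round fold changes to 2 decimals and percentages to 1, the conventional
printed precision.

## The synthetic cohort generator

The generator's defaults are the package's reference study conditions:
50 trios plus 100 unrelated samples (250 genomes), 3,000 small-variant
sites and 600 SV loci over two 50-Mb chromosomes; small-variant de novo
rate 0.003 per child (inside the 0.2–0.5% envelope reported for
short-read WGS), SV de novo rate 0.005; two callers with 5%/10% false
positive rates, 5% false-negative rates and 10 bp breakpoint jitter;
split-read evidence mean 8 (true) vs 1 (false) and pair-end mean 6 vs
1; switch and point-flip error rates 1%; genotype-probability noise
0.05. Allele frequencies mix a 10% singleton point mass with a
Beta(0.3, 1.5) spectrum, logit-jittered per super-population
(sd = 0.3) to exercise per-population HWE stratification; five
super-population labels are assigned round-robin. The panel size of
3,000 sites is chosen so the default cohort yields over 1e5 assessed
heterozygous junctions, the scale at which a 1% switch rate is
recoverable within tight binomial error.

De novo injection is calibrated so the *expected fraction of a child's
non-reference variants that are de novo* equals the configured rate:
with `m` inherited non-reference variants, the number of injected de
novos is Binomial(m, f/(1−f)), placed at sites where the whole trio is
hom-ref. Every corruption (caller FP/FN/jitter, phasing switches and
flips, genotyper errors) writes an injection log sufficient to compute
true FP/FN/switch labels without re-deriving them; all outputs are
byte-reproducible from (seed, config).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and coalescent
structure (sites are independent), realistic sequence content,
read-level artifacts, caller-correlated errors (the two callers err
independently, whereas real callers share failure modes in repetitive
sequence), cell-line somatic artifacts inflating singleton counts, and
chromosome X (male-X logic is exercised by explicit fixtures instead).
Evidence features for true and false SVs are well separated by default
so the boost model is learnable at small n; the separation is a knob,
and shrinking it is the intended way to probe threshold-selection
behaviour under harder conditions.

## Problem sizes and runtime

The test suite and the acceptance script run on one CPU in minutes:
the end-to-end integration condition uses the default 250-genome / 600-SV
cohort (~3 s); rate-recovery conditions size themselves so that at
least 1e4–1e5 events are assessed (e.g. 6,000 SNV sites and 1,200 SVs
for the flip-rate recovery); the HWE oracle comparison enumerates every
genotype configuration up to n = 50. These sizes are the package's
chosen reference conditions; all of them are config arguments.

## Known limitations

* The boost scorer reproduces the published *procedure*, not the
  published model; absolute scores are not comparable across scorers.
* FDR-driven threshold selection assumes validation labels are a
  representative sample of the scored population; the conservative
  upper-bound estimator mitigates but cannot remove label-coverage
  bias (false SVs that never manifest as trio de novos are invisible
  to the labeller and are controlled only indirectly, through the
  retention rule).
* Benchmarking matches variant representations exactly after
  normalisation; semantically equivalent complex representations are
  counted as discordant.
* The SV flip rate's flanking-SNV pairing (two-sided majority,
  nearer-flank tie-break, 50 kb window) is one defensible reading of
  "SV–flanking-SNV pairs"; rates under other pairings differ at the
  margin and the pairing is recorded in the report metadata.
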