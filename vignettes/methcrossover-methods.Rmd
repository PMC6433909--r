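---
title: "Methods: cross-contrast differential methylation with methcrossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-contrast differential methylation with methcrossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcrossover)
```

This vignette is the package's own account of the statistical
procedures it implements, the assumptions behind them, and the design
choices made where the problem was genuinely open. The running setting
is a whole-blood RRBS cohort with three groups — lean controls, obese
subjects, and colorectal-cancer (CRC) patients — analysed as two
case–control contrasts against the shared controls, followed by a
cross-contrast comparison of the resulting alteration sets.

## Preprocessing

**Site filters.** Per sample, sites need at least 5X coverage
(`min_coverage`, reads), sites above the sample's 99.9th coverage
percentile are discarded as likely PCR artefacts
(`max_coverage_quantile`, computed with linear interpolation, strict
exceedance), and the sex chromosomes and mitochondrion are excluded so
that sex composition and copy-number oddities cannot masquerade as
group effects. One subtlety: a percentile re-estimated on its own
output shifts slightly, so a single pass is not idempotent at the
margin. `filter_calls()` therefore applies the percentile rule to
convergence (usually one extra pass touching well under 0.2% of
sites), which makes the filter a projection: applying it twice equals
applying it once.

**Coverage normalization.** Each sample's coverages are scaled by
(grand median of per-sample median coverages) / (sample median),
rounded with a floor of one read, and methylated counts are scaled by
the same factor, so per-site methylation levels β = m/c move by at
most one count of rounding.

**Histogram transformation.** To remove sample-level distributional
shifts (conversion efficiency, composition) before testing, each case
sample's β values are mapped onto the pooled-control empirical
distribution by monotone quantile matching: a site at empirical
quantile q within its own sample (mid-rank convention, ties share a
rank) is assigned the pooled-control q-quantile, and the methylated
count is re-rounded against the unchanged coverage. No standard algorithm exists for this
equalization step; empirical quantile matching was chosen because it is monotone,
parameter-free, and distribution-equalizing by construction. Two
properties are worth stating precisely: the map never inverts the
order of two sites (and maps ties to ties), but it may *collapse*
neighbouring distinct values where the control quantile function is
flat, so rank preservation holds in the non-inversion sense.
Equalization is exact up to count discreteness: at low coverage the β
values live on a lattice (multiples of 1/c) whose atoms alias against
any fixed histogram binning, so binned distances between transformed
case and control distributions bottom out at the lattice resolution
even though the Kolmogorov–Smirnov distance is small.

## DMC calling

Each CpG is tested with a binomial logistic regression on
(methylated, unmethylated) counts,

  logit(π) = β₀ + β₁·I(case) + β₂·age,

with the p-value from the likelihood-ratio test of β₁ (χ², 1 df).
The LRT was preferred to the Wald test for small-sample stability;
age enters as a continuous covariate (the natural default
coding) and absorbs the strong
age–methylation association so that the age-discrepant CRC contrast
is not confounded. Sites covered in fewer than three individuals per
group are skipped entirely rather than fitted on vanishing degrees of
freedom. Non-convergent fits are reported with p = 1 and a flag, never
silently dropped; complete separation with a converged deviance (the
strongest possible signal) is *not* flagged, since the LRT remains
valid there. Multiplicity is handled by Benjamini–Hochberg over all
tested sites — the conventional, conservative choice — behind a
pluggable q-value column. A site is significant when |Δmeth| ≥ 10
percentage points (unweighted mean of per-sample β, case minus
control, robust to coverage imbalance; a coverage-weighted variant is
a one-line change in `dmr_subject_means()` style) *and* q < 0.05.

The caller is binomial, not beta-binomial: between-subject
overdispersion is deliberately out of scope, matching standard
logistic-regression DMC callers. The consequence is quantified, not
hidden: under beta-binomial data (φ > 0) the caller's type-I error is
inflated, so the calibration and recovery simulations below are run at
φ = 0, exercising the caller under its own sampling model; the
generator's default φ = 0.05 is used everywhere a calibrated error
rate is not being asserted (e.g. the end-to-end smoke run).

## DMR segmentation

RRBS coordinates are strongly clustered (MspI fragments), so the
distances between consecutive tested CpGs are bimodal on the log
scale. `distance_cutoff()` fits a two-component Gaussian mixture
(`mclust`, unequal variances) to the pooled log10 consecutive-distance
values and places the merge cutoff at the point between the two
component means where the weighted densities cross (found by
`uniroot`). Degenerate situations — fewer than 100 tested sites,
component means closer than 0.2 log10 units, a failed fit, or no
density crossing between the means — fall back to 100 bp.

Runs of tested CpGs with gaps at or below the cutoff become candidate
regions. The region p-value is a signed Stouffer combination,
z = Φ⁻¹(1 − p/2)·sign(Δmeth) summed over members and divided by √n,
so that direction-inconsistent members cancel rather than reinforce;
the correlation correction used by some segmenters is deliberately
omitted (a documented simplification — neighbouring CpGs are
positively correlated, so region p-values are anti-conservative and
are used for ranking, not gating). Reported regions pass exactly three
rules: ≥3 CpGs, ≥1 significant DMC, and |mean Δmeth| > 5 pp
(strict); region q-values are computed for ranking but not used as a
gate.

## Cross-contrast overlap and concordance

Overlapping DMCs are the exact (chrom, pos) intersection of the two
contrasts' significant sets; each overlapping site contributes its two
per-contrast direction signs to a 2×2 hyper/hypo quadrant table.
Association between the contrasts is tested by the χ² independence
test on that quadrant table, without Yates correction (the motivating
tables hold tens of thousands of sites; a `correct` flag exists).
The quadrant-independence
reading is implemented because it is the only 2×2 formulation that
uses all four direction cells. The concordant fraction is
(hyper-hyper + hypo-hypo)/n_overlap.

DMR overlap needs an interval rule: we use ≥1 bp intersection (configurable) with one-to-one greedy
pairing by largest intersection, ties broken toward the leftmost
partner — the simplest reproducible rule that never double-counts a
region. Overlap percentages are 100·n_overlap/(contrast total).

## Annotation and context profiles

The promoter is the 2 kb window immediately upstream of the TSS on the
gene strand. A feature spanning several categories is assigned by
precedence promoter > exon > intron > intergenic (promoter-first,
reflecting the regulatory reading of promoter methylation), with the assigning gene chosen by
largest intersection. UTRs are collapsed into exon because the toy
gene models carry no UTR boundaries; the enum is extensible. Island
context is island / shore (within 2 kb of an island, UCSC convention)
/ open sea; shelves are omitted as adding little at toy-annotation
resolution. "Which specific set does the overlap resemble?" is
made quantitative as the total-variation distance between normalized
direction-by-category count profiles.

## Candidate selection

For every overlapping DMR, each subject's summary is the
coverage-weighted mean Σm/Σc over member CpGs covered in that subject
(missing when none are). Regions testable in all three groups (≥3
non-missing subjects per group) get a Kruskal–Wallis p across groups
and pairwise Mann–Whitney U p-values. The selection threshold is
p ≤ 0.1, the conventional marginal-significance level. Which pairwise
comparisons must pass is a design choice; both case-vs-control
comparisons are required (configurable to all
three), matching the selection intent of finding regions altered in
*both* conditions. No multiplicity correction is applied at this stage; raw
nonparametric p-values are reported. The MWU
is exact — full enumeration over all C(m+n, m) group assignments of
the pooled values, which handles ties correctly — whenever both groups
have ≤8 subjects, with the two-sided p defined symmetrically as
P(U ≤ min(u, mn−u)) + P(U ≥ max(u, mn−u)); larger groups use the
tie-corrected normal approximation without continuity correction.
All-tied rows return p = 1.

## Enrichment

The EASE score is the one-sided hypergeometric tail probability with
the query–term overlap decremented by one: P(X ≥ k−1) for
X ~ Hypergeom(N, K, n). The decrement makes single-gene overlaps
unremarkable by construction (p = 1), a deliberate conservatism.
Term databases are user-supplied GMT files (a synthetic toy collection
ships in `inst/extdata/`); the default background is the full gene
universe of the supplied annotation. Terms are reported significant at
p < 0.05.

## Expression concordance

TMM factors are coded directly from the published algorithm: reference
= library whose 75th count-proportion percentile is closest to the
mean; M = log2 proportion ratio and A = mean log2 proportion over
genes expressed in both libraries; double trimming (30% on M, 5% on A,
rank-based); factor = 2 to the precision-weighted mean M, weights from
the asymptotic binomial variance; factors rescaled to geometric mean
one. The independent implementation in edgeR serves as a cross-check
oracle in the tests, never as the implementation. Log-CPM uses a
reads-per-million prior, prior_j = prior·L_j/10⁶ with denominator
L_j + 2·prior_j: this form is an exact function of count proportions
(globally rescaling all libraries changes nothing) and coincides with
the conventional `log2((count + 0.5)/(lib + 1)·10⁶)` at a one-million-
read library. The concordance report row-centers log-CPM per gene,
averages per condition, and compares the sign of the
condition-2 − condition-1 difference with the expected direction of
expression change on demethylation (|difference| ≤ 10⁻⁸ is "neutral").

## The synthetic-data generator

`simulate_methylation()` emulates the cohort the analysis assumes:
group sizes default to 15/10/15 with ages 40±15, 36±10 and 53±9 years;
CpGs arrive in clusters (~8 sites ~30 bp apart, clusters a few kb
apart) mimicking reduced-representation enrichment, which is what
gives the distance-mixture cutoff something real to estimate;
background methylation is a bimodal Beta mixture (45% low, 45% high,
10% intermediate — defaults documented here, not claimed to match any
particular cohort);
coverage is negative-binomial (mean 30, size 8); methylated counts are
beta-binomial with overdispersion φ = 0.05 by default (φ = 0 gives
exact binomial sampling); an optional age slope of 0.002/yr on the
logit exercises the caller's covariate. Planted regions carry signed
Δβ effects per contrast in five concordance classes; their baselines
are drawn inside the band that lets the full effect be realized
without hitting the [0.01, 0.99] clip, so a planted |Δβ| is the
effect the caller actually faces. Each output stream is seeded at a
stable offset from the master seed. `simulate_annotation()` frames
each planted region with a dedicated gene so its subregion is known by
construction, fills remaining space with disjoint background genes,
and grows islands over CpG clusters to a target coverage fraction
(default 0.4 of CpGs). `simulate_expression()` draws negative-binomial
counts for a two-condition, two-replicate design with planted log2
fold-changes and ±20% library spread.

What passing tests on these data do *not* show: the generator has no
cell-composition heterogeneity, batch structure, SNP contamination,
strand asymmetry, or spatial correlation of methylation beyond the
planted regions — so recovery and calibration results speak to the
statistical machinery under its stated model, not to robustness
against those real-data features.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use: 5,000 null sites
at 5 vs 5 subjects, 30X, β = 0.3 for type-I calibration; 50 planted
concordant regions (5 CpGs, |Δβ| = 0.3, 10 vs 10 subjects) among 5,000
background CpGs for region recovery; 250 planted regions at 80%
concordance over 2,000 background CpGs for concordance recovery
(≥1,000 overlapping DMCs); exhaustive EASE enumeration over all
margins ≤ 30; full MWU enumeration for group sizes ≤ 6; and the
15/10/15 smoke cohort over 2×1,200 background CpGs with 40 planted
regions. These sizes were chosen as the smallest at which the asserted
properties are statistically meaningful. Ties in rank tests use
mid-ranks; BH ties are left as `p.adjust` returns them; χ² on a
quadrant table with a zero margin is reported NA with a warning rather
than fabricated; degenerate mixture fits fall back to 100 bp; a
degenerate (constant) control β distribution makes the histogram
transform error out.

## Known limitations

Per-site tests ignore between-subject overdispersion (see above);
region p-values ignore inter-CpG correlation; symmetric-CpG strand
collapsing is not performed (sites are kept as given); annotation is
gene-span based, not isoform-aware; and the expression module verifies
direction concordance only — it is not a differential-expression
analysis.
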