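---
title: "Models and methods: heterochiasmy and QTL analysis in an outbred four-way cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiasmr)
```

This vignette is the package's own account of its models, algorithms and the
design choices behind them: what is assumed, which parameters matter, what
the simulator does and does not emulate, and the numerical conventions used
throughout.

## The cross and its genotype algebra

A four-way ("cp") cross has two outbred parents, each heterozygous with two
distinct haplotypes: dam haplotypes `a`/`b` and sire haplotypes `c`/`d`. By
convention `a` and `c` carry the first allele of each parent's genotype
string. Markers come in three informativeness classes:

| type   | dam        | sire       | observable classes | resolution |
|--------|------------|------------|--------------------|------------|
| nn×np  | nn (homoz) | np         | nn, np             | sire only  |
| lm×ll  | lm         | ll (homoz) | ll, lm             | dam only   |
| ef×eg  | ef         | eg         | ee, ef, eg, fg     | both       |
| hk×hk  | hk         | hk         | hh, hk, kk         | both, but `hk` is ambiguous |

The `hk` heterozygote cannot be phased for either parent (the `h` could have
come from the dam's `a` or the sire's `c`), so it contributes an unknown
label to both parental phase sequences; the homozygotes `hh` and `kk` resolve
both parents. This asymmetry is why roughly half of hk×hk calls are
uninformative for crossover analysis while the marker remains fully usable
(three observable classes) for the QTL scan.

File dialects are deliberately minimal CSVs (see `?read_map`). The genotype
file accepts either phase codes (`ac`, `bd`, `-c`, `a-`, `hk`, `-`) or raw
allele pairs (`ee`, `np`, ...); both normalise to the same internal
representation. `lm×ll` is accepted on input even though two-parent analyses
ignore it, since dam-only markers legitimately occur in maps of this kind.

## Crossover detection

For one offspring, one parent and one linkage group, the phase sequence is
the ordered vector of haplotype labels at informative markers; missing and
ambiguous calls are unknown. The obligate crossover count is the minimal
number of phase switches consistent with the knowns: one event per label
change between consecutive known-label markers. A label change across a run
of unknowns counts as exactly one event — the parsimony resolution — placed
at the midpoint of the bounding known markers. The test suite proves this
equals a brute-force minimal-switch oracle exhaustively for all two-label
sequences up to length 12 and on random sequences with unknowns.

Positions are interval-censored: an event is known only to lie between its
flanking markers. We use the flank midpoint as the point position and
percent positions against the linkage-group length, defined as the last
marker's cM position (positions are 0-based at the first marker). Groups
with a single marker have zero length and are excluded from positional
analyses with a warning.

## The even-parity double-crossover correction

A single genotyping error flips one call, creating two apparent phase
switches a few markers apart. The correction chains events (per offspring ×
parent × linkage group, sorted by midpoint) into clusters within a window
`W` and then applies a parity rule:

- **even cluster** — net phase change zero, the signature of error, all
  members removed;
- **odd cluster, size k > 1** — net change is one switch; under the default
  `collapse_to_one` policy the cluster collapses to one representative at
  the median member's midpoint (`keep_all` retains all members, for
  sensitivity probing);
- **singleton** — retained.

Two chaining readings of "a second crossover within W" are provided: `gap`
(default; an event joins while its gap to the previous event is ≤ W) and
`anchor` (while within W of the cluster's first event). Gap chaining is the
common de-duplication reading and behaves continuously as clusters grow.
Whether the window is measured between marker positions or event midpoints
is genuinely open; midpoints are used here. Under `collapse_to_one` the
retained count is congruent mod 2 to the raw count per chromosome — net
phase change along a chromosome is invariant — and this parity conservation
is tested property-style.

The default `W = 50` cM, with 25 and 10 cM as standard sensitivity settings
(`window_sensitivity()` tabulates the ratio across all three). Note the
correction deliberately sacrifices genuine tight double crossovers; with
realistic crossover interference such pairs are rare (below), so the
trade is strongly favourable whenever the genotyping error rate is
non-negligible.

## The meiosis simulator

`simulate_cross()` exists so that every downstream stage can be validated
against known truth without any external data.

**Crossover process.** Crossover counts and positions follow a stationary
gamma-renewal process on the density-transformed axis: inter-crossover
spacings on the warped scale are Gamma(ν, ν) (unit mean), the first spacing
drawn from the Erlang equilibrium mixture so the process is stationary and
the expected count is exactly map length/100. Mapping the renewal points
through the positional density's quantile function gives the marginal
position law. With `interference_nu = 1` this is exactly a Poisson count
with i.i.d. positions. The default ν = 8 encodes strong crossover
interference of the magnitude typical for vertebrate meiosis; it is also a
coherence requirement — the even-parity correction is premised on true
double crossovers being rare within the window, and a no-interference
simulator would violate the assumption the method it validates is built on.
At ν = 8 only ~5% of consecutive crossovers fall within 50 cM of each other
on the genetic scale.

**Positional densities.** The maternal density is center-biased, modelled
as Beta(2, 2) — a choice, not an estimate: nothing in the motivating
setting pins the exact shape beyond "biased toward the center". The
paternal density is telomere-biased: a piecewise-uniform density with
`telomere_mass = 0.95` of its mass in the distal 20% of the axis (split
between both ends on fused metacentrics), reflecting that male crossovers
are essentially confined to chromosome ends with almost none elsewhere.

**Karyotype defaults.** 42 linkage groups — 8 fused metacentric (120 cM
female length) and 34 acrocentric (60 cM) — with male lengths = female/2.7,
16 groups flagged residually tetraploid, and one acrocentric sex-linked
group. Markers are evenly spaced in cM (isolating algorithmic behaviour
from map-density artifacts), 90 per group in an equal mix of nn×np, ef×eg
and hk×hk.

**Residual tetraploidy.** In flagged groups the male-informative signal is
removed in a terminal fraction (`tetraploid_drop_frac = 0.3`, the end
opposite the centromere; both ends on metacentrics): sire-only markers are
dropped from the map and both-informative markers are re-typed to dam-only,
emulating marker loss during diploid-assuming map filtering. Masking hides
genuine male crossovers, so the observed female:male ratio in masked strata
is inflated by construction — recovery-of-truth experiments therefore run
with masking off, and masking-on runs are used to study the inflation
itself.

**Sex.** The sex-linked group carries an XY-like locus at its centromeric
end; offspring sex is the transmitted sire haplotype there (expected 1:1).
Male recombination on this group is confined to the distal
`pseudoautosomal_frac = 0.2`, which produces the expected scan signature:
near-perfect sex linkage over most of the group with a LOD decline at the
pseudoautosomal end.

**Corruption.** Genotyping errors substitute a call uniformly among the
other legal codes for its marker type at rate `error_rate` (0.005); calls
go missing at `missing_rate` (0.005). The uncorrupted genotypes are kept
alongside (`geno_clean`), enabling exact attribution of error-induced
events in tests.

**What the simulator does not emulate.** Real marker spacing is irregular
and clustered; real genotyping errors are not symmetric across codes
(allele dropout is directional in RADseq data); missingness is not
independent across markers and individuals; segregation distortion arises
only through sampling, not biology; there is one family, no population
structure, and map order is assumed correct. Passing tests therefore
validate the algorithms under clean assumptions, not the full messiness of
field data.

## Quality control

Filters run in a fixed order: segregation-distortion removal → duplicate
detection → crossover-count outliers → optional per-offspring missingness →
phenotype trimming.

- **Segregation distortion:** per-marker chi-square against 1:1 (df 1),
  1:2:1 (df 2) or 1:1:1:1 (df 3), markers removed at raw P ≤ 0.01 — no
  multiple-testing correction, matching standard map-filtering practice.
  P-values are checked against `chisq.test` to 1e-10 in tests.
- **Duplicates:** pairwise identity proportion over mutually non-missing
  calls, pairs ≥ 0.9 reported; the second member of a pair is dropped. The
  threshold presumes a genome-scale marker set — with only a few linkage
  groups, sib-sharing variance can push honest pairs above 0.9.
- **Crossover-count outliers:** raw obligate counts exceeding
  `median + 10 · max(MAD, 1)` (plain MAD, no consistency constant) are
  removed; the `max(·, 1)` guards the MAD = 0 case. The rule
  operationalises the ad hoc removal of grossly inflated samples; an
  explicit id-exclusion list is also accepted.
- **Phenotype outliers:** single-pass k = 3 SD trim. Single-pass is a
  deliberate choice (iterative re-estimation removes more and more); it is
  conservative at small n — a documented example shows a 100 among four 1s
  survives because it drags the SD up with it. The composition of the
  structural filters is idempotent; the SD trim, being single-pass by
  definition, is not re-applied.

## Heterochiasmy summaries and centromere inference

Summaries count retained events per parent, overall and per stratum, with
the sex-linked group excluded from autosomal totals and class strata but
reported separately (its removed-event totals likewise). Ratios are stored
as raw quotients and reported to one decimal. Per-chromosome means are
means over linkage groups of per-group totals. Positional histograms use
5% bins on the percent axis with fused metacentrics treated as one 0–100%
axis; the "external 20%" share uses the closed intervals [0, 20] and
[80, 100].

Centromere-end inference for acrocentric groups assigns the centromere
opposite the terminal 20% holding ≥ 80% of male events (minimum 5 events,
otherwise undetermined). Two refinements matter in practice:

1. **Isolated events only.** A collapsed odd-cluster representative sits at
   the median member's midpoint; when the cluster mixed a true crossover
   with an error pair, the representative can inherit the *error's*
   position anywhere within the window. Using only singleton-cluster
   events (`use = "isolated"`) keeps positions clean.
2. **Interval-aware terminal assignment.** Because positions are censored
   to the flanking interval, an event is counted as terminal when its
   flanking interval reaches into the terminal 20% (right flank for the
   distal end, left flank for the proximal end). Midpoint assignment blurs
   genuinely terminal events across the 20% line by roughly the marker
   spacing and systematically deflates the confidence.

## The QTL scan

The scan statistic is marker regression at marker positions only — no
inter-marker grid and no mixture-model interval mapping. At each marker the
genotype classes are the legal observed codes for its type (two, three or
four classes); offspring missing the trait, a covariate or that marker's
genotype are dropped marker-wise, and

LOD = (n/2) · log10(RSS_reduced / RSS_full),

reduced = covariates only, full = covariates + genotype-class factor. This
choice trades the modest power gain of interval mapping for transparency
and an exactly permutation-testable statistic; on dense maps the two
approaches localise QTL nearly identically. When RSS_full < 1e-12 · TSS the
fit is perfect up to numerical noise and a capped sentinel LOD of 50 is
reported. LOD is invariant under affine transformation of the trait (both
RSS terms scale together), which the tests assert to 1e-9.

**Covariates and transforms.** Sex enters as a covariate when a two-group
F-test gives P ≤ 0.20 (a deliberately liberal screen, reducing residual
variance). Traits flagged `log` are log-transformed before analysis; no
automatic normality decision is imposed, but a Shapiro–Wilk advisory prints
when the trait deviates strongly.

**Permutation thresholds.** The trait is permuted across offspring — within
sex strata whenever sex is a covariate, preserving the covariate's marginal
association under the null — and the genome-wide threshold is the (1 − α)
quantile of the per-permutation maximum LOD over all markers (α = 0.05);
chromosome-wide thresholds take per-group maxima at α = 0.01. Defaults use
1,000 permutations in the pipeline; the calibration experiments in the
acceptance suite use 200 permutations × hundreds of null scans, which is
sufficient because the exchangeability argument is exact at any permutation
count. Thresholds with α ≥ 1 are 0 (LOD is bounded below by 0). The
permutation engine precomputes a thin-QR projection per marker and applies
it to all permuted trait vectors at once; it is verified against a direct
`lm()` oracle to 1e-8.

**Support intervals.** 1.5-LOD intervals: the widest contiguous marker span
around the peak with LOD ≥ peak − 1.5, expanded one marker beyond on each
side, truncated at group edges. With markers of mixed informativeness the
contiguity can break at a weakly informative marker adjacent to the peak;
the coverage guarantees are therefore stated (and tested) on homogeneous
fully-informative markers.

**Multi-QTL fits.** Selected peaks enter a joint linear model (plus sex
when flagged); total PVE = 100 (1 − RSS/TSS) and per-term PVE is drop-one:
100 (RSS_without − RSS_full)/TSS. Collinear terms are dropped with a
warning. Genotype-class means and effects are reported per marker,
sex-split when sex is in the model. The sex-by-genotype interaction test is
gatekept: the full model (genotype × sex) must be significant against the
null before the interaction F-test (full vs additive) is attempted; empty
sex × genotype cells skip the test with a warning.

**Binary sex scan.** Offspring sex coded 0/1 is scanned with the same
linear marker regression; with a 1:1 trait the permutation null for the max
LOD remains valid, so no logistic variant is needed to identify the
sex-linked group.

## Reproducibility, problem sizes, and the pipeline

All simulator randomness flows from the config seed; permutation seeds are
explicit arguments. `run_pipeline()` runs input → QC → crossovers →
heterochiasmy → scan in fixed order, records every stage's parameters and
the seed in `MANIFEST.json`, and rerunning a config reproduces the bundle
byte-for-byte (tested).

Validation problem sizes were chosen to keep the whole suite comfortably
desk-scale while leaving no statistical ambiguity: full-geometry
heterochiasmy recovery at 170 offspring × 42 groups × ~3,700 markers;
detector–oracle equivalence exhaustive to length 12; permutation type-I
calibration with 300–500 null scans at 200 permutations on a 100-marker
map; sex-linkage detection over 8–20 replicates; PVE recovery over 20–60
replicates. `scripts/acceptance.R` recomputes the headline quantities from
scratch in about a minute.

## Known limitations

- The correction removes genuine double crossovers within the window; at
  W comparable to chromosome length this biases counts low for the parent
  with more mid-chromosome recombination (the dam), which is why the
  window-sensitivity table is part of the standard output.
- Marker regression discards inter-marker information and treats `hk`
  offspring as their own class rather than reconstructing phases; with
  strongly distorted or sparse maps an interval-mapping engine would
  localise better.
- Centromere inference presumes the male telomere-bias mechanism; in a
  species without it the calls are meaningless (they will mostly return
  undetermined).
- The phenotype model is additive-Gaussian per haplotype substitution;
  dominance within a parent's haplotype pair is not separately modelled.
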