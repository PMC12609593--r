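---
title: "Quantifying absolute and presumably active rDNA copies in sperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying absolute and presumably active rDNA copies in sperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnactive)
```

## The measurement problem

Human genomes carry several hundred tandem ribosomal DNA (rDNA)
transcription units, and only a fraction of them — those with a
hypomethylated promoter — are thought to be transcription-competent.
`rdnactive` implements the two-assay strategy used to quantify both
quantities in sperm:

1. **Absolute copy number** per haploid genome comes from droplet digital
   PCR (ddPCR): the rDNA target and a single-copy reference gene (such as
   *TBP*) are partitioned into ~20,000 droplets, and template
   concentrations are recovered from the positive-droplet fractions by
   Poisson occupancy.
2. **Presumably active copy number** comes from deep bisulfite sequencing
   (DBS) of a promoter amplicon with 25 CpGs: each sequenced molecule is an
   epiallele whose per-read methylation is binned in 10 % steps, and the
   active copy number is the absolute copy number multiplied by the
   fraction of retained reads with methylation ≤ 10 %.

A cohort statistics layer reproduces the inferential workflow such data are
analysed with (rank tests, Spearman correlations, a confounder-adjusted
logistic pregnancy model), and a synthetic-cohort generator provides ground
truth for every stage.

## ddPCR quantification

For a well with `k` positive droplets of `n`, the mean copies per droplet
are `lambda = -ln(1 - k/n)`, multiplied by the well's dilution factor; the
concentration in copies/µL divides by the droplet volume (default
0.85 nL — the droplet-reader convention; it rescales concentrations but
cancels from every ratio). The copy number is

```
CN = (lambda_target / lambda_reference) * m_ref
```

`m_ref` is the copy number of the reference gene in the genome of
interest. The default is `m_ref = 1`: a single-copy autosomal gene counts
once per haploid sperm genome. Use `m_ref = 2` to express copy numbers per
diploid genome (for blood, roughly twice the sperm scale). This parameter
is deliberately explicit because the two conventions differ by a factor of
two and are easy to conflate.

Confidence intervals use a Wilson score interval on each positive fraction,
mapped through the (monotone) occupancy transform, and combined across the
two wells by the delta method on the log ratio. The Wilson form was chosen
for stability at small positive counts; intervals are a package addition
rather than part of the original computation.

The target is modelled in a separate well diluted 10× by default. At a
realistic reference loading (`ref_lambda ≈ 0.03`) an undiluted
several-hundred-copy target would drive the positive fraction towards
saturation, where `-ln(1 - p)` becomes unstable; saturated wells are
flagged and refuse to produce an estimate. A duplex layout is supported
through `classify_droplets()`, which turns two-channel amplitude tables
into the four droplet categories under user-supplied thresholds (threshold
choice is manual in instrument software, so it is an input here, not an
inference).

## Bisulfite read processing

Reads are placed on the amplicon by an ungapped, bisulfite-aware scan:
both read and reference are collapsed to "bisulfite space" (C treated as
T) so that converted bases score as matches, and the placement minimising
mismatches wins if it reaches an 80 % identity floor. Indels are not
modelled — the assay is one short amplicon and the dominant artefacts are
substitutions; anything below the floor is rejected as non-amplicon.

Per read, three calls follow:

* **Conversion rate** — over non-CpG reference cytosines, the fraction read
  as T among those read as T or C. Bases other than C/T (sequencing
  errors) are excluded from both numerator and denominator rather than
  being counted as unconverted. The filter is strict: a read at exactly
  95 % fails. At least 10 informative positions are required
  (`qc_insufficient` otherwise); the packaged amplicon provides 48.
* **Allele** — the base at the A/G variant site. Only major-allele (G)
  reads are retained, so that sequence variants cannot masquerade as
  methylation differences. A and ambiguous calls (including an uncovered
  variant) are filtered.
* **Methylation** — each covered CpG cytosine is methylated (C),
  unmethylated (T) or ambiguous (anything else); the per-read percentage
  uses analyzable CpGs only, with at least 20 of 25 required
  (`cpg_missing` otherwise). The per-read minimum is a package decision;
  it keeps partially covered reads from diluting profiles while tolerating
  a few ambiguous columns.

Bin edges are `[0,10], (10,20], …, (90,100]`: the first bin is closed at
10 so bin membership coincides exactly with the "presumably active ≤ 10 %"
definition. Per-sample mean methylation defaults to the pooled CpG-call
fraction (total methylated calls over total analyzable calls); for
complete 25-CpG reads this equals the mean of per-read percentages, and
`mean_method = "per_read"` switches the convention.

Paired 150-nt mates are merged before calling: each mate is placed
independently, overlaps take the consensus and conflicting columns become
ambiguous `N`. Mate handling is a package decision (the upstream
instrument software's behaviour is not re-specified here).

## Active copy number and semen classification

`binned_copy_numbers()` multiplies the absolute copy number by each bin
fraction; unrounded values conserve the total exactly and are used for all
statistics, while reported per-sample values are rounded half-up to
integers (the reporting convention for copy numbers). Rounding before
analysis is available but off by default to avoid rounding bias.

`classify_semen()` applies WHO 5th-edition lower reference limits
(volume ≥ 1.5 mL, concentration ≥ 15 × 10⁶/mL, total motility ≥ 40 %,
normal morphology ≥ 4 %). Laboratories that classify on progressive
motility can use the `"progressive_motility"` preset (≥ 32 %). The
cryptozoospermia cut-off (0.1 × 10⁶/mL) follows common andrology usage.
Subtype labels (oligo-/astheno-/teratozoospermia, OAT, cryptozoospermia)
are additive, and OAT requires all three of the defining deficits.

## Cohort statistics

* **Mann–Whitney U** is implemented with midranks. The asymptotic variant
  uses tie-corrected variance and *no* continuity correction, matching the
  convention of the clinical statistics packages such cohorts are analysed
  with; the exact variant computes the full permutation null by dynamic
  programming over doubled ranks (exact under ties, feasible far beyond
  enumeration) and is selected automatically for combined n ≤ 25. On the
  minima lists `{43,47,50,55,56}` vs `{61,65,67,69,69}` the asymptotic
  two-sided p is 0.0088 (rounds to 0.009) and the exact p is 2/252 ≈
  0.0079 — both are reported, the asymptotic one as the headline.
* **Spearman correlation** is the Pearson correlation of midranks with a
  t-approximation for p.
* **Normality checks** (Lilliefors-corrected Kolmogorov–Smirnov,
  Shapiro–Wilk) are reported for QC only; group comparisons stay
  rank-based regardless.
* **Pregnancy model**: binary logistic regression of outcome on a copy
  number variable plus concentration, motility, morphology, age and BMI
  (z-standardised by default). "Logistic" is a package decision — the
  adjustment set is what matters; separation and non-convergence are
  flagged.
* **Minimum-CN analysis** extracts the k = 5 smallest active copy numbers
  overall and within the pregnancy group, compares them by Mann–Whitney,
  and reports the pregnancy-group minimum as the empirical floor of
  "sufficient" active copies.
* α = 0.05 two-sided throughout; no multiple-testing correction is
  applied, matching the analysis style the package reproduces.

## The synthetic cohort generator

The generator is the package's ground-truth instrument; its defaults *are*
the study conditions, not tuning knobs.

* 94 donors with normal and 96 with abnormal semen parameters; absolute
  copy number truncated-normal (mean 236, SD 58, bounds 100–420 copies per
  haploid genome); age ~ TN(39, 7) on 25–57 years; BMI ~ TN(26.5, 4.5).
* Each donor has two per-copy methylation modes drawn across donors from
  Beta distributions: active mean 2 %, inactive mean 22 %. The inactive
  mean is the one place the generator departs from a naive two-state
  picture: cohorts of this kind show mean promoter methylation of 12–14 %
  *together with* ~45–50 % of reads at ≤ 10 % methylation, and those two
  facts jointly pin the inactive mode near 22 % (a 60 % inactive mode
  would force mean methylation above 30 %). The modes are parameters, so
  well-separated configurations (e.g. 2 % vs 60 %) remain available and
  are exercised in tests.
* Donor-level expected methylation is linear: NSP baseline 12.1 % at the
  mean age, +1.8 percentage points for ASP donors, +0.35 pp per year of
  age, residual SD 1.9 pp. The active-copy fraction then solves the
  mixture identity `meth = f·p_active + (1−f)·p_inactive`, and the
  expected hypomethylated-read fraction follows in closed form from the
  binomial mixture (`expected_hypomethylated_fraction()`). The slope and
  residual SD were calibrated once so that the cohort-level Spearman
  correlation between age and active copy number is ≈ −0.54 and the
  methylation SD matches the 3.2–3.6 pp seen in such cohorts.
* Semen parameters are drawn so NSP donors always pass the WHO-5
  classifier and ASP donors fail it in the parameter(s) of their subtype
  (subtype mix ≈ 49 asthenozoospermia, 37 OAT, 4 oligo-, 4 terato-,
  2 cryptozoospermia per 96).
* Pregnancy is Bernoulli under a logistic model on z-standardised active
  CN, concentration, motility, morphology and age (coefficients 1.0,
  0.25, 0.15, 0.40, −0.10; intercept 0.18), calibrated once so that
  samples with pregnancy average ≈ 24 more absolute copies and the
  pregnancy rate is ≈ 0.53. One donor's outcome is blanked by default to
  exercise the unknown-outcome path. Because pregnancy is driven through
  active CN, the induced active-CN gap (≈ 35 copies) is larger relative
  to the absolute-CN gap than in real cohorts, where part of the outcome
  signal rides on absolute CN directly — a known simplification.
* Reads: each molecule is an active or inactive copy; unmethylated
  cytosines convert to T except for a 0.5 % conversion-failure rate;
  sequencing substitutions at 0.1 % per base; 2 % of reads carry the
  minor A allele. Sidecar tables record per-read truth. Quality-score
  realism, adapters and spike-ins are out of scope.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the analysis assumes (two methylation modes, an
age-methylation trend, group offsets, Poisson droplet occupancy). It does
not emulate PCR bias between methylated and unmethylated templates,
chimeric reads, position-dependent error rates, or donor-specific
conversion efficiency — so recovery results validate the computation, not
the wet-lab assay.

## Numerical choices and problem sizes

* Saturated wells (positive fraction ≥ 1 − 10⁻¹²) are flagged at
  generation and are an error at estimation.
* Exact Mann–Whitney uses doubled midranks so all rank sums are integers;
  the two-sided p sums the symmetric tail masses.
* Reported copy numbers round half-up; statistics use unrounded values.
* Bin-fraction sums are validated to 10⁻⁶; conservation invariants
  (Σ bin CNs = absolute CN, read-count conservation across filters) are
  property-tested.
* Default test and verification sizes: 250 reads per donor for the
  end-to-end cohort run, 500 replicate wells for the ddPCR recovery
  experiment, 10,000 reads for the zero-error equivalence check, 2,000
  null replicates for the rank-test size check. These sizes give Monte
  Carlo error comfortably below the effects being checked while keeping
  a full verification run in the minutes range.

## Known limitations

* The aligner is ungapped; reads from indel-bearing molecules are rejected
  rather than rescued.
* Only the promoter amplicon is modelled; coding-region methylation and
  genome-wide context are out of scope.
* The pregnancy model ignores female-side factors entirely, as any
  sperm-only analysis must.
* Conversion failure inflates measured methylation by roughly
  `rate × (1 − methylation)` — about +0.4 pp at defaults. Group
  *differences* are essentially unaffected (the bias cancels), which is
  why calibration checks compare differences, not levels.
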