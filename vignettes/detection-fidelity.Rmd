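---
title: "Detection fidelity of low-abundance AR hotspot mutations in cell-free DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection fidelity of low-abundance AR hotspot mutations in cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ARfidelity)
```

## The scientific problem

Circulating cell-free DNA (cfDNA) from castration-resistant prostate cancer
patients carries tumour-derived fragments at very low abundance. Hotspot
mutations in the androgen receptor (AR) ligand-binding domain — L702H, W742C,
H875Y, F877L, T878A — confer resistance to AR-directed therapies, so plasma
assays that detect them at allele fractions well below 1% are clinically
attractive. At those fractions, however, a deep-sequencing variant call is
only a few dozen reads above a background produced by PCR polymerase errors,
sequencing miscalls, and alignment artifacts. The question this package
addresses is *detection fidelity*: given a candidate call at, say, 0.2%
allelic fraction, is it a true somatic variant or an amplification artifact?

The workflow has four parts, each a module of the package:

1. **Locus model** (`ar_hotspot_loci()`, `parse_codon_notation()`,
   `gc_content()`, `repeat_features()`): defines the five hotspot loci with
   their codon-change notation (e.g. `tTC>cTC` for F877L, lowercase marking
   the substituted base) and computes sequence-context features — GC content
   and homopolymer/dinucleotide repeat structure — that bear on whether an
   artifact-prone locus is explicable by local sequence context.
2. **NGS caller** (`call_variants()`): applies a conjunctive filter cascade
   to per-sample, per-locus stranded allele counts.
3. **ddPCR quantification** (`raw_allelic_fraction()`,
   `poisson_fractional_abundance()`, `copy_number()`): quantifies mutant
   abundance by droplet digital PCR, the orthogonal validation platform.
4. **Fidelity analysis** (`estimate_error_rate()`, `compare_locus_rates()`,
   `classify_concordance()`, `fidelity_report()`): estimates locus- and
   polymerase-specific amplification error rates from wild-type controls and
   classifies each sequencing call as validated or false positive by
   cross-platform concordance.

A stochastic simulator (`simulate_preamplification()`,
`simulate_ngs_counts()`, `simulate_ddpcr()`, `simulate_cohort()`) generates
synthetic data under the same error model, so every estimator can be tested
against known ground truth.

## The filter cascade

`call_variants()` consumes aggregated allele-count records (the ingestion
boundary is counts, not raw reads; alignment is out of scope). A read
contributes only if its base quality is at least 25 **and** its mapping
quality is strictly greater than 18. A non-reference allele is then called
only if **all** of the following hold:

* at least 15 alternate reads (inclusive);
* support on both strands;
* allelic fraction strictly greater than 0.15% — the fraction is computed as
  `100 * alt / ref`, mutant over *wild-type* reads, not over total reads
  (see below);
* at most 50% allelic fraction;
* the alternate count is at least twice the next-highest non-reference
  allele's count at the site;
* the variant is not provisionally called in more than 50% of cohort
  samples (a cohort-level artifact screen, applied last).

Failures are recorded per rule in the `reasons` column, so a filtered
candidate documents exactly which gates it failed.

### Why mutant over wild-type

Two conventions exist for "percent mutant": `100*alt/ref` and
`100*alt/(alt+ref)`. At these fractions they differ only in the second
decimal, but the published two-decimal values discriminate them: 33 mutant
vs 7924 wild-type reads prints as 0.42 under the ratio convention and 0.41
under the total convention. The packaged fixtures reproduce every published
cell only under `alt/ref`, which is therefore the default
(`allelic_fraction_percent(convention = "ref")`). Printed-table comparisons
use round-half-up at the table's precision (base R's `round()` rounds half
to even, which breaks several cells).

## The amplification error model

Preamplification is modelled as a branching process. In each cycle every
molecule duplicates with probability `p` (the per-cycle efficiency); each
newly synthesised copy of a wild-type template acquires the locus's
signature substitution with probability `e`, the per-base-per-duplication
error rate; parents persist and back-mutation is ignored. To first order in
`e` the expected mutant fraction after `c` cycles at efficiency 1 is

> E[mutant fraction] ≈ c · e / 2,

the accumulation law exposed as `expected_error_fraction()`. The factor 2
arises because an error in cycle `k` is propagated by only the descendants
of one strand lineage; averaging over cycles gives `c/2` effective
opportunities. Inverting the law gives the estimator used by
`estimate_error_rate()`:

> ê = 2 · f_obs / c,

with a Clopper–Pearson exact binomial interval on the observed mutant
fraction mapped through the same transform. The `model_factor` argument
makes the factor 2 explicit and overridable. Note the CI covers *counting*
uncertainty only — it does not model the extra variance from amplification
"jackpots" (an error in cycle 1 is amplified 2^(c−1)-fold), which widens the
true sampling distribution at very small input pool sizes. The simulator
reproduces that heavy tail; the estimator's interval is therefore validated
by simulation at realistic pool sizes (coverage ≥ 93% is asserted in the
test suite) rather than claimed exact.

### Polymerase profiles and calibration

`ar_polymerase_profiles()` ships three profiles with vendor-reported
per-base error rates: a standard hot-start Taq (2×10⁻⁵), a proofreading
high-fidelity enzyme (4.4×10⁻⁷), and an ultra-high-fidelity enzyme whose
vendor states only an upper bound (">100× Taq", encoded as
`reported_bound = 2e-7` with `reported_rate = NA`).
`fold_over_reported()` handles both forms: a point rate yields a fold ratio;
a bound yields a consistency verdict.

Locus-specific multipliers calibrate each profile's *effective* rate at each
hotspot to the wild-type-control artifact fractions observed on the
validation data: e.g. the high-fidelity enzyme at F877L uses
`e = 2 × 2.1e-4 / 22 ≈ 1.9e-5` (multiplier ≈ 43 over its reported base
rate), T878A uses the analogous value from its control counts, and W742C and
all ultra-high-fidelity multipliers are 0 (no artifact was ever observed).
These defaults are the *study conditions* — 909 input genome equivalents
(3 mL plasma × 303 GE/mL, one AR template per male genome equivalent since
AR is X-linked), 22 preamplification cycles, efficiency 0.95 — not tuning
knobs, and the test suite treats them as frozen.

### Implementation notes

The simulator draws pooled binomials rather than per-molecule fates:
duplications ~ Binomial(total, p), allocation of duplications to mutant
molecules ~ hypergeometric, new mutants ~ Binomial(duplicated wild-type,
e). This is exactly equivalent in distribution to the per-molecule process
(the test suite checks this against a brute-force per-lineage oracle with a
Kolmogorov–Smirnov test). Above `molecule_cap` (default 5×10⁶) molecules
the simulator switches to a flagged approximate mode: deterministic bulk
growth with Poisson-sampled new mutants, preserving the mean and the mutant
count's dominant variance component.

## ddPCR quantification

Droplet digital PCR partitions the sample into ~20,000 droplets and counts
mutant-positive and wild-type-positive droplets. The package reports:

* **Raw ratio** `100 * mut_pos / wt_pos` (`raw_allelic_fraction()`) — the
  default, because the published validation tables print exactly this
  statistic and omit total droplet counts. When a preamplified sample
  saturates the wild-type channel to zero while mutant droplets remain, the
  fraction is reported as 100 with a `saturated` attribute rather than
  infinity.
* **Poisson-corrected fractional abundance** `100·λm/(λm+λw)` with
  `λ = −ln(1 − positives/total)` (`poisson_fractional_abundance()`) —
  computed only when droplet totals are available (simulated data); with no
  total it returns `NA` flagged `NO_TOTAL` rather than guessing.

Replicate wells merge by summing droplet counts (`merge_replicates()`),
which commutes with quantification. Copy number calls
(`copy_number()`) scale the target concentration by a reference assay with
declared expected copies (1 for an X-linked reference in a male sample, 2
for an autosomal reference) and call an increase at a ratio ≥ 1.9
(inclusive).

## Cross-platform concordance

`classify_concordance()` encodes the validation logic:

* a mutant-positive no-template control invalidates the run (error);
* a polymerase whose preamplified wild-type control shows mutant droplets is
  **artifact-prone** at that locus; its patient results cannot validate a
  call;
* a sequencing call that is mutant-positive by ddPCR under at least one
  clean (non-artifact-prone) polymerase is **VALIDATED**;
* a call that is negative under every clean polymerase assayed is a
  **FALSE_POSITIVE**;
* a call in a healthy control sample is a **FALSE_POSITIVE** regardless of
  ddPCR assays — a known-negative sample cannot carry a true somatic
  variant, and this rule covers control calls that were never taken to
  ddPCR;
* anything else (e.g. only artifact-prone assays available) is
  **NOT_ASSESSED**.

On the packaged cohort fixture this reproduces the study-level conclusion:
all six F877L sequencing calls (five patients plus the male control) are
false positives of high-fidelity-polymerase amplification error, the T878A
call is a false positive, and the single W742C call is validated.

```{r concordance}
controls <- c("Male Control", "Female Control")
calls <- call_variants(cohort_ngs_counts(), control_samples = controls)
conc <- classify_concordance(calls, cohort_droplet_counts(),
                             control_samples = controls)
conc$records[, c("sample_id", "locus_id", "verdict")]
```

`compare_locus_rates()` formalises "F877L errors faster than T878A": over
the seven patient samples assayed at both loci under the high-fidelity
polymerase, the F877L artifact fraction is higher in 7/7 pairs, giving an
exact two-sided Wilcoxon signed-rank p of 2/2⁷ = 0.015625.

## What the simulator does and does not emulate

The generator reproduces the mechanisms the analysis depends on:
polymerase- and locus-specific artifact accumulation, binomial sequencing
count sampling with strand allocation and miscalls, and Poisson droplet
occupancy. It deliberately does **not** emulate:

* *heterogeneous artifact penetrance across samples*: every simulated sample
  shares a locus's artifact rate, so once artifacts clear the read-level
  filters they tend to appear in most samples and are removed by the
  cohort-prevalence (>50%) filter. In the real cohort the F877L artifact
  reached the calling threshold in only 6 of 13 samples and slipped under
  that filter — a sample-to-sample variability (input mass, fragmentation)
  the generator does not model;
* per-read FASTQ output, alignment, or linkage between loci on one
  fragment;
* droplet fluorescence amplitudes (inputs are classified counts).

## Numerical conventions

* Printed-table comparisons use round-half-up at the table's precision.
* Saturated ratios (denominator zero, numerator positive) return 100 with a
  `saturated` attribute; 0/0 fractions are errors, not NaN.
* All simulation entry points accept an `rng_seed` and restore the caller's
  RNG state; `simulate_cohort()` is byte-for-byte deterministic under a
  fixed seed.
* The packaged FASTA context windows are synthetic 41-mers carrying the
  correct reference base and codon context at the central site; they
  exercise the context-feature code and are not assertions about
  reference-genome sequence, and the locus coordinates in the packaged YAML
  are likewise illustrative.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes every quantity above from the installed
package and writes them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Deterministic values (published-table reproduction, calls, verdicts, error
rates, the signed-rank test) are seed-invariant; simulator calibration and
interval-coverage values derive all randomness from `--seed`.
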