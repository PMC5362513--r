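# ARfidelity

Tools for assessing the detection fidelity of low-allele-fraction androgen
receptor (AR) hotspot mutations in plasma-derived cell-free DNA.

## The problem

Five hotspot mutations in the AR ligand-binding domain — L702H, W742C,
H875Y, F877L, T878A — confer resistance to AR-directed prostate-cancer
therapies and are sought in plasma cell-free DNA at allele fractions well
below 1%. At that level a deep-sequencing call rests on a few dozen reads,
and PCR polymerase errors introduced during preamplification can produce an
artifact signal of exactly the same size. This package implements the full
fidelity-assessment workflow:

- **Locus model** — hotspot definitions with codon-change notation
  (`tTC>cTC`-style, lowercase marking the substituted base) and
  sequence-context features (GC content, homopolymer and dinucleotide
  repeat structure) from FASTA windows.
- **NGS caller** — a conjunctive filter cascade over per-sample, per-locus
  stranded allele counts: base quality ≥ 25 and mapping quality > 18 at the
  read level; then ≥ 15 alternate reads, both strands, allelic fraction
  > 0.15% and ≤ 50%, alternate count ≥ 2× the next non-reference allele, and
  a cohort-prevalence screen (> 50% of samples ⇒ artifact). Allelic
  fraction is `100·alt/ref` (mutant over wild-type reads).
- **ddPCR quantification** — raw mutant/wild-type droplet ratios, Poisson
  fractional abundance with exact binomial confidence intervals, replicate
  merging by summation, and reference-scaled copy-number calls (increase at
  ratio ≥ 1.9).
- **Amplification simulator** — a branching-process model of
  preamplification error (per-cycle duplication with probability
  `efficiency`, per-duplication signature error with probability `e`),
  plus sequencing-count and droplet-partitioning samplers and a whole-cohort
  generator, all seed-deterministic.
- **Fidelity analysis** — error-rate estimation `ê = 2·f_obs/cycles` from
  preamplified wild-type controls with Clopper–Pearson intervals,
  fold-over-vendor-fidelity comparison, exact paired signed-rank comparison
  of locus error rates, and cross-platform concordance classification
  (VALIDATED / FALSE_POSITIVE / NOT_ASSESSED, with artifact-prone
  locus–polymerase flagging).

The central model: after `c` preamplification cycles at efficiency 1, a
polymerase with per-base-per-duplication error rate `e` yields an expected
artifact fraction of about `c·e/2` at a susceptible site. At `c = 22`, even
a high-fidelity enzyme's observed F877L error rate (ê ≈ 3×10⁻⁵, some 70-fold
above its reported overall rate) produces artifact fractions of ~0.2% —
precisely the range of the clinical calls, which is why orthogonal ddPCR
validation against wild-type controls is required.

## Worked example

The package ships the validation cohort as plain-text fixtures: aggregated
sequencing allele counts for 11 patients and 2 healthy controls
(`cohort_ngs_counts()`) and droplet-count tables for the ddPCR validation
assays (`cohort_droplet_counts()`).

```r
library(ARfidelity)

controls <- c("Male Control", "Female Control")
calls <- call_variants(cohort_ngs_counts(), control_samples = controls)
print(calls)
#> Variant calls: 8 candidate(s), 8 CALLED
#>     sample_id locus_id alt alt_count ref_count fwd_count rev_count af_percent
#>     JHU Pt 10    F877L   C        51     20322        26        25       0.25
#>     JHU Pt 11    F877L   C        15      7334         8         7       0.20
#>      JHU Pt 3    F877L   C        26     11152        13        13       0.23
#>      JHU Pt 3    W742C   T        21      4519        11        10       0.46
#>      JHU Pt 4    T878A   G        33      7924        17        16       0.42
#>      JHU Pt 7    F877L   C        36     13386        18        18       0.27
#>      JHU Pt 8    F877L   C        25      8863        13        12       0.28
#>  Male Control    F877L   C        30     17609        15        15       0.17
#>  status reasons
#>  CALLED
#>  ... (8 rows)
```

F877L is called in 5 of 11 patients — and in a healthy male control, the
first hint of trouble. Cross-platform validation resolves it:

```r
report <- fidelity_report(
  cohort_ngs_counts(), cohort_droplet_counts(),
  polymerases = list(Phusion = ar_polymerase_profiles()$phusion,
                     SuperFi = ar_polymerase_profiles()$superfi),
  control_samples = controls)
print(report)
#> == Fidelity report ==
#>
#> Sequencing calls by locus (of 11 patients):
#>  locus_id n_patient_calls n_control_calls
#>     F877L               5               1
#>     T878A               1               0
#>     W742C               1               0
#>
#> Amplification error rates (preamplified wild-type controls):
#>  locus_id polymerase cycles mut    wt    e_hat   ci_low  ci_high
#>     F877L    Phusion     22  11 30348 3.30e-05 1.64e-05 5.90e-05
#>     F877L    SuperFi     22   0 44104 0.00e+00 0.00e+00 7.60e-06
#>     T878A    Phusion     22   2 36329 5.00e-06 6.06e-07 1.81e-05
#>     T878A    SuperFi     22   0 21511 0.00e+00 0.00e+00 1.56e-05
#>     F877L    Phusion     12   1  8539 1.95e-05 4.94e-07 1.09e-04
#>     T878A    Phusion     12   1  9617 1.73e-05 4.39e-07 9.66e-05
#>     W742C    Phusion     22   0 17573 0.00e+00 0.00e+00 1.91e-05
#>     W742C    SuperFi     22   0 37069 0.00e+00 0.00e+00 9.05e-06
#>  fold_over_reported consistent_with_reported
#>                74.9                    FALSE
#>                 0.0                     TRUE
#>                11.4                    FALSE
#>                 0.0                     TRUE
#>                44.4                    FALSE
#>                39.4                    FALSE
#>                 0.0                     TRUE
#>                 0.0                     TRUE
#>
#> Cross-platform concordance
#> Artifact-prone loci: F877L under Phusion; T878A under Phusion
#>     sample_id locus_id alt ngs_af_percent n_ddpcr_assays n_clean_assays
#>     JHU Pt 10    F877L   C      0.2509596              2              1
#>     JHU Pt 11    F877L   C      0.2045269              2              1
#>      JHU Pt 3    F877L   C      0.2331420              2              1
#>      JHU Pt 3    W742C   T      0.4647046              2              2
#>      JHU Pt 4    T878A   G      0.4164563              2              1
#>      JHU Pt 7    F877L   C      0.2689377              2              1
#>      JHU Pt 8    F877L   C      0.2820715              2              1
#>  Male Control    F877L   C      0.1703674              0              0
#>         verdict
#>  FALSE_POSITIVE
#>  FALSE_POSITIVE
#>  FALSE_POSITIVE
#>       VALIDATED
#>  FALSE_POSITIVE
#>  FALSE_POSITIVE
#>  FALSE_POSITIVE
#>  FALSE_POSITIVE
```

Every F877L call — and the T878A call — is an amplification artifact of the
high-fidelity polymerase; only the W742C call survives validation. The
paired comparison confirms F877L errors accumulate faster than T878A under
the same enzyme (higher in 7/7 shared samples, exact signed-rank
p = 0.015625).

Simulated data with known ground truth come from the same error model:

```r
cohort <- simulate_cohort(
  n_patients = 11,
  true_mutations = list(`Pt 3` = list(locus_id = "W742C", af = 0.0046)),
  rng_seed = 42)
calls <- call_variants(cohort$ngs_counts,
                       control_samples = c("Male Control", "Female Control"))
```

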