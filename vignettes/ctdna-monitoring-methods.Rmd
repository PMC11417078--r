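---
title: "Methods: ctDNA therapy monitoring from duplicate cfDNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA therapy monitoring from duplicate cfDNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnamon)
```

## The monitoring problem

Patients with locally advanced rectal cancer receive neoadjuvant
radio(chemo)therapy before surgery. A blood draw contains cell-free DNA
(cfDNA) from normal tissue turnover; in cancer patients a small fraction of
it is circulating tumor DNA (ctDNA), recognizable by somatic mutations that
the patient's germline does not carry. Comparing plasma drawn before the
first radiotherapy fraction (t0) and right after the final fraction (t1)
asks whether the tumor-derived signal responded to therapy.

Three contaminant classes masquerade as tumor signal in plasma:

* **germline variants** — heterozygous in every cell, VAF near 0.5 in both
  plasma and leukocytes;
* **clonal hematopoiesis (CHIP)** — age-related somatic mutations of blood
  cell clones, present at matching low VAF in plasma *and* the leukocyte
  (buffycoat) compartment, often recurrent at hotspot positions across
  individuals;
* **recurrent technical artifacts** — position-specific sequencing or PCR
  errors that reappear library after library.

The pipeline removes them in two stages. Stage one is patient-level:
a candidate must be supported in **both** duplicate cfDNA libraries of a
sample and must be absent as germline from the patient's matched buffycoat.
Stage two is cohort-level and is the package's core statistic: the
candidate's VAF must be **strictly greater than `multiplier` times the
`percentile`th-percentile VAF of all patients' buffycoat libraries at that
genomic position** (defaults: 2 x the 95th percentile). A position that is
noisy or CHIP-prone in many unrelated leukocyte samples earns a high
background threshold; a clean position earns a threshold near zero.

## The quantile filter in detail

For a position with buffycoat VAFs $v_{(1)} \le \dots \le v_{(n)}$ over the
$n$ buffycoat libraries (libraries with zero depth at the position are
excluded and logged), the percentile is computed by sorted linear
interpolation at rank $h = p/100\,(n-1)$ (0-based):

$$q_p = v_{(\lfloor h\rfloor + 1)} + (h - \lfloor h\rfloor)\,
  \bigl(v_{(\lfloor h\rfloor + 2)} - v_{(\lfloor h\rfloor + 1)}\bigr).$$

This is the dominant percentile convention (base R's type 7), and the test
suite pins it against an independent recomputation, boundary cases
included. The verdict uses the **strict** inequality
$\mathrm{VAF} > m\,q_p$: a variant sitting exactly on the threshold fails.
The evaluated VAF is the larger of the two pooled timepoint VAFs — a
mutation real at either timepoint is real — and per-timepoint verdicts are
recorded for audit. The patient's own buffycoat is part of the panel: the
background definition is "all buffycoat libraries", taken literally.

Two open choices were resolved as follows. Each timepoint's verdict is
also emitted, but the maximum decides `passed`, because a variant that
disappears at t1 (therapy response) must not be discarded by its own
decline. And the panel is built from VAFs, not raw counts, because the
background being thresholded is a frequency, not a depth-dependent count.

## Candidate detection thresholds

Detection requires `min_alt_reads = 3` alt reads in *each* duplicate at
`min_depth = 100`. At the default 10,000x per-library depth, a variant at
the biological detection limit of the smallest plasma sample in the
bundled cohort (VAF about 5e-4, i.e. 5 expected alt reads per library) is
seen with at least 3 reads in one library with probability ~0.875, and the
duplicate-concordance requirement squares the *error* suppression, not the
signal: for true variants at VAF >= 0.005 joint detection probability
exceeds 99.9% (binomial oracle in the tests). Requiring support in both
duplicates is the natural first validation stage of a duplicate-sampling
design.

A buffycoat site is germline when its VAF reaches 0.25 with at least 10
alt reads — catching heterozygous (~0.5) and homozygous (~1.0) sites with
room for allelic imbalance, while deliberately leaving low-VAF CHIP to the
cohort quantile filter; that division of labor (germline subtraction
per-patient, CHIP/artifact suppression cohort-wide) mirrors how the two
compartments carry information. Buffycoat sites below `min_depth` are
unevaluable: they are excluded from candidacy and logged rather than
trusted in either direction.

## Genome equivalents and the biological detection limit

A plasma sample with mass $M$ ng contains
$\lfloor 1000\,M / 6.51 \rfloor$ diploid genome copies (6.51 pg per
average female diploid genome). Truncation, not rounding, is used: a
partial genome is not a detectable copy, and truncation is the only rule
consistent with the copy numbers the bundled cohort table reproduces
(5.25 ng gives 806.45, reported as 806 diploid / 1612 haploid). A relative
epsilon (1e-9) is added before the floor so that exactly divisible masses
(3.255 ng = 500 genomes) are not lost to binary floating-point
representation. The biological limit of detection is one haploid tumor
genome among all haploid genome equivalents assayed,
$100 / (2 \times \text{diploid copies})$ percent, reported half-up to two
decimals (R's `round()` is banker's rounding, so an explicit half-up
helper is used for all reported roundings, including nearest-ng medians).

## Response classification

Each validated variant's change between t0 and t1 is `down`, `up`, or
`stable`; `stable` means the difference is within `stable_rel_tol`
(default 10%) of the larger VAF, quantifying "nearly constant" — the
tolerance is a user parameter because the underlying notion is a judgment
call. A patient is `decrease` (only downs), `increase` (only ups),
`mixed` (both), or `ctdna_negative` (no validated variants). Patients
whose variants are all stable are grouped with `increase` and flagged
`stable_only`: ctDNA that persists through therapy is the non-clearing
signal, the clinically relevant opposite of a decrease. Responder status
dichotomizes the Dworak tumor regression grade at TRG >= 3; the bundled
cohort contains no TRG 2, so the rule extends the printed dichotomy
conservatively. Association between ctDNA status and response uses the
two-tailed Fisher's exact test, implemented by full hypergeometric
enumeration with the probability-mass rule (all tables with the observed
margins whose probability does not exceed the observed table's, with the
conventional 1e-7 relative tie tolerance); tests pin it to a brute-force
`choose()` enumeration to 1e-12 and to `stats::fisher.test`.

## What the synthetic cohort emulates

`sim_config()` defaults are the study conditions of the bundled cohort:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 17 | cohort size |
| `protocol_mix` | 5 SCRT : 6 RAPIDO : 6 fRCT | exact largest-remainder allocation |
| `responder_fraction` | 9/17 | Dworak TRG 3-4 |
| `ctdna_positive_fraction` | 12/17 | patients with tumor variants |
| `vaf_range_t0` | [0.001, 0.084] | log-uniform pre-therapy tumor VAFs |
| `response_effect` | 0.2 | responders' t1 VAF multiplier (5-fold drop) |
| `nonresponder_effect_range` | [0.5, 2] | per-variant t1 multiplier, non-responders |
| `n_tumor_variants_range` | 1–4 | per ctDNA-positive patient |
| `n_chip_variants_per_patient` | 2 | CHIP hotspot positions |
| `chip_vaf_range` | [0.005, 0.05] | typical CHIP clone sizes |
| `germline_het_count` | 10 | heterozygous sites per patient |
| `depth_mean` | 10,000 | Poisson per-library depth (ultradeep) |
| `error_rate_mean` / `max` | 5e-4 / 5e-3 | Gamma per-site background error |

Counts are binomial: at every site of every library, alt reads are
$\mathrm{Bin}(\text{depth}, \text{expected VAF} + e_s)$ with a per-site
error rate $e_s$ drawn once from a right-skewed Gamma and shared by all
libraries at that site — position-specific recurrence is exactly the
artifact structure the quantile filter targets. Duplicate libraries are
independent draws from the same expectation, which makes pooling an
unbiased VAF estimator (property-tested).

CHIP is modelled as cohort-level recurrent hotspots: every patient's
buffycoat carries a VAF drawn from `chip_vaf_range` at each hotspot, with
the matching plasma at the same expected VAF. This is a deliberate
simplification — real CHIP is a mixture of private clones and recurrent
hotspots (e.g. *DNMT3A*, *TET2*), and a *private* CHIP clone in a single
patient barely moves the cohort percentile, so the quantile filter alone
would keep it. The generator models the hotspot component because that is
the class the cohort filter is designed for; the limitation is stated
here precisely because passing tests on this generator say nothing about
private-clone CHIP, which would require the matched-buffycoat VAF itself
as an additional per-patient filter.

The site universe is desk-scale: 127 genes x 3 assayable sites rather
than every base of an 800 kb target (the `panel_design()` object records
the real panel's parameters). Other things the generator does not
emulate: read-level effects (UMI structure, strand bias, base quality),
depth variation beyond Poisson, indel representation beyond an anchored
ref/alt pair, and correlated plasma masses between timepoints.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise full 17-patient
cohorts (about 32,000 count rows each) over 30–50 seeds, a size chosen so
each Monte-Carlo property aggregates several hundred tumor variants and
thousands of contaminant variants while a complete run stays in the tens
of seconds. Tumor recovery is assessed in the regime the filter promises:
variants whose expected VAF exceeds twice the observed background
percentile plus three binomial standard errors at pooled depth. Below
that band a variant's fate is a coin toss by construction, and the
recovery criterion would measure noise.

Degenerate inputs are defined rather than left to chance: VAF at zero
depth is an error (the caller must exclude the site, not divide by zero);
an empty validated set is a valid `ctdna_negative` classification, not an
error; an empty cohort is a configuration error; a position absent from
every buffycoat library is an error naming the position, while a position
missing from *some* libraries simply shrinks that position's VAF list
(count logged). Percentile ties and the exact-threshold boundary resolve
by the strict inequality. Protocol allocation is deterministic
(largest remainder) so a 17-patient cohort reproduces the 5/6/6 mix
exactly; all other labels are Bernoulli draws.

## Known limitations

* The filter's behaviour on private (non-recurrent) CHIP clones is
  untested by design; see above.
* The biological detection limit ignores fragment-size selection and
  extraction efficiency; it is a genome-counting bound, not an assay
  guarantee.
* The association test is a single pre-specified 2x2 Fisher test;
  no survival or multivariable analysis is in scope.
* Gene-level frequencies divide by mutated patients, which is the
  convention that matches the reporting this package reproduces, but it
  inflates frequencies in cohorts with low detection rates; both counts
  are emitted so either denominator can be formed.
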