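---
title: "False conclusion rates in STR kinship testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{False conclusion rates in STR kinship testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinerr)
```

## The problem

Relationship testing decides whether two or three individuals stand in an
alleged family relationship from their genotypes at a panel of autosomal
STR markers. The decision statistic is a likelihood ratio (LR), and many
laboratories convert it to a categorical conclusion with a threshold
(commonly LR = 100 or 1,000). Any threshold on a continuous statistic
produces errors: truly related individuals whose LR falls short (false
negatives) and unrelated individuals whose LR exceeds it (false
positives). `kinerr` estimates those error rates per relationship, panel
and policy, and converts them into expected numbers of wrongly interpreted
cases under a global caseload model.

## Likelihood model

All computations assume Hardy–Weinberg equilibrium within loci and
linkage equilibrium between loci, with genotype probabilities
$P(aa) = p_a^2$ and $P(ab) = 2 p_a p_b$ from a population allele frequency
table.

**Pairwise relationships** are summarized by the probabilities
$(k_0, k_1, k_2)$ that the pair shares 0, 1 or 2 alleles identical by
descent at a locus. The per-locus LR of genotypes $G_1, G_2$ is

$$\mathrm{LR} = k_0 + k_1 \frac{P(G_2 \mid G_1, \text{1 IBD})}{P(G_2)}
             + k_2 \frac{[G_1 = G_2]}{P(G_2)},$$

where the one-IBD term conditions on which of $G_1$'s alleles is the
shared one (probability $1/2$ each for a heterozygote) and draws the
remaining allele of $G_2$ from the population. Configurations with no
Mendelian-compatible sharing contribute zero, so a wholly mismatched pair
has LR $= k_0$ — in particular 0 for parent–child, which makes a single
incompatible locus an exclusion.

**Trios** use the paternity index, conditioning on the mother:
$\mathrm{PI} = P(G_c \mid G_m, \text{AF is father}) /
P(G_c \mid G_m, \text{random man})$, enumerated over the
maternal/paternal assignments of the child's alleles. Two boundary rules
are deliberate design choices:

* *Maternal incompatibility* (the mother cannot have produced the child at
  a locus) falls back to the motherless duo LR of (child, alleged father)
  at that locus, rather than returning a spurious 0 from the untested
  maternal link.
* Conditioning on the mother is *not* the same as ignoring her: with
  mother $aa$ and child $ab$ the paternal allele is known to be $b$ and
  $\mathrm{PI} = t(\mathrm{AF}, b)/p_b$ (where $t$ is the Mendelian
  transmission probability), while the motherless duo LR is
  $[t(\mathrm{AF},a)p_b + t(\mathrm{AF},b)p_a]/(2 p_a p_b)$. The test
  suite therefore validates the trio PI against a direct
  transmission-enumeration oracle over all genotype triples, not against
  the duo formula.

Per-locus LRs are multiplied across the panel in log10 space; the combined
LR is 0 exactly when a locus LR is 0 and is reported both raw and as
log10.

### Mutation handling

The per-meiosis STR mutation rate is of order $10^{-3}$, so mutation
handling matters mainly through exclusions. Two LR modes are provided:

* `strict_zero` (default): a Mendelian incompatibility gives locus LR 0.
* `rate_floor`: zero transmission probabilities are replaced by a single
  aggregate rate $\mu$ (default 0.002), not a length-weighted stepwise
  matrix — enough to keep one-locus mismatches from annihilating an
  otherwise overwhelming LR, while remaining simple to reason about.

Simulation-side mutation is **off by default**: the gene-dropping child
receives exact parental alleles. An optional stepwise model mutates each
transmitted allele with probability $\mu$, one step up or down the
marker's numeric allele ladder with equal probability, reflecting at the
ends; it exists for sensitivity analysis, and requires allele labels that
parse as repeat counts.

Co-ancestry (theta) correction and genotyping error (dropout, silent
alleles) are out of scope; LRs assume independent HWE draws.

## Simulation design

Each scenario is simulated by Mendelian gene dropping: founders drawn
under HWE, children receiving one allele per parent with probability 1/2.
Hidden individuals (the duo's untyped co-parent, the siblings' parents,
the cousins' grandparent couple and spouses) are simulated and discarded.
The unrelated arm replaces the tested link with independent founders; for
the trio, the mother–child pair remains real and only the alleged father
is unrelated, matching casework where maternity is not in dispute.

The estimator streams replicates in fixed chunks of 100,000, so memory use
does not grow with the replicate count, and the related and unrelated arms
run on independently seeded RNG streams. Binomial standard errors are
reported with every rate so that scaled-down runs remain interpretable.

For small panels an exact oracle (`exact_rates_bruteforce()`) enumerates
every joint genotype configuration with its probability under the
IBD-state mixture and under unrelatedness (state spaces up to $10^7$), and
the Monte-Carlo estimator is required, in the test suite, to agree with it
within four binomial standard errors.

## Decision policies

* **binary**: inclusion at $\mathrm{LR} \ge t_\mathrm{incl}$, exclusion
  otherwise. The false negative rate counts every related case not called
  inclusion.
* **ternary**: exclusion only at $\mathrm{LR} \le t_\mathrm{excl}$;
  between the thresholds the case is inconclusive. The false negative rate
  counts only related cases called exclusion.

The inconclusive interval is *open* ($t_\mathrm{excl} < \mathrm{LR} <
t_\mathrm{incl}$, e.g. $0.01 < \mathrm{LR} < 100$), so boundary values are
decisions — ties on floating-point equality classify as
inclusion/exclusion, never as inconclusive. The binary/ternary pair also
covers both readings of "false negative" (inconclusive counted as
negative, or not) without further switches.

LR distributions are reported as decade-binned log10 histograms with
open-ended tails and a dedicated LR = 0 bin, whose counts always sum to
the replicate count.

## The synthetic population model

No population allele frequency table ships with the package; frequencies
are an input (`read_frequencies()`, CSV `marker,allele,frequency`, with
per-marker sums in [0.99, 1.01] renormalized to absorb published-table
rounding). For self-contained runs, `generate_frequency_set()` draws, per
marker, an allele count uniform on [5, 15] and frequencies from a
symmetric Dirichlet with concentration 1. For a symmetric Dirichlet with
$A$ alleles and concentration $\alpha$, the expected homozygosity is
$(\alpha + 1)/(A\alpha + 1)$, so these defaults give expected
heterozygosities between 0.67 ($A = 5$) and 0.875 ($A = 15$) — the band
observed for forensic STR panels. Allele labels are consecutive integer
repeat counts so the stepwise mutation ladder is well defined.

What the generator does **not** emulate: the empirical frequency spectra
of real populations (real STR marker frequencies are not
Dirichlet-symmetric), population substructure and co-ancestry, intermediate
alleles, and between-marker heterozygosity correlations within a kit.
Consequently, tests on synthetic frequencies establish *qualitative*
properties — the ordering of error rates across relationships, the
threshold trade-off, the gain from 6 extra markers, the effect of an
inconclusive range — not the error-rate magnitudes a specific population
table would give. Magnitudes are reproducible only given the same
frequency input; this is why the published per-rate values enter the
caseload projection as printed inputs rather than as simulation targets.

## The caseload projection

The projection multiplies, per (case type, arm, threshold) cell:

$$\text{cases of type} \times \text{arm fraction} \times
  \text{lab fraction} \times \text{false rate},$$

with the related arm using false negative rates and the unrelated arm
false positive rates. Three modeling conventions are fixed by the
published arithmetic this reproduces:

* expected counts round **half away from zero** to the nearest integer
  (9.555 → 10, 1.47 → 1, 7.7 → 8, 8.96 → 9), which `round()`'s
  half-to-even rule would not reproduce;
* the related/unrelated split (e.g. 72%/28%) is applied uniformly across
  case types — a simplification, since true exclusion fractions surely
  differ by case type;
* laboratories without a threshold for a case type (e.g. the 80% of
  full-sibling labs that report only the LR) contribute no decisions and
  no rows.

The grand total is reported both as the rounded sum of unrounded cell
values and as the sum of rounded cells (the two differ by 1 for the
15-marker preset: 62,408 vs 62,409; both exceed 60,000).

```{r table1}
project(caseload_preset("table1_identifiler"))
```

`project_from_simulation()` accepts rate tables from `estimate_rates()` or
`exact_rates_bruteforce()` instead of typed-in rates, wiring the two
stages together.

## Numerical choices and problem sizes

* Combined LRs accumulate as sums of log10 per-locus LRs; products of
  hundreds of loci can underflow doubles, log10 sums cannot.
* Frequency CSV round-trips are lossless to 1e-12 (17 significant digits
  on write); generated sets are pure functions of their seed and leave the
  caller's RNG state untouched.
* The enumeration oracle caps its joint state space at $10^7$
  configurations and directs larger problems to Monte-Carlo.
* The test suite runs Monte-Carlo checks at $10^5$ replicates per arm
  (with the per-locus unit-mean LR invariant at $10^6$), sized so the full
  suite completes in about a minute while keeping four-standard-error
  bands tight enough to detect real defects; the acceptance script uses
  $10^5$ replicates per arm. Distribution-level claims (e.g. trio false
  rates, which are below $10^{-4}$ on typical panels) are not resolvable
  at these sizes and are asserted non-strictly where relevant.

## Known limitations

Unlinked autosomal loci only (no X/Y markers, no linked-marker support);
no theta correction; no genotyping-error or dropout model; wrongly-stated
relationship scenarios (an uncle claimed as father, half siblings claimed
as full) have no simulation presets, though any simulated truth can be
evaluated under any pairwise hypothesis via `simulate_lr_sample()`'s
building blocks; and the caseload model propagates no uncertainty — it is
a point projection, faithful to the published arithmetic it mirrors.
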