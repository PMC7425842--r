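# kinerr

**How often do DNA familial relationship tests reach the wrong
conclusion?** `kinerr` is an R package for forensic geneticists, statistical
reviewers and policy analysts who want to quantify the false negative,
false positive and inconclusive rates of likelihood-ratio based kinship
testing on autosomal STR panels — and to project what those rates imply at
the scale of the global relationship-testing caseload.

## The statistics at the core

A kinship case is evaluated with a likelihood ratio comparing two
hypotheses about the observed genotypes *G*:

LR = P(G | alleged relationship) / P(G | unrelated)

For a **pairwise** relationship summarized by IBD-sharing probabilities
(k₀, k₁, k₂) — parent–child (0, 1, 0), full siblings (¼, ½, ¼), half
siblings (½, ½, 0), first cousins (¾, ¼, 0) — the per-locus LR is

LR = k₀ + k₁ · P(G₂ | G₁, 1 IBD) / P(G₂) + k₂ · [G₁ = G₂] / P(G₂)

with Hardy–Weinberg genotype probabilities P(aa) = p², P(ab) = 2pq. For a
**standard trio** (mother, child, alleged father) the per-locus LR is the
paternity index

PI = P(G_child | G_mother, AF is the father) / P(G_child | G_mother, a
random man is the father),

enumerated over the maternal/paternal assignments of the child's alleles.
Loci are unlinked, so the combined LR is the product over the panel
(accumulated in log₁₀ space). A laboratory's decision policy thresholds the
combined LR: *binary* (inclusion at LR ≥ t, exclusion otherwise) or
*ternary* with an inconclusive range such as 0.01 < LR < 100.

The package simulates each scenario by Mendelian gene dropping from
founders drawn under Hardy–Weinberg equilibrium, estimates the error rates
by Monte-Carlo (with an exact enumeration oracle for small panels), and
multiplies them through a caseload model: total cases × related/unrelated
split × case-type mix × laboratory threshold mix × false rate.

## Worked example

```r
library(kinerr)

# 1. a synthetic population model for a 15-marker panel
fs <- generate_frequency_set(builtin_panel("identifiler15"), seed = 7)
fs
#> Frequency set 'synthetic' on panel 'identifiler15' (15 markers)
#>   alleles/marker: 5-15, mean expected heterozygosity 0.832

# 2. error rates for full-sibling testing under a ternary policy
est <- estimate_rates("full_sib", fs, decision_policy("ternary", 100, 0.01),
                      n_sims = 1e5, seed = 1)
est
#> full_sib on identifiler15, ternary policy (t_incl = 100, t_excl = 0.01), n = 100000 per arm
#>   FN 0.00078 (SE 8.8e-05)   FP 0.00053 (SE 7.3e-05)
#>   inconclusive: related 0.08951, unrelated 0.1146

# 3. the published global caseload projection for 15-marker kits
project(caseload_preset("table1_identifiler"))
```

The projection prints one row per (case type, arm, LR threshold): for
example, 7.5 million trio cases × 72% truly related × 65% of labs at LR 100
× a 0.058% false negative rate → **2,036** biological fathers expected to
be falsely excluded; summing all ten rows gives

```
#> Grand total: 62408 (sum of unrounded values 62408.485; rounded rows sum to 62409)
```

i.e. more than 60,000 cases wrongly interpreted. In `est` above, FN is the
fraction of true sibling pairs decided *exclusion*, FP the fraction of
unrelated pairs decided *inclusion*, and the inconclusive fractions show
how much of each arm falls in 0.01 < LR < 100. For half siblings and first
cousins those inconclusive fractions reach ~70% and ~99%: current STR
panels have little power for distant relationships.

A thin command-line wrapper over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kinerr.R", package = "kinerr"))')
Rscript $CLI make-freqs --panel identifiler15 --seed 1 --out freqs.csv
Rscript $CLI rates --freqs freqs.csv --relationships trio,parent_child \
        --t-incl 100,1000 --n-sims 100000 --seed 1 --out rates_out
Rscript $CLI project --preset table1_identifiler --out table1.csv
```

## Scope

The package models autosomal STR panels with unlinked loci and
theta = 0 (no co-ancestry correction), treats mutation either strictly
(exclusion annihilates the LR) or through an aggregate rate floor, and does
not model genotyping error, silent alleles, X/Y markers, or
posterior-probability reporting. See the methods vignette
(`vignettes/kinship-error-rates.Rmd`) for the model, the synthetic
frequency generator, and the numerical choices.
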