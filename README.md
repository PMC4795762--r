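# finfusion

Phenotypic assortment tests and fission-fusion group simulation for
behavioural ecology.

## The problem

In fission-fusion societies such as wild guppy (*Poecilia reticulata*)
shoals, males move frequently between mixed-sex groups. Because male
attractiveness to females depends on coloration and body size *relative
to nearby rivals*, males might be expected to settle where their rivals
are less attractive — which would leave a population signature:
non-random phenotypic assortment of males within groups. `finfusion` is
for researchers who have grouped ("gambit-of-the-group") samples of
male phenotypes, or who want to model the group dynamics that could
produce them.

## What it computes

**Assortment test.** For groups `g` with `n_g` males and trait values
`x_ig`, the statistic is the pooled within-group ANOVA mean square

```
s²_W = Σ_g Σ_i (x_ig − x̄_g)² / Σ_g (n_g − 1),
```

compared against a Monte Carlo null that conserves the number of groups
and every group's size while shuffling the pooled males uniformly at
random (default 10,000 iterations). Low `s²_W` relative to the null
means groupmates are more similar than chance (positive assortment);
the decision is two-tailed at 2.5% per tail.

**Fission-fusion simulator.** An agent-based model: males drawn from a
bivariate normal over (colour, length) move between groups with
probability `exp(a)/(1+exp(a))` where

```
a = α + β_C (c̄_g − c_i) + β_S (s̄_g − s_i) + β_R R_g,
```

so duller, smaller males in male-biased groups move most. The
within-group variance of both traits is tracked over time to ask
whether such rules generate stable assortment (they do not — movers
must land somewhere, and relative attractiveness is local).

**Sensitivity sweeps** vary the male count or one movement rate at a
time, with five replicate runs per value and replicate-averaged OLS
trends of variance on time.

**Choice statistics.** Dichotomous-choice association-time analysis:
arcsine-square-root transform, one-sample and paired t-tests against
the 0.50 chance value (π/4 transformed), treatment classification of
stimulus pairs (1 mm / 0.01 similarity thresholds), and linear models
of choice strength on phenotype covariates with type-II F-tests.

**Synthetic data** generators emulate the field structure (67 shoals,
2–6 males and 1–15 females each, field-scale trait moments) and can
inject assortment of known strength, so power and type-I error of the
whole pipeline are measurable.

## Worked example

```r
library(finfusion)

st  <- sample_shoal_structure(67, seed = 1)
ph  <- sample_male_phenotypes(sum(st$n_males),
                              field_phenotype_distribution(), seed = 2)
obs <- assign_males_to_shoals(ph, st, assortment = 0, seed = 3)
assortment_randomization(obs, "length", n_iterations = 10000, seed = 4)
#> Membership-conserving randomization test of phenotypic assortment
#>   trait: length
#>   observed within-group variance: 2.13054
#>   null: 10000 iterations, mean 1.9943 [1.78741, 2.17936]
#>   percentile rank: 0.9179  empirical p: 0.1642
#>   decision: random
```

The observed within-group variance (2.13 mm²) sits inside the central
95% of the membership-conserving null, so this (deliberately random)
population is correctly called unassorted. Injecting full positive
assortment into the same males flips the call:

```r
sorted <- assign_males_to_shoals(ph, st, assortment = 1,
                                 trait = "length", seed = 3)
assortment_randomization(sorted, "length", n_iterations = 10000, seed = 4)
#>   observed within-group variance: 0.00253328
#>   percentile rank: 0.0001  empirical p: 0.0002
#>   decision: positive_assortment
```

The simulator, at its strong phenotype-dependent defaults:

```r
sim <- run_simulation(population_config(seed = 1))
sim
#> Fission-fusion simulation: 170 males, 67 groups, 100 steps
#>   movement: alpha=0 beta_c=20 beta_s=20 beta_r=1
#>   moves: 8242 of 17000 selections (48.5%)
#>   final within-group variance: colour 7.153, length 2.289
summary(sim)
#>    trait         slope           se n_steps_used
#> 1 colour  0.0025986354 0.0020068311          100
#> 2 length -0.0006140936 0.0006495674          100
```

Despite strong movement rules, neither trait's within-group variance
trends with time (slopes indistinguishable from zero) — movement alone
does not build assortment.

A thin command-line wrapper over the same functions ships in
`inst/cli/finfusion.R` (subcommands `synth`, `assort`, `simulate`,
`sweep`, `prefs`; every run writes a `.prov.json` provenance record
beside its output).

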