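# markresight

Detecting competitive effects on animal behaviour from open-plot
mark–resight experiments.

When a range-expanding competitor (such as a habitat-modifying sea urchin)
moves into the habitat of a resident grazer (such as a commercially fished
abalone), the first detectable impacts are often behavioural: residents
shift from exposed to sheltered microhabitat, move further, and become
harder to resight — long before any effect on growth or survival is
measurable. `markresight` implements a complete analysis pipeline for the
field design that detects these effects: tagged animals in replicate
3 × 3 m unfenced plots, surveyed repeatedly across density-manipulation
phases (before / with added competitors / after their removal), with each
animal scored on every visit as **E**xposed, **S**heltered, **O**utside
the plot, or **L**ost, and positioned by triangulation from the two
nearest star pickets.

## The models

**Behavioural transitions.** State sequences are modelled as a first-order
Markov chain fitted as a multinomial log-linear model: the probability of
state *j* at visit *t*+1 given state *i* at *t* is

  p_ij = exp(β_ij) / Σ_k exp(β_ik),

with one reference state per row fixed at β = 0. Chain order (zero vs
first), time homogeneity, plot effects and treatment effects on the whole
transition matrix are tested with χ² likelihood-ratio tests; individual
transitions (e.g. E→S) are compared between treatments with two-sample
proportion tests.

**Movement.** Step lengths between consecutive positions are fitted by
maximum likelihood to Pareto, exponential, and doubly truncated variants
on the detectable-movement window [0.1 m, 4 m]; the truncated Pareto
density is

  f(x) = α a^α x^−(α+1) / (1 − (a/b)^α),  a ≤ x ≤ b.

AIC/BIC rank the candidate families (a heavy-tailed winner is the
Lévy-flight signature), and likelihood-ratio tests compare the shape α
between treatments. Animals are also dichotomised as sedentary
(≤ 0.4 m/week) or mobile (> 0.4 m/week) and the mobile fraction is
modelled over repeated occasions with a binary GEE (unstructured working
correlation, robust Wald tests), with Williams-corrected G-tests for
planned per-occasion contrasts.

**Resightability.** The percentage of the tagged cohort relocated per plot
and occasion is analysed with two-way (treatment × time) repeated-measures
ANOVA using the Greenhouse–Geisser correction, and Šidák-adjusted planned
comparisons on phase-pooled means.

A synthetic-data generator reproduces the whole experimental structure
(replicate plots, phases, per-group transition matrices, truncated-Pareto
steps, per-state detection probabilities, picket triangulation), so every
stage is testable without field data.

## Worked example

```r
library(markresight)

cfg <- analysis_config(scenario = "exp2", seed = 1)  # 9-week design,
rep <- run_analysis(cfg)                             # 3 treatments x 3 plots
rep$flags
#>        pEE_down_urchin         pES_up_urchin      mobile_up_urchin
#>                   TRUE                  TRUE                  TRUE
#>      mobile_up_abalone   resight_down_urchin  resight_down_abalone
#>                   TRUE                  TRUE                 FALSE

rep$stages$transitions$order_test
#> Likelihood-ratio chi-square test
#>   H0: order-0 chain
#>   H1: order-1 chain
#>   X2 = 155.6, df = 9, p = 6.042e-29

sapply(rep$stages$stepdist$fits, function(f) f$truncated_pareto$estimate)
#>    0U25A   18U25A    0U50A
#> 1.748310 0.695293 0.761053
```

Behaviour is strongly first-order (the order test rejects the
independence model), and the fitted truncated-Pareto shape drops from
α ≈ 1.7 in control plots to α ≈ 0.7 under added urchins or abalone — a
much heavier-tailed step distribution, i.e. more long relocation moves.
The flags summarise the directional asymmetry: urchin addition shifts
residents out of the exposed state, raises the mobile fraction and
depresses resightability; extra conspecifics affect movement but not
resightability.

A command-line front end with `generate` and `analyze` subcommands is
installed at `inst/cli/markresight.R`.

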