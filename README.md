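# feedlife

Lifetime energy-budget simulation of resource acquisition and allocation
in dairy cows, and global sensitivity analysis of feed efficiency.

## The scientific problem

Feed efficiency (FE) — the fraction of the energy an animal acquires
from feed that ends up in product — is usually treated as a single
phenotype. Physiologically it is the product of two distinct,
genetically variable processes: **acquisition** (dry-matter intake and
its digestion into metabolizable energy, ME) and **allocation** (the
partitioning of that ME among growth, gestation, lactation and somatic
functions). Because high production also feeds back on body reserves,
fertility and survival, the efficiency ranking of genotypes can differ
between a single lactation and a whole lifetime. feedlife is a
daily-step, individual-based simulator built to study exactly that
dissociation. It is aimed at quantitative geneticists and livestock
systems modellers who want an animal "building block" in which
acquisition and allocation can be varied independently.

## The model in brief

A female is simulated from birth to death, culling or a 20-year
horizon. Each day:

* **Acquisition**: intake is a basal maturation curve
  `AcqB = AcqB_GEN (1 − 0.8 e^(−k t))` plus, while lactating, a
  lactation-induced component `AcqL = Lac · AcqL_Max · AcqL_Dyn(DIM)`;
  intake times the resource's gross energy density and a
  metabolizability fraction gives the day's ME.
* **Allocation**: a conserved unit of "priority" is distributed over
  four compartments (growth `AllocG`, survival `AllocS`, gestation
  `AllocPf`, lactation `AllocPc`) whose levels are the day's partition
  coefficients. Priority flows — e.g.
  `f_G2S = AllocG·G2S_GEN + 0.01·AllocPf`,
  `f_Pc2S = AllocPc·Lac·(Pc2S_GEN + 0.06·AllocPf·Gest)` — are
  integrated by fixed-step RK4; parturition and drying-off apply
  discrete priority shifts. The coefficients sum to 1 at every step by
  construction.
* **Utilization**: partitioned energies become structural mass, gravid
  uterus, milk, and body reserves (deposited from somatic surplus,
  mobilized under deficit); maintenance scales with metabolic body
  mass.
* **Physiology**: conception is a seeded Bernoulli draw per
  insemination with probability logistic in milk yield, body condition
  and energy balance; gestation lasts 282 d; culling strikes at 200
  days open from parity 2; 15 consecutive uncovered-maintenance days
  kill.

Four genetic-scaling parameters represent a genotype: `G2S_GEN`,
`Pc2S_GEN` (allocation trajectory rates) and `AcqB_GEN`, `AcqL_GEN`
(intake asymptotes). Feed efficiency is
`FE = 100 · Σ E_milk / Σ ME_acquired`, computed over the second
lactation (`fe_lac2`) and over the whole life (`fe_life`). The
sensitivity experiment crosses the four parameters at three levels
(±15 % on the trait scale) into a complete 3⁴ factorial — 81 genotypes
× 20 seeded replicates — and decomposes output variance by factorial
ANOVA into per-term sensitivity indices.

## Worked example

```r
library(feedlife)

life <- simulate_cow(seed = 11)
life
#> <cow_life> CULLED at 9.0 years; 7 lactation(s); FE_life 42.3%, FE_lac2 52.6%

glance(life)[, c("fe_life", "fe_lac2", "e_acq_life", "e_milk_life",
                 "longevity", "n_lactations")]
#>   fe_life fe_lac2 e_acq_life e_milk_life longevity n_lactations
#>     42.35   52.64     482018      204131      9.03            7
```

This cow acquired 482 GJ of ME over a 9-year life, exported 42.35 % of
it as energy for milk production, and ran 7 lactations before failing
to conceive within 200 days of her seventh calving and being culled at
drying-off. Her second-lactation efficiency (52.6 %) is higher than her
lifetime efficiency because the lifetime figure also carries the
non-productive rearing phase and dry periods. `tidy(life)` returns the
full daily trajectory (intake, allocation coefficients, masses, milk,
body condition, energy balance) and `autoplot(life)` plots it.

The factorial experiment and its sensitivity decomposition:

```r
res <- run_design(n_reps = 20, base_seed = 1)     # 81 x 20 lifetimes, ~3 min
marginal_means(res, "fe_lac2")                    # per-factor L/M/H means
tidy(anova_sensitivity(res, "fe_life"))           # variance shares per term
plot_marginals(res, "fe_life")
```

Under the bundled calibration the experiment reproduces the hallmark
pattern: lactation-level efficiency rises steeply with allocation to
lactation (−6 %/+7 % around the medium) and is flat in both acquisition
parameters, while lifetime efficiency instead falls with allocation to
growth, rises with lactation acquisition, and peaks at the *medium*
level of allocation to lactation — the trade-off between per-lactation
output and lifespan.

Configuration is a flat YAML file (`load_config("my.yaml")`, or
`overrides = list(acql_gen = 9)`); every model constant is a documented
key, and `inst/cli/feedlife.R` provides `simulate` and `experiment`
commands for shell use.

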