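# residuekit

Tools for interpreting organic residues absorbed in archaeological
cooking pottery, built around one question: when cereal agriculture
(rice and broomcorn millet) arrives in a foraging region, does everyday
cooking actually change? The package is aimed at archaeometric
researchers working with integrated GC-MS peak areas, compound-specific
δ<sup>13</sup>C measurements, seed-impression surveys and radiocarbon
date lists.

## What it computes

**Molecular classification.** Heated starchy grains leave a distinctive
APAA-C18 positional-isomer signature: a sample is *cereal-consistent*
when its isomeric ratio E/H > 6 (strict). Heated aquatic oils are called
from C20/C22 APAAs, a phytanic-acid diastereomer ratio SRR% > 75, or an
APAA C20/total-C18 ratio > 0.06; broomcorn millet from the miliacin
flag; conifer resin from its diterpenoid markers.

**Isotopic source assignment.** δ<sup>13</sup>C of palmitic and stearic
acid is compared against 68%-confidence bivariate-normal reference
ellipses (Mahalanobis contour at the χ²₂ quantile), with Suess
correction of modern references and a concentration-weighted mixing
model: for each fatty acid, δ_mix = Σᵢ fᵢcᵢδᵢ / Σᵢ fᵢcᵢ.

**Rank-based tests.** Tie-corrected Kruskal–Wallis, Dunn post hoc z
tests, Wilcoxon rank-sum (Mann–Whitney W, exact null by enumeration on
small tie-free samples) and the η²_H / ε² effect sizes — implemented
from first principles and cross-checked in the test suite against base R
and full permutation enumeration.

**Seed impressions per potsherd.** A hierarchical negative-binomial
model with sherd-count exposure and a site-level random intercept,

y<sub>s,t</sub> ~ NegBin(λ<sub>region,phase,t</sub> · n<sub>sherds,s</sub> · e<sup>u_s</sup>, φ_t),  u_s ~ N(0, σ_u),

sampled by MCMC (JAGS) and summarised as posterior medians with 95% HPD
intervals.

**Arrival dates.** Radiocarbon calibration on a calendar grid plus a
uniform-phase boundary model: dated events uniform between the regional
arrival *a* and a phase end *b*, posterior over (*a*, *b*) by Metropolis
sampling, reported as 95% HPD in cal BP and BCE.

**Synthetic data.** `synth_config()` + `gen_residue_table()`,
`gen_seed_counts()`, `gen_radiocarbon_dates()` simulate every input with
recorded ground truth, so the whole pipeline is verifiable by parameter
recovery without any external data.

## Worked example

```r
library(residuekit)

cfg <- synth_config(seed = 42)

# 1. classify a simulated 254-sherd survey
sim <- gen_residue_table(cfg)
cl  <- classify_samples(sim$samples)
summarize_flags(cl, by = "site")
#>           site  n millet aquatic cereal_consistent resin
#> 1 AsahiS_early 60     12      18                 2     6
#> 2   AsahiS_mid 52      7      25                 1     3
#> 3    MamizukaS 40      7      15                 3     2
#> 4   NakamichiS 18      0       6                 0     2
#> 5      NakayaS 31      8      11                 0     4
#> 6    TenshojiS 15      2       5                 0     4
#> 7    UshimakiS 38      8      18                 2     2

# 2. per-sherd seed-impression rates with 95% HPDs
sc  <- gen_seed_counts(cfg)
fit <- fit_seed_model(sc$records, n_chains = 2, n_draws = 1500,
                      n_warmup = 2000, seed = 42)
head(summarize_rates(fit), 4)
#>             region      phase  taxon      median      hpd_low    hpd_high
#> 1 CentralHighlands EarlyYayoi millet 0.001619902 0.0001942201 0.004216423
#> 2 CentralHighlands EarlyYayoi   rice 0.001545867 0.0002048106 0.004194225
#> 3 CentralHighlands  LateJomon millet 0.004952727 0.0020077474 0.009667689
#> 4 CentralHighlands  LateJomon   rice 0.011378752 0.0052242768 0.020807907

# 3. regional arrival date from 20 simulated dates (true arrival 2700 BP)
rc  <- gen_radiocarbon_dates(synth_config(seed = 1))
estimate_arrival(rc$dates, rc$curve, region = "Tokai", seed = 1)
#> Arrival posterior [Tokai]: 95% HPD 2715-2615 cal BP (765 BCE to 665 BCE), 20 dates
```

The flag table counts, per site, how many sherds carry each molecular
marker (`n` sums to 254). The rate table reads, e.g., ~0.0016 millet
impressions per sherd in the Early Yayoi highlands with a 95% HPD of
(0.0002, 0.0042); the simulation truth for that cell is 0.001. The
arrival HPD of 2715–2615 cal BP covers the configured true arrival of
2700 cal BP.

A thin CLI over the same functions is installed at
`inst/scripts/residuekit.R` (subcommands `classify`, `stats`,
`seedmodel`, `arrival`, `simulate`).

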