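---
title: "Methods: from lipid residues to crop arrival dates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lipid residues to crop arrival dates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residuekit)
```

residuekit analyses the organic residues absorbed in archaeological
cooking pottery to ask when, and how intensively, cereal crops (rice and
broomcorn millet) entered the culinary repertoire of a region that was
previously foraging-based. This vignette documents the models behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
user extending the package should know about.

## Molecular classification

Prolonged cooking of unsaturated fats in a ceramic vessel produces
ω-(o-alkylphenyl)alkanoic acids (APAAs). The C18 homolog forms from the
common C18 unsaturated fatty acids of essentially any fat, but the
relative abundance of its positional isomers retains information about
the source. The package uses the ratio of the E and H isomers,
`compute_eh_ratio()`: experimentally heated rice and millet consistently
give high E/H, so a sample is flagged *cereal-consistent* when E/H
strictly exceeds a threshold (default 6, `classify_cereal()`). The
inequality is strict everywhere in the package — a value exactly at a
threshold is never a positive call. The ratio is invariant under any
common rescaling of the integrated areas, so no normalisation of the
chromatographic areas is required.

Heated aquatic oils are recognised by `classify_aquatic()` through three
criteria, OR-combined by default:

* presence of C20 and/or C22 APAAs (formed from the long-chain
  polyunsaturated fatty acids characteristic of aquatic organisms);
* a phytanic-acid diastereomer ratio (SRR%) strictly above 75%;
* the C20 APAA area relative to the *total* C18 APAA area strictly above
  0.06.

The third criterion's published shorthand ("APAA 18/20") is ambiguous
about which homolog is the numerator; we implement it as
C20-relative-abundance, which matches the aquatic-biomarker literature
the criterion descends from, and expose the threshold in
`aquatic_criteria()` so the inverse reading can be configured. Isoprenoid
fatty acids (phytanic, pristanic, TMTD) are recorded as supporting
evidence but never suffice on their own, because they also occur in
ruminant fats; an optional strict mode (`require_isoprenoid = TRUE`)
demands isoprenoid support before APAA-based calls. Miliacin — a
triterpene methyl ether essentially exclusive to broomcorn millet — and
conifer-resin markers (dehydroabietic acid and its oxidation products)
enter as upstream presence flags: their detection is an instrument-side
decision made during selected-ion monitoring, not something recomputable
from integrated areas.

## Isotopic source assignment

The δ13C values of palmitic (C16:0) and stearic (C18:0) acid measured by
GC-c-IRMS place each residue in a two-dimensional space in which
authentic reference products occupy characteristic regions. Reference
"ranges" are realised as bivariate-normal confidence ellipses
(`fit_reference_ellipse()`): the sample mean and covariance of the
reference points define a Mahalanobis contour scaled by the
chi-square(2 df) quantile of the coverage level (default 0.68). This is
the standard geometry for such biplots; the Monte-Carlo coverage test in
the suite confirms the 68% ellipse captures 68% ± 3% of draws from a
known bivariate normal. `assign_source()` reports, per class, the
Mahalanobis distance and an inside/outside call.

Modern reference tissues are depleted in 13C by fossil-fuel CO2 and must
be Suess-corrected before comparison with archaeological material
(`suess_correct()`). With an atmospheric δ13C record the correction is
the additive offset `preindustrial_ref − atm(year)` with a
pre-industrial reference of −6.4 ‰; without a record, a constant +1.9 ‰
is applied to samples collected after 2010. Archaeological references
(food crusts) are never corrected. Samples missing either fatty-acid δ
value are excluded from assignment rather than imputed — both
coordinates define the space.

Because absorbed residues are usually mixtures, `mix_isotopes()` forward
models the measured δ of each fatty acid as the average of the
ingredient endpoints weighted by ingredient fraction *and* that
ingredient's original concentration of the fatty acid. The mixture
therefore always lies in the convex hull of its endpoints and is biased
toward lipid-rich (animal) ingredients — the reason a minor cereal input
is nearly invisible isotopically, and the reason the molecular criteria
above are needed at all. `big_delta()` (δ13C18:0 − δ13C16:0) is provided
as the conventional ruminant-fat discriminator.

## Rank-based group comparisons

Residue measurements are small-sample, skewed and tie-prone, so group
comparisons are rank-based throughout. `kruskal_wallis()`,
`dunn_posthoc()` and `wilcoxon_rank_sum()` are implemented directly on
pooled mid-ranks with the standard tie corrections, rather than wrapping
an existing implementation, so that their exact behaviour (tie handling,
continuity correction, the W convention) is pinned by the package's own
tests — which cross-check every statistic against both base R and full
enumeration of the permutation null on small instances.

Choices a user should know:

* `W` follows the Mann–Whitney convention of the first sample
  (`sum(ranks of x) − n_x(n_x+1)/2`); ties produce half-integer values.
* The Wilcoxon p-value is exact (full enumeration via a subset-sum
  dynamic program) whenever the data are tie-free and
  `n_x · n_y ≤ 2500`; otherwise a normal approximation with tie and
  continuity correction is used.
* Dunn's pairwise z tests default to Holm adjustment; `none`,
  `bonferroni` and `bh` are selectable, since published analyses often
  omit this detail.
* Two rank-based effect sizes are available (`kw_effect_size()`):
  η²_H = (H − k + 1)/(n − k) and ε² = H/(n − 1), both floored to [0, 1].
  Reported effect sizes in the literature rarely state which was used,
  so both are exposed.

## The seed-impression model

Counts of crop seed impressions in pottery fabric are a presence proxy
with strong site-level clustering: a handful of sherds from a single
site can dominate a naive pooled rate. `fit_seed_model()` therefore fits

```
y_{s,t} ~ NegBin(mean = λ_{region(s), phase(s), t} · n_sherds_s · exp(u_s),
                 size = φ_t)
u_s     ~ Normal(0, σ_u)
```

with the sherd count as an exposure offset, a lognormal site random
intercept, one rate λ per region × phase × taxon cell, and one
dispersion φ per taxon. Priors (`seed_model_priors()`): Normal(−3, 2) on
log λ — weakly informative over the plausible per-sherd range 10⁻⁴–1 —
half-Normal(0, 1) on σ_u, and half-Normal(0, 1) on φ^(−1/2). The
dispersion scale deserves a note: a more diffuse prior on φ^(−1/2)
(e.g. scale 5) concentrates substantial mass on extreme overdispersion,
which lets the model explain a cell of all-zero counts by dispersion
alone and leaves the rate prior-dominated; with the tighter default, an
all-zero cell observed over thousands of sherds is correctly pinned to a
rate below 10⁻³ per sherd. Sampling is by JAGS (Gibbs/slice updates),
with per-chain Wichmann–Hill RNG seeds derived from the user seed so
that draws are bit-identical across runs. `summarize_rates()` reports
posterior medians with 95% highest-posterior-density intervals and
refuses (by default) to summarise a posterior whose rate parameters have
R-hat above 1.05.

`hpd_interval()` computes the shortest contiguous interval containing
the target mass by scanning sorted draws — for skewed posteriors (rates
near zero) this is visibly shorter and more honest than an equal-tailed
interval.

## Radiocarbon calibration and arrival estimation

`calibrate_date()` evaluates the standard calibration model — the
measured conventional radiocarbon age is normal around the curve value
with variance σ² + sd(θ)² — on a regular calendar grid (1-year
resolution by default, linear interpolation of the curve), normalised to
integrate to 1.

`estimate_arrival()` implements a uniform-phase boundary model: each
rice-associated dated event is assumed uniform in calendar time between
the unknown regional arrival `a` and the end of the modelled phase `b`
(`a > b` in years BP). Marginalising event times gives per-date
likelihood `(C_i(a) − C_i(b))/(a − b)` where `C_i` is the cumulative
integral of that date's calibration likelihood — precomputed once on the
grid, so each MCMC step costs an interpolation. Priors are uniform over
the curve window; `b` can be fixed by configuration or estimated with a
uniform hyperprior (the default). The posterior is sampled by
random-walk Metropolis with Robbins–Monro adaptation toward 30%
acceptance during warm-up only, frozen afterwards, so fixed seeds give
bit-identical chains. This is a deliberately simplified re-model: it
captures the first-order logic of published arrival estimates (the
oldest phase boundary consistent with the dated events) without outlier
down-weighting or inter-regional dispersal structure, and we make no
claim of reproducing any published interval exactly — the recovery tests
instead verify that the 95% HPD covers a known simulated arrival at
nominal frequency.

Internally all times are calendar years BP (datum 1950 CE); reporting
converts with `bp_to_bce()`.

## The synthetic-data generator

`synth_config()` fixes the study conditions; the generators emulate:

* **Residue survey** (`gen_residue_table()`): 254 sherds over a
  six-site, two-region layout with site sizes proportional to a
  realistic survey (35/35/108 coastal, 30/15/15 highland); per-vessel
  1–3-component source mixtures with Dirichlet fractions;
  concentration-weighted isotope mixing plus 0.3 ‰ analytical noise;
  82% of sherds yielding measurable δ13C; APAA preservation in 20% of
  sherds; class-specific lognormal E/H (cereals centred at 10, others
  1.2–2) and truncated-normal SRR% (aquatic centred at 85%); miliacin
  sensitivity 0.8 to mimic degradation. Every latent assignment is
  recorded in a truth table.
* **Seed counts** (`gen_seed_counts()`): 2 regions × 3 phases × 15
  sites, true rates log-evenly spanning 0.001–0.5 per sherd, site effect
  SD 0.5, dispersion 1.5, lognormal sherd counts (median 150).
* **Radiocarbon** (`gen_radiocarbon_dates()`): true arrivals 2700 /
  2750 cal BP, 400-year phases, 20 dates per region at σ = 25 on a
  linear toy curve (optionally wiggled) with 10-year curve error.

What the generator does **not** emulate: diagenetic covariance between
markers (preservation is independent across sherds), inter-laboratory
isotope offsets, curve plateaux of real calibration curves, taphonomic
loss structured by sherd fabric, and spatial autocorrelation between
sites. Passing recovery tests therefore demonstrate correctness of the
inference machinery under the stated model, not robustness to every
pathology of real assemblages.

## Problem sizes and numerical choices

The verification suite runs the seed model at reduced MCMC settings (one
chain, 800 warm-up / 800 retained draws for the 50-replicate recovery
study; two chains and more draws in the convergence-gated examples) and
the arrival model at 3000–4000 draws — sizes chosen so the full
distributional checks (coverage of 95% HPDs across replicates,
68%-ellipse coverage of 10⁴ draws, HPD of 10⁵ normal draws) complete on
a laptop in minutes. Degenerate inputs are defined, not errors, where a
definition exists: an all-tied Kruskal–Wallis sample has H = 0, p = 1;
constant draws have a zero-width HPD; a missing E or H isomer yields a
missing ratio, and a missing ratio yields a missing (not negative)
cereal call. Validation errors always name the offending row and column.
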