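---
title: "Life-table demography and factorial ANOVA for host-parasite toxicity assays"
author: "lifetabtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-table demography and factorial ANOVA for host-parasite toxicity assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetabtox)
```

## The experimental system

`lifetabtox` analyses chronic (21-day) *Daphnia* life-history assays in
which a toxicant gradient is fully crossed with a parasite challenge — the
kind of design used to ask whether a contaminant and a biological enemy act
independently on the host, or whether the contaminant interferes with the
parasite itself (as azole fungicides do with the microparasitic yeast
*Metschnikowia bicuspidata*). The canonical layout is 2 host clones x 4
toxicant concentrations x 2 parasite treatments x 20 replicate vessels
(320 experimental units), each holding one neonate followed daily; a
follow-up variant crosses 6 concentrations with single versus double
parasite challenge (480 units).

The package covers the whole analysis chain: validated tidy I/O of daily
individual records, endpoint derivation, demographic estimation, per-clone
factorial ANOVA, and a stochastic individual-based generator of the same
designs so that every stage can be tested and power-analysed without any
external data.

## Data model and endpoints

A record holds one individual's death day (the sentinel `duration + 1`
means censored alive at test end), its daily counts of living offspring,
and its infection status at inspection. Experiment day and age in days are
treated as identical: neonates are under 24 h old at day 0, and day 1 is
the first full exposure day. An individual with death day *d* is counted
as surviving to ages *x* < *d* only — the daily census precedes brood
counting. The challenge schedule (who is inoculated, and on which days)
belongs to the design, not the record, so a tidy CSV needs only nine
columns and round-trips exactly.

Four endpoints are derived:

* **Age at first reproduction (AFR)** — first day with a brood; missing if
  the individual never reproduced (never coded as infinity; ANOVA uses
  complete cases).
* **Fecundity at day 14** — cumulative living offspring over days 1-14,
  defined only for females alive through day 14. Day 14 is used because
  parasite-induced mortality starts around then and would otherwise
  confound the fecundity measure.
* **Reproductive output at day 21** — cumulative offspring over the whole
  assay, *including* the partial totals of individuals that died from day 4
  onward, so the endpoint integrates effects on both survival and
  fecundity. Deaths before day 4 are excluded as accidental early-age
  mortality. This exclusion is an endpoint-level rule, applied here and not
  at I/O time, so raw data files stay complete; the excluded individuals
  still count in the mortality and infection proportions.
* **Cell proportions** — mortality (dead by day 21 over all individuals)
  and infection (infected over all inspected individuals). Because hosts
  are inspected at death or at day 21, the infection denominator is every
  individual with known status, not only survivors; numerators and
  denominators are reported explicitly so the alternative convention can be
  recomputed.

## Demography: Euler-Lotka and the jackknife

Survival and reproduction are condensed into the per-capita intrinsic rate
of population increase *r* (day^-1^), the root of the Euler-Lotka equation

$$1 = \sum_{x=0}^{n} e^{-rx} \, l_x m_x,$$

where $l_x$ is the probability of surviving to age $x$ and $m_x$ the mean
number of living offspring per female alive at age $x$. The
mean-per-survivor convention makes $l_x m_x$ the per-capita expected
offspring at age $x$, the standard life-table identity; ages where no one
is alive take $m_x = 0$, with $l_x = 0$ making the product vanish. The
left-hand side is strictly decreasing in $r$ whenever reproduction occurs
at a positive age, so the root is unique. It is found by a bracketing
search on $[-10, 10]$ day^-1^ (geometrically expanded if needed — far wider
than any biologically possible rate) followed by refinement to
$|f(r)| \le 10^{-10}$; robustness was preferred over speed since each solve
is microseconds. A cohort whose lifetime reproduction $\sum l_x m_x$ falls
below one has a negative rate and is reported as such, never clipped; a
cohort with no reproduction has no root and is reported as missing.

One treatment cell (the 20 replicates of a clone x concentration x
parasite combination) forms one cohort. Because *r* is a cohort-level
statistic, replication for ANOVA comes from jackknife pseudo-values:
$r_i = n\hat r - (n-1)\hat r_{(-i)}$, one per cohort member, computed from
the full-cohort and leave-one-out solutions. On a cohort of identical
individuals every pseudo-value equals the full-cohort estimate. If a
leave-one-out cohort loses its only reproducing member its pseudo-value is
missing and is dropped from the downstream ANOVA (complete-case, with the
count reported). No early-death exclusion is applied to these cohorts: the
exclusion rule is scoped to the reproductive-output endpoint only.

## Factorial statistics

Each clone is analysed separately with a two-way fixed-effects ANOVA
(concentration x parasite treatment, with interaction) per endpoint; AFR is
natural-log transformed to temper its pronounced variance heterogeneity,
all other endpoints are analysed raw. Because the clones are tested in
separate families, the working significance level is Dunn-Sidak adjusted:
$\alpha' = 1 - (1-\alpha)^{1/k}$ with $k$ the number of clones, giving
0.0253 (conventionally quoted as 0.025) for two clones at family
$\alpha = 0.05$.

The design is balanced by construction, but mortality and the endpoint
definitions make the analysed data unbalanced. No ordering of the two main
effects is privileged, so partial (Type II) sums of squares are the
default decomposition; sequential (Type I) is available by flag and
coincides with Type II on balanced data (a property the test suite checks
on random balanced tables against an independently coded cell-means
oracle). F is the term mean square over the residual mean square. A
degenerate fit with zero residual variance reports F and P as missing
rather than infinite, so batch analyses survive pathological inputs.
Residual diagnostics (per-cell variance ratio, skewness, excess kurtosis)
are descriptive only — mirroring the practice of judging residual plots —
and no automatic decision is taken. No post-hoc multiple comparisons are
performed.

## The synthetic-data generator

The generator draws one daily trajectory per experimental unit:

* accidental early death with probability 0.02, uniform over days 1-3;
* daily Bernoulli survival at a baseline hazard of 0.003 day^-1^ plus a
  Hill-shaped toxicant term `max_added * c^h / (EC50^h + c^h)`;
* infection drawn independently at each challenge experienced alive, with
  per-challenge success `p_control(clone) * s(c)` where
  `s(c) = 1 / (1 + (c/EC50)^h)` is the toxicant's suppression of parasite
  success — a smooth logistic chosen over a hard threshold so that partial
  suppression at low doses can emerge while an abrupt, threshold-like
  suppression pattern is reproduced by a steep slope;
* infected hosts die on a day drawn uniformly from 14-17 (the
  parasite-kill window), unless an earlier hazard killed them first;
* broods at the individual age at first reproduction (mean 8 d, sd 0.8 d,
  plus a Hill-shaped dose delay, rounded to whole days) and every 3 days
  thereafter while alive, with Poisson sizes around a dose-declining mean
  of 10 offspring per brood, an optional hormetic bump at intermediate
  doses, a 5% brood penalty per experienced challenge (the small fitness
  cost of an unsuccessful challenge), and a further 15% penalty when
  infected.

The baseline rates were chosen once as realistic for 21-day *Daphnia*
chronic tests at 20 °C: control mortality stays below the 20% validity
ceiling and control females release well over 60 offspring, and the
resulting control *r* of roughly 0.3-0.4 day^-1^ is in the usual range for
well-fed daphniids. Reproducibility is by design: one master seed spawns
per-unit substreams keyed by a hash of the unit's factor coordinates, so
the same seed gives a bit-identical experiment and adding replicates never
perturbs existing units.

Three presets encode the study conditions: `"copper"` (0/25.0/28.8/33.1
ug/L; added mortality only near the top concentration, no infection
suppression, slight hormesis), `"tebuconazole"` (0/154/192/240 ug/L;
steep suppression with EC50 5 ug/L and Hill slope 6, monotone fecundity
decline, delayed first reproduction, no direct mortality) and
`"followup"` (0/6.25/12.5/25.0/50.0/100.0 ug/L crossed with single versus
double challenge on days 5 versus 3+5, clone-specific control infectivity
of about 0.90 and 0.58 per challenge). With these parameters the
tebuconazole presets give essentially complete infection suppression from
12.5 ug/L upward and partial suppression (roughly 10-30% infection) at
6.25 ug/L, matching the observed pattern.

What the generator does *not* emulate: within-host spore dynamics,
transmission between vessels, latent (delayed rather than suppressed)
infection, clutch-level structure beyond Poisson noise, and real-world
measurement error in daily censusing. Passing recovery tests therefore
demonstrates that the pipeline detects effects of the simulated kind and
size, not that any particular field data set will behave this way.

## Calibration and recovery checks

The test suite verifies, among others:

* the Euler-Lotka solver against the closed form $\ln(l_x m_x)/x$ on
  single-term schedules and against an independent bisection oracle on
  1000 random schedules (both to 1e-8);
* jackknife pseudo-values against an independently coded leave-one-out
  loop, and exact collapse on identical cohorts;
* ANOVA sums of squares against a definitional cell-means oracle on
  balanced tables, and type-I error calibration at the adjusted
  $\alpha = 0.025$ under a null simulation (1000 replicates, binomial
  confidence band);
* end-to-end signature recovery on the fungicide preset across 100 seeds:
  zero infection at all concentrations at or above 12.5 ug/L, a
  significant concentration effect on day-14 fecundity in both clones, and
  a parasite effect on reproductive output localised at the zero
  concentration — significant parasite main effect and concentration x
  parasite interaction, with the simple effect at 0 ug/L significant. The
  localisation is deliberately expressed through the interaction: the
  generator's challenge penalty is a true (if small) parasite effect at
  every concentration, so demanding strict non-significance at each
  nonzero dose would test the noise level rather than the signature.

Problem sizes in the routine suite are desk-scale (presets at 2-8
replicates where full size adds nothing; full 20-replicate runs where the
design arithmetic itself is under test), which keeps the whole
suite under a minute while the acceptance checks run the full designs.

## Known limitations

* The per-concentration residual-degrees-of-freedom bookkeeping of any
  particular historical data set cannot be reproduced exactly without the
  raw data; the pipeline reports its own complete-case dfs.
* Infection suppression and delayed infection are observationally
  equivalent within a 21-day window; the generator models suppression
  only.
* No dose-response (ECx) fitting, survival regression or mixed models:
  the analysis deliberately mirrors the fixed-effects factorial ANOVA
  practice of the assays it supports.
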