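---
title: "Climate-window inference for breeding phenology: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-window inference for breeding phenology: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestwin)
```

## The problem

Montane birds time their breeding against climate signals that are far less
obvious than "a warm spring": snowpack built the previous autumn, mid-winter
minimum temperatures, or soil moisture after melt can all carry information
about invertebrate food availability months later. Given a daily climate
record and per-nest breeding outcomes over about a decade, the question is:
*which climate variable, averaged over which calendar period, best explains
year-to-year variation in each breeding response?*

`nestwin` answers this with an exhaustive **absolute sliding-window
search**. An absolute window is a calendar-dated period shared by every
nest of a season (as opposed to windows relative to each individual's own
event date). For each candidate window the per-season mean of a climate
variable becomes a covariate; a response model with that covariate competes
against an intercept-only null by AICc, and the improvement
$\Delta\mathrm{AICc} = \mathrm{AICc}_{\mathrm{climate}} -
\mathrm{AICc}_{\mathrm{null}}$ ranks the windows (more negative is better).

## Window grid

Windows are indexed by integer day offsets from a season **anchor**, 1
September of the preceding calendar year, so that autumn windows attach to
the following breeding season. The grid contains every contiguous
`[open, close]` pair with

* duration at least 14 days (shorter periods are unlikely to be
  biologically meaningful as cues),
* `open` no earlier than the anchor,
* `close` no later than a response-specific **reference date**: the
  earliest first egg date ever recorded at the site for breeding
  initiation, that date + 9 days for clutch size (the maximum laying
  span), and + 40 days for brood size, nestling mass and mass CV (laying,
  incubation/hatching and 16 days in the nest).

For a span of $D$ days this gives $(D-13)(D-12)/2$ windows — 27 028 for a
full 1 September to 3 May span. Because offsets are anchored to 1
September, the same window can be laid onto every season; in leap years the
spring dates shift by one calendar day, which is irrelevant at the
precision of the method. A `stride` argument coarsens both endpoints to an
`n`-day grid; day resolution (`stride = 1`) is the default, and the
simulation studies in the test suite use `stride = 3` to keep tens of
searches per property inside a desk-scale budget.

The per-window covariate is the arithmetic mean of the daily values, with
missing days excluded; if fewer than 80% of a window's days are present
(`completeness_floor`) the covariate is set missing for that year and the
affected nests drop from both the climate and the null model, keeping the
two on identical rows.

## Response models

Dates (first egg day-of-year), mean day-16 nestling mass and the log of the
within-nest coefficient of variation in mass are modelled as Gaussian
linear models fitted by maximum likelihood (`fit_gaussian_lm()`); the
variance MLE uses the $n$ denominator and is counted in $k$ for AICc, so
the single-covariate model has $k = 3$ and the null $k = 2$. Wald $t$
statistics use the usual unbiased variance with $n - p$ degrees of freedom.

Clutch and brood sizes are counts that are typically *under*-dispersed, so
they use a mean-parameterized **generalized Poisson** GLM with log link
(`fit_genpois_glm()`). With $\lambda = 1 - 1/\sqrt{\phi}$ and
$\theta = \mu/\sqrt{\phi}$,

$$P(Y = y) = \theta\,(\theta + \lambda y)^{y-1}
  e^{-\theta - \lambda y} / y!,$$

which has mean $\mu$ and variance $\phi\mu$ and reduces exactly to the
Poisson at $\phi = 1$. Admissibility requires $\lambda > -1$, i.e.
$\phi > 1/4$; the optimizer parameterizes $\phi = 1/4 + e^{\eta}$ and
starts from a Poisson fit. At an interior optimum the joint ML equations
imply the fitted intercept-only mean equals the sample mean exactly; for
degenerate (zero-variance) responses the dispersion runs to the boundary,
the first-moment property no longer holds, and the fit is flagged
`converged = FALSE` rather than silently reported. The CV of nestling mass
uses the sample ($n-1$) standard deviation and is natural-log transformed;
nests with CV = 0 or broods of one have no defined (log-)CV and are
excluded from that response.

AICc is $-2\ell + 2k + 2k(k+1)/(n-k-1)$ throughout, with $k$ counting
dispersion/variance parameters in both families so that same-family
$\Delta$AICc is unaffected by the convention.

For speed, the Gaussian search path evaluates every window at once from
per-year sufficient statistics (the response enters only through per-year
counts, sums and sums of squares, and window means come from cumulative
sums of the daily series). This is algebraically exact ML, and the test
suite asserts equality with `fit_gaussian_lm()` refits and with an
independently coded `stats::lm()` brute-force loop. Generalized-Poisson
searches fit window by window with cached null fits.

## Equivalence and overlap collapsing

All windows within 2 $\Delta$AICc of the best are treated as equivalent in
performance. Because neighbouring windows share most of their days, the
equivalence set is usually a cloud of near-duplicates: windows whose day
sets overlap with temporal Jaccard $\ge 0.75$ are grouped and only the
lowest-$\Delta$AICc member of each group survives, while genuinely
disjoint equal performers are all retained and reported. The overall
lowest-$\Delta$AICc survivor is the **chosen** window. The 0.75 threshold
quantifies "overlapped substantially", which the protocol leaves verbal;
it is deliberately high so that only near-duplicates collapse.

## The randomization gate (P-rand)

An exhaustive search over tens of thousands of windows will often find
*some* window that beats the null by chance. The guard is a **year-block
randomization** test: year labels are permuted as a bijection over the
observed years, so every nest of a season moves together and each season's
climate stays with its true year. Permutation (rather than resampling with
replacement) is used because it preserves every year's sample size
exactly; identity draws are allowed. For each of `n_rand = 100`
randomizations the *full* search is rerun and its top window's
$\Delta$AICc and estimate sign recorded. Only randomizations whose sign
matches the observed effect are compared (the question is whether the
observed directional relationship could arise by chance); sign is taken at
each randomization's own top window, and zero estimates count as
non-matching. The observed window passes when at most
$\lfloor 0.05\,n_{\mathrm{rand}}\rfloor$ (5 of 100) sign-matched
randomizations beat it. Failed randomization searches are logged and
counted as non-better, which is conservative in the passing direction
only when failures are rare; the count is reported either way.

Because permuting year blocks is equivalent to re-pairing year groups with
covariate columns, the randomizations reuse the precomputed search context
and cost almost nothing for Gaussian responses.

## Final-model selection

Per response and site, the per-variable chosen windows pass through four
stages:

1. **Screen** — keep a variable only if its single-covariate model beats
   the null by likelihood-ratio test at $\alpha = 0.05$ *and* its
   randomization gate passed. An empty survivor set is a valid outcome
   ("no significant climatic predictors").
2. **Dedupe** — within similarity families (the three air temperatures;
   soil moisture depths; soil temperature depths; snow depth, SWE and
   precipitation accumulation), variables whose chosen windows overlap at
   Jaccard $\ge 0.75$ collapse to the lowest-AICc member. Only the
   temperature family is dictated by the protocol; the other groupings
   extend the same logic to variables that are near-copies of one another
   physically.
3. **Prune collinear** — among survivors, while any pair of per-year
   covariates has $|r| \ge 0.7$ (Pearson), drop the higher-AICc member.
   The 0.7 cutoff is the conventional collinearity rule of thumb; the
   protocol states none.
4. **All subsets** — fit every non-empty subset of the remaining
   variables on a common row set and report all models within 2 AICc of
   the best, with estimates, standard errors, $t$/$z$ statistics and
   AICc. All-subsets (with a $2^{12}$ guard never reached at realistic
   scale) keeps "combinations compared using AICc" exact rather than
   stepwise-approximate.

The across-year variation diagnostic is a likelihood-ratio chi-square of a
year-factor model against the intercept-only null (family matched to the
response); long-term drift is an OLS slope of a value on year with a
two-sided $t$ test. `run_full_analysis()` chains everything per site and
response, derives per-stage seeds deterministically from the config seed,
and `validate_run()` re-checks every structural invariant of the output
bundle.

## The synthetic-data generator

`simulate_climate()` produces the eleven daily variables from a small
mechanistic sketch: seasonal sinusoid + per-season year effect + AR(1)
noise for mean temperature (AR coefficient 0.7, innovation s.d. 2.2 °C,
year s.d. 1.2 °C — winter spells at this scale persist about a week, as
montane records do); positive diurnal half-ranges for min/max;
winter-peaking precipitation occurrence with gamma amounts; snow
accumulation below a 1 °C threshold with degree-day melt (2.5 mm SWE per
degree-day) and a fixed pack density of 0.35; soil moisture as a leaky
integrator of rain and melt; soil temperatures as depth-damped running
means of air temperature, insulated under snowpack. The high site is 3 °C
colder with 25% more precipitation, giving reliably deeper snow. Defaults
are sized to the study system: ten seasons (2013–2022), two sites, ~40–60
nests per site-year.

`simulate_breeding()` plants known window effects: per year the true
window's realized mean covariate $c$ drives Gaussian responses
$\mathcal{N}(\beta_0 + \beta_1 c, \sigma)$ and generalized-Poisson counts
with mean $e^{\beta_0 + \beta_1 c}$ and dispersion $\phi = 0.8$ (mild
underdispersion, typical of clutch-type counts). Nestling masses are drawn
per nestling around each nest's mean so the within-nest CV is *emergent*,
brood size is capped at clutch size, and a small fraction of renests and
second broods (2.5% and 1.3%, the study's observed order) is injected to
exercise the first-attempt filter. Default effect sizes and windows echo
the study system (autumn maximum temperature advancing low-elevation
laying, autumn SWE raising low-elevation brood size, spring temperature
raising high-elevation counts).

In the recovery and calibration experiments the planted slope is set from
the *realized* covariate spread — `slope = s · resid_sd / sd(c)` — so "a
standardized effect of s" is exact by construction rather than nominal.

What the generator does **not** emulate: spatial structure within sites,
observation error in nest detection, density dependence or carry-over
effects between seasons, physically realistic snow hydrology, and
correlated missingness in station records. Passing tests therefore show
that the inference machinery recovers effects of known size under the
assumed model families and realistic autocorrelation — not that any
particular field dataset satisfies those assumptions.

## Numerical choices and degenerate inputs

* Ties in $\Delta$AICc are broken deterministically by (open, close), so
  searches are bit-reproducible; the search itself involves no randomness.
* Windows whose covariate is constant across years (e.g. snow depth
  identically zero in early autumn), or that leave fewer than two distinct
  years or a perfect fit (zero residual variance), are excluded as failed
  fits and counted in `n_failed`.
* Fits with too few rows for the AICc correction ($n \le k+1$) carry
  `AICc = Inf` rather than erroring, so exact-interpolation toy fits can
  still report coefficients; the standalone `aicc()` refuses them.
* Station averaging falls back to the single reporting station on days
  where one record is missing (logged), trading a slight inhomogeneity for
  much better window completeness.
* Precipitation re-anchoring treats any negative day-to-day decrement as a
  provider counter reset; the accumulation reported on each 1 September is
  0 by definition of the anchor, so the anchor day's own increment never
  enters the season total.
* Physical inconsistencies in ingested climate data (negative snow,
  `tmin > tavg > tmax` ordering violations) are flagged, never altered.

## Problem sizes used in the shipped experiments

The unit and acceptance suites run entirely on synthetic data: recovery
and null-calibration studies use 10 years × 30 nests at `stride = 3` over
20 seeds each; the power property of the randomization gate uses 10 seeds
at `n_rand = 30`; the brute-force ranking oracle uses a 40-day span (378
windows, 5 years × 8 nests). The acceptance script runs the full
100-randomization gate on a 10-season, 50-nests-per-year dataset. These
sizes were chosen so that every property is exercised end-to-end in well
under a minute per block while leaving the estimated rates far from their
decision boundaries.

## Known limitations

* Climate covariates are year-level, shared by all nests of a site-year;
  models contain no year random effect, mirroring the simple per-nest
  LM/GLM reporting of the protocol. Effective replication for the climate
  slope is therefore the number of years, not nests — the randomization
  gate, not the nominal standard error, is the honest guard.
* Only mean aggregation within windows is supported (no slopes, maxima or
  weighted kernels), and only absolute windows (no per-individual relative
  windows).
* The generalized-Poisson support truncation for strong underdispersion
  means the pmf normalizes only approximately (error < 1e-6 for
  $\phi \gtrsim 0.3$ at moderate means).
* Sign matching in the randomization gate uses each randomization's own
  top window; assessing it at the observed window's dates is a defensible
  alternative the interface does not currently expose.
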