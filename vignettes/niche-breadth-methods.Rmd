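---
title: "Quantifying the breadth of adaptation across a chemical gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the breadth of adaptation across a chemical gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichespan)
```

## The problem

Serial-transfer laboratory evolution adapts a bacterial population to one
environment — here, *Escherichia coli* strains carrying progressively
larger engineered genome deletions, evolved in a minimal glucose medium
(the reference combination, C0). The scientific question is not only
whether fitness in C0 recovers, but what happens to fitness *around* C0:
does adaptation to one point of chemical space widen or narrow the
strain's niche?

`nichespan` implements the full quantitative chain for that question:

1. maximal growth rates from plate-reader OD600 curves;
2. fitness profiles along the concentration gradient of each medium
   constituent, summarised by the normalized niche-space statistic $S$
   and the niche broadness $S_T$;
3. a simulator of the serial-transfer protocol with stepwise mutation
   fixation;
4. the statistical comparisons (exact-permutation Spearman correlations,
   per-condition Welch tests) used to summarise a study.

A synthetic-data generator with known ground truth produces every input,
so the whole pipeline is testable end to end without external data.

## The environmental gradient

The reference medium is mixed from seven pure compounds (glucose,
K~2~HPO~4~, KH~2~PO~4~, MgSO~4~, thiamine·HCl, FeSO~4~, (NH~4~)~2~SO~4~),
which dissociate into eight ionic-form constituents — the *chemical
niches*: glucose, K^+^, PO~4~^3−^, Mg^2+^, SO~4~^2−^, NH~4~^+^, Fe^2+^
and thiamine. `build_design_matrix()` varies one compound at a time on a
logarithmic scale: with the default of four levels per compound at step
×10 (multiplicative factors $10^{-2}, 10^{-1}, 10^{1}, 10^{2}$), the 28
single-compound variants plus C0 give 29 combinations. The symmetric
placement keeps C0 interior to every profile, which stabilises the cubic
fits; the exact exponents are a package choice, since only "a logarithmic
scale" is inherent to the design. Because several compounds share ions
(three sulfate salts; two potassium phosphates), the map from compounds
to constituents is many-to-one and profiles pool points across compounds
(below).

## From OD600 curves to maximal growth rates

For consecutive reads $C_i, C_{i+1}$ at times $t_i, t_{i+1}$ the
interval rate is

$$\mu_i = \frac{\ln(C_{i+1}/C_i)}{t_{i+1}-t_i}.$$

Reads at or below the detection floor `od_floor` (default 0.003 OD, a
typical plate-reader noise level) are excluded before rates are formed:
log-ratios of noise-floor readings are meaningless. Rates may be
negative and enter selection unweighted.

The fitness estimate is the mean of the best window of five consecutive
rates. The selection criterion asks for the window with the *largest
mean and the smallest standard deviation* — two objectives, so a total
order is needed. `max_growth_rate()` ranks windows by the conservative
score $\bar\mu_w - 2\,\mathrm{SD}_w$ and reports the winning window's
mean. For a genuine exponential phase the SD term vanishes and the rule
reduces to the maximal mean; for windows whose large mean is a noise
artifact (log-ratios of barely-detectable ODs swing by whole units) the
penalty is decisive. A plain maximal-mean rule is an order statistic
over ~90 windows of noise and overestimates the rate substantially on
realistic curves; the penalized score removes that bias while leaving
every noise-free case untouched. Near-ties in the score (relative
tolerance $10^{-6}$) are broken by the smaller SD, then by the earlier
window. Windows never straddle excluded intervals.

Wells that never rise above the detection floor have no measurable
exponential phase; `fitness_replicates()` records their rate as zero
(flagged `below_detection`) so that non-permissive gradient conditions
stay in the fitness table. Replicates aggregate as mean ± SE
($\mathrm{SD}/\sqrt n$). A per-plate blank can be subtracted via
`blank_od`; the default performs no subtraction.

Transfers are scored by the same logic over a whole interval:
generations $= \log_2(C_i/C_j)$ and rate $= \ln(C_i/C_j)/(t_i-t_j)$,
with $C_j$ the theoretical post-dilution OD. Redox assays reduce to the
OLS slope of OD490 against time divided by the culture's OD600.

## The niche-space statistic S

For one genome, population and constituent, the profile pairs
$x = \log_{10}$(concentration) with the mean growth rate of each
combination that varies the constituent, plus C0. Constituents fed by
several compounds pool all of them: the SO~4~^2−^ profile collects the
MgSO~4~, FeSO~4~ and (NH~4~)~2~SO~4~ series (13 points), while
single-compound constituents have 5. If a combination drops a
constituent to zero concentration, the point is placed at a pseudo-floor
one decade below the smallest nonzero level (configurable), since
$\log 0$ is undefined.

The profile is fitted by ordinary least squares with a cubic polynomial

$$\mu(x) = a x^3 + b x^2 + c x + d,$$

with $x$ first rescaled so the profile spans $[0,1]$. The area under the
fit is evaluated analytically from the antiderivative (no quadrature),
and the statistic normalizes it by both axes:

$$S = \frac{\mathrm{Area}}{\mu_{\max}\,(x_{\max}-x_{\min})},$$

so $S = 1$ means full fitness across the whole gradient and the result
is invariant to affine transformations of the $x$ axis and to positive
rescaling of $\mu$ — the package verifies both invariances in its tests,
which also makes the choice of fitting on $\log_{10}$ concentration
innocuous. Two open choices were resolved as follows:

* $\mu_{\max}$ is the *maximal observed mean rate* of the profile, not
  the fitted curve's maximum: normalization "rescales the maxima of the
  growth rate to one unit" from data, and the fitted cubic can overshoot
  between points. Consequently $S$ can marginally exceed 1 when the fit
  overshoots.
* The fitted polynomial is integrated as-is, including negative
  excursions; `clip_negative = TRUE` clips them to zero (numerically, on
  a 2001-point grid) for sensitivity analysis.

The niche broadness of a genome/population is the sum over the eight
constituents, $S_T = \sum_i S_i$, reported together with the population
SD of the eight values (an evenness measure). A full five-genome,
two-population study yields 80 $S$ values and 40 evolutionary changes
$\Delta S = S_\mathrm{Evo} - S_\mathrm{Anc}$.

## The synthetic study and its ground truth

`simulate_study()` emulates the fitness assay: 5 genomes × 2 populations
(ancestral, evolved) × 29 combinations × 6 replicate wells, read every
30 min for 48 h. Each curve follows lagged exponential growth from
OD 0.001 capped sharply at carrying capacity 1.0. The sharp ceiling is
deliberate: in minimal media the Monod half-saturation constant is
orders of magnitude below the initial substrate concentration, so the
specific rate holds near its maximum until substrate exhausts. A smooth
logistic would make the rate decline as $\mu(1-\mathrm{OD}/K)$ from the
very first read, leaving no constant-rate window at measurable OD — an
artifact of the curve model, not of bacterial physiology, and one that
defeats any windowed maximal-rate estimator. Observed ODs add 2%
multiplicative and 0.003-OD additive Gaussian noise, matching
plate-reader noise floors.

The ground-truth landscape gives every (genome, population, constituent)
a unimodal (Gaussian in $\log_{10}$ concentration) rate response peaking
at the C0 concentration, with three built-in, recoverable effects:

* genome reduction lowers the ancestral peak rate (25% per Mb deleted;
  wild-type peak 0.7 h^−1^);
* evolution recovers the peak by a deletion-proportional factor
  (+35% per Mb), so evolved/ancestral ratios rise with deletion size;
* for glucose, SO~4~^2−^ and NH~4~^+^ the ancestral response *narrows*
  with deletion (35% width loss per Mb from a base width of 1.2
  decades) and evolution restores the full width — the breadth effect
  the $S$ statistic is built to detect.

A variant combination's true rate evaluates the response of the
constituent(s) its varied compound feeds, taking the minimum across them
(limiting-nutrient rule); C0 takes the minimum over all eight, which at
the default peaks equals the shared peak rate. The deletion sizes
attached to the N0/N7/N14/N20/N28 panel (0–1230 kb) are synthetic
placeholders with realistic magnitudes. All randomness derives from one
master seed via stable metadata hashing, so any subset of the study
regenerates identically.

What the generator does *not* emulate: strain-specific lag variation,
plate edge effects, OD nonlinearity at high density, correlated
(drift-like) instrument noise, and diauxic or biphasic growth. Passing
tests therefore demonstrate correctness of the estimators under a clean
growth model with realistic read noise, not robustness to every real
plate-reader pathology.

Recovery at the study's conditions: the median error of the six-replicate
rate estimate across a 0.1–0.9 h^−1^ grid is ~2–3%. The slowest grid
point (0.1 h^−1^) is materially worse (~20–30% error) because a culture
starting at OD 0.001 barely clears the detection floor within 48 h —
a faithful property of the assay, not of the estimator.

## The serial-transfer simulator

Each transfer dilutes the culture into eight wells at $10^{1}..10^{8}$,
grows them for 12 or 24 h (12 h if any well is predicted to reach
OD 0.01 by then), and carries forward the well whose final OD lies in
the early-exponential selection range 0.01–0.1. When several qualify the
largest dilution wins — it has spent the fewest generations near
crowding; when none qualifies the well closest to the range on the
log-OD scale is taken and flagged. Generations and rate estimates follow
the transfer equations above.

Mutation supply is Poisson per generation at rate
$0.002\,(1 + 1.5\,\mathrm{Mb})$, rising with deletion size. Sweeps are
deterministic logistic trajectories
$f(g) = f_0 / (f_0 + (1-f_0)e^{-sg})$ (written in the overflow-stable
form) with per-generation coefficient $s = \ln 2 \cdot \delta/\mu$ for a
rate effect $\delta$, starting at $f_0 = 10^{-4}$ and counted as fixed
at $f \ge 0.999$; one sweep runs at a time and later arrivals queue
(zero-lag queuing can represent observed co-fixation). Drift is not
modelled: at bottlenecks of $10^5$–$10^7$ cells it is negligible for
sweeps at these coefficients. Effects are Gamma-distributed (shape 3)
with mean $0.5\,e^{-4\mu}$ h^−1^ — diminishing-returns epistasis in the
absolute current rate, so slower backgrounds (within a lineage as it
adapts, and across genomes with larger deletions) gain more per
mutation, and the pre-fixation rate anticorrelates with the realized
gain. Fixed effects add to the growth rate; the mean population rate
during a sweep is $\mu_\mathrm{base} + f\,\delta$.

## Statistics

Spearman's $\rho$ uses midranks. For $n \le 9$ — genome-panel
correlations have $n = 5$, where the $t$ approximation is unreliable —
the two-sided p-value enumerates all $n!$ permutations exactly (120 at
$n=5$; the smallest achievable two-sided p is then $2/120 \approx
0.017$). Evolved-vs-ancestral comparisons per (combination, genome) use
the two-tailed Welch $t$ test by default (replicate variances are not
assumed equal; `var_equal = TRUE` gives the pooled form). Raw p-values
are reported, as in the study's heatmaps; a Benjamini–Hochberg column is
emitted alongside without replacing them.

## Numerical and reproducibility choices

* Window near-ties: relative tolerance $10^{-6}$ on the selection score,
  then smaller SD, then earliest window.
* Degenerate inputs error early and name the offending profile or key:
  profiles need ≥4 distinct $x$; all-zero fitness profiles have no
  defined $S$; constant vectors have no rank correlation.
* Areas are analytic; the only grid evaluation is the optional negative
  clipping.
* The pipeline (`run_all()`) writes CSVs plus a JSON manifest with file
  hashes and row counts; identical (config, seed) pairs produce
  byte-identical outputs.
* Test and example problem sizes (six replicates, 48-h curves, 50-day
  evolution runs, 10–20 seeds for sign-recovery checks) are the study's
  own scale and run in well under two minutes each.

## Limitations

The response curves are phenomenological, not metabolic: nothing
explains *why* a constituent limits growth. Clonal interference,
population heterogeneity, and glycerol-stock pauses are not simulated.
$S$ carries no confidence interval (none is defined for it here); a
bootstrap over replicates would be the natural extension. The cubic is a
smoothing device, not a mechanistic dose–response model — with only 4–5
concentrations per single-compound constituent it is the highest-order
polynomial the data support.
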