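---
title: "A string model of achievable fundamental frequency range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A string model of achievable fundamental frequency range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalrange)
```

## The model and its assumptions

Mammalian vocal folds are layered fiber-gel constructs: collagen and
elastin fibers (the vocal ligament) and muscle fibers embedded in a
viscoelastic ground substance. When one fibrous layer carries most of
the tension, the fold vibrates like a thick string in a viscous medium
and the string modes dominate. `vocalrange` adopts that simplification
wholesale: the fundamental frequency of a string fixed at both ends is

$$f_0 = \frac{1}{2L}\sqrt{\frac{\mu'}{\rho}},$$

with vibrating length $L$, effective fiber stress $\mu'$, and tissue
density $\rho$. Three assumptions follow.

1. **One effective stress.** $\mu'$ lumps the shear and tensile
   contributions of the dominant fibrous layer into a single scalar; the
   package makes no attempt to decompose it.
2. **Exponential stress-strain law.** Fiber stress grows as
   $\mu' = A e^{B\varepsilon}$ with strain
   $\varepsilon = (L - L_0)/L_0$ measured from the cadaveric length
   $L_0$. $A$ (kPa) is the stress at the reference length; the
   dimensionless exponent $B$ quantifies tissue nonlinearity. Measured
   values run from about 4.4 (rat) to 16.2 (male rhesus monkey).
3. **String modes only.** Gel (continuum) modes, vibration amplitude,
   collision mechanics and acoustic output are outside the model; they
   matter mostly near the lower end of the range.

Dividing the string formula at two lengths and substituting the stress
law gives the range equation the whole package revolves around:

$$\frac{f_{o2}}{f_{o1}} =
  \left(\frac{L_2}{L_1}\right)^{-1}
  e^{\tfrac{1}{2} B (L_2 - L_1)/L_0}.$$

The amplitude $A$ cancels exactly — a property the test suite checks by
chaining `string_fo()` and `fiber_stress()` against `fo_ratio()` on
randomized inputs (agreement to 1e-9 relative). At $B = 0$ the ratio
reduces to $L_1/L_2$: without stress nonlinearity, elongation *lowers*
frequency, the ordinary size principle. Range in octaves is
$\log_2(f_{o2}/f_{o1})$, a surface over the two morphological
variables $B$ and $L_2/L_1$ — the morphospace. The mapping is
many-to-one: very different morphologies (stiff tissue with little
elongation, or compliant tissue with much elongation) reach the same
range.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `rho` | kg/m³ | 1040 | soft-tissue density, ~1.04 g/cm³ |
| `l1_fraction` ($L_1/L_0$) | — | 0.7 | shortest phonatory length measured in humans; exposed everywhere the range equation is used |
| `L2/L1` | — | free | elongation permitted by cricothyroid joint mobility; human limit ~2, measured values 1.2–2.5 |
| `B` | — | free | tissue nonlinearity; measured 4.4–16.2 across species |

External interfaces use the units of the comparative literature — mm,
kPa, kg, Hz — while the frequency formula is evaluated in SI. The
conversion lives in one place (`string_fo()`); nothing else converts.

## Inversions and numerical choices

`required_B()` is a closed form,
$B = 2\ln(r_t \cdot x)/(l_1 (x - 1))$ for target ratio $r_t$ and
elongation ratio $x$. A negative result means the target is reachable on
length change alone; it is returned flagged rather than clipped.

`required_length_ratio()` inverts the range equation numerically with
`stats::uniroot` (bracketed Brent) on $x \in [1, 10]$. Writing
$c = B\,l_1/2$, the surface $e^{c(x-1)}/x$ is strictly increasing on
$x \ge 1$ only when $c > 1/x$ everywhere, i.e. $B > 2/l_1$ (about 2.86
at the default $l_1 = 0.7$). Below that bound the inversion refuses with
an explanatory error instead of silently returning one of two branches.
The bracket cap of 10 is roughly four times the largest elongation ratio
reported in any species; a target outside the bracket raises an
infeasibility error (CLI exit code 3). The root tolerance is 1e-9 so the
round-trip through `achievable_octaves()` holds to 1e-6 octaves even
where the surface is steep. Rounding to presentation precision (octaves
to 2 decimals, ratios to 1) happens only in the CLI layer, never inside
operations.

## The species table and the regressions

The packaged table (`load_species_table()`) holds 16 species from a
0.02 kg bat to a 5000 kg elephant — 20 records, since human, rhesus
monkey, elk and mule deer carry separate male and female rows. Columns:
body mass (kg), cadaveric fold length $L_0$ (mm), stress-law parameters
$A$ and $B$ where measured (11 records), and the observed f0 range where
reported (11 species). Stress laws are stored as two numeric columns,
not expression strings. The elephant length is a literature value rather
than a direct measurement; its source column records only that it is
literature-derived.

Three regression families, all plain OLS (`stats::lm`) — no
phylogenetic correction, matching the analysis being reproduced:

- **Length versus mass** (`fit_length_mass()`): power law fitted on
  log10–log10 scale. The default sex policy is `"average"` (arithmetic
  mean of each trait over the sexes in which it was measured) with all
  16 species included, because that protocol reproduces the published
  coefficients ($L_0 \approx 3.2\,M^{0.40}$, $r^2 = 0.97$); both the
  policy and the inclusion set are ordinary parameters.
- **f0 bounds versus mass** (`fit_fo_bounds()`): the same power-law
  machinery on the 11 ranged species. These two fits are *re-estimated*,
  never asserted from published coefficients: no OLS protocol we could
  construct (sex handling, units, inclusion sets) reproduces the
  published lower-bound exponent of −0.305 — the refit value is about
  −0.40 with comparable $r^2$. The package therefore treats the refit as
  the definitive output, and the test suite pins the refit values.
  Relatedly, the ratio of the two published bound laws is mass-dependent
  (their exponents differ), so no single cross-species "average ratio"
  is computed from them here.
- **B versus length** (`fit_b_length()`): linear on the original scale
  over the nine sex-specific records with a measured stress law,
  excluding the rhesus monkey by default. Both rhesus rows are treated
  as the outlier (both carry extreme $B$); with them included the slope
  p-value rises far above 0.05 and the trend disappears, which the
  package reports rather than hides. Canine mucosa and muscle values
  quoted in the literature are not in the table — the fit takes an
  `include_rhesus` switch, not a hard-coded point set.

`fit_linear()` defines $r^2 = 0$ and $p = 1$ for a constant response
instead of propagating NaN. Records with missing fields are dropped
per-fit and counted in the fit's `excluded` field, never imputed. Slope
p-values are two-sided t-tests on $n-2$ degrees of freedom; the tests
cross-check them against the textbook formula computed by hand.

## What the synthetic generator emulates

`generate_table()` forward-simulates a cross-species table through the
package's own primitives: masses log-uniform over the observed range
(0.02–5000 kg); lengths from the fitted power law
$3.28\,M^{0.4}$ with lognormal scatter (default $\sigma_{\log_{10}} =
0.1$, the right order for the residuals of the real fit); $B$ from the
fitted linear trend $6.285 + 0.0468 L_0$ plus Gaussian noise truncated
at zero; per-species elongation ratios uniform on 1.2–2.5 (the span of
measured values); stress amplitudes log-uniform on 0.5–5.5 kPa (the
span of the real table); and f0 bounds from the string model itself.
The $B$ noise sigma defaults to 1.5, approximately the residual spread
around the real B–length trend; neither the trend's weakness nor its
direction survives at that noise level, which is faithful to the data.
Noise is multiplicative (log10) for lengths — biological scatter in
sizes is multiplicative — and additive for $B$, for which no
distributional information exists.

Two details deserve honesty. First, the printed f0 bounds are ordered
(`fo1 <= fo2`): in the rare low-$B$ draw where the length penalty beats
the stress gain, the raw frequency ratio falls below 1 and the bounds
swap, so generated tables always pass the same validation as real ones.
Second, the generator produces *independent* species — no phylogenetic
covariance, no shared measurement protocols, no within-species
variation. Recovery experiments on synthetic tables therefore show that
the fitting machinery is unbiased under the stated noise model (the
suite checks |bias| < 0.02 on the exponent over 200 replicates at the
study's size of 16 species), not that real comparative data meet those
assumptions.

Determinism: each table is a pure function of its `synthetic_spec`,
whose seed is applied locally (the caller's RNG stream is restored);
replicate seeds in `recovery_experiment()` are `seed + replicate`.

## Problem sizes

The test suite's stochastic components use 25–50 randomized cases per
identity and 200 replicates of 16 species for the recovery experiment —
ample for the ~0.01 Monte Carlo precision the bias check needs, and the
whole suite runs in seconds.

## Known limitations

- The string model ignores gel modes, so predictions near the lower
  bound of a species' range are the least trustworthy.
- $l_1 = 0.7$ is a human measurement applied to all species for want of
  data; the parameter is exposed everywhere precisely because that
  assumption is weak.
- The allometric fits are ordinary OLS on species means; shared ancestry
  is not modelled, so standard errors are optimistic.
- The f0 ranges in the table mix calls, audible repertoires and
  excised-larynx measurements of very different quality; the package
  stores the sources but invents no quality weighting.
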