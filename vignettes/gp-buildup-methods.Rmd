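---
title: "Computing energy-absorption buildup factors with the GP fitting method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing energy-absorption buildup factors with the GP fitting method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpbuildup)
```

## The problem

When a photon beam enters a thick absorber — a shield, a phantom, a human
body — the response at depth is not just the exponentially attenuated
uncollided flux.  Compton-scattered and secondary photons *build up*
behind the attenuation front, and for tissue-like low-Z materials the
deposited energy at tens of mean free paths can exceed the uncollided
estimate by four to five orders of magnitude.  The energy-absorption
buildup factor $B(E, x)$ is the multiplicative correction: the ratio of
the total deposited energy to the energy deposited by uncollided photons
alone, for a point isotropic source of energy $E$ at a penetration depth
of $x$ mean free paths (mfp).

Reference buildup factors exist for elements and a handful of compounds
(the ANSI/ANS-6.4.3-1991 standard), but not for arbitrary mixtures such
as organs and tissues.  This package implements the standard
interpolation route from elemental reference data to an arbitrary
multi-element material, in three steps.

## Step 1: the equivalent atomic number

Buildup is dominated by multiple Compton scattering, so a mixture is
assigned an energy-dependent *equivalent atomic number* $Z_{eq}$ by
matching its Compton-to-total attenuation ratio

$$R(E) = \frac{(\mu/\rho)_{\mathrm{Compton}}}{(\mu/\rho)_{\mathrm{total}}}$$

against the same ratio for pure elements.  The mixture coefficient is
the weight-fraction sum of elemental coefficients.  With $R$ enclosed by
the ratios $R_1, R_2$ of adjacent elements $Z_1, Z_2 = Z_1 + 1$,

$$Z_{eq} = \frac{Z_1(\log R_2 - \log R) + Z_2(\log R - \log R_1)}
                {\log R_2 - \log R_1}.$$

For cortical bone at 0.03 MeV, $R = 0.1313$ falls between aluminium
($R_1 = 0.1438$) and silicon ($R_2 = 0.1145$), giving $Z_{eq} = 13.40$:

```{r}
interpolate_zeq(0.1313, 13, 0.1438, 14, 0.1145)
```

Elements Z = 4–30 are used for bracketing; a ratio outside their span is
a hard error rather than an extrapolation, because the formula is an
interpolation between measured neighbours.  Where the elemental ratio
sequence is non-monotone in Z (it flattens above ~1 MeV), more than one
adjacent pair can enclose $R$; we take the pair with the smallest $Z_1$,
which makes the output deterministic.  Published $Z_{eq}$ tabulations
above 1 MeV may not be exactly reproducible under any single
deterministic rule, which is why the high-energy rows are reported, not
asserted, in our validation.

## Step 2: GP fitting parameters

Elemental libraries in the ANSI/ANS-6.4.3-1991 style tabulate five
geometric-progression (GP) fitting parameters $(a, b, c, d, X_k)$ per
element and per energy on a fixed 25-point grid from 0.015 to 15 MeV
(`standard_energy_grid()`).  Each parameter $P$ is interpolated to the
material's $Z_{eq}$ between the floor and ceiling elements on
$\log Z$:

$$P = \frac{P_1(\log Z_2 - \log Z_{eq}) + P_2(\log Z_{eq} - \log Z_1)}
           {\log Z_2 - \log Z_1}.$$

Adjacent integers are the tightest available bracket, each parameter is
interpolated independently, and an integer $Z_{eq}$ passes the library
row through unchanged.  GP parameters are defined only on the 25 grid
energies; we deliberately do not interpolate them in energy.

## Step 3: the GP buildup formula

$$B(E, x) = \begin{cases}
  1 + (b - 1)\dfrac{K^x - 1}{K - 1}, & K \neq 1\\[4pt]
  1 + (b - 1)\,x, & K = 1
\end{cases}
\qquad
K(E, x) = c\,x^a + d\,\frac{\tanh(x/X_k - 2) - \tanh(-2)}
                           {1 - \tanh(-2)},$$

valid for $x \le 40$ mfp (we refuse to extrapolate beyond that).
$b$ is the buildup factor at 1 mfp and $K$ is the per-mfp dose
multiplication factor.

```{r}
muscle <- reference_gp_params("skeletal_muscle")
grid <- buildup_grid(muscle, depths = c(1, 5, 15, 40))
peak_energy(grid, 40)
```

The deep-penetration buildup of tissue peaks in the Compton-dominated
window (0.05–0.2 MeV), bounded below by $E_{pe}$ (photoelectric =
Compton) and above by $E_{pp}$ (Compton = pair production), both
computed by `crossover_energy()` as roots of the log-coefficient
difference.

## Numerical choices

* **Energy interpolation** of attenuation coefficients is log-log
  linear throughout: the standard scheme for photon cross sections,
  exact for power laws and monotone between nodes.  No splines.
* **Crossover energies** are located by bisection (in log energy, to
  match the interpolant) to a relative tolerance of $10^{-6}$; the sign
  of the log-difference must change exactly once across the grid nodes
  inside the caller's bracket, otherwise the call errors instead of
  silently picking a root.
* **Removable singularity** at $K = 1$: the linear branch is used when
  $|K - 1| < 10^{-8}$, and the two branches agree to better than
  $10^{-6}$ over $x \in \{1, \dots, 40\}$ at $K = 1 \pm 10^{-9}$ (a
  tested invariant).
* **$x = 0$ and $x = 1$** are evaluated by their algebraic identities
  ($B = 1$ and $B = b$): at $x = 0$, $K$ diverges for the common case
  $a < 0$, and at $x = 1$ evaluating the quotient re-rounds
  $1 + (b - 1)$ by one ulp, which would spoil the exact 1-mfp identity
  that the $b$ parameter is defined by.
* **Zeq bracketing ties** (non-monotone elemental ratios) resolve to
  the smallest $Z_1$; an exact elemental match returns a degenerate
  bracket and the element's own Z.
* **Degenerate compositions**: duplicate elements are rejected at parse
  time; raw weight-fraction sums may deviate from 1 by at most
  $2\times10^{-3}$ (printed compositions carry rounding) and are then
  rescaled to sum to 1 exactly.

## The coherent-scattering convention

Reference tabulations do not always say whether the "total" attenuation
coefficient includes coherent (Rayleigh) scattering.  For the ratio $R$
and the crossover energies this package defaults to the total *without*
coherent scattering, since coherent events do not remove photons in the
buildup sense; for the effective atomic number $Z_{\mathrm{eff}}$ of
total photon interaction the customary choice *with* coherent scattering
is the default.  Both conventions are exposed as an argument on every
affected function and recorded in every CLI output header, because
$Z_{eq}$ values above ~1 MeV are visibly sensitive to the choice and
published tables cannot settle it.

## Tissue-equivalence screening

`zeff_curve()` implements the cross-section-ratio method,
$Z_{\mathrm{eff}} = \sigma_a / \sigma_e$ with
$\sigma_a = (\mu/\rho)_m / (N_A \sum_i w_i / A_i)$ and
$\sigma_e = N_A^{-1} \sum_i f_i (A_i/Z_i) (\mu/\rho)_i$ ($f_i$ = number
fractions).  More elaborate interpolation-based $Z_{\mathrm{eff}}$
definitions exist in the literature; we implement the direct ratio
method only, and document rather than resolve the divergence.
`equivalence_bands()` then reports maximal energy runs where a candidate
substitute's $Z_{\mathrm{eff}}$ stays within a tolerance (default 5%
relative — a pragmatic screening choice, configurable) of the organ's.
Compositions of commercial substitutes (MS20, SB3, Alderson materials,
…) are not packaged; users supply composition files.

## Data the package ships, and data it does not

The package ships, at printed precision, published reference
tabulations for the thirteen built-in materials: $Z_{eq}$ and the
energy-absorption GP parameters of the twelve organ/tissue compositions,
water buildup factors (GP method versus the ANSI standard), and
approximate $E_{pe}/E_{pp}/E_{peak}$ values.  These drive regression
tests and the worked examples.

It does **not** ship the elemental inputs those tabulations were derived
from: the ANSI/ANS-6.4.3-1991 GP parameter library is a copyrighted
standard, and element cross sections should come from the user's
XCOM/WinXCom installation.  `read_attenuation()` and `read_gp_library()`
document the CSV schemas; dropping `xcom_elements.csv` and
`ansi_gp_elements.csv` into the package's `extdata` directory activates
the full-pipeline validation tests (water buildup within 0.5% per cell;
tissue $Z_{eq}$ within ±0.02 below 1 MeV).  Until then those two checks
fail with a message saying exactly that — we prefer an honest red over a
silently skipped validation.

## What the synthetic generator emulates — and what it does not

`synthetic_attenuation()` builds element datasets from single power laws
per interaction process (photoelectric $\propto Z^4\!/A \cdot E^{-3}$,
Compton $\propto Z/A \cdot E^{-0.3}$, coherent
$\propto Z^2\!/A \cdot E^{-2}$, pair $\propto Z^2\!/A \cdot \ln(E/1.022)$
above threshold).  This reproduces the structural features the pipeline
relies on — ratios strictly decreasing in Z, positivity, realistic
crossover ordering — and makes every interpolation stage exactly
solvable, so tests can demand $10^{-12}$ recovery of planted values.  It
does not reproduce absorption edges, binding effects on incoherent
scattering, or the true magnitudes of cross sections; passing tests on
synthetic data therefore validate the *numerics*, not agreement with
measured photon data.  The same applies to `synthetic_gp_library()`,
whose parameters are exactly linear in $\log Z$ by construction.
Optional jitter is off by default; enabling it requires a seed, and the
jitter perturbs law constants rather than individual cells so the
analytic structure (and hence the oracles) survive.

Problem sizes in the shipped tests: elements Z = 1–30, a ~100-point
energy grid for synthetic data, the 25-point standard grid for GP work,
depths 1–40 mfp, and all 300 published tissue parameter rows — a
configuration that keeps the full suite near ten seconds while covering
every code path.

## Known limitations

* Energy-absorption buildup only; exposure (air-kerma) buildup factors
  and Berger/Taylor/three-exponential forms are out of scope.
* Depths are capped at 40 mfp (the GP formula's stated domain), and GP
  evaluation is restricted to the 25 standard grid energies.
* One published peak-energy value is not reproducible from the printed
  parameter tables: evaluating the ovary rows at 40 mfp peaks at
  0.15 MeV rather than the published 0.1 MeV — the two buildup values
  differ by under 1%, within the 3-decimal rounding of the printed
  parameters.  Skeletal muscle (0.1 MeV) and cortical bone (0.2 MeV)
  reproduce exactly.
* Recomputing the published water percent-error column from the printed
  buildup columns does not reproduce it exactly (the published values
  were evidently computed before rounding); our comparison asserts the
  recomputed range instead.
* No density handling: depth is in mfp, not centimetres; converting to
  physical depth needs the material density and total coefficient.
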