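---
title: "Mapping a coupled folding-and-binding transition state with Phi-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a coupled folding-and-binding transition state with Phi-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phibind)
```

## The scientific problem

An intrinsically disordered peptide that folds only upon binding its
partner domain passes through a rate-limiting transition state whose
structure cannot be observed directly. Phi-value analysis infers it
indirectly: each residue is mutated, and the effect of the mutation on
the association rate constant is compared with its effect on the overall
binding stability,

$$\Phi = \frac{\ln(k^{\mathrm{ref}}_{\mathrm{ass,fast}} /
                  k^{\mathrm{mut}}_{\mathrm{ass,fast}})}
              {\ln(K_d^{\mathrm{mut}} / K_d^{\mathrm{ref}})}.$$

A Phi near 1 means the residue's interactions are already formed at the
transition state; near 0, not yet formed; negative, the mutation
*speeds* barrier crossing, the signature of nonnative contacts.
`phibind` computes Phi on two parallel branches: an *equilibrium* branch
using the anisotropy-titration $K_{d,\mathrm{Equb}}$ and a *kinetic*
branch using $K_{d,\mathrm{Kin}} = k_{\mathrm{diss}} /
k_{\mathrm{ass,fast}}$; agreement between the branches is itself a
useful internal control.

## The kinetic model

The package's forward model is the induced-fit three-state scheme

$$A + B \overset{k_{on}}{\underset{k_{off}}{\rightleftharpoons}} C
  \overset{k_f}{\underset{k_u}{\rightleftharpoons}} D,$$

with the labelled peptide A, the partner B in pseudo-first-order excess,
an encounter complex C and the folded bound state D. Under
pseudo-first-order conditions the bound subsystem is a 2x2 linear
system; its two relaxation rates are available in closed form
(`eigen_rates()`), and the closed form is validated in the test suite
against numerical eigen-decomposition on a thousand random schemes. The
fast eigenvalue is asymptotically linear in partner concentration with
slope $k_{on}$ — the observed fast association phase — while the slow
eigenvalue is bounded by $k_f + k_u$ and concentration-insensitive,
matching the low-amplitude slow phase seen in stopped-flow experiments
on such systems. Which microscopic transition the experimental slow
phase reports on is not settled; modelling it as the bound-state
isomerization is a choice of this package's simulator, not an
experimental fact.

Two further observables follow from the scheme:

* `equilibrium_kd()`: $K_d = (k_{off}/k_{on}) / (1 + k_f/k_u)$, the
  detailed-balance dissociation constant over both bound states;
* `apparent_koff()`: the slow eigenvalue of the bound system when
  rebinding is blocked by a competitor trap — the quantity a
  competition-dissociation experiment measures as its asymptote.

These differ for three-state schemes. The trap eigenvalue is bounded
above by $k_u$: when mutation pushes $k_{off}$ far above $k_f + k_u$,
escape from D becomes rate limiting and the kinetic branch saturates
while the equilibrium branch keeps weakening. Kinetic and equilibrium
$K_d$ therefore agree closely only while $k_{off} \ll k_f + k_u$. The
default synthetic panel is deliberately parameterized inside that
regime; the one variant outside it carries no kinetic signal at all
(below), which is also how such extreme mutants behave at the bench.

## Rate extraction

* **Traces.** `fit_exponential()` fits one or two exponentials with
  rates parameterized on the log scale (positivity by construction) and
  deterministic initial guesses from the trace itself, so refits are
  bit-reproducible. Model choice is by AICc with a margin of 2
  (`choose_phases()`); two-phase fits whose rates collapse within 5% of
  each other, or whose amplitudes fall below the noise floor, are
  flagged degenerate. Non-convergence flags the result rather than
  raising, because single unusable variants must not halt a panel.
* **Association series.** The fast rates are regressed on concentration
  with $1/\mathrm{SE}^2$ weights; the slope is $k_{\mathrm{ass,fast}}$.
  A negative fitted slope is a hard error (unphysical).
* **Slow phase.** Reported as the mean across concentrations plus the
  p-value of a slope test against zero, so concentration independence
  is a checkable claim rather than an assumption.
* **Competition series.** $k_{obs}(c) = k_{\mathrm{diss}}\,c/(c +
  K_{1/2})$, a saturating hyperbola through the origin; the asymptote is
  $k_{\mathrm{diss}}$. The functional form is a package choice — only
  the asymptote is scientifically interpreted. Constant series leave
  $K_{1/2}$ unidentifiable and are flagged saturated; decreasing series
  are a model-mismatch error; series that have not visibly plateaued
  (max more than 10% above the runner-up) warn.

## Equilibrium branch

Titrations are fit with the depletion-corrected (quadratic) isotherm
via `fraction_bound()`, not the hyperbolic approximation: probe
concentrations comparable to the tightest $K_d$ values otherwise bias
the fit. Anisotropies are averaged directly, with total fluorescence
intensity assumed unchanged on binding. Fits with $K_d$ beyond the
titrated range or relative SE above 50% are flagged poorly determined —
exactly the low-affinity situation in which kinetic and equilibrium
estimates drift apart experimentally.

Residual helicity uses the standard linear two-point calibration of the
222 nm mean residue ellipticity between coil and helix baselines with
temperature and chain-length corrections (`helix_baselines()`); the
constants are documented configuration, since instrument-grade baseline
constants vary between laboratories.

## Phi statistics and reporting rules

* $\Delta\Delta G = RT\ln(K_d^{mut}/K_d^{ref})$, destabilizing
  positive, $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The
  default temperature (298.15 K) is configuration, not a measured value.
* Errors are first-order delta-method propagation on log-transformed
  quantities, validated against $10^5$-sample Monte Carlo in the test
  suite. The correlation induced by the shared reference record is
  ignored (all inputs treated as independent); this is stated in the
  output metadata. A known consequence: the combined SE of
  $\Phi_{\mathrm{Average}}$, $\sqrt{\sigma_1^2+\sigma_2^2}/2$, ignores
  the strong positive correlation between the two branches (they share
  the association-rate numerator) and therefore undercovers; the
  package's own coverage study uses the two branch Phi values, whose
  SEs are the validated delta-method quantities.
* **Reporting filter.** A Phi-value is reported only when *both*
  branches give $\Delta\Delta G \ge 0.34$ kcal mol$^{-1}$ (inclusive
  boundary). Stabilizing mutations are never reportable: the filter is
  written for destabilization, and a near-zero denominator makes Phi
  statistically meaningless.
* **Consistency control.** Variants whose two $\Delta\Delta G$ branches
  disagree by more than twice the combined SE are excluded from the
  reported pattern. An absolute floor of $10^{-4}$ kcal mol$^{-1}$
  keeps machine-precision differences on noiseless data from flagging.
* **Composite surface mutations.** Solvent-exposed positions probed by
  Ala-Gly scanning are reported as the Ala-to-Gly step with the Ala
  variant as reference; the 0.34 filter is applied to this composite
  $\Delta\Delta G$. Thermodynamic-cycle additivity (WT to Ala plus Ala
  to Gly equals WT to Gly) holds to machine precision and is asserted
  in the tests.
* **Classification.** Reportable, consistent Phi values are binned:
  $\Phi + \mathrm{SE} < 0$ (minus a $10^{-8}$ numerical guard) is a
  nonnative-contact candidate; $|\Phi| \le 0.1$ unstructured;
  $\le 0.5$ weakly structured; above, structured. The thresholds are
  interpretive configuration defaults, not measured boundaries.

## The synthetic panel generator

Because no deposited dataset exists for this kind of experiment, the
package generates its own, with ground truth carried alongside. Truth
is expressed directly in the quantities the analysis identifies — the
total destabilization $\Delta\Delta G_{true}$ and the fraction
$\Phi_{true}$ felt by the association rate — and inverted into
microscopic constants: $k_{on}$ scales as $(K_d^{mut}/K_d^{ref})^{-\Phi_{true}}$,
the residual destabilization goes to $k_{off}$, and $k_f$, $k_u$ stay
at wild-type values (encoding the observed insensitivity of the slow
phase to mutation, which the test suite checks stays within 1.5-fold).

The default panel emulates a kinked two-helix disordered peptide:
eleven interface Ala variants across helix A, the interhelical kink and
helix B; six solvent-exposed Ala/Gly positions, three per helix; a
contiguous patch of negative $\Phi_{true}$ in the kink; one
4.1 kcal/mol variant (three orders of magnitude in $K_d$) whose bound
state produces no fluorescence change, so its association fit is
flagged unusable and the variant is excluded from kinetics while its
equilibrium affinity remains measurable. Eleven of the 23 mutant
records clear the dual-branch 0.34 kcal/mol filter by construction.

Numerical design conditions, chosen once:

* Wild-type scheme $k_{on} = 4\times10^6$ M$^{-1}$s$^{-1}$, $k_{off} =
  0.02$ s$^{-1}$, $k_f = 4$ s$^{-1}$, $k_u = 1$ s$^{-1}$ ($K_d$ = 1 nM).
  Two constraints fix this choice: $k_{off} \ll k_f + k_u$ for every
  measurable variant (kinetic/equilibrium agreement, above), and
  $k_{on}B \gg k_f + k_u$ across the concentration series so the fast
  phase stays concentration-dominated — the avoided crossing of the two
  eigenvalue branches must lie below the lowest concentration for every
  variant, or the association slope is biased.
* Stopped-flow series 10-60 uM partner (eight concentrations) at 0.1 uM
  probe; 220-point log-spaced time grid over 1 ms - 2 s, resolving both
  phases; trace noise 2% of the signal range.
* Titrations: 2 nM probe, eleven points log-spaced 1.5 decades below to
  2 decades above the variant's affinity (as an experimenter would
  design after a pilot), plus a blank; anisotropy noise 0.002.
* Competition series: eight concentrations, 0.25-32 times the 1 uM
  half-saturation constant; 3% relative noise on observed rates.
* CD: wild-type residual fraction helix 0.17; Gly variants 0.03 lower,
  interface Ala variants 0.01 lower; 2% noise on ellipticities.

The noise model is i.i.d. Gaussian (relative on competition rates);
real stopped-flow data add dead-time truncation, photobleaching and
heteroscedastic shot noise that the generator does not emulate, so
passing recovery tests demonstrate estimator correctness under the
stated noise model, not instrument robustness.

## Study panels and problem sizes

Two additional fixed configurations support the package's own
validation studies:

* `recovery_panel_config()` — twenty two-state variants with
  $\Delta\Delta G_{true}$ on an even grid over 0.4-4.1 kcal/mol and
  $\Phi_{true}$ spanning -0.2 to 0.5 in reverse order (anti-monotone
  pairing keeps every variant's observed rates inside the simulated
  instrument window). The two-state scheme is used because the kinetic
  and equilibrium definitions of $K_d$ coincide there exactly, making
  recovery error purely estimator error; over this $\Delta\Delta G$
  span a three-state panel would add the $k_u$-ceiling bias discussed
  above. The recovery study runs 100 noise seeds; at zero noise,
  recovery is exact to solver tolerance (observed ~$10^{-15}$).
* `lfe_panel_config()` — a dissociation-dominated two-state panel
  ($\Phi_{true} = 0$ outside the kink, a negative kink patch) used for
  the linear free-energy partition (slopes 1 and 0 for
  $\log k_{\mathrm{diss}}$ and $\log k_{\mathrm{ass}}$ against
  $\log K_d$), the kinetic-vs-equilibrium agreement table, and the
  transition-state classification map. This panel is analysed at zero
  noise so the checks are deterministic oracle comparisons.

## Degenerate inputs and numerical choices

Log-scale parameterization keeps rates and $K_d$ positive without
constrained optimization; SEs are mapped back by the delta method.
Pure-offset traces flag degenerate. Identical Ala/Gly records give
$\Delta\Delta G = 0$ with an undefined Phi, not an error. Equal mutant
and reference $K_d$ in `phi_value()` is a hard error (zero
denominator). Pseudo-first-order violations (partner below 10x probe)
warn rather than error, since the validity threshold is conventional.
Zero-width confidence intervals from noiseless fits carry a $10^{-6}$
relative guard in the $K_d$-agreement table so solver tolerance alone
cannot miss the identity line.

## Known limitations

* The identification of the slow association phase with bound-state
  isomerization is a modelling convention; the pipeline's Phi-values do
  not depend on it (they use only the fast phase and the dissociation
  asymptote), but simulated slow-phase behaviour does.
* Shared-reference correlations are ignored throughout the error
  propagation; Phi SEs for variants compared against a noisy reference
  are mildly conservative on the branch values and anticonservative on
  the averaged value (see above).
* The helicity calculator is a two-point baseline interpolation, not a
  spectrum deconvolution.
* Global multi-trace fitting, dead-time correction and conformational-
  selection schemes are out of scope.
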