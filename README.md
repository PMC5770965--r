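# phibind

Phi-value analysis of coupled folding-and-binding kinetics.

Intrinsically disordered peptides such as the kinase-inducible domain of
a transcription factor fold into helical structure only upon binding a
partner domain. The rate-limiting transition state of that coupled
folding-and-binding reaction cannot be observed directly; Phi-value
analysis infers its structure residue by residue, by asking how much of
each mutation's destabilization is already felt in the association rate:

    Phi = ln(k_ass_fast^ref / k_ass_fast^mut) / ln(Kd^mut / Kd^ref)

with the dissociation constant measured two ways — from equilibrium
anisotropy titrations (`Kd_Equb`) and from the rate constants
(`Kd_Kin = k_diss / k_ass_fast`). Phi near 1: interactions formed at the
transition state; near 0: not formed; negative: the mutation speeds
barrier crossing (nonnative contacts).

`phibind` implements the full analysis as a tested pipeline:

* **Kinetic model** — closed-form relaxation rates, equilibrium and
  trap-apparent dissociation constants of the induced-fit three-state
  scheme A + B &#8652; C &#8652; D, plus an exact trace simulator
  (`kinetic_scheme`, `eigen_rates`, `equilibrium_kd`, `apparent_koff`,
  `simulate_traces`).
* **Trace fitting** — AICc-selected one/two-exponential fits, weighted
  association-series regression for `k_ass_fast`, slow-phase summary,
  and the competition-asymptote fit for `k_diss`.
* **Equilibrium binding** — depletion-corrected anisotropy isotherms
  (`fraction_bound`, `fit_anisotropy_isotherm`) and a residual-helicity
  calculator from 222 nm mean residue ellipticity.
* **Phi statistics** — `delta_delta_g`, `phi_value` and `kd_kin` with
  delta-method error propagation validated against Monte Carlo, the
  dual-branch 0.34 kcal/mol reporting filter, composite Ala-Gly
  treatment of solvent-exposed positions, kinetic/equilibrium
  consistency control, linear free-energy tables and transition-state
  classification (`phi_report`, `lfe_table`, `compare_kd`).
* **Synthetic data** — a seeded mutant-panel generator with ground
  truth (`make_panel`, `generate_dataset`, `generate_cd`), so every
  stage is testable without any external dataset.

## Worked example

The three-state scheme and its observables:

```r
library(phibind)
sc <- kinetic_scheme(k_on = 1e6, k_off = 1, k_f = 5, k_u = 0.5)
eigen_rates(sc, c(5e-6, 1e-5, 2e-5))
#>   partner_conc lambda_fast lambda_slow
#> 1        5e-06     8.00000    3.500000
#> 2        1e-05    11.79436    4.705638
#> 3        2e-05    21.31613    5.183867
apparent_koff(sc)        # 0.0779 s^-1 (competition asymptote)
kinetic_kd_scheme(sc)    # 7.79e-08 M
equilibrium_kd(sc)       # 9.09e-08 M
```

The fast phase grows linearly with partner concentration (slope k_on)
while the slow phase stays below k_f + k_u = 5.5 s^-1; the kinetic and
equilibrium Kd differ by the ratio of the trap eigenvalue to the
detailed-balance off-rate — close, because k_off << k_f + k_u here.

The full pipeline on the default synthetic mutant panel (23 variants of
a kinked two-helix peptide, study-condition noise):

```r
panel <- make_panel()
ds    <- generate_dataset(panel, acquisition_config(), seed = 1)
rates <- fit_panel(ds)
rep   <- phi_report(rates)
#> phi_report: 23 variants in, 11 reportable Phi-values
rep$region_summary
#>    region n phi_mean phi_min phi_max n_negative
#> 1 helix_A 3    0.265    0.22   0.319          0
#> 2 helix_B 5    0.321    0.25   0.415          0
#> 3    kink 3   -0.067   -0.11  -0.032          3
```

Eleven variants destabilize the complex by at least 0.34 kcal/mol on
both the equilibrium and kinetic branch and so yield reportable
Phi-values. All are low (maximum ~0.4): the transition state is largely
unstructured. The interhelical kink shows a contiguous patch of
negative Phi — candidates for nonnative contacts that form only at the
barrier. One strongly destabilized variant (three orders of magnitude
in Kd) gives no stopped-flow signal change; it is flagged and excluded
from the kinetic branch automatically.

A shell front end for the three stages lives at `inst/cli/phibind.R`:

```sh
Rscript inst/cli/phibind.R simulate --out data/ --seed 1
Rscript inst/cli/phibind.R fit      --data data/ --out rates.tsv
Rscript inst/cli/phibind.R phi      --rates rates.tsv --out report/
```

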