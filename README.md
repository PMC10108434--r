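# saltfold

Tools for dissecting the electrostatics of protein folding in highly charged
domains — the kind of acidic protein-interaction module (an SH3 domain with a
net charge near −12 is the motivating case) whose binding surface destabilises
the fold through like-charge repulsion, and which salt stabilises through
Debye–Hückel screening and territorial ion binding.

The package is aimed at protein biophysicists who measure chemical
denaturation and folding kinetics in varying salt, record backbone ¹⁵N
relaxation, run MD simulations with explicit ions, or compare charge
composition across ortholog alignments — and want one tested, scriptable
pipeline from raw curves to the derived thermodynamic, kinetic, dynamic and
evolutionary quantities.

## What it computes

**Equilibrium stability.** Two-state linear-extrapolation fits of
fluorescence denaturation curves,

&nbsp;&nbsp;&nbsp;&nbsp;signal(u) = [F_N + a·u + (F_D + b·u)·K(u)] / (1 + K(u)),&nbsp;&nbsp;
K(u) = exp(−(ΔG° − m_eq·u)/RT),

and the ionic-strength dependence of stability: the Debye–Hückel screening
law ΔG(I) = ΔG° + m_salt·√I fitted against the linear-in-I (direct binding /
Hofmeister) and log-I competitors, ranked by R².

**Folding kinetics.** Single-exponential unfolding traces, the linear
unfolding arm of the chevron plot (ln k_u vs [urea], extrapolated to water),
folding rates from detailed balance k_f = k_u·exp(ΔG°/RT), the Tanford beta
β_urea = 1 − RT·m_ku/m_eq, and the salt Φ-value decomposition

&nbsp;&nbsp;&nbsp;&nbsp;ΔΔG_{D→‡} = −RT·ln(k_f^high/k_f^low),&nbsp;&nbsp;
ΔΔG_{D→N} = −RT·ln[(k_f/k_u)^high/(k_f/k_u)^low],&nbsp;&nbsp;
Φ_f^salt = ΔΔG_{D→‡}/ΔΔG_{D→N},

which locates the salt-sensitive electrostatics on the folding pathway
(Φ > 1: more repulsion in the transition state than in the native state).

**NMR relaxation.** Chemical shift perturbations √((0.1·ΔδN)² + ΔδH²),
off-resonance R1ρ → R2 conversion (R1ρ = R1·cos²θ + R2·sin²θ,
θ = arctan(ν_SL/Ω)), and Lipari–Szabo model-free "model 2" fitting of
¹⁵N R1/R2/NOE: per-residue order parameters S² and internal times τ_e with a
globally optimised isotropic tumbling time τ_c.

**Trajectory ion statistics.** From multi-model PDB trajectories with
explicit ions: per-residue ion-contact fractions (4 Å heavy-atom cutoff to
the charged group), mean numbers of distinct cations/anions in contact per
frame, salt-bridge occupancies (lysine NZ to aspartate CG / glutamate CD),
Kabsch-superposed backbone RMSF, and hydrogen-bond counts.

**Sequence charge.** Net charge profiles (+1 K/R, −1 D/E), ortholog-family
charge statistics with 95% CIs, and a mutual-information covariation scan
with average-product correction, a pooled within-column permutation null and
Benjamini–Hochberg FDR control.

**Synthetic data.** Every input above has a seeded generator
(`sim_equilibrium_curve()`, `sim_unfolding_trace()`, `sim_salt_series()`,
`sim_relaxation_set()`, `sim_toy_trajectory()`, `sim_alignment()`), so the
full pipeline runs and is tested without any external data.

## Worked example

The salt Φ-value for the Fyn R40N SH3 domain from its published rate
constants (k_f 5.5 → 25 s⁻¹ and k_u 0.08 → 0.09 s⁻¹ over a 600 mM NaCl jump,
20 °C):

```r
library(saltfold)
compute_salt_ddG(kf_low = 5.5, kf_high = 25,
                 ku_low = 0.08, ku_high = 0.09,
                 temperature_K = 293.15)
#>   ddG_Ddagger_kJ ddG_Ddagger_se ddG_DN_kJ ddG_DN_se phi_f_salt phi_f_salt_se phi_defined
#> 1          -3.69              0      -3.4         0       1.08             0        TRUE
```

Salt stabilises the transition state (−3.7 kJ/mol) slightly more than the
native state (−3.4 kJ/mol), so Φ_f^salt ≈ 1.1 > 1: the electrostatic
repulsion relieved by salt is already fully present at the transition state.

A synthetic equilibrium melt, fitted and compared across salt models:

```r
curve <- sim_equilibrium_curve(dG0 = 12.4, m_eq = 5, bn_int = 1, bn_slope = -0.01,
                               bd_int = 0.2, bd_slope = 0.005,
                               urea_M = seq(0, 9, 0.5), noise_sd = 0.01, seed = 42)
fit_equilibrium_curve(curve)
#> <two_state_eq_fit>
#>   dG0  = 13.271 kJ/mol (SE 1.31)
#>   m_eq = 5.325 kJ/mol/M (SE 0.416)
#>   Cm   = 2.492 M, RSS = 0.0016, T = 303.15 K

ser <- sim_salt_series(dG0 = 4.4, m_salt = 9,
                       ionic_strength_M = c(0.005, 0.02, 0.08, 0.3, 0.8),
                       noise_sd = 0.2, seed = 42)
compare_salt_models(ser)
#>   model    intercept slope r_squared    rss  rank
#> 1 sqrt_I        4.49  8.99     0.998 0.0768     1
#> 2 linear_I      5.84  8.85     0.950 1.83       2
#> 3 log_I        11.7   1.40     0.880 4.42       3
```

The √I law wins, as it must for data generated under Debye–Hückel screening.
The Tanford beta for an unfolding-arm slope of 0.177 M⁻¹ against an
equilibrium m-value of 5 kJ/mol/M at 30 °C:

```r
compute_beta_urea(m_ku = 0.177, m_eq = 5, temperature_K = 303.15)
#>   beta_urea beta_urea_se
#> 1     0.911            0
```

β_urea ≈ 0.91 means ~91% of the denaturant-sensitive surface burial is
already in place at the transition state — a compact, near-native transition
state. Fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures; `run_pipeline(demo_config(seed = 1))` runs every block end to end
and `write_report()` serialises the result to JSON/CSV.

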