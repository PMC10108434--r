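---
title: "Methods: salt-dependent folding energetics, dynamics and sequence charge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-dependent folding energetics, dynamics and sequence charge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltfold)
```

saltfold analyses the folding of highly charged protein domains along four
experimental axes — chemical denaturation at varying ionic strength, unfolding
kinetics, backbone ¹⁵N relaxation, and ion statistics from simulation
trajectories — plus the evolutionary axis of sequence charge. This vignette is
the package's own account of the models it fits, the parameters that matter,
the numerical choices made, and what the synthetic-data generators do and do
not emulate.

## Two-state equilibrium model

All equilibrium analysis assumes a two-state folder under the linear
extrapolation method (LEM): the unfolding free energy is linear in denaturant,
ΔG(u) = ΔG° − m_eq·u, with ΔG° > 0 meaning the folded state is favoured in
water (sign convention used throughout). The observed fluorescence is the
population-weighted average of two linear baselines:

$$\mathrm{signal}(u) = \frac{F_N + a u + (F_D + b u)\,K(u)}{1 + K(u)},
\qquad K(u) = e^{-(\Delta G^\circ - m_\mathrm{eq} u)/RT}.$$

Six parameters are fitted by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) from a deterministic multi-start grid: baselines are
seeded by linear regression on the curve extremes, and eight (ΔG°, m_eq)
starts combine m_eq ∈ {1, 2, 4, 8} kJ/mol/M with two midpoint guesses (the
mid-signal crossing and the median urea). The start with the lowest residual
sum of squares wins; ties cannot occur in practice because RSS comparisons are
on doubles. Standard errors come from the least-squares covariance matrix.

Degenerate inputs are rejected on three grounds: (i) the signal range must
exceed three times the point noise, estimated model-free from second
differences (sd(Δ²y)/√6); (ii) the fitted baseline separation at the midpoint
must exceed three times the residual SD; (iii) the fitted ΔG° and m_eq must be
identifiable (standard error smaller than the estimate). The third guard
matters for marginally stable proteins: when the midpoint sits below ~1 M
urea the native baseline is sampled by only a couple of points and a
least-squares fit can wander into a meaningless low-RSS solution; reporting
"no transition detected" is the honest outcome there.

Constants: R = 8.314 J mol⁻¹ K⁻¹; energies in kJ/mol; default temperature
303.15 K (30 °C plate-reader conditions), overridable per data set. Ionic
strength is computed as I = ½Σc_iz_i² over listed species only — buffer ions
are excluded unless the caller lists them, matching the convention of
reporting salt-only concentrations.

## Ionic-strength models and design of the stability series

Debye–Hückel screening predicts stability linear in √I; direct ion binding
and Hofmeister effects predict (approximately) linearity in I; a logarithmic
shape is the third competitor. `fit_salt_model()` fits each by ordinary (or
inverse-variance weighted) least squares and `compare_salt_models()` ranks
the three by R², tie-broken by RSS, always reporting all fits.

The package's canonical synthetic stability series uses
I = {0.005, 0.02, 0.08, 0.3, 0.8} M. The choice is a power calculation, not
an aesthetic one: with noise proportional to the dG range (5% in the test
suite), discrimination among the three laws depends only on the geometry of
the I grid, and single-decade grids (e.g. 0.05–0.8 M) leave √I vs linear
ambiguous in a substantial fraction of noisy replicates. Spanning slightly
over two decades — experimentally, a low-salt point near 5 mM up to 800 mM —
gives the comparison enough leverage at the low-I end, where the three
shapes diverge most. The test suite verifies both that noiseless √I data are
recovered exactly and that the √I law is selected in at least 95% of 2000
seeded replicates under this design.

## Unfolding kinetics and the salt Φ-value

Unfolding traces are fitted to offset + amplitude·e^(−kt); starting values
come from a log-linear regression on the baseline-subtracted signal. The
unfolding arm of the chevron is a straight line in (urea, ln k_u); its
intercept extrapolates the water unfolding rate k_u° and its slope is the
kinetic m-value m_ku (M⁻¹). Only the unfolding arm is modelled: refolding
kinetics, chevron curvature and folding-arm fitting are out of scope.

Folding rates follow from detailed balance, k_f° = k_u°·exp(ΔG°/RT), with
first-order (delta-method) error propagation from the regression covariances.
The Tanford beta is computed on the free-energy scale,

$$\beta_\mathrm{urea} = 1 - \frac{RT\,m_{ku}}{m_\mathrm{eq}},$$

the standard convention in which β is the fraction of the equilibrium
m-value accrued between the denatured and transition states; RT converts the
ln-rate slope m_ku onto the kJ/mol/M scale of m_eq.

The salt decomposition compares two conditions at one temperature:
ΔΔG_{D→‡} = −RT·ln(k_f^high/k_f^low) and
ΔΔG_{D→N} = −RT·ln[(k_f/k_u)^high/(k_f/k_u)^low], with
Φ_f^salt = ΔΔG_{D→‡}/ΔΔG_{D→N}. Φ is a ratio of logarithms, hence exactly
temperature-invariant — asserted numerically to 1e−12 in the tests. When
|ΔΔG_{D→N}| falls below 0.1 kJ/mol the ratio is meaningless and Φ is
returned as `NA` with a `phi_defined = FALSE` flag rather than an error.
Because the equilibrium constant can also be measured directly, the
denominator may alternatively be supplied from equilibrium fits
(`ddG_DN_equilibrium`), and both Φ routes are then reported; they coincide
exactly when K_eq = k_f/k_u, and differ in real data by the extent to which
kinetics and equilibrium disagree. Energy diagrams report only
prefactor-free differences (barrier shifts and ΔG_{D→N}), never absolute
barrier heights.

In the full-pipeline recovery test, traces are sampled at 10 Hz over one
minute with amplitude-to-noise 50 — a plate-reader-realistic design under
which the water unfolding rate, extrapolated from five urea points on the
7–9 M limb, is recovered with median relative error below 3%.

## NMR relaxation: model-free "model 2"

Chemical shift perturbations use the standard weighting
√((0.1·ΔδN)² + ΔδH²). Off-resonance rotating-frame rates are converted by
R2 = (R1ρ − R1·cos²θ)/sin²θ with θ = arctan(ν_SL/Ω); Ω → 0 gives θ = 90° and
R2 = R1ρ, and inputs implying R2 ≤ 0 are rejected as inconsistent.

The dynamics model is Lipari–Szabo "model 2": a generalised order parameter
S² ∈ [0, 1] and one internal correlation time τ_e per residue, with isotropic
global tumbling τ_c shared across residues,

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
  + \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right],\qquad
  \tau^{-1} = \tau_c^{-1} + \tau_e^{-1},$$

entering the standard dipolar + CSA expressions for ¹⁵N R1, R2 and NOE.
Constants are kept in one table (`saltfold_constants()`): γH = 2.675e8,
γN = −2.713e7 rad s⁻¹ T⁻¹, r_NH = 1.02 Å, Δσ = −160 ppm; the default field
is 600 MHz (14.1 T). Spectral densities are evaluated at frequency
magnitudes; the sign of γN enters only through the γH/γN factor in the NOE,
which is what makes ¹⁵N NOEs ≤ 1. Exchange terms (models 3–5) and the
axially symmetric diffusion tensor are not implemented; anisotropic tumbling
would require bond-vector orientations that the package's CSV interface does
not carry, and is recorded as an extension.

Fitting minimises χ² = Σ[(obs − calc)/σ]² with per-rate σ from the input
(equal weights when absent). Per residue, (S², τ_e) is found at fixed τ_c by
bounded Levenberg–Marquardt, multi-started from a coarse grid that
deliberately stays off the S² = 1 boundary — at S² = 1 the internal term
vanishes, τ_e drops out of the model, and the resulting degenerate ridge is
a spurious local minimum that traps single-start optimisers. The global τ_c
is then a one-dimensional Brent search on [1, 20] ns over the profiled χ²,
run in two stages: a coarse pass, then a refinement parametrised as an
offset from the coarse minimum. The offset trick matters because Brent's
attainable precision has a √ε·|x| floor (~1e−7 relative at τ_c ≈ 6 ns), and
τ_c error is amplified severalfold into τ_e through parameter compensation;
with the two-stage search the zero-noise round trip recovers all of S², τ_e
and τ_c to better than 1e−6 relative, which the acceptance suite asserts.
Residues with R2 < R1 — impossible for nanosecond tumbling — are excluded
with a warning before fitting.

## Trajectory ion statistics

Trajectories are multi-model PDB files (MODEL/ENDMDL) read and written via
bio3d; ions are recognised by residue name across common dialects (NA+/NA/
SOD, K+/K/POT, CL-/CL/CLA) rather than by record type, since PDB writers
disagree on ATOM vs HETATM for ions. Charged groups follow standard naming:
lysine NZ; aspartate CG/OD1/OD2; glutamate CD/OE1/OE2. Salt-bridge distances
use the single NZ-to-distal-carbon (CG/CD) distance; ion contacts by default
count any atom of the charged group within the cutoff (an OR over the group),
with a strict bridge-atom-only rule available as an option. The cutoff
defaults to 4 Å, heavy atoms only.

All fractions are computed per run and summarised as mean ± SD across
independent runs, mirroring how repeat simulations are reported. The
vectorised implementation is required by the test suite to agree *exactly*
with a brute-force all-pairs distance oracle on small fixtures, and all
fraction statistics are invariant to rigid motion of every frame.

Backbone RMSF superposes each frame onto the ensemble mean by Kabsch SVD in
two passes (fit to the mean, recompute the mean, fit again) — the reference
choice is stated because trajectory tools differ here — then averages
per-atom RMSF over the backbone selection (N, CA, C, O) within each residue.
Hydrogen bonds are counted between donor heavy atoms (N/O with a hydrogen
assigned by proximity within 1.2 Å in the first frame) and N/O acceptors in
other residues, at defaults of 3.0 Å donor–acceptor distance and 135°
donor–H–acceptor angle; both are configurable since the criterion is a
convention, not a measurement. Input trajectories are assumed pre-imaged; no
periodic-boundary handling is attempted.

## Sequence charge and covariation

Net charge counts +1 for K/R and −1 for D/E at neutral pH; histidine,
termini and pKa shifts are ignored — the integer-counting style standard for
comparing surface charge across homologs. Alignment charge summaries ignore
gaps and report a normal-approximation 95% CI on the family mean.

Covariation uses mutual information (bits) over column pairs, gaps as a 21st
symbol, with the average-product correction
MI_apc = MI − MI_i·MI_j/MĪ to strip shared-background signal. Since the
field has no single standard here, the method is deliberately transparent:
significance comes from a permutation null built by shuffling every column
independently, and the shuffled APC statistics of *all* pairs are pooled
into one null distribution. The pooling is the key design choice: a per-pair
null of B permutations bounds p-values below by 1/(B+1), so no pair could
ever clear Benjamini–Hochberg across ~1,770 pairs without B in the tens of
thousands; pooled statistics are exchangeable across pairs under the
independence null and give p-value resolution 1/(B·P+1) at B = 1000 default
permutations. P-values use the add-one rule and ties count against
significance, keeping them conservative. Benjamini–Hochberg then controls
the FDR across pairs.

One property of FDR control is worth stating plainly: with a single true
positive and calibrated p-values, the probability that *some* null pair is
also declared significant at q < 0.05 is ≈ 1 − e^(−2·0.05) ≈ 9.5%,
independent of the number of pairs. Detection of a genuinely covarying pair
is essentially certain on 262-sequence alignments (the tests require ≥ 95%
over 100 seeds and observe it at the top rank), but "exactly one pair
significant" cannot be guaranteed at the 95% level by any honest BH
procedure; occasional single false positives are the price of FDR rather
than FWER control.

## The synthetic-data generators

Each generator draws from one seeded RNG stream and restores the caller's
RNG state, so identical (seed, parameters) give byte-identical output. Noise
is i.i.d. Gaussian on the measured quantity — fluorescence signal, ΔG, or
(relative) relaxation rates — the model under which least squares is the
maximum-likelihood fit. Defaults mirror the study conditions the package
targets: marginal stability (ΔG° = 4.4 kJ/mol) against a salt-stabilised
condition, m_eq = 5 kJ/mol/M, unfolding rates near 0.1 s⁻¹, τ_c = 5.76 ns at
600 MHz, 262-sequence ortholog alignments over 60 columns with a planted
covarying pair at positions (40, 47) and a mean net charge of −10.

The generators emulate the *statistical structure* the analyses assume, not
the underlying physics. Toy trajectories place ions at 3 Å (inside the 4 Å
cutoff) or 8 Å (outside) of their target group by Bernoulli draws — geometry
is a vehicle for occupancy, nothing more; there is no force field, no water,
no correlation between frames. Alignments have independent columns apart
from one deterministic complementary pair, a consensus-plus-minor-variants
background (85/10/5 by default), fixed charged columns that set the target
charge exactly, and two balanced K/E columns that give the per-sequence
charge a variance of 2 about the target; real ortholog families have
phylogenetic correlation, indels and composition drift that none of this
captures. A passing test suite therefore certifies the estimators — round
trips, calibration, invariances — not the realism of any simulated data set.
Relaxation noise is relative (a fraction of each rate), reflecting how rate
uncertainties scale in practice; the fluorescence noise magnitude is a free
parameter, as no canonical value exists.

## Pipeline and reproducibility

`run_pipeline()` executes the blocks in dependency order (equilibrium before
kinetics, so derived folding rates use fitted stabilities; traces before
arms), isolates block failures, and seeds every generator from the single
config seed, making reruns byte-identical. Reports carry a config hash, the
seed and the package version, serialise losslessly to JSON at full double
precision, and export CSV tables including a per-condition folding summary
(condition, ku, kf, beta_urea, phi_f_salt). Validation reports every problem
in a config at once rather than failing on the first. The test-suite problem
sizes (e.g. 100-seed recovery sweeps, 2000-seed model selection, 200
permutations in the acceptance covariation scan against a default of 1000)
are chosen so the whole suite runs in a few minutes on one CPU while keeping
Monte-Carlo error well inside the asserted margins.

## Known limitations

- Strictly two-state equilibrium and single-exponential kinetics: no
  intermediates, no chevron curvature, no folding arm.
- Isotropic tumbling only in the model-free fit; no R_ex/exchange terms.
- Ion statistics assume pre-imaged trajectories and heavy-atom geometry;
  hydrogen-bond donor assignment needs explicit hydrogens.
- Charge counting ignores histidine and pH; covariation MI on fewer than
  ~20 sequences is meaningless and is refused.
- The energy-diagram barrier heights are relative by construction; absolute
  barriers would require a kinetic prefactor the data do not determine.
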