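---
title: "Absolute binding free energies with abfe: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute binding free energies with abfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfe)
```

## The thermodynamic cycle

`abfe` analyses absolute binding free-energy calculations organised around a
six-state alchemical cycle. The fully interacting ligand in solution (A) is
decoupled from its environment — charges annihilated, van der Waals
interactions switched off through a soft core — giving
$\Delta G_{\mathrm{solv}}^{\mathrm{elec+vdw}}$ (A→B). The non-interacting
ligand is then restrained (B→C); because nothing interacts, the free energy of
imposing a six-degree-of-freedom harmonic restraint at standard concentration
has a closed form (below). State C is equivalent to the non-interacting,
restrained ligand inside the receptor (D). Recoupling the ligand in the
restrained complex gives $\Delta G_{\mathrm{prot}}^{\mathrm{elec+vdw}}$ (D→E),
and releasing the restraint in the fully coupled complex gives
$\Delta G_{\mathrm{prot}}^{\mathrm{restr}}$ (E→F). The standard binding free
energy is the signed sum

$$\Delta G^\circ_{\mathrm{bind}} =
  \Delta G_{\mathrm{solv}}^{\mathrm{elec+vdw}} +
  \Delta G_{\mathrm{solv}}^{\mathrm{restr}} +
  \Delta G_{\mathrm{prot}}^{\mathrm{elec+vdw}} +
  \Delta G_{\mathrm{prot}}^{\mathrm{restr}} + \sum_i c_i,$$

with $c_i$ additive corrections (finite-size charge corrections, long-range
dispersion). Corrections are *input slots*: computing them requires
Poisson–Boltzmann or molecular-dynamics machinery outside this package's
scope, but their application — including the warning when the per-frame
spread of a charge correction reaches 0.05 kcal/mol — is implemented
(`apply_charge_correction()`). The reported uncertainty is the root sum
square of the leg uncertainties, which treats legs as independent; within one
environment the two complex legs share a simulation and are in fact
correlated, so the root-sum-square is mildly conservative there.

Leg ordering is a genuine design choice the cycle does not fix: we restrain
the ligand in the complex at full coupling first, then annihilate charges,
then decouple the van der Waals interactions. Turning charges off before the
repulsive cores vanish avoids bare point charges overlapping other sites, and
restraining before any decoupling keeps the ligand defined relative to the
receptor throughout.

## Lambda schedules

`build_lambda_schedule()` produces the ladder of
$(\lambda_{\mathrm{restr}}, \lambda_{\mathrm{coul}}, \lambda_{\mathrm{vdw}})$
triples for one environment. Defaults follow the protocol the package's
benchmark data were produced with: coulomb spacing 0.1, van der Waals spacing
0.05, and a 12-value non-uniform restraint ladder
`r paste(default_restraint_lambdas, collapse = ", ")` concentrated near zero,
where the restraint free-energy derivative is largest. Boundary states shared
by consecutive legs are counted once, giving 42 complex and 31 solvent
windows:

```{r}
nrow(build_lambda_schedule("complex"))
nrow(build_lambda_schedule("solvent"))
```

## Decorrelation

Window time series are correlated. `statistical_inefficiency()` estimates
$g = 1 + 2\tau$ by summing normalized autocovariances with the triangular
$(1 - t/N)$ factor, truncating at the first non-positive autocorrelation —
the standard fast estimator; a constant series returns $g = 1$ by convention.
`prepare_samples()` drops the first `floor(discard_fraction * n)` frames of
each window as equilibration (the protocol's default is 10%), then thins with
stride $\lceil g \rceil$ from the first retained frame. An integer stride
trades a few retained samples for a deterministic, exactly reproducible index
set; fractional-index thinning would retain marginally more data but makes
index sets depend on floating-point rounding.

## MBAR

`mbar_solve()` implements the multistate Bennett acceptance ratio on the
cross-evaluated reduced potentials $u_{kl n} = U_l(x_{kn})/k_BT$: the
dimensionless free energies satisfy

$$f_k = -\ln \sum_{n=1}^{N}
  \frac{e^{-u_{kn}}}{\sum_l N_l \, e^{f_l - u_{ln}}},$$

solved by self-consistent iteration with log-sum-exp stabilization, switching
to a damped Newton step on the sampled-state subspace when the update stalls
(the iteration is linearly convergent and slows badly at weak overlap; the
objective is convex, so Newton with step halving is safe). Convergence is
declared at $\max_k |\Delta f_k| < 10^{-10}$ and $f_1 \equiv 0$. States with
no samples are evaluated as perturbation states. The solver reports the state
overlap matrix and flags fits where consecutive states share essentially no
phase space. An information-matrix covariance (`mbar_covariance()`) is
available as a diagnostic only: reported uncertainties always come from the
bootstrap, because asymptotic MBAR errors are known to understate the true
spread on correlated data.

## Bootstrap uncertainties and repeats

`bootstrap_free_energy()` builds `n_boot = 200` replicates: replicate 1 is
the unresampled data, and each further replicate resamples the decorrelated
samples with replacement *independently within each sampling state*,
preserving the per-state counts. The reported value is the replicate mean and
the uncertainty the replicate standard deviation, converted with $k_BT$ at
the data temperature. Resampling decorrelated (not raw) frames is the reading
consistent with bootstrapping "uncorrelated data"; resampling raw frames
would re-introduce the autocorrelation the subsampling removed.

Even so, a single-run bootstrap tends to understate run-to-run variability,
since it cannot see slow modes a single trajectory never crossed.
`combine_repeats()` therefore pools the replicate
sets of independent repeats — three repeats of 200 give a pool of 600 — and
reports the pool's mean and sample standard deviation, capturing both the
estimator's statistical error and the between-repeat spread.

Every public stochastic operation takes one integer seed; internal streams
(solvent/complex sampling, per-leg bootstraps) are derived from it by fixed
offsets, so a pipeline run is bit-reproducible from a single integer.

## The Boresch restraint and its analytic free energy

The restraint fixes one distance $r$ (receptor anchor P1 to ligand anchor
L1), two angles $\theta_A, \theta_B$ and three dihedrals
$\phi_A, \phi_B, \phi_C$ with harmonic potentials; dihedral deviations are
wrapped to $(-180^\circ, 180^\circ]$ before squaring. In the stiff-spring
limit the cost of restraining a non-interacting ligand at standard
concentration is

$$\Delta G_{\mathrm{restr}} = k_BT \ln\!\left[
  \frac{8\pi^2 V^\circ \sqrt{K_r K_{\theta_A} K_{\theta_B}
        K_{\phi_A} K_{\phi_B} K_{\phi_C}}}
       {r_0^2 \sin\theta_{A0} \sin\theta_{B0} \,(2\pi k_BT)^3}\right],$$

with $V^\circ = 1660.539\,\text{Å}^3$ (1 mol/L). The formula diverges as
reference angles approach 0 or 180°, and the implementation raises a
singularity error there.

`boresch_quadrature_dG()` evaluates the same quantity without the stiff
approximation: the restrained configurational integral factorizes over the
six internal coordinates with Jacobian $r^2 \sin\theta_A \sin\theta_B$, so
each factor is a one-dimensional adaptive quadrature over its full domain.
The two routes differ by a real Jacobian correction of order $k_BT^2/K$ per
bending angle: at the conventional force constant of 10 kcal/mol/rad² and
298.15 K the exact integral is about 0.034 kcal/mol above the analytic
formula, shrinking to below 0.01 kcal/mol only for $K \gtrsim 70$. The
package reports the analytic value (the field's convention, and what the
benchmark protocol used) and exposes the quadrature as a check; the residual
stiff-spring bias at $K = 10$ should be kept in mind when it matters.

A note on units: force constants printed as "10 kcal mol⁻¹ Å⁻² [deg⁻²]" are
ambiguous for the angular terms — per square degree is a factor
$(180/\pi)^2 \approx 3283$ stiffer than per square radian. The constructor
accepts either declaration (`angle_k_unit`) and canonicalizes to rad⁻²; the
package default and all internal arithmetic use rad⁻².

## The toy host–guest generator

`toy_model()` defines the synthetic system the estimators are validated on:
a rigid triatomic guest (only rigid-body translation/rotation are sampled)
interacting with three fixed host sites through Lorentz–Berthelot-combined
Lennard-Jones terms and Coulomb charges in a 20 Å cubic box, plus the Boresch
restraint anchored at a reference bound pose. Defaults were chosen once to
look like a weak, realistic host–guest binder: well depths of 0.3–0.5
kcal/mol per site pair, σ = 3 Å, partial charges of ±0.06–0.12 e, giving a
bound-pose interaction energy near −2 kcal/mol and
$\Delta G^\circ_{\mathrm{bind}} \approx -1.1$ kcal/mol — micromolar-scale
affinity, deep enough that the coupling legs are non-trivial and shallow
enough that both sampling and the brute-force oracle converge on a desk.
Restraint force constants default to 10 kcal/mol/Å² (rad⁻²), the
conventional choice.

The decoupling of the vanishing interactions uses a Beutler-type soft core
with $\alpha = 0.5$ and linear λ prefactor,

$$E_{\mathrm{vdw}}^{\mathrm{sc}}(r;\lambda) = \lambda\, 4\varepsilon\left[
  \frac{\sigma^{12}}{(\alpha\sigma^6(1-\lambda) + r^6)^2} -
  \frac{\sigma^6}{\alpha\sigma^6(1-\lambda) + r^6}\right],$$

finite at $r = 0$ for every $\lambda < 1$. Coulomb interactions are scaled
linearly and, by the leg ordering above, are only ever non-zero while the
repulsive cores are fully present, so no charge–core singularity arises.

Sampling uses Metropolis Monte Carlo — one translation (±0.75 Å per axis)
and one rotation (±25° about a random axis through the first guest site) per
replica per sweep — rather than molecular dynamics: the statistical target, a
Boltzmann ensemble per λ state, is identical, and MC needs no force
evaluation. One replica runs per state; every 100 sweeps an exchange round
performs $2K^2$ random state-pair swap attempts with Metropolis acceptance on
reduced-potential differences, approximating Gibbs-sampling state mixing. The
sampler reports neighbour-pair swap acceptance and the probability that a
replica changes state per round; on the default coarse complex ladder these
land around 0.3–0.9 and 0.77 respectively. No periodic images are applied to
the guest–host interaction — the box only bounds translation — so finite-size
electrostatics enter only through the correction input slots.

Two oracles provide ground truth. `sample_gaussian_states()` draws exactly
from a ladder of harmonic states with known
$f_k = -\ln(\sigma_k\sqrt{2\pi})$, isolating the estimator from the sampler.
`quadrature_binding_dG()` integrates the fully coupled, unrestrained guest
over the box and all orientations by stratified Monte Carlo (default: a
10×10×10 translation grid with 2000 random orientations per cell) and
returns $-k_BT\ln[V_{\mathrm{box}}\langle e^{-U/k_BT}\rangle / V^\circ]$
with a standard error; it refuses to report if the relative error of the
integral exceeds 1%. With all interactions zeroed both the pipeline and the
oracle must give exactly $-k_BT\ln(V_{\mathrm{box}}/V^\circ)$
(−0.932 kcal/mol for the 20 Å box), a closed-form sign-convention check for
the whole cycle.

What the toy does *not* emulate: explicit solvent (the solvent legs are
exactly flat), conformational flexibility of ligand or receptor, realistic
force-field roughness, and periodic electrostatics. Passing the validation
suite therefore demonstrates that the *analysis machinery* — schedules,
decorrelation, MBAR, bootstrap, cycle assembly, sign conventions — is
correct, not that any particular molecular system is well sampled.

## Validation problem sizes

The package validates itself at deliberately desk-scale sizes: estimator
consistency on two-state Gaussian problems with 50,000 samples per state and
200 bootstrap replicates; end-to-end cycle validation on coarse ladders (16
complex / 10 solvent states) with 20,000 sweeps per state, 200 bootstrap
replicates, and 20 independent seeds, compared to the quadrature oracle at
the three-combined-standard-deviation level (at least 19 of 20 seeds must
agree). Because the assembled cycle uses the analytic restraint term, the
stiff-spring correction discussed above is expected to appear as a small
positive offset of order 0.03 kcal/mol against the oracle, well inside that
statistical tolerance at these run lengths.

## Benchmark statistics

`benchmark_summary()` reproduces the accuracy/precision summary of the
packaged BRD4(1) inhibitor set: MAE, RMSE, Pearson's r and Spearman's ρ
(midranks for ties) of calculated against experimental standard binding free
energies, each with a paired bootstrap over ligands. From the one-decimal
stored values the crystal-structure campaign gives MAE 0.6 and RMSE 0.8
kcal/mol, the docking campaign 1.0 and 1.4 kcal/mol, and the docking *scores*
an RMS error of 4.2 kcal/mol — docking finds poses well but ranks affinities
poorly. Plug-in correlations computed from the rounded stored values
(r ≈ 0.87, ρ ≈ 0.86 for the crystal campaign) are a little above the
originally reported 0.84/0.82, which were presumably computed from unrounded
values and/or reported as bootstrap means; both plug-in and bootstrap columns
are therefore reported side by side and only the plug-in value is treated as
the statistic of record. Similarly, a ligand-resampling bootstrap puts the
spread of the crystal-campaign MAE at ≈0.2 kcal/mol; how the originally
reported ±0.1 was obtained is not stated anywhere we can verify, so the
package reports what its own estimator defines. Summary statistics are always
recomputed from the free-energy columns, never from stored difference
columns, which carry rounding artifacts.

Ligand 11's experimental value comes from a single measurement; its missing
uncertainty is stored as `NA`, not zero, so nothing downstream mistakes
"unreported" for "exact".

For a ligand with several plausible binding modes,
`combine_binding_modes()` combines per-mode results through the sum of
binding constants, $\Delta G = -k_BT\ln\sum_i e^{-\Delta G_i/k_BT}$
(log-sum-exp stabilized). The combined value can only be strengthened by
adding a mode, and collapses to the best mode when the others are far weaker.
Mode uncertainties are propagated by redrawing one bootstrap value per mode
and recombining (10,000 seeded draws); nothing in the combination itself
says how the uncertainty *should* be propagated, and this choice keeps the
full replicate distributions in play rather than assuming normality.

## Configuration and interfaces

Energy tables travel as TSV (header `state` plus one column per evaluated
state, one row per sample) or as an xvg-style dialect that ignores `#`/`@`
lines. Temperatures are supplied in configuration, never inferred from files.
Run configurations are YAML — one schema covering legs, restraint (with its
force-constant unit declared), temperature, estimator settings and
corrections; YAML was chosen as the single configuration syntax supported by
the installed stack. Results serialize to JSON in kcal/mol; reduced
(dimensionless) energies appear only internally. A thin command-line wrapper
(`run_cli()`, installed as `inst/scripts/abfe`) exposes `schedule`,
`estimate`, `cycle`, `combine-modes`, `simulate-toy` and `benchmark`
subcommands with exit codes 0/1/2 for success/computation error/usage error.

## Known limitations

- Only MBAR is provided; no thermodynamic integration or exponential
  averaging, and only a single equilibration cut per window.
- The analytic restraint term is the stiff-spring limit; at soft force
  constants (≲ 70 kcal/mol/rad²) it carries an O($k_BT^2/K$) bias that the
  quadrature check quantifies but the reported cycle does not remove.
- Bootstrap uncertainties from a single run understate run-to-run spread;
  pooling repeats via `combine_repeats()` is the supported remedy.
- The toy generator validates the analysis, not molecular realism: no
  solvent, no flexibility, no periodic electrostatics.
- Restraint anchor atoms are inputs; the package does not select them from
  structures, and no trajectory parsing is provided — energies arrive as
  tables.
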