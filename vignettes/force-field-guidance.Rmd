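---
title: "Force-field guidance for 3D molecular generation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field guidance for 3D molecular generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

3D generative models for structure-based drug design — flow-matching and
diffusion architectures that place atoms directly in a protein pocket —
are trained on data likelihood alone. Nothing in that objective knows
about bond-stretch stiffness or steric repulsion, and the generated poses
show it: strained rings, compressed contacts, torsions far from any
rotamer. The standard remedy is to minimize every generated pose with a
classical force field afterwards. `ffguide` moves that physics *into* the
sampling loop instead: at every step the model's current estimate of the
final structure is nudged down the gradient of a molecular-mechanics
energy, so the trajectory itself is steered toward physically plausible
conformations. The generator is never retrained; the guidance is a
plug-in at inference time.

## The potential

The guiding energy couples a ligand $X$ to a rigid pocket $Y$:

$$E(X,Y) \;=\; \mathrm{MMFF94}(X) \;+\; E_{\mathrm{vdW}}(X,Y) \;+\; E_{Q}(X,Y).$$

MMFF94 was chosen over protein force fields (AMBER/CHARMM) because the
energy must be evaluated and differentiated hundreds of times per
generated molecule; MMFF94 is parameterized for exactly the drug-like
chemistry being generated and is cheap. The pocket is a *model system*:
its atoms are typed with element-level MMFF94-style nonbonded parameters
and carry fixed partial charges read from the input (a charge sidecar or
PQR column, with a Gasteiger fallback); those charges are never
recomputed during a run.

### Intramolecular terms

`energy_intra()` implements the seven MMFF94 terms over a parameter set
extracted by the RDKit typing machinery (`parameterize()` shells out to a
bundled adapter script once per molecule; parameters depend only on the
graph, not the conformation, so one set serves a whole trajectory):

* cubic bond stretch, $\tfrac{143.9325}{2} k_b\,\Delta r^2 (1 - 2\Delta r
  + \tfrac{7}{3}\Delta r^2)$;
* cubic-corrected angle bend in degrees with constant $-0.006981317$
  (the value the reference implementation uses, which the textbook
  rounds to $-0.007$), and the linear-angle special case
  $143.9325\,k_a(1+\cos\theta)$;
* stretch–bend coupling;
* Wilson out-of-plane angle at trigonal centers;
* three-fold torsion cosine series;
* buffered 14-7 van der Waals with the donor–acceptor-scaled pair
  parameters;
* buffered Coulomb, dielectric $D = 1$, buffer $\delta = 0.05$ Å,
  distance exponent 1, 0.75 scaling on 1-4 pairs.

Pairs separated by one or two bonds are excluded from both nonbonded
terms; everything else interacts — there are no distance cutoffs
anywhere, including across the protein–ligand interface. Equivalence
with the reference implementation is not assumed but *tested*: over a
100-molecule fixture panel the absolute total-energy deviation stays
below $10^{-4}$ kcal/mol (in practice $\sim 10^{-13}$).

### Cross-terms

`cross_energy()` sums the same buffered 14-7 and buffered Coulomb forms
over all ligand × pocket atom pairs. The minimum-energy radius follows
the MMFF94 combination rule
$R^*_{ij} = \tfrac12 (R^*_i + R^*_j)\,(1 + 0.2(1 - e^{-12\gamma^2}))$;
the well depth uses the geometric mean
$\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}$. The exact MMFF94
well-depth rule requires atomic polarizabilities, which a per-atom
$(\epsilon, R^*)$ pocket table cannot carry; the geometric mean is the
standard fallback when only per-atom well depths are available, and the
cross-term kernel is verified against an independent scalar transcription
of both formulas rather than against the toolkit. The pocket is rigid:
`gradient_total()` differentiates with respect to ligand coordinates
only.

### Gradients

All derivatives are analytic (hand-derived, vectorized over term tables)
rather than produced by an autodiff framework; the contract is the same —
central finite differences (step $10^{-5}$ Å) agree to a relative error
below $10^{-5}$, and the net force under rigid translation vanishes to
$10^{-8}$. Degenerate geometries (coincident atoms, collinear angles) are
guarded by small epsilons in the distance and angle kernels and tested
for NaN-freedom; the guards sit at $10^{-12}$ Å (distances) and
$10^{-8}$ (sines), far below chemically meaningful scales.

## The samplers

Both samplers use clean-sample prediction: the network (here, a toy
denoiser) maps a noisy state $X_t$ and time $t \in [0,1]$ to an estimate
$\hat X_1$ of the final structure. That choice is what makes energy
guidance natural — a molecular energy is only meaningful on a plausible
structure, and $\hat X_1$ is the best available one at every step.

**Flow matching** (`flow_sample()`): Euler integration of the recovered
vector field $u = (\hat X_1 - X_t)/(1 - t)$ with uniform steps. The
$1/(1-t)$ factor is finite at the last step ($t = 1 - \Delta t$); the
denominator is nevertheless clamped at $10^{-6}$ as a guard.

**Diffusion** (`diffusion_sample()`): a discrete schedule of $T$ steps
with time relabeling $\tau(t) = \lfloor T(1-t)\rceil$, cosine
$\bar\alpha$ by default ($T = 100$; both configurable). Each iteration
denoises, optionally corrects $\hat X_1$, and draws the previous state
from the Gaussian forward-process posterior (`compute_posterior()`) with
the standard mean coefficients and variance derived from the
$\bar\alpha$ sequence. The terminal step has zero variance and returns
$\hat X_1$ exactly. One honest numerical note: the posterior mean with
$\hat X_1 = X_t$ equals $X_t$ only approximately — the two coefficients
sum to 1 exactly at the terminal step and drift from 1 toward the noisy
end of the schedule. That is a property of the standard closed form, not
an implementation artifact, and the tests pin the coefficients against
an independent scalar recomputation at every step.

**Guidance injection** (`guidance_step()`): the correction
$\hat X_1 \leftarrow \hat X_1 - \lambda g$ is applied to the clean-sample
estimate *before* the Euler or posterior update, at every step within a
configurable time window (default: the whole trajectory; the window
exists because it is an open modelling choice whether early, highly noisy
estimates deserve guidance). Guidance touches coordinates only;
categorical atom/bond state passes through unchanged. If a mid-trajectory
structure cannot be parameterized, the default is to skip the correction
with a warning (`skip_on_param_failure = TRUE`), so the guided sampler
degrades gracefully to its base algorithm instead of aborting a batch.

### Choosing $\lambda$ and normalization

With raw gradients, the theory is clean: a step $\lambda < 2/L$, with $L$
the local Lipschitz constant of the gradient, cannot increase the energy.
The acceptance checks estimate $L$ numerically (power iteration on
finite-difference Hessian-vector products) and verify descent at
$\lambda = 1/L$, plus the expected possibility of overshoot at
$4/L$. But $L$ is geometry-dependent and dominated by stiff bond terms,
so raw-gradient steps are impractically small for routine use. The
default is therefore `normalize_gradient = "rms_per_atom"`: the gradient
is divided by its per-molecule RMS atom norm, making $\lambda$ an RMS
per-atom displacement in Å. The default $\lambda = 0.1$ Å is a gentle
nudge relative to typical bond lengths; the paired toy experiments in the
tests use $0.05$ Å. The normalization mode is part of the configuration
object, so runs are self-describing. $\lambda = 0$ reduces the guided
code path bit-for-bit to the unguided algorithms (verified over seeded
runs), which makes ablations trustworthy.

## Post-optimization and metrics

`minimize()` performs conditional minimization: L-BFGS directions with
Armijo backtracking on the total energy, ligand coordinates free, pocket
rigid. The accepted-energy sequence is non-increasing by construction and
the stopping rule is a gradient max-norm threshold (default
$10^{-2}$ kcal/mol/Å) or the iteration cap. A bespoke loop is used
instead of `stats::optim()` because the monotonicity contract and the
gradient-norm stopping rule are part of the interface; endpoint agreement
with the reference minimizer (within 0.5 kcal/mol from identical starts)
is enforced by the tests, not assumed.

`strain_energy()` is the headline pose metric: the intramolecular energy
gap between the pose and its minimized geometry, per heavy atom. The
relaxation is intramolecular (gas-phase) by default, matching the
metric's definition as *ligand* strain; a `conditional` flag switches
both evaluations to the pocket-conditioned total for users who want
in-site strain. `validity()` is operational: a record is valid iff it
parses, sanitizes and initializes an MMFF94 parameter set.

## What the synthetic fixtures emulate — and what they do not

No trained generator or curated complex data ships with the package, so
the guided-vs-unguided experiments run on synthetic components chosen to
isolate the mechanism:

* `make_fixture_set()`: ~50 packaged drug-like SMILES, ETKDG-embedded
  with fixed seeds — chemically realistic small molecules with reliable
  MMFF typing.
* `make_toy_pocket()`: charged point sets, a ring cage, a distant shell —
  geometries with known symmetries and limits, so cross-term tests have
  closed-form expectations.
* `make_toy_denoiser()`: deterministic clean-sample predictors. The
  `strained_target` variant proposes a fixed, deliberately distorted
  conformer plus $t$-decaying noise and a weak pull toward the current
  state — emulating the failure mode guidance exists to fix (a generator
  confidently proposing strained geometry).

Paired experiments fix all seeds per pair, so guided and unguided runs
differ *only* in $\lambda$; with 200 pairs per sampler the mean final
energy and mean strain are lower under guidance (one-sided paired tests
at $\alpha = 0.01$). These experiments demonstrate that the guidance
term does what it claims against a known adversary. They do not
demonstrate performance on real generative models: a trained denoiser
has structured, state-dependent errors, couples 2D graph decisions to 3D
coordinates, and operates on far larger molecules in real pockets.
Docking-score improvements, interaction counts and benchmark-scale
strain reductions are therefore out of scope here and require trained
weights and external docking software.

## Numerical and design choices, collected

* Units: Å, kcal/mol, elementary charges, degrees inside the angle
  kernels.
* Pocket rule boundaries: "within 3.5 Å" is closed ($\le$); residue size
  is strict ($> 10$ atoms).
* Pocket hydrogens present in the input are kept; protonation is the
  input's responsibility.
* Pocket vdW parameters: element-default table (values are MMFF94
  self-pair parameters of representative atom types). Per-residue typing
  of a truncated, bond-order-free protein fragment would be guesswork;
  an explicit per-element table is predictable and documented.
* Electrostatic dielectric for cross-terms: constant $D = 1$,
  configurable in `cross_term_spec()`; a distance-dependent dielectric
  is a one-line change but is not the default because the intramolecular
  term uses $D = 1$ and the two should match.
* Problem sizes in the shipped tests and acceptance script (100-molecule
  oracle panel, 10-fixture gradient/minimizer checks, 200 sampler pairs
  on a 9-atom ligand with 12 flow steps / $T = 15$ diffusion steps,
  50 synthetic proteins) were chosen so the full pipeline exercises
  every claim at desk scale with deterministic seeds.
* Mol-block coordinates carry four decimals; wherever full precision
  matters (reference minimizer endpoints, gradient checks) coordinates
  are passed as numeric arrays, not re-read from text.

## Known limitations

* The pocket is rigid and unpolarizable; induced-fit and solvent effects
  are absent by design.
* Element-default pocket vdW parameters are coarser than per-type MMFF94
  assignment; cross-term energies are internally consistent but not
  toolkit-reproducible the way intramolecular energies are.
* Guidance assumes the denoiser's clean-sample estimate is at least
  parameterizable; early in a diffusion trajectory that may fail, and
  the step is then skipped rather than repaired.
* MMFF94 (not the MMFF94s variant) is implemented, matching the default
  of the reference toolkit; molecules outside MMFF94's element coverage
  (e.g. boron) are invalid by definition of the validity metric.
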