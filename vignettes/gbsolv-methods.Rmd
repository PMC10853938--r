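---
title: "Methods: generalized-Born descriptors and a dense network for solvation free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized-Born descriptors and a dense network for solvation free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsolv)
```

# The problem

The standard-state solvation free energy $\Delta G^\circ_{\mathrm{solv}}$ —
the free-energy change of moving a solute from gas phase into a solvent —
controls reaction thermodynamics in solution, particularly for ions.
Continuum-solvation calculations split it into an electrostatic
polarization term and a nonelectrostatic correction (cavitation,
dispersion).  Generalized-Born (GB) models express the electrostatics
directly through atomic charges $\{Q_I\}$, radii $\{R_I\}$, and a smooth
pair function, with no explicit cavity surface; the monatomic term
$(1-1/\varepsilon)\,Q_I^2/R_I$ is Born's classical result for a spherical
ion in a dielectric $\varepsilon$.

`gbsolv` treats the GB self and pair energies, together with simple
surface/volume estimates and three bulk solvent descriptors, not as an
energy expression to be summed but as a *physical feature vector* for a
small dense neural network regression.  The only inputs are Cartesian
coordinates, the total solute charge, and the solvent's registry entry.

# Atomic charges by electronegativity equalization

Charges come from an electronegativity-equalization (EE) model: every
atom's effective electronegativity — intrinsic value $A_I$ plus hardness
and neighbor terms — equalizes to a common $\chi$ at the solution of one
linear system,

$$2 B_I Q_I + \sum_{J \ne I} Y_{IJ} Q_J - \chi = -A_I
\quad (I = 1 \ldots N), \qquad \sum_I Q_I = Q_{\mathrm{tot}}.$$

$A_I$ and $B_I$ depend on the element *and* its coordination number (CN);
the bundled table spans H, C–F, Si–Cl, Br, and I with per-CN rows (for
example O distinguishes CN 1 from CN 2–3, P has rows for CN 1–3, 4, and 5),
and the global lengths $\kappa = 0.991$ Å, $\kappa_2 = 1.371$ Å.  Design
choices a reimplementer would have to make, fixed here and pinned by
tests:

* **Diagonal convention.**  The diagonal is $2B_I$, the derivative of an
  $A_IQ + B_IQ^2$ atomic energy.  A decoupled-atoms test pins the factor.
* **Off-diagonal coupling.**  $Y_{IJ} = 1/(r_{IJ} + \kappa\,
  e^{-r_{IJ}/\kappa_2})$: symmetric, strictly positive, strictly
  decreasing at the tabulated parameter values, Coulombic ($\propto
  1/r$) at large separation, and finite at short range.  $Y$ and $B$
  share the same $\text{Å}^{-1}$-like unit system — the tabulated $B$
  values (0.4–1.5) are commensurate with $Y$ at bonding distances
  (≈0.5), so no additional energy-conversion constant enters the system.
* **Coordination numbers.**  $\mathrm{CN}_I$ counts neighbors within
  $1.2\times$ the covalent-radius sum (tolerance configurable), then
  clamps into the nearest CN range the parameter table lists for that
  element; an isolated atom falls back to the lowest listed range, ties
  resolve to the lower range.
* **Conservation.**  The constraint row enforces $\sum Q_I =
  Q_{\mathrm{tot}}$; one step of iterative refinement keeps the residual
  at machine precision ($<10^{-15}$ e in the fuzz tests).

Parameter refitting against externally supplied target charges uses the
downhill simplex (Nelder–Mead, via `stats::optim`) on exactly the
$(A, B)$ rows the training molecules exercise, plus $\kappa$ and
$\kappa_2$; $B$, $\kappa$, $\kappa_2$ are optimized on a log scale so
positivity can never be violated, and the objective is the charge RMSE
with every atom weighted equally.  Convergence tolerance is $10^{-6}$ on
the RMSE; non-convergence returns the best point found, with a warning.

# Surfaces and volumes by spherical-cap subtraction

Exposed atomic surface areas and volumes use pairwise spherical-cap
subtraction.  For spheres $I, J$ at distance $r_{IJ}$ the crossing plane
sits at the signed offset

$$a = \frac{r_{IJ}^2 + R_I^2 - R_J^2}{2\,r_{IJ}},$$

and the cap of sphere $I$ buried inside $J$ has height $h = R_I - a$
(clamped to $[0, 2R_I]$), area $\Delta S_{IJ} = 2\pi R_I h$, and volume
$\Delta V_{IJ} = \pi h^2 (3R_I - h)/3$.  Then

$$S_I = \max\Bigl(0,\; 4\pi R_I^2 - \sum_J \Delta S_{IJ}\Bigr), \qquad
V_I = \max\Bigl(0,\; \tfrac{4}{3}\pi R_I^3 - \sum_J \Delta V_{IJ}\Bigr),$$

summing over every $J$ whose sphere overlaps $I$'s
($r_{IJ} < R_I + R_J$) — overlap, not bondedness, is the natural
criterion because the cap terms vanish continuously at contact; a
bonded-only mode exists for sensitivity checks.  Radii are unmodified
Bondi van der Waals values.  The estimate is exact for isolated atoms and
any two-sphere configuration (pinned against Monte-Carlo sampling to
three-sigma at $10^6$ samples); under multiple overlap it
over-subtracts, which is why negative per-atom values are clamped at
zero.  That bias is acceptable by construction: the quantities serve as
regression descriptors, not as reported areas.

# The feature vector

The raw descriptor vector concatenates, in a fixed order:

1. atom count; 2. total charge $Q_{\mathrm{tot}}$; 3. total volume
$V_{\mathrm{tot}} = \sum_I V_I$; 4. total surface $S_{\mathrm{tot}} =
\sum_I S_I$;
5–13. per-element surface sums $S_L$ for the nine feature elements
$L \in \{$H, C, N, O, F, S, Cl, Br, I$\}$;
14–22. Born self terms $E_1(L) = 332.06\,(1 - 1/\varepsilon) \sum_{I \in
L} Q_I^2 / R_I$ (kcal/mol);
23–58. Born pair terms $E_2(L_1, L_2) = 332.06\,(1 - 1/\varepsilon)
\sum Q_I Q_J / f_{IJ}$ over unordered atom pairs of each retained element
pair, with the Still pair function
$f_{IJ} = \sqrt{r_{IJ}^2 + R_I R_J\, e^{-r_{IJ}^2 / (c\,R_I R_J)}}$,
$c = 4$;
59–61 (nonaqueous only): the solvent's dielectric constant, boiling
point, and heavy-atom count, drawn from an editable registry.

That makes 58 features for the aqueous model and 61 for the nonaqueous
one.  Of the $9 \cdot 10 / 2 = 45$ possible element pairs, 36 are
retained by default: pair terms for element combinations that barely
occur in a training set are near-degenerate point-mass features, so the
default list drops the nine rarest combinations in organic solutes
(halogen–halogen and S–Br/S–I); the list is a plain-text config and any
subset of the 45 defines a valid schema, with all downstream dimensions
following the active list.  Si and P are parameterized for charges and
enter the global size terms, but have no element-resolved slots.

The Coulomb constant 332.06 kcal·Å/(mol·e²) converts charge pairs to
kcal/mol, and the dielectric factor is $(1 - 1/\varepsilon)$ with no
extra $\tfrac12$; a single global sign convention is irrelevant to the
regression (the network absorbs it), so tests pin magnitudes and ratios.

# Dimensionality reduction

Feature blocks are strongly correlated (totals versus element sums, self
versus pair terms), so the raw vector is standardized per feature
(z-scored; constant columns get unit scale) and projected onto the
leading principal components, dropping the nine smallest — 58→49 and
61→52.  The PCA is computed by singular value decomposition; component
signs follow a largest-absolute-loading-positive convention so the
transform is deterministic.  Scores are *not* rescaled after projection
(the common PCA default); the `whiten` argument restores per-component
unit variance for experimentation.  Standardizing before projection makes
the decomposition correlation-based, which is the only scale-free choice
when features mix Å², Å³, kcal/mol, and counts.

# The network and its training

The regressor is a dense network with two rectified-linear hidden layers
and a linear output, all with biases: $(49, 16, 8, 1)$ for water —
$(49{+}1)\cdot16 + (16{+}1)\cdot8 + (8{+}1) = 945$ parameters — and
$(52, 14, 7, 1)$ for nonaqueous solvents, 855 parameters.  Training
minimizes the weighted squared error plus an L2 penalty,

$$\mathcal{L} = \frac{\sum_i w_i (y_i - \hat y_i)^2}{\sum_i w_i}
  + \lambda \sum \lVert W \rVert^2, \qquad \lambda = 0.01,$$

with the Nesterov-accelerated adaptive-moment (Nadam) optimizer
(learning rate 0.001, or 0.0001 for fine work; $\beta_1 = 0.9$,
$\beta_2 = 0.999$), implemented here in plain R matrix algebra with
hand-derived backpropagation.  A fifth of the records are held out for
validation; the split is random per seed and stratified by the solute
charge class so that ionic metrics remain meaningful at small counts.
Per-record weights default to 1, with up-weighting of ions available as
the natural use of the hook (ions are the scarce class).  Reports carry
the full metric set: mean signed error, MAE, RMSE, and the slope,
intercept, and $R^2$ of predicted-versus-reference.  Training is
bit-reproducible given the seed; a non-finite loss aborts with a
diagnostic rather than returning garbage.  With every hidden unit driven
inactive the prediction collapses to the output bias — a structural
property of the architecture worth knowing when interpreting predictions
for weakly solvated solutes.

# Ionic data augmentation

Reference data for ions are scarce, and implicit-solvent electrostatics
gives a principled way to multiply them.  Assuming the nonelectrostatic
share of $\Delta G^\circ_{\mathrm{solv}}$ is independent of
$\varepsilon$, a measured ionic record rescales to a new dielectric
constant $\varepsilon_{\mathrm{new}} \in (10, 200)$ as

$$\Delta G^\circ(\varepsilon_{\mathrm{new}}) = \Delta G^\circ_{\mathrm{ref}}
 + E_{\mathrm{elst}} \left[
 \frac{1 - 1/\varepsilon_{\mathrm{new}}}{1 - 1/\varepsilon_{\mathrm{real}}}
 - 1 \right],$$

where $E_{\mathrm{elst}}$ is the record's own GB electrostatic total
$-\tfrac{332.06}{2}(1 - 1/\varepsilon)\sum_{I,J} Q_I Q_J / f_{IJ}$ (with
$f_{II} = R_I$) at its real dielectric constant — the only
$\varepsilon$-scalable quantity available before any model exists.  The
map is the identity at $\varepsilon_{\mathrm{new}} =
\varepsilon_{\mathrm{real}}$ and whenever the electrostatic share is
zero, and is monotone in $\varepsilon_{\mathrm{new}}$.  Boiling-point
replication copies records across a grid within (40, 210) °C, changing
only the solvent boiling point; targets and geometry are untouched.
Neutral records are never extrapolated.

# The synthetic-data generator

Everything above is testable offline because the package generates its
own study material.  `random_molecule()` grows a connected cluster: each
new atom bonds to a random existing heavy atom at $0.9$–$1.1\times$ the
covalent-radius sum in a random direction, rejecting placements closer
than $0.8\times$ the covalent sum to any other atom (up to 200 attempts,
then the least-crowded candidate).  The default composition emulates how
a curated solvation database covers chemistry rather than natural
abundance:

* **Neutrals** (3–12 atoms) draw from a heteroatom-rich mix (H 30, C 25,
  N 10, O 12, F 6, S 5, Cl 6, Br 3, I 3 by weight) so that every retained
  element pair appears in at least a few percent of molecules — the same
  representation argument that motivates the 36-pair default.
* **Ions** (3–7 atoms, charge ±1) draw from H/C/N/O/S chemistry only:
  real ionic solutes are protonated amines, oxyanions, and the like, and
  small — and small ions are exactly the extreme-feature records a
  trainable model must see often.
* **Class mix** defaults to 60/20/20 neutral/cation/anion, emulating an
  ion-augmented training table rather than a raw measurement collection.
* **Solvents** default to eight registry entries spanning
  $\varepsilon \approx 1.9$–47.

Labels come from a *declared* rule: a fixed linear functional of the
standardized compact descriptors (atom count, volume, surface, net
charge, solvent polarity and boiling point, O/C surface shares) projected
into the reduced feature space — hence exactly linear in the network's
inputs, with the coefficient vector reported in `truth$coef` — plus
Gaussian noise of $\sigma = 0.5$ kcal/mol, giving label spreads of a few
kcal/mol as real solvation data have.  Ionic records carry loss weight 3.
A recovery experiment (2000 records, the nonaqueous pipeline, 300 epochs
at batch 64) reaches a held-out RMSE within about 10–15% of the noise
floor; ordinary least squares on the same reduced features serves as the
independent oracle of attainable accuracy.

What the generator does *not* emulate — and hence what passing tests do
not show — includes real conformational chemistry (bond angles are
random, not valence-driven), measured solvation labels, tautomers and
conformer ensembles, and the systematic errors of any experimental
database.  Recovery of a declared label rule validates the plumbing and
the optimization, not chemical accuracy; accuracy claims require training
on real reference data through the same interfaces (any CSV in the
training-table layout is accepted).

# Numerical choices and degenerate inputs

* Linear solves check the reciprocal condition number and fail with a
  condition-number diagnostic below $10^{-13}$.
* Nearest-range CN clamping breaks ties toward the lower range; raw
  counts are available via `params = NULL`.
* Cap heights clamp to $[0, 2R_I]$; tangent spheres produce exactly zero
  overlap; containment produces exactly the full sphere.
* Per-atom areas and volumes clamp at zero under heavy multiple overlap.
* `fit_transform` refuses rank-deficient targets; the dataset generator
  lowers the retained dimension to the realized rank when asked for
  fewer records than features.
* Transform component signs and network initialization are fixed by
  seed; all stochastic steps (splits, shuffling, generation) derive from
  explicit seed arguments and restore the caller's RNG state.

Desk-scale problem sizes used by the test suite and the verification
script: 1000 fuzzed molecules for conservation, $10^6$ Monte-Carlo
samples per cap check, four small molecules (14 atoms total) for simplex
recovery, and 2000 records for the end-to-end learning check.

# Known limitations

Coordination-number parameterization covers H, C–F, Si–Cl, Br, I only;
unusual coordination (clamped into the tabulated ranges) and strongly
distorted bonds are outside the model's intended domain.  EE charges can
over-delocalize across weakly bound fragments, which propagates into the
Born terms.  The surface/volume estimator is approximate under multiple
overlap by design.  The shipped 36-pair list is a representation-based
default, not a fitted selection; projects with different chemistry should
revisit it through the config file.
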