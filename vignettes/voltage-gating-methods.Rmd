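---
title: "Methods: voltage-gating analysis in voltgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voltage-gating analysis in voltgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltgate)
```

voltgate packages the analysis stack used to dissect voltage activation of
ion channels — developed with the BK channel's Core-MT construct in mind,
where the S4 voltage sensor moves only ~3 Å yet drives pore opening. This
vignette explains the models behind each module, the parameters that
matter, what the synthetic generators do and do not emulate, and the
numerical and design choices that were genuinely open.

## Coordinate conventions

All coordinates are in ångströms with the membrane normal along +z, z = 0
at the membrane centre and the extracellular side at positive z, so
activation-associated outward movement of S4 charges appears as positive
z-displacement. Residue numbering is the author (human BK) numbering read
from the PDB; the package never renumbers. Boxes are orthorhombic only —
triclinic input is an explicit unsupported error, since the systems this
stack targets are rectangular (~160×160×110 Å³). The default
transmembrane-helix ranges are S1 T109–S135, S2 F148–A170, S3 V181–L199,
S4 G205–N225, S5 S230–S259 and S6 A313–E324 (below the glycine hinge), and
charged-group positions follow the guanidinium CZ atom for Arg and the
side-chain carboxyl carbon for Asp/Glu.

## Gating-charge thermodynamics

The gating charge per voltage sensor is the field-weighted displacement
of its charges between conformational states,

$$\Delta Q = \sum_i q_i\,\Delta f_i,$$

where the coupling factor (electrical distance) $f_s(i)$ is the fraction
of the transmembrane potential felt by charge $q_i$ in state $s$. It is
extracted from charging free energies at two voltages,

$$f_s(i) = \frac{\Delta G_s(V_2, q_i) - \Delta G_s(V_1, q_i)}
{q_i\,(V_2 - V_1)},$$

each $\Delta G$ computed by thermodynamic integration of the mean force
$\langle \partial H/\partial\lambda\rangle$ over the charging parameter
λ = 0, 0.1, …, 1.0 (11 windows).

Numerical choices:

* **Trapezoid, not Simpson.** The λ grid is fixed at step 0.1, and
  charging in a near-linear dielectric gives a nearly linear mean force,
  for which the trapezoid is exact; Simpson would suggest spurious extra
  accuracy on noisy window means. On the test curve m(λ) = λ² the 11-point
  trapezoid gives 0.335 against the exact 1/3 — this discretisation bias
  is intentional and frozen in the tests.
* **Sign convention.** f rises from the intracellular side (f = 0) to the
  extracellular side (f = 1), and per-residue contributions are computed
  as $q\,(f_\text{open} - f_\text{closed})$, so outward movement of a
  positive charge contributes positively. This is the ordering under which
  the conventional per-residue signs (e.g. R210 = +0.25 e) come out
  right; the widely quoted $q(f_c - f_o)$ form is the same quantity with f
  referenced to the intracellular side.
* **Errors.** Window standard errors come from block averaging (default
  5 blocks — the block count is rarely stated in the literature; 5 gives
  a stable between-block estimator at the 4-ns window lengths typical of
  charging runs) and propagate through the trapezoid weights in
  quadrature.
* **Units.** 1 e·mV = 0.0230605 kcal/mol is fixed in one constants table,
  as is the Coulomb conversion 14399.645 mV·Å/e.

The package consumes mean-force tables (CSV:
`residue,state,voltage_mV,lambda,mean_force_kcal_mol,stderr`) rather than
running MD. A toy analytic engine (`slab_ti_curves()`) generates exact
mean forces for the membrane-slab system so the whole chain — TI,
coupling factors, gating-charge table — is exercisable end to end against
the capacitor ground truth $\sum_i q_i\,\Delta z_i / L$, which it must
reproduce to 1e-10.

## Electrostatic field maps

Field maps answer how the protein reshapes the local electric field: each
atom's charge is spread as a spherical Gaussian with inverse width
β = 0.25 Å⁻¹ on a 1 Å periodic grid, and the Poisson equation
$\nabla^2\phi = -4\pi\rho$ is solved spectrally (FFT), with the k = 0 mode
dropped. Dropping k = 0 both neutralises non-neutral cells (uniform
background) and fixes the zero-mean gauge — consequently only potential
*differences* are physically meaningful, and the package treats absolute
map values as gauge-dependent.

The external transmembrane potential is added as a piecewise-linear ramp
over a stated membrane span: zero below, V above, linear within. With the
span set to the full box this reproduces the constant-field convention
E = V/L_z; with a narrower span it matches the slab systems, where the
analytic "sensed fraction" at height z is exactly the ramp — the mechanism
by which charges can feel most of the applied voltage over a short
physical distance once the protein concentrates the field.

Validation uses the closed form for a periodic Gaussian charge: φ(r) =
q·erf(βr)/r plus the uniform-background term 2πq r²/(3V) plus a gauge
constant, which the solver matches to ≈0.2% on a 48³ grid over
2 Å < r < L/4. The smeared density is the object solved for — no
point-charge short-range correction is added, so maps are smeared
potentials by construction. Dielectric screening is implicit (none): these
are vacuum-like Poisson maps of the simulation's charge distribution, not
Poisson–Boltzmann calculations.

## Conformational, hydration and permeation metrics

All per-frame metrics return tidy tibbles (`time_ns, chain, value`), with
per-chain rows plus a `chain == "mean"` row where the four subunits share
residue numbering. Running averages (centred window, default 50 frames)
are presentation-only.

* **Helix tilt** uses the first principal component of the segment's Cα
  coordinates, oriented N→C and folded into 0–90°. A principal axis is
  robust for short or bent segments (e.g. S6 313–324), unlike per-residue
  backbone vectors. Discrete Cα sampling couples helical phase to height
  and biases the axis by ~2° at 12 residues, falling below 0.5° for whole
  helical turns of ~36+ residues; the tests use constructed 72-residue
  helices for this reason.
* **RMSD** superposes with the Kabsch least-squares fit (via bio3d) and is
  cross-checked against an independent quaternion (Horn) oracle to 1e-6.
* **Contacts** follow the minimal heavy-atom distance rule: occupancy =
  fraction of frames with min distance ≤ 5 Å; contact iff occupancy
  ≥ 75%. Hydrogens are excluded by element, with an atom-name fallback.
* **Pore radius profiles** re-implement the HOLE idea deterministically:
  per z-slice the radius is max over candidate centres of (min over atoms
  of distance minus vdW radius), searched on a 0.25 Å xy grid around the
  axis hint and refined by Nelder–Mead from the best eight starts (the
  radius field is a min of cones, so single-start refinement can sit on
  the wrong ridge). The search stays within `search_radius` of the hint;
  slices with no nearby atoms report a bulk sentinel (default 15 Å).
* **Pore waters** are counted between the centre of mass of the lower
  boundary ring (L312) and the plane through the upper ring's COM (P320),
  using the water O position, within a lateral radius of the pore axis.
  The z-based published definition needs a lateral bound to exclude bulk
  and lipid-phase waters; 10 Å is the default and is flagged as a choice,
  as is the O-position convention.
* **Permeation** uses a two-plane double-crossing state machine on z with
  explicit periodic-recycling detection (a frame-to-frame jump larger than
  half the box is recycling, not pore passage). This counts an event only
  for excursions that enter below the lower plane and exit above the
  upper one (or the reverse), is immune to recrossings between the
  planes, and is exactly time-reversal symmetric. Conductance is
  g = N·e/(T·V), reported in pS.
* **Free-energy surfaces** are −RT ln P̂(x,y) at T = 300 K, min-shifted to
  zero with +Inf in empty bins; the 4 kcal/mol contour used in displays is
  presentation-only.

## Dynamic-network coupling

Residues are nodes at Cα positions. The coupling matrix is the
Pearson-normalised covariance of superposed Cα fluctuations
$C_{ij} = \langle \Delta r_i\!\cdot\!\Delta r_j\rangle /
\sqrt{\langle\Delta r_i^2\rangle\langle\Delta r_j^2\rangle}$ — written as
a "covariance" in much of the literature, but the edge weight
$w_{ij} = -\log|C_{ij}|$ only stays nonnegative if |C| ≤ 1, which forces
the normalised form. Edges exist on 5 Å / 75% contacts; C = 0 edges are
dropped (infinite weight), and |C| > 1 input is rejected as unnormalised.

* **Optimal paths** are Floyd–Warshall shortest paths with
  strict-improvement updates in fixed node order, making tie-breaks
  deterministic. **Suboptimal paths** are *all* simple paths within 1.5×
  the optimal length, enumerated by depth-first search with pruning at
  the bound and a `max_paths` guard (default 1000, with a truncation
  flag). Both are validated against exhaustive enumeration on ≤8-node
  graphs.
* **Communities** use Girvan–Newman divisive clustering: edges removed by
  highest betweenness computed with w as distances, partition kept at
  maximum modularity with |C| as edge strength, ties broken on the lowest
  edge index. Components are never merged. The strength/distance pairing
  is exposed so alternatives can be compared.
* **Entropies** are Gaussian-mixture estimates: the node coordinate x is
  the scalar distance of the node to its mean position, the density is a
  1-D (or 2-D for joints) GMM with components chosen by BIC over 1–5, and
  H is the sample mean of −ln ρ̂(x). Model fitting uses mclust's
  deterministic model-based initialisation on a fixed subset, so no
  randomness enters the estimate — determinism by construction replaces
  the random-restart schemes sometimes used. Mutual information is
  M = Hᵢ + Hⱼ − Hᵢⱼ, clipped at zero (with a warning when materially
  negative); duplicated nodes short-circuit to M = Hᵢ.
* **Information flow** treats $A_{ij} = |C_{ij}|\,M_{ij}$ as conductances
  (|C| rather than signed C, since the Laplacian formalism requires
  nonnegative conductances and the signed product is ambiguous for
  anticorrelated pairs). The Laplacian is L = D − A (the standard
  definition), potentials solve the reduced system with the sink grounded
  and one unit of current injected at the source, and the node flow is
  $f_i = \tfrac12\sum_j |P_i - P_j| A_{ij}$, with f = 1 at the endpoints
  by the unit-supply convention. This equals current-flow (random-walk)
  betweenness for the pair and is checked against a dense pseudo-inverse
  oracle to 1e-8. Flows are invariant under uniform conductance scaling;
  interior nodes satisfy Kirchhoff balance. For tetramers, flows are
  computed per chain (an optional sum is trivial with dplyr), since
  cross-chain pooling conflates four parallel pathways.

## Synthetic systems: what they do and do not emulate

The generators provide desk-scale inputs with analytic ground truth; they
are first-class, tested code, not fixtures.

* **Elastic networks** draw i.i.d. frames from the Gaussian with
  covariance $k_BT\,H^+$, H the anisotropic spring Hessian and $H^+$ its
  pseudo-inverse with near-zero (rigid-body) modes removed by a relative
  eigenvalue tolerance — a generic 3-D network sheds exactly 6 modes, and
  degenerate fixtures (a dimer) shed more, which the tolerance handles.
  The exact covariance, its residue-residue correlation, and any planted
  two-block partition are returned alongside. Frames are *independent*:
  the generator emulates fluctuation statistics, not kinetics, so nothing
  about autocorrelation or convergence rates of real MD is tested by it.
* **Slab systems** place point charges in a box with a linear
  transmembrane potential over a stated span, making every electrical
  distance exact: f(z) = 0 below, 1 above, linear within. This exposes
  the capacitor ground truth for gating-charge recovery but has no
  protein-reshaped field, no dielectric inhomogeneity and no sampling
  noise — it validates bookkeeping and quadrature at machine precision,
  not force-field physics.
* **Pore scripts** place single-bead waters (the counter needs only
  positions) inside a cylindrical pore region with scripted per-frame
  counts, park distractor bulk waters outside it, and move ions along
  scripted z(t); crossing counts are established on the exact unwrapped
  paths, summed over periodic plane images. No sterics, no
  electrostatics, no water structure.

Consequently, passing tests demonstrate that the estimators and counters
are *correct* (they recover what is analytically true), not that real
trajectories are well-sampled or that force fields are accurate; known
quantitative gaps of the underlying simulations (e.g. classical force
fields underestimating single-channel conductance by roughly an order of
magnitude) are inherited by any real-data analysis and are outside the
package's control.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive runs: 10⁴
frames for covariance/entropy recovery (tolerances 5% Frobenius,
0.05/0.1 nat), 10⁴ samples for GMM estimates, 48³ grids for the Poisson
closed-form check, 100 random ≤8-node graphs for path oracles, and a few
hundred frames for scripted pore systems. Seeds are mandatory fields of
every generator spec rather than ambient state, and the pipeline writes a
JSON manifest (parameters, seed, checksums) with every run, so each run
is reconstructible from its outputs.

## Known limitations

* TI input is consumed as mean-force tables; which atoms' charges are
  scaled during residue charging is a property of the upstream
  simulations, and the toy engine scales a single point charge.
* Only tilt magnitude is implemented; a tilt/bend decomposition for kinked
  helices (e.g. S5) is not formalised here.
* The pore-water lateral bound and O-position convention are package
  choices where the published definitions are z-based only.
* Field maps carry a zero-mean gauge; absolute potentials are not
  comparable across maps, only differences.
* No SASA, secondary-structure assignment, lipid-tail pore occupancy, or
  trajectory clustering.
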