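---
title: "Sphere-model scattering curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sphere-model scattering curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasbead)
```

## The modelling problem

Small-angle X-ray and neutron scattering (SAXS/SANS) measure the radially
averaged intensity $I(Q)$ of a macromolecule in solution, with
$Q = 4\pi \sin\theta / \lambda$. The data are low resolution: they cannot by
themselves determine an atomic structure, but they can *reject* candidate
structures whose calculated curves disagree with experiment. Constrained
modelling therefore generates many atomistic conformations of the target
(from crystal structures, homology models and conformational sampling --
all outside the scope of this package), computes a theoretical curve for
each, and ranks the candidates by goodness of fit. `sasbead` implements the
curve-calculation and ranking machinery: coarse-graining, hydration,
the Debye equation, Guinier analysis and R-factor scoring.

All internal lengths are nanometres and all $Q$ values reciprocal
nanometres; PDB coordinates in angstroms are converted exactly once on read
and once on write.

## Coarse-graining by grid transformation

An atomistic model is reduced to a bead model by histogramming atoms on a
cubic grid of side $s$ (`grid_transform()`). Every box holding at least
`cutoff` atoms (default 4 for atomistic input) becomes one sphere at the box
centre with radius $s/2$. The literature is ambiguous on whether the
threshold is inclusive; we implement the inclusive rule `count >= cutoff`,
with a `strict` flag for the strictly-greater variant, and each workflow run
records the semantics in its manifest.

The grid is anchored at the per-axis minimum coordinate, with an optional
fixed `origin` for reproducible grids across related models. The model
volume is reported in the *box* convention $n s^3$ by default, which is
self-consistent with grid occupancy (the boxes tile space); the literal
*sphere* convention $n \tfrac{4}{3}\pi (s/2)^3$ is also available because
the classical description "sum of the component sphere volumes" admits
either reading. The choice is a logged parameter, not a hidden constant.

The box side is not free: it is tuned (`optimize_box_side()`) so that the
bead-model volume matches the *sequence-derived* dry volume of the
macromolecule, computed by `macromolecule_properties()` from consensus
unhydrated residue volumes (27 amino-acid and monosaccharide codes; the
volume table ships as editable YAML, and only the consensus set is wired
into modelling). The objective $|V(s) - V_\mathrm{target}|$ is
piecewise-constant in $s$ with many local plateaus, so instead of a
golden-section search (which can settle on a non-global plateau) we use a
deterministic two-stage grid scan: 0.01 nm steps across the full bracket
(default 0.1--1.5 nm), then 0.001 nm steps around the coarse optimum. This
costs roughly 160 grid transforms and is exact at the stated resolution.

## The hydration monolayer

SAXS sees a hydration shell -- bound water is denser than bulk
(0.0245 nm^3^ per bound molecule against 0.0299 nm^3^ in bulk) -- whereas
SANS in heavy water does not. About 0.3 g of water binds per gram of
protein, so the hydrated target volume is
$V_\mathrm{dry} + 0.3 M / m_w \times 0.0245\ \mathrm{nm}^3$.
`hydrate_sphere_model()` reaches it in four steps:

1. every dry sphere spawns 26 candidate spheres on the corners, edge
   mid-points and face centres of a cube of side $4r$ centred on it
   (offsets $\{-2r, 0, 2r\}^3$ minus the null offset);
2. a grid conversion at the dry box side removes excess candidates (only
   boxes holding at least `hydration_cutoff` spheres survive);
3. the original dry spheres are added back, because thin extended features
   can be filtered away in step 2;
4. a final grid conversion at cutoff 1 removes overlaps.

Because the dry centres already sit on a lattice of pitch $s$ (and the
candidate offsets are exactly $\pm s$), the step 2 and step 4 filter grids
are anchored at (minimum centre $- s/2$), which places every existing centre
exactly at a filter-box centre. Anchoring at the raw minimum coordinate --
the natural choice for atom clouds -- would shift the entire shell by half
a box and could displace dry centres; centre-aligned anchoring makes step 4
an exact deduplication and guarantees that every dry sphere survives
hydration. `optimize_hydration_cutoff()` tabulates the hydrated volume over
candidate cutoffs 1--14 (the effective monolayer typically emerges in the
upper half of that range for globular shapes) and picks the cutoff closest
to the sequence-derived hydrated volume; the table is non-increasing in the
cutoff, which the tests verify.

## Debye curves from pair-distance histograms

The scattered intensity of $n$ identical spheres is the Debye double sum
over pairs. Evaluated naively it is $O(n^2)$ per $Q$ point, so the package
bins the $n(n-1)/2$ pair distances into a histogram (counts $A_j$ at
distances $d_j$) and computes

$$\frac{I(Q)}{I(0)} = g(Q)\left[\frac{1}{n} +
\frac{2}{n^2}\sum_{j=1}^m A_j\,\frac{\sin(Q d_j)}{Q d_j}\right],\qquad
g(Q) = \left[\frac{3(\sin Qr - Qr\cos Qr)}{(Qr)^3}\right]^2 ,$$

where $g(Q)$ is the squared form factor of a uniform sphere of radius $r$
and the $1/n$ term carries the self-correlations; since
$\sum_j A_j = n(n-1)/2$, the bracket tends to 1 as $Q \to 0$ and the curve
is normalized by construction. Two binning modes are provided: *modern*
(bins spanning the minimum-to-maximum pair distance; the bin count comes
from `curve.radbins`) and *classic* (400 bins of user-chosen width starting
at zero, with an overflow error -- never silent truncation -- if a distance
falls outside). When all pair distances coincide the modern histogram
collapses to a single bin. The theoretical $Q$ grid is
`curve.npoints` equal steps on $(0, q_\mathrm{max}]$; $Q = 0$ is excluded
and both $\sin x / x$ factors are series-expanded below $10^{-3}$
(amplitude) and $10^{-6}$ (interference) to avoid $0/0$.

With 2000 bins the histogrammed curve tracks the exact all-pairs sum to a
few parts in $10^{4}$ for models of up to 200 spheres (the tests and the
acceptance script measure this deviation explicitly).

## SANS smearing and the incoherent baseline

Neutron instruments smear sharp features through wavelength spread
$\Delta\lambda/\lambda$ and beam divergence $\Delta\theta$.
`smear_curve()` convolves the curve with a unit-area Gaussian whose width
follows the convention

$$\sigma(Q) = \frac{1}{2\sqrt{2\ln 2}}
\sqrt{\left(\frac{4\pi}{\lambda}\Delta\theta\right)^2 +
\left(Q\,\frac{\Delta\lambda}{\lambda}\right)^2},$$

i.e. the two user-specified instrument widths are treated as FWHM
contributions added in quadrature and converted to a Gaussian standard
deviation. This is an explicit package convention -- instrument resolution
functions vary -- and `sigma_fun` lets users inject an exact form. The
convolution is discrete on the curve's own grid with reflective edge
handling; the kernel is renormalized pointwise, so constant curves are
preserved exactly and the zero-width limit is the identity. Triangular or
trapezoidal profiles and experimental desmearing are out of scope.

Residual-proton incoherent scattering in heavy-water SANS adds a flat
offset, typically 0.5--1.5% of $I(0)$. `apply_incoherent_baseline()` adds
`fraction * I(0)` uniformly, warns above the typical band and refuses
fractions over 5%; the workflow applies it only to the *written* curve,
after R-factor fitting is complete, never before.

## Guinier analysis and the R factor

`guinier_rg()` fits $\ln I$ against $Q^2$ (unweighted least squares -- no
experimental error model is in scope) and reports
$R_g = \sqrt{-3\,\mathrm{slope}}$ and $I(0)$; it warns when the fitted
window leaves the $0.5 \le Q R_g \le 1.5$ validity band and refuses windows
with under three points, non-positive intensities or a non-negative slope.
For elongated particles `guinier_rxs()` fits $\ln(IQ)$ against $Q^2$
($R_{xs} = \sqrt{-2\,\mathrm{slope}}$) in a higher window that must not
overlap the $R_g$ window.

Model-vs-experiment agreement uses a crystallographic-style R factor on
matched grids: each experimental $Q$ in the comparison window is paired
with the nearest theoretical $Q$ (ties toward lower $Q$), then

$$R(\eta) = 100 \times
\frac{\sum \big|\,|I_\mathrm{expt}| - \eta\,|I_\mathrm{theo}|\,\big|}
     {\sum |I_\mathrm{expt}|}$$

is minimized over the scale factor $\eta$, which scales the theoretical
curve onto the experimental one. $R(\eta)$ is piecewise-linear and convex
with breakpoints at $\eta_k = |I_{e,k}|/|I_{t,k}|$, so the minimum is found
exactly on the finite breakpoint set (ties toward the smaller $\eta$) --
no iterative tolerance is involved and the result is deterministic.

## Workflows

`analyse_directory()` runs the whole chain over a directory of PDB models
in sorted name order: the X-ray branch hydrates each bead model before the
curve calculation; the neutron branch uses the dry model (the shell is
invisible in heavy water; an override flag exists for methodological
experiments) and smears when `curve.smear` is set. Each branch writes
sphere models and curves under `<out>/<method>/models` and
`<out>/<method>/curves`, and two tab-separated tables summarize the
experimental Guinier values and the per-model comparisons (R factor and
$\eta$ per experimental curve). A model yielding zero spheres at the chosen
cutoff becomes a `failed` row rather than aborting a thousand-model run,
and a run manifest records the grid, hydration, binning and smearing
settings together with the threshold semantics. There is no randomness
anywhere in the pipeline, so two runs on identical inputs are
byte-identical -- a property the tests assert literally.

`optimize_params_workflow()` chains the sequence properties and the two
optimizers, and warns when a supplied sequence disagrees with the
structure's residue count by more than 5%: the optimizer can inflate the
grid to match a larger target volume, but it cannot place the missing
volume in the right region, so completing the model is preferable.

## Synthetic fixtures and what the tests show

`make_atom_cloud()` samples uniform balls, rods, dumbbells and lattices
with fixed seeds and attaches their analytic $R_g$ and envelope volume
(ball $\sqrt{3/5}\,R$; rod $\sqrt{L^2/12 + a^2/2}$; dumbbell via the
parallel-axis theorem). `write_atom_pdb()` groups 8 atoms per residue by
default, a realistic heavy-atom packing rate, so a fixture written to PDB
carries a sensible sequence-derived volume; deliberately oversampled clouds
(used where stable gridding at cutoff 1 needs at least ~50 points per box)
override the grouping so that structure and sequence stay self-consistent.
`make_experimental_curve()` adds seeded multiplicative Gaussian noise.

These fixtures have uniform density, sharp envelopes and no internal
structure, contrast variation or inter-particle interference. Passing tests
therefore demonstrate the correctness of the geometry, the scattering
mathematics and the bookkeeping -- not the biophysical fidelity of any
particular protein model, which depends on the quality of the candidate
structures supplied by the user.

Problem sizes in the shipped tests and acceptance script were chosen as
representative desk-scale cases: fixture clouds of 2--13 thousand atoms,
bead models up to ~7000 spheres, 20 random models of up to 200 spheres for
the Debye oracle comparison, and curves of 40--400 points.

## Numerical choices and known limitations

* Grid indices use `floor((x - origin)/s + 1e-9)`; the epsilon keeps
  lattice-aligned sphere centres from straddling box boundaries during
  hydration regridding and is irrelevant for generic atom coordinates.
* Degenerate inputs fail loudly and specifically: empty models, windows
  with under three points, rising Guinier slopes, classic-histogram
  overflow, duplicate experimental $Q$ values, already-smeared curves.
* A zero-sphere grid result warns and returns an empty model so that batch
  workflows can record the failure and continue.
* The residue-volume YAML supports alternative parameter sets by label, but
  only the consensus set participates in modelling.
* Molecular weights use standard average residue masses plus one water per
  chain; the 280 nm absorption coefficient uses the standard
  Trp/Tyr/half-cystine extinction model (all cysteines assumed paired).
  With the consensus packing volumes, typical-protein partial specific
  volumes evaluate near 0.79 cm^3^/g, a little above the familiar
  experimental 0.73 -- a property of the volume set, not a bug.
* Multi-model NMR PDB files, mmCIF, per-atom form factors, $\chi^2$
  statistics and $P(r)$ inversion are out of scope.

## A worked example

```{r example}
ball <- make_atom_cloud("ball", n = 4000, radius = 2, seed = 1)
dry <- grid_transform(ball, boxside = 0.4, cutoff = 1)
wet <- hydrate_sphere_model(dry, hydration_cutoff = 5)
c(dry = sphere_model_volume(dry), wet = sphere_model_volume(wet))

curve <- debye_curve(distance_histogram(wet, nbins = 400),
                     seq(0.02, 2, length.out = 120))
fit <- guinier_rg(curve, 0.25, 0.75)
fit$rg                      # close to sqrt(3/5) * (2 + shell)

noisy <- make_experimental_curve(curve, noise_fraction = 0.02, seed = 2)
r_factor(curve, noisy, 0.1, 1.6)
```
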