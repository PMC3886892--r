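---
title: "Methods: restrained dimerization free-energy landscapes with memdimer"
author: "memdimer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restrained dimerization free-energy landscapes with memdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

When two membrane proteins approach each other laterally in a bilayer, the
free energy of association along their centre-of-mass separation — the
potential of mean force (PMF) — is shaped not only by direct protein-protein
contact but by the lipids trapped between them.  If the proteins' relative
*orientation* is held fixed, the PMF resolves a ladder of *restrained
metastable states*: local minima at separations where exactly one, two, or
three lipids pack optimally into the gap.  `memdimer` implements the full
analysis chain for this kind of experiment:

1. umbrella sampling along the inter-protein separation with a harmonic
   bias, plus a torque-only orientational restraint per protein;
2. PMF reconstruction by the weighted histogram analysis method (WHAM),
   with histogram-overlap diagnostics and a split-half convergence
   assessment;
3. landscape anatomy: quadratic sub-bin location of (meta)stable minima,
   well depths, and the outer "annulus-overlap" barrier;
4. prediction of the metastable separations from the annular lipid density
   around a *single* protein, by overlaying the radial density profile
   with its reversed copy;
5. probe-accessible (Shrake–Rupley) surface areas and the buried-area
   versus well-depth relation across orientational configurations.

Because production coarse-grained bilayer trajectories are not
distributable at package scale, `memdimer` ships a first-class synthetic
generator — a quasi-2D Langevin toy membrane — that reproduces the
*statistical* structure those analyses rely on, so that every stage is
exercised end-to-end by seeded, reproducible code.

# The toy membrane

`toy_config()` describes a periodic square box in the membrane plane
containing up to two rigid protein bodies of elliptical cross-section
(each a ring of `n_body_particles` particles) and `n_lipids` lipid discs.
Dynamics are overdamped (first-order) Langevin at fixed temperature:

$$ \mathrm{d}x = \frac{F}{\gamma}\,\mathrm{d}t +
   \sqrt{2 k_B T\, \mathrm{d}t/\gamma}\; \xi , $$

the cheapest dynamics whose stationary distribution is Boltzmann — which
is all that umbrella sampling and WHAM require.  Rigid bodies translate
with friction $n_b\gamma$ and rotate with friction $\gamma\sum_i |r_i|^2$,
driven by the summed forces and torques on their ring particles.

All pairs interact through a purely repulsive half-harmonic soft core,
$U(r) = \tfrac{\varepsilon}{2}(1 - r/\sigma)^2$ for $r<\sigma$.  We chose
this over a Lennard-Jones-type (WCA) core deliberately: its maximum force
is bounded ($\varepsilon/\sigma$), so the overdamped Euler–Maruyama
integrator is stable at practical timesteps, while at
$\varepsilon = 60\,k_BT$ the discs are effectively hard and develop the
same packing shells a harshly repulsive core would.

**Units.** Everything is in dimensionless toy units; the declared
`length_scale_nm` (default 1) is echoed into every output header so no toy
number can masquerade as a physical one.

**Default study conditions** (fixed once, from the physics): box side 15,
240 lipids of diameter 0.8 (packing fraction ≈ 0.57 of the free area —
dense enough for pronounced annular shells, safely below 2D freezing),
semi-axes 1.5/1.0, ring of 24 particles of diameter 0.6, $T=1$,
$\gamma=1$, timestep $10^{-3}$ (the stability number
$\Delta t\,\varepsilon/\sigma^2 \approx 0.09$ keeps single-step
displacements far below a lipid radius).  The modest axis ratio is a
compromise: stronger anisotropy would sharpen the wide-versus-narrow
contrast, but a narrow end much finer than a lipid locks into the
partner's lipid shells, and flat faces much longer than a lipid make
gap lipid exchange unequilibratably slow (see Limitations).  At this
density the first lipid shell sits ≈ 1.7 from the COM along the wide
face and successive shells are spaced ≈ one lipid diameter — the
structure the prediction step requires.

**What the toy does *not* emulate:** lipid chemistry and internal
structure, leaflet asymmetry (the upper/lower leaflet tags are
bookkeeping labels that exercise the channel logic; all discs live in one
plane), membrane elasticity, hydrophobic mismatch, and any specific
protein-protein attraction.  Passing tests on the toy therefore
demonstrate the *pipeline* and the lipid-packing mechanism, not chemical
accuracy for any real protein.

**Initial placement** is a jittered lattice excluding the body interiors,
with bounded rejection retries; an over-filled box is a placement error,
never a silent overlap.

# Restraints

The umbrella bias is the standard harmonic potential on the inter-COM
separation, $E = \tfrac{k}{2}(d-d_0)^2$, applied equally and oppositely to
the two bodies (`umbrella_energy_force()`).

The orientational restraint (`rotational_restraint()`) is a pivot-free
"radial motion" potential acting on the ring particles about the
out-of-plane axis through their current centre of mass:

$$ V = \frac{k_{rot}}{2} \sum_i
  \frac{\big[(\mathbf v \times \mathbf r_i)\cdot \Omega\, \mathbf r_i^0\big]^2}
       {|\mathbf v \times \mathbf r_i|^2 + \epsilon'} $$

with $\mathbf r_i$ the COM-relative positions, $\mathbf r_i^0$ the
COM-relative reference positions, $\Omega$ a rotation matrix (identity to
pin a fixed orientation) and $\epsilon'$ a small area-scale regularizer.
Three properties make it "torque-only", and they are the contract our
tests enforce rather than any particular algebraic form:

* the forces sum to zero (the potential depends only on COM-relative
  positions, so no net momentum is injected);
* the resultant is a torque along $\pm\mathbf v$;
* radial force components vanish to second order in the angular
  displacement.

Defaults $k_{rot}=60$, $\epsilon'=10^{-2}$ keep the toy rotational drift
within a few degrees over a standard window, which is what the
restrained-orientation analysis needs; both are configurable and echoed
into output metadata.  `rotational_drift()` reports the per-frame
least-squares (2D Kabsch) rotation angle against the reference, and
refuses mirror-image fits rather than returning a silent angle.

**Angle convention** (project-wide): orientation angles are measured in
degrees, counter-clockwise viewed from the extracellular side, from the
directed line COM(A)→COM(B) to the arrow from a protein's COM through its
marker particle on the wide face.  Thus 0° points the wide face at the
partner, and the four canonical configurations are (0°, 0°), (0°, 180°),
(0°, 90°), (90°, 90°).  For the mirror-symmetric toy ellipse the parallel
and anti-parallel wide-wide configurations are degenerate by
construction; we keep both presets because the recipe is written for
bodies that need not have that symmetry.

# WHAM

`build_histograms()` bins all windows on one shared grid (default bin
width 0.02 toy units, configurable); with an explicit range, out-of-range
samples are counted and reported, never silently dropped.
`solve_wham()` runs the standard self-consistent iteration over window
free-energy shifts $f_k$,

$$ p_b \propto \frac{\sum_k n_{kb}}{\sum_k N_k e^{(f_k - U_k(x_b))/T}},
 \qquad e^{-f_k/T} = \sum_b e^{-U_k(x_b)/T} p_b , $$

declared converged when no $f_k$ changes by more than the tolerance
(default $10^{-6}$ energy units) between iterations.  Design choices:

* bins with zero counts are reported as gaps (`NA`) — we never invent
  free energies by interpolation;
* windows not connected through jointly occupied bins are an error, not a
  silently disjoint solution;
* delipidated and lipidated windows at the same centre are pooled into
  one input set, with a provenance flag — sampling both states of the
  slow lipid-exchange process is what makes the contact region converge;
* the only statistical error estimate is the split-half discrepancy
  (`split_half_convergence()`): two full WHAM solutions on contiguous,
  non-intersecting halves of every window, referenced identically.  We
  deliberately do not bootstrap or use autocorrelation-weighted variants.

For validation the package carries exact 1D reference systems
(`potential_spec_1d()`, `sample_boltzmann_1d()`, `exact_free_energy_1d()`):
an inverse-CDF Boltzmann sampler and quadrature free energies against
which the WHAM solution can be compared bin by bin.

# Landscape anatomy

`find_local_minima()` keeps interior bins lower than both neighbours with
prominence at least 0.25 energy units by default — enough to suppress
sampling ripple while keeping genuinely shallow metastable states.
`quadratic_fit_minimum()` then fits a least-squares parabola over a
window (default two bins on each side) and reports the vertex to sub-bin
resolution, its curvature (non-positive curvature is a rejection, not a
minimum), and the sensitivity of the location to one-bin changes of the
window.  `well_depth()` is the deepest fitted minimum of a
zero-referenced profile — a negative number, per the convention that the
PMF is pinned to zero at large separation.  `find_barrier()` returns the
highest interior maximum in a search range, or an absent result (`NULL`)
for monotone profiles.

In the toy recipe PMFs are pinned at separation 7.0, the largest window,
where the inter-protein structure has decayed; the histogram support is
restricted to the window-centre range because bins beyond the outermost
windows are sampled only by exponential tails and would otherwise
contribute spurious edge minima.

# Annulus analysis and separation prediction

`align_frames()` rigidly transforms every frame so the chosen protein
superposes on its reference pose (2D Kabsch over the ring particles;
lipids are carried along minimum-image relative to the protein).
`accumulate_density()` histograms lipid observations on a square grid
around the protein (default: region side 8, 120×120 cells);
`radial_projection()` samples that map by bilinear interpolation along a
fan of lines from the COM (defaults: ±15° half-window, 1° spacing —
mandatory provenance entries, since reasonable values are a judgement
call), and `mean_profile()` averages leaflet channels.

`detect_peaks()` locates shell peaks with prominence and minimum-spacing
filters plus three-point parabolic refinement.  `predict_separations()`
then implements the overlay construction: place the profile's x-reversed
copy at trial separation $s$ (a reversed peak $r_j$ lands at $s-r_j$) and
choose $s$ so the prescribed peak pairs coincide —

* 1 intervening lipid: peak 1 on reversed peak 1, $s = 2r_1$;
* 2 lipids: peak 1 on reversed peak 2, $s = r_1 + r_2$;
* 3 lipids: peak 1 on reversed peak 3 *and* peak 2 on reversed peak 2 —
  overdetermined, resolved by least squares over the two prescribed
  pairs, $s = \big((r_1+r_3) + 2r_2\big)/2$.

The predicted separation is the position of the reversed profile's
origin — the predicted centre of the second protein.  In the end-to-end
toy experiment these predictions agree with the quadratic-fitted PMF
minima to within half a lipid diameter, which is the scale of agreement
one can ask of a desk-scale analogue.

To label which PMF minimum corresponds to how many intervening lipids,
`count_intervening_lipids()` counts, frame by frame, the lipids whose
centres lie between the two bodies' facing surfaces within ±0.6 of the
inter-COM axis (0.75 lipid diameters — wide enough for the single-file
channel, narrow enough to exclude the first off-axis shell).

# Buried surface area

`accessible_area()` is a deterministic Shrake–Rupley implementation: a
golden-angle spiral point set (default 960 points per sphere, 480 in the
frame-averaged profiles) on each probe-inflated sphere, points buried in
any other inflated sphere removed.  Toy bodies are treated as spheres of
the ring-particle radius at fixed out-of-plane coordinate — the probe
geometry of a surface calculation, kept in the toy's plane.  The probe
radius defaults to the toy lipid radius (0.4): the "solvent" whose
exclusion matters here is a lipid, which is also why the buried area
$A_{buried} = A_A + A_B - A_{complex}$ is the natural interface measure.
`buried_area_profile()` averages over the frames of the *stiffer* fine
windows (whose conformations stay close to the window centre),
`area_at_minimum()` evaluates a straight-line fit within ±0.3 of the PMF
minimum (one-sided fits are flagged as extrapolated), and
`depth_vs_area()` regresses well depth on buried area across
configurations; dispersion is reported as a standard deviation and
labelled as such.

# The canonical experiment

`experiment_plan()` bundles the full recipe; `run_experiment()` executes
it and writes TSV outputs plus a JSON manifest that reproduces
bit-for-bit under the same plan.  Defaults, chosen once:

* a stiff fine grid through the contact region — 0.05 spacing from 2.4
  to 4.6 with $k=400$, 1400 samples per centre split equally between a
  delipidated and a lipidated start, frames kept for the surface-area
  and lipid-count analyses — and a coarse tail grid bridging to the
  reference — 0.15 spacing from 4.6 to 6.1 with $k=100$ and 6000
  samples per window.  Free-energy differences accumulate stitching
  error along the chain of windows, so the tail grid is kept as short
  as a flat reference allows and carries most of the sampling time;
* per-configuration truncation of both grids just below the bodies'
  geometric contact separation (`toy_contact_separation()`): windows
  deep inside the overlap region cannot be sampled — the rings would
  interlock — exactly as a separation scan starts at the repulsive
  wall;
* 5000 equilibration steps per window, discarded;
* annulus shell peaks detected at 5% of the first-shell height with a
  minimum spacing of half a lipid diameter: the outer shells are
  10–15% relative modulations, well above bin noise at the configured
  sampling but far below the first shell;
* PMF minima matched to their lipid-count states conservatively: a
  minimum is "the" n-lipid metastable state only if its mean
  intervening-lipid count lies within 0.35 of n (mixed-count minima
  are transition shoulders, not states);
* minima reported at plan level with prominence 0.06 (the split-half
  ripple in the stiff-window region is ≈ 0.05 $k_BT$; 0.25, the
  conservative function default, filters out the genuinely shallow
  two-lipid state);
* the "restrained global minimum" is the deepest minimum of the
  contact region; tail ripples are listed in the minima table but never
  promoted to the well;
* a 216 000-step single-protein run (245 lipids, restoring the two-body
  packing fraction) for the annulus analysis — the second and third
  shell peaks are weak, and their positions enter the separation
  predictions directly, so this run carries generous sampling;
* per-window and per-configuration seeds derived deterministically from
  the master seed.

These problem sizes are the package's declared desk scale: large enough
that the wide-wide PMF resolves its contact well, its one- and two-lipid
metastable minima and the outer barrier, while a full four-configuration
experiment completes in minutes on one CPU.  The residual slow-mode
sampling noise in the long-range tail (of order 0.2–0.4 $k_BT$, visible
in the split-half discrepancy) is the honest price of that scale; it
perturbs absolute depths more than minima locations, which are set by
local structure.

`run_unrestrained_control()` repeats the pipeline with $k_{rot}=0$: the
bodies rotate freely, the lipid-packing shoulders wash out, and the
contact well and outer barrier persist — the control that shows the
metastable ladder is a property of the *restrained* system.

# Numerical choices and degenerate inputs

* Timestep $6\times10^{-4}$ keeps the maximum single-step displacement
  from the bounded repulsion well below a lipid radius; non-finite
  coordinates abort with the offending step number.
* A cell list handles lipid-lipid forces; forces, not positions, are the
  only quantities recomputed each step, and identical
  (config, restraints, seed) triples give bit-identical trajectories
  (the integrator consumes R's RNG stream under `set.seed()`).
* WHAM iterates in linear space with a normalization each sweep; the
  tolerance acts on the shifts $f_k$ in energy units.  Degenerate cases —
  empty windows, disconnected support, references in unsampled gaps —
  are errors that name the offender.
* Quadratic fits centre the abscissa before regression for conditioning;
  exact collinearity is rejected as non-curvature.
* `zero_reference()` subtracts the value of the bin containing the
  reference, making it exactly zero and the operation idempotent.

# Limitations

* The toy is quasi-2D with one disc per lipid: per-bead species channels
  of real coarse-grained lipids collapse into one density, and the
  leaflet distinction is purely formal.
* The toy protein is only ~4 lipid radii across, against ~25 nm vs
  0.47 nm in a real coarse-grained bilayer system.  Two consequences:
  (i) absolute well depths inherit a per-configuration offset of
  several tenths of $k_BT$ from the slow lipid modes along the
  window-to-reference stitch, so the *ordering of depths across
  orientations* has little statistical power at desk scale even though
  minima locations are stable; (ii) the narrow end's radius of
  curvature is comparable to a lipid, so a narrow tip can seat into
  the partner's first lipid shell (a commensurability effect with no
  analogue at realistic scale separation) and deepen the wide–narrow
  well.  The buried-area stratification, which is purely geometric, is
  unaffected; the depth stratification should be read with the
  split-half error in hand.
* Depths are relative to a finite reference separation inside a periodic
  box; they are comparable across configurations of the same plan, not
  absolute binding free energies.
* The split-half discrepancy is the only uncertainty estimate, by
  design; it underestimates errors from modes slower than half a window.
* No kinetics: nothing here says how fast the system crosses its
  barriers, only where they are.
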