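# memdimer

Free-energy landscapes of restrained membrane-protein dimerization.

## The problem

When two membrane proteins are held at a fixed relative orientation and
pushed together along the line joining their centres of mass, the free
energy of association — the potential of mean force (PMF),
F(d) = −k<sub>B</sub>T ln p(d) up to a constant — is shaped by the
lipids caught between them.  Restraining the orientations resolves
*restrained metastable states*: local PMF minima at separations where
exactly 1, 2 or 3 lipids pack optimally into the inter-protein gap.
Those separations can be *predicted* without any two-protein
simulation, from the annular lipid shells around a single protein:
overlay the radial lipid density ρ(r) with its x-reversed copy at trial
separation s and choose s so that prescribed shell peaks coincide
(s = 2r₁ for one intervening lipid, r₁+r₂ for two, ((r₁+r₃)+2r₂)/2 for
three).  The depth of the association well, in turn, tracks the
lipid-probe buried surface area of the dimer interface,
A<sub>buried</sub> = A<sub>A</sub> + A<sub>B</sub> − A<sub>complex</sub>.

`memdimer` implements this entire analysis chain for umbrella-sampling
data — harmonic separation biases plus torque-only orientational
restraints, WHAM reconstruction with overlap and split-half
convergence diagnostics, quadratic sub-bin location of minima and
barriers, annulus-density prediction, Shrake–Rupley surface areas —
together with a seeded quasi-2D Langevin toy membrane and exact 1D
Boltzmann reference systems, so the whole pipeline runs and is tested
end-to-end without external trajectory data.  It is aimed at people
who compute membrane-protein association PMFs from coarse-grained
simulations and want the orientation-resolved analysis as reusable,
validated code.

## Worked example

An exactly solvable 1D double-well (minima at 3 and 5, a 3 T barrier),
sampled with 15 umbrella windows of 10⁴ draws and reconstructed by WHAM:

```r
library(memdimer)

dw <- potential_spec_1d("double_well", params = c(4, 1, 3), domain = c(2, 6.5))
windows <- generate_umbrella_dataset(dw, seq(2.5, 6, by = 0.25),
                                     k_umb = 40, n_samples = 10000, seed = 1)
h <- build_histograms(windows, bin_width = 0.05, range = c(2.5, 6))
min(overlap_diagnostics(h)$overlap)
#> [1] 0.3607

pmf <- zero_reference(solve_wham(h), reference_separation = 4)
pmf
#> PMF profile: 70 bins on [2.525, 5.975], zero at 4.000
#>   WHAM: 566 iterations, final residual 9.86e-07

exact <- zero_reference(exact_free_energy_1d(dw, h$edges), 4)
good <- is.finite(pmf$free_energy) & colSums(h$counts) >= 100
sqrt(mean((pmf$free_energy[good] - exact$free_energy[good])^2))
#> RMS deviation from the exact free energy: 0.076 T

for (r in fit_minima(pmf, prominence_threshold = 1)) print(r)
#> global minimum at 2.9954 (depth -2.950, curvature 21.25, window [2.925, 3.125])
#> local minimum at 5.0083 (depth -2.911, curvature 15.89, window [4.875, 5.075])
```

Every adjacent window pair overlaps by at least 36%, the reconstruction
agrees with the closed-form free energy to 0.08 T on well-sampled bins,
and the quadratic fits recover both wells (truth: 3 and 5, equal depth)
to within half a bin.

The annulus overlay that predicts lipid-packed separations works from
shell peak positions alone.  With shells at 1.62, 2.01 and 2.40:

```r
shells <- data.frame(position = c(1.62, 2.01, 2.40))
for (n in 1:3) print(predict_separations(shells, n))
#> predicted separation 3.2400 with 1 intervening lipid(s)
#> predicted separation 3.6300 with 2 intervening lipid(s)
#> predicted separation 4.0200 with 3 intervening lipid(s)
```

The full toy experiment — four orientational configurations, each with
a stiff umbrella grid through the contact region and a coarse grid out
to the flat reference, WHAM, minima classified by their mean
intervening-lipid count, buried-area profiles, and the single-protein
annulus prediction — runs from one object:

```r
plan <- experiment_plan(seed = 1)
res  <- run_experiment(plan, outdir = "memdimer-out")
res$configurations$wide_wide_parallel$minima_table
res$prediction$predictions
res$depth_area_fit
```

and writes per-configuration PMFs, minima and buried-area tables, the
annulus profile and peaks, and a machine-readable `manifest.json` that
reproduces bit-for-bit under the same plan.  See the methods vignette
(`vignettes/memdimer-methods.Rmd`) for the model, the restraint
potential, all defaults and their rationale, and known limitations.

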