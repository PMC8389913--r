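# titania

Construction of hydroxylated TiO2 nanosurfaces and quantitative analysis of
phospholipid adsorption on them.

## The problem

When titanium dioxide nanomaterials (implant coatings, sunscreen particles,
photocatalysts) meet a cell membrane, phospholipids adsorb onto the hydrated
oxide surface through a small set of distinct contact geometries — direct
phosphate–Ti contact, amine/choline hydrogen bonding, water-mediated
phosphate contact.  Molecular-dynamics studies of this interface need a
reproducible chain of steps around the MD engine itself:

* **building** anatase/rutile slabs with a chosen Miller face, or spherical
  nanoparticles, and counting the undercoordinated surface titanium
  (Ti with 5 or 4 oxygen neighbours instead of the bulk 6);
* **hydroxylating** the surface the way water does at neutral pH —
  OH groups on 30% of randomly picked 5-fold Ti plus every 4-fold Ti,
  so N_OH = floor(0.30 · N_Ti(5)) + N_Ti(4) — and accounting for the
  resulting surface charge density sigma = N_OH · q_OH / area;
* **composing** the simulated system: lipid counts from half-coverage
  bilayer arithmetic at 0.6 nm² per lipid, 0.15 M NaCl plus the
  neutralizing cation excess;
* **analysing** trajectories into number-density profiles n(r) of the
  closest lipid headgroup atom versus distance to the nearest non-hydroxyl
  surface atom, and from them the per-mode binding probability

      P_b = ∫[r1, r2] n(r) dr / ∫[0, r_max] n(r) dr,

  occurrence-weighted mean residence times (lower bounds, because finite
  trajectories censor long dwells), and the fraction of lipids adsorbed
  within the 1 nm headgroup layer.

`titania` implements all of that in R, for structural-modelling and
simulation-analysis workflows.  Because microsecond MD is not
desk-computable, the package also ships a **synthetic-trajectory
generator** — an alternating-renewal process with known binding-mode
occupancies, dwell times and peak geometry — so that every analysis
estimator is validated against exact ground truth.  The methods vignette
(`vignettes/titania-methods.Rmd`) documents the model and every numerical
convention.

## Worked example

Build the anatase(101) slab at its published lateral size, hydroxylate it,
and analyse a synthetic 1 μs / 80-lipid trajectory:

```r
library(titania)

slab   <- build_slab("anatase", "101", n_u = 18, n_v = 7, n_layers = 3)
census <- compute_coordination(slab)
census
#> Ti-O coordination census (cutoff 2.60 A): 1512 Ti
#>   N_Ti(5) = 504, N_Ti(4) = 0; full distribution: 5:504 6:1008

plan <- plan_hydroxylation(census, fraction = 0.30, seed = 1,
                           exposed_area_nm2 = 2 * slab$face_area / 100)
plan
#> hydroxylation plan: 151 OH (151 of Ti(5) at 30%, 0 Ti(4)); q_OH = -0.40 e; seed 1
#>   surface charge density: -0.619 e/nm^2

fit <- binding_analysis(generate_distance_series(traj_spec(seed = 1)))
fit
#> lipid-TiO2 binding analysis: 80 lipids, 200000 frames (1e+03 ns)
#>   mode1              [0.110, 0.260) nm  P_b =   1.8%  residence >= 85.7 ns (17 events)
#>   mode2              [0.260, 0.360) nm  P_b =  20.2%  residence >= 7.6 ns (2127 events)
#>   mode3              [0.360, 0.730) nm  P_b =  24.2%  residence >= 5.9 ns (3286 events)
#>   adsorbed within 1.0 nm: 46.2%
```

Reading the numbers: the slab exposes 504 five-fold-coordinated Ti over its
two faces and zero four-fold ones, so the hydroxylation rule places
floor(0.30 × 504) = 151 OH groups, giving a surface charge density of
−0.62 e/nm² at the default hydroxyl charge of −0.40 e.  The fitted analysis
resolves the three generated binding modes as peaks of the closest-atom
density profile — a rare long-lived direct contact near 0.235 nm, a
hydrogen-bonding mode near 0.29 nm, and a water-mediated mode near
0.435 nm — and recovers their occupancies (`coef(fit)`), dwell means, and
the overall adsorbed fraction; the generator's ground-truth labels
(`label_truth()`) confirm each of them within the tolerances stated in the
vignette.  `binding_mode_table(fit)` and `adsorption_table(fit)` emit the
standard reporting tables, `plot(fit)` draws the profile with the detected
mode boundaries, and `simulate(fit)` generates new trajectories from the
fitted parameters.

A YAML-configured end-to-end run (build → hydroxylate → synthesize →
profile → bind, with every artifact seed-stamped) is available as
`run_pipeline()`.

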