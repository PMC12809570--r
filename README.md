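# memiso

Structure and dynamics of all-cis versus all-trans lipid bilayers.

Some *Pseudomonas* species survive sudden membrane stress by enzymatically
flipping the cis double bonds of their phospholipid tails to trans — a
response that acts in minutes, long before new lipid synthesis can.  A cis
double bond kinks the acyl chain; trans leaves it nearly straight.  `memiso`
quantifies what that one stereochemical change does to a bilayer: thickness
and total membrane volume, per-type area per lipid, acyl-chain order,
lateral diffusion, the kink angle at the unsaturation, and how often the
double bond itself comes within reach of the membrane surface, where a
peripheral enzyme could act on it.

The model system is a 100-lipid two-leaflet patch of the *P. putida* inner
membrane — PE and PG glycerophospholipids plus cardiolipin, per-leaflet
counts PYPE 10 / POPE 7 / YOPE 14 / PYPG 11 / POPG 6 / PVCL2 2, all
unsaturations Δ9.

## What it computes

For trajectories (PDB/GRO structures, DCD trajectories, or the built-in
synthetic generator):

* **thickness** — phosphate-to-phosphate distance between leaflets, and
  **volume** = box X × box Y × thickness;
* **area per lipid** — a ≤1 Å grid at ±18 Å from the phosphate midplane,
  each grid point assigned to the nearest lipid residue of that leaflet
  (exactly conservative: every cell assigned once);
* **order parameter** — S_CH = ⟨3 cos²θ − 1⟩/2 per carbon, θ between each
  C–H bond and the bilayer normal;
* **lateral diffusion** — MSD = ⟨|x − x₀|²⟩ of lipid-residue centroids in
  the membrane plane, and D = MSD/(2·n·t) with n = 2, estimated per chunk
  with standard errors over chunk × replicate samples
  (1 Å²/ns = 1 × 10⁻⁷ cm²/s);
* **kink angle** — interior angle at the double bond between the terminal
  and carbonyl carbons of the tail;
* **surface accessibility** — signed depth of double-bond carbons relative
  to the per-leaflet phosphate plane, and the fraction within 5 Å of it,
  plus the cis/trans accessibility ratio.

`isomerize_all()` converts membranes between conditions by rotating
everything distal to each C=C bond 180° about the bond axis (an exact
isometry and involution), and `synthetic_spec()`/`simulate_trajectory()`
generate seeded bilayer trajectories whose thickness, order, diffusion,
kink and surface-excursion statistics are all known in closed form — the
basis of the package's parameter-recovery test battery.

## Worked example

Generate a paired all-cis / all-trans replicate set at the default study
conditions and run every metric:

```r
library(memiso)

cfg <- pipeline_config(
  spec_cis   = synthetic_spec("cis",   seed = 1,   n_frames = 201),
  spec_trans = synthetic_spec("trans", seed = 901, n_frames = 201),
  n_replicates = 2)
report <- run_pipeline(cfg)
report
```

```
<comparison_report> cis vs trans over 4 replicates

           metric       cis     trans difference percent_vs_trans ...
       kink_angle 1.354e+02 1.494e+02 -1.397e+01          -9.3541
              sch 1.508e-01 2.500e-01 -9.919e-02         -39.6769
 surface_fraction 8.744e-03 1.545e-03  7.199e-03         465.8537
        thickness 3.901e+01 4.001e+01 -1.000e+00          -2.5005
           volume 1.267e+05 1.237e+05  3.056e+03           2.4714

surface fractions: cis 0.8744%, trans 0.1545%, ratio 5.66

diffusion (D = MSD/2nt, endpoint per chunk):
  type D_A2ns    D_cm2s se_A2ns n_samples condition
  PYPE 0.6461 6.461e-08 0.05308        10       cis
  PYPE 0.5002 5.002e-08 0.03683        10     trans
 PVCL2 0.2982 2.982e-08 0.05389        10       cis
  ...
```

Reading the output: the all-trans membrane is ~1 Å thicker but packs
tighter — the all-cis membrane carries ~2.5% more total volume and a larger
area per lipid.  Trans chains are straighter (kink angle 149° vs 135°) and
more ordered (S_CH 0.25 vs 0.15), and diffuse 10–20% more slowly
(5.0–5.2 vs 6.0–6.7 × 10⁻⁸ cm²/s; cardiolipin is roughly half as mobile
either way).  The sharpest contrast is accessibility: cis double bonds sit
within 5 Å of the phosphate plane ~0.9% of the time versus ~0.15% for
trans — a ~6-fold difference in how often the bond is presented to the
membrane surface.

Individual metrics are available directly — `thickness(traj)`,
`area_per_lipid(traj)`, `sch(traj)`, `msd(traj, n_chunks = 5)` with
`diffusion_coefficient()`, `kink_angles(traj)`, `double_bond_zdist(traj)`,
`surface_fraction(traj)` — on any annotated trajectory, whether simulated
or loaded with `read_structure()` / `read_trajectory()`.  Lipid
atom-naming roles come from a plain-text YAML table
(`inst/extdata/lipid_definitions.yaml`) that can be copied and extended.

## Limitations

XTC input is not supported (DCD, GRO, PDB are); boxes must be orthorhombic;
the generator models statistical structure (diffusion, order, depth
mixtures), not molecular energetics.  See the methods vignette
(`vignettes/membrane-isomerization.Rmd`) for the models, parameter
defaults, and numerical conventions.
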