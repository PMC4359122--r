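# bodyhull

Subject-specific **body segment parameters** (BSP) — per-segment mass,
centre of mass and full inertia tensor — from 3D surface scans of standing
subjects, for biomechanists running inverse dynamics who want
subject-specific values instead of population regression tables.

A multi-camera photogrammetry rig produces an unordered point cloud of the
skin surface; `bodyhull` implements everything downstream of that cloud:

1. scale/orient the cloud into a metric world frame (+z vertical) from a
   landmark pair of known separation (e.g. subject stature);
2. cut it into anatomical segments with landmark-defined planes
   (configuration-driven; the default ships head, trunk, and left/right
   upper arm, forearm, hand, thigh, shank, foot);
3. replace each segment by its **minimum convex hull** — optionally after
   subdividing curved segments (foot, shank, forearm, hand by default) with
   transverse cuts, hulling the parts and recombining them via the
   parallel-axis theorem, which reduces the hull's systematic volume
   overestimation of concave shapes;
4. integrate exact polyhedral mass properties at segment densities
   (trunk 940 kg/m³ so the lungs are part of the enclosed volume,
   1000 kg/m³ elsewhere), correct shod feet by a factor (default 0.51), and
5. close the total to the measured body mass with one pro-rata factor

   `s = m_subject / Σ m_hull,i`

   applied to every segment's mass **and** inertia tensor (moments and
   products), so reported masses sum exactly to body mass.

A synthetic humanoid generator with closed-form ground truth (spheres,
elliptical cylinders, truncated cones, plus volume-preserving *bent*
cylinders emulating shank/forearm curvature) provides end-to-end
validation, and an independent Monte-Carlo integrator cross-checks the
polyhedral integrals. See `vignette("hull-bsp-methods")` for the method in
full.

## Worked example

```r
library(bodyhull)

body <- generate_default_humanoid(height = 1.80, total_mass = 90.3)
scan <- sample_surface(body, n_points = 5000, seed = 42)
fit  <- body_bsp(scan$cloud, scan$landmarks, body$segmentation,
                 subject_record("S1", mass = 90.3, height = 1.80),
                 foot_factor = 1)   # barefoot synthetic subject
fit
```

```
Body segment parameters: subject 'S1' (90.3 kg, 1.80 m)
  hull mass before closure: 117.6 kg; pro-rata factor s = 0.7681
            name mass_kg mass_pct volume_m3 com_long_pct
       hand_left  0.5744   0.6361 0.0007479        50.90
    forearm_left  1.5410   1.7070 0.0020070        46.40
  upper_arm_left  3.2740   3.6260 0.0042630        50.00
      hand_right  0.5748   0.6366 0.0007484        50.90
   forearm_right  1.5410   1.7060 0.0020060        46.40
 upper_arm_right  3.2740   3.6260 0.0042620        50.00
            head  4.6810   5.1830 0.0060940        51.54
     upper_trunk 15.8600  17.5600 0.0219600        50.86
       mid_trunk 15.8300  17.5300 0.0219200        50.11
     lower_trunk 15.8200  17.5200 0.0219200        49.25
      thigh_left  7.8880   8.7350 0.0102700        45.63
      shank_left  3.6560   4.0480 0.0047590        43.53
       foot_left  2.1190   2.3470 0.0027590        50.00
     thigh_right  7.8890   8.7360 0.0102700        45.63
     shank_right  3.6570   4.0500 0.0047610        43.53
      foot_right  2.1220   2.3500 0.0027620        50.00
```

Reading the output: hull volumes times density summed to 117.6 kg, so every
segment was rescaled by `s = 0.7681`; the reported masses sum to exactly
90.3 kg and `mass_pct` to 100. `com_long_pct` is the CoM position along the
anatomical longitudinal axis (z; x for the foot) as a percentage of segment
length from the proximal landmark — 50 % for symmetric cylinders, ≈ 45.6 %
for the tapering thigh frustum. `summary(fit)` adds the full inertia
tensors (kg·m², about each segment's CoM in its anatomical axes; products
of inertia are stored signed), e.g. the left hand's diagonal here is
`1.28e-03, 1.42e-03, 4.39e-04` kg·m². Against the generator's closed-form
truth, these estimates recover segment masses within 2 % at this sampling
density (within 0.2 % at 20 000 points per segment).

For real scans: `read_point_cloud()` (ASCII PLY/OBJ/XYZ),
`read_landmarks()` (JSON), `scale_and_orient()`, then `body_bsp()` with
`default_segmentation()` — or drive everything from the shell with the
`inst/cli/bodyhull` script (`synth`, `segment`, `hull`, `validate`, `bsp`
subcommands). `write_bsp_report()` emits CSV/JSON with a header recording
subject, options and `s`.

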