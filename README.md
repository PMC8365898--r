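# vertamorph

Landmark-based para-sagittal plane morphometry of sub-axial cervical
vertebral endplates, with a full observer-reliability toolchain.

## The problem

Endplate dimensions between the mid-sagittal plane and the uncinate
processes matter for cervical implant design and preoperative planning, but
the para-sagittal region has few identifiable landmarks, so reproducible
section planes are hard to define on 3D vertebra models. `vertamorph`
implements a landmark-based construction on a triangle mesh of a single
vertebra (C3–C7):

1. **Mid-sagittal plane (MSP)** — the plane through three midline landmarks:
   the posterior endplate valley (PEV), the intersection point of the
   bilateral laminae, and the midpoint of the posterior rim of the inferior
   endplate (an extended landmark list triggers orthogonal regression).
2. **Lateral planes** — parallel to the MSP through the tip of each uncinate
   process.
3. **Quarter para-sagittal planes (QPSP)** — the average (mid-)planes
   between the MSP and each lateral plane.

Intersecting the vertebral body with the MSP and both QPSPs yields three
closed section curves. After re-alignment into the anatomical frame
(anterior `ap`, superior `si`, left `lr`), each curve is partitioned at its
four rim corners and three linear dimensions are measured per curve:

- **SED** — anteroposterior depth of the superior endplate (rim-to-rim chord),
- **IED** — anteroposterior depth of the inferior endplate (chord between
  the anterior and posterior rims of the inferior concave),
- **IECD** — inferior endplate concavity depth (maximum perpendicular
  distance from that chord to the endplate curve),

giving the nine per-vertebra values `LSED … RIED`. Reliability of repeated
measurements is assessed with Shapiro–Wilk-routed paired comparisons
(paired *t* vs exact Wilcoxon matched-pairs signed-rank) and intraclass
correlation coefficients (two-way random, absolute agreement, single
measures, ICC(2,1); values strictly above 0.75 are classed *excellent*).

Because no patient data ship with the package, a parametric vertebra
generator provides watertight meshes with closed-form truth:
`SED(x) = D0·√(1−(2x/W)²)` and `IECD(x) = c0·(1−(2x/W)²)` at lateral offset
`x ∈ {−W/4, 0, +W/4}`, plus an observer model (landmark jitter and
per-landmark bias) and a whole-study simulator.

## Worked example

```r
library(vertamorph)

fix <- generate_vertebra(vertebra_params())  # W=24, D0=16, H=12, c0=2.4 (mm)
measure_vertebra(fix$mesh, fix$truth$landmarks)
#>   label   sed_mm  iecd_mm   ied_mm
#> 1     L 13.84271 1.797333 13.84271
#> 2     M 16.00000 2.400000 16.00000
#> 3     R 13.84271 1.797333 13.84271
```

The mid-sagittal depths recover the generator parameters exactly
(MSED = D0 = 16 mm, MIECD = c0 = 2.4 mm); the quarter-plane values agree
with the closed forms 16·√0.75 ≈ 13.856 mm and 2.4·0.75 = 1.8 mm to about
0.1 % at the default 0.8 mm mesh resolution.

A simulated two-observer study (12 subjects × C3–C7, 0.3 mm landmark
jitter, observer two with a small systematic landmarking bias):

```r
design <- study_design()
dat <- simulate_measurement_study(design, mode = "geometric")
tab <- reliability_report(dat)
range(c(tab$intra_icc, tab$inter_icc))
#> [1] 0.8612431 0.9981102
mean(tab$intra_icc >= tab$inter_icc)
#> [1] 0.7333333
```

All 45 level × dimension cells are *excellent* (ICC > 0.75) for both the
intra- and inter-observer comparison, and the unbiased repeat sessions of
observer one agree better than the biased second observer in most cells.

Real meshes are measured the same way:

```r
case <- load_case("vertebra.stl", "landmarks.json", level = "C5")
rec  <- measure_vertebra(case$mesh, case$landmarks)
write_measurements(rec, "vertebra.csv", specimen_id = "S01", level = "C5")
```

A thin command-line wrapper lives at `inst/cli/vertamorph.R` with
subcommands `measure`, `slice`, `report`, `simulate`, and `gen-fixture`.

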