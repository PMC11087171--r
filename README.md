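# ringplan

Multi-field IMRT planning toolkit for whole breast / chest wall plus
regional lymph nodes on ring-gantry (Halcyon/Ethos-class) treatment
machines.

## The problem

Ring-gantry linacs have a closed 100 cm bore and a longitudinal field size
limited to 14 cm from the isocenter, which rules out the conventional
monoisocentric three-field technique (tangents + supraclavicular field)
whenever the regional nodes must be treated with the breast or chest wall.
A practical alternative is a single-isocenter arrangement of 15–17 static
IMRT fields that mimics a partial VMAT arc while keeping per-field skin
flash editable for free-breathing patients. `ringplan` implements that
workflow — and everything needed to evaluate it — for medical physicists
and dosimetrists who want a scriptable, TPS-independent implementation:

* **Beam placement** — the full arrangement is derived from one planner
  choice, the medial tangent angle θ. In lateral-sign units (+ toward the
  ipsilateral hemithorax) the gantry offsets are
  `−8k, …, −8, 0, +8, +16, +32, +48, +144, +160, +176, +184, +192, +200,
  +208, +216, +240±8`, i.e. a medial fan, a 96° jump to the lateral fan,
  and a posterior axillary boost (PAB) 24° past the last lateral field.
  No two fields are ever directly opposed (min over pairs of
  `||Δ|−180| ≥ 4°`). Bore clearance of points outside the CT (the
  contralateral elbow) is checked against the 500 mm bore radius.
* **Planning volumes** — exact Euclidean margin morphology on voxel masks:
  CTV→PTV expansion (5 mm; 0 mm for internal mammary nodes), skin pullback
  (5 mm breast / 2 mm post-mastectomy), esophagus PRV cropping (3 mm),
  conformity ring (body ∖ (PTV ⊕ 5 mm)), virtual bolus shells.
* **DVH metrics** — `VxGy[%/cc]`, `Dxcc[Gy]`/`Dx%[Gy]` (sorted-accumulation
  with within-voxel interpolation), `Mean`, `Max`, from raw voxel doses.
* **Scorecards** — piecewise-linear score functions with red / yellow /
  green / blue bands; shipped left/right cards total exactly 200 points,
  the technique-comparison card 153.
* **Gamma QA** — global 3% / 2 mm gamma analysis with a 10% low-dose
  threshold, for 2D planes and 3D grids, with an institutional 95%
  pass-rate check.
* **Exact rank-sum comparison** — two-sided Wilcoxon rank-sum p-values by
  full enumeration (midranks for ties); two separated groups of five give
  the exact floor p = 2/252 ≈ 0.00794.
* **Thorax phantom + toy dose engine** — a parametric synthetic thorax and
  a ray-cast dose simulator so the entire pipeline runs end to end with no
  clinical data.

## Worked example

```r
library(ringplan)

# 15-field left-sided arrangement from a 310 degree medial tangent
arr <- generate_arrangement(310, "LEFT")
arr$fields[c(2, 7, 15), ]
#>                  id           role offset_deg gantry_deg
#>  F02_MEDIAL_TANGENT MEDIAL_TANGENT          0        310
#>     F07_LATERAL_ARC    LATERAL_ARC        144         94
#>             F15_PAB            PAB        240        190

# synthetic thorax, simulated dose, scored against the 200-point card
ph     <- build_phantom(phantom_spec("LEFT", c(64, 64, 48), c(4, 4, 4)))
dose   <- simulate_dose(arr, ph)
card   <- packaged_card("left")
specs  <- do.call(rbind, lapply(card$functions, function(f)
            data.frame(structure = f$structure, metric = f$metric)))
report <- score_plan(card, metrics_table(dose, ph$structures, specs))
report$total
#> [1] 109.4872
```

The medial tangent sits at 310°, the first lateral field at
`310 + 48 + 96 = 94°` (mod 360), the PAB at `310 + 240 = 190°`. The plan
total of ≈109 of 200 points reflects the phantom engine's nature: nodal
coverage and conformity rows score at or near their maxima (the simulated
dose is homogeneous across each target), while absolute organ-at-risk rows
(heart mean, lung V20Gy) sit in their failing bands because the toy engine
does not trade target dose against organ dose the way a clinical optimizer
does. Comparisons *between* phantom plans are meaningful; absolute clinical
realism is not claimed.

```r
# exact rank-sum: ipsilateral lung V20Gy for five phantoms planned two ways
exact_ranksum_p(c(28.2, 27.5, 29.0, 28.9, 30.1),   # comparator technique
                c(19.6, 19.1, 20.3, 18.8, 19.9))   # multi-field IMRT
#> [1] 0.007936508   # = 2/252, complete separation of two fives
```

A thin command-line wrapper over the same functions ships in
`inst/cli/rtplan.R` (subcommands `beams`, `metrics`, `score`, `gamma`,
`ranksum`, `phantom`, `run`).

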