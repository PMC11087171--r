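---
title: "Methods: multi-field breast/nodal IMRT planning on ring-gantry machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-field breast/nodal IMRT planning on ring-gantry machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringplan)
```

# The planning problem

Ring-gantry linacs of the Halcyon/Ethos class have a closed 100 cm bore and
a longitudinal field size limited to 14 cm from the isocenter under a
half-beam block. Treating the whole breast or chest wall *together with* the
supraclavicular, axillary and internal mammary nodes therefore cannot use
the conventional monoisocentric three-field (tangents plus supraclavicular)
technique. One workable alternative is a single-isocenter, multi-field
(15–17 beam) static IMRT arrangement that mimics a partial VMAT arc while
keeping per-field fluence editable — important for free-breathing patients,
where skin flash on the tangential fields mitigates respiratory motion.

`ringplan` implements that workflow as a scriptable toolkit: beam placement,
planning-volume construction, DVH metrics, piecewise-linear scorecards,
gamma-index QA, exact rank-sum cohort comparison, and a synthetic thorax
phantom so the entire chain can be exercised (and tested) without clinical
data.

# Beam placement

All angles are IEC 61217 gantry angles (0° anterior, 90° at the patient's
left), normalized to `[0, 360)` after any arithmetic. The planner makes one
choice — the medial tangent angle — and every other field is derived from it
by a fixed offset sequence, rotated laterally over the ipsilateral
hemithorax:

* up to four optional extra medial fields in 8° steps (default one,
  giving 15 fields in total);
* the medial tangent, then two fields in 8° steps and two in 16° steps
  going laterally;
* a 96° jump from the most lateral of those fields to the first lateral
  field (skipping the arc segment that would enter through the
  contralateral breast or directly oppose the medial fields);
* two fields in 16° steps and five in 8° steps continuing laterally;
* a posterior axillary boost (PAB) 24° past the final lateral field,
  adjustable by ±8° for anatomy.

```{r beams}
arr <- generate_arrangement(310, "LEFT")
arr$fields[c(1, 2, 7, 15), ]
```

Three conventions in this module were genuinely open and are fixed as
follows:

* **Lateral rotation sign.** "Laterally" is resolved to +1 (increasing
  gantry angle) for left-sided targets and −1 for right-sided ones, so the
  gantry sweeps over the ipsilateral hemithorax and the PAB lands
  posteriorly for typical tangent angles. Right-sided arrangements are exact
  mirrors of left-sided ones about the 0°/180° axis.
* **"Final medial field".** The 96° jump is measured from the most lateral
  field of the medial group (offset +48°), which reproduces the 14-offset
  base sequence and the partial-arc intent.
* **Opposed-beam tolerance.** Directly opposed beams degrade plan quality;
  an arrangement is rejected when any pair satisfies
  `||Δgantry| − 180| < 4°`, half the smallest placement increment. All
  on-lattice arrangements clear this bound by construction (the closest
  pairs sit at 176°/184°), so a violation signals a pathological manual
  edit rather than a bad tangent choice.

`check_bore_clearance()` screens collision points that are usually outside
the CT field of view (most often the contralateral elbow, localized at
simulation by its lateral distance from midline and height above the couch)
against the bore radius (default 500 mm) minus a safety margin (default
10 mm), measured radially from the rotation axis.

# Planning-volume morphology

Margins are Euclidean and voxel-center exact: a voxel belongs to an
expansion iff its center lies within the radius of some occupied voxel
center, with anisotropic spacing respected (CT slices are commonly 1.5 mm
against finer in-plane spacing). Voxel-center membership (rather than
partial-volume weighting) keeps every operation deterministic and
oracle-checkable; all outputs share the input geometry bit for bit. One
consequence worth knowing: on a discrete lattice, expanding by `a` then `b`
is contained in (but not always equal to) expanding by `a + b`, because the
intermediate point of the triangle inequality need not be a voxel center.

The default `margin_policy()` encodes the institutional rules: 5 mm
CTV-to-PTV margins for breast and nodal volumes, 0 mm for the internal
mammary chain (CTV = PTV), skin pullback of 5 mm for intact-breast and 2 mm
for post-mastectomy planning volumes, a 3 mm esophagus PRV margin cropped
out of the supraclavicular PTV, a 5 mm margin around the total PTV when
carving the conformity ring, and a 5 mm virtual bolus shell. The clinical
convention is itself ambiguous on one point — intact-breast PTVs are
described both as "pulled back to match the CTV" (5 mm) and chest walls as
not pulled back while post-mastectomy planning uses 2 mm — so both depths
are exposed in the policy rather than resolved silently.

Edge behavior: voxels outside the grid are *not* treated as body exterior,
so a body cropped by the scan boundary does not erode planning volumes from
that face. The bolus shell is purely geometric here; its dosimetric effect
(a tissue-density shell) is applied only inside the phantom simulator.

# DVH metrics

Metrics are computed from raw voxel doses, never from a binned curve, which
avoids binning bias in hot-spot metrics such as V52.5Gy. Canonical strings
(`"V50Gy[%]"`, `"D0.03cc[Gy]"`, `"Mean[Gy]"`, …) parse to typed specs.
`DxCC` sorts voxel doses descending, accumulates volume with anchor points
at whole-voxel volumes, and interpolates linearly within the voxel that
crosses the requested volume; requests at or below one voxel volume return
the hottest voxel's dose (within-voxel interpolation cannot exceed the
maximum). This matters because 0.03 cc is usually smaller than one voxel,
and the acceptance tolerance for `DxCC` against a brute-force oracle is
correspondingly half a voxel's dose span; `V` and `Mean` agree with voxel
enumeration exactly. Cumulative DVH curves default to 0.05 Gy bins and are
used for plotting and the mean-dose/integral identity, not for metrics.

# Dosimetric scorecards

Each metric is scored by a piecewise-linear function from a failing
breakpoint (0 points) through optional intermediate anchors to a
deliberately unachievable maximum; values beyond either terminal clamp.
Bands translate points into the usual colors: red below the acceptable
range, yellow, green at the clinical benchmark (by default 80% of a
function's maximum, configurable per function), blue reserved for the
unachievable terminal. Totals are sums of row points, so improving any one
metric can never lower a plan's total.

The shipped cards fix the published maxima — 200 points for the dedicated
left- and right-sided IMRT cards, 153 for the technique-comparison card —
but the per-metric weights inside those totals are this package's own
design (the published rubrics state totals and clinical criteria, not
weights): coverage metrics carry the largest weights, then heart,
ipsilateral lung, and contralateral structures. Failing breakpoints sit at
the clinical criteria (ipsilateral lung V20Gy fails above 35%, heart mean
above 5 Gy, heart D0.03cc above 53 Gy, …), green anchors at the
institutional expected values. The left/right cards additionally carry the
two conformity rows that dominate field-number comparisons — near-maximum
dose to the body and to the conformity ring (body minus PTV + 5 mm) — with
failing points at 110% of the 50 Gy prescription and benchmarks at 105%.
Cards serialize to a JSON schema and round-trip losslessly.

# Gamma-index QA

`gamma_index()` implements the global-normalization gamma test at the usual
patient-QA criteria: 3% dose difference, 2 mm distance to agreement, 10%
low-dose threshold, for 2D planes (the measurement geometry) and 3D grids
alike. Open choices, fixed as defaults and exposed in `gamma_params()`:

* normalization dose is the reference maximum (the convention paired with a
  10% threshold); a prescribed normalization is available;
* the threshold applies to reference points only — evaluated points below
  it may still serve as comparison candidates;
* search radius 3× the DTA, evaluated dose linearly interpolated at DTA/10
  steps (the step is capped at DTA/2). Reference positions are snapped to
  the interpolation lattice, bounding the geometric error by half a step.

Two closed forms pin the implementation down: a uniform +3% offset yields
gamma exactly 1 everywhere (spatial search cannot absorb a uniform offset),
and +4% yields 4/3. A dense brute-force search with independent bilinear
interpolation serves as the test oracle on random planes.

# Exact rank-sum comparison

Cohort comparisons use the exact two-sided Wilcoxon rank-sum test by full
enumeration of all `choose(n + m, n)` group assignments (bounded at 10^6;
larger cohorts are refused rather than silently approximated). Ties receive
midranks, and the two-sided p-value doubles the smaller tail, capped at 1 —
with ties the null distribution is not symmetric, so tail doubling is the
honest two-sided rule. For two groups of five with complete separation the
smallest attainable p-value is `2/252 ≈ 0.00794`, which is exactly what
separated coverage metrics produce. Note that a two-sided p-value of
0.00476 is *below* this floor for n = m = 5 and cannot arise from this
test; such a value would indicate a one-sided test or a different
procedure, and this package deliberately exposes only the two-sided exact
form.

# The thorax phantom and its dose engine

The phantom reduces the clinical structure set to the scored subset: body,
breast (CTV 5 mm inside the skin), supraclavicular and three-level axillary
node spheres, an IMN chain along the sternum, heart, both lungs (density
0.3 against tissue 1.0), esophagus and contralateral breast. Planning
volumes are built through the morphology module, so the phantom exercises
the same code paths as external data. Right-sided phantoms are exact
mirrors. A per-phantom seed jitters solid centers and semi-axes (default
SD 3 mm in cohort generation) to emulate inter-patient variation; the
construction is bit-reproducible given the seed.

The dose engine is deliberately simple — parallel (non-divergent) rays,
exponential attenuation (0.005/mm) of density-scaled radiological depth
without build-up, apertures equal to the beam's-eye-view projection of each
field's target expanded by a 7 mm margin (standing in for skin flash), and
a 4 mm Gaussian penumbra. Per-ray fluence is compensated to the mean
radiological depth of the field's target in that ray's aperture bin, so
each field delivers a uniform dose across its target; this is the engine's
stand-in for inverse-optimized fluence modulation and is what lets
multi-field arrangements spread entrance dose over more directions, the
geometric effect behind the field-number experiment. The summed dose is
normalized so the median breast/chest-wall PTV dose equals the 50 Gy
prescription (25 fractions, 45 Gy nodal level carried in the parameters).

What the phantom does and does not show: doses are linear in field weights,
nonnegative, reproducible, and geometrically faithful (coverage responds to
aperture margin, conformity to field count, laterality mirrors exactly) —
but absolute organ-at-risk doses are far higher than any optimized clinical
plan achieves, because nothing in the engine trades target dose against
organ dose. Median normalization also puts the prescription isodose at
exactly 50% of the target by construction, so prescription-level V-metrics
hover near 50 and the informative coverage metrics on the phantom are the
near-prescription ones (V47.5Gy, V45Gy). Passing tests therefore validate
the *machinery* (placement, morphology, metrics, scoring, statistics), not
clinical dose realism; the clinical DVH values reported for real patients
are not reproducible here and are not targets.

The comparator technique for paired cohorts is a four-field stand-in (a
breast-shaped tangent pair 184° apart, an anterior nodal field and a PAB,
the nodal fields shaped to the nodal PTVs only), which reproduces the
*statistical structure* of a technique comparison: several metrics separate
completely across five phantom pairs and return the exact floor p-value of
2/252 from either direction.

# Problem sizes and numerical choices

The phantom's documented default is a 128×128×96 grid at 2 mm isotropic
spacing. The test suite and the worked examples run the same code on
64×64×48 at 4 mm (and 48×48×32 at 5 mm for unit tests), which preserves
every geometric property being asserted while keeping the full suite to a
few minutes on one core; ray marching steps at the smallest voxel spacing.
Morphology oracles run on grids up to 20³ where the all-pairs brute force
is exact and fast. Ties in sorting (equal voxel doses) need no tie-break:
every metric is a function of the multiset of doses. Degenerate inputs are
rejected loudly — empty masks, zero reference maxima, all-zero field
weights, PTVs escaping the body, enumeration beyond the exact regime.

# Known limitations

* No DICOM reader: volumes are exchanged through the package's gzipped
  plain-text array-volume format (`write_volume()` / `read_volume()`).
* The dose engine is not a clinical dose algorithm (no divergence, no
  build-up, no scatter, no MLC sequencing) and must not be used for
  anything but method development and testing.
* Couch and collimator angles are fixed at 0; dual-isocenter feathering and
  fluence editing are out of scope.
* The exact rank-sum test refuses cohorts beyond the enumeration bound
  rather than switching to a normal approximation.
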