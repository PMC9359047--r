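# anatmatch

Knowledge-based radiotherapy treatment planning by **direct 3D patient
anatomy match**. Given a new patient's contours and a database of previously
treated patients with their achieved dose–volume parameters, `anatmatch`
finds the anatomically most similar database patients and transfers their
achieved rectum and bladder V50Gy values to the new patient as personalized,
demonstrably achievable optimization constraints.

The package is aimed at medical-physics researchers studying knowledge-based
planning (KBP) for pelvic (e.g. cervical-cancer) IMRT, where the standard
protocol template must be tightened per patient according to how close the
rectum and bladder sit to the planning target volume (PTV).

## Method

Anatomical similarity is scored on full 3D binary masks rather than
low-dimensional surrogates (OVH, distance-to-target histograms):

1. **PTV registration (translation only).** The candidate's PTV mask is
   aligned to the test patient's PTV by maximizing the voxel overlap

   `S(u,v,w) = Σ_xyz  I_test(x,y,z) · I_match(x−u, y−v, z−w)`,

   which is equivalent to minimizing the binary squared error. The
   correlation over all integer translations is computed with zero-padded
   3D FFTs (linear, not circular, correlation; masks are cropped to their
   bounding boxes first), and an exact spatial-domain implementation
   (`bruteForceCorrelation`) serves as a verification oracle.
2. **Dice ranking, two stages.** After moving the candidate's PTV, rectum
   and bladder by the single PTV-registration translation, similarity is
   the Dice coefficient `DSC = 2|A∩B| / (|A|+|B|)`. The top 20 patients by
   PTV DSC are kept; among them, the top 3 by rectum DSC and — independently
   — the top 3 by bladder DSC are selected.
3. **Constraint transfer.** The minimum achieved V50Gy among each organ's
   top 3 becomes that organ's personalized constraint; every other row of
   the institutional objective template (PTV uniform 50 Gy / Dmin 49.5 /
   Dmax 52 / V50Gy ≥ 96 %, femoral heads, small intestine, spinal cord) is
   kept verbatim.

DVH utilities (`cumulativeDVH`, `vAtDose`, `dAtVolume`, `doseMax`,
`homogeneityIndex = 100·(D2−D98)/D_Rx`, `evaluatePlan`,
`comparePlanCohorts`) evaluate plans against the clinical goals
(PTV V50Gy > 96 %; rectum/bladder V50Gy < 50 %; femoral heads and small
intestine V50Gy < 10 %; small-intestine Dmax < 52 Gy; cord Dmax < 45 Gy)
and compare plan cohorts with a paired t-test.

Because no clinical database ships with the package, a **synthetic pelvic
cohort generator** (`makePhantom`, `makeDatabase`) produces jittered
ellipsoid/tube/sphere anatomies on a common 2.5 mm grid, and a logistic
dose-falloff surrogate (`synthDose`) assigns each phantom an achievable
dose, so the complete pipeline is testable end to end.

## Worked example

```r
library(anatmatch)

db   <- makeDatabase(30, phantomParams(), doseModelParams(), seed = 7)
test <- db[[30]]                      # leave-one-out: ID match is excluded
sel  <- matchPatient(test, db, kPtv = 20, kOar = 3)
sel
#> MatchSelection: 29 scored, top-20 PTV match
#>   rectum top:  SYN010, SYN002, SYN018
#>   bladder top: SYN013, SYN029, SYN018
#>   constraints: rectum V50Gy 9.06%, bladder V50Gy 8.28%
```

The score table holds, per candidate, the PTV/rectum/bladder Dice values
and the registration translation in voxels:

```r
head(scoreTable(sel)[order(-scoreTable(sel)$dsc_ptv), ], 3)
#>    patient_id   dsc_ptv dsc_rectum dsc_bladder tu tv tw
#> 2      SYN002 0.9756352  0.6007394   0.5310884  5  0 -1
#> 23     SYN023 0.9753140  0.2004890   0.5782930  7 -1  2
#> 11     SYN011 0.9675491  0.5248092   0.5464295  1 -2 -1
```

`deriveConstraints()` yields the personalized objective set: the template
with the rectum and bladder rows replaced by the transferred V50Gy values
(9.06 % and 8.28 % here — the smallest achieved value among each organ's
three best-matched patients):

```r
deriveConstraints(sel, db)
#>          structure       metric     value units
#> 1              PTV MinimumV50Gy 96.000000     %
#> 2              PTV         Dmax 52.000000    Gy
#> 3              PTV         Dmin 49.500000    Gy
#> 4              PTV  UniformDose 50.000000    Gy
#> 5           rectum        V50Gy  9.062254     %
#> 6          bladder        V50Gy  8.279763     %
#> 7   femoral_head_L        V45Gy  5.000000     %
#> 8   femoral_head_R        V45Gy  5.000000     %
#> 9  small_intestine        V45Gy 10.000000     %
#> 10 small_intestine         Dmax 50.000000    Gy
#> 11     spinal_cord         Dmax 42.000000    Gy
```

Evaluating this patient's synthetic plan against the clinical goals:

```r
res <- evaluatePlan(synthDose(test@structures, doseModelParams()),
                    test@structures)
res$goals[, c("structure", "metric", "value", "comparator", "goal", "status")]
#>         structure metric        value comparator goal  status
#> 1         bladder  V50Gy 1.617952e+01          <   50    pass
#> 2  femoral_head_L  V50Gy 0.000000e+00          <   10    pass
#> 3  femoral_head_R  V50Gy 0.000000e+00          <   10    pass
#> 4             PTV  V50Gy 1.000000e+02          >   96    pass
#> 5          rectum  V50Gy 3.914037e+01          <   50    pass
#> 6 small_intestine   Dmax           NA          <   52 missing
#> 7 small_intestine  V50Gy           NA          <   10 missing
#> 8     spinal_cord   Dmax 2.411998e-04          <   45    pass
```

Structures absent from a patient (here the small intestine, which the
phantom does not model) are reported as `missing`, never as failures.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch under a
given seed — it synthesizes an 81-patient cohort, matches held-out test
patients in leave-one-out fashion, derives their constraints, and evaluates
a synthetic plan against the clinical goals — then writes the JSON report
to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The package covers contour I/O and rasterization, registration, similarity
matching, constraint derivation, DVH evaluation and the synthetic cohort.
Treatment-planning-system integration (plan creation, beam placement,
ring-structure scripting, inverse optimization) is out of scope; the
hand-off artifact is the TPS-agnostic `objectives.json`. Because neither a
DICOM nor a NIfTI reader is available in this R stack, contours, doses and
cached masks use documented plain-text JSON formats with the same semantics
(see `?readContourSet`, `?readDoseGrid`, `?writePatientRecord`).
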