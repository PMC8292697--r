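# rtqa — radiotherapy quality surveillance toolkit

`rtqa` is a desk-scale R implementation of the computational core of a
radiotherapy quality-surveillance platform, for medical physicists,
radiation-oncology informaticists and quality managers who want the
machinery of plan- and practice-level QA without a clinical deployment:

* **DICOM-RT I/O** — read/write the RT Structure Set, RT Dose and RT Plan
  storage classes (Explicit VR Little Endian) into a small, typed data
  model; all geometry in the DICOM patient coordinate system, mm.
* **TG-263 nomenclature** — normalize raw planning-system structure names
  and suggest standardized names by exact/synonym lookup plus normalized
  Levenshtein similarity, for human confirmation.
* **DVH engine** — rasterize contours onto the dose grid (even-odd rule,
  boundary-inclusive, optional supersampling) and evaluate cumulative DVHs
  plus the standard metric grammar: `Dx%`, `Dx cc`, `Vx Gy`, `Dmean`,
  `Dmax`, `Dmin`. Metrics are computed on exact occupancy-weighted voxel
  doses, never on curve bins. For a cumulative DVH, V(d) is the percent of
  structure volume receiving at least dose d; Dx% is the dose to the
  hottest x% of the volume.
* **Constraint grading** — PASS / acceptable VARIATION / FAIL per
  dose constraint (boundary equality satisfies a limit), with worst-of
  plan status and `NOT_EVALUABLE` handling for absent structures.
* **Clinical templates** — discrete consult / simulation / on-treatment /
  end-of-treatment / follow-up records with schema validation (AJCC,
  CTCAE, ECOG vocabularies as configuration), automatic NCCN prostate risk
  grouping, cross-template auto-population, and a lossless
  narrative-render / discrete-extract round trip.
* **CQM engine** — clinical quality measures as declarative JSON decision
  trees over record/plan/DVH features, producing per-measure pass/fail
  (1/0) scorecards with replayable path traces.
* **De-identification** — keyed pseudonyms, uniform per-patient date
  shifting (intervals preserved), DICOM UID remapping that keeps the
  RTSTRUCT/RTDOSE/RTPLAN triplet consistent, and sha-256 integrity
  sealing over a canonical serialization.
* **Benchmarking** — per-practice, per-measure pass rates and outlier
  flagging by the exact binomial central interval at the pooled national
  rate.
* **Synthetic data** — geometric phantoms with analytically known volumes,
  analytic dose fields (uniform, linear gradient, spherical falloff) and
  schema-conformant synthetic prostate/lung patient records, so the whole
  pipeline is testable without clinical data.

## Worked example

A cylindrical "rectum" phantom beside a spherical-falloff dose field,
renamed to TG-263, with DVH metrics graded against a constraint:

```r
library(rtqa)

frame  <- rtqa_uid("demo")
rectum <- make_structure(
  phantom_spec("CYLINDER", center = c(0, 20, 0), dimensions = c(12, 40),
               slice_thickness = 2), name = "rect", roi_number = 1L)
field  <- dose_field_spec("SPHERICAL_FALLOFF", center = c(0, 0, 0),
                          peak = 82, radius = 100)
grid   <- make_dose_grid(field, origin = c(-40, -40, -24),
                         spacing = c(2, 2, 2), shape = c(41, 41, 25),
                         frame_of_reference = frame)

suggest_tg263("rect", read_lexicon())
#>   tg263_name score match_kind
#> 1     Rectum     1    SYNONYM

dvh <- compute_dvh(rasterize_structure(rectum, grid, supersample = 2), grid)
dvh
#> <rt_dvh> rect: 17.92 cc, Dmean 62.38 Gy, Dmax 75.44 Gy
for (m in c("V70Gy", "D2%", "Dmean"))
  cat(sprintf("%-6s %6.2f\n", m, as.numeric(evaluate_metric(dvh, m))))
#> V70Gy    6.81
#> D2%     72.30
#> Dmean   62.38
```

`V70Gy = 6.81` means 6.81% of the structure volume receives at least
70 Gy; `D2% = 72.30` is the dose (Gy) to its hottest 2%. Grading against
a `V70Gy <= 20% (variation <= 25%)` constraint:

```r
curve <- dvh; curve$structure_name <- "Rectum"
evaluate_constraint(curve,
  dose_constraint("Rectum", "V70Gy", "LE", pass_limit = 20,
                  variation_limit = 25))$status
#> [1] "PASS"
```

Synthetic records feed the derived-field and CQM machinery:

```r
rec <- make_patient_record("PROSTATE", seed = 8,
  overrides = list(psa = 22, gleason_primary = 4L, gleason_secondary = 4L))
rec$encounters$CONSULT$fields$risk_group
#> [1] "HIGH"   # auto-calculated from T stage, Gleason and PSA
```

A command-line front end (`exec/rtqa`) wraps the same functions:
`rtqa ingest | rename | dvh | grade | score | anonymize | aggregate | synth`.

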