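---
title: "rtqa: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rtqa: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtqa)
```

`rtqa` implements the computational core of radiotherapy quality
surveillance: dose-volume evaluation of treatment plans, standardized
structure naming, discrete clinical documentation, rule-based quality
measures, de-identification, and cross-practice benchmarking. This
vignette records the model conventions, the tunable parameters, and the
design decisions that were genuinely open, so results can be interpreted
and reproduced precisely.

## Data model and coordinate conventions

All geometry lives in the DICOM patient coordinate system in millimetres.
Structures are sets of closed planar contours (constant z per contour,
at least three points). Dose grids are regular, axial and non-tilted
(identity direction cosines); any other orientation is rejected
explicitly rather than resampled, because silent reorientation is a
classic source of DVH errors. Voxel indices never leak outside the DVH
engine. Stored dose values are integers times a scaling factor, so a
write/read cycle quantizes doses to `scaling/2` at worst (default
`1e-4` Gy per unit); `DS`-encoded coordinates are written with 10
significant digits.

Relative-unit dose grids are converted to Gy at read time using the plan
prescription; without a prescription the read fails, because every
downstream metric and constraint is defined on absolute dose.

## Rasterization

The DVH geometry engine rasterizes each structure *on the dose grid* —
the dose is never interpolated or resampled:

* **In-plane membership** is decided at voxel centres, or averaged over
  an `s × s` grid of sub-centres when `supersample = s`. Membership uses
  the even-odd (parity) rule across all polygons on a plane, so holes
  subtract; points exactly on a polygon boundary count as inside. The
  boundary convention is arbitrary but must be fixed and shared with the
  verification oracle; "inside" was chosen so a contour drawn exactly
  through voxel centres behaves like a closed region.
* **Slab assignment.** Each distinct contour plane represents a slab of
  the structure's slice thickness (the median spacing of its contour
  planes; the grid spacing if only one contour exists). Every grid plane
  adopts the polygons of its nearest contour plane when it lies within
  half a slab. A grid plane that falls exactly on one of the two outer
  faces — half a slab beyond the first or last contour — contributes with
  weight 1/2. This midpoint treatment matters when contour slabs align
  exactly with grid planes (the common case for synthetic phantoms):
  counting face planes fully inflates every solid by a full voxel layer
  top and bottom, dropping them deflates it by the same amount, and the
  half-weight removes the systematic term. With 2 mm slabs on a 1 mm
  grid this puts a 20 mm box at exactly its analytic volume at
  `supersample = 4` and a 20 mm sphere within 2%.
* **Degenerate inputs.** A contour farther than half the median grid
  plane spacing from every grid plane raises an out-of-grid error; a
  structure with zero total occupancy raises a degenerate-structure
  error. Nothing is silently dropped.

`supersample = 1` is the convention used when comparing against the
brute-force voxel-loop oracle (membership is then binary and the two
implementations must agree to numerical round-off); `supersample = 4` is
a good default for small organs on coarse grids.

## DVH curves and metrics

The exported cumulative curve V(d) is binned (default `bin_width =
0.01` Gy) for plotting and export only. The exact, occupancy-weighted
voxel doses are retained on the `rt_dvh` object and **all metrics are
evaluated on them**, so binning error can never touch a pass/fail
decision.

Metric conventions, which differ between planning systems and are
therefore stated explicitly here:

* `Dmax`/`Dmin`/`Dmean` are the maximum / minimum / weighted mean of
  voxel doses with nonzero occupancy.
* `Dx%` is the dose to the hottest x% of the volume. On the
  descending-sorted dose atoms with cumulative volume fractions
  $c_1 < c_2 < \dots$, `Dx%` equals the first atom's dose for
  $x \le c_1$ and interpolates linearly between $(c_i, d_i)$ and
  $(c_{i+1}, d_{i+1})$ otherwise; at an atom boundary it returns exactly
  that atom's dose. For two equal-volume atoms at 10 and 30 Gy this gives
  `D50% = 30` (the hottest half is entirely the 30 Gy group) and
  `D75% = 20` (midway through the colder atom's step).
* `Dx cc` converts the absolute volume through the structure's total
  volume and evaluates `Dx%`; an argument exceeding the total volume is
  a domain error (reported as `NOT_EVALUABLE` at the constraint level).
* `Vx Gy` is the volume fraction (or absolute cc) with dose `>= x`,
  boundary inclusive — consistent with the constraint-grading convention
  below.

## Constraint grading

A constraint is `(structure, metric, comparator, pass_limit,
variation_limit)`. Boundary equality satisfies a limit (≤ / ≥, never
< / >), because published constraint tables are written with inclusive
comparators. Status is `PASS` if the comparator holds against the pass
limit, else `VARIATION` against the variation limit, else `FAIL`; the
plan status is the worst evaluable status, and `NOT_EVALUABLE` rows
(missing structures, domain errors) are always listed but never counted.
Constraint sets are editable JSON; the shipped prostate/lung files are
illustrative placeholders, not transcriptions of any protocol.

## Nomenclature standardization

Raw names are normalized (lowercase, separator collapse, laterality
tokens `lt/left/l → l`, `rt/right/r → r`) and matched against a starter
lexicon of ~40 prostate/lung structures with synonyms. Exact and synonym
matches score 1.0; otherwise candidates are ranked by normalized
Levenshtein similarity `1 − d/max(len)` with default `threshold = 0.70`
and `k = 5`, ties broken alphabetically. The method is deliberately
simple and auditable; learned relabeling approaches exist but need
training data this package does not assume. Suggestions below 1.0 are
never auto-applied — applying a mapping is a separate, explicit act, and
two raw names mapping to one canonical name is rejected (no merges).

## Clinical templates and derived fields

Template schemas (consult, simulation directive, on-treatment visit,
end of treatment, follow-up; prostate and lung) are JSON configuration,
as are the AJCC/CTCAE/ECOG vocabularies, the NCCN risk table and the
auto-population flow map — these standards are versioned data, not code.
Validation severities: missing required field or range/vocabulary
violation → ERROR; missing optional field or field unknown to the
schema → WARNING.

The NCCN prostate grouping is the three-tier rule: LOW iff T ≤ T2a and
Gleason sum ≤ 6 and PSA < 10; HIGH iff T ≥ T3a or Gleason sum ≥ 8 or
PSA > 20; otherwise INTERMEDIATE. The favorable/unfavorable intermediate
sub-split is intentionally out of scope — it adds vocabulary, not
mechanics. The encoded table is verified against an independently
hand-coded version of the published rule over the full
T × Gleason × PSA cross product.

Narratives use single-line `{field}` placeholders (optionally
`{TEMPLATE.field}`); plain names resolve across encounters in workflow
order. Absent optional fields render `[not recorded]`, which maps back
to "absent" on extraction. Extraction matches the boilerplate's literal
chunks left to right (non-greedy), with the final literal anchored to
the end of the narrative so trailing numeric values containing the
literal (e.g. `8.3` before a closing period) parse correctly. No
conditionals are supported: that keeps the inverse mapping decidable and
property-testable.

## CQM decision trees

Measures are JSON decision trees (`EQ NE LT LE GT GE IN EXISTS`
predicates over a declared feature dictionary; leaves `PASS`, `FAIL`,
`NOT_APPLICABLE`). All structural validation — cycles, dangling
branches, unknown features (reported with the nearest known field),
unknown operators — happens at load time; evaluation is a pure
root-to-leaf walk that records a replayable path trace.

Two semantics were genuinely open and are fixed as follows:

* A predicate on a **missing field** (other than `EXISTS`) yields
  `NOT_EVALUABLE`, never a silent `FAIL`: surveillance must distinguish
  "bad care" from "missing data".
* `NOT_APPLICABLE` is an authored leaf — eligibility carve-outs live in
  the tree, keeping the engine a pure interpreter.

Features are flattened under `record.*`, `plan.*` and `dvh.*`
namespaces (per-constraint values and statuses plus the plan status);
a cross-namespace collision is an error. The shipped prostate/lung rule
sets are structural illustrations, not published measure content.

## De-identification and integrity

Pseudonyms and remapped UIDs come from a keyed one-way derivation
(HMAC-SHA-256 under a secret held in the anonymization map), so
re-identification requires the key but longitudinal linkage is
preserved and re-runs are deterministic. All dates of a patient shift by
one uniform offset drawn from ±`date_shift_range` days (default 90), so
every interval — treatment duration, follow-up timing — survives
de-identification. DICOM UI attributes are remapped except storage-class
UIDs, consistently across a structure-set/dose/plan triplet processed
with one map, so cross-references (frame of reference, referenced SOP
instances) stay valid. Identity handling fails closed: an identity field
the policy does not cover is an error. The identifier categories in the
default policy follow the usual safe-harbor list and are configuration.

Integrity envelopes are SHA-256 digests over a canonical, key-sorted
JSON serialization (logically equal payloads digest identically).
`verify_seal()` returns `FALSE` with a reason — and appends to an audit
trail — rather than raising; the caller's contract is to reject the
payload.

## Benchmarking

Per practice and measure, `NOT_APPLICABLE` and `NOT_EVALUABLE` results
are excluded from the denominator. A practice is flagged on a measure
iff its pass count falls outside the central binomial acceptance region
`[qbinom(α/2, n, p), qbinom(1−α/2, n, p)]` at its own `n` and the pooled
national rate `p` (default `α = 0.05`). The exact binomial rule was
chosen over funnel plots or hierarchical models as the simplest
defensible baseline; the method and `α` are attached to the output, and
a Bonferroni switch exists but is off by default — surveillance favours
sensitivity, and the choice is surfaced rather than hidden.

## Synthetic data: what it does and does not emulate

The generator produces (a) box/cylinder/sphere phantoms with attached
analytic volumes (64-vertex circle discretization by default; the
regular n-gon area deficit `1 − (n/2π)·sin(2π/n)` is < 0.2% at n = 64);
(b) uniform, linear-gradient and spherical-falloff dose fields sampled
at voxel centres; and (c) prostate/lung records filling the full
template chain with schema-conformant values drawn reproducibly from a
seed, with derived fields (risk group) computed by the production code
path. Record generation never touches the global RNG state.

These fixtures give every module an analytically known or independently
enumerable truth, which is what the test suite exercises. They do *not*
emulate anatomical shape complexity, planning realism (no optimizer, no
beam model), population-calibrated clinical distributions, or free-text
documentation; passing tests therefore demonstrate correctness of the
computational conventions above, not clinical performance on real data.

## Verification sizes and numerical choices

The test suite and the verification script use desk-scale problems
chosen to make the oracles (explicit voxel loops, exhaustive truth
tables, DP edit distance) cheap while still covering every code path:
100 random phantom/field pairs on 14×14×8 grids at 2 mm for the DVH
oracle comparison (agreement required to 1e-9 percentage points at
`supersample = 1`), a 29³ grid at 1 mm for the sphere-volume check,
exhaustive enumeration (≤ 4⁴ assignments per tree) for the CQM oracle,
and 100 records for the narrative round trip. Geometric tolerances use
an epsilon of 1e-6 mm for plane/slab coincidence and 1e-9 mm for
boundary tests.

## Known limitations

* DICOM support is deliberately minimal: Explicit VR Little Endian only,
  the RT tag subset this package writes, axial non-tilted grids, 32-bit
  dose. Files from arbitrary planning systems may use dialects outside
  this subset.
* One contour-plane spacing per structure (the median) is assumed when
  assigning slabs; strongly non-uniform slice spacing will bias volumes.
* No biological indices (EUD/TCP/NTCP), no dose recomputation, no
  CT/image handling.
* The narrative grammar has no conditionals or repetition; it is a
  round-trippable subset, not a report generator.
* Outlier flagging ignores case-mix: it is a screening rule, not a
  risk-adjusted comparison.
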