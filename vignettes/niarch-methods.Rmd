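---
title: "niarch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{niarch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niarch)
```

## What this package does

`niarch` is a self-contained toolkit for preparing neuroimaging data for
sharing. It walks DICOM data through the same stations a hosted image
repository would: discovery and grouping of raw files, removal of
protected header fields, annotation with sharing identifiers, placement
into a project/subject/session/scan archive with validation on arrival,
NIfTI-1 conversion, and automated quality assessment with reports that
contextualize a scan against a reference population. Everything runs
locally; the "server side" is a directory tree plus a JSON index, so the
entire workflow can be exercised, tested and audited on one machine.

## Data model

One parsed DICOM file becomes a `dicom_entity`: a map from
`(group,element)` tags to values, plus the decoded pixel matrix. Files
are grouped into subjects by Patient ID (0010,0020), into imaging
sessions by Study Instance UID (0020,000D), and into scans by Series
Instance UID (0020,000E). The split of a session into scans on Series
Instance UID is a deliberate choice: the attribute is the DICOM-native
delimiter of a single acquisition and matches how hierarchical archives
place data, even though other conventions (series number, acquisition
number) exist in the wild.

Volume assembly orders slices by the projection of Image Position
(Patient) onto the slice normal — the cross product of the row and
column direction cosines — ascending, with instance number as the tie
break. Timepoints of a 4D series are recognized by repeated slice
positions: `n` files over `s` distinct positions make `n/s` timepoints,
with each position's files assigned to timepoints in instance-number
order. This is vendor-neutral and needs no private tags. Voxel indices
are 0-based and the affine maps indices to millimetres, following the
NIfTI convention; NIfTI-1 files are written through the RNifti library
with the affine stored in the sform.

## De-identification

The default `anonymization_profile()` lists twenty protected attributes:
accession number, institution, the six physician name/identification
attributes, series of patient attributes (birth date, insurance plan,
primary language, other IDs and names, birth name, age, address,
mother's birth name). The action is *removal* — the attribute is deleted
from the header, not blanked — because an absent attribute cannot leak
through tooling that renders empty strings. A `blank` action exists for
workflows whose downstream tools require the attributes to be present;
the conformance audit deliberately counts a blanked protected attribute
as a violation, so the default removal profile is the only one that
audits clean.

Profiles are data, not code: a YAML or JSON file with a `protected` list
of `"gggg,eeee"` tags can express alternative schemes (clinical
supplement-style profiles, site-specific additions) without touching the
package.

Sharing identifiers travel inside the data in Study Comments
(0032,4000), using the wire format

```
incf:user=<u>;project=<p>;subject=<s>;session=<e>
```

with fields in fixed order. Identifiers are restricted to
`[A-Za-z0-9_-]`, length 1–64, which makes the format injection-proof
without escaping and keeps labels usable as directory names. Annotation
validates before writing, replaces any prior Study Comments content, and
round-trips exactly (serialization is a bijection on valid annotations).

Patient ID itself is not in the protected list: the archive replaces
subject identity with the user-chosen subject label, and the original
Patient ID never propagates past grouping.

## The archive workflow

`ingest()` replays the arrival-side checks per imaging session, in
order: a parseable and consistent annotation, a registered user, label
validation against the holdings (project given, identifier characters,
ownership, session collision), and the anonymization audit. Any failure
rejects the session *atomically* — nothing of it is archived and a
rejection report naming the offending files and tags is written under
`reports/`, standing in for the e-mail a hosted service would send. All
validation happens before the first byte is placed, so a rejected ingest
leaves the holdings exactly as they were.

Accepted scans land at `<project>/<subject>/<session>/<scan>/` with
`dicom/`, `nifti/` and `qa/` subdirectories. Permissions are flat and
project-scoped: each project has one owner, and sharing (or deletion)
flips for the whole project at once, only at the owner's request.

QA dispatch follows three gates: structural QA runs only for scans whose
Series Description equals `MPRAGE` case-insensitively (a declared-type
gate; lexicon-based matching of structural scan names is out of scope
because it cannot be made exhaustive), while time-series and diffusion
QA are attempted for every scan and report *not applicable* when their
prerequisites fail — fewer than two timepoints, or no gradient
information. A prerequisite failure is an expected outcome, not an
error; an internal error marks the record `failed` without corrupting
it.

## Structural QA

The statistics are the point; the segmenter is a means. For each region
— head, brain, white matter, gray matter, CSF, exterior — the package
reports minimum and maximum, robust minimum and maximum, mean, standard
deviation, voxel count and volume, and the scalar

$$\mathrm{SNR} = \frac{\overline{I}_{\mathrm{brain}}}{\sigma_{\mathrm{exterior}}},$$

the mean brain intensity over the standard deviation of intensity
outside the head. Two wording conventions exist for the noise region
("external to the brain" vs "exterior to the head"); the package uses
exterior-to-head — air, past a 3-voxel buffer around the scalp — because
skull and scalp voxels are signal, not noise, and the buffer keeps
partial-volume voxels out of the noise estimate. When the exterior
standard deviation is zero (noiseless synthetic data) the ratio is
flagged undefined rather than returned as infinity.

Numerical conventions, all configurable: the robust range is the
2nd/98th percentile by the *nearest-rank* method
(`sorted[ceiling(p * n)]`); standard deviations of region statistics use
the population formula (divide by `N`), matching common image-statistics
tools. Region statistics agree with a direct masked reduction to within
1e-9 relative — this is asserted in the tests.

The native segmenter targets phantom-like data: voxels above the Otsu
threshold are morphologically closed (6-connectivity, radius 1) and
hole-filled, and the head is the largest connected component of the
result. Hole filling matters: on a T1-like object the threshold can sit
above the CSF mean, which would otherwise hollow out the mask or detach
the scalp shell from the brain core. The brain is the head eroded by 2
voxels (the phantom's scalp shell is thin by construction); tissue
classes are a 3-class 1D k-means over brain intensities, initialized at
the 1/6, 3/6, 5/6 quantiles for determinism, with ascending class means
labelled CSF, gray, white; the exterior is the complement of the head
dilated by 3 voxels. Real anatomy violates these assumptions (bias
fields, open skull boundaries, partial volume); for real data,
externally computed masks can be supplied to `region_stats()` and
`structural_snr()` directly, which is the intended extension hook.

## Time-series QA

Per timepoint, the mean volume intensity and the intensity-weighted
center of mass (in voxel coordinates, where step changes read directly
as voxel displacements). Per voxel, over a mask:

- tSNR: temporal mean over raw temporal standard deviation
  (denominator `T − 1`);
- SFNR: temporal mean over the standard deviation of residuals after
  removing a second-order polynomial trend (denominator `T − 3`,
  correcting for the model degrees of freedom).

The scalars are means over the mask. Slow drift inflates only the raw
temporal SD, so tSNR falls below SFNR in drifting data while SFNR keeps
estimating signal over fluctuation noise; both definitions follow the
convention established by the fBIRN stability protocols. Which variant a
given legacy tool's "mean SNR" denotes is ambiguous; this package
implements raw tSNR and documents it as such. The default analysis mask
is voxels above 20% of the robust (98th percentile) maximum of the
temporal-mean image — deterministic and phantom-friendly. Voxels with
zero temporal SD are excluded and counted.

## Diffusion QA

The gradient table is read from the per-volume b-value (0018,9087) and
gradient orientation (0018,9089) attributes. The check suite: spatial
consistency across volumes (fail), unit-norm directions for nonzero b
within tolerance 0.01 (fail), zero direction with nonzero b (fail),
duplicate directions with antipodal pairs counted as duplicates because
tensor estimation cannot distinguish `v` from `−v` (warn), fewer than 6
unique non-collinear directions — the minimum for a tensor fit — (warn),
nonzero b outside [100, 10000] s/mm² (warn), and a missing b = 0 volume
(warn). The overall verdict is pass exactly when no check fails;
warnings inform. Thresholds are package defaults with no universal
standard behind them; they are exposed in `diffusion_check_options()`.
Slice-wise and interlace intensity-artifact detection, eddy/motion
metrics and tensor fitting are out of scope.

## The synthetic generator

The generator is first-class, tested code, and its ground truth is the
oracle for every recovery claim. It emulates: PHI-bearing headers (the
full 20-field profile with plausible values, logged per file),
multi-subject/multi-session trees (the assignment map is the grouping
oracle), structural phantoms (nested ellipsoids — white core, gray
shell, CSF shell, a thin bright scalp — over an offset Gaussian
background; tissue means 300/600/900, structural noise SD 10 by
default), 4D time series (an ellipsoid of signal 1000 with noise SD 20 —
a design ratio S/σ = 50 — over 200 timepoints, with scheduled global
spikes, step displacements and linear drift, all logged), and DWI series
with the gradient table encoded per volume and signal attenuated as
`S0·exp(−b·ADC)` with ADC 7e-4 mm²/s.

Two encoding choices keep 16-bit unsigned DICOM faithful to the
continuous model: the structural background rides on an offset of five
noise SDs so clipping at zero never biases the noise SD that the SNR
statistic divides by, and the time-series background is faint (offset of
four background-SDs) so it barely weighs on the center of mass — the
expected center-of-mass step under a displacement `δ` is `δ` times the
signal mass fraction, which the generator reports (about 0.96 at the
default geometry). Quantization to integers adds variance `1/12`, which
is negligible against the default noise variances.

What the phantoms do *not* emulate: realistic anatomy, bias fields,
k-space artifacts, physiological noise, vendor private tags, compressed
or multiframe DICOM. Passing recovery tests therefore demonstrates the
correctness of the statistics and the plumbing, not the robustness of
the native segmenter on clinical data.

All randomness flows from the single seed in the spec; a fixed seed
makes the emitted tree byte-identical across runs (the writer is
canonical, UIDs are seed-derived counters, and no timestamps are
written).

## Problem sizes and tolerances

The test suite runs phantoms at 32³–64³ voxels for structural work and
up to 200 timepoints for time-series recovery; these sizes hold the
stochastic recovery claims (SNR and SFNR within 5% of design truth,
brain-mask Dice ≥ 0.9, tissue accuracy ≥ 0.85) with comfortable margin
while keeping a full run in tens of seconds. Exact claims (round trips,
partition properties, brute-force agreement at 1e-9 relative) do not
depend on size. The drift condition uses a 5% linear signal drift over
the run — strong for a stability phantom — which separates tSNR from
SFNR by a factor of about 0.8 while leaving the drift-corrected SFNR
within its recovery tolerance.

## Known limitations

- The DICOM layer reads classic single-frame little-endian files only;
  enhanced multiframe and compressed transfer syntaxes are out of scope.
- Sequence (SQ) attributes are treated as opaque text; sufficient for a
  removal-only profile, not for selective edits inside sequences.
- The native segmenter assumes a single bright connected object on a
  darker background; it is not a brain extraction tool for clinical
  data.
- De-facing, burned-in annotation detection, date shifting and UID
  remapping are not implemented; the protected-field profile is the
  whole de-identification surface.
- The user model is a flat name registry without authentication; it
  reproduces ownership semantics, not security.
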