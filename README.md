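# niarch

Sharing neuroimaging data is mostly blocked by plumbing: raw scanner
output is DICOM with identifying information embedded in its headers,
and publishing it requires de-identification, consistent labeling, a
sane archive layout, and some automated assurance that the images are
worth downloading. `niarch` packages that whole path for R users —
researchers or archive maintainers who want to prepare, validate and
quality-check DICOM data locally, with every step scriptable and
testable.

The toolkit provides:

- **DICOM discovery and grouping** — directory scans, grouping by
  Patient ID / Study Instance UID / Series Instance UID into
  subjects, sessions and scans, volume assembly (3D and 4D) and
  NIfTI-1 export.
- **De-identification** — a removal profile of 20 protected header
  fields (physician and institution identifiers, birth dates, age,
  address, alternate patient IDs, ...), a conformance audit that
  reports every retained protected field, and a sharing annotation
  carried in Study Comments
  (`incf:user=<u>;project=<p>;subject=<s>;session=<e>`).
- **A local archive** emulating a hosted repository's arrival
  workflow: per-session validation (annotation, user, labels,
  anonymization) with atomic rejection and rejection reports,
  placement into `<project>/<subject>/<session>/<scan>/`,
  project-scoped sharing policy, and QA dispatch.
- **Quality assessment**, natively implemented:
  - *structural* (for scans declared `MPRAGE`): per-region intensity
    statistics over white matter, gray matter, CSF, brain, head and
    exterior, and
    SNR = mean(brain) / sd(exterior);
  - *time series*: per-timepoint mean-intensity and center-of-mass
    traces, per-voxel tSNR = mean/sd and
    SFNR = mean / sd(residuals after 2nd-order polynomial detrend);
  - *diffusion*: gradient-table sanity checks — unit-norm directions,
    b-value plausibility, direction counts, duplicate (antipodal)
    directions, b0 presence, spatial consistency — with
    pass/fail/warn findings and an XML report.
- **A seeded phantom generator** producing PHI-rich DICOM trees,
  structural/time-series/diffusion phantoms with ground-truth masks
  and artifact logs, and synthetic reference populations for report
  histograms. Fixed seed ⇒ byte-identical trees.

## Worked example

Generate a synthetic session (one MPRAGE-like structural scan, one 4D
time series, one 7-volume DWI, all with the 20 protected fields
populated), audit it, and push it through the upload workflow:

```r
library(niarch)
raw_dir <- file.path(tempdir(), "raw")
arc_dir <- file.path(tempdir(), "archive")

spec <- read_phantom_spec(system.file("extdata", "example_phantom.yaml",
                                      package = "niarch"))
tree <- synth_dicom_tree(spec, raw_dir)

ents <- scan_directory(raw_dir)
verify_anonymization(ents)
#> <anonymization_audit> 4960 violation(s):
#>                                       filepath       tag             name
#> 1  .../SYN001/sess01/scan01/i0001.dcm 0008,0050 Accession Number
#> 2  .../SYN001/sess01/scan01/i0001.dcm 0008,0080 Institution Name
#> ...
```

248 files, each carrying all 20 protected fields: 4960 violations. The
upload command anonymizes, annotates, validates, archives and runs QA
in one step (`agree = TRUE` acknowledges the usage agreement):

```r
labels <- data.frame(patient_id = "SYN001", project = "DEMO",
                     subject = "S01", session = "E01")
res <- cmd_upload(raw_dir, user = "alice", labels = labels,
                  archive_root = arc_dir, agree = TRUE)
res
#> <cli_result> status: 0 - 3 scan(s) archived

archive_records(archive_open(arc_dir))[, c("project", "subject_label",
                                           "session_label", "scan_id",
                                           "qa_status")]
#>                project subject_label session_label scan_id qa_status
#> DEMO/S01/E01/1    DEMO           S01           E01       1      done
#> DEMO/S01/E01/2    DEMO           S01           E01       2      done
#> DEMO/S01/E01/3    DEMO           S01           E01       3      done

qa <- jsonlite::fromJSON(file.path(arc_dir, "DEMO", "S01", "E01", "1",
                                   "qa", "structural.json"))
qa$snr
#> [1] 56.46011
```

The structural SNR of ~56 reflects the phantom's design: brain tissue
means of 300/600/900 against exterior noise of SD 10. Each scan's `qa/`
directory also holds the QA JSON, trace CSVs, the diffusion XML report,
and — after `build_report()` — a Markdown/JSON report with the scan's
SNR/SFNR marked against a reference histogram. A rejected upload (for
example, a file that still carries a protected field) archives nothing
and writes a rejection report naming the file and tag under
`<archive>/reports/`.

A command-line wrapper with `upload`, `qa`, `generate` and
`archive ls/share/private/rm` subcommands ships at
`inst/cli/niarch.R`.

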