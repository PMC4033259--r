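# Archive workflow: label validation, ingest acceptance/rejection,
# QA dispatch gating, sharing policy, reports.

phi_all <- function() {
  ex <- as.list(paste0("V", seq_along(all_protected_tags)))
  names(ex) <- all_protected_tags
  ex
}

# anonymized + annotated entities for one scan
prepared_entities <- function(note, pid = "P1", study = "1.1",
                              series = "1.1.1", n_slices = 3, n_t = 1,
                              extra = list()) {
  ents <- tiny_scan_entities(n_slices, n_t = n_t, pid = pid, study = study,
                             series = series, extra = extra)
  lapply(ents, function(e) annotate(apply_profile(e), note))
}

new_archive <- function(users = "alice") {
  archive_create(withr::local_tempdir(.local_envir = parent.frame()),
                 users = users)
}

test_that("label validation flags missing project, bad characters,
           collisions and foreign ownership", {
  arc <- new_archive()
  ok <- share_annotation("alice", "P1", "S01", "E01")
  expect_identical(nrow(validate_labels(ok, arc)), 0L)

  no_proj <- share_annotation("alice", "", "S01", "E01", validate = FALSE)
  expect_true("no_project" %in% validate_labels(no_proj, arc)$code)

  bad <- share_annotation("alice", "P1", "S 01", "E01", validate = FALSE)
  expect_true("invalid_characters" %in% validate_labels(bad, arc)$code)

  ingest(arc, prepared_entities(ok))
  expect_true("session_exists" %in% validate_labels(ok, arc)$code)

  other <- share_annotation("mallory", "P1", "S99", "E01")
  expect_true("not_project_owner" %in% validate_labels(other, arc)$code)
})

test_that("a clean annotated session archives with pending QA", {
  arc <- new_archive()
  note <- share_annotation("alice", "P1", "S01", "E01")
  res <- ingest(arc, prepared_entities(note))
  expect_identical(nrow(res$records), 1L)
  expect_identical(res$records$qa_status, "pending")
  expect_length(res$rejections, 0)
  recs <- archive_records(arc)
  expect_identical(recs$project, "P1")
  expect_true(dir.exists(file.path(recs$path, "dicom")))
  expect_true(file.exists(file.path(recs$path, "nifti", "scan.nii.gz")))
})

test_that("a retained protected field rejects the whole session and
           leaves holdings untouched", {
  arc <- new_archive()
  note <- share_annotation("alice", "P1", "S01", "E01")
  ingest(arc, prepared_entities(note))
  before <- archive_records(arc)
  tree_before <- sort(list.files(file.path(arc$root, "P1"),
                                 recursive = TRUE))

  note2 <- share_annotation("alice", "P1", "S02", "E01")
  ents <- prepared_entities(note2, pid = "P2", study = "2.1",
                            series = "2.1.1")
  ents[[2]] <- dcm_set(ents[[2]], "0010,1010", "034Y")  # re-inject PHI
  ents[[2]]$filepath <- "offender.dcm"
  res <- ingest(arc, ents)
  expect_identical(nrow(res$records), 0L)
  expect_length(res$rejections, 1)
  expect_identical(res$rejections[[1]]$reason, "anonymization check failed")
  expect_identical(archive_records(arc), before)
  expect_identical(sort(list.files(file.path(arc$root, "P1"),
                                   recursive = TRUE)), tree_before)
  # the report names the offending file and tag
  rep <- readLines(res$rejections[[1]]$report)
  expect_true(any(grepl("offender.dcm", rep, fixed = TRUE)))
  expect_true(any(grepl("0010,1010", rep, fixed = TRUE)))
})

test_that("missing or inconsistent annotations reject as invalid", {
  arc <- new_archive()
  plain <- tiny_scan_entities(2)
  res <- ingest(arc, lapply(plain, apply_profile))
  expect_identical(res$rejections[[1]]$reason, "invalid annotation")
  expect_identical(nrow(archive_records(arc)), 0L)

  unknown <- prepared_entities(share_annotation("eve", "PX", "S01", "E01"))
  res2 <- ingest(arc, unknown)
  expect_identical(res2$rejections[[1]]$reason, "unknown user")
})

test_that("no archived file ever contains a protected tag", {
  arc <- new_archive()
  note <- share_annotation("alice", "P1", "S01", "E01")
  ents <- tiny_scan_entities(3, extra = phi_all())
  ents <- lapply(ents, function(e) annotate(apply_profile(e), note))
  ingest(arc, ents)
  archived <- list.files(arc$root, pattern = "\\.dcm$", recursive = TRUE,
                         full.names = TRUE)
  expect_gt(length(archived), 0)
  for (f in archived) for (tag in all_protected_tags)
    expect_false(header_contains_tag(f, tag))
})

test_that("QA dispatch gates on declared type, timepoints and gradients", {
  arc <- new_archive()
  tree_dir <- withr::local_tempdir()
  spec <- phantom_spec("structural", dim = c(24, 24, 24),
                       scan_kinds = c("structural", "timeseries",
                                      "diffusion"),
                       seed = 67)
  synth_dicom_tree(spec, tree_dir)
  res <- cmd_upload(tree_dir, user = "alice",
                    labels = make_labels("SYN001"),
                    archive_root = arc$root, agree = TRUE, run_qa = FALSE)
  expect_identical(res$status, 0L)
  recs <- archive_records(arc)
  expect_identical(nrow(recs), 3L)

  keys <- paste(recs$project, recs$subject_label, recs$session_label,
                recs$scan_id, sep = "/")
  qa <- lapply(keys, function(k) dispatch_qa(arc, k))
  names(qa) <- recs$scan_id

  # scan 1: MPRAGE structural -> structural QA present, others n/a
  expect_s3_class(qa[["1"]]$structural, "structural_qa_result")
  expect_s3_class(qa[["1"]]$timeseries, "qa_not_applicable")
  expect_s3_class(qa[["1"]]$diffusion, "qa_not_applicable")
  # scan 2: 4D BOLD -> time-series QA, no structural
  expect_null(qa[["2"]]$structural)
  expect_s3_class(qa[["2"]]$timeseries, "timeseries_qa_result")
  # scan 3: DWI -> diffusion QA present
  expect_null(qa[["3"]]$structural)
  expect_s3_class(qa[["3"]]$diffusion, "diffusion_qa_result")
  expect_true(all(vapply(qa, function(x) x$qa_status, "") == "done"))
  expect_true(all(archive_records(arc)$qa_status == "done"))
})

test_that("sharing policy flips at project scope and is owner-only", {
  arc <- new_archive(users = c("alice", "bob"))
  n1 <- share_annotation("alice", "P1", "S01", "E01")
  n2 <- share_annotation("alice", "P1", "S02", "E01")
  ingest(arc, c(prepared_entities(n1),
                prepared_entities(n2, pid = "Q", study = "3.1",
                                  series = "3.1.1")))
  expect_true(all(archive_records(arc)$shared))
  expect_error(set_sharing(arc, "P1", FALSE, "bob"), "permission error")
  expect_true(all(archive_records(arc)$shared))
  set_sharing(arc, "P1", FALSE, "alice")
  expect_false(any(archive_records(arc)$shared))

  expect_error(archive_delete_project(arc, "P1", "bob"), "permission error")
  archive_delete_project(arc, "P1", "alice")
  expect_identical(nrow(archive_records(arc)), 0L)
  expect_false(dir.exists(file.path(arc$root, "P1")))
})

test_that("reports embed reference histograms whose counts conserve the
           reference population", {
  arc <- new_archive()
  tree_dir <- withr::local_tempdir()
  spec <- phantom_spec("structural", dim = c(24, 24, 24), seed = 71)
  synth_dicom_tree(spec, tree_dir)
  cmd_upload(tree_dir, user = "alice", labels = make_labels("SYN001"),
             archive_root = arc$root, agree = TRUE, run_qa = FALSE)
  dispatch_qa(arc, "P1/S01/E01/1")

  ref <- synth_reference(100, seed = 3)
  rep <- build_report(arc, "P1/S01/E01/1", reference = ref)
  h <- rep$snr_histogram
  expect_identical(sum(h$counts), 100L)
  expect_identical(h$n, 100L)
  # the scan's own value is marked when inside the plotted range
  expect_true(h$marker >= min(h$breaks) && h$marker <= max(h$breaks))
  expect_true(h$marker_in_range)
  expect_true(file.exists(rep$report_md))
  js <- jsonlite::fromJSON(rep$report_json)
  expect_identical(sum(js$snr_histogram$counts), 100L)

  # empty reference: histogram omitted with a note
  arc2 <- new_archive()
  tree2 <- withr::local_tempdir()
  synth_dicom_tree(phantom_spec("structural", dim = c(24, 24, 24),
                                seed = 72), tree2)
  cmd_upload(tree2, user = "alice", labels = make_labels("SYN001"),
             archive_root = arc2$root, agree = TRUE, run_qa = FALSE)
  dispatch_qa(arc2, "P1/S01/E01/1")
  rep2 <- build_report(arc2, "P1/S01/E01/1")
  expect_null(rep2$snr_histogram)
  expect_true(any(grepl("histogram omitted", readLines(rep2$report_md))))
})
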