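# Local archive emulating the server-side workflow: anonymization check on
# arrival, label validation, project/subject/session/scan placement, QA
# dispatch, sharing policy and reports.

.arc_state_path <- function(root) file.path(root, "archive.json")

.arc_read <- function(archive) {
  jsonlite::fromJSON(.arc_state_path(archive$root), simplifyVector = FALSE)
}

.arc_write <- function(archive, state) {
  jsonlite::write_json(state, .arc_state_path(archive$root),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Create or open a local archive
#'
#' The archive lives under one root directory: a JSON index of records,
#' projects and known users, a `reports/` directory for rejection and QA
#' reports, and one `<project>/<subject>/<session>/<scan>/` directory per
#' archived scan holding `dicom/`, `nifti/` and `qa/`.
#'
#' @param root Archive root directory.
#' @param users Initial user registry (a flat list of user names; there
#'   are no passwords — ownership checks only compare names).
#' @return An `archive` handle.
#' @export
archive_create <- function(root, users = character(0)) {
  if (file.exists(.arc_state_path(root)))
    stop("archive already exists at ", root)
  dir.create(file.path(root, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  archive <- structure(list(root = root), class = "archive")
  .arc_write(archive, list(users = as.list(users), projects = list(),
                           records = list(), report_seq = 0))
  archive
}

#' @rdname archive_create
#' @export
archive_open <- function(root) {
  if (!file.exists(.arc_state_path(root)))
    stop("no archive found at ", root)
  structure(list(root = root), class = "archive")
}

#' @export
print.archive <- function(x, ...) {
  st <- .arc_read(x)
  cat("<archive>", x$root, "\n  ", length(st$records), "record(s), ",
      length(st$projects), "project(s), ", length(st$users), "user(s)\n")
  invisible(x)
}

#' Register a user in the archive's registry
#'
#' @param archive An [archive_open()] handle.
#' @param user User name (must satisfy the identifier rule).
#' @return The archive handle, invisibly.
#' @export
archive_add_user <- function(archive, user) {
  if (!identifier_valid(user)) stop("invalid user name: ", user)
  st <- .arc_read(archive)
  if (!user %in% unlist(st$users)) {
    st$users <- c(st$users, list(user))
    .arc_write(archive, st)
  }
  invisible(archive)
}

#' List archive records
#'
#' @param archive An archive handle.
#' @return Data frame with one row per archived scan: project,
#'   subject_label, session_label, scan_id, owner, shared, qa_status,
#'   path.
#' @export
archive_records <- function(archive) {
  st <- .arc_read(archive)
  if (length(st$records) == 0)
    return(data.frame(project = character(0), subject_label = character(0),
                      session_label = character(0), scan_id = character(0),
                      owner = character(0), shared = logical(0),
                      qa_status = character(0), path = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(st$records, function(r)
    data.frame(project = r$project, subject_label = r$subject_label,
               session_label = r$session_label, scan_id = r$scan_id,
               owner = r$owner, shared = isTRUE(r$shared),
               qa_status = r$qa_status, path = r$path,
               stringsAsFactors = FALSE)))
}

#' Validate sharing labels against the archive's holdings
#'
#' Checks, in order: a project is given; user/project/subject/session
#' identifiers use only allowed characters; the project (if it exists)
#' belongs to the acting user; and the (project, subject, session)
#' combination does not collide with an existing session. Issues are
#' returned as data, never raised.
#'
#' @param note A [share_annotation()] (may be built with
#'   `validate = FALSE`).
#' @param archive An archive handle.
#' @return Data frame of issues (columns `code`, `message`); zero rows
#'   means the labels are acceptable.
#' @export
validate_labels <- function(note, archive) {
  issues <- data.frame(code = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(code, message)
    rbind(issues, data.frame(code = code, message = message,
                             stringsAsFactors = FALSE))
  if (is.null(note$project) || !length(note$project) ||
      is.na(note$project) || !nzchar(note$project))
    issues <- add("no_project", "no project given")
  for (f in c("user", "project", "subject", "session")) {
    v <- note[[f]]
    if (!is.null(v) && length(v) == 1 && !is.na(v) && nzchar(v) &&
        !identifier_valid(v))
      issues <- add("invalid_characters",
                    sprintf("%s identifier '%s' uses invalid characters", f, v))
  }
  st <- .arc_read(archive)
  if (length(note$project) == 1 && !is.na(note$project) &&
      nzchar(note$project)) {
    proj <- st$projects[[note$project]]
    if (!is.null(proj) && !identical(proj$owner, note$user))
      issues <- add("not_project_owner",
                    sprintf("project '%s' is owned by another user",
                            note$project))
  }
  recs <- archive_records(archive)
  if (nrow(recs) && length(note$project) == 1 && length(note$subject) == 1 &&
      length(note$session) == 1) {
    hit <- recs$project == note$project &
      recs$subject_label == note$subject &
      recs$session_label == note$session
    if (any(hit))
      issues <- add("session_exists",
                    sprintf("session '%s/%s/%s' already exists",
                            note$project, note$subject, note$session))
  }
  issues
}

.write_rejection_report <- function(archive, reason, details) {
  st <- .arc_read(archive)
  st$report_seq <- st$report_seq + 1
  n <- st$report_seq
  .arc_write(archive, st)
  base <- file.path(archive$root, "reports",
                    sprintf("rejection-%03d", n))
  jsonlite::write_json(list(reason = reason, details = details),
                       paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  md <- c(sprintf("# Ingest rejection %03d", n), "",
          sprintf("Reason: %s", reason), "",
          vapply(details, function(d) paste0("- ", d), ""))
  writeLines(md, paste0(base, ".md"))
  paste0(base, ".md")
}

#' Ingest annotated, anonymized DICOM data into the archive
#'
#' Replays the server-side arrival workflow per imaging session: every
#' entity must carry a parseable Study Comments annotation agreeing
#' across the session; the user must be in the registry; labels must
#' validate against the holdings; and the anonymization check must be
#' clean. Any failure rejects the whole session — nothing of it is
#' archived and a rejection report naming the offending files and tags is
#' written under `reports/`. Accepted sessions are placed at
#' `<project>/<subject>/<session>/<scan>/`, the anonymized entities are
#' written into `dicom/`, a NIfTI-1 export into `nifti/`, and the record
#' enters the index with `qa_status = "pending"`.
#'
#' @param archive An archive handle.
#' @param entities List of annotated [dicom_entity()] objects.
#' @param profile The [anonymization_profile()] to verify against.
#' @return List with `records` (data frame of accepted scans) and
#'   `rejections` (list of `list(reason, report, details)`).
#' @export
ingest <- function(archive, entities, profile = anonymization_profile()) {
  subjects <- group_entities(entities)
  accepted <- list(); rejections <- list()

  for (subj in subjects) for (sess in subj$sessions) {
    sess_entities <- do.call(c, lapply(sess$scans, function(s) s$entities))
    notes <- lapply(sess_entities, function(e)
      parse_annotation(dcm_string(e, "0032,4000")))
    if (any(vapply(notes, is.null, TRUE))) {
      bad <- vapply(sess_entities[vapply(notes, is.null, TRUE)],
                    function(e) as.character(e$filepath), "")
      rep <- .write_rejection_report(
        archive, "invalid annotation",
        c(sprintf("session %s: missing or unparseable Study Comments",
                  sess$study_uid), bad))
      rejections[[length(rejections) + 1]] <-
        list(reason = "invalid annotation", report = rep, details = bad)
      next
    }
    keys <- vapply(notes, serialize_annotation, "")
    if (length(unique(keys)) != 1) {
      rep <- .write_rejection_report(
        archive, "inconsistent annotation",
        sprintf("session %s: %d distinct annotations", sess$study_uid,
                length(unique(keys))))
      rejections[[length(rejections) + 1]] <-
        list(reason = "inconsistent annotation", report = rep,
             details = unique(keys))
      next
    }
    note <- notes[[1]]

    st <- .arc_read(archive)
    if (!note$user %in% unlist(st$users)) {
      rep <- .write_rejection_report(
        archive, "unknown user",
        sprintf("user '%s' is not registered", note$user))
      rejections[[length(rejections) + 1]] <-
        list(reason = "unknown user", report = rep, details = note$user)
      next
    }
    issues <- validate_labels(note, archive)
    if (nrow(issues)) {
      rep <- .write_rejection_report(archive, "label validation failed",
                                     issues$message)
      rejections[[length(rejections) + 1]] <-
        list(reason = "label validation failed", report = rep,
             details = issues$message)
      next
    }
    audit <- verify_anonymization(sess_entities, profile)
    if (!audit$clean) {
      det <- sprintf("protected field %s (%s) present in %s",
                     audit$violations$tag, audit$violations$name,
                     audit$violations$filepath)
      rep <- .write_rejection_report(archive, "anonymization check failed",
                                     det)
      rejections[[length(rejections) + 1]] <-
        list(reason = "anonymization check failed", report = rep,
             details = det, violations = audit$violations)
      next
    }

    # session accepted: write scans, then commit records
    st <- .arc_read(archive)
    if (is.null(st$projects[[note$project]]))
      st$projects[[note$project]] <- list(owner = note$user, shared = TRUE)
    shared <- isTRUE(st$projects[[note$project]]$shared)
    for (i in seq_along(sess$scans)) {
      scan <- sess$scans[[i]]
      scan_id <- {
        sn <- dcm_string(scan$entities[[1]], "0020,0011")
        if (is.na(sn) || !nzchar(sn)) as.character(i) else sn
      }
      scan_dir <- file.path(archive$root, note$project, note$subject,
                            note$session, scan_id)
      dir.create(file.path(scan_dir, "dicom"), recursive = TRUE,
                 showWarnings = FALSE)
      dir.create(file.path(scan_dir, "nifti"), showWarnings = FALSE)
      dir.create(file.path(scan_dir, "qa"), showWarnings = FALSE)
      for (j in seq_along(scan$entities))
        write_dicom(scan$entities[[j]],
                    file.path(scan_dir, "dicom", sprintf("i%05d.dcm", j)))
      nifti_path <- tryCatch({
        vol <- assemble_volume(scan)
        export_nifti(vol, file.path(scan_dir, "nifti", "scan.nii.gz"))
        file.path(scan_dir, "nifti", "scan.nii.gz")
      }, error = function(e) NA_character_)
      rec <- list(project = note$project, subject_label = note$subject,
                  session_label = note$session, scan_id = scan_id,
                  owner = note$user, shared = shared,
                  qa_status = "pending", path = scan_dir,
                  nifti = nifti_path,
                  declared_type = scan$declared_type)
      st$records[[paste(note$project, note$subject, note$session,
                        scan_id, sep = "/")]] <- rec
      accepted[[length(accepted) + 1]] <- rec
    }
    .arc_write(archive, st)
  }

  records <- if (length(accepted))
    do.call(rbind, lapply(accepted, function(r)
      data.frame(project = r$project, subject_label = r$subject_label,
                 session_label = r$session_label, scan_id = r$scan_id,
                 owner = r$owner, shared = r$shared,
                 qa_status = r$qa_status, path = r$path,
                 stringsAsFactors = FALSE)))
  else data.frame()
  list(records = records, rejections = rejections)
}

.record_key <- function(r)
  paste(r$project, r$subject_label, r$session_label, r$scan_id, sep = "/")

#' Dispatch quality assessment for one archived scan
#'
#' Structural QA runs only for scans whose declared type (Series
#' Description) equals `MPRAGE`, case-insensitively. Time-series and
#' diffusion QA are attempted for every scan and report not-applicable
#' when their prerequisites are unmet (a single timepoint, or no gradient
#' information). QA results are written as JSON (plus the diffusion XML
#' report and trace CSV where applicable) into the scan's `qa/`
#' directory; an internal error marks the record `failed` without
#' corrupting it.
#'
#' @param archive An archive handle.
#' @param record_key `"project/subject/session/scan"` key (see
#'   [archive_records()]).
#' @return A list with `structural`, `timeseries`, `diffusion` results
#'   (each a QA result, a [qa_not_applicable()] marker, or `NULL` for the
#'   structural gate not matching) and `qa_status`.
#' @export
dispatch_qa <- function(archive, record_key) {
  st <- .arc_read(archive)
  rec <- st$records[[record_key]]
  if (is.null(rec)) stop("unknown record: ", record_key)
  qa_dir <- file.path(rec$path, "qa")
  dir.create(qa_dir, showWarnings = FALSE, recursive = TRUE)

  out <- list(structural = NULL, timeseries = NULL, diffusion = NULL)
  status <- "done"

  res <- tryCatch({
    entities <- scan_directory(file.path(rec$path, "dicom"))
    scan <- group_entities(entities)[[1]]$sessions[[1]]$scans[[1]]
    volume <- assemble_volume(scan)

    if (toupper(rec$declared_type) == "MPRAGE") {
      sres <- structural_qa(volume)
      out$structural <- sres
      jsonlite::write_json(
        list(snr = sres$snr, snr_defined = sres$snr_defined,
             stats = sres$stats),
        file.path(qa_dir, "structural.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
    }

    tres <- timeseries_qa(volume)
    out$timeseries <- tres
    if (inherits(tres, "qa_not_applicable")) {
      jsonlite::write_json(list(status = "not_applicable",
                                reason = tres$reason),
                           file.path(qa_dir, "timeseries.json"),
                           auto_unbox = TRUE)
    } else {
      jsonlite::write_json(
        list(mean_snr = tres$mean_snr, mean_sfnr = tres$mean_sfnr,
             snr_defined = tres$snr_defined,
             n_timepoints = tres$n_timepoints,
             mean_intensity = tres$mean_intensity),
        file.path(qa_dir, "timeseries.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
      write_traces_csv(tres, file.path(qa_dir, "timeseries_traces.csv"))
    }

    dres <- diffusion_qa(scan, volume = if (volume$n_timepoints > 1) volume
                                        else NULL)
    out$diffusion <- dres
    if (inherits(dres, "qa_not_applicable")) {
      jsonlite::write_json(list(status = "not_applicable",
                                reason = dres$reason),
                           file.path(qa_dir, "diffusion.json"),
                           auto_unbox = TRUE)
    } else {
      jsonlite::write_json(list(overall = dres$overall,
                                checks = dres$checks),
                           file.path(qa_dir, "diffusion.json"),
                           auto_unbox = TRUE)
      write_diffusion_xml(dres, file.path(qa_dir, "diffusion.xml"))
    }
    TRUE
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(qa_dir, "qa_error.log"))
    FALSE
  })
  if (!res) status <- "failed"

  st <- .arc_read(archive)
  st$records[[record_key]]$qa_status <- status
  .arc_write(archive, st)
  out$qa_status <- status
  out
}

#' Set the sharing policy of a project
#'
#' Sharing is a project-level property: all records of the project flip
#' together. Only the project owner may change it.
#'
#' @param archive An archive handle.
#' @param project Project name.
#' @param shared New sharing flag.
#' @param acting_user User requesting the change.
#' @return The archive handle, invisibly.
#' @export
set_sharing <- function(archive, project, shared, acting_user) {
  st <- .arc_read(archive)
  proj <- st$projects[[project]]
  if (is.null(proj)) stop("unknown project: ", project)
  if (!identical(proj$owner, acting_user))
    stop("permission error: '", acting_user, "' does not own project '",
         project, "'")
  st$projects[[project]]$shared <- shared
  for (k in names(st$records))
    if (identical(st$records[[k]]$project, project))
      st$records[[k]]$shared <- shared
  .arc_write(archive, st)
  invisible(archive)
}

#' Remove a project and all its data from the archive
#'
#' @inheritParams set_sharing
#' @return The archive handle, invisibly.
#' @export
archive_delete_project <- function(archive, project, acting_user) {
  st <- .arc_read(archive)
  proj <- st$projects[[project]]
  if (is.null(proj)) stop("unknown project: ", project)
  if (!identical(proj$owner, acting_user))
    stop("permission error: '", acting_user, "' does not own project '",
         project, "'")
  st$projects[[project]] <- NULL
  keep <- vapply(st$records, function(r) !identical(r$project, project),
                 TRUE)
  st$records <- st$records[keep]
  .arc_write(archive, st)
  unlink(file.path(archive$root, project), recursive = TRUE)
  invisible(archive)
}

#' Build a QA report for an archived scan
#'
#' Writes `report.md` and `report.json` into the scan's `qa/` directory:
#' the raw QA metric tables plus, for the structural SNR and time-series
#' SFNR, a histogram of a reference population with the scan's own value
#' marked. The reference defaults to the archive's other holdings and may
#' be supplemented with an external vector of values (for example a
#' synthetic reference population from [synth_reference()]). With no
#' reference values available the histogram is omitted with a note.
#'
#' @param archive An archive handle.
#' @param record_key Record key (QA must have completed).
#' @param reference Optional data frame with columns `snr` and/or `sfnr`,
#'   or a numeric vector treated as SNR values.
#' @param breaks Number of histogram bins.
#' @return Invisibly, a list with `report_md`, `report_json`, and the
#'   histogram objects.
#' @export
build_report <- function(archive, record_key, reference = NULL,
                         breaks = 12) {
  st <- .arc_read(archive)
  rec <- st$records[[record_key]]
  if (is.null(rec)) stop("unknown record: ", record_key)
  if (!identical(rec$qa_status, "done"))
    stop("QA has not completed for ", record_key)
  qa_dir <- file.path(rec$path, "qa")

  read_json_if <- function(p)
    if (file.exists(p)) jsonlite::fromJSON(p, simplifyVector = TRUE)
    else NULL
  struct <- read_json_if(file.path(qa_dir, "structural.json"))
  ts <- read_json_if(file.path(qa_dir, "timeseries.json"))
  diff <- read_json_if(file.path(qa_dir, "diffusion.json"))

  if (is.numeric(reference)) reference <- data.frame(snr = reference)

  # reference from the archive's own holdings: other scans' metrics
  arc_snr <- c(); arc_sfnr <- c()
  for (k in setdiff(names(st$records), record_key)) {
    o <- st$records[[k]]
    os <- read_json_if(file.path(o$path, "qa", "structural.json"))
    if (!is.null(os) && isTRUE(os$snr_defined))
      arc_snr <- c(arc_snr, os$snr)
    ot <- read_json_if(file.path(o$path, "qa", "timeseries.json"))
    if (!is.null(ot) && isTRUE(ot$snr_defined))
      arc_sfnr <- c(arc_sfnr, ot$mean_sfnr)
  }
  ref_snr <- c(arc_snr, reference$snr)
  ref_sfnr <- c(arc_sfnr, reference$sfnr)

  mk_hist <- function(vals, own) {
    if (length(vals) == 0) return(NULL)
    rng <- range(c(vals, own), na.rm = TRUE)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = breaks + 1)
    h <- graphics::hist(vals, breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, n = length(vals),
         marker = own,
         marker_in_range = !is.na(own) && own >= rng[1] && own <= rng[2])
  }
  own_snr <- if (!is.null(struct) && isTRUE(struct$snr_defined))
    struct$snr else NA_real_
  own_sfnr <- if (!is.null(ts) && isTRUE(ts$snr_defined))
    ts$mean_sfnr else NA_real_
  hist_snr <- if (!is.na(own_snr)) mk_hist(ref_snr, own_snr) else NULL
  hist_sfnr <- if (!is.na(own_sfnr)) mk_hist(ref_sfnr, own_sfnr) else NULL

  report <- list(record = record_key,
                 structural = struct, timeseries = ts, diffusion = diff,
                 snr_histogram = hist_snr, sfnr_histogram = hist_sfnr)
  json_path <- file.path(qa_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  md <- c(sprintf("# QA report: %s", record_key), "")
  if (!is.null(struct)) {
    md <- c(md, "## Structural QA", "",
            sprintf("SNR: %s",
                    if (isTRUE(struct$snr_defined))
                      sprintf("%.3f", struct$snr) else "undefined"),
            "", "| region | n voxels | mean | sd | min | max |",
            "|---|---|---|---|---|---|")
    for (r in names(struct$stats)) {
      s <- struct$stats[[r]]
      if (isTRUE(s$defined))
        md <- c(md, sprintf("| %s | %d | %.2f | %.2f | %.1f | %.1f |",
                            r, s$n_voxels, s$mean, s$sd, s$min, s$max))
      else md <- c(md, sprintf("| %s | (empty) | | | | |", r))
    }
    md <- c(md, "")
  }
  if (!is.null(ts)) {
    md <- c(md, "## Time-series QA", "",
            if (!is.null(ts$status)) sprintf("Status: %s (%s)", ts$status,
                                             ts$reason)
            else sprintf("tSNR: %.3f; SFNR: %.3f over %d timepoints",
                         ts$mean_snr, ts$mean_sfnr, ts$n_timepoints), "")
  }
  if (!is.null(diff)) {
    md <- c(md, "## Diffusion QA", "",
            if (!is.null(diff$status)) sprintf("Status: %s (%s)",
                                               diff$status, diff$reason)
            else sprintf("Overall: %s", diff$overall), "")
  }
  hist_md <- function(h, label) {
    if (is.null(h))
      return(c(sprintf("%s histogram omitted: no reference values.", label),
               ""))
    c(sprintf("## %s reference histogram (n = %d)", label, h$n), "",
      sprintf("Scan value %.3f%s", h$marker,
              if (h$marker_in_range) " (marked within plotted range)"
              else " (outside plotted range)"),
      "",
      sprintf("- [%.2f, %.2f): %d", utils::head(h$breaks, -1),
              utils::tail(h$breaks, -1), h$counts),
      "")
  }
  if (!is.na(own_snr)) md <- c(md, hist_md(hist_snr, "SNR"))
  if (!is.na(own_sfnr)) md <- c(md, hist_md(hist_sfnr, "SFNR"))
  md_path <- file.path(qa_dir, "report.md")
  writeLines(md, md_path)

  invisible(list(report_md = md_path, report_json = json_path,
                 snr_histogram = hist_snr, sfnr_histogram = hist_sfnr))
}
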