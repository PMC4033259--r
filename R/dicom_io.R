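# Directory discovery, subject/session/scan grouping, volume assembly and
# NIfTI-1 export.

#' Scan a directory tree for DICOM files
#'
#' Walks `root` (recursively by default), parsing every regular file.
#' Non-DICOM files are skipped silently and counted, matching a tolerant
#' upload tool that accepts mixed directories.
#'
#' @param root Directory to scan.
#' @param recursive Descend into subdirectories?
#' @return List of [dicom_entity()] objects, with attribute `skipped`
#'   giving the number of non-DICOM files encountered.
#' @export
scan_directory <- function(root, recursive = TRUE) {
  if (length(root) != 1 || !dir.exists(root))
    stop("input error: directory does not exist: ", root)
  files <- list.files(root, recursive = recursive, full.names = TRUE,
                      no.. = TRUE)
  files <- files[!dir.exists(files)]
  files <- sort(files)
  entities <- lapply(files, function(f) {
    tryCatch(read_dicom(f), error = function(e) NULL)
  })
  ok <- !vapply(entities, is.null, TRUE)
  if (!any(ok)) stop("no valid data: no DICOM files found under ", root)
  structure(entities[ok], skipped = sum(!ok))
}

.scan_series <- function(series_uid, entities) {
  inst <- vapply(entities, function(e) {
    v <- dcm_instance_number(e); if (is.na(v)) .Machine$integer.max else v
  }, 0L)
  paths <- vapply(entities, function(e) as.character(e$filepath), "")
  entities <- entities[order(inst, paths)]

  has_grad <- any(vapply(entities, function(e)
    !is.null(e$tags[["0018,9087"]]), TRUE))
  pos <- t(vapply(entities, dcm_slice_position, numeric(3)))
  n_unique_pos <- nrow(unique(round(pos, 3)))
  hint <- if (has_grad) "diffusion"
  else if (n_unique_pos < length(entities)) "timeseries"
  else if (length(entities) > 1) "structural"
  else "unknown"

  structure(list(
    series_uid = series_uid,
    modality_hint = hint,
    declared_type = dcm_string(entities[[1]], "0008,103e", default = ""),
    entities = entities), class = "scan_series")
}

#' Group DICOM entities into subjects, sessions and scans
#'
#' Subjects are delimited by Patient ID (0010,0020), imaging sessions by
#' Study Instance UID (0020,000D) and scans by Series Instance UID
#' (0020,000E). Entities lacking a patient ID or study UID are excluded
#' with a warning. The grouping is an exact partition of the admitted
#' entities and is invariant to input order.
#'
#' @param entities List of [dicom_entity()].
#' @return List of `subject_group` objects, each with `patient_id` and a
#'   list `sessions` of `session_group`s (fields `study_uid`, `patient_id`,
#'   `scans`); scans are `scan_series` objects sorted by instance number.
#' @export
group_entities <- function(entities) {
  pid <- vapply(entities, function(e) {
    v <- dcm_patient_id(e); if (is.na(v)) "" else v
  }, "")
  suid <- vapply(entities, function(e) {
    v <- dcm_study_uid(e); if (is.na(v)) "" else v
  }, "")
  seruid <- vapply(entities, function(e) {
    v <- dcm_series_uid(e); if (is.na(v)) "" else v
  }, "")
  bad <- pid == "" | suid == "" | seruid == ""
  if (any(bad)) {
    warning(sum(bad), " entit", if (sum(bad) == 1) "y" else "ies",
            " missing Patient ID, Study or Series Instance UID; excluded")
    entities <- entities[!bad]
    pid <- pid[!bad]; suid <- suid[!bad]; seruid <- seruid[!bad]
  }
  subjects <- lapply(sort(unique(pid)), function(p) {
    sel_p <- pid == p
    sessions <- lapply(sort(unique(suid[sel_p])), function(s) {
      sel_s <- sel_p & suid == s
      scans <- lapply(sort(unique(seruid[sel_s])), function(ser) {
        .scan_series(ser, entities[sel_s & seruid == ser])
      })
      structure(list(study_uid = s, patient_id = p, scans = scans),
                class = "session_group")
    })
    structure(list(patient_id = p, sessions = sessions),
              class = "subject_group")
  })
  subjects
}

#' @export
print.subject_group <- function(x, ...) {
  cat("<subject_group> ", x$patient_id, ": ", length(x$sessions),
      " session(s)\n", sep = "")
  invisible(x)
}

.slice_normal <- function(orientation) {
  r <- orientation[1:3]; c0 <- orientation[4:6]
  c(r[2] * c0[3] - r[3] * c0[2],
    r[3] * c0[1] - r[1] * c0[3],
    r[1] * c0[2] - r[2] * c0[1])
}

#' Construct a volume stack
#'
#' Container for an assembled 3D or 4D intensity array plus geometry. The
#' affine maps 0-based voxel indices `(i, j, k)` (row, column, slice) to
#' patient-space millimetres, following the NIfTI convention.
#'
#' @param data 3D or 4D numeric array.
#' @param voxel_size Length-3 positive voxel dimensions in mm.
#' @param affine 4x4 voxel-to-mm transform; default is a scaled identity.
#' @return A `volume_stack` object with fields `data`, `voxel_size`,
#'   `n_timepoints` and `affine`.
#' @export
volume_stack <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3, 4)) stop("data must be a 3D or 4D array")
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(list(
    data = data,
    voxel_size = as.numeric(voxel_size),
    n_timepoints = if (nd == 4) dim(data)[4] else 1L,
    affine = affine), class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat("<volume_stack> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = "x"),
      " mm, ", x$n_timepoints, " timepoint(s)\n", sep = "")
  invisible(x)
}

#' Assemble a scan series into a 3D/4D volume
#'
#' Slices are ordered by the projection of Image Position (Patient) onto
#' the slice normal (cross product of the row and column direction
#' cosines), ascending; ties break by instance number. Timepoints are
#' identified by repeated slice positions: a series with `n` entities over
#' `s` distinct positions yields `n/s` timepoints, each position's entities
#' assigned to timepoints in instance-number order.
#'
#' @param scan A `scan_series` from [group_entities()].
#' @return A [volume_stack()].
#' @export
assemble_volume <- function(scan) {
  ents <- scan$entities
  shapes <- t(vapply(ents, function(e)
    c(nrow(e$pixel), ncol(e$pixel)), numeric(2)))
  spacings <- t(vapply(ents, dcm_pixel_spacing, numeric(2)))
  if (nrow(unique(shapes)) != 1 || nrow(unique(round(spacings, 6))) != 1)
    stop("spatial inconsistency: entities differ in pixel shape or spacing")
  rows <- shapes[1, 1]; cols <- shapes[1, 2]
  spacing <- spacings[1, ]

  orient <- dcm_orientation(ents[[1]])
  normal <- .slice_normal(orient)
  pos <- t(vapply(ents, dcm_slice_position, numeric(3)))
  proj <- round(as.numeric(pos %*% normal), 3)

  upos <- sort(unique(proj))
  n_slices <- length(upos)
  n <- length(ents)
  if (n %% n_slices != 0)
    stop("duplicate slice positions: entity count is not a multiple of ",
         "distinct slice positions")
  n_t <- n %/% n_slices
  counts <- table(proj)
  if (any(counts != n_t))
    stop("duplicate slice positions within a timepoint")

  data <- array(0, dim = c(rows, cols, n_slices, n_t))
  for (k in seq_len(n_slices)) {
    idx <- which(proj == upos[k])
    inst <- vapply(ents[idx], function(e) {
      v <- dcm_instance_number(e); if (is.na(v)) .Machine$integer.max else v
    }, 0L)
    idx <- idx[order(inst)]
    for (t in seq_len(n_t)) data[, , k, t] <- ents[[idx[t]]]$pixel
  }
  if (n_t == 1) dim(data) <- c(rows, cols, n_slices)

  dz <- if (n_slices > 1) stats::median(diff(upos)) else {
    v <- dcm_numeric(ents[[1]], "0018,0050")
    if (length(v) == 1 && v > 0) v else 1
  }
  voxel_size <- c(spacing[1], spacing[2], dz)

  col_dir <- orient[4:6]; row_dir <- orient[1:3]
  origin <- pos[which(proj == upos[1])[1], ]
  affine <- rbind(cbind(col_dir * spacing[1], row_dir * spacing[2],
                        normal * dz, origin),
                  c(0, 0, 0, 1))
  dimnames(affine) <- NULL
  volume_stack(data, voxel_size = voxel_size, affine = affine)
}

#' Export a volume stack as NIfTI-1
#'
#' Voxel data round-trips bit-identically for integer intensities; the
#' affine is stored in the sform and preserved to well below 1e-6.
#'
#' @param volume A [volume_stack()].
#' @param out Output path (`.nii` or `.nii.gz`).
#' @return `out`, invisibly.
#' @export
export_nifti <- function(volume, out) {
  stopifnot(inherits(volume, "volume_stack"))
  img <- RNifti::asNifti(volume$data)
  aff <- volume$affine
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 0L))
  ok <- tryCatch({RNifti::writeNifti(img, out); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(out)) stop("I/O error: could not write ", out)
  invisible(out)
}

#' Read a NIfTI-1 file as a volume stack
#'
#' @param path NIfTI file.
#' @return A [volume_stack()].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  vs <- RNifti::pixdim(img)[1:3]
  volume_stack(array(as.numeric(img), dim = dim(img)),
               voxel_size = vs, affine = matrix(aff[1:16], 4, 4))
}
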