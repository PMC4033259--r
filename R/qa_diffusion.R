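# Diffusion QA: gradient-table extraction and pass/fail/warn sanity checks.

#' Default thresholds for the diffusion check suite
#'
#' @param unit_norm_tol Allowed deviation of a gradient direction from
#'   unit norm.
#' @param b_range Plausible range for nonzero b-values (s/mm^2); values
#'   outside it are flagged as suspicious.
#' @param min_directions Minimum number of unique non-collinear nonzero-b
#'   directions below which a warning is raised.
#' @return List of thresholds.
#' @export
diffusion_check_options <- function(unit_norm_tol = 0.01,
                                    b_range = c(100, 10000),
                                    min_directions = 6) {
  list(unit_norm_tol = unit_norm_tol, b_range = b_range,
       min_directions = min_directions)
}

#' Construct a gradient table
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Matrix `n x 3` of gradient directions (direction cosines).
#' @return A `gradient_table` object (`bvals`, `bvecs`, `n_volumes`).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs disagree in length")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 n_volumes = length(bvals)), class = "gradient_table")
}

#' Extract the gradient table of a scan series
#'
#' Reads the b-value (0018,9087) and gradient direction (0018,9089)
#' attributes of each volume in the series (volumes are delimited the same
#' way [assemble_volume()] delimits timepoints). A series with no
#' diffusion attributes at all signals not-applicable — such data simply
#' fails the diffusion QA prerequisite; a series where only some volumes
#' carry them is an incomplete gradient table, a hard failure.
#'
#' @param scan A `scan_series`.
#' @return List with `status` (`"ok"`, `"absent"` or `"incomplete"`) and,
#'   when ok, `table`, a [gradient_table()].
#' @export
extract_gradients <- function(scan) {
  ents <- scan$entities
  orient <- dcm_orientation(ents[[1]])
  normal <- .slice_normal(orient)
  pos <- t(vapply(ents, dcm_slice_position, numeric(3)))
  proj <- round(as.numeric(pos %*% normal), 3)
  upos <- sort(unique(proj))
  n_t <- length(ents) %/% length(upos)
  if (n_t < 1) n_t <- 1

  # representative entity per volume: entities at the first slice position,
  # in instance order
  idx <- which(proj == upos[1])
  inst <- vapply(ents[idx], function(e) {
    v <- dcm_instance_number(e); if (is.na(v)) .Machine$integer.max else v
  }, 0L)
  reps <- ents[idx[order(inst)]]

  has_b <- vapply(reps, function(e) !is.null(e$tags[["0018,9087"]]), TRUE)
  if (!any(has_b)) return(list(status = "absent"))
  if (!all(has_b)) return(list(status = "incomplete"))

  bvals <- vapply(reps, function(e) dcm_numeric(e, "0018,9087")[1], 0)
  bvecs <- t(vapply(reps, function(e) {
    v <- dcm_numeric(e, "0018,9089")
    if (length(v) == 3) v else c(0, 0, 0)
  }, numeric(3)))
  list(status = "ok", table = gradient_table(bvals, bvecs))
}

.add_check <- function(checks, name, status, detail = "") {
  rbind(checks, data.frame(name = name, status = status, detail = detail,
                           stringsAsFactors = FALSE))
}

.unique_directions <- function(bvecs, tol = 1e-3) {
  # unique up to antipodal symmetry (tensor estimation cannot distinguish
  # v from -v); returns indices of representatives
  n <- nrow(bvecs)
  nrm <- sqrt(rowSums(bvecs^2))
  unit <- bvecs / ifelse(nrm > 0, nrm, 1)
  reps <- integer(0)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in reps) {
      if (abs(sum(unit[i, ] * unit[j, ])) >= 1 - tol) { dup <- TRUE; break }
    }
    if (!dup) reps <- c(reps, i)
  }
  reps
}

#' Run the diffusion sanity-check suite
#'
#' Pass/fail checks: spatial consistency (all volumes share grid and voxel
#' size, and the volume count matches the table), unit-norm gradient
#' directions for nonzero b, and no zero direction with nonzero b.
#' Warnings: duplicate directions (antipodal pairs count as duplicates),
#' fewer than `min_directions` unique non-collinear nonzero-b directions,
#' nonzero b-values outside the plausible range, and a missing b=0
#' volume. All findings are statuses, never exceptions, and the overall
#' verdict is pass exactly when no check fails.
#'
#' @param volume The assembled 4D [volume_stack()], or `NULL` when
#'   assembly itself failed (recorded as a spatial failure).
#' @param table A [gradient_table()].
#' @param opts Thresholds from [diffusion_check_options()].
#' @return A `diffusion_qa_result`: data frame `checks` (name, status,
#'   detail) and `overall` (`"pass"`/`"fail"`).
#' @export
run_checks <- function(volume, table, opts = diffusion_check_options()) {
  checks <- data.frame(name = character(0), status = character(0),
                       detail = character(0), stringsAsFactors = FALSE)

  if (is.null(volume)) {
    checks <- .add_check(checks, "spatial", "fail",
                         "volumes are spatially inconsistent")
  } else {
    nt <- if (length(dim(volume$data)) == 4) dim(volume$data)[4] else 1L
    if (nt != table$n_volumes)
      checks <- .add_check(checks, "spatial", "fail",
                           sprintf("%d volumes but %d gradient entries",
                                   nt, table$n_volumes))
    else
      checks <- .add_check(checks, "spatial", "pass",
                           "consistent grid across volumes")
  }

  b <- table$bvals
  v <- table$bvecs
  nrm <- sqrt(rowSums(v^2))
  dwi <- b > 0

  zero_dir <- dwi & nrm == 0
  if (any(zero_dir))
    checks <- .add_check(checks, "gradient_norm", "fail",
                         sprintf("zero direction with nonzero b at volume(s) %s",
                                 paste(which(zero_dir), collapse = ",")))
  else {
    off <- dwi & abs(nrm - 1) > opts$unit_norm_tol
    if (any(off))
      checks <- .add_check(checks, "gradient_norm", "fail",
                           sprintf("non-unit direction norm at volume(s) %s",
                                   paste(which(off), collapse = ",")))
    else
      checks <- .add_check(checks, "gradient_norm", "pass",
                           "all nonzero-b directions unit norm")
  }

  if (any(dwi)) {
    reps <- .unique_directions(v[dwi, , drop = FALSE])
    n_unique <- length(reps)
    if (n_unique < sum(dwi))
      checks <- .add_check(checks, "duplicate_directions", "warn",
                           sprintf("%d duplicate (or antipodal) direction(s)",
                                   sum(dwi) - n_unique))
    else
      checks <- .add_check(checks, "duplicate_directions", "pass",
                           "no duplicate directions")
    if (n_unique < opts$min_directions)
      checks <- .add_check(checks, "direction_count", "warn",
                           sprintf("non-standard number of gradient directions: %d unique (< %d)",
                                   n_unique, opts$min_directions))
    else
      checks <- .add_check(checks, "direction_count", "pass",
                           sprintf("%d unique directions", n_unique))
  }

  suspicious <- dwi & (b < opts$b_range[1] | b > opts$b_range[2])
  if (any(suspicious))
    checks <- .add_check(checks, "b_values", "warn",
                         sprintf("suspicious b-values at volume(s) %s: %s",
                                 paste(which(suspicious), collapse = ","),
                                 paste(b[suspicious], collapse = ",")))
  else
    checks <- .add_check(checks, "b_values", "pass",
                         "nonzero b-values within plausible range")

  if (!any(b == 0))
    checks <- .add_check(checks, "b0_present", "warn", "no b=0 volume")
  else
    checks <- .add_check(checks, "b0_present", "pass",
                         sprintf("%d b=0 volume(s)", sum(b == 0)))

  structure(list(checks = checks,
                 overall = if (any(checks$status == "fail")) "fail"
                           else "pass"),
            class = "diffusion_qa_result")
}

#' @export
print.diffusion_qa_result <- function(x, ...) {
  cat("<diffusion_qa_result> overall:", x$overall, "\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%-4s] %-20s %s\n", x$checks$status[i],
                x$checks$name[i], x$checks$detail[i]))
  invisible(x)
}

#' Run the full diffusion QA procedure for a scan
#'
#' Extracts the gradient table and runs the check suite. A scan without
#' diffusion attributes yields a not-applicable marker; an incomplete
#' table yields an immediate failing result.
#'
#' @param scan A `scan_series`.
#' @param volume Optional pre-assembled volume; assembled from the scan
#'   when `NULL` (an assembly failure becomes a spatial check failure).
#' @param opts Thresholds from [diffusion_check_options()].
#' @return A `diffusion_qa_result` or [qa_not_applicable()].
#' @export
diffusion_qa <- function(scan, volume = NULL,
                         opts = diffusion_check_options()) {
  g <- extract_gradients(scan)
  if (g$status == "absent")
    return(qa_not_applicable("no diffusion gradient information present"))
  if (g$status == "incomplete") {
    checks <- data.frame(name = "gradient_table", status = "fail",
                         detail = "incomplete gradient table: some volumes lack diffusion attributes",
                         stringsAsFactors = FALSE)
    return(structure(list(checks = checks, overall = "fail"),
                     class = "diffusion_qa_result"))
  }
  if (is.null(volume))
    volume <- tryCatch(assemble_volume(scan), error = function(e) NULL)
  run_checks(volume, g$table, opts)
}

#' Read / write FSL-format gradient tables
#'
#' `bval` is one space-separated row of b-values; `bvec` is three rows
#' (x, y, z components).
#'
#' @param table A [gradient_table()].
#' @param bval_path,bvec_path Output/input paths.
#' @return `write_bval_bvec`: invisibly, the two paths;
#'   `read_bval_bvec`: a [gradient_table()].
#' @export
write_bval_bvec <- function(table, bval_path, bvec_path) {
  writeLines(paste(format(table$bvals, trim = TRUE, digits = 17),
                   collapse = " "), bval_path)
  writeLines(apply(t(table$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  gradient_table(bvals, t(do.call(rbind, rows)))
}

#' Write a diffusion QA result as a flat XML report
#'
#' One `<check>` element per finding, with `name`, `status` and `detail`
#' attributes, under a root carrying the overall verdict.
#'
#' @param result A `diffusion_qa_result`.
#' @param path Output XML path.
#' @return `path`, invisibly.
#' @export
write_diffusion_xml <- function(result, path) {
  root <- xml2::xml_new_root("DiffusionQA", overall = result$overall)
  for (i in seq_len(nrow(result$checks)))
    xml2::xml_add_child(root, "check",
                        name = result$checks$name[i],
                        status = result$checks$status[i],
                        detail = result$checks$detail[i])
  xml2::write_xml(root, path)
  invisible(path)
}
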