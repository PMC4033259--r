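# Time-series QA: per-timepoint summary traces and temporal SNR / SFNR.

#' A not-applicable QA marker
#'
#' Returned when a QA procedure's prerequisites are not met (for example
#' time-series QA on single-timepoint data, or diffusion QA on data with
#' no gradient information), so a failed prerequisite is a reported
#' outcome rather than an error.
#'
#' @param reason Human-readable reason.
#' @return A `qa_not_applicable` object.
#' @export
qa_not_applicable <- function(reason) {
  structure(list(status = "not_applicable", reason = reason),
            class = "qa_not_applicable")
}

#' @export
print.qa_not_applicable <- function(x, ...) {
  cat("<qa not applicable>", x$reason, "\n")
  invisible(x)
}

.as_timepoint_matrix <- function(volume) {
  d <- dim(volume$data)
  matrix(volume$data, nrow = prod(d[1:3]), ncol = d[4])  # voxels x time
}

#' Mean volume intensity at each timepoint
#'
#' @param volume A 4D [volume_stack()].
#' @return Numeric vector of per-timepoint means, or a
#'   [qa_not_applicable()] marker for 3D input (single-timepoint data
#'   cannot support time-series QA).
#' @export
volume_mean_trace <- function(volume) {
  stopifnot(inherits(volume, "volume_stack"))
  if (length(dim(volume$data)) != 4)
    return(qa_not_applicable("single timepoint: time-series QA requires 4D data"))
  colMeans(.as_timepoint_matrix(volume))
}

#' Center of mass at each timepoint
#'
#' The intensity-weighted centroid, in 0-based voxel coordinates, of every
#' timepoint; step changes in a coordinate trace reveal subject motion at
#' a glance. Timepoints with zero total intensity yield `NA` coordinates
#' and are flagged.
#'
#' @param volume A 4D [volume_stack()].
#' @return A `n_timepoints x 3` matrix (columns `x`, `y`, `z`), with
#'   attribute `undefined` listing all-zero timepoints; or a
#'   [qa_not_applicable()] marker for 3D input.
#' @export
com_trace <- function(volume) {
  stopifnot(inherits(volume, "volume_stack"))
  if (length(dim(volume$data)) != 4)
    return(qa_not_applicable("single timepoint: time-series QA requires 4D data"))
  d <- dim(volume$data)
  m <- .as_timepoint_matrix(volume)
  tot <- colSums(m)
  grid <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  com <- vapply(1:3, function(ax) as.numeric(crossprod(m, grid[[ax]])),
                numeric(d[4]))
  com <- com / tot
  com[tot == 0, ] <- NA_real_
  colnames(com) <- c("x", "y", "z")
  attr(com, "undefined") <- which(tot == 0)
  com
}

.detrend_residuals <- function(m, order = 2) {
  # m: voxels x time; remove a per-voxel polynomial trend of given order
  tt <- seq_len(ncol(m))
  tc <- (tt - mean(tt)) / stats::sd(tt)
  X <- stats::poly(tc, degree = order, raw = FALSE)
  X <- cbind(1, X)
  # residual maker applied from the right: R = m (I - X (X'X)^-1 X')
  H <- X %*% solve(crossprod(X), t(X))
  m - m %*% H
}

#' Temporal SNR and signal-to-fluctuation-noise ratio
#'
#' Per voxel, tSNR is the temporal mean divided by the raw temporal
#' standard deviation; SFNR is the temporal mean divided by the standard
#' deviation of the residuals after removing a second-order polynomial
#' trend (so slow drift inflates only the raw temporal SD, and SFNR is
#' never below tSNR when the detrend removes variance). SD denominators
#' are degree-of-freedom corrected (`T-1` raw, `T-1-order` detrended).
#' Scalars are means over the analysis mask; voxels with zero temporal SD
#' are excluded and counted.
#'
#' @param volume A 4D [volume_stack()] with at least 5 timepoints.
#' @param mask Logical 3D array, or `"auto"`: voxels above
#'   `auto_fraction` of the robust (98th percentile) maximum of the
#'   temporal-mean image.
#' @param detrend_order Polynomial order for the SFNR detrend.
#' @param auto_fraction Threshold fraction for the auto mask.
#' @return List with `mean_snr`, `mean_sfnr`, `n_voxels`, `n_excluded`,
#'   and `defined` (false when every mask voxel was excluded).
#' @export
tsnr_sfnr <- function(volume, mask = "auto", detrend_order = 2,
                      auto_fraction = 0.2) {
  stopifnot(inherits(volume, "volume_stack"))
  if (length(dim(volume$data)) != 4)
    return(qa_not_applicable("single timepoint: time-series QA requires 4D data"))
  nt <- dim(volume$data)[4]
  if (nt < 5)
    stop("tsnr_sfnr requires at least 5 timepoints, got ", nt)
  m <- .as_timepoint_matrix(volume)
  tmean <- rowMeans(m)
  if (identical(mask, "auto")) {
    rmax <- .nearest_rank(sort(tmean), 0.98)
    sel <- tmean > auto_fraction * rmax
  } else {
    if (!identical(dim(mask), dim(volume$data)[1:3]))
      stop("mask grid does not match volume grid")
    sel <- as.vector(mask)
  }
  mm <- m[sel, , drop = FALSE]
  mu <- rowMeans(mm)
  sd_raw <- sqrt(rowSums((mm - mu)^2) / (nt - 1))
  res <- .detrend_residuals(mm, order = detrend_order)
  sd_det <- sqrt(rowSums(res^2) / (nt - 1 - detrend_order))
  keep <- sd_raw > 0 & sd_det > 0
  if (!any(keep))
    return(list(mean_snr = NA_real_, mean_sfnr = NA_real_,
                n_voxels = 0L, n_excluded = sum(!keep), defined = FALSE))
  list(mean_snr = mean(mu[keep] / sd_raw[keep]),
       mean_sfnr = mean(mu[keep] / sd_det[keep]),
       n_voxels = sum(keep),
       n_excluded = sum(!keep),
       defined = TRUE)
}

#' Run the full time-series QA procedure
#'
#' Computes the mean-intensity trace, the center-of-mass traces and the
#' scalar tSNR/SFNR summary. Data with a single timepoint yields a
#' not-applicable marker.
#'
#' @inheritParams tsnr_sfnr
#' @return A `timeseries_qa_result` list (`mean_intensity`, `com`,
#'   `mean_snr`, `mean_sfnr`, `n_timepoints`, `n_excluded`) or a
#'   [qa_not_applicable()] marker.
#' @export
timeseries_qa <- function(volume, mask = "auto") {
  trace <- volume_mean_trace(volume)
  if (inherits(trace, "qa_not_applicable")) return(trace)
  com <- com_trace(volume)
  nt <- dim(volume$data)[4]
  scal <- if (nt >= 5) tsnr_sfnr(volume, mask = mask)
          else list(mean_snr = NA_real_, mean_sfnr = NA_real_,
                    n_voxels = 0L, n_excluded = 0L, defined = FALSE)
  structure(list(mean_intensity = trace,
                 com = com,
                 mean_snr = scal$mean_snr,
                 mean_sfnr = scal$mean_sfnr,
                 snr_defined = scal$defined,
                 n_excluded = scal$n_excluded,
                 n_timepoints = nt),
            class = "timeseries_qa_result")
}

#' @export
print.timeseries_qa_result <- function(x, ...) {
  cat("<timeseries_qa_result>", x$n_timepoints, "timepoints; tSNR:",
      if (x$snr_defined) signif(x$mean_snr, 5) else "undefined",
      " SFNR:", if (x$snr_defined) signif(x$mean_sfnr, 5) else "undefined",
      "\n")
  invisible(x)
}

#' Write time-series QA traces as CSV
#'
#' Columns: `timepoint` (1-based), `mean_intensity`, `com_x`, `com_y`,
#' `com_z`.
#'
#' @param result A `timeseries_qa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path) {
  df <- data.frame(timepoint = seq_len(result$n_timepoints),
                   mean_intensity = result$mean_intensity,
                   com_x = result$com[, "x"],
                   com_y = result$com[, "y"],
                   com_z = result$com[, "z"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
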