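# Structural QA: native head/brain/tissue segmentation, per-region
# intensity statistics and the structural SNR statistic.

# --- binary 3D morphology (6-connectivity), vectorized over whole arrays ---

.shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.dilate1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L))
    out <- out | .shift3(mask, ax, s)
  out
}

.erode1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- .shift3(mask, ax, s)
    # voxels at the array border lose their off-grid neighbour: treat the
    # outside as background so erosion shrinks from the boundary too
    out <- out & nb
  }
  out
}

#' Binary dilation / erosion of a 3D mask
#'
#' Iterated one-step 6-connectivity morphology (diamond structuring
#' element of the given radius).
#'
#' @param mask Logical 3D array.
#' @param r Radius in voxels (number of iterations).
#' @return Logical 3D array.
#' @export
morph_dilate <- function(mask, r = 1) {
  for (i in seq_len(r)) mask <- .dilate1(mask)
  mask
}

#' @rdname morph_dilate
#' @export
morph_erode <- function(mask, r = 1) {
  for (i in seq_len(r)) mask <- .erode1(mask)
  mask
}

#' Fill interior holes of a 3D mask
#'
#' Background connected (6-connectivity) to the array border stays
#' background; any enclosed cavity becomes foreground. This makes a head
#' mask solid even when interior tissue (for example CSF) falls below the
#' foreground threshold.
#'
#' @param mask Logical 3D array.
#' @return Logical 3D array with cavities filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  outside[1, , ] <- TRUE; outside[d[1], , ] <- TRUE
  outside[, 1, ] <- TRUE; outside[, d[2], ] <- TRUE
  outside[, , 1] <- TRUE; outside[, , d[3]] <- TRUE
  outside <- outside & !mask
  repeat {
    grown <- .dilate1(outside) & !mask
    grown <- grown | outside
    if (identical(grown, outside)) break
    outside <- grown
  }
  !outside
}

#' Largest 6-connected component of a 3D mask
#'
#' Label propagation: every foreground voxel starts with a unique label and
#' repeatedly takes the minimum over its 6-neighbourhood until a fixed
#' point; components then share a label.
#'
#' @param mask Logical 3D array.
#' @return Logical 3D array retaining only the largest component.
#' @export
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- array(Inf, d)
      src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      dst <- src
      n <- d[ax]
      if (s > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
      else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
      nb[dst[[1]], dst[[2]], dst[[3]]] <- lab[src[[1]], src[[2]], src[[3]]]
      new <- pmin(new, nb)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  labs <- lab[mask]
  counts <- table(labs)
  best <- as.numeric(names(counts)[which.max(counts)])
  mask & !is.na(lab) & lab == best
}

#' Otsu threshold of an intensity array
#'
#' Maximizes between-class variance over a fixed-bin histogram.
#'
#' @param x Numeric array or vector.
#' @param nbins Number of histogram bins.
#' @return Threshold value on the intensity scale.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- as.numeric(
    tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nbins),
             nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[nbins]; tot_mu <- mu[nbins]
  w0 <- w[-nbins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-nbins] / w0
  m1 <- (tot_mu - mu[-nbins]) / w1
  bcv <- ifelse(valid, w0 * w1 * (m0 - m1)^2, -Inf)
  br[which.max(bcv) + 1]
}

#' Segment a structural volume into head, brain, tissue and exterior masks
#'
#' A native segmenter for phantom-like structural data: the voxels above
#' the Otsu threshold are morphologically closed and hole-filled (so dark
#' interior tissue cannot hollow the mask), and the head is the largest
#' connected component of the result; the brain is the head eroded by
#' `erode_margin` voxels; tissue
#' classes are a 3-class 1D k-means over brain intensities with ascending
#' class means labelled CSF, gray matter, white matter; the exterior is
#' the complement of the head dilated by `exterior_margin` voxels (the
#' in-between shell is a buffer belonging to neither). Externally supplied
#' masks can replace this segmenter wherever a `region_masks` list is
#' accepted.
#'
#' @param volume A [volume_stack()] (3D).
#' @param erode_margin Erosion radius (voxels) taking head to brain.
#' @param exterior_margin Dilation radius (voxels) separating exterior
#'   from head.
#' @return A `region_masks` list with logical arrays `head`, `brain`,
#'   `white`, `gray`, `csf`, `exterior`.
#' @export
segment_structural <- function(volume, erode_margin = 2,
                               exterior_margin = 3) {
  stopifnot(inherits(volume, "volume_stack"))
  if (length(dim(volume$data)) != 3)
    stop("structural segmentation requires a 3D volume")
  x <- volume$data
  if (all(x == 0)) stop("empty image: volume is all zero")

  th <- otsu_threshold(x)
  fg <- x > th
  if (!any(fg)) stop("empty image: nothing above threshold")
  fg <- morph_erode(morph_dilate(fg, 1), 1)  # closing
  head <- largest_component(fill_holes(fg))
  brain <- morph_erode(head, erode_margin)
  exterior <- !morph_dilate(head, exterior_margin)

  white <- gray <- csf <- array(FALSE, dim(x))
  if (any(brain)) {
    vals <- x[brain]
    centers <- stats::quantile(vals, c(1, 3, 5) / 6, names = FALSE)
    if (length(unique(centers)) == 3) {
      km <- stats::kmeans(vals, centers = matrix(centers, ncol = 1))
      ord <- order(km$centers)  # ascending: CSF, gray, white
      cls <- match(km$cluster, ord)
    } else {
      cls <- rep(3L, length(vals))
    }
    idx <- which(brain)
    csf[idx[cls == 1]] <- TRUE
    gray[idx[cls == 2]] <- TRUE
    white[idx[cls == 3]] <- TRUE
  }
  structure(list(head = head, brain = brain, white = white, gray = gray,
                 csf = csf, exterior = exterior), class = "region_masks")
}

.nearest_rank <- function(sorted, p) {
  n <- length(sorted)
  sorted[pmin(n, pmax(1L, ceiling(p * n)))]
}

.one_region_stats <- function(vals, voxvol, robust_probs) {
  if (length(vals) == 0)
    return(list(defined = FALSE, n_voxels = 0L, volume = 0,
                min = NA_real_, max = NA_real_, robust_min = NA_real_,
                robust_max = NA_real_, mean = NA_real_, sd = NA_real_))
  s <- sort(vals)
  m <- mean(vals)
  list(defined = TRUE,
       n_voxels = length(vals),
       volume = length(vals) * voxvol,
       min = s[1], max = s[length(s)],
       robust_min = .nearest_rank(s, robust_probs[1]),
       robust_max = .nearest_rank(s, robust_probs[2]),
       mean = m,
       sd = sqrt(mean((vals - m)^2)))
}

#' Per-region intensity statistics
#'
#' For each region mask: minimum and maximum, robust minimum and maximum
#' (2nd/98th percentile by the nearest-rank method), mean, standard
#' deviation (population formula, dividing by N), voxel count and volume
#' in mm^3. Empty regions yield undefined statistics rather than an error.
#'
#' @param volume A [volume_stack()].
#' @param masks A `region_masks` list (any named list of logical masks
#'   over the same grid works).
#' @param robust_probs Percentile pair for the robust range.
#' @return Named list of per-region stats lists (`defined`, `n_voxels`,
#'   `volume`, `min`, `max`, `robust_min`, `robust_max`, `mean`, `sd`).
#' @export
region_stats <- function(volume, masks, robust_probs = c(0.02, 0.98)) {
  stopifnot(inherits(volume, "volume_stack"))
  voxvol <- prod(volume$voxel_size)
  regions <- masks[!names(masks) %in% ""]
  lapply(regions, function(m) {
    if (!identical(dim(m), dim(volume$data)))
      stop("mask grid does not match volume grid")
    .one_region_stats(volume$data[m], voxvol, robust_probs)
  })
}

#' Structural signal-to-noise ratio
#'
#' The mean image intensity within the brain divided by the standard
#' deviation of the intensity in the exterior region (population SD). A
#' zero exterior SD makes the ratio undefined; this is flagged rather than
#' returned as infinity. The statistic is invariant under global intensity
#' scaling.
#'
#' @param volume A [volume_stack()].
#' @param masks A `region_masks` list with `brain` and `exterior`.
#' @return List with `snr` (numeric or `NA`) and `defined` (logical).
#' @export
structural_snr <- function(volume, masks) {
  stopifnot(inherits(volume, "volume_stack"))
  if (!any(masks$brain) || !any(masks$exterior))
    stop("brain and exterior masks must be non-empty")
  ext <- volume$data[masks$exterior]
  s <- sqrt(mean((ext - mean(ext))^2))
  if (s == 0) return(list(snr = NA_real_, defined = FALSE))
  list(snr = mean(volume$data[masks$brain]) / s, defined = TRUE)
}

#' Run the full structural QA procedure
#'
#' Segments the volume, computes per-region statistics and the structural
#' SNR.
#'
#' @param volume A [volume_stack()] (3D).
#' @param masks Optional externally supplied `region_masks`; when `NULL`
#'   the native segmenter is used.
#' @return A `structural_qa_result` list: `stats` (per-region), `snr`,
#'   `snr_defined`.
#' @export
structural_qa <- function(volume, masks = NULL) {
  if (is.null(masks)) masks <- segment_structural(volume)
  snr <- structural_snr(volume, masks)
  structure(list(stats = region_stats(volume, masks),
                 snr = snr$snr, snr_defined = snr$defined),
            class = "structural_qa_result")
}

#' @export
print.structural_qa_result <- function(x, ...) {
  cat("<structural_qa_result> SNR:",
      if (x$snr_defined) signif(x$snr, 5) else "undefined", "\n")
  for (r in names(x$stats)) {
    s <- x$stats[[r]]
    if (s$defined)
      cat(sprintf("  %-8s n=%d mean=%.2f sd=%.2f range=[%.1f, %.1f]\n",
                  r, s$n_voxels, s$mean, s$sd, s$min, s$max))
    else cat(sprintf("  %-8s (empty)\n", r))
  }
  invisible(x)
}

#' Write region masks as NIfTI files
#'
#' @param masks A `region_masks` list.
#' @param volume The [volume_stack()] the masks belong to (for geometry).
#' @param dir Output directory; one `<region>.nii.gz` per mask.
#' @return Named vector of written paths, invisibly.
#' @export
export_masks <- function(masks, volume, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- vapply(names(masks), function(r) {
    v <- volume_stack(array(as.integer(masks[[r]]), dim(masks[[r]])),
                      voxel_size = volume$voxel_size, affine = volume$affine)
    export_nifti(v, file.path(dir, paste0(r, ".nii.gz")))
  }, "")
  invisible(out)
}
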