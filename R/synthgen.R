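# Seeded generator of synthetic DICOM fixtures with ground truth:
# PHI-rich multi-subject trees, structural phantoms with tissue masks,
# 4D time-series phantoms with logged artifacts, and diffusion series
# with controllable gradient tables.

.PHI_VALUES <- c(
  "0008,0050" = "ACC123456",
  "0008,0080" = "GENERAL HOSPITAL",
  "0008,0090" = "SMITH^JOHN^DR",
  "0008,0096" = "REF-ID-001",
  "0008,1048" = "JONES^MARY",
  "0008,1049" = "REC-ID-002",
  "0008,1050" = "BROWN^JAMES",
  "0008,1052" = "PERF-ID-003",
  "0008,1060" = "DAVIS^SUSAN",
  "0008,1062" = "READ-ID-004",
  "0010,0030" = "19800101",
  "0010,0050" = "INS-PLAN-42",
  "0010,0101" = "ENG",
  "0010,1000" = "ALT-ID-1",
  "0010,1001" = "DOE^JANE",
  "0010,1002" = "ALT-ID-2",
  "0010,1005" = "MAIDEN^NAME",
  "0010,1010" = "034Y",
  "0010,1040" = "123 MAIN ST ANYTOWN",
  "0010,1060" = "MOTHER^MAIDEN")

.default_bvecs <- function() {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  v / sqrt(rowSums(v^2))
}

#' Specify a synthetic phantom
#'
#' Collects every knob of the generator: phantom kind and geometry,
#' intensity model, artifact schedule, gradient table, tree layout and
#' the PHI fields to populate. A fixed seed makes the emitted file tree
#' byte-identical across runs.
#'
#' Intensity defaults: tissue means 300 (CSF), 600 (gray), 900 (white)
#' with additive Gaussian noise; the background carries a positive offset
#' of five noise SDs so that 16-bit unsigned encoding never clips the
#' noise distribution. Time-series phantoms default to a signal-to-noise
#' design of S/sigma = 1000/20 = 50 over 200 timepoints, with an
#' ellipsoid of at least 1000 signal voxels.
#'
#' @param kind `"structural"`, `"timeseries"` or `"diffusion"`.
#' @param dim Grid dimensions (length 3).
#' @param voxel_size Voxel size in mm.
#' @param tissue_means Named means for `csf`, `gray`, `white`.
#' @param scalp_mean Intensity of the head shell outside the brain.
#' @param noise_sd SD of the additive Gaussian noise in the object
#'   (intensity units); defaults to 10 for structural and diffusion
#'   phantoms and 20 for time series.
#' @param background_mean Background offset; default `5 * noise_sd` for
#'   structural phantoms (keeping the full noise distribution above zero
#'   for 16-bit unsigned encoding) and `4 * background_sd` otherwise
#'   (a faint air background that barely weighs on the center of mass).
#' @param background_sd Background noise SD (time-series/diffusion kinds).
#' @param signal Time-series signal level S.
#' @param n_timepoints Number of timepoints (time-series kind).
#' @param spikes List of `list(t =, factor =)` global intensity spikes.
#' @param shifts List of `list(t =, delta = c(dx, dy, dz))`: from
#'   timepoint `t` onward the phantom is rendered displaced by `delta`
#'   voxels.
#' @param drift Linear drift fraction over the run applied to the signal
#'   (0 = none).
#' @param bvals,bvecs Gradient table (diffusion kind).
#' @param adc Apparent diffusion coefficient (mm^2/s) used to attenuate
#'   the diffusion signal.
#' @param n_subjects,n_sessions Tree layout for [synth_dicom_tree()].
#' @param scan_kinds Kinds of the scans emitted per session (defaults to
#'   a single scan of `kind`).
#' @param phi_fields Protected tags to populate in every file; `"all"`
#'   expands to the full 20-tag profile.
#' @param seed Integer seed driving all randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("structural", "timeseries", "diffusion"),
                         dim = NULL,
                         voxel_size = c(1, 1, 1),
                         tissue_means = c(csf = 300, gray = 600, white = 900),
                         scalp_mean = 750,
                         noise_sd = NULL,
                         background_mean = NULL,
                         background_sd = NULL,
                         signal = 1000,
                         n_timepoints = 200,
                         spikes = list(),
                         shifts = list(),
                         drift = 0,
                         bvals = c(0, rep(1000, 6)),
                         bvecs = rbind(c(0, 0, 0), .default_bvecs()),
                         adc = 7e-4,
                         n_subjects = 1,
                         n_sessions = 1,
                         scan_kinds = NULL,
                         phi_fields = character(0),
                         seed = 1) {
  kind <- match.arg(kind)
  if (is.null(dim))
    dim <- switch(kind, structural = c(64, 64, 64),
                  timeseries = c(32, 32, 12), diffusion = c(16, 16, 8))
  if (is.null(noise_sd))
    noise_sd <- switch(kind, structural = 10, timeseries = 20,
                       diffusion = 10)
  if (is.null(background_sd)) background_sd <- min(noise_sd, 2)
  if (is.null(background_mean))
    background_mean <- if (kind == "structural") 5 * noise_sd
                       else 4 * background_sd
  if (is.null(scan_kinds)) scan_kinds <- kind
  if (identical(phi_fields, "all")) phi_fields <- names(.PHI_VALUES)
  for (sp in spikes)
    if (sp$t < 1 || sp$t > n_timepoints)
      stop("invalid spec: spike time ", sp$t, " outside 1..", n_timepoints)
  for (sh in shifts)
    if (sh$t < 1 || sh$t > n_timepoints)
      stop("invalid spec: shift time ", sh$t, " outside 1..", n_timepoints)
  if (length(bvals) != nrow(bvecs))
    stop("invalid spec: bvals and bvecs disagree in length")
  structure(list(kind = kind, dim = dim, voxel_size = voxel_size,
                 tissue_means = tissue_means, scalp_mean = scalp_mean,
                 noise_sd = noise_sd, background_mean = background_mean,
                 background_sd = background_sd, signal = signal,
                 n_timepoints = n_timepoints, spikes = spikes,
                 shifts = shifts, drift = drift, bvals = bvals,
                 bvecs = bvecs, adc = adc, n_subjects = n_subjects,
                 n_sessions = n_sessions, scan_kinds = scan_kinds,
                 phi_fields = tolower(phi_fields), seed = seed),
            class = "phantom_spec")
}

.ellipsoid_r2 <- function(dim, center, radii) {
  x <- (seq_len(dim[1]) - center[1]) / radii[1]
  y <- (seq_len(dim[2]) - center[2]) / radii[2]
  z <- (seq_len(dim[3]) - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Render a structural phantom with ground-truth masks
#'
#' Nested ellipsoids: a white-matter core, a gray-matter shell, an outer
#' CSF shell (together the brain), and a thin bright scalp/skull shell
#' (together the head) over a noisy offset background. The head shell is
#' only two voxels thick so a head-based segmentation is a close proxy
#' for the brain.
#'
#' @param spec A [phantom_spec()] of kind `"structural"`.
#' @return List: `volume` (a [volume_stack()] with integer intensities as
#'   encoded to DICOM), `truth` (noiseless array, region masks, tissue
#'   label array with 1=CSF 2=gray 3=white, noiseless brain mean,
#'   `noise_sd`).
#' @export
synth_structural <- function(spec) {
  set.seed(spec$seed)
  d <- spec$dim
  center <- (d + 1) / 2
  rb <- pmax(3, d * c(0.34, 0.31, 0.28))      # brain semi-axes
  rh <- rb + 2                                 # head = brain + thin shell
  rg <- rb * 0.85                              # gray/CSF boundary
  rw <- rb * 0.60                              # white/gray boundary

  brain <- .ellipsoid_r2(d, center, rb) <= 1
  head <- .ellipsoid_r2(d, center, rh) <= 1
  graycore <- .ellipsoid_r2(d, center, rg) <= 1
  white <- .ellipsoid_r2(d, center, rw) <= 1
  gray <- graycore & !white
  csf <- brain & !graycore

  labels <- array(0L, d)
  labels[csf] <- 1L; labels[gray] <- 2L; labels[white] <- 3L

  noiseless <- array(spec$background_mean, d)
  noiseless[head] <- spec$scalp_mean
  noiseless[csf] <- spec$tissue_means[["csf"]]
  noiseless[gray] <- spec$tissue_means[["gray"]]
  noiseless[white] <- spec$tissue_means[["white"]]

  data <- noiseless + stats::rnorm(prod(d), sd = spec$noise_sd)
  data <- round(pmin(pmax(data, 0), 65535))

  list(volume = volume_stack(data, voxel_size = spec$voxel_size),
       truth = list(noiseless = noiseless,
                    masks = list(head = head, brain = brain, white = white,
                                 gray = gray, csf = csf, exterior = !head),
                    labels = labels,
                    brain_mean = mean(noiseless[brain]),
                    noise_sd = spec$noise_sd))
}

.render_signal_mask <- function(d, delta = c(0, 0, 0)) {
  center <- (d + 1) / 2 + delta
  radii <- d * c(0.32, 0.29, 0.42)
  .ellipsoid_r2(d, center, radii) <= 1
}

#' Render a 4D time-series phantom with an artifact log
#'
#' An ellipsoid of constant signal S over a low offset background, with
#' independent Gaussian noise at every voxel and timepoint. Scheduled
#' artifacts: global intensity spikes (whole volume scaled at one
#' timepoint), step displacements of the ellipsoid (from a timepoint
#' onward), and a linear signal drift over the run.
#'
#' @param spec A [phantom_spec()] of kind `"timeseries"`.
#' @return List: `volume` (4D integer [volume_stack()]), `truth` (signal
#'   mask, S, noise SD, background, spike/shift/drift log, and the signal
#'   mass fraction of each shift — the expected center-of-mass step is
#'   `delta` times that fraction).
#' @export
synth_timeseries <- function(spec) {
  set.seed(spec$seed)
  d <- spec$dim; nt <- spec$n_timepoints
  base_mask <- .render_signal_mask(d)
  shift_at <- function(t) {
    delta <- c(0, 0, 0)
    for (sh in spec$shifts) if (t >= sh$t) delta <- delta + sh$delta
    delta
  }
  spike_factor <- function(t) {
    f <- 1
    for (sp in spec$spikes) if (t == sp$t) f <- f * sp$factor
    f
  }
  data <- array(0, c(d, nt))
  for (t in seq_len(nt)) {
    m <- .render_signal_mask(d, shift_at(t))
    driftf <- 1 + spec$drift * (t - 1) / max(1, nt - 1)
    frame <- array(spec$background_mean, d)
    frame[m] <- spec$signal * driftf
    noise <- array(stats::rnorm(prod(d), sd = spec$background_sd), d)
    noise[m] <- stats::rnorm(sum(m), sd = spec$noise_sd)
    frame <- (frame + noise) * spike_factor(t)
    data[, , , t] <- frame
  }
  data <- round(pmin(pmax(data, 0), 65535))
  sig_mass <- spec$signal * sum(base_mask)
  bg_mass <- spec$background_mean * (prod(d) - sum(base_mask))
  list(volume = volume_stack(data, voxel_size = spec$voxel_size),
       truth = list(signal_mask = base_mask, signal = spec$signal,
                    noise_sd = spec$noise_sd,
                    background_mean = spec$background_mean,
                    spikes = spec$spikes, shifts = spec$shifts,
                    drift = spec$drift,
                    signal_mass_fraction = sig_mass / (sig_mass + bg_mass)))
}

#' Render a diffusion phantom with its gradient table
#'
#' One 3D ellipsoid volume per gradient-table entry, attenuated as
#' `S0 * exp(-b * ADC)`.
#'
#' @param spec A [phantom_spec()] of kind `"diffusion"`.
#' @return List: `volume` (4D integer [volume_stack()]), `truth` (the
#'   [gradient_table()], `adc`, `S0`).
#' @export
synth_diffusion <- function(spec) {
  set.seed(spec$seed)
  d <- spec$dim
  nvol <- length(spec$bvals)
  mask <- .render_signal_mask(d)
  data <- array(0, c(d, nvol))
  for (v in seq_len(nvol)) {
    frame <- array(spec$background_mean, d)
    frame[mask] <- spec$signal * exp(-spec$bvals[v] * spec$adc)
    frame <- frame + stats::rnorm(prod(d), sd = spec$background_sd)
    data[, , , v] <- frame
  }
  data <- round(pmin(pmax(data, 0), 65535))
  list(volume = volume_stack(data, voxel_size = spec$voxel_size),
       truth = list(table = gradient_table(spec$bvals, spec$bvecs),
                    adc = spec$adc, S0 = spec$signal))
}

.series_description <- function(kind) {
  switch(kind, structural = "MPRAGE", timeseries = "BOLD_resting",
         diffusion = "DWI_6dir")
}

.base_entity <- function(spec, uid) {
  e <- dicom_entity(tags = list(), vrs = character(0))
  e <- dcm_set(e, "0008,0016", .SOP_MR_IMAGE)
  e <- dcm_set(e, "0008,0060", "MR")
  e <- dcm_set(e, "0028,0002", 1L)
  e <- dcm_set(e, "0028,0004", "MONOCHROME2")
  e <- dcm_set(e, "0028,0100", 16L)
  e <- dcm_set(e, "0028,0101", 16L)
  e <- dcm_set(e, "0028,0102", 15L)
  e <- dcm_set(e, "0028,0103", 0L)
  for (tag in spec$phi_fields)
    e <- dcm_set(e, tag, .PHI_VALUES[[tag]])
  e
}

#' Emit a synthetic DICOM tree with a ground-truth sidecar
#'
#' Builds `n_subjects x n_sessions` imaging sessions, each holding one
#' scan per entry of `scan_kinds`, as classic explicit-VR little-endian
#' DICOM files under `out`, plus a `ground_truth.json` sidecar. Every
#' populated PHI field is recorded in the PHI log; the returned ground
#' truth carries the per-file subject/session assignment, the source
#' arrays exactly as encoded, region masks and artifact logs — sufficient
#' to serve as the oracle for grouping, anonymization, assembly and QA.
#'
#' @param spec A [phantom_spec()].
#' @param out Output directory (created; must not already contain files).
#' @return Invisibly, a list: `files`, `assignment` (data frame file /
#'   patient_id / study_uid / series_uid), `phi_log` (data frame file /
#'   tag / value), `scans` (named by `subject/session/scan`, each with
#'   `kind`, `truth`, `array`), `sidecar` path.
#' @export
synth_dicom_tree <- function(spec, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  uid_root <- sprintf("1.2.826.0.1.3680043.9.7411.%d", spec$seed)
  uid_n <- 0L
  next_uid <- function() {
    uid_n <<- uid_n + 1L
    sprintf("%s.%d", uid_root, uid_n)
  }

  files <- character(0)
  assign_rows <- list(); phi_rows <- list(); scans <- list()

  for (si in seq_len(spec$n_subjects)) {
    pid <- sprintf("SYN%03d", si)
    for (se in seq_len(spec$n_sessions)) {
      study_uid <- next_uid()
      sess_dir <- file.path(out, pid, sprintf("sess%02d", se))
      dir.create(sess_dir, recursive = TRUE, showWarnings = FALSE)
      for (ki in seq_along(spec$scan_kinds)) {
        kind <- spec$scan_kinds[ki]
        series_uid <- next_uid()
        scan_dir <- file.path(sess_dir, sprintf("scan%02d", ki))
        dir.create(scan_dir, showWarnings = FALSE)

        if (identical(kind, spec$kind)) {
          sub_spec <- spec
        } else {
          # scans of another kind inside a mixed tree use that kind's own
          # intensity defaults at a compact grid
          sub_spec <- phantom_spec(
            kind = kind,
            dim = switch(kind, structural = c(32, 32, 32),
                         timeseries = c(16, 16, 8),
                         diffusion = c(16, 16, 8)),
            voxel_size = spec$voxel_size,
            n_timepoints = if (kind == "timeseries") 20
                           else spec$n_timepoints,
            bvals = spec$bvals, bvecs = spec$bvecs,
            phi_fields = spec$phi_fields, seed = spec$seed)
        }
        # per-scan seed keeps noise independent across the tree but
        # reproducible
        sub_spec$seed <- spec$seed + 1000L * si + 100L * se + ki
        gen <- switch(kind,
                      structural = synth_structural(sub_spec),
                      timeseries = synth_timeseries(sub_spec),
                      diffusion = synth_diffusion(sub_spec))
        arr <- gen$volume$data
        dims <- dim(arr)
        n_slices <- dims[3]
        n_t <- if (length(dims) == 4) dims[4] else 1L
        if (length(dims) == 3) dim(arr) <- c(dims, 1L)

        for (t in seq_len(n_t)) for (s in seq_len(n_slices)) {
          e <- .base_entity(sub_spec, uid_root)
          e <- dcm_set(e, "0010,0010", sprintf("SYNTHETIC^%s", pid))
          e <- dcm_set(e, "0010,0020", pid)
          e <- dcm_set(e, "0020,000d", study_uid)
          e <- dcm_set(e, "0020,000e", series_uid)
          e <- dcm_set(e, "0020,0011", as.character(ki))
          e <- dcm_set(e, "0008,103e", .series_description(kind))
          e <- dcm_set(e, "0008,0018", next_uid())
          e <- dcm_set(e, "0020,0013",
                       as.character((t - 1L) * n_slices + s))
          e <- dcm_set(e, "0020,0032",
                       sprintf("0\\0\\%g", (s - 1) * spec$voxel_size[3]))
          e <- dcm_set(e, "0020,0037", "1\\0\\0\\0\\1\\0")
          e <- dcm_set(e, "0028,0010", dims[1])
          e <- dcm_set(e, "0028,0011", dims[2])
          e <- dcm_set(e, "0028,0030",
                       sprintf("%g\\%g", spec$voxel_size[1],
                               spec$voxel_size[2]))
          e <- dcm_set(e, "0018,0050", sprintf("%g", spec$voxel_size[3]))
          if (kind == "diffusion") {
            e <- dcm_set(e, "0018,9087", spec$bvals[t])
            e <- dcm_set(e, "0018,9089", spec$bvecs[t, ])
          }
          e$pixel <- matrix(as.integer(arr[, , s, t]), dims[1], dims[2])
          path <- file.path(scan_dir, sprintf("i%04d.dcm",
                                              (t - 1L) * n_slices + s))
          write_dicom(e, path)
          files <- c(files, path)
          assign_rows[[length(assign_rows) + 1L]] <-
            data.frame(file = path, patient_id = pid,
                       study_uid = study_uid, series_uid = series_uid,
                       stringsAsFactors = FALSE)
          if (length(spec$phi_fields))
            phi_rows[[length(phi_rows) + 1L]] <-
              data.frame(file = path, tag = spec$phi_fields,
                         value = unname(.PHI_VALUES[spec$phi_fields]),
                         stringsAsFactors = FALSE)
        }
        scans[[sprintf("%s/sess%02d/scan%02d", pid, se, ki)]] <-
          list(kind = kind, truth = gen$truth, array = gen$volume$data,
               series_uid = series_uid)
      }
    }
  }

  assignment <- do.call(rbind, assign_rows)
  phi_log <- if (length(phi_rows)) do.call(rbind, phi_rows)
             else data.frame(file = character(0), tag = character(0),
                             value = character(0), stringsAsFactors = FALSE)
  sidecar <- file.path(out, "ground_truth.json")
  relify <- function(df) {
    if (nrow(df))
      df$file <- ifelse(startsWith(df$file, out),
                        substring(df$file, nchar(out) + 2), df$file)
    df
  }
  jsonlite::write_json(list(
    seed = spec$seed, kind = spec$kind,
    n_subjects = spec$n_subjects, n_sessions = spec$n_sessions,
    scan_kinds = spec$scan_kinds,
    assignment = relify(assignment), phi_log = relify(phi_log),
    artifact_log = list(spikes = spec$spikes, shifts = spec$shifts,
                        drift = spec$drift)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(files = files, assignment = assignment, phi_log = phi_log,
                 scans = scans, sidecar = sidecar))
}

#' Load a phantom spec from a YAML file
#'
#' Field names mirror the arguments of [phantom_spec()]; `bvecs` is given
#' as a list of 3-vectors, `spikes`/`shifts` as lists of maps.
#'
#' @param path YAML spec file.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(phantom_spec)))]
  if (!is.null(args$bvecs))
    args$bvecs <- do.call(rbind, lapply(args$bvecs, as.numeric))
  if (!is.null(args$spikes))
    args$spikes <- lapply(args$spikes, function(s)
      list(t = s$t, factor = s$factor))
  if (!is.null(args$shifts))
    args$shifts <- lapply(args$shifts, function(s)
      list(t = s$t, delta = as.numeric(s$delta)))
  for (f in c("dim", "voxel_size", "bvals"))
    if (!is.null(args[[f]])) args[[f]] <- as.numeric(args[[f]])
  if (!is.null(args$tissue_means))
    args$tissue_means <- unlist(args$tissue_means)
  do.call(phantom_spec, args)
}

#' Synthetic reference distributions for report histograms
#'
#' Draws a synthetic population of structural SNR and time-series SFNR
#' values with realistic central values and spread. This stands in for a
#' reference scan collection when contextualizing a scan's QA metrics; it
#' is simulated, not measured data.
#'
#' @param n Population size.
#' @param seed Seed.
#' @return Data frame with columns `snr` and `sfnr`.
#' @export
synth_reference <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(snr = pmax(1, stats::rnorm(n, mean = 120, sd = 25)),
             sfnr = pmax(1, stats::rnorm(n, mean = 75, sd = 15)))
}
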