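# Shared fixture builders. Everything is generated in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A minimal in-memory DICOM entity with the geometry tags volume assembly
# needs. `slice` is 1-based; `t` the timepoint.
tiny_entity <- function(pid = "P1", study = "1.2.3.1", series = "1.2.3.2",
                        slice = 1, t = 1, n_slices = 1, rows = 4, cols = 4,
                        pixel = NULL, extra = list(), path = NA_character_) {
  e <- dicom_entity(filepath = path)
  e <- dcm_set(e, "0008,0018", sprintf("1.9.%s.%d.%d", series, t, slice))
  e <- dcm_set(e, "0010,0020", pid)
  e <- dcm_set(e, "0020,000d", study)
  e <- dcm_set(e, "0020,000e", series)
  e <- dcm_set(e, "0020,0013", as.character((t - 1) * n_slices + slice))
  e <- dcm_set(e, "0020,0032", sprintf("0\\0\\%g", slice - 1))
  e <- dcm_set(e, "0020,0037", "1\\0\\0\\0\\1\\0")
  e <- dcm_set(e, "0028,0010", rows)
  e <- dcm_set(e, "0028,0011", cols)
  e <- dcm_set(e, "0028,0100", 16L)
  e <- dcm_set(e, "0028,0030", "1\\1")
  for (tag in names(extra)) e <- dcm_set(e, tag, extra[[tag]])
  if (is.null(pixel))
    pixel <- matrix(seq_len(rows * cols) %% 1024L, rows, cols)
  e$pixel <- pixel
  e
}

# Entities forming one scan of `n_slices` x `n_t`
tiny_scan_entities <- function(n_slices, n_t = 1, ...) {
  out <- list()
  for (t in seq_len(n_t)) for (s in seq_len(n_slices))
    out[[length(out) + 1]] <- tiny_entity(slice = s, t = t,
                                          n_slices = n_slices, ...)
  out
}

all_protected_tags <- anonymization_profile()$protected

# Byte-level sweep of the header region (everything before the Pixel Data
# element) for protected tag encodings.
header_contains_tag <- function(path, tag) {
  buf <- readBin(path, "raw", file.info(path)$size)
  enc <- function(g, e) as.raw(c(g %% 256, g %/% 256, e %% 256, e %/% 256))
  hex <- strsplit(tag, ",")[[1]]
  pat <- enc(strtoi(hex[1], 16L), strtoi(hex[2], 16L))
  pix <- enc(0x7fe0, 0x0010)
  find_pat <- function(p, upto = length(buf)) {
    cand <- which(buf[seq_len(upto - 3)] == p[1])
    for (k in cand)
      if (identical(buf[k:(k + 3)], p)) return(k)
    0L
  }
  end <- find_pat(pix)
  if (end == 0L) end <- length(buf) - 3
  find_pat(pat, upto = end) > 0L
}

make_labels <- function(pids, project = "P1") {
  data.frame(patient_id = pids, project = project,
             subject = sprintf("S%02d", seq_along(pids)),
             session = "E01", stringsAsFactors = FALSE)
}

# Build a scan_series from a flat entity list via the public grouping API
.scan_from <- function(entities) {
  group_entities(entities)[[1]]$sessions[[1]]$scans[[1]]
}
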