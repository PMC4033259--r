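# Directory scanning, grouping, volume assembly, NIfTI export.

test_that("scan_directory finds DICOM files and counts skipped ones", {
  d <- withr::local_tempdir()
  for (i in 1:10)
    write_dicom(tiny_entity(slice = i, n_slices = 10),
                file.path(d, sprintf("f%02d.dcm", i)))
  writeLines("notes about the acquisition session, not an image file",
             file.path(d, "readme.txt"))
  writeLines("x,y\n1,2", file.path(d, "table.csv"))
  ents <- scan_directory(d)
  expect_length(ents, 10)
  expect_identical(attr(ents, "skipped"), 2L)
})

test_that("scan_directory errors on missing or DICOM-free directories", {
  expect_error(scan_directory(file.path(tempdir(), "does-not-exist-xyz")),
               "input error")
  d <- withr::local_tempdir()
  writeLines("just text here, nothing resembling an image at all today",
             file.path(d, "a.txt"))
  expect_error(scan_directory(d), "no valid data")
})

test_that("recursive scan collects files from nested subdirectories", {
  d <- withr::local_tempdir()
  for (sub in c("a", "b", "c")) {
    dir.create(file.path(d, sub))
    for (i in 1:4)
      write_dicom(tiny_entity(series = paste0("1.2.3.", sub), slice = i,
                              n_slices = 4),
                  file.path(d, sub, sprintf("f%d.dcm", i)))
  }
  expect_length(scan_directory(d, recursive = TRUE), 12)
})

test_that("grouping partitions entities by patient, study and series", {
  ents <- c(
    tiny_scan_entities(3, pid = "A", study = "1.1", series = "1.1.1"),
    tiny_scan_entities(3, pid = "A", study = "1.2", series = "1.2.1"),
    tiny_scan_entities(3, pid = "B", study = "2.1", series = "2.1.1"),
    tiny_scan_entities(3, pid = "B", study = "2.2", series = "2.2.1"))
  subj <- group_entities(ents)
  expect_length(subj, 2)
  expect_identical(vapply(subj, function(s) s$patient_id, ""), c("A", "B"))
  expect_identical(sum(vapply(subj, function(s) length(s$sessions), 0L)), 4L)
  # exact partition: session file counts sum to the number of entities
  n_files <- sum(unlist(lapply(subj, function(s)
    lapply(s$sessions, function(x)
      vapply(x$scans, function(sc) length(sc$entities), 0L)))))
  expect_identical(n_files, length(ents))
})

test_that("single patient and session collapse to one group", {
  ents <- tiny_scan_entities(5, pid = "only", study = "9.1", series = "9.1.1")
  subj <- group_entities(ents)
  expect_length(subj, 1)
  expect_length(subj[[1]]$sessions, 1)
})

test_that("entities without identifiers are excluded with a warning", {
  good <- tiny_scan_entities(2, pid = "A", study = "1.1", series = "1.1.1")
  bad <- tiny_entity(pid = "A")
  bad <- dcm_remove(bad, "0020,000d")
  expect_warning(subj <- group_entities(c(good, list(bad))), "excluded")
  expect_identical(
    length(subj[[1]]$sessions[[1]]$scans[[1]]$entities), 2L)
})

test_that("grouping reproduces a randomized generator assignment and is
           permutation-invariant", {
  set.seed(404)
  for (rep in 1:3) {
    k <- sample(1:3, 1); m <- sample(1:3, 1)
    tree_dir <- withr::local_tempdir()
    spec <- phantom_spec("diffusion", dim = c(6, 6, 2),
                         bvals = c(0, 1000), bvecs = rbind(c(0, 0, 0),
                                                           c(1, 0, 0)),
                         n_subjects = k, n_sessions = m,
                         seed = 100 + rep)
    tree <- synth_dicom_tree(spec, tree_dir)
    ents <- scan_directory(tree_dir)
    subj <- group_entities(ents)
    expect_length(subj, k)
    expect_identical(sum(vapply(subj, function(s) length(s$sessions), 0L)),
                     k * m)
    # per-file assignment matches the generator's ground-truth map
    truth <- tree$assignment
    for (s in subj) for (sess in s$sessions) for (scan in sess$scans)
      for (e in scan$entities) {
        row <- truth[truth$file == as.character(e$filepath), ]
        expect_identical(row$patient_id, s$patient_id)
        expect_identical(row$study_uid, sess$study_uid)
        expect_identical(row$series_uid, scan$series_uid)
      }
    # shuffling the input yields identical groups
    shuffled <- group_entities(sample(ents))
    strip_paths <- function(g) lapply(g, function(s) {
      s$sessions <- lapply(s$sessions, function(x) {
        x$scans <- lapply(x$scans, function(sc) {
          sc$entities <- lapply(sc$entities, function(e) e$tags)
          sc
        })
        x
      })
      s
    })
    expect_identical(strip_paths(shuffled), strip_paths(subj))
  }
})

test_that("assembly produces the right shapes for 3D and 4D series", {
  s3 <- .scan_from(tiny_scan_entities(20, rows = 8, cols = 8))
  v3 <- assemble_volume(s3)
  expect_identical(dim(v3$data), c(8L, 8L, 20L))
  expect_identical(v3$n_timepoints, 1L)

  s4 <- .scan_from(tiny_scan_entities(20, n_t = 5, rows = 8, cols = 8))
  v4 <- assemble_volume(s4)
  expect_identical(dim(v4$data), c(8L, 8L, 20L, 5L))
  expect_identical(v4$n_timepoints, 5L)
})

test_that("assembled voxels equal the generator's source array exactly", {
  tree_dir <- withr::local_tempdir()
  spec <- phantom_spec("timeseries", dim = c(8, 8, 4), n_timepoints = 6,
                       seed = 5)
  tree <- synth_dicom_tree(spec, tree_dir)
  scan <- group_entities(scan_directory(tree_dir))[[1]]$sessions[[1]]$scans[[1]]
  vol <- assemble_volume(scan)
  truth <- tree$scans[[1]]$array
  expect_identical(dim(vol$data), dim(truth))
  expect_equal(vol$data, truth, tolerance = 0)
})

test_that("assembly rejects inconsistent geometry and duplicate slices", {
  mixed <- c(tiny_scan_entities(2, rows = 4, cols = 4),
             tiny_scan_entities(2, rows = 6, cols = 6))
  expect_error(assemble_volume(.scan_from(mixed)), "spatial inconsistency")

  dup <- tiny_scan_entities(4)
  dup[[2]] <- dcm_set(dup[[2]], "0020,0032", "0\\0\\0")  # same as slice 1
  expect_error(assemble_volume(.scan_from(dup)), "duplicate slice")
})

test_that("NIfTI export round-trips voxels exactly and affine to 1e-6", {
  arr <- array(sample.int(4096, 8 * 8 * 5, replace = TRUE), c(8, 8, 5))
  aff <- rbind(cbind(diag(c(1.5, 2, 3.2)), c(-10, 4, 7)), c(0, 0, 0, 1))
  v <- volume_stack(arr, voxel_size = c(1.5, 2, 3.2), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  export_nifti(v, f)
  r <- read_nifti_volume(f)
  expect_equal(r$data, arr, tolerance = 0, ignore_attr = TRUE)
  expect_lt(max(abs(r$affine - aff)), 1e-6)

  arr4 <- array(1:(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  v4 <- volume_stack(arr4)
  f4 <- withr::local_tempfile(fileext = ".nii")
  export_nifti(v4, f4)
  img <- RNifti::niftiHeader(RNifti::readNifti(f4))
  expect_identical(img$dim[1], 4L)  # dim[0] in NIfTI numbering: rank 4
})
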