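# Diffusion QA: gradient extraction, the check suite, and a randomized
# corruption sweep against an independent re-evaluation of the rules.

unit6 <- function() {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  v / sqrt(rowSums(v^2))
}

# Independent oracle: a straight-line re-statement of the rule set,
# evaluated per rule without sharing code with run_checks().
oracle_statuses <- function(bvals, bvecs, n_vol_mismatch = FALSE,
                            norm_tol = 0.01, b_lo = 100, b_hi = 10000,
                            min_dirs = 6) {
  out <- c(spatial = if (n_vol_mismatch) "fail" else "pass")
  dwi <- which(bvals > 0)
  nrm <- sqrt(rowSums(bvecs^2))
  out["gradient_norm"] <-
    if (any(nrm[dwi] == 0) || any(abs(nrm[dwi] - 1) > norm_tol)) "fail"
    else "pass"
  if (length(dwi)) {
    u <- bvecs[dwi, , drop = FALSE] / pmax(nrm[dwi], 1e-12)
    n_unique <- 0
    seen <- list()
    for (i in seq_len(nrow(u))) {
      is_dup <- FALSE
      for (s in seen)
        if (abs(sum(u[i, ] * s)) >= 1 - 1e-3) is_dup <- TRUE
      if (!is_dup) { seen <- c(seen, list(u[i, ])); n_unique <- n_unique + 1 }
    }
    out["duplicate_directions"] <-
      if (n_unique < length(dwi)) "warn" else "pass"
    out["direction_count"] <- if (n_unique < min_dirs) "warn" else "pass"
  }
  out["b_values"] <-
    if (any(bvals[dwi] < b_lo | bvals[dwi] > b_hi)) "warn" else "pass"
  out["b0_present"] <- if (!any(bvals == 0)) "warn" else "pass"
  out
}

vol_for <- function(n) volume_stack(array(1, c(4, 4, 2, n)))

test_that("a well-formed b0 + 6 unit directions table passes everything", {
  tb <- gradient_table(c(0, rep(1000, 6)), rbind(c(0, 0, 0), unit6()))
  res <- run_checks(vol_for(7), tb)
  expect_identical(res$overall, "pass")
  expect_true(all(res$checks$status == "pass"))
})

test_that("designated corruptions trigger their designated findings", {
  base_v <- rbind(c(0, 0, 0), unit6())
  base_b <- c(0, rep(1000, 6))

  bad_norm <- base_v; bad_norm[2, ] <- c(2, 0, 0)
  r <- run_checks(vol_for(7), gradient_table(base_b, bad_norm))
  expect_identical(r$checks$status[r$checks$name == "gradient_norm"], "fail")
  expect_identical(r$overall, "fail")

  zerodir <- base_v; zerodir[3, ] <- 0
  r <- run_checks(vol_for(7), gradient_table(base_b, zerodir))
  expect_identical(r$checks$status[r$checks$name == "gradient_norm"], "fail")

  lowb <- base_b; lowb[2] <- 50
  r <- run_checks(vol_for(7), gradient_table(lowb, base_v))
  expect_identical(r$checks$status[r$checks$name == "b_values"], "warn")
  expect_identical(r$overall, "pass")  # warnings never fail the scan

  r <- run_checks(vol_for(4),
                  gradient_table(c(0, rep(1000, 3)),
                                 rbind(c(0, 0, 0), unit6()[1:3, ])))
  expect_identical(r$checks$status[r$checks$name == "direction_count"],
                   "warn")

  # antipodal pair counts as a duplicate
  anti <- rbind(c(0, 0, 0), unit6()[1:5, ], -unit6()[1, , drop = FALSE])
  r <- run_checks(vol_for(7), gradient_table(base_b, anti))
  expect_identical(r$checks$status[r$checks$name == "duplicate_directions"],
                   "warn")

  no_b0 <- gradient_table(rep(1000, 6), unit6())
  r <- run_checks(vol_for(6), no_b0)
  expect_identical(r$checks$status[r$checks$name == "b0_present"], "warn")

  # volume count mismatch is a spatial failure
  r <- run_checks(vol_for(5), gradient_table(base_b, base_v))
  expect_identical(r$checks$status[r$checks$name == "spatial"], "fail")
})

test_that("randomized corrupted tables agree with the rule-set oracle and
           overall = pass iff no fail", {
  set.seed(53)
  for (rep in 1:40) {
    n <- sample(3:9, 1)
    bvals <- sample(c(0, 50, 800, 1000, 12000), n, replace = TRUE)
    bvecs <- matrix(stats::rnorm(3 * n), n, 3)
    nrm <- sqrt(rowSums(bvecs^2))
    normalize <- stats::runif(n) < 0.7
    bvecs[normalize, ] <- bvecs[normalize, ] / nrm[normalize]
    bvecs[stats::runif(n) < 0.1, ] <- 0
    mism <- stats::runif(1) < 0.2
    tb <- gradient_table(bvals, bvecs)
    res <- run_checks(vol_for(if (mism) n + 1 else n), tb)
    oracle <- oracle_statuses(bvals, bvecs, n_vol_mismatch = mism)
    got <- stats::setNames(res$checks$status, res$checks$name)
    for (nm in names(oracle))
      if (nm %in% names(got))
        expect_identical(unname(got[nm]), unname(oracle[nm]),
                         label = sprintf("rep %d check %s", rep, nm))
    expect_identical(res$overall,
                     if (any(got == "fail")) "fail" else "pass")
    # order-invariance / idempotence: re-running gives identical output
    expect_identical(run_checks(vol_for(if (mism) n + 1 else n), tb), res)
  }
})

test_that("gradient extraction reads per-volume diffusion tags", {
  tree_dir <- withr::local_tempdir()
  spec <- phantom_spec("diffusion", dim = c(6, 6, 2), seed = 59)
  synth_dicom_tree(spec, tree_dir)
  scan <- group_entities(scan_directory(tree_dir))[[1]]$sessions[[1]]$scans[[1]]
  g <- extract_gradients(scan)
  expect_identical(g$status, "ok")
  expect_identical(g$table$n_volumes, 7L)
  expect_equal(g$table$bvals, c(0, rep(1000, 6)))
  expect_equal(g$table$bvecs[2:7, ], unit6(), tolerance = 1e-6)
})

test_that("scans without diffusion tags are not applicable; partial tags
           fail as incomplete", {
  plain <- .scan_from(tiny_scan_entities(4))
  expect_identical(extract_gradients(plain)$status, "absent")
  expect_s3_class(diffusion_qa(plain), "qa_not_applicable")

  ents <- tiny_scan_entities(2, n_t = 4)
  for (i in seq_along(ents)) {
    t_idx <- (dcm_instance_number(ents[[i]]) - 1) %/% 2 + 1
    if (t_idx <= 2) {  # tag only volumes 1-2 of 4
      ents[[i]] <- dcm_set(ents[[i]], "0018,9087", 1000)
      ents[[i]] <- dcm_set(ents[[i]], "0018,9089", c(1, 0, 0))
    }
  }
  partial <- .scan_from(ents)
  expect_identical(extract_gradients(partial)$status, "incomplete")
  r <- diffusion_qa(partial)
  expect_identical(r$overall, "fail")
  expect_match(r$checks$detail[1], "incomplete gradient table")
})

test_that("bval/bvec files round-trip and the XML report is well-formed", {
  tb <- gradient_table(c(0, rep(1000, 6)), rbind(c(0, 0, 0), unit6()))
  bval <- withr::local_tempfile(); bvec <- withr::local_tempfile()
  write_bval_bvec(tb, bval, bvec)
  rt <- read_bval_bvec(bval, bvec)
  expect_equal(rt$bvals, tb$bvals)
  expect_equal(rt$bvecs, tb$bvecs, tolerance = 1e-12)

  res <- run_checks(vol_for(7), tb)
  xmlf <- withr::local_tempfile(fileext = ".xml")
  write_diffusion_xml(res, xmlf)
  doc <- xml2::read_xml(xmlf)
  expect_identical(xml2::xml_attr(doc, "overall"), "pass")
  expect_length(xml2::xml_find_all(doc, "//check"), nrow(res$checks))
})
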