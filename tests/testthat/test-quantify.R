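test_that("read_ms1 keeps only MS1 spectra, sorted by time", {
  spec <- single_peptide_run(apex = 1e5, sigma_log = 0.05, seed = 3)
  sim <- ms1screen:::simulate_scans(spec)
  n <- length(sim$times)
  # interleave dummy MS2 spectra, then expect them to be discarded
  times <- as.vector(rbind(sim$times, sim$times + spec$scan_interval / 2))
  peaks <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    peaks[[2 * i - 1]] <- sim$peaks[[i]]
    peaks[[2 * i]] <- cbind(mz = c(200, 300), intensity = c(5e3, 6e3))
  }
  hdr_levels <- rep(c(1L, 2L), n)
  f_mixed <- tempfile(fileext = ".mzML")
  ms1screen:::write_ms1_mzml(times * 1, peaks, f_mixed,
                             ms_levels = hdr_levels)
  f_pure <- tempfile(fileext = ".mzML")
  generate_run(spec, f_pure)

  expect_message(mixed <- read_ms1(f_mixed), "discarded")
  pure <- read_ms1(f_pure)
  expect_identical(mixed$n_ms2_dropped, n)
  expect_identical(length(mixed$times), n)
  expect_equal(mixed$times, pure$times)
  expect_equal(mixed$index$mz, pure$index$mz)
  expect_equal(mixed$index$intensity, pure$index$intensity)
  expect_false(is.unsorted(mixed$times))
})

test_that("the ppm window is boundary inclusive", {
  for (ppm in c(5, 6)) {
    spec <- single_peptide_run(apex = 1e5, ppm_offset = ppm,
                               max_abs_ppm = 10)
    run <- read_run(spec)
    xic <- extract_xic(run, 500, ppm_tol = 5)
    if (ppm == 5) expect_gt(max(xic$intensity), 0)
    else expect_identical(max(xic$intensity), 0)
  }
})

test_that("peak status follows the scans-across-peak gate", {
  xic0 <- data.frame(time = seq(0, 30, 0.025), intensity = 0)
  pk0 <- detect_peak(xic0, 10)
  expect_identical(pk0$status, "ABSENT")
  expect_identical(pk0$scans_across_peak, 0L)

  for (k in c(7, 8)) {
    cal <- apex_for_scans(k, 0.2, 0.05, 1000, 10)
    spec <- single_peptide_run(apex = cal$apex_intensity, fwhm = 0.2,
                               scan_interval = 0.05, rt_apex = cal$rt_apex)
    run <- read_run(spec)
    pk <- detect_peak(extract_xic(run, 500), 10, noise_floor = 1000)
    expect_identical(pk$scans_across_peak, as.integer(k))
    expect_identical(pk$status, if (k >= 8) "QUANTIFIED" else "BLQ")
  }
})

test_that("increasing min_scans never upgrades a BLQ to QUANTIFIED", {
  cal <- apex_for_scans(9, 0.2, 0.05, 1000, 10)
  spec <- single_peptide_run(apex = cal$apex_intensity, fwhm = 0.2,
                             scan_interval = 0.05, rt_apex = cal$rt_apex)
  run <- read_run(spec)
  xic <- extract_xic(run, 500)
  status <- vapply(1:14, function(ms) {
    detect_peak(xic, 10, noise_floor = 1000, min_scans = ms)$status
  }, character(1))
  # QUANTIFIED for low thresholds, BLQ beyond, never back
  expect_identical(status, c(rep("QUANTIFIED", 9), rep("BLQ", 5)))
})

test_that("multiple peaks in the window resolve to the nearest apex", {
  t <- seq(0, 30, 0.05)
  y <- 1e5 * exp(-(t - 10.05)^2 / (2 * 0.03^2)) +
       1e5 * exp(-(t - 10.4)^2 / (2 * 0.03^2))
  pk <- detect_peak(data.frame(time = t, intensity = y), 10.1,
                    noise_floor = 1000)
  expect_equal(pk$rt_apex, 10.05, tolerance = 1e-9)
})

test_that("normalization uses the median quantified IS area", {
  q <- rbind(quant_row("IS_A", "QUANTIFIED", norm = 9),
             quant_row("IS_B", "QUANTIFIED", norm = 10),
             quant_row("IS_C", "QUANTIFIED", norm = 11))
  q$is_standard <- TRUE
  q$area <- c(9, 10, 11)
  expect_equal(normalization_factor(q), 10)
  expect_equal(normalization_factor(q[1, ]), 9)
  q$status <- "BLQ"
  expect_error(normalization_factor(q), "normalization is impossible")
})

test_that("scaling a run's intensities leaves normalized areas unchanged", {
  res <- study_result()
  run <- read_ms1(res$paths$mzml_high)
  lib <- res$res$library
  q1 <- quantify_run(run, lib)
  scaled <- run
  scaled$peaks <- lapply(run$peaks, function(p) {
    p[, 2] <- p[, 2] * 7; p
  })
  scaled$index$intensity <- run$index$intensity * 7
  q2 <- quantify_run(scaled, lib)
  expect_equal(q2$normalized_area, q1$normalized_area, tolerance = 1e-12)
  expect_identical(q2$status, q1$status)
  expect_equal(attr(q2, "normalization_factor"),
               7 * attr(q1, "normalization_factor"), tolerance = 1e-12)
})

test_that("cross-run pairing respects the alignment tolerance", {
  qn <- quant_row("A", "QUANTIFIED", rt_apex = 10.0, norm = 20)
  qh <- quant_row("A", "QUANTIFIED", rt_apex = 10.8, norm = 50)
  pair <- match_across_runs(qn, qh)
  expect_identical(pair$status_normal, "QUANTIFIED")
  expect_identical(pair$status_high, "QUANTIFIED")

  qh2 <- quant_row("A", "QUANTIFIED", rt_apex = 11.3, norm = 50)
  pair2 <- match_across_runs(qn, qh2)
  expect_identical(pair2$status_high, "ABSENT")   # later peak demoted
  expect_identical(pair2$status_normal, "QUANTIFIED")

  pair3 <- match_across_runs(qn, qn)
  expect_identical(pair3$rt_diff, 0)
})

test_that("fold changes implement ratio, tie and pseudo semantics", {
  pairs <- match_across_runs(
    rbind(quant_row("A", "QUANTIFIED", norm = 20),
          quant_row("B", "BLQ"),
          quant_row("C", "QUANTIFIED", norm = 5),
          quant_row("D", "BLQ"),
          quant_row("E", "ABSENT")),
    rbind(quant_row("A", "QUANTIFIED", norm = 50),
          quant_row("B", "QUANTIFIED", norm = 40),
          quant_row("C", "QUANTIFIED", norm = 5),
          quant_row("D", "BLQ"),
          quant_row("E", "QUANTIFIED", norm = 9)))
  fc <- fold_changes(pairs)
  expect_equal(fc$ratio[fc$accession == "A"], 2.5)
  expect_identical(fc$direction[fc$accession == "A"], "HIGH")
  expect_false(fc$pseudo[fc$accession == "A"])
  expect_equal(fc$ratio[fc$accession == "B"], 100)
  expect_true(fc$pseudo[fc$accession == "B"])
  expect_equal(fc$ratio[fc$accession == "C"], 1)
  expect_identical(fc$direction[fc$accession == "C"], "NORMAL")
  expect_true(fc$pseudo[fc$accession == "E"])
  expect_identical(fc$direction[fc$accession == "E"], "HIGH")
  expect_false("D" %in% fc$accession)             # both BLQ: unquantifiable
  expect_identical(attr(fc, "unquantifiable"), "D")
})

test_that("swapping the runs inverts directions and keeps ratios", {
  res <- study_result()
  qn <- res$res$quant_normal
  qh <- res$res$quant_high
  fwd <- fold_changes(match_across_runs(qn, qh))
  # feed the runs in swapped roles: HIGH data as "normal" and vice versa
  rev <- fold_changes(match_across_runs(qh, qn))
  m <- match(fwd$accession, rev$accession)
  expect_false(any(is.na(m)))
  expect_equal(fwd$ratio, rev$ratio[m], tolerance = 1e-12)
  flip <- c(NORMAL = "HIGH", HIGH = "NORMAL")
  expect_identical(unname(flip[fwd$direction]), rev$direction[m])
})

test_that("recovered fold changes track the ground truth within 15%", {
  for (seed in c(101, 202, 303)) {
    res <- study_result(seed)
    fc <- res$res$fold_changes
    tru <- res$fixture$manifest$proteins
    m <- merge(fc[!fc$pseudo, ], tru[, c("accession", "true_fc")],
               by = "accession")
    expect_identical(nrow(m), 30L)
    expect_true(all(abs(m$ratio / m$true_fc - 1) < 0.15))
    # directions agree wherever the true change is away from unity
    strong <- m$true_fc >= 1.3
    expect_identical(m$direction[strong],
                     tru$direction[match(m$accession[strong],
                                         tru$accession)])
  }
})
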