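test_that("a zero-apex peptide contributes no centroids", {
  spec <- single_peptide_run(apex = 0)
  sim <- simulate_scans(spec)
  mzs <- unlist(lapply(sim$peaks, function(p) p[, 1]))
  expect_false(any(abs(mzs - 500) < 1))   # only the three IS peptides remain
})

test_that("noiseless scan counts match the closed-form Gaussian evaluation", {
  # independently evaluate I(t) = A exp(-(t - rt)^2 / (2 sigma^2)) on the
  # scan grid and count the times with I(t) >= noise floor
  A <- 1e6; fwhm <- 0.2; delta <- 0.05; nf <- 1e3; rt <- 10
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  grid <- seq(0, 30, by = delta)
  oracle <- sum(A * exp(-(grid - rt)^2 / (2 * sigma^2)) >= nf)
  expect_equal(oracle, 13L)

  spec <- single_peptide_run(apex = A, fwhm = fwhm, scan_interval = delta,
                             noise_floor = nf, rt_apex = rt)
  sim <- simulate_scans(spec)
  n_with_centroid <- sum(vapply(sim$peaks, function(p) {
    any(abs(p[, 1] - 500) / 500 * 1e6 <= 1)
  }, logical(1)))
  expect_identical(n_with_centroid, oracle)
})

test_that("identical specs and seeds give identical peak lists", {
  spec <- single_peptide_run(apex = 1e5, seed = 99, sigma_log = 0.05)
  s1 <- simulate_scans(spec)
  s2 <- simulate_scans(spec)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".mzML"); f2 <- tempfile(fileext = ".mzML")
  generate_run(spec, f1); generate_run(spec, f2)
  r1 <- read_ms1(f1); r2 <- read_ms1(f2)
  expect_equal(r1$index, r2$index)
})

test_that("run and peptide validation names the offending field", {
  pep <- peptide_spec("PEPK", 2, 500, 10, 0.2, 1e4)
  expect_error(run_spec("r", "NORMAL", 30, 0, 1000, 1, pep, default_is()),
               "scan_interval")
  expect_error(run_spec("r", "NORMAL", 0.1, 0.025, 1000, 1, pep,
                        default_is()), "duration")
  expect_error(run_spec("r", "NORMAL", 30, 0.025, 1000, 1, pep,
                        default_is()[1:2, ]), "is_peptides")
  expect_error(run_spec("r", "NORMAL", 30, 0.025, 1000, 1,
                        peptide_spec("PEPK", 2, 500, 10, 0.2, 1e4,
                                     ppm_offset = 7),
                        default_is()), "ppm_offset")
  expect_error(run_spec("r", "NORMAL", 30, 0.025, 1000, 1,
                        peptide_spec("PEPK", 2, 500, 99, 0.2, 1e4),
                        default_is()), "rt_apex")
})

test_that("trapezoidal XIC area converges to the Gaussian integral", {
  # oracle: closed form A * sigma * sqrt(2 pi); 5% agreement required once
  # the scan interval is at most fwhm / 8
  A <- 1e6; fwhm <- 0.2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  analytic <- A * sigma * sqrt(2 * pi)
  for (delta in c(fwhm / 8, fwhm / 12)) {
    spec <- single_peptide_run(apex = A, fwhm = fwhm, scan_interval = delta,
                               noise_floor = 10)
    run <- read_run(spec)
    pk <- detect_peak(extract_xic(run, 500), rt_expected = 10,
                      noise_floor = 10)
    expect_equal(pk$status, "QUANTIFIED")
    expect_lt(abs(pk$area / analytic - 1), 0.05)
  }
})

test_that("apex_for_scans realizes exact above-noise scan counts", {
  for (k in c(1, 2, 3, 7, 8, 15)) {
    cal <- apex_for_scans(k, peak_fwhm = 0.2, scan_interval = 0.05,
                          noise_floor = 1000, rt_target = 10)
    spec <- single_peptide_run(apex = cal$apex_intensity, fwhm = 0.2,
                               scan_interval = 0.05, rt_apex = cal$rt_apex)
    sim <- simulate_scans(spec)
    n <- sum(vapply(sim$peaks, function(p) {
      any(abs(p[, 1] - 500) / 500 * 1e6 <= 1)
    }, logical(1)))
    expect_identical(n, as.integer(k))
  }
  expect_error(apex_for_scans(1, 0.2, 0.001, 1000, 10), "too wide")
})

test_that("identification tables reflect the manifest's presence patterns", {
  fx <- study_result()$fixture
  tabs <- generate_ident_tables(fx$manifest)
  prot <- fx$manifest$proteins
  hi_only <- prot$accession[prot$presence == "high-only"]
  no_only <- prot$accession[prot$presence == "normal-only"]
  expect_true(all(hi_only %in% tabs$high$accession))
  expect_false(any(hi_only %in% tabs$normal$accession))
  expect_false(any(no_only %in% tabs$high$accession))
  expect_identical(sort(unique(tabs$normal$accession)),
                   sort(prot$accession[prot$presence != "high-only"]))
})

test_that("an empty manifest yields empty tables and duplicates error", {
  empty <- fixture_manifest(
    data.frame(accession = character(), presence = character(),
               stringsAsFactors = FALSE),
    data.frame(accession = character(), sequence = character(),
               ion_score = numeric(), proteotypic = logical(),
               stringsAsFactors = FALSE),
    params = list()
  )
  tabs <- generate_ident_tables(empty)
  expect_identical(nrow(tabs$normal), 0L)
  expect_identical(nrow(tabs$high), 0L)

  fx <- study_result()$fixture
  dup <- fx$manifest$proteins
  dup <- rbind(dup, dup[1, ])
  expect_error(fixture_manifest(dup, fx$manifest$peptides,
                                fx$manifest$params), "duplicate accession")
})

test_that("the study fixture has the mandated tier structure", {
  fx <- study_result()$fixture
  counts <- expected_counts(fx$manifest)
  expect_identical(counts$candidates, 36L)
  expect_identical(counts$primary_high, 24L)
  expect_identical(counts$primary_normal, 6L)
  expect_identical(counts$secondary, 6L)
  # exactly one proteotypic peptide per protein
  per <- tapply(fx$manifest$peptides$proteotypic,
                fx$manifest$peptides$accession, sum)
  expect_true(all(per == 1))
})

test_that("changing the seed moves jitter but not the comparison itself", {
  f1 <- build_study_fixture(11)
  f2 <- build_study_fixture(22)
  expect_identical(f1$manifest$proteins, f2$manifest$proteins)
  expect_identical(f1$manifest$peptides$sequence,
                   f2$manifest$peptides$sequence)
  expect_identical(f1$manifest$peptides$mz, f2$manifest$peptides$mz)
  expect_false(identical(f1$manifest$peptides$rt_run_normal,
                         f2$manifest$peptides$rt_run_normal))
  expect_false(identical(f1$manifest$peptides$ppm_run_high,
                         f2$manifest$peptides$ppm_run_high))
})

test_that("a manifest survives the YAML round trip", {
  fx <- build_study_fixture(5)
  f <- tempfile(fileext = ".yml")
  write_manifest(fx$manifest, f)
  back <- read_manifest(f)
  expect_equal(back$proteins$accession, fx$manifest$proteins$accession)
  expect_equal(back$peptides$mz, fx$manifest$peptides$mz)
  expect_equal(back$params$noise_floor, fx$manifest$params$noise_floor)
})
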