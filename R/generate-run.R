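#' Simulate the centroid peak lists of a run
#'
#' Evaluates every peptide's Gaussian elution profile on the uniform scan
#' grid, applies seeded multiplicative log-normal intensity jitter, and drops
#' centroids that fall below the noise floor (centroid dropout). Peptides are
#' recorded at `mz * (1 + ppm_offset * 1e-6)`.
#'
#' @param spec A [run_spec()].
#' @return List with `times` (minutes, one per scan) and `peaks` (one
#'   two-column `mz`/`intensity` matrix per scan, m/z ascending).
#' @export
simulate_scans <- function(spec) {
  stopifnot(inherits(spec, "run_spec"))
  pep <- rbind(
    spec$peptides[, c("mz", "rt_apex", "peak_fwhm", "apex_intensity",
                      "ppm_offset")],
    spec$is_peptides[, c("mz", "rt_apex", "peak_fwhm", "apex_intensity",
                         "ppm_offset")]
  )
  times <- seq(0, spec$duration, by = spec$scan_interval)
  n_scan <- length(times)
  n_pep <- nrow(pep)
  mz_obs <- pep$mz * (1 + pep$ppm_offset * 1e-6)
  sigma <- pep$peak_fwhm / (2 * sqrt(2 * log(2)))

  # noise drawn as one scan x peptide matrix so the draw order is fixed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  jitter <- if (spec$sigma_log > 0 && n_pep > 0) {
    matrix(exp(stats::rnorm(n_scan * n_pep, 0, spec$sigma_log)),
           nrow = n_scan, ncol = n_pep)
  } else {
    matrix(1, nrow = n_scan, ncol = n_pep)
  }

  peaks <- vector("list", n_scan)
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  for (i in seq_len(n_scan)) {
    t <- times[i]
    inten <- pep$apex_intensity *
      exp(-(t - pep$rt_apex)^2 / (2 * sigma^2)) *
      jitter[i, ] * spec$global_intensity_scale
    keep <- which(inten >= spec$noise_floor & pep$apex_intensity > 0)
    if (length(keep) == 0) {
      peaks[[i]] <- empty
    } else {
      ord <- keep[order(mz_obs[keep])]
      peaks[[i]] <- cbind(mz = mz_obs[ord], intensity = inten[ord])
    }
  }
  list(times = times, peaks = peaks)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated run to mzML
#'
#' Simulates the run with [simulate_scans()] and writes one centroid MS1
#' spectrum per scan to an mzML file (retention times stored in seconds, as
#' the format prescribes). Identical specs and seeds give identical peak
#' lists.
#'
#' @param spec A [run_spec()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
generate_run <- function(spec, path) {
  sim <- simulate_scans(spec)
  write_ms1_mzml(sim$times, sim$peaks, path)
  invisible(path)
}

# times in minutes; peaks a list of mz/intensity matrices; ms_levels allows
# interleaving dummy fragment spectra when emulating merged acquisitions
write_ms1_mzml <- function(times, peaks, path, ms_levels = NULL) {
  n <- length(times)
  stopifnot(length(peaks) == n)
  if (is.null(ms_levels)) ms_levels <- rep(1L, n)
  counts <- vapply(peaks, nrow, integer(1))
  tic <- vapply(peaks, function(p) sum(p[, 2]), numeric(1))
  bp <- function(p, col) if (nrow(p)) p[which.max(p[, 2]), col] else 0
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(ms_levels), polarity = rep(1L, n),
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = times * 60,
    basePeakMZ = vapply(peaks, bp, numeric(1), col = 1L),
    basePeakIntensity = vapply(peaks, bp, numeric(1), col = 2L),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(peaks, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(peaks, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = ifelse(ms_levels > 1L, pmax(seq_len(n) - 1L, 1L), 0L),
    precursorMZ = ifelse(ms_levels > 1L, 500, 0),
    precursorCharge = ifelse(ms_levels > 1L, 2L, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(peaks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
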