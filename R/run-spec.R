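#' Build a table of simulated peptide elution profiles
#'
#' Each row describes one peptide ion as it will appear in a simulated MS1
#' run: a Gaussian elution profile of given apex intensity and width, recorded
#' at a fixed m/z with a per-peptide calibration offset in ppm.
#'
#' @param sequence Amino-acid sequence (character).
#' @param charge Integer charge state, >= 1.
#' @param mz Theoretical m/z in Th, > 0.
#' @param rt_apex Elution apex in minutes.
#' @param peak_fwhm Chromatographic full width at half maximum, minutes, > 0.
#' @param apex_intensity Apex intensity in arbitrary counts (0 allowed: the
#'   peptide then contributes no centroids).
#' @param n_scans_above_noise Target number of scans above the noise floor
#'   (ground-truth annotation; informative only).
#' @param ppm_offset Observed-vs-theoretical mass error in parts per million.
#' @param ion_score Search-engine ion score to report in identification
#'   tables.
#' @return A `data.frame` with one row per peptide.
#' @export
peptide_spec <- function(sequence, charge, mz, rt_apex, peak_fwhm,
                         apex_intensity, n_scans_above_noise = NA_real_,
                         ppm_offset = 0, ion_score = NA_real_) {
  df <- data.frame(
    sequence = as.character(sequence),
    charge = as.integer(charge),
    mz = as.numeric(mz),
    rt_apex = as.numeric(rt_apex),
    peak_fwhm = as.numeric(peak_fwhm),
    apex_intensity = as.numeric(apex_intensity),
    n_scans_above_noise = as.numeric(n_scans_above_noise),
    ppm_offset = as.numeric(ppm_offset),
    ion_score = as.numeric(ion_score),
    stringsAsFactors = FALSE
  )
  df
}

validate_peptides <- function(pep, duration, max_abs_ppm = 5,
                              what = "peptides") {
  if (!is.data.frame(pep)) stop(sprintf("'%s' must be a data.frame", what))
  need <- c("sequence", "charge", "mz", "rt_apex", "peak_fwhm",
            "apex_intensity", "ppm_offset")
  miss <- setdiff(need, names(pep))
  if (length(miss))
    stop(sprintf("'%s' is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  if (nrow(pep) == 0) return(invisible(pep))
  if (any(pep$charge < 1)) stop(sprintf("'%s': charge must be >= 1", what))
  if (any(pep$mz <= 0)) stop(sprintf("'%s': mz must be > 0", what))
  if (any(pep$peak_fwhm <= 0))
    stop(sprintf("'%s': peak_fwhm must be > 0", what))
  if (any(pep$apex_intensity < 0))
    stop(sprintf("'%s': apex_intensity must be >= 0", what))
  if (any(pep$rt_apex < 0 | pep$rt_apex > duration))
    stop(sprintf("'%s': rt_apex must lie within the run duration", what))
  if (any(abs(pep$ppm_offset) > max_abs_ppm))
    stop(sprintf("'%s': |ppm_offset| must be <= %g ppm", what, max_abs_ppm))
  invisible(pep)
}

#' Specify one synthetic LC-MS1 run
#'
#' Collects everything needed to simulate a centroid MS1 acquisition: a
#' uniform scan grid, a hard noise floor below which centroids drop out,
#' multiplicative log-normal intensity jitter, the target peptides, and the
#' spiked internal-standard (IS) peptides used downstream for between-run
#' normalization.
#'
#' @param run_id Label for the run.
#' @param group Sample group, `"NORMAL"` or `"HIGH"`.
#' @param duration Run length in minutes.
#' @param scan_interval MS1 cycle time in minutes; the run must hold at least
#'   10 scans.
#' @param noise_floor Intensity (counts) below which centroids are dropped.
#' @param seed Integer seed; fully determines the simulated peak lists.
#' @param peptides,is_peptides Peptide tables from [peptide_spec()]. At least
#'   3 IS peptides are required; across the two runs of a comparison they must
#'   be identical in sequence, charge and m/z.
#' @param global_intensity_scale Multiplier applied to every intensity
#'   (emulates between-run instrument response drift), > 0.
#' @param sigma_log Standard deviation of the log-normal multiplicative noise
#'   on each centroid intensity; 0 gives a noiseless run.
#' @param max_abs_ppm Bound on each peptide's |ppm_offset|.
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(run_id, group = c("NORMAL", "HIGH"), duration,
                     scan_interval, noise_floor, seed, peptides,
                     is_peptides, global_intensity_scale = 1,
                     sigma_log = 0.05, max_abs_ppm = 5) {
  group <- match.arg(group)
  if (!is.numeric(scan_interval) || scan_interval <= 0)
    stop("'scan_interval' must be > 0")
  if (!is.numeric(duration) || duration / scan_interval < 10)
    stop("'duration' must allow at least 10 scans")
  if (!is.numeric(noise_floor) || noise_floor < 0)
    stop("'noise_floor' must be >= 0")
  if (!is.numeric(global_intensity_scale) || global_intensity_scale <= 0)
    stop("'global_intensity_scale' must be > 0")
  if (!is.data.frame(is_peptides) || nrow(is_peptides) < 3)
    stop("'is_peptides' must contain at least 3 internal-standard peptides")
  validate_peptides(peptides, duration, max_abs_ppm, "peptides")
  validate_peptides(is_peptides, duration, max_abs_ppm, "is_peptides")
  structure(list(
    run_id = as.character(run_id), group = group,
    duration = as.numeric(duration),
    scan_interval = as.numeric(scan_interval),
    noise_floor = as.numeric(noise_floor), seed = as.integer(seed),
    peptides = peptides, is_peptides = is_peptides,
    global_intensity_scale = as.numeric(global_intensity_scale),
    sigma_log = as.numeric(sigma_log)
  ), class = "run_spec")
}

#' @export
print.run_spec <- function(x, ...) {
  cat(sprintf("<run_spec> %s [%s]: %.1f min @ %.3f min/scan, %d targets + %d IS\n",
              x$run_id, x$group, x$duration, x$scan_interval,
              nrow(x$peptides), nrow(x$is_peptides)))
  invisible(x)
}

#' Apex intensity yielding an exact number of above-noise scans
#'
#' Solves the noiseless Gaussian elution model for the apex intensity that
#' places exactly `n_scans` scan times at or above the noise floor, snapping
#' the apex onto the scan grid (odd counts) or halfway between two scans
#' (even counts). Used to build boundary-probing runs for the
#' scans-across-peak reliability gate.
#'
#' @param n_scans Desired number of scans with intensity >= `noise_floor`.
#' @param peak_fwhm,scan_interval,noise_floor As in [run_spec()].
#' @param rt_target Approximate apex time, minutes; snapped to the grid.
#' @param margin Safety factor (> 1) by which the outermost retained scan
#'   clears the noise floor.
#' @return List with `apex_intensity` and the snapped `rt_apex`.
#' @export
apex_for_scans <- function(n_scans, peak_fwhm, scan_interval, noise_floor,
                           rt_target, margin = 1.02) {
  stopifnot(n_scans >= 1, margin > 1)
  sigma <- peak_fwhm / (2 * sqrt(2 * log(2)))
  # distance of the outermost kept / first dropped scan from the apex
  if (n_scans %% 2 == 1) {
    rt_apex <- round(rt_target / scan_interval) * scan_interval
    d_keep <- ((n_scans - 1) / 2) * scan_interval
    d_drop <- ((n_scans + 1) / 2) * scan_interval
  } else {
    rt_apex <- (floor(rt_target / scan_interval) + 0.5) * scan_interval
    d_keep <- (n_scans / 2 - 0.5) * scan_interval
    d_drop <- (n_scans / 2 + 0.5) * scan_interval
  }
  gap <- exp((d_drop^2 - d_keep^2) / (2 * sigma^2))
  if (margin >= gap)
    stop(sprintf(paste0("cannot realize exactly %d scans: the peak is too ",
                        "wide relative to the scan interval (needed margin < %.4f)"),
                 n_scans, gap))
  apex <- noise_floor * margin * exp(d_keep^2 / (2 * sigma^2))
  list(apex_intensity = apex, rt_apex = rt_apex)
}
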