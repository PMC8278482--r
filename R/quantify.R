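#' Read the MS1 scans of an mzML run
#'
#' Opens an mzML file, keeps only MS level 1 spectra (data-dependent MS2
#' scans interleaved in the file are discarded and counted), sorts scans by
#' retention time, and builds a flat centroid index for fast extracted-ion-
#' chromatogram queries.
#'
#' @param path Path to an mzML file.
#' @return An object of class `ms1_run`: `times` (minutes), `peaks` (list of
#'   centroid matrices), `n_ms2_dropped`, `run_id`.
#' @export
read_ms1 <- function(path) {
  if (!file.exists(path)) stop("cannot read mzML file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  is_ms1 <- hd$msLevel == 1L
  if (!any(is_ms1)) stop("no MS1 spectra in ", path)
  n_ms2 <- sum(!is_ms1)
  if (n_ms2 > 0)
    message(sprintf("%s: discarded %d non-MS1 spectra", basename(path),
                    n_ms2))
  idx <- which(is_ms1)[order(hd$retentionTime[is_ms1])]
  peaks <- lapply(idx, function(i) {
    p <- mzR::peaks(fh, i)
    colnames(p) <- c("mz", "intensity")
    p
  })
  times <- hd$retentionTime[idx] / 60
  # flat, m/z-sorted centroid index across scans
  ns <- vapply(peaks, nrow, integer(1))
  all_mz <- unlist(lapply(peaks, function(p) p[, 1]), use.names = FALSE)
  all_int <- unlist(lapply(peaks, function(p) p[, 2]), use.names = FALSE)
  scan_of <- rep(seq_along(peaks), ns)
  o <- order(all_mz)
  structure(list(
    times = times, peaks = peaks, n_ms2_dropped = n_ms2,
    run_id = sub("\\.mzML$", "", basename(path), ignore.case = TRUE),
    index = list(mz = all_mz[o], intensity = all_int[o], scan = scan_of[o])
  ), class = "ms1_run")
}

#' @export
print.ms1_run <- function(x, ...) {
  cat(sprintf("<ms1_run> %s: %d MS1 scans over %.1f min (%d MS2 dropped)\n",
              x$run_id, length(x$times), diff(range(x$times)),
              x$n_ms2_dropped))
  invisible(x)
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' Per scan, sums the intensities of all centroids whose mass error relative
#' to the target, `|mz - mz_target| / mz_target * 1e6`, is at most `ppm_tol`
#' (boundary inclusive); scans with no matching centroid contribute zero.
#'
#' @param run An [read_ms1()] object.
#' @param mz_target Target m/z in Th.
#' @param ppm_tol Mass tolerance in ppm, > 0.
#' @return A `data.frame` with ascending `time` (minutes) and `intensity`.
#' @export
extract_xic <- function(run, mz_target, ppm_tol = 5) {
  stopifnot(inherits(run, "ms1_run"), ppm_tol > 0, mz_target > 0)
  lo <- mz_target * (1 - ppm_tol * 1e-6)
  hi <- mz_target * (1 + ppm_tol * 1e-6)
  ix <- run$index
  from <- findInterval(lo, ix$mz, left.open = TRUE) + 1L
  to <- findInterval(hi, ix$mz)
  intensity <- numeric(length(run$times))
  if (to >= from) {
    sel <- from:to
    agg <- rowsum(ix$intensity[sel], ix$scan[sel])
    intensity[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(time = run$times, intensity = intensity)
}

#' Detect and integrate a targeted chromatographic peak
#'
#' Looks for the library entry's peak inside the retention-time window
#' `rt_expected +/- rt_tol` (inclusive): the apex is the above-noise scan of
#' maximal intensity in the window (ties resolved to the scan nearest
#' `rt_expected`), the peak bounds are extended from the apex in both
#' directions over contiguous above-noise scans, `scans_across_peak` counts
#' the scans within the bounds, and the area is the trapezoidal integral of
#' the intensity trace over the bounds.
#'
#' Status follows the scans-across-peak reliability gate: `QUANTIFIED` with
#' at least `min_scans` scans, `BLQ` (below limit of quantification, no area
#' reported) with 1 to `min_scans - 1` scans, `ABSENT` when no above-noise
#' scan lies in the window.
#'
#' @param xic An XIC from [extract_xic()].
#' @param rt_expected Expected retention time, minutes.
#' @param rt_tol RT tolerance for library interrogation, minutes.
#' @param noise_floor Intensity threshold separating signal from noise;
#'   `NULL` uses the 10th percentile of the XIC's nonzero intensities.
#' @param min_scans Minimum scans-across-peak for reliable quantification.
#' @return One-row `data.frame`: `status`, `rt_apex`, `scans_across_peak`,
#'   `area` (counts x min, `QUANTIFIED` only, else NA).
#' @export
detect_peak <- function(xic, rt_expected, rt_tol = 0.5, noise_floor = NULL,
                        min_scans = 8) {
  stopifnot(rt_tol > 0, min_scans >= 1)
  t <- xic$time; y <- xic$intensity
  absent <- data.frame(status = "ABSENT", rt_apex = NA_real_,
                       scans_across_peak = 0L, area = NA_real_,
                       stringsAsFactors = FALSE)
  if (length(y) == 0 || all(y <= 0)) return(absent)
  nf <- if (is.null(noise_floor)) {
    as.numeric(stats::quantile(y[y > 0], 0.10, names = FALSE))
  } else noise_floor

  in_win <- which(abs(t - rt_expected) <= rt_tol & y > nf)
  if (length(in_win) == 0) return(absent)
  cand <- in_win[y[in_win] == max(y[in_win])]
  apex <- cand[which.min(abs(t[cand] - rt_expected))]

  left <- apex
  while (left > 1 && y[left - 1] > nf) left <- left - 1
  right <- apex
  while (right < length(y) && y[right + 1] > nf) right <- right + 1
  scans <- as.integer(right - left + 1)
  status <- if (scans >= min_scans) "QUANTIFIED" else "BLQ"
  area <- if (status == "QUANTIFIED" && scans >= 2) {
    pracma::trapz(t[left:right], y[left:right])
  } else NA_real_
  data.frame(status = status, rt_apex = t[apex],
             scans_across_peak = scans, area = area,
             stringsAsFactors = FALSE)
}

#' Internal-standard normalization factor of a run
#'
#' The factor is the median peak area of the run's reliably quantified
#' internal-standard entries. Dividing every target area by it removes
#' between-run differences in injected amount and instrument response.
#'
#' @param quant A per-run quantification table from [quantify_run()].
#' @return The factor (positive scalar).
#' @export
normalization_factor <- function(quant) {
  is_q <- quant$is_standard & quant$status == "QUANTIFIED"
  if (!any(is_q))
    stop("no internal-standard peak could be reliably quantified in run '",
         quant$run_id[1], "': normalization is impossible; re-acquire or ",
         "regenerate the run")
  stats::median(quant$area[is_q])
}

#' Quantify a targeted library against one run
#'
#' Extracts an XIC for every library entry, detects and gates its peak, and
#' attaches internal-standard-normalized areas.
#'
#' @param run An [read_ms1()] object.
#' @param library_tbl Library from [build_library()].
#' @param ppm_tol,rt_tol,min_scans,noise_floor Passed to [extract_xic()] and
#'   [detect_peak()].
#' @param normalize Attach `normalized_area` (requires at least one
#'   quantified IS entry).
#' @return A `data.frame`, one row per library entry: `run_id, accession,
#'   tier, is_standard, status, rt_apex, scans_across_peak, area,
#'   normalized_area`.
#' @export
quantify_run <- function(run, library_tbl, ppm_tol = 5, rt_tol = 0.5,
                         min_scans = 8, noise_floor = NULL,
                         normalize = TRUE) {
  rows <- lapply(seq_len(nrow(library_tbl)), function(i) {
    e <- library_tbl[i, ]
    xic <- extract_xic(run, e$mz_target, ppm_tol)
    pk <- detect_peak(xic, e$rt_expected, rt_tol, noise_floor, min_scans)
    cbind(data.frame(run_id = run$run_id, accession = e$accession,
                     tier = e$tier, is_standard = e$is_standard,
                     stringsAsFactors = FALSE), pk)
  })
  quant <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run_id = character(), accession = character(),
               tier = character(), is_standard = logical(),
               status = character(), rt_apex = numeric(),
               scans_across_peak = integer(), area = numeric(),
               stringsAsFactors = FALSE)
  if (normalize && nrow(quant)) {
    f <- normalization_factor(quant)
    quant$normalized_area <- quant$area / f
    attr(quant, "normalization_factor") <- f
  } else {
    quant$normalized_area <- NA_real_
  }
  rownames(quant) <- NULL
  quant
}

#' Pair target quantifications across the two runs
#'
#' For each non-IS library accession, pairs the NORMAL and HIGH
#' quantifications. When both runs detected a peak (`QUANTIFIED` or `BLQ`)
#' the pair is aligned only if the apexes differ by at most `align_tol`
#' minutes (inclusive); otherwise the later-eluting peak is treated as
#' `ABSENT` for pairing.
#'
#' @param quant_normal,quant_high Tables from [quantify_run()] against the
#'   same library.
#' @param align_tol RT tolerance for chromatogram alignment, minutes.
#' @return A `data.frame`, one row per accession: statuses, normalized
#'   areas, apex RTs per group and their difference.
#' @export
match_across_runs <- function(quant_normal, quant_high, align_tol = 1.0) {
  stopifnot(align_tol > 0)
  qn <- quant_normal[!quant_normal$is_standard, , drop = FALSE]
  qh <- quant_high[!quant_high$is_standard, , drop = FALSE]
  acc <- union(qn$accession, qh$accession)
  i_n <- match(acc, qn$accession); i_h <- match(acc, qh$accession)
  pick <- function(tab, i, col, default) {
    v <- rep(default, length(i)); ok <- !is.na(i)
    v[ok] <- tab[[col]][i[ok]]; v
  }
  out <- data.frame(
    accession = acc,
    tier = ifelse(is.na(i_n), pick(qh, i_h, "tier", NA_character_),
                  pick(qn, i_n, "tier", NA_character_)),
    status_normal = pick(qn, i_n, "status", "ABSENT"),
    status_high = pick(qh, i_h, "status", "ABSENT"),
    rt_normal = pick(qn, i_n, "rt_apex", NA_real_),
    rt_high = pick(qh, i_h, "rt_apex", NA_real_),
    normalized_normal = pick(qn, i_n, "normalized_area", NA_real_),
    normalized_high = pick(qh, i_h, "normalized_area", NA_real_),
    stringsAsFactors = FALSE
  )
  both <- out$status_normal != "ABSENT" & out$status_high != "ABSENT"
  out$rt_diff <- ifelse(both, abs(out$rt_normal - out$rt_high), NA_real_)
  misaligned <- both & out$rt_diff > align_tol
  if (any(misaligned)) {
    later_high <- out$rt_high >= out$rt_normal
    demote_high <- misaligned & later_high
    demote_normal <- misaligned & !later_high
    out$status_high[demote_high] <- "ABSENT"
    out$normalized_high[demote_high] <- NA_real_
    out$status_normal[demote_normal] <- "ABSENT"
    out$normalized_normal[demote_normal] <- NA_real_
  }
  out[order(out$accession), , drop = FALSE]
}

#' Fold changes with BLQ / absent pseudo-ratio semantics
#'
#' For pairs quantified in both runs the ratio is
#' `max(aN/aH, aH/aN)` on normalized areas, with the direction set to the
#' larger side (ties to NORMAL). A pair that is reliably quantified in one
#' run but `BLQ` or `ABSENT` in the other receives the pseudo-quantitative
#' fold change (`pseudo_value`, default 100) in the quantified group's
#' direction — scans-across-peak correlates with abundance, so a quantified
#' vs non-quantifiable asymmetry marks a large but not precisely measurable
#' change. Pairs with no reliably quantified side yield no fold change; they
#' are recorded in the `"unquantifiable"` attribute.
#'
#' @param pairs Table from [match_across_runs()].
#' @param pseudo_value Pseudo fold change for asymmetric BLQ/absent pairs.
#' @return A `data.frame`: `accession, tier, ratio, direction, pseudo,
#'   status_normal, status_high`.
#' @export
fold_changes <- function(pairs, pseudo_value = 100.0) {
  qn <- pairs$status_normal == "QUANTIFIED"
  qh <- pairs$status_high == "QUANTIFIED"
  emit <- qn | qh
  p <- pairs[emit, , drop = FALSE]
  qn <- qn[emit]; qh <- qh[emit]
  ratio <- numeric(nrow(p)); direction <- character(nrow(p))
  pseudo <- logical(nrow(p))
  both <- qn & qh
  if (any(both)) {
    a_n <- p$normalized_normal[both]; a_h <- p$normalized_high[both]
    ratio[both] <- pmax(a_n / a_h, a_h / a_n)
    direction[both] <- ifelse(a_h > a_n, "HIGH", "NORMAL")
    pseudo[both] <- FALSE
  }
  one <- !both
  if (any(one)) {
    ratio[one] <- pseudo_value
    direction[one] <- ifelse(qh[one], "HIGH", "NORMAL")
    pseudo[one] <- TRUE
  }
  out <- data.frame(accession = p$accession, tier = p$tier, ratio = ratio,
                    direction = direction, pseudo = pseudo,
                    status_normal = p$status_normal,
                    status_high = p$status_high, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unquantifiable") <- pairs$accession[!emit]
  out
}
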