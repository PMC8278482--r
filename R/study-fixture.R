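#' Build the packaged study-like fixture
#'
#' Constructs a two-group comparison with known ground truth whose structure
#' mirrors a pooled normal vs high-pHu sarcoplasmic-proteome screen:
#'
#' * 24 high-only and 6 normal-only identifications (primary candidate tier);
#' * 6 shared identifications with a protein-score ratio of at least 2
#'   (secondary tier), for 36 candidates in total;
#' * 35 shared identifications with score ratios below 1.5 (non-candidates),
#'   2 proteins whose peptides all fall below the ion-score acceptance
#'   threshold, and 5 spiked internal-standard (IS) proteins;
#' * true abundances such that targeted MS1 quantification certifies exactly
#'   26 of the 36 candidates at a 2-fold change: 2 candidates with no MS1
#'   signal at all in the normal run, 4 detected below the limit of
#'   quantification (1-3 scans above noise) in the normal run, and 20
#'   quantified in both runs with true fold changes of 2.5-50; the other 10
#'   candidates have true fold changes of at most 1.8.
#'
#' The tier structure, true fold changes, sequences and m/z targets are fixed
#' (they define the comparison); `seed` drives only retention-time and ppm
#' jitter and the centroid intensity noise of the runs.
#'
#' @param seed Integer seed.
#' @return List with elements `manifest` (a [fixture_manifest()]), `runs`
#'   (two [run_spec()] objects, `normal` and `high`) and `annotation` (an
#'   accession-to-function-class lookup table).
#' @export
build_study_fixture <- function(seed = 1L) {
  prot <- study_protein_table()
  pp <- list(seed = as.integer(seed), duration = 30, scan_interval = 0.025,
             noise_floor = 1000, sigma_log = 0.05, peak_fwhm = 0.2)

  # structural randomness (sequences, m/z, extra-peptide placement) is tied
  # to a fixed internal seed so the comparison itself is seed-invariant
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(104729L)
  pep <- study_peptide_table(prot)
  n_run <- sum(pep$in_run)
  mz_slots <- sample(seq(420, 1180, length.out = n_run))
  rt_slots <- sample(seq(3, 27, length.out = n_run))
  pep$mz[pep$in_run] <- mz_slots
  pep$mz[!pep$in_run] <- round(stats::runif(sum(!pep$in_run), 400, 1200), 3)
  rt_base <- numeric(nrow(pep))
  rt_base[pep$in_run] <- rt_slots
  rt_base[!pep$in_run] <- stats::runif(sum(!pep$in_run), 2, 28)

  # per-study jitter under the user's seed
  set.seed(as.integer(seed))
  n <- nrow(pep)
  jit <- function(a) stats::runif(n, -a, a)
  pep$rt_ident_normal <- round(rt_base + jit(0.1), 4)
  pep$rt_ident_high <- round(rt_base + jit(0.1), 4)
  pep$ppm_ident_normal <- round(jit(2), 3)
  pep$ppm_ident_high <- round(jit(2), 3)
  pep$rt_run_normal <- rt_base + jit(0.1)
  pep$rt_run_high <- rt_base + jit(0.1)
  pep$ppm_run_normal <- round(jit(2), 3)
  pep$ppm_run_high <- round(jit(2), 3)
  run_seeds <- sample.int(1e7, 2)

  # true abundances from the protein table's quantification class
  pep$apex_normal <- 0
  pep$apex_high <- 0
  base_apex <- 3e4   # 30x the noise floor: quantifiable targets sit well
                     # clear of the LOQ, so tail truncation at the noise
                     # floor stays within a few percent of the peak area
  is_apex <- c(2e4, 3e4, 5e4, 6.5e4, 8e4)
  is_i <- 0
  for (i in which(pep$in_run)) {
    acc <- pep$accession[i]
    p <- prot[match(acc, prot$accession), ]
    if (grepl("^IS_", acc)) {
      is_i <- is_i + 1
      pep$apex_normal[i] <- pep$apex_high[i] <- is_apex[is_i]
    } else if (p$quant_class == "quantified") {
      lo <- base_apex
      hi <- base_apex * p$true_fc
      if (p$direction == "HIGH") {
        pep$apex_normal[i] <- lo; pep$apex_high[i] <- hi
      } else {
        pep$apex_normal[i] <- hi; pep$apex_high[i] <- lo
      }
    } else if (p$quant_class == "blq_normal") {
      cal <- apex_for_scans(3, pp$peak_fwhm, pp$scan_interval,
                            pp$noise_floor, pep$rt_run_normal[i],
                            margin = 1.08)
      pep$apex_normal[i] <- cal$apex_intensity
      pep$rt_run_normal[i] <- cal$rt_apex
      pep$apex_high[i] <- 3e4
    } else if (p$quant_class == "absent_normal") {
      pep$apex_normal[i] <- 0
      pep$apex_high[i] <- 5e4
    }
  }

  # nominal scans above noise on the noiseless grid (ground truth)
  grid <- seq(0, pp$duration, by = pp$scan_interval)
  sigma <- pp$peak_fwhm / (2 * sqrt(2 * log(2)))
  nsc <- function(apex, rt) {
    if (apex <= 0) return(0L)
    sum(apex * exp(-(grid - rt)^2 / (2 * sigma^2)) >= pp$noise_floor)
  }
  pep$n_scans_normal <- NA_integer_
  pep$n_scans_high <- NA_integer_
  for (i in which(pep$in_run)) {
    pep$n_scans_normal[i] <- nsc(pep$apex_normal[i], pep$rt_run_normal[i])
    pep$n_scans_high[i] <- nsc(pep$apex_high[i], pep$rt_run_high[i])
  }

  m <- fixture_manifest(prot, pep, pp)
  runs <- run_specs_from_manifest(m, run_seeds)
  ann <- prot[prot$function_class != "", c("accession", "function_class")]
  rownames(ann) <- NULL
  list(manifest = m, runs = runs, annotation = ann)
}

# the fixed composition of the study-like comparison
study_protein_table <- function() {
  fc_hi <- c(12, 2.5, 3, 4, 5, 6, 8, 10, 15, 20, 25, 30, 50)
  fc_hi_low <- c(1.0, 1.2, 1.3, 1.5, 1.6, 1.8)
  hi_acc <- c("DBI", "ACAA2", "PRDX6", "HQ04", "HQ05", "CRYAB",
              sprintf("HQ%02d", 7:24))
  hi <- data.frame(
    accession = hi_acc, presence = "high-only",
    quant_class = c("absent_normal", "absent_normal", rep("blq_normal", 3),
                    rep("quantified", 19)),
    true_fc = c(NA, NA, NA, NA, NA, fc_hi, fc_hi_low),
    direction = "HIGH", stringsAsFactors = FALSE
  )
  no <- data.frame(
    accession = sprintf("NQ%02d", 1:6), presence = "normal-only",
    quant_class = "quantified",
    true_fc = c(2.5, 4, 8, 20, 1.4, 1.7),
    direction = "NORMAL", stringsAsFactors = FALSE
  )
  sec <- data.frame(
    accession = c("HSPA8", "AHNAK", "HSPB1", "LDHA", "PGM1", "TF"),
    presence = "both",
    quant_class = c("blq_normal", rep("quantified", 5)),
    true_fc = c(NA, 3, 5, 2.5, 1.6, 1.3),
    direction = c("HIGH", "HIGH", "HIGH", "HIGH", "HIGH", "NORMAL"),
    stringsAsFactors = FALSE
  )
  shared <- data.frame(
    accession = sprintf("SH%02d", 1:35), presence = "both",
    quant_class = "none", true_fc = NA_real_, direction = NA_character_,
    stringsAsFactors = FALSE
  )
  flt <- data.frame(
    accession = c("FLT01", "FLT02"), presence = "both",
    quant_class = "none", true_fc = NA_real_, direction = NA_character_,
    stringsAsFactors = FALSE
  )
  is <- data.frame(
    accession = sprintf("IS_ALM%02d", 1:5), presence = "both",
    quant_class = "is", true_fc = NA_real_, direction = NA_character_,
    stringsAsFactors = FALSE
  )
  p <- rbind(hi, no, sec, shared, flt, is)

  # per-group protein scores: primary candidates score 22-115 in their group
  # (absent elsewhere); secondary pairs have ratio >= 2 toward `direction`;
  # shared non-candidates stay below a 1.5-fold score ratio
  p$score_normal <- NA_real_
  p$score_high <- NA_real_
  p$score_high[p$presence == "high-only"] <- round(seq(22, 115,
                                                       length.out = 24))
  p$score_normal[p$presence == "normal-only"] <- round(seq(25, 110,
                                                           length.out = 6))
  sec_hiscore <- c(315, 180, 140, 200, 160, 150)
  sec_ratio <- c(3.2, 2.5, 2.2, 2.0, 2.4, 2.8)
  si <- match(sec$accession, p$accession)
  for (k in seq_along(si)) {
    hi_s <- sec_hiscore[k]
    lo_s <- hi_s / sec_ratio[k]
    if (p$direction[si[k]] == "HIGH") {
      p$score_high[si[k]] <- hi_s; p$score_normal[si[k]] <- lo_s
    } else {
      p$score_normal[si[k]] <- hi_s; p$score_high[si[k]] <- lo_s
    }
  }
  shi <- grep("^SH", p$accession)
  base <- round(seq(60, 400, length.out = length(shi)))
  rr <- rep(c(1.0, 1.1, 1.2, 1.3, 1.45), length.out = length(shi))
  hi_side <- rep(c(TRUE, FALSE), length.out = length(shi))
  p$score_high[shi] <- ifelse(hi_side, base, round(base / rr, 1))
  p$score_normal[shi] <- ifelse(hi_side, round(base / rr, 1), base)
  fli <- grep("^FLT", p$accession)
  p$score_high[fli] <- c(21, 23)
  p$score_normal[fli] <- c(22, 20)
  isi <- grep("^IS_", p$accession)
  p$score_high[isi] <- p$score_normal[isi] <- seq(80, 120, length.out = 5)

  classes <- c("metabolic", "chaperone/stress", "structural-contractile",
               "transport", "other")
  p$function_class <- ""
  named <- c(DBI = "metabolic", ACAA2 = "metabolic", PRDX6 = "chaperone/stress",
             CRYAB = "chaperone/stress", HSPA8 = "chaperone/stress",
             HSPB1 = "chaperone/stress", AHNAK = "structural-contractile",
             LDHA = "metabolic", PGM1 = "metabolic", TF = "transport")
  p$function_class[match(names(named), p$accession)] <- unname(named)
  rest <- p$function_class == "" & (p$presence != "both" |
                                      p$accession %in% sec$accession)
  p$function_class[rest] <- rep(classes, length.out = sum(rest))
  rownames(p) <- NULL
  p
}

# peptide evidence: one proteotypic (max ion score, in-run for MS1 targets)
# peptide per protein, plus extra identification-only peptides on a fixed
# cadence, some below the acceptance threshold
study_peptide_table <- function(prot) {
  is_target <- prot$quant_class != "none"
  rows <- list()
  for (i in seq_len(nrow(prot))) {
    acc <- prot$accession[i]
    flt <- grepl("^FLT", acc)
    score_ref <- max(prot$score_normal[i], prot$score_high[i], na.rm = TRUE)
    top <- if (flt) 15 else max(20, round(score_ref * 0.6))
    rows[[length(rows) + 1]] <- data.frame(
      accession = acc, sequence = random_tryptic(1), charge = sample(2:3, 1),
      ion_score = top, proteotypic = TRUE, in_run = is_target[i] && !flt,
      stringsAsFactors = FALSE
    )
    if (!flt && i %% 3 == 0)   # a sub-threshold match that filtering removes
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, sequence = random_tryptic(1), charge = 2L,
        ion_score = 15, proteotypic = FALSE, in_run = FALSE,
        stringsAsFactors = FALSE
      )
    if (!flt && i %% 5 == 0)   # a second accepted match, below the top score
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, sequence = random_tryptic(1), charge = 2L,
        ion_score = max(19, top - 10), proteotypic = FALSE, in_run = FALSE,
        stringsAsFactors = FALSE
      )
    if (flt)
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, sequence = random_tryptic(1), charge = 2L,
        ion_score = 12, proteotypic = FALSE, in_run = FALSE,
        stringsAsFactors = FALSE
      )
  }
  pep <- do.call(rbind, rows)
  pep$mz <- NA_real_
  pep
}

random_tryptic <- function(n, min_len = 8, max_len = 16) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Expected tier and certification counts of a manifest
#'
#' Tallies, from ground truth alone, what triage and certification should
#' find: candidate tiers from presence patterns and score ratios, and the
#' certified set from quantification classes and true fold changes.
#'
#' @param m A [fixture_manifest()].
#' @param ratio_threshold,fc_threshold Thresholds matching the pipeline.
#' @return Named list of counts.
#' @export
expected_counts <- function(m, ratio_threshold = 2, fc_threshold = 2) {
  p <- m$proteins
  p <- p[!grepl("^IS_", p$accession), ]
  # proteins whose every peptide is below the acceptance score never reach
  # triage
  sp <- split(m$peptides$ion_score, m$peptides$accession)
  kept <- names(sp)[vapply(sp, function(s) any(s >= 19), logical(1))]
  p <- p[p$accession %in% kept, ]
  excl <- p$presence != "both"
  ratio <- pmax(p$score_normal / p$score_high, p$score_high / p$score_normal)
  sec <- !excl & ratio >= ratio_threshold
  pseudo <- p$quant_class %in% c("blq_normal", "blq_high", "absent_normal",
                                 "absent_high")
  cert <- (excl | sec) &
    (pseudo | (p$quant_class == "quantified" &
                 !is.na(p$true_fc) & p$true_fc >= fc_threshold))
  list(
    primary = sum(excl), primary_high = sum(p$presence == "high-only"),
    primary_normal = sum(p$presence == "normal-only"),
    secondary = sum(sec), candidates = sum(excl | sec),
    certified = sum(cert)
  )
}
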