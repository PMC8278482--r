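#' Pipeline configuration
#'
#' Collects every tunable threshold of the screen with its default. The
#' defaults are the settings of the screening procedure this package
#' implements; each is anchored at the stage that consumes it.
#'
#' @param min_ion_score Qualitative acceptance: minimum peptide ion score.
#' @param score_ratio_threshold Secondary-tier protein-score ratio.
#' @param ppm_tol XIC mass tolerance, ppm.
#' @param rt_tol RT tolerance for library interrogation, minutes.
#' @param align_tol RT tolerance for chromatogram alignment, minutes.
#' @param min_scans Minimum scans-across-peak for reliable quantification.
#' @param pseudo_value Pseudo fold change for asymmetric BLQ/absent pairs.
#' @param fc_threshold Certification fold-change threshold.
#' @param noise_floor XIC noise floor in counts; `NULL` derives it per XIC
#'   as the 10th percentile of nonzero intensities.
#' @param seed Seed recorded in the run log (the screen itself is
#'   deterministic; only synthetic-data generation consumes seeds).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_ion_score = 19, score_ratio_threshold = 2.0,
                            ppm_tol = 5, rt_tol = 0.5, align_tol = 1.0,
                            min_scans = 8, pseudo_value = 100.0,
                            fc_threshold = 2.0, noise_floor = NULL,
                            seed = NULL) {
  cfg <- list(min_ion_score = min_ion_score,
              score_ratio_threshold = score_ratio_threshold,
              ppm_tol = ppm_tol, rt_tol = rt_tol, align_tol = align_tol,
              min_scans = min_scans, pseudo_value = pseudo_value,
              fc_threshold = fc_threshold, noise_floor = noise_floor,
              seed = seed)
  if (min_ion_score < 0) stop("'min_ion_score' must be >= 0")
  pos <- c("score_ratio_threshold", "ppm_tol", "rt_tol", "align_tol",
           "min_scans", "pseudo_value", "fc_threshold")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(sprintf("'%s' must be positive", nm))
  }
  if (!is.null(noise_floor) && noise_floor <= 0)
    stop("'noise_floor' must be positive (or NULL for the data-driven rule)")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "(data-driven)" else
                  format(x[[nm]])))
  }
  invisible(x)
}

#' Certify biomarkers from fold changes
#'
#' A fold change becomes a certified biomarker call when its (normalized
#' area) ratio reaches `fc_threshold`, inclusive; pseudo-ratio entries pass
#' whenever `pseudo_value >= fc_threshold`. Calls are sorted by direction,
#' then by descending ratio.
#'
#' @param fc Fold-change table from [fold_changes()].
#' @param fc_threshold Minimum certified fold change.
#' @return A `data.frame` of biomarker calls: `accession, tier, direction,
#'   fold_change, pseudo`.
#' @export
certify <- function(fc, fc_threshold = 2.0) {
  stopifnot(fc_threshold > 0)
  keep <- fc$ratio >= fc_threshold
  out <- data.frame(accession = fc$accession[keep], tier = fc$tier[keep],
                    direction = fc$direction[keep],
                    fold_change = fc$ratio[keep], pseudo = fc$pseudo[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$direction, -out$fold_change, out$accession), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach functional classes to biomarker calls
#'
#' Joins a user-supplied annotation table (`accession`,
#' `function_class`) onto the calls; accessions without an annotation get
#' class `"unannotated"`. An accession mapped to more than one distinct
#' class is an error (ambiguous annotation).
#'
#' @param calls Calls from [certify()].
#' @param annotation `data.frame` with columns `accession` and
#'   `function_class`, or a path to such a TSV.
#' @return The calls with a `function_class` column; per-class counts in
#'   the `"class_counts"` attribute.
#' @export
annotate_calls <- function(calls, annotation) {
  if (is.character(annotation)) {
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  if (!all(c("accession", "function_class") %in% names(annotation)))
    stop("format error: annotation table needs columns ",
         "'accession' and 'function_class'")
  ann <- unique(annotation[, c("accession", "function_class")])
  dup <- unique(ann$accession[duplicated(ann$accession)])
  if (length(dup))
    stop("ambiguous annotation (multiple classes) for: ",
         paste(dup, collapse = ", "))
  i <- match(calls$accession, ann$accession)
  calls$function_class <- ifelse(is.na(i), "unannotated",
                                 ann$function_class[i])
  attr(calls, "class_counts") <- table(calls$function_class)
  calls
}

#' Run the full biomarker screen
#'
#' Orchestrates the stepped procedure end to end: read and filter the two
#' identification tables, triage candidates, build the targeted library,
#' quantify both MS1 runs, pair across runs, compute fold changes, certify,
#' and (optionally) annotate. All intermediate tables, a run log listing
#' every configured threshold, and the final biomarker table are written to
#' `out_dir`. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @param ident_normal,ident_high Paths to the two identification TSVs.
#' @param mzml_normal,mzml_high Paths to the two MS1 mzML runs.
#' @param annotation Optional annotation table (path or `data.frame`).
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return List with every stage's table: `ident`, `candidates`, `library`,
#'   `quant_normal`, `quant_high`, `pairs`, `fold_changes`, `biomarkers`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), ident_normal,
                         ident_high, mzml_normal, mzml_high,
                         annotation = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  idn <- stage("ident_normal", {
    filter_identifications(read_ident_table(ident_normal, "NORMAL"),
                           config$min_ion_score)
  })
  idh <- stage("ident_high", {
    filter_identifications(read_ident_table(ident_high, "HIGH"),
                           config$min_ion_score)
  })
  cand <- stage("triage",
                triage_candidates(idn, idh, config$score_ratio_threshold))
  lib <- stage("library", build_library(cand, idn, idh))
  qn <- stage("quant_normal", {
    quantify_run(read_ms1(mzml_normal), lib, config$ppm_tol, config$rt_tol,
                 config$min_scans, config$noise_floor)
  })
  qh <- stage("quant_high", {
    quantify_run(read_ms1(mzml_high), lib, config$ppm_tol, config$rt_tol,
                 config$min_scans, config$noise_floor)
  })
  pairs <- stage("match", match_across_runs(qn, qh, config$align_tol))
  fc <- stage("fold_change", fold_changes(pairs, config$pseudo_value))
  calls <- stage("certify", certify(fc, config$fc_threshold))
  if (!is.null(annotation)) {
    calls <- stage("annotate", annotate_calls(calls, annotation))
  }
  res <- list(ident = list(normal = idn, high = idh), candidates = cand,
              library = lib, quant_normal = qn, quant_high = qh,
              pairs = pairs, fold_changes = fc, biomarkers = calls,
              config = config)
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ident_table(res$ident$normal,
                    file.path(out_dir, "ident_normal_filtered.tsv"))
  write_ident_table(res$ident$high,
                    file.path(out_dir, "ident_high_filtered.tsv"))
  write_tsv_table(res$candidates, file.path(out_dir, "candidates.tsv"))
  write_tsv_table(res$library, file.path(out_dir, "library.tsv"))
  write_tsv_table(res$quant_normal, file.path(out_dir, "quant_normal.tsv"))
  write_tsv_table(res$quant_high, file.path(out_dir, "quant_high.tsv"))
  write_tsv_table(res$pairs, file.path(out_dir, "pairs.tsv"))
  write_tsv_table(res$fold_changes, file.path(out_dir, "fold_changes.tsv"))
  write_tsv_table(res$biomarkers, file.path(out_dir, "biomarkers.tsv"))
  cfg <- res$config
  log_lines <- c(
    sprintf("ms1screen run log  (%s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(cfg), function(nm) {
      sprintf("%s = %s", nm,
              if (is.null(cfg[[nm]]))
                "10th percentile of nonzero XIC intensities"
              else format(cfg[[nm]]))
    }, character(1)),
    sprintf("candidates = %d (primary %d, secondary %d)",
            nrow(res$candidates), sum(res$candidates$tier == "PRIMARY"),
            sum(res$candidates$tier == "SECONDARY")),
    sprintf("certified biomarkers = %d", nrow(res$biomarkers))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
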