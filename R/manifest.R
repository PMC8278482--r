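#' Construct a fixture manifest
#'
#' A manifest is the ground truth behind one simulated two-group comparison:
#' a protein table (presence pattern, per-group protein scores, true fold
#' change, quantification class, function class), a peptide table (the
#' identification evidence and, for peptides present in the MS1 runs, their
#' simulated elution parameters per run), and the generator parameters.
#'
#' @param proteins `data.frame` with columns `accession`, `presence`
#'   (`"normal-only"`, `"high-only"` or `"both"`), `score_normal`,
#'   `score_high` (NA where absent), `true_fc` (NA for quantification
#'   exclusives), `direction` (`"NORMAL"`/`"HIGH"`/NA), `quant_class`
#'   (`"quantified"`, `"blq_normal"`, `"blq_high"`, `"absent_normal"`,
#'   `"absent_high"` or `"none"` for proteins without an MS1 target),
#'   `function_class`.
#' @param peptides `data.frame` with columns `accession`, `sequence`,
#'   `charge`, `mz`, `ion_score`, `proteotypic`, `in_run`, plus per-group
#'   identification coordinates (`rt_ident_normal`, `rt_ident_high`,
#'   `ppm_ident_normal`, `ppm_ident_high`) and, for `in_run` peptides,
#'   per-run simulation columns (`rt_run_normal`, `rt_run_high`,
#'   `ppm_run_normal`, `ppm_run_high`, `apex_normal`, `apex_high`).
#' @param params List of generator parameters (`seed`, `duration`,
#'   `scan_interval`, `noise_floor`, `sigma_log`, `peak_fwhm`).
#' @return An object of class `fixture_manifest`.
#' @export
fixture_manifest <- function(proteins, peptides, params) {
  m <- structure(list(proteins = proteins, peptides = peptides,
                      params = params), class = "fixture_manifest")
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  p <- m$proteins
  if (anyDuplicated(p$accession))
    stop("duplicate accession in manifest: ",
         paste(unique(p$accession[duplicated(p$accession)]), collapse = ", "))
  ok <- p$presence %in% c("normal-only", "high-only", "both")
  if (!all(ok))
    stop("invalid presence pattern for: ",
         paste(p$accession[!ok], collapse = ", "))
  orphan <- setdiff(p$accession, m$peptides$accession)
  if (length(orphan))
    stop("proteins without peptides: ", paste(orphan, collapse = ", "))
  # each protein's proteotypic flag marks exactly its top-ion-score peptide
  sp <- split(m$peptides, m$peptides$accession)
  bad <- vapply(sp, function(d) {
    sum(d$proteotypic) != 1L ||
      d$ion_score[d$proteotypic] < max(d$ion_score)
  }, logical(1))
  if (any(bad))
    stop("proteotypic flag must mark exactly the max-ion-score peptide: ",
         paste(names(sp)[bad], collapse = ", "))
  invisible(m)
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("<fixture_manifest> %d proteins, %d peptides (%d in-run)\n",
              nrow(x$proteins), nrow(x$peptides), sum(x$peptides$in_run)))
  print(table(x$proteins$presence))
  invisible(x)
}

#' Serialize / read a manifest as a YAML config file
#'
#' @param m A [fixture_manifest()].
#' @param path File path.
#' @return `read_manifest` returns the `fixture_manifest`; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "fixture_manifest"))
  yaml::write_yaml(list(
    params = m$params,
    proteins = lapply(seq_len(nrow(m$proteins)),
                      function(i) as.list(m$proteins[i, ])),
    peptides = lapply(seq_len(nrow(m$peptides)),
                      function(i) as.list(m$peptides[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  bind1 <- function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
  }
  fixture_manifest(bind1(raw$proteins), bind1(raw$peptides), raw$params)
}

.ident_cols <- c("accession", "protein_score", "peptide", "charge", "mz",
                 "rt_min", "ion_score")

#' Emulate the per-group identification exports of a comparison
#'
#' Produces the two delimited identification tables (one per sample group)
#' that a database-search export would yield for the manifest: one row per
#' peptide-spectrum match carrying the protein score, the peptide sequence,
#' charge, observed m/z, retention time and ion score. Group-exclusive
#' proteins appear only in their group's table.
#'
#' @param m A [fixture_manifest()].
#' @return Named list with `normal` and `high` data frames (columns
#'   `accession, protein_score, peptide, charge, mz, rt_min, ion_score`).
#' @export
generate_ident_tables <- function(m) {
  stopifnot(inherits(m, "fixture_manifest"))
  one_group <- function(group) {
    gl <- tolower(group)
    present <- m$proteins$presence %in% c("both", paste0(gl, "-only"))
    prot <- m$proteins[present, , drop = FALSE]
    pep <- m$peptides[m$peptides$accession %in% prot$accession, ,
                      drop = FALSE]
    if (nrow(pep) == 0) {
      out <- data.frame(accession = character(), protein_score = numeric(),
                        peptide = character(), charge = integer(),
                        mz = numeric(), rt_min = numeric(),
                        ion_score = numeric(), stringsAsFactors = FALSE)
      return(out)
    }
    idx <- match(pep$accession, prot$accession)
    data.frame(
      accession = pep$accession,
      protein_score = prot[[paste0("score_", gl)]][idx],
      peptide = pep$sequence,
      charge = as.integer(pep$charge),
      mz = pep$mz * (1 + pep[[paste0("ppm_ident_", gl)]] * 1e-6),
      rt_min = pep[[paste0("rt_ident_", gl)]],
      ion_score = pep$ion_score,
      stringsAsFactors = FALSE
    )
  }
  list(normal = one_group("NORMAL"), high = one_group("HIGH"))
}

#' Build the two run specifications encoded in a manifest
#'
#' @param m A [fixture_manifest()].
#' @param seeds Integer vector of length 2: seeds for the NORMAL and HIGH
#'   run's centroid noise.
#' @return Named list of two [run_spec()] objects (`normal`, `high`).
#' @export
run_specs_from_manifest <- function(m, seeds) {
  stopifnot(inherits(m, "fixture_manifest"), length(seeds) == 2)
  pp <- m$params
  one <- function(group, seed) {
    gl <- tolower(group)
    pep <- m$peptides[m$peptides$in_run, , drop = FALSE]
    is_acc <- grepl("^IS_", pep$accession)
    mk <- function(d) peptide_spec(
      sequence = d$sequence, charge = d$charge, mz = d$mz,
      rt_apex = d[[paste0("rt_run_", gl)]], peak_fwhm = pp$peak_fwhm,
      apex_intensity = d[[paste0("apex_", gl)]],
      ppm_offset = d[[paste0("ppm_run_", gl)]], ion_score = d$ion_score
    )
    run_spec(
      run_id = paste0("sim_", gl), group = group, duration = pp$duration,
      scan_interval = pp$scan_interval, noise_floor = pp$noise_floor,
      seed = seed, peptides = mk(pep[!is_acc, , drop = FALSE]),
      is_peptides = mk(pep[is_acc, , drop = FALSE]),
      sigma_log = pp$sigma_log
    )
  }
  list(normal = one("NORMAL", seeds[1]), high = one("HIGH", seeds[2]))
}
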