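# shared fixtures, built once per test run and cached

.cache <- new.env(parent = emptyenv())

# simulate the study-like comparison and run the full screen on it
study_result <- function(seed = 101) {
  key <- paste0("study_", seed)
  if (is.null(.cache[[key]])) {
    dir <- file.path(tempdir(), paste0("ms1screen_study_", seed))
    paths <- simulate_study(dir, seed = seed)
    res <- run_pipeline(pipeline_config(), paths$ident_normal,
                        paths$ident_high, paths$mzml_normal,
                        paths$mzml_high, annotation = paths$annotation)
    .cache[[key]] <- list(paths = paths, fixture = paths$fixture, res = res)
  }
  .cache[[key]]
}

# a three-IS standard set reused by small synthetic runs
default_is <- function(rt = c(5, 15, 20)) {
  peptide_spec(sprintf("ISPEP%dK", seq_along(rt)), 2,
               mz = seq(600, by = 50, length.out = length(rt)),
               rt_apex = rt, peak_fwhm = 0.2, apex_intensity = 5e4)
}

# one-target run: a single peptide at m/z 500, rt 10 min
single_peptide_run <- function(apex, seed = 1, sigma_log = 0,
                               fwhm = 0.2, scan_interval = 0.025,
                               noise_floor = 1000, rt_apex = 10,
                               ppm_offset = 0, max_abs_ppm = 5) {
  run_spec("probe", "NORMAL", duration = 30,
           scan_interval = scan_interval, noise_floor = noise_floor,
           seed = seed,
           peptides = peptide_spec("PEPTIDEK", 2, 500, rt_apex, fwhm, apex,
                                   ppm_offset = ppm_offset),
           is_peptides = default_is(), sigma_log = sigma_log,
           max_abs_ppm = max_abs_ppm)
}

# generate, write and read back a run in one step
read_run <- function(spec) {
  f <- tempfile(fileext = ".mzML")
  generate_run(spec, f)
  read_ms1(f)
}

# small in-memory identification table
ident_from_rows <- function(rows, group) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_ident_table(f, group)
}

ident_rows <- function(accession, protein_score, peptide, charge = 2,
                       mz = 500, rt_min = 10, ion_score = 50) {
  data.frame(accession = accession, protein_score = protein_score,
             peptide = peptide, charge = charge, mz = mz, rt_min = rt_min,
             ion_score = ion_score, stringsAsFactors = FALSE)
}

# quantification row in the shape quantify_run() emits
quant_row <- function(accession, status, rt_apex = 10, norm = 1,
                      tier = "PRIMARY", run_id = "r") {
  data.frame(run_id = run_id, accession = accession, tier = tier,
             is_standard = FALSE, status = status, rt_apex = rt_apex,
             scans_across_peak = if (status == "ABSENT") 0L else 10L,
             area = if (status == "QUANTIFIED") norm else NA_real_,
             normalized_area = if (status == "QUANTIFIED") norm else NA_real_,
             stringsAsFactors = FALSE)
}
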