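#' Write a complete simulated study to disk
#'
#' Materializes a fixture — either the packaged study-like comparison
#' ([build_study_fixture()]) or a user manifest — as the file set the
#' pipeline consumes: two identification TSVs, two centroid MS1 mzML runs,
#' an annotation TSV and the serialized manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param manifest Optional [fixture_manifest()]; default builds the
#'   study-like fixture with `seed`.
#' @return Named list of the written paths, invisibly.
#' @export
simulate_study <- function(out_dir, seed = 1L, manifest = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(manifest)) {
    fx <- build_study_fixture(seed)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    fx <- list(manifest = manifest,
               runs = run_specs_from_manifest(manifest,
                                              sample.int(1e7, 2)),
               annotation = manifest$proteins[
                 manifest$proteins$function_class != "",
                 c("accession", "function_class")])
  }
  paths <- list(
    ident_normal = file.path(out_dir, "ident_normal.tsv"),
    ident_high = file.path(out_dir, "ident_high.tsv"),
    mzml_normal = file.path(out_dir, "run_normal.mzML"),
    mzml_high = file.path(out_dir, "run_high.mzML"),
    annotation = file.path(out_dir, "annotation.tsv"),
    manifest = file.path(out_dir, "manifest.yml")
  )
  tabs <- generate_ident_tables(fx$manifest)
  utils::write.table(tabs$normal, paths$ident_normal, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tabs$high, paths$ident_high, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  generate_run(fx$runs$normal, paths$mzml_normal)
  generate_run(fx$runs$high, paths$mzml_high)
  utils::write.table(fx$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(fx$manifest, paths$manifest)
  invisible(c(paths, list(fixture = fx)))
}
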