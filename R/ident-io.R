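#' Read a per-group identification table
#'
#' Reads a tab-separated identification export (one row per peptide-spectrum
#' match with its protein's accession and score) into an identification
#' table: a `data.frame` with one row per peptide match and the columns
#' `accession, group, protein_score, peptide, charge, mz, rt_min, ion_score`.
#' Rows with a non-numeric score/charge/m-z/RT or a charge outside 1-4 are
#' reported with their line numbers and skipped; more than 10% bad rows, or a
#' missing column, is a fatal format error. When an accession recurs, its
#' peptide rows are merged under one protein and the maximum reported protein
#' score is kept.
#'
#' @param path Path to the TSV file (header
#'   `accession, protein_score, peptide, charge, mz, rt_min, ion_score`).
#' @param group Sample group the table describes, `"NORMAL"` or `"HIGH"`.
#' @return An identification table (`data.frame`).
#' @export
read_ident_table <- function(path, group = c("NORMAL", "HIGH")) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("identification table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("accession", "protein_score", "peptide", "charge", "mz",
            "rt_min", "ion_score")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("format error in '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(raw) == 0) return(as_ident_tbl(empty_ident(), group))

  num <- function(x) suppressWarnings(as.numeric(x))
  ps <- num(raw$protein_score); ch <- num(raw$charge)
  mz <- num(raw$mz); rt <- num(raw$rt_min); is_ <- num(raw$ion_score)
  bad <- is.na(ps) | is.na(ch) | is.na(mz) | is.na(rt) | is.na(is_) |
    ch < 1 | ch > 4 | mz <= 0 | is_ < 0 |
    !nzchar(raw$accession) | !nzchar(raw$peptide)
  if (any(bad)) {
    lines <- which(bad) + 1L           # +1 for the header line
    if (mean(bad) > 0.10)
      stop(sprintf("'%s': %d of %d rows malformed (lines %s)", path,
                   sum(bad), nrow(raw),
                   paste(utils::head(lines, 10), collapse = ", ")))
    warning(sprintf("'%s': skipped %d malformed row(s) at line(s) %s", path,
                    sum(bad), paste(lines, collapse = ", ")))
  }
  tbl <- data.frame(
    accession = raw$accession, group = group, protein_score = ps,
    peptide = raw$peptide, charge = as.integer(ch), mz = mz, rt_min = rt,
    ion_score = is_, stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  # merge duplicate accessions: one protein score per accession (maximum)
  tbl$protein_score <- stats::ave(tbl$protein_score, tbl$accession,
                                  FUN = max)
  rownames(tbl) <- NULL
  as_ident_tbl(tbl, group)
}

empty_ident <- function() {
  data.frame(accession = character(), group = character(),
             protein_score = numeric(), peptide = character(),
             charge = integer(), mz = numeric(), rt_min = numeric(),
             ion_score = numeric(), stringsAsFactors = FALSE)
}

as_ident_tbl <- function(tbl, group) {
  attr(tbl, "group") <- group
  class(tbl) <- c("ident_tbl", "data.frame")
  tbl
}

#' Apply the qualitative acceptance filter
#'
#' Removes peptide matches whose ion score falls below the acceptance
#' threshold (the threshold itself passes) and drops proteins left with no
#' accepted peptide. The default of 19 is the identity/extensive-homology
#' score that a 1% false-discovery-rate search yielded for the study data;
#' other datasets should derive their own value from their decoy search.
#'
#' @param ident An identification table from [read_ident_table()].
#' @param min_ion_score Minimum accepted peptide ion score (inclusive).
#' @return The filtered identification table.
#' @export
filter_identifications <- function(ident, min_ion_score = 19) {
  stopifnot(min_ion_score >= 0)
  out <- ident[ident$ion_score >= min_ion_score, , drop = FALSE]
  rownames(out) <- NULL
  as_ident_tbl(out, attr(ident, "group"))
}

#' Select each protein's proteotypic peptide
#'
#' For every accession, returns the single peptide match with the maximal ion
#' score — the peptide that represents the protein in targeted MS1
#' quantification. Ties are broken deterministically by lexicographic
#' sequence order, then by charge.
#'
#' @param ident A (filtered) identification table.
#' @return A `data.frame` with one row per accession.
#' @export
select_proteotypic <- function(ident) {
  if (nrow(ident) == 0) {
    stop("no peptides to select a proteotypic peptide from")
  }
  ord <- order(ident$accession, -ident$ion_score, ident$peptide,
               ident$charge)
  out <- ident[ord, , drop = FALSE]
  out <- out[!duplicated(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is an accession a spiked internal standard?
#'
#' IS proteins are tagged by the `IS_` accession-prefix convention and are
#' excluded from candidate triage (they exist for normalization only).
#'
#' @param accession Character vector of accessions.
#' @return Logical vector.
#' @export
is_standard <- function(accession) grepl("^IS_", accession)

#' Write an identification table
#'
#' Writes the table in the same TSV dialect it is read from, with an added
#' `proteotypic` logical column marking each protein's representative
#' peptide.
#'
#' @param ident An identification table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ident_table <- function(ident, path) {
  out <- as.data.frame(ident)[, c("accession", "protein_score", "peptide",
                                  "charge", "mz", "rt_min", "ion_score")]
  if (nrow(out)) {
    proto <- select_proteotypic(ident)
    key <- paste(out$accession, out$peptide, out$charge)
    out$proteotypic <- key %in% paste(proto$accession, proto$peptide,
                                      proto$charge)
  } else {
    out$proteotypic <- logical(0)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the two generated identification tables to TSV
#'
#' @param tables List with `normal` and `high` tables, as returned by
#'   [generate_ident_tables()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_ident_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ident_normal.tsv", "ident_high.tsv"))
  utils::write.table(tables$normal, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tables$high, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
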