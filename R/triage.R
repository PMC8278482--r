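#' Tiered candidate triage by protein-score presence and ratio
#'
#' Screens the two groups' filtered identification tables into biomarker
#' candidates. Proteins identified in exactly one group form the PRIMARY
#' tier. Proteins shared by both groups enter the SECONDARY tier when the
#' protein-score ratio between groups — `max(sN/sH, sH/sN)`, the score being
#' a coarse abundance indicator — reaches `ratio_threshold` (inclusive).
#' Shared proteins below the threshold are excluded, as are internal-standard
#' proteins (`IS_` prefix). Shared proteins with a non-positive score on
#' either side are excluded with a warning (their ratio is undefined).
#'
#' @param normal,high Filtered identification tables ([read_ident_table()] +
#'   [filter_identifications()]).
#' @param ratio_threshold Minimum protein-score ratio for the secondary tier.
#' @return A `data.frame` of candidates sorted by (tier, accession):
#'   `accession`, `tier` (`"PRIMARY"`/`"SECONDARY"`), `direction_hint`
#'   (group of exclusive presence, or of the larger score), `score_ratio`
#'   (NA for PRIMARY).
#' @export
triage_candidates <- function(normal, high, ratio_threshold = 2.0) {
  stopifnot(ratio_threshold > 0)
  ps <- function(tbl) {
    p <- tbl[!duplicated(tbl$accession), c("accession", "protein_score")]
    p[!is_standard(p$accession), , drop = FALSE]
  }
  pn <- ps(normal); ph <- ps(high)
  only_n <- setdiff(pn$accession, ph$accession)
  only_h <- setdiff(ph$accession, pn$accession)
  shared <- intersect(pn$accession, ph$accession)

  n_prim <- length(only_n) + length(only_h)
  prim <- data.frame(
    accession = c(only_n, only_h),
    tier = rep("PRIMARY", n_prim),
    direction_hint = c(rep("NORMAL", length(only_n)),
                       rep("HIGH", length(only_h))),
    score_ratio = rep(NA_real_, n_prim), stringsAsFactors = FALSE
  )

  sec <- data.frame(accession = character(), tier = character(),
                    direction_hint = character(), score_ratio = numeric(),
                    stringsAsFactors = FALSE)
  if (length(shared)) {
    sn <- pn$protein_score[match(shared, pn$accession)]
    sh <- ph$protein_score[match(shared, ph$accession)]
    undef <- sn <= 0 | sh <= 0
    if (any(undef)) {
      warning("protein score <= 0, ratio undefined; excluding: ",
              paste(shared[undef], collapse = ", "))
    }
    ratio <- pmax(sn / sh, sh / sn)
    keep <- !undef & ratio >= ratio_threshold
    sec <- data.frame(
      accession = shared[keep], tier = rep("SECONDARY", sum(keep)),
      direction_hint = ifelse(sh[keep] >= sn[keep], "HIGH", "NORMAL"),
      score_ratio = ratio[keep], stringsAsFactors = FALSE
    )
  }
  out <- rbind(prim, sec)
  out <- out[order(out$tier, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the targeted proteotypic-peptide library
#'
#' One library entry per candidate, taken from its proteotypic peptide (the
#' accepted peptide with the maximum ion score). For PRIMARY candidates the
#' evidence comes from the group where the protein was identified; for
#' SECONDARY candidates sequence, charge and target m/z come from the
#' higher-scoring group's evidence and the expected retention time is the
#' mean of the peptide's RT across the groups where it was observed, which
#' centers the RT search window. All internal-standard proteins present in
#' the tables are appended as flagged entries — they are quantified alongside
#' the targets to provide the per-run normalization factor.
#'
#' @param candidates Candidate table from [triage_candidates()].
#' @param normal,high The filtered identification tables.
#' @return A `data.frame` library: `accession, sequence, charge, mz_target,
#'   rt_expected, tier, is_standard`.
#' @export
build_library <- function(candidates, normal, high) {
  proto_n <- if (nrow(normal)) select_proteotypic(normal) else empty_ident()
  proto_h <- if (nrow(high)) select_proteotypic(high) else empty_ident()

  entry <- function(accession, tier, direction_hint) {
    src <- if (identical(direction_hint, "NORMAL")) proto_n else proto_h
    other <- if (identical(direction_hint, "NORMAL")) proto_h else proto_n
    i <- match(accession, src$accession)
    rt <- src$rt_min[i]
    j <- match(accession, other$accession)
    # same peptide seen in the other group -> center the window between them
    if (!is.na(j) && other$peptide[j] == src$peptide[i] &&
        other$charge[j] == src$charge[i]) {
      rt <- mean(c(rt, other$rt_min[j]))
    }
    data.frame(accession = accession, sequence = src$peptide[i],
               charge = src$charge[i], mz_target = src$mz[i],
               rt_expected = rt, tier = tier, is_standard = FALSE,
               stringsAsFactors = FALSE)
  }

  lib <- list()
  for (k in seq_len(nrow(candidates))) {
    lib[[k]] <- entry(candidates$accession[k], candidates$tier[k],
                      candidates$direction_hint[k])
  }
  # spiked IS peptides, matched across both groups' evidence
  is_acc <- union(proto_n$accession[is_standard(proto_n$accession)],
                  proto_h$accession[is_standard(proto_h$accession)])
  for (acc in is_acc) {
    e <- entry(acc, NA_character_,
               if (acc %in% proto_h$accession) "HIGH" else "NORMAL")
    e$is_standard <- TRUE
    lib[[length(lib) + 1]] <- e
  }
  out <- if (length(lib)) do.call(rbind, lib) else
    data.frame(accession = character(), sequence = character(),
               charge = integer(), mz_target = numeric(),
               rt_expected = numeric(), tier = character(),
               is_standard = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write candidates / library tables
#'
#' @param x Candidate or library `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
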