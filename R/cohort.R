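#' The 25 thalamic nuclei per hemisphere
#'
#' Nomenclature of the probabilistic histology-based thalamic segmentation
#' shipped with FreeSurfer: anterior (AV), lateral (LD, LP), ventral (VA,
#' VAmc, VLa, VLp, VPL, VM), intralaminar (CeM, CL, Pc, CM, Pf), medial
#' (Pt, MV_re, MDm, MDl), geniculate (LGN, MGN), and pulvinar/posterior
#' (L_Sg, PuA, PuM, PuL, PuI) groups.
#'
#' @return Character vector of 25 subfield labels.
#' @export
thalamic_subfields <- function() {
  c(
    "AV", "LD", "LP", "VA", "VAmc", "VLa", "VLp", "VPL", "VM",
    "CeM", "CL", "Pc", "CM", "Pf", "Pt", "MV_re", "MDm", "MDl",
    "LGN", "MGN", "L_Sg", "PuA", "PuM", "PuL", "PuI"
  )
}

COHORT_GROUPS <- c("CS", "NC")
CLINICAL_SCORES <- c("FMA", "RAVLT_SR", "RAVLT_LR", "N_ACC", "N_RT", "S_ACC", "S_RT")
HEMISPHERES <- c("ipsi", "contra")

#' Validate a cohort table
#'
#' Checks the contract every group analysis relies on: unique `subject_id`,
#' `group` in {CS, NC}, `gender` in {male, female}, at least one scanner
#' level, positive `tiv`. Clinical scores may be missing (NA) and are never
#' imputed.
#'
#' @param cohort Data frame with columns `subject_id`, `group`, `age`,
#'   `gender`, `scanner`, `tiv`, and optionally the clinical scores
#'   FMA, RAVLT_SR, RAVLT_LR, N_ACC, N_RT, S_ACC, S_RT.
#' @param require_both_groups If `TRUE` (default) both CS and NC must be
#'   non-empty.
#' @return The cohort as a tibble with `group`, `gender`, `scanner` as
#'   factors (scanner levels sorted alphabetically).
#' @export
validate_cohort <- function(cohort, require_both_groups = TRUE) {
  need <- c("subject_id", "group", "age", "gender", "scanner", "tiv")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) abort(paste0("Cohort is missing columns: ", paste(miss, collapse = ", ")))
  cohort <- as_tibble(cohort)
  if (anyDuplicated(cohort$subject_id)) {
    abort("Duplicate subject_id in cohort table.")
  }
  if (!all(cohort$group %in% COHORT_GROUPS)) {
    abort(paste0(
      "Unknown group level(s): ",
      paste(setdiff(unique(cohort$group), COHORT_GROUPS), collapse = ", ")
    ))
  }
  if (!all(cohort$gender %in% c("male", "female"))) {
    abort("`gender` must be 'male' or 'female'.")
  }
  if (any(!is.finite(cohort$tiv)) || any(cohort$tiv <= 0)) {
    abort("`tiv` must be positive and finite.")
  }
  cohort$group <- factor(cohort$group, levels = COHORT_GROUPS)
  cohort$gender <- factor(cohort$gender, levels = c("male", "female"))
  cohort$scanner <- factor(as.character(cohort$scanner))
  if (require_both_groups && any(table(cohort$group) == 0L)) {
    abort("Both groups (CS, NC) must be non-empty.")
  }
  cohort
}

#' Read a cohort table from TSV
#'
#' @param path Path to a tab-separated file with a header row.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble; see [validate_cohort()].
#' @export
read_cohort_table <- function(path, require_both_groups = TRUE) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(df, require_both_groups = require_both_groups)
}

#' Write a cohort table to TSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a thalamic subfield volume table
#'
#' Long format: one row per (subject, hemisphere, subfield). Hemispheres are
#' labelled `ipsi` / `contra` (for this right-hemisphere-lesion design,
#' ipsi = right, contra = left). Besides the 25 nuclei, a
#' `whole_thalamus` row per hemisphere is allowed (and produced by the
#' generator) carrying the hemisphere total.
#'
#' @param volumes Data frame with columns `subject_id`, `hemisphere`,
#'   `subfield`, `volume` (mm^3).
#' @param subfields Expected subfield set (default [thalamic_subfields()]).
#' @return The table as a tibble, checked for completeness and positivity.
#' @export
validate_subfield_volumes <- function(volumes, subfields = thalamic_subfields()) {
  need <- c("subject_id", "hemisphere", "subfield", "volume")
  miss <- setdiff(need, names(volumes))
  if (length(miss)) abort(paste0("Volume table missing columns: ", paste(miss, collapse = ", ")))
  volumes <- as_tibble(volumes)
  if (!all(volumes$hemisphere %in% HEMISPHERES)) {
    abort("`hemisphere` must be 'ipsi' or 'contra'.")
  }
  known <- c(subfields, "whole_thalamus")
  if (!all(volumes$subfield %in% known)) {
    abort(paste0(
      "Unknown subfield label(s): ",
      paste(setdiff(unique(volumes$subfield), known), collapse = ", ")
    ))
  }
  if (any(!is.finite(volumes$volume)) || any(volumes$volume <= 0)) {
    abort("Subfield volumes must be positive and finite.")
  }
  counts <- dplyr::count(
    dplyr::filter(volumes, .data$subfield != "whole_thalamus"),
    .data$subject_id, .data$hemisphere
  )
  if (nrow(counts) && !all(counts$n == length(subfields))) {
    abort(paste0(
      "Each subject/hemisphere must carry exactly the configured ",
      length(subfields), " subfields."
    ))
  }
  if (anyDuplicated(volumes[, c("subject_id", "hemisphere", "subfield")])) {
    abort("Duplicate (subject, hemisphere, subfield) rows.")
  }
  volumes
}

#' Read a subfield volume table from TSV
#'
#' @param path Path to a tab-separated file with a header row.
#' @inheritParams validate_subfield_volumes
#' @return A validated volume tibble.
#' @export
read_subfield_volumes <- function(path, subfields = thalamic_subfields()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_subfield_volumes(df, subfields = subfields)
}

#' Extract one seed's volumes aligned to a cohort
#'
#' Pulls the volume of a single (subfield, hemisphere) seed — or the
#' bilateral whole-thalamus total when `subfield = "whole_thalamus"` and
#' `hemisphere = "both"` — ordered to match `cohort$subject_id`.
#'
#' @param volumes Validated subfield volume table.
#' @param cohort Validated cohort tibble.
#' @param subfield Subfield name or `"whole_thalamus"`.
#' @param hemisphere `"ipsi"`, `"contra"`, or `"both"` (whole thalamus only).
#' @return Numeric vector of volumes, one per cohort row.
#' @export
seed_volumes <- function(volumes, cohort, subfield, hemisphere = "ipsi") {
  if (hemisphere == "both") {
    if (subfield != "whole_thalamus") {
      abort("hemisphere = 'both' is only meaningful for the whole thalamus.")
    }
    sel <- dplyr::filter(volumes, .data$subfield == "whole_thalamus")
    agg <- dplyr::summarise(
      dplyr::group_by(sel, .data$subject_id),
      volume = sum(.data$volume), .groups = "drop"
    )
  } else {
    agg <- dplyr::filter(
      volumes,
      .data$subfield == !!subfield, .data$hemisphere == !!hemisphere
    )
  }
  hit <- match(cohort$subject_id, agg$subject_id)
  if (anyNA(hit)) {
    abort(paste0("Seed '", subfield, "' (", hemisphere, ") missing for some subjects."))
  }
  agg$volume[hit]
}
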