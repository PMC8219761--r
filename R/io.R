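## Delimited-file readers/writers shared by all stages. All files are
## comma-separated UTF-8 with "." decimal and a mandatory header row;
## missing covariates are empty cells.

.COHORT_REQUIRED <- c("subject_id", "pair_id", "group", "age_at_entry",
                      "exam_type", "exam_purpose", "exam_era")
.COHORT_COVARIATES <- c("age_at_diagnosis", "menopausal_status", "n_ftp",
                        "breastfeeding", "er_status", "bmi_class")
.MATCHING_VARS <- c("exam_type", "exam_purpose", "exam_era")

#' Validate the matched-pair structure of a cohort table
#'
#' Enforces the 1:1 matched case-case invariants: every \code{pair_id}
#' occurs exactly twice, once per MBD group; within a pair the examination
#' matching variables are identical and ages at cohort entry differ by at
#' most \code{ageTolerance} years.
#'
#' @param cohort data.frame of subject records.
#' @param ageTolerance maximum within-pair difference in age at entry
#'   (years); default 5, the matching rule.
#' @return the cohort, invisibly, after validation.
#' @export
validateCohort <- function(cohort, ageTolerance = 5) {
  missing_cols <- setdiff(.COHORT_REQUIRED, colnames(cohort))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("cohort structure error: duplicated subject_id")
  if (nrow(cohort) && !all(cohort$group %in% .GROUPS))
    stop("cohort schema error: group must be one of ",
         paste(.GROUPS, collapse = ", "))
  split_idx <- split(seq_len(nrow(cohort)), cohort$pair_id)
  for (pid in names(split_idx)) {
    idx <- split_idx[[pid]]
    if (length(idx) != 2L)
      stop(sprintf("cohort structure error: pair '%s' has %d members", pid,
                   length(idx)))
    grp <- cohort$group[idx]
    if (length(unique(grp)) != 2L)
      stop(sprintf("cohort structure error: pair '%s' has two '%s' members",
                   pid, grp[1]))
    for (mv in intersect(.MATCHING_VARS, colnames(cohort))) {
      v <- cohort[[mv]][idx]
      if (!identical(v[1], v[2]))
        stop(sprintf(
          "cohort structure error: matching variable '%s' differs in pair '%s'",
          mv, pid))
    }
    if (abs(diff(cohort$age_at_entry[idx])) > ageTolerance)
      stop(sprintf(
        "cohort structure error: ages at entry in pair '%s' differ by more than %g years",
        pid, ageTolerance))
  }
  invisible(cohort)
}

#' Read a matched case-case cohort table
#'
#' @param path CSV file with one row per subject (see
#'   [writeCohort()] for the schema).
#' @param ageTolerance passed to [validateCohort()].
#' @return validated data.frame of subject records.
#' @export
readCohort <- function(path, ageTolerance = 5) {
  cohort <- read.csv(path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  validateCohort(cohort, ageTolerance = ageTolerance)
  cohort
}

#' Write a cohort table
#'
#' @param cohort data.frame of subject records.
#' @param path output CSV path.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a concentration panel with LOQ metadata
#'
#' @param path CSV with column \code{subject_id} plus one numeric column per
#'   feature.
#' @param loqPath CSV with columns \code{feature}, \code{family}, \code{loq}
#'   and optionally \code{compound_id}, one row per feature of \code{path}.
#' @param cohort optional cohort data.frame; when given, subjects are
#'   aligned to the cohort order and must match exactly.
#' @return a \linkS4class{QuantPanel} (censoring mask derived as
#'   value < LOQ; imputation happens downstream).
#' @export
readQuantPanel <- function(path, loqPath, cohort = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% colnames(tab))
    stop("panel schema error: missing 'subject_id' column")
  loqs <- read.csv(loqPath, stringsAsFactors = FALSE)
  need <- c("feature", "family", "loq")
  if (!all(need %in% colnames(loqs)))
    stop("LOQ schema error: need columns ", paste(need, collapse = ", "))
  feats <- setdiff(colnames(tab), "subject_id")
  no_loq <- setdiff(feats, loqs$feature)
  if (length(no_loq))
    stop("LOQ schema error: no LOQ entry for feature(s) ",
         paste(utils::head(no_loq, 5), collapse = ", "))
  mat <- t(as.matrix(tab[, feats, drop = FALSE]))
  colnames(mat) <- tab$subject_id
  if (any(mat < 0, na.rm = TRUE))
    stop("panel value error: negative concentration")
  if (!is.null(cohort)) {
    if (!setequal(cohort$subject_id, colnames(mat)))
      stop("panel structure error: subjects do not match the cohort")
    mat <- mat[, cohort$subject_id, drop = FALSE]
  }
  fm <- loqs[match(feats, loqs$feature), , drop = FALSE]
  rownames(mat) <- fm$feature
  meta <- data.frame(family = fm$family, loq = fm$loq,
                     row.names = fm$feature)
  if ("compound_id" %in% colnames(fm)) meta$compound_id <- fm$compound_id
  QuantPanel(mat, meta)
}

#' Write a concentration panel and its LOQ table
#'
#' @param panel a \linkS4class{QuantPanel}.
#' @param path output CSV for the subjects-by-features table.
#' @param loqPath output CSV for the feature/family/LOQ table.
#' @export
writeQuantPanel <- function(panel, path, loqPath) {
  mat <- t(concentrations(panel))
  out <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  fm <- featureMeta(panel)
  loqs <- data.frame(feature = rownames(panel), family = fm$family,
                     loq = fm$loq,
                     compound_id = if ("compound_id" %in% colnames(fm))
                       fm$compound_id else NA_character_)
  write.csv(loqs, loqPath, row.names = FALSE, na = "")
  invisible(path)
}

#' Read spectra for one experiment type
#'
#' One matrix file per experiment: first column \code{subject_id}, remaining
#' header fields are the ppm grid (descending).
#'
#' @param path CSV matrix file.
#' @param experiment \code{"noesy"}, \code{"cpmg"} or \code{"diffusion"}.
#' @return a \linkS4class{SpectrumSet}.
#' @export
readSpectra <- function(path, experiment) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ppm <- as.numeric(colnames(tab)[-1])
  if (anyNA(ppm)) stop("spectra schema error: header must be the ppm grid")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  colnames(mat) <- NULL
  methods::new("SpectrumSet", experiment = experiment, ppm = ppm,
               intensity = mat)
}

#' Write spectra for one experiment type
#'
#' @param spectra a \linkS4class{SpectrumSet}.
#' @param path output CSV path.
#' @export
writeSpectra <- function(spectra, path) {
  mat <- spectra@intensity
  out <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE)
  colnames(out)[-1] <- format(spectra@ppm, digits = 15, trim = TRUE,
                              scientific = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an association result table
#'
#' One row per feature-by-model result, in the layout of a published
#' association table: OR (95\% CI) per SD, raw p, FDR-adjusted p.
#'
#' @param results data.frame of association results (see
#'   [runFeaturePanel()]).
#' @param path output CSV path.
#' @export
writeAssociationTable <- function(results, path) {
  if (!nrow(results)) stop("association table error: no results to write")
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 8)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back an association result table
#'
#' @param path CSV written by [writeAssociationTable()].
#' @return data.frame of association results.
#' @export
readAssociationTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
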