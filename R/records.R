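# Per-eye tabular records: severity stage, demographics, QC indices, and
# computed OCTA parameters.  Cohorts are plain data.frames (one row per eye)
# so the statistics layer composes with ordinary R tooling.

EYE_REQUIRED_COLS <- c("eye_id", "stage", "age", "sex", "q_score")
EYE_KNOWN_COLS <- c(EYE_REQUIRED_COLS, "ssi", "cmt_um")

#' Construct a single eye record
#'
#' @param eye_id opaque identifier (one record per eye per subject).
#' @param stage ordered severity stage: 0 = healthy, 1 = diabetes without
#'   retinopathy, 2 = mild, 3 = moderate, 4 = severe NPDR.
#' @param age age in years (> 0).
#' @param sex `"M"` or `"F"`.
#' @param q_score device scan-quality index (>= 0).
#' @param ssi signal strength index, optional.
#' @param cmt_um central macular thickness in micrometres, optional.
#' @param params named list/vector of computed parameters (e.g. `SCP_VD`).
#' @return one-row data.frame.
#' @export
eye_record <- function(eye_id, stage, age, sex, q_score, ssi = NA_real_,
                       cmt_um = NA_real_, params = NULL) {
  rec <- data.frame(eye_id = as.character(eye_id), stage = as.integer(stage),
                    age = as.numeric(age), sex = as.character(sex),
                    q_score = as.numeric(q_score), ssi = as.numeric(ssi),
                    cmt_um = as.numeric(cmt_um), stringsAsFactors = FALSE)
  if (!is.null(params)) for (nm in names(params)) rec[[nm]] <- as.numeric(params[[nm]])
  validate_eye_table(rec)
  rec
}

validate_eye_table <- function(tab) {
  miss <- setdiff(EYE_REQUIRED_COLS, names(tab))
  if (length(miss))
    stop("eye table is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tab$stage) || !all(tab$stage %in% 0:4))
    stop("stage must be an integer in 0..4 ",
         "(0 healthy, 1 DM no DR, 2 mild, 3 moderate, 4 severe NPDR)")
  if (any(!is.na(tab$age) & tab$age <= 0)) stop("age must be > 0")
  if (any(!tab$sex %in% c("M", "F", NA))) stop("sex must be 'M' or 'F'")
  if (any(!is.na(tab$q_score) & tab$q_score < 0)) stop("q_score must be >= 0")
  if (anyDuplicated(tab$eye_id)) stop("duplicate eye_id: one record per eye")
  invisible(tab)
}

#' Eligibility screen for an eye record
#'
#' Applies the acquisition QC gates and the central macular edema exclusion:
#' eligible iff Q-score >= 6, SSI >= 50, and central macular thickness not
#' greater than 320 um (men) / 305 um (women).  Missing SSI or CMT values
#' skip the corresponding criterion (reported in `skipped`), since cohorts
#' may arrive pre-filtered.
#'
#' @param rec a one-row data.frame or named list with `q_score` and
#'   optionally `ssi`, `sex`, `cmt_um`.
#' @return list with `eligible` (logical), `failed` (character vector of
#'   failed criteria among `"q_score"`, `"ssi"`, `"macular_edema"`), and
#'   `skipped` (criteria not assessable).
#' @export
qc_eligible <- function(rec) {
  failed <- character(0)
  skipped <- character(0)
  q <- rec$q_score
  if (is.null(q) || is.na(q)) stop("q_score is required for QC screening")
  if (q < 6) failed <- c(failed, "q_score")
  ssi <- rec$ssi
  if (is.null(ssi) || is.na(ssi)) {
    skipped <- c(skipped, "ssi")
  } else if (ssi < 50) failed <- c(failed, "ssi")
  cmt <- rec$cmt_um
  sex <- rec$sex
  if (is.null(cmt) || is.na(cmt) || is.null(sex) || is.na(sex)) {
    skipped <- c(skipped, "macular_edema")
  } else {
    limit <- if (identical(sex, "M")) 320 else 305
    if (cmt > limit) failed <- c(failed, "macular_edema")
  }
  list(eligible = length(failed) == 0L, failed = failed, skipped = skipped)
}

#' Load a per-eye parameter table from CSV
#'
#' Expects one row per eye with at least `eye_id`, `stage`, `age`, `sex`,
#' `q_score`; `ssi`, `cmt_um` and any parameter columns (e.g. `SCP_VD`,
#' `MCP_VD`, `SCP_VLD`, `SCP_AFI`, `FAZ`) are carried through unchanged.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
load_parameter_table <- function(path) {
  header <- names(read.csv(path, nrows = 1))
  classes <- c(eye_id = "character", sex = "character")  # "F" is not FALSE
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = classes[intersect(names(classes), header)])
  if (!"stage" %in% names(tab))
    stop("parameter table has no 'stage' column: ", path)
  validate_eye_table(tab)
  tab
}

#' Write a per-eye parameter table to CSV
#'
#' @param tab data.frame as returned by [load_parameter_table()] or
#'   [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
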