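# CSV dialect for the two claims tables.  UTF-8, comma-separated, header
# row, integer day offsets; death_day is empty when the patient is not
# observed to die during follow-up.

PATIENT_COLS <- c("patient_id", "discharge_day", "death_day", "group",
                  "site_id", "age", "sex", "stemi", "prior_mi",
                  "prior_med_use")
DISP_COLS <- c("patient_id", "med_class", "fill_day", "days_supplied")

#' Write a cohort and its claims to CSV
#'
#' @param patients,dispensations Data frames as produced by
#'   [simulate_cohort()] (or read back by [read_claims()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths of the two files written
#'   (`patients.csv`, `dispensations.csv`).
#' @export
write_claims <- function(patients, dispensations, dir) {
  stopifnot(all(PATIENT_COLS %in% names(patients)),
            all(DISP_COLS %in% names(dispensations)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(dir, "patients.csv")
  dp <- file.path(dir, "dispensations.csv")
  utils::write.csv(patients[, PATIENT_COLS, drop = FALSE], pp,
                   row.names = FALSE, na = "")
  utils::write.csv(dispensations[, DISP_COLS, drop = FALSE], dp,
                   row.names = FALSE, na = "")
  invisible(c(patients = pp, dispensations = dp))
}

#' Read a cohort and its claims from CSV
#'
#' @param dir Directory containing `patients.csv` and `dispensations.csv`.
#' @return List with validated data frames `patients` and `dispensations`.
#' @export
read_claims <- function(dir) {
  pp <- file.path(dir, "patients.csv")
  dp <- file.path(dir, "dispensations.csv")
  for (f in c(pp, dp)) if (!file.exists(f))
    stop("missing input file: ", f, call. = FALSE)
  patients <- utils::read.csv(pp, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character",
                                             site_id = "character"))
  dispensations <- utils::read.csv(dp, stringsAsFactors = FALSE,
                                   colClasses = c(patient_id = "character"))
  validate_claims(patients, dispensations)
  list(patients = patients, dispensations = dispensations)
}

#' Validate the two claims tables
#'
#' Checks column presence, day ordering (death strictly after discharge),
#' positive days supplied, and known medication classes.  Errors name the
#' offending table and rows.
#'
#' @param patients,dispensations The two tables.
#' @return Invisibly `TRUE`.
#' @export
validate_claims <- function(patients, dispensations) {
  miss <- setdiff(PATIENT_COLS, names(patients))
  if (length(miss)) stop("patients table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(DISP_COLS, names(dispensations))
  if (length(miss)) stop("dispensations table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(patients$patient_id))
    stop("duplicated patient_id in patients table", call. = FALSE)
  bad <- which(!is.na(patients$death_day) &
                 patients$death_day <= patients$discharge_day)
  if (length(bad))
    stop("death_day on or before discharge_day for patient rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (nrow(dispensations)) {
    bad <- which(dispensations$days_supplied < 1)
    if (length(bad))
      stop("days_supplied < 1 in dispensation rows: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    bad <- which(!dispensations$med_class %in% MED_CLASSES)
    if (length(bad))
      stop("unknown med_class in dispensation rows: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
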