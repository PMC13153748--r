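#' Japanese fiscal year of a date
#'
#' Fiscal years run April 1 through March 31 and are labelled by the starting
#' calendar year, the convention under which Japanese insurers report claims:
#' 2016-04-01 through 2017-03-31 is fiscal year 2016.
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts).
#' @return integer vector of fiscal-year labels.
#' @examples
#' fiscal_year(as.Date(c("2016-04-01", "2016-03-31", "2019-12-15")))
#' @export
fiscal_year <- function(dates) {
  d <- as.Date(dates)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  y - as.integer(m < 4L)
}

.MODALITIES <- c("CT", "MRI", "NONE")

#' Construct a validated claims table
#'
#' Bundles the three long-format tables the analysis consumes: visit records
#' (one row per patient-facility-date service contact, flagged when it is an
#' imaging examination), enrollment spans, and facility attributes (bed
#' counts). Validation enforces the data contract: the modality is `NONE`
#' exactly when the row is not an imaging exam, every patient seen has an
#' enrollment span and every facility visited has an attribute row. Duplicate
#' identical visit rows are collapsed to one (with a message).
#'
#' @param visits data.frame with columns `patient_id`, `facility_id`,
#'   `service_date` (`Date`), `is_imaging_exam` (logical), `modality`
#'   (`"CT"`, `"MRI"` or `"NONE"`).
#' @param enrollments data.frame with `patient_id`, `start_date`, `end_date`.
#' @param facilities data.frame with `facility_id`, `bed_count`
#'   (0 encodes a clinic without beds).
#' @return an object of class `claims_table` (a list of the three tables).
#' @export
claims_table <- function(visits, enrollments, facilities) {
  visits <- as.data.frame(visits)
  enrollments <- as.data.frame(enrollments)
  facilities <- as.data.frame(facilities)

  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop_shareduse(what, " is missing required column(s): ",
                     paste(missing, collapse = ", "),
                     class = "shareduse_schema_error")
    }
  }
  need(visits, c("patient_id", "facility_id", "service_date",
                 "is_imaging_exam", "modality"), "visits")
  need(enrollments, c("patient_id", "start_date", "end_date"), "enrollments")
  need(facilities, c("facility_id", "bed_count"), "facilities")

  visits$patient_id <- as.character(visits$patient_id)
  visits$facility_id <- as.character(visits$facility_id)
  visits$service_date <- as.Date(visits$service_date)
  visits$is_imaging_exam <- as.logical(visits$is_imaging_exam)
  visits$modality <- as.character(visits$modality)
  enrollments$patient_id <- as.character(enrollments$patient_id)
  enrollments$start_date <- as.Date(enrollments$start_date)
  enrollments$end_date <- as.Date(enrollments$end_date)
  facilities$facility_id <- as.character(facilities$facility_id)
  facilities$bed_count <- as.integer(facilities$bed_count)

  if (anyNA(visits$service_date)) {
    stop_shareduse("unparseable service_date in visits row(s): ",
                   paste(utils::head(which(is.na(visits$service_date)), 10),
                         collapse = ", "),
                   class = "shareduse_validation_error")
  }
  bad_mod <- !(visits$modality %in% .MODALITIES)
  if (any(bad_mod)) {
    stop_shareduse("unknown modality value(s): ",
                   paste(unique(visits$modality[bad_mod]), collapse = ", "),
                   class = "shareduse_validation_error")
  }
  inconsistent <- xor(visits$is_imaging_exam, visits$modality != "NONE")
  if (any(inconsistent)) {
    stop_shareduse("modality must be NONE exactly when is_imaging_exam is ",
                   "FALSE; offending row(s): ",
                   paste(utils::head(which(inconsistent), 10), collapse = ", "),
                   class = "shareduse_validation_error")
  }
  if (anyNA(enrollments$start_date) || anyNA(enrollments$end_date)) {
    stop_shareduse("unparseable enrollment dates",
                   class = "shareduse_validation_error")
  }
  if (any(enrollments$start_date > enrollments$end_date)) {
    stop_shareduse("enrollment start_date after end_date for patient(s): ",
                   paste(enrollments$patient_id[
                     enrollments$start_date > enrollments$end_date],
                     collapse = ", "),
                   class = "shareduse_validation_error")
  }
  if (any(facilities$bed_count < 0, na.rm = TRUE) ||
      anyNA(facilities$bed_count)) {
    stop_shareduse("bed_count must be a nonnegative integer",
                   class = "shareduse_validation_error")
  }

  orphan_p <- setdiff(unique(visits$patient_id), enrollments$patient_id)
  if (length(orphan_p)) {
    stop_shareduse("visits reference patient_id(s) absent from enrollments: ",
                   paste(orphan_p, collapse = ", "),
                   class = "shareduse_referential_error")
  }
  orphan_f <- setdiff(unique(visits$facility_id), facilities$facility_id)
  if (length(orphan_f)) {
    stop_shareduse("visits reference facility_id(s) absent from facilities: ",
                   paste(orphan_f, collapse = ", "),
                   class = "shareduse_referential_error")
  }

  ndup <- nrow(visits) - nrow(unique(visits))
  if (ndup > 0) {
    message("collapsed ", ndup, " duplicate visit row(s)")
    visits <- unique(visits)
  }
  o <- order(visits$patient_id, visits$service_date, visits$facility_id,
             visits$modality)
  visits <- visits[o, , drop = FALSE]
  rownames(visits) <- NULL
  enrollments <- enrollments[order(enrollments$patient_id), , drop = FALSE]
  rownames(enrollments) <- NULL
  facilities <- facilities[order(facilities$facility_id), , drop = FALSE]
  rownames(facilities) <- NULL

  structure(list(visits = visits, enrollments = enrollments,
                 facilities = facilities),
            class = "claims_table")
}

#' @export
print.claims_table <- function(x, ...) {
  cat("<claims_table>\n")
  cat("  visits:     ", nrow(x$visits), " rows, ",
      length(unique(x$visits$patient_id)), " patients, ",
      length(unique(x$visits$facility_id)), " facilities\n", sep = "")
  cat("  imaging:    ", sum(x$visits$is_imaging_exam), " exams (",
      sum(x$visits$modality == "CT"), " CT, ",
      sum(x$visits$modality == "MRI"), " MRI)\n", sep = "")
  cat("  enrollments:", nrow(x$enrollments), "\n")
  cat("  facilities: ", nrow(x$facilities), "\n")
  invisible(x)
}

#' Read a claims table from CSV files
#'
#' Reads the three CSV files of the external data contract (UTF-8, header
#' row, comma-separated): `visits.csv` with `patient_id, facility_id,
#' service_date, is_imaging_exam, modality`; `enrollments.csv` with
#' `patient_id, start_date, end_date`; `facilities.csv` with
#' `facility_id, bed_count`. Dates are ISO-8601 (`YYYY-MM-DD`) and
#' `is_imaging_exam` is 0/1. Malformed rows are rejected with an error, never
#' silently dropped.
#'
#' @param visits_path,enrollments_path,facilities_path file paths.
#' @return a validated [claims_table()].
#' @export
read_claims <- function(visits_path, enrollments_path, facilities_path) {
  rd <- function(path) {
    as.data.frame(data.table::fread(path, colClasses = "character",
                                    encoding = "UTF-8"))
  }
  visits <- rd(visits_path)
  enrollments <- rd(enrollments_path)
  facilities <- rd(facilities_path)

  if ("is_imaging_exam" %in% names(visits)) {
    flag <- visits$is_imaging_exam
    if (!all(flag %in% c("0", "1", "TRUE", "FALSE"))) {
      stop_shareduse("is_imaging_exam must be 0/1",
                     class = "shareduse_validation_error")
    }
    visits$is_imaging_exam <- flag %in% c("1", "TRUE")
  }
  if ("service_date" %in% names(visits)) {
    d <- as.Date(visits$service_date, format = "%Y-%m-%d")
    if (anyNA(d)) {
      stop_shareduse("unparseable service_date value(s): ",
                     paste(utils::head(unique(
                       visits$service_date[is.na(d)]), 10), collapse = ", "),
                     class = "shareduse_validation_error")
    }
    visits$service_date <- d
  }
  for (col in c("start_date", "end_date")) {
    if (col %in% names(enrollments)) {
      d <- as.Date(enrollments[[col]], format = "%Y-%m-%d")
      if (anyNA(d)) {
        stop_shareduse("unparseable ", col, " in enrollments",
                       class = "shareduse_validation_error")
      }
      enrollments[[col]] <- d
    }
  }
  claims_table(visits, enrollments, facilities)
}

#' Write a claims table to CSV files
#'
#' Inverse of [read_claims()]: writes `visits.csv`, `enrollments.csv` and
#' `facilities.csv` under `dir` in the external contract format. A read
#' followed by a write reproduces the input up to row/column order.
#'
#' @param claims a [claims_table()].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_claims <- function(claims, dir) {
  stopifnot(inherits(claims, "claims_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- claims$visits
  v$service_date <- format(v$service_date, "%Y-%m-%d")
  v$is_imaging_exam <- as.integer(v$is_imaging_exam)
  e <- claims$enrollments
  e$start_date <- format(e$start_date, "%Y-%m-%d")
  e$end_date <- format(e$end_date, "%Y-%m-%d")
  paths <- file.path(dir, c("visits.csv", "enrollments.csv", "facilities.csv"))
  data.table::fwrite(v, paths[1])
  data.table::fwrite(e, paths[2])
  data.table::fwrite(claims$facilities, paths[3])
  invisible(paths)
}

#' Restrict a claims table to the study population
#'
#' Applies the study inclusion criteria: a patient is retained when (a) a
#' single enrollment span covers the whole study window (continuous insurance
#' coverage; a gap of any length excludes) and (b) the patient has at least
#' one imaging examination dated inside the window. All visits of retained
#' patients are kept, including visits outside the window, so that detection
#' windows straddling the boundary remain evaluable. Exclusion counts by
#' reason are attached as attribute `"exclusions"`; a patient failing both
#' criteria is counted under `coverage_gap`.
#'
#' @param claims a [claims_table()].
#' @param study_start,study_end study window bounds (`Date`), inclusive.
#' @return a filtered `claims_table` with attribute `exclusions`
#'   (named list `coverage_gap`, `no_exam`).
#' @export
filter_population <- function(claims, study_start, study_end) {
  stopifnot(inherits(claims, "claims_table"))
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start <= study_end)

  enr <- claims$enrollments
  covered_ids <- unique(enr$patient_id[
    enr$start_date <= study_start & enr$end_date >= study_end])
  v <- claims$visits
  exam_in_window <- v$is_imaging_exam & v$service_date >= study_start &
    v$service_date <= study_end
  examined_ids <- unique(v$patient_id[exam_in_window])

  all_ids <- unique(enr$patient_id)
  keep <- intersect(covered_ids, examined_ids)
  n_gap <- length(setdiff(all_ids, covered_ids))
  n_noexam <- length(setdiff(intersect(all_ids, covered_ids), examined_ids))

  out <- claims_table(
    v[v$patient_id %in% keep, , drop = FALSE],
    enr[enr$patient_id %in% keep, , drop = FALSE],
    claims$facilities
  )
  attr(out, "exclusions") <- list(coverage_gap = n_gap, no_exam = n_noexam)
  out
}
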