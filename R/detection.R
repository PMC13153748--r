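#' Detection rule parameters
#'
#' The shared-use rule operationalizes the study's "continuous 3-month" and
#' "continuous 6-month" periods as fixed 91- and 182-day windows
#' (calendar-month arithmetic is ambiguous across month lengths). The
#' multi-source policy decides what happens when several facilities satisfy
#' the source conditions for one exam: `"nearest"` (default) keeps the single
#' facility whose qualifying visit is closest in time to the exam, `"all"`
#' emits one event per qualifying source.
#'
#' @param isolation_window_days positive integer, Condition-1 half-window
#'   (default 91).
#' @param continuity_window_days positive integer, maximum source visit-course
#'   span (default 182); must be >= `isolation_window_days`.
#' @param multi_source_policy `"nearest"` or `"all"`.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(isolation_window_days = 91L,
                             continuity_window_days = 182L,
                             multi_source_policy = c("nearest", "all")) {
  multi_source_policy <- match.arg(multi_source_policy)
  isolation_window_days <- as.integer(isolation_window_days)
  continuity_window_days <- as.integer(continuity_window_days)
  stopifnot(isolation_window_days >= 1L,
            continuity_window_days >= isolation_window_days)
  structure(list(isolation_window_days = isolation_window_days,
                 continuity_window_days = continuity_window_days,
                 multi_source_policy = multi_source_policy),
            class = "detection_params")
}

# Internal cores operate on one patient's visit rows (data.frame) with
# service_date as integer days, so the exported per-exam predicates and the
# full detector share a single implementation.

# Condition 1: the exam is the only imaging visit (either modality) at its
# facility in every 91-day window containing it, i.e. no other imaging exam
# at (patient, facility) within +/- iso days.
.cond1_core <- function(pv, facility, exam_day, exam_modality, iso) {
  img <- pv[pv$is_imaging_exam & pv$facility_id == facility, , drop = FALSE]
  self <- img$day == exam_day & img$modality == exam_modality
  other <- img[!self, , drop = FALSE]
  !any(abs(other$day - exam_day) <= iso)
}

# Conditions 2+3 for one candidate source facility: find the tightest pair of
# visit dates u < v bracketing the exam with span <= cont and no imaging exam
# at the source inside [u, v]. For each start u the only end that matters is
# the earliest visit >= exam day (wider ends only add content), so the scan
# is linear in the number of visit dates.
.source_window_core <- function(pv, source, exam_day, cont) {
  rows <- pv[pv$facility_id == source, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  dates <- sort(unique(rows$day))
  img_dates <- unique(rows$day[rows$is_imaging_exam])
  starts <- dates[dates <= exam_day]
  if (!length(starts)) return(NULL)
  best <- NULL
  for (u in starts) {
    ends <- dates[dates >= exam_day & dates > u]
    if (!length(ends)) next
    v <- ends[1L]
    if (v - u > cont) next
    if (any(img_dates >= u & img_dates <= v)) next
    cand <- c(u, v)
    if (is.null(best) ||
        (v - u) < (best[2] - best[1]) ||
        ((v - u) == (best[2] - best[1]) && u > best[1])) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  in_win <- dates[dates >= best[1] & dates <= best[2]]
  list(window_start = best[1], window_end = best[2],
       visit_count = length(in_win),
       nearest_gap = min(abs(in_win - exam_day)))
}

.qualifying_sources_core <- function(pv, target, exam_day, cont) {
  facs <- setdiff(unique(pv$facility_id), target)
  out <- list()
  for (s in facs) {
    w <- .source_window_core(pv, s, exam_day, cont)
    if (!is.null(w)) out[[s]] <- w
  }
  if (!length(out)) {
    return(data.frame(facility_id = character(), window_start = as.Date(character()),
                      window_end = as.Date(character()), visit_count = integer(),
                      nearest_gap = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    facility_id = names(out),
    window_start = as.Date(vapply(out, `[[`, 0, "window_start"),
                           origin = "1970-01-01"),
    window_end = as.Date(vapply(out, `[[`, 0, "window_end"),
                         origin = "1970-01-01"),
    visit_count = vapply(out, function(x) as.integer(x$visit_count), 0L),
    nearest_gap = vapply(out, function(x) as.integer(x$nearest_gap), 0L),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$facility_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.patient_day_frame <- function(claims, patient) {
  pv <- claims$visits[claims$visits$patient_id == patient, , drop = FALSE]
  pv$day <- as.integer(pv$service_date)
  pv
}

#' Condition 1: is an imaging exam isolated at its facility?
#'
#' TRUE iff the patient has no other imaging examination (CT or MRI) at the
#' exam's facility within `isolation_window_days` days of the exam date —
#' the strongest reading of "only a single diagnostic imaging visit within a
#' continuous 3-month period": every such window containing the exam holds
#' just that one imaging visit.
#'
#' @param exam a list or one-row data.frame with `patient_id`, `facility_id`,
#'   `service_date`, `modality`.
#' @param claims a [claims_table()].
#' @param params a [detection_params()].
#' @return logical scalar.
#' @export
condition1_isolated <- function(exam, claims, params = detection_params()) {
  pv <- .patient_day_frame(claims, as.character(exam$patient_id))
  .cond1_core(pv, as.character(exam$facility_id),
              as.integer(as.Date(exam$service_date)),
              as.character(exam$modality),
              params$isolation_window_days)
}

#' Conditions 2-3: facilities qualifying as the exam's source
#'
#' Returns every facility (other than the exam's) where the patient has two
#' or more visit dates `u < v` bracketing the exam date with span
#' `v - u <= continuity_window_days`, and no imaging examination at that
#' facility inside `[u, v]` (the source requests, but does not perform, the
#' exam). The reported window is the tightest qualifying bracket (minimum
#' span, ties broken by the later start).
#'
#' @inheritParams condition1_isolated
#' @return data.frame with columns `facility_id`, `window_start`,
#'   `window_end`, `visit_count` (visit dates inside the window) and
#'   `nearest_gap` (days from the exam to the nearest in-window visit).
#' @export
qualifying_sources <- function(exam, claims, params = detection_params()) {
  pv <- .patient_day_frame(claims, as.character(exam$patient_id))
  .qualifying_sources_core(pv, as.character(exam$facility_id),
                           as.integer(as.Date(exam$service_date)),
                           params$continuity_window_days)
}

#' Pick one source facility among qualifying candidates
#'
#' Under the `"nearest"` policy the candidate whose nearest in-window visit
#' is closest to the exam date wins; ties go to the larger visit count, then
#' to the lexicographically smallest facility id.
#'
#' @param candidates data.frame as returned by [qualifying_sources()].
#' @param exam the exam (unused beyond documentation; the gap is
#'   precomputed per candidate).
#' @return a single facility id, or `NA_character_` when `candidates` is
#'   empty (no source: the caller emits no event).
#' @export
select_source <- function(candidates, exam = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NA_character_)
  o <- order(candidates$nearest_gap, -candidates$visit_count,
             candidates$facility_id)
  candidates$facility_id[o[1L]]
}

.empty_events <- function() {
  data.frame(patient_id = character(), source_facility_id = character(),
             target_facility_id = character(),
             exam_date = as.Date(character()),
             modality = character(), fiscal_year = integer(),
             stringsAsFactors = FALSE)
}

.sort_events <- function(ev) {
  o <- order(ev$exam_date, ev$patient_id, ev$target_facility_id,
             ev$source_facility_id)
  ev <- ev[o, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect shared-use events in one fiscal-year / modality stratum
#'
#' Scans every imaging examination of the given modality whose date falls in
#' the given fiscal year, keeps those passing Condition 1
#' ([condition1_isolated()]) with at least one qualifying source
#' ([qualifying_sources()]), and emits one event per exam (policy
#' `"nearest"`) or one per qualifying source (policy `"all"`). Strata are
#' assigned by exam date; the surrounding source visit windows may cross
#' fiscal-year boundaries. Output is sorted by
#' (exam_date, patient_id, target, source) and is invariant to input row
#' order.
#'
#' @param claims a validated [claims_table()].
#' @param modality `"CT"` or `"MRI"`.
#' @param fy integer fiscal year (e.g. 2016).
#' @param params a [detection_params()].
#' @return data.frame of events: `patient_id`, `source_facility_id`,
#'   `target_facility_id`, `exam_date`, `modality`, `fiscal_year`.
#' @export
detect_shared_use <- function(claims, modality, fy,
                              params = detection_params()) {
  stopifnot(inherits(claims, "claims_table"), modality %in% c("CT", "MRI"))
  fy <- as.integer(fy)
  v <- claims$visits
  sel <- v$is_imaging_exam & v$modality == modality &
    fiscal_year(v$service_date) == fy
  exams <- v[sel, , drop = FALSE]
  if (nrow(exams) == 0L) return(.empty_events())

  v$day <- as.integer(v$service_date)
  by_patient <- split(v, v$patient_id)
  iso <- params$isolation_window_days
  cont <- params$continuity_window_days

  rows <- vector("list", nrow(exams))
  for (i in seq_len(nrow(exams))) {
    e <- exams[i, ]
    pv <- by_patient[[e$patient_id]]
    d <- as.integer(e$service_date)
    if (!.cond1_core(pv, e$facility_id, d, e$modality, iso)) next
    cand <- .qualifying_sources_core(pv, e$facility_id, d, cont)
    if (nrow(cand) == 0L) next
    src <- if (params$multi_source_policy == "nearest") {
      select_source(cand)
    } else {
      cand$facility_id
    }
    rows[[i]] <- data.frame(
      patient_id = e$patient_id, source_facility_id = src,
      target_facility_id = e$facility_id, exam_date = e$service_date,
      modality = e$modality, fiscal_year = fy,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.empty_events())
  .sort_events(do.call(rbind, rows))
}

#' Detect shared-use events in every stratum at once
#'
#' Convenience wrapper running [detect_shared_use()] for each combination of
#' modality and fiscal year present among the imaging exams (or an explicit
#' set) and row-binding the results.
#'
#' @inheritParams detect_shared_use
#' @param modalities,fiscal_years strata to scan; default: all present.
#' @return data.frame of events across strata.
#' @export
detect_all_strata <- function(claims, modalities = NULL, fiscal_years = NULL,
                              params = detection_params()) {
  v <- claims$visits
  img <- v[v$is_imaging_exam, , drop = FALSE]
  if (is.null(modalities)) modalities <- sort(unique(img$modality))
  if (is.null(fiscal_years)) {
    fiscal_years <- sort(unique(fiscal_year(img$service_date)))
  }
  out <- list()
  for (m in modalities) {
    for (y in fiscal_years) {
      out[[paste(m, y)]] <- detect_shared_use(claims, m, y, params)
    }
  }
  if (!length(out)) return(.empty_events())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
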