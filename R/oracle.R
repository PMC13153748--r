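#' Brute-force reference detector
#'
#' Reference implementation of [detect_shared_use()] by exhaustive
#' enumeration: for every imaging exam of the stratum it scans all visit rows
#' to test Condition 1, then for every facility in the facility table it
#' enumerates *all* pairs of the patient's visit dates there to test
#' Conditions 2-3, with no indexing or pruning. Intended as the independent
#' oracle for equivalence testing and for the synthetic generator's
#' verification pass; identical semantics, deliberately naive construction.
#'
#' @inheritParams detect_shared_use
#' @return data.frame of events, same contract and sort order as
#'   [detect_shared_use()].
#' @export
brute_force_oracle <- function(claims, modality, fy,
                               params = detection_params()) {
  stopifnot(inherits(claims, "claims_table"), modality %in% c("CT", "MRI"))
  fy <- as.integer(fy)
  v <- claims$visits
  iso <- params$isolation_window_days
  cont <- params$continuity_window_days
  events <- list()

  for (i in seq_len(nrow(v))) {
    if (!v$is_imaging_exam[i]) next
    if (v$modality[i] != modality) next
    d <- as.integer(v$service_date[i])
    if (fiscal_year(v$service_date[i]) != fy) next
    p <- v$patient_id[i]
    target <- v$facility_id[i]

    # Condition 1: no other imaging exam at the target within +/- iso days
    isolated <- TRUE
    for (j in seq_len(nrow(v))) {
      if (j == i) next
      if (!v$is_imaging_exam[j]) next
      if (v$patient_id[j] != p) next
      if (v$facility_id[j] != target) next
      dj <- as.integer(v$service_date[j])
      if (dj == d && v$modality[j] == v$modality[i]) next  # duplicate of self
      if (abs(dj - d) <= iso) { isolated <- FALSE; break }
    }
    if (!isolated) next

    # Conditions 2-3: every facility, every pair of visit dates
    cands <- list()
    for (s in claims$facilities$facility_id) {
      if (s == target) next
      dates <- integer()
      img_dates <- integer()
      for (j in seq_len(nrow(v))) {
        if (v$patient_id[j] != p) next
        if (v$facility_id[j] != s) next
        dates <- c(dates, as.integer(v$service_date[j]))
        if (v$is_imaging_exam[j]) {
          img_dates <- c(img_dates, as.integer(v$service_date[j]))
        }
      }
      dates <- unique(dates)
      if (length(dates) < 2L) next
      best_u <- NA_integer_; best_v <- NA_integer_
      for (u in dates) {
        for (w in dates) {
          if (!(u < w)) next
          if (!(u <= d && d <= w)) next
          if (w - u > cont) next
          has_img <- FALSE
          for (x in img_dates) if (x >= u && x <= w) has_img <- TRUE
          if (has_img) next
          if (is.na(best_u) ||
              (w - u) < (best_v - best_u) ||
              ((w - u) == (best_v - best_u) && u > best_u)) {
            best_u <- u; best_v <- w
          }
        }
      }
      if (is.na(best_u)) next
      in_win <- dates[dates >= best_u & dates <= best_v]
      cands[[s]] <- list(facility_id = s,
                         visit_count = length(in_win),
                         nearest_gap = min(abs(in_win - d)))
    }
    if (!length(cands)) next

    if (params$multi_source_policy == "nearest") {
      best <- NULL
      for (cnd in cands) {
        if (is.null(best)) { best <- cnd; next }
        if (cnd$nearest_gap < best$nearest_gap ||
            (cnd$nearest_gap == best$nearest_gap &&
             cnd$visit_count > best$visit_count) ||
            (cnd$nearest_gap == best$nearest_gap &&
             cnd$visit_count == best$visit_count &&
             cnd$facility_id < best$facility_id)) {
          best <- cnd
        }
      }
      srcs <- best$facility_id
    } else {
      srcs <- vapply(cands, `[[`, "", "facility_id")
    }
    for (s in srcs) {
      events[[length(events) + 1L]] <- data.frame(
        patient_id = p, source_facility_id = s, target_facility_id = target,
        exam_date = v$service_date[i], modality = v$modality[i],
        fiscal_year = fy, stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(.empty_events())
  .sort_events(do.call(rbind, events))
}
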