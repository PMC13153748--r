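#' Configuration for the synthetic claims generator
#'
#' Describes a synthetic prefecture: facilities grouped into communities, a
#' planted directed shared-use network over them, patients hosting the
#' planted episodes, background noise visits, and deliberate rule violations.
#' Defaults mirror the study conditions: fiscal years 2016-2019 (April-March)
#' with every patient continuously enrolled for the whole window.
#'
#' Edges may be supplied explicitly via `planted_edges` (data.frame with
#' `source`, `target`, `modality`, `fiscal_year`, `n_events`) or drawn by
#' [plant_network()] from the community structure: each unordered facility
#' pair is connected with probability `within_community_prob` when the two
#' facilities share a community and `between_community_prob` otherwise, and a
#' fraction `reciprocity_fraction` of connected pairs (deterministically
#' rounded) carries both directions. Both directions of a mutual pair share
#' one (modality, fiscal year) stratum, so planted reciprocity is recoverable
#' from per-stratum networks.
#'
#' @param n_facilities,n_patients positive integers.
#' @param n_communities positive integer, `<= n_facilities`.
#' @param planted_edges optional explicit edge table (see above).
#' @param reciprocity_fraction real in `[0, 1]`.
#' @param within_community_prob,between_community_prob dyad connection
#'   probabilities.
#' @param events_per_edge events planted on each directed edge (>= 1).
#' @param modalities,fiscal_years strata sampled per dyad.
#' @param noise_visit_rate mean number of extra non-imaging visits per
#'   patient (Poisson), at random facilities and dates.
#' @param violation_mix named integer vector `c(cond1=, cond2=, cond3=)`:
#'   number of episodes injected that violate exactly that condition.
#' @param study_start,study_end enrollment window (defaults FY2016-FY2019).
#' @param seed integer master seed; all randomness flows from it through
#'   per-patient substreams, so adding patients does not reshuffle existing
#'   ones.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_facilities, n_patients, n_communities = 1L,
                             planted_edges = NULL,
                             reciprocity_fraction = 0,
                             within_community_prob = 0.3,
                             between_community_prob = 0.01,
                             events_per_edge = 1L,
                             modalities = c("CT", "MRI"),
                             fiscal_years = 2016:2019,
                             noise_visit_rate = 0,
                             violation_mix = c(cond1 = 0L, cond2 = 0L,
                                               cond3 = 0L),
                             study_start = as.Date("2016-04-01"),
                             study_end = as.Date("2020-03-31"),
                             seed = 0L) {
  stopifnot(n_facilities >= 1, n_patients >= 1,
            n_communities >= 1, n_communities <= n_facilities,
            reciprocity_fraction >= 0, reciprocity_fraction <= 1,
            within_community_prob >= 0, within_community_prob <= 1,
            between_community_prob >= 0, between_community_prob <= 1,
            events_per_edge >= 1, noise_visit_rate >= 0,
            all(modalities %in% c("CT", "MRI")))
  vm <- c(cond1 = 0L, cond2 = 0L, cond3 = 0L)
  vm[names(violation_mix)] <- as.integer(violation_mix)
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("source", "target", "modality", "fiscal_year",
                    "n_events") %in% names(planted_edges)))
    if (any(planted_edges$source == planted_edges$target)) {
      stop_shareduse("planted edges must have source != target",
                     class = "shareduse_generation_error")
    }
    if (any(planted_edges$n_events < 1)) {
      stop_shareduse("planted edges need n_events >= 1",
                     class = "shareduse_generation_error")
    }
  }
  structure(list(
    n_facilities = as.integer(n_facilities),
    n_patients = as.integer(n_patients),
    n_communities = as.integer(n_communities),
    planted_edges = planted_edges,
    reciprocity_fraction = reciprocity_fraction,
    within_community_prob = within_community_prob,
    between_community_prob = between_community_prob,
    events_per_edge = as.integer(events_per_edge),
    modalities = modalities,
    fiscal_years = as.integer(fiscal_years),
    noise_visit_rate = noise_visit_rate,
    violation_mix = vm,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    seed = as.integer(seed)), class = "generator_config")
}

.facility_ids <- function(n) sprintf("F%03d", seq_len(n))
.patient_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Plant a directed shared-use network with community structure
#'
#' Draws the planted edge set described in [generator_config()]. Facilities
#' are assigned to `n_communities` contiguous, near-equal blocks; edges fall
#' predominantly within communities; `reciprocity_fraction` of connected
#' dyads (rounded to the nearest count, selected at random) become mutual,
#' the rest get a single random direction. Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return data.frame of directed edges (`source`, `target`, `modality`,
#'   `fiscal_year`, `n_events`) with attribute `community_of` (named integer
#'   vector over all facility ids).
#' @export
plant_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  facs <- .facility_ids(config$n_facilities)
  community_of <- sort(rep_len(seq_len(config$n_communities),
                               config$n_facilities))
  names(community_of) <- facs

  if (!is.null(config$planted_edges)) {
    edges <- config$planted_edges
    attr(edges, "community_of") <- community_of
    return(edges)
  }

  if (config$n_facilities < 2L) {
    if (config$reciprocity_fraction > 0) {
      stop_shareduse("reciprocity requested but only self-pairs available",
                     class = "shareduse_generation_error")
    }
    edges <- data.frame(source = character(), target = character(),
                        modality = character(), fiscal_year = integer(),
                        n_events = integer(), stringsAsFactors = FALSE)
    attr(edges, "community_of") <- community_of
    return(edges)
  }

  edges <- with_substream(config$seed, 0L, {
    pairs <- utils::combn(facs, 2L)
    same <- community_of[pairs[1, ]] == community_of[pairs[2, ]]
    p <- ifelse(same, config$within_community_prob,
                config$between_community_prob)
    connected <- stats::runif(ncol(pairs)) < p
    idx <- which(connected)
    n_dyads <- length(idx)
    n_mutual <- round(config$reciprocity_fraction * n_dyads)
    mutual_idx <- if (n_mutual > 0) {
      idx[sample.int(n_dyads, n_mutual)]
    } else integer()
    out <- list()
    for (k in idx) {
      a <- pairs[1, k]; b <- pairs[2, k]
      modality <- sample(config$modalities, 1L)
      fy <- if (length(config$fiscal_years) == 1L) config$fiscal_years else
        sample(config$fiscal_years, 1L)
      if (k %in% mutual_idx) {
        out[[length(out) + 1L]] <- data.frame(
          source = c(a, b), target = c(b, a), modality = modality,
          fiscal_year = fy, n_events = config$events_per_edge,
          stringsAsFactors = FALSE)
      } else {
        flip <- stats::runif(1) < 0.5
        out[[length(out) + 1L]] <- data.frame(
          source = if (flip) b else a, target = if (flip) a else b,
          modality = modality, fiscal_year = fy,
          n_events = config$events_per_edge, stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      data.frame(source = character(), target = character(),
                 modality = character(), fiscal_year = integer(),
                 n_events = integer(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, out)
    }
  })
  rownames(edges) <- NULL
  attr(edges, "community_of") <- community_of
  edges
}

# One planted episode for a patient: visit rows plus the truth record.
# kind: "event" or "cond1"/"cond2"/"cond3" violations. Margins keep every
# constructed date inside the enrollment window.
.build_episode <- function(kind, source, target, modality, fy,
                           study_start, study_end) {
  fy_lo <- as.integer(as.Date(sprintf("%d-04-01", fy)))
  fy_hi <- as.integer(as.Date(sprintf("%d-03-31", fy + 1L)))
  lo <- max(fy_lo, as.integer(study_start) + 125L)
  hi <- min(fy_hi, as.integer(study_end) - 125L)
  if (lo > hi) {
    stop_shareduse("study window too short to fit detection windows in FY ",
                   fy, class = "shareduse_generation_error")
  }
  d <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
  row <- function(fac, day, img, mod) {
    data.frame(facility_id = fac, day = day, is_imaging_exam = img,
               modality = mod, stringsAsFactors = FALSE)
  }
  rows <- list(row(target, d, TRUE, modality))
  if (kind == "event" || kind == "cond1") {
    g1 <- sample(7:80, 1L); g2 <- sample(7:80, 1L)
    rows <- c(rows, list(row(source, d - g1, FALSE, "NONE"),
                         row(source, d + g2, FALSE, "NONE")))
    if (kind == "cond1") {
      delta <- sample(c(-1L, 1L), 1L) * sample(7:60, 1L)
      rows <- c(rows, list(row(target, d + delta, TRUE, modality)))
    }
  } else if (kind == "cond2") {
    # bracketing pair exists but spans > 182 days
    g1 <- sample(92:120, 1L); g2 <- sample(92:120, 1L)
    rows <- c(rows, list(row(source, d - g1, FALSE, "NONE"),
                         row(source, d + g2, FALSE, "NONE")))
  } else if (kind == "cond3") {
    # multiple visits in a tight course, but none bracketing the exam
    s1 <- sample(7:50, 1L); s2 <- sample(7:70, 1L)
    rows <- c(rows, list(row(source, d - s1 - s2, FALSE, "NONE"),
                         row(source, d - s1, FALSE, "NONE")))
  }
  list(rows = do.call(rbind, rows), exam_day = d)
}

.single_patient_claims <- function(pid, visit_rows, study_start, study_end,
                                   facilities) {
  visits <- data.frame(
    patient_id = pid, facility_id = visit_rows$facility_id,
    service_date = as.Date(visit_rows$day, origin = "1970-01-01"),
    is_imaging_exam = visit_rows$is_imaging_exam,
    modality = visit_rows$modality, stringsAsFactors = FALSE)
  claims_table(
    unique(visits),
    data.frame(patient_id = pid, start_date = study_start,
               end_date = study_end, stringsAsFactors = FALSE),
    facilities)
}

#' Generate synthetic claims with planted ground truth
#'
#' Forward-simulates a claims table realizing the planted network of
#' [plant_network()]: each planted event becomes one patient episode (an
#' isolated imaging exam at the target bracketed by two non-imaging visits
#' at the source within the continuity window); each requested violation
#' becomes an episode failing exactly the labelled condition (Condition 1: a
#' second imaging exam at the target within 91 days; Condition 2: the
#' bracketing source visits span more than 182 days; Condition 3: a tight
#' source visit course that does not bracket the exam date). Remaining
#' patients carry only background noise visits. Every patient with imaging
#' rows is then verified against [brute_force_oracle()] under default
#' detection parameters; when noise visits corrupt an episode (e.g. by
#' creating a closer qualifying source), that patient's noise is redrawn
#' (bounded retries, then an error). Ground truth is therefore exact, not
#' probabilistic. Each patient is at most one episode's host; generation
#' fails as infeasible when episodes outnumber patients.
#'
#' @param config a [generator_config()].
#' @return list with `claims` (a [claims_table()]) and `truth` (list:
#'   `events` data.frame, `non_events` data.frame with `violated_condition`,
#'   `community_of` named integer vector, `edges` the planted edge table).
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  facs <- .facility_ids(config$n_facilities)
  facilities <- data.frame(
    facility_id = facs,
    bed_count = with_substream(config$seed, -1L, {
      n <- length(facs)
      beds <- integer(n)
      hospital <- stats::runif(n) > 0.55
      beds[hospital] <- pmin(600L, as.integer(round(
        exp(stats::rnorm(sum(hospital), mean = 3.9, sd = 1.1)))))
      beds
    }), stringsAsFactors = FALSE)

  edges <- plant_network(config)
  community_of <- attr(edges, "community_of")

  # episode roster: planted events, then violations
  ep <- list()
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      for (k in seq_len(edges$n_events[i])) {
        ep[[length(ep) + 1L]] <- list(
          kind = "event", source = edges$source[i], target = edges$target[i],
          modality = edges$modality[i], fy = edges$fiscal_year[i])
      }
    }
  }
  viol <- with_substream(config$seed, -2L, {
    out <- list()
    for (cond in c("cond1", "cond2", "cond3")) {
      n <- config$violation_mix[[cond]]
      if (n == 0L) next
      for (k in seq_len(n)) {
        if (config$n_facilities < 2L) {
          stop_shareduse("violations need >= 2 facilities",
                         class = "shareduse_generation_error")
        }
        pair <- sample(facs, 2L)
        out[[length(out) + 1L]] <- list(
          kind = cond, source = pair[1], target = pair[2],
          modality = sample(config$modalities, 1L),
          fy = if (length(config$fiscal_years) == 1L) config$fiscal_years
               else sample(config$fiscal_years, 1L))
      }
    }
    out
  })
  ep <- c(ep, viol)
  if (length(ep) > config$n_patients) {
    stop_shareduse("config infeasible: ", length(ep), " planted episodes ",
                   "but only ", config$n_patients, " patients",
                   class = "shareduse_generation_error")
  }

  pids <- .patient_ids(config$n_patients)
  all_visits <- vector("list", config$n_patients)
  truth_events <- list()
  truth_nonevents <- list()
  max_retries <- 50L

  simulate_patient <- function(i, pid) {
      episode <- if (i <= length(ep)) ep[[i]] else NULL
      base_rows <- NULL
      expected <- NULL
      if (!is.null(episode)) {
        built <- .build_episode(episode$kind, episode$source, episode$target,
                                episode$modality, episode$fy,
                                config$study_start, config$study_end)
        base_rows <- built$rows
        if (episode$kind == "event") {
          expected <- data.frame(
            patient_id = pid, source_facility_id = episode$source,
            target_facility_id = episode$target,
            exam_date = as.Date(built$exam_day, origin = "1970-01-01"),
            modality = episode$modality, fiscal_year = episode$fy,
            stringsAsFactors = FALSE)
        } else {
          expected <- .empty_events()
        }
      }
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        n_noise <- if (config$noise_visit_rate > 0) {
          stats::rpois(1L, config$noise_visit_rate)
        } else 0L
        noise_rows <- if (n_noise > 0L) {
          data.frame(
            facility_id = sample(facs, n_noise, replace = TRUE),
            day = sample(seq(as.integer(config$study_start),
                             as.integer(config$study_end)), n_noise,
                         replace = TRUE),
            is_imaging_exam = FALSE, modality = "NONE",
            stringsAsFactors = FALSE)
        } else NULL
        rows <- rbind(base_rows, noise_rows)
        if (is.null(rows) || nrow(rows) == 0L) {
          return(list(rows = NULL, episode = episode, exam_day = NA))
        }
        if (!any(rows$is_imaging_exam)) {
          return(list(rows = rows, episode = episode, exam_day = NA))
        }
        # verification pass: the oracle on this patient alone must return
        # exactly the intended events
        pc <- .single_patient_claims(pid, rows, config$study_start,
                                     config$study_end, facilities)
        img <- pc$visits[pc$visits$is_imaging_exam, , drop = FALSE]
        strata <- unique(data.frame(modality = img$modality,
                                    fy = fiscal_year(img$service_date),
                                    stringsAsFactors = FALSE))
        got <- list()
        for (s in seq_len(nrow(strata))) {
          got[[s]] <- brute_force_oracle(pc, strata$modality[s],
                                         strata$fy[s])
        }
        got <- do.call(rbind, got)
        ok <- if (is.null(expected) || nrow(expected) == 0L) {
          nrow(got) == 0L
        } else {
          nrow(got) == nrow(expected) &&
            all(got$source_facility_id == expected$source_facility_id) &&
            all(got$target_facility_id == expected$target_facility_id) &&
            all(got$exam_date == expected$exam_date) &&
            all(got$modality == expected$modality)
        }
        if (ok) {
          return(list(rows = rows, episode = episode,
                      exam_day = if (!is.null(episode)) {
                        as.integer(pc$visits$service_date[
                          pc$visits$is_imaging_exam][1])
                      } else NA,
                      built_exam = if (!is.null(base_rows)) {
                        base_rows$day[base_rows$is_imaging_exam][1]
                      } else NA))
        }
        if (attempt > max_retries) {
          stop_shareduse("noise rejection sampling failed for patient ", pid,
                         " after ", max_retries, " retries",
                         class = "shareduse_generation_error")
        }
      }
  }

  for (i in seq_len(config$n_patients)) {
    pid <- pids[i]
    res <- with_substream(config$seed, i, simulate_patient(i, pid))
    if (!is.null(res$rows)) {
      res$rows <- data.frame(patient_id = pid, res$rows,
                             stringsAsFactors = FALSE)
      all_visits[[i]] <- res$rows
    }
    if (!is.null(res$episode)) {
      exam_date <- as.Date(res$built_exam, origin = "1970-01-01")
      rec <- data.frame(
        patient_id = pid, source_facility_id = res$episode$source,
        target_facility_id = res$episode$target, exam_date = exam_date,
        modality = res$episode$modality, fiscal_year = res$episode$fy,
        stringsAsFactors = FALSE)
      if (res$episode$kind == "event") {
        truth_events[[length(truth_events) + 1L]] <- rec
      } else {
        rec$violated_condition <- as.integer(sub("cond", "", res$episode$kind))
        truth_nonevents[[length(truth_nonevents) + 1L]] <- rec
      }
    }
  }

  visits <- do.call(rbind, all_visits[!vapply(all_visits, is.null, TRUE)])
  if (is.null(visits)) {
    visits <- data.frame(patient_id = character(), facility_id = character(),
                         day = integer(), is_imaging_exam = logical(),
                         modality = character(), stringsAsFactors = FALSE)
  }
  visits$service_date <- as.Date(visits$day, origin = "1970-01-01")
  visits$day <- NULL
  visits <- unique(visits[, c("patient_id", "facility_id", "service_date",
                              "is_imaging_exam", "modality")])
  enrollments <- data.frame(patient_id = pids,
                            start_date = config$study_start,
                            end_date = config$study_end,
                            stringsAsFactors = FALSE)
  claims <- claims_table(visits, enrollments, facilities)

  events <- if (length(truth_events)) {
    .sort_events(do.call(rbind, truth_events))
  } else .empty_events()
  non_events <- if (length(truth_nonevents)) {
    ne <- do.call(rbind, truth_nonevents)
    ne[order(ne$exam_date, ne$patient_id), , drop = FALSE]
  } else {
    cbind(.empty_events(), violated_condition = integer())
  }
  rownames(non_events) <- NULL

  list(claims = claims,
       truth = list(events = events, non_events = non_events,
                    community_of = community_of, edges = edges))
}
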