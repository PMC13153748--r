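# Fixture builders. Dates are expressed as day offsets from the FY2016 start
# so that toy episodes ("exam on day 100") read like the rule definitions.

.base_date <- as.Date("2016-04-01")
day <- function(n) .base_date + n

make_claims <- function(visits,
                        enrollments = NULL,
                        facilities = NULL) {
  if (is.null(enrollments)) {
    enrollments <- data.frame(
      patient_id = unique(visits$patient_id),
      start_date = .base_date,
      end_date = .base_date + 1460,
      stringsAsFactors = FALSE)
  }
  if (is.null(facilities)) {
    facilities <- data.frame(
      facility_id = sort(unique(visits$facility_id)),
      bed_count = 0L, stringsAsFactors = FALSE)
  }
  claims_table(visits, enrollments, facilities)
}

visit_row <- function(patient, facility, d, modality = "NONE") {
  data.frame(patient_id = patient, facility_id = facility,
             service_date = d,
             is_imaging_exam = modality != "NONE",
             modality = modality, stringsAsFactors = FALSE)
}

# The canonical 3-visit shared-use episode: source visits on days 70 and 130
# at S, one isolated CT on day 100 at T.
toy_episode_claims <- function(extra = NULL) {
  v <- rbind(
    visit_row("P1", "S", day(70)),
    visit_row("P1", "S", day(130)),
    visit_row("P1", "T", day(100), "CT"),
    extra)
  make_claims(v)
}

toy_exam <- function(patient = "P1", facility = "T", d = day(100),
                     modality = "CT") {
  list(patient_id = patient, facility_id = facility, service_date = d,
       modality = modality)
}

# A random generator configuration whose patient count is sized to fit the
# planted episodes (one episode per patient) plus noise-only patients.
random_generator_config <- function(seed) {
  args <- list(
    n_facilities = 8L + (seed %% 9L),
    n_patients = 1L,
    n_communities = 2L,
    within_community_prob = 0.2,
    between_community_prob = 0.04,
    reciprocity_fraction = 0.2,
    events_per_edge = 1L + (seed %% 2L),
    noise_visit_rate = 2,
    violation_mix = c(cond1 = seed %% 3L, cond2 = (seed + 1L) %% 3L,
                      cond3 = (seed + 2L) %% 3L),
    seed = seed)
  cfg <- do.call(generator_config, args)
  n_ep <- sum(plant_network(cfg)$n_events) + sum(cfg$violation_mix)
  args$n_patients <- n_ep + 10L
  do.call(generator_config, args)
}

events_frame <- function(src, tgt, modality = "CT", fy = 2016L,
                         patient = NULL) {
  data.frame(
    patient_id = if (length(src)) patient %||% paste0("P", seq_along(src))
                 else character(),
    source_facility_id = src, target_facility_id = tgt,
    exam_date = rep(as.Date(sprintf("%d-06-01", fy)), length(src)),
    modality = rep(modality, length(src)),
    fiscal_year = rep(as.integer(fy), length(src)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

event_key <- function(ev) {
  paste(ev$patient_id, ev$source_facility_id, ev$target_facility_id,
        format(ev$exam_date), ev$modality, ev$fiscal_year, sep = "|")
}

# Events table realizing a planted edge table (weights = n_events), for
# building networks directly from plant_network() output.
edges_to_events <- function(edges) {
  ex <- edges[rep(seq_len(nrow(edges)), edges$n_events), , drop = FALSE]
  events_frame(ex$source, ex$target, modality = ex$modality[1],
               fy = ex$fiscal_year[1],
               patient = paste0("P", seq_len(nrow(ex))))
}
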