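#' Proportion of shared use per 100 examinations
#'
#' The annual-summary "proportion" column is shared exams per 100 total
#' exams (a percentage), displayed to 3 decimals: 1507 shared of 287,782
#' total prints as 0.524.
#'
#' @param shared,total nonnegative counts (`shared <= total`).
#' @param digits display rounding (default 3); `NULL` for full precision.
#' @return numeric; `NA` when `total` is 0.
#' @export
shared_use_proportion <- function(shared, total, digits = 3) {
  p <- ifelse(total > 0, 100 * shared / total, NA_real_)
  if (!is.null(digits)) p <- round(p, digits) else p
}

#' Annual examination volumes and shared-use proportions
#'
#' One row per (fiscal year, modality) stratum: total imaging exams of that
#' modality in the claims, detected shared-use events, and the proportion of
#' collaborative use per 100 examinations (full precision in
#' `proportion_per_100`, display rounding in `proportion_display`).
#'
#' @param claims the (filtered) [claims_table()] the events were detected
#'   from.
#' @param events data.frame of detected events across strata
#'   (see [detect_all_strata()]).
#' @return data.frame of `VolumeSummaryRow`s sorted by modality, year.
#' @export
volume_summary <- function(claims, events) {
  stopifnot(inherits(claims, "claims_table"))
  v <- claims$visits
  img <- v[v$is_imaging_exam, , drop = FALSE]
  img_fy <- fiscal_year(img$service_date)
  strata <- unique(rbind(
    data.frame(modality = img$modality, fiscal_year = img_fy,
               stringsAsFactors = FALSE),
    data.frame(modality = events$modality, fiscal_year = events$fiscal_year,
               stringsAsFactors = FALSE)))
  if (nrow(strata) == 0L) {
    return(data.frame(fiscal_year = integer(), modality = character(),
                      total_exams = integer(), shared_exams = integer(),
                      proportion_per_100 = numeric(),
                      proportion_display = numeric(),
                      stringsAsFactors = FALSE))
  }
  strata <- strata[order(strata$modality, strata$fiscal_year), , drop = FALSE]
  out <- lapply(seq_len(nrow(strata)), function(i) {
    m <- strata$modality[i]; y <- strata$fiscal_year[i]
    total <- sum(img$modality == m & img_fy == y)
    shared <- sum(events$modality == m & events$fiscal_year == y)
    data.frame(fiscal_year = y, modality = m, total_exams = total,
               shared_exams = shared,
               proportion_per_100 = shared_use_proportion(shared, total,
                                                          digits = NULL),
               proportion_display = shared_use_proportion(shared, total),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Source/target facility summaries per stratum
#'
#' For each (fiscal year, modality) stratum and each role: the number of
#' distinct facilities, the mean and sample SD (n-1 denominator) of
#' per-facility event counts (requests made, for sources; requests received,
#' for targets), and the mean/SD of bed counts over those facilities. SDs
#' are `NA` when fewer than two facilities hold the role.
#'
#' @param claims a [claims_table()] supplying bed counts.
#' @param events data.frame of detected events across strata.
#' @return data.frame of `FacilitySummaryRow`s.
#' @export
facility_summary <- function(claims, events) {
  stopifnot(inherits(claims, "claims_table"))
  beds <- stats::setNames(claims$facilities$bed_count,
                          claims$facilities$facility_id)
  strata <- unique(data.frame(modality = events$modality,
                              fiscal_year = events$fiscal_year,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$modality, strata$fiscal_year), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    m <- strata$modality[i]; y <- strata$fiscal_year[i]
    ev <- events[events$modality == m & events$fiscal_year == y, ,
                 drop = FALSE]
    for (role in c("source", "target")) {
      col <- paste0(role, "_facility_id")
      counts <- table(ev[[col]])
      k <- length(counts)
      fac_beds <- beds[names(counts)]
      rows[[length(rows) + 1L]] <- data.frame(
        fiscal_year = y, modality = m, role = role, facility_count = k,
        requests_mean = if (k > 0) mean(as.numeric(counts)) else NA_real_,
        requests_sd = if (k > 1) stats::sd(as.numeric(counts)) else NA_real_,
        beds_mean = if (k > 0) mean(fac_beds) else NA_real_,
        beds_sd = if (k > 1) stats::sd(fac_beds) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(fiscal_year = integer(), modality = character(),
                      role = character(), facility_count = integer(),
                      requests_mean = numeric(), requests_sd = numeric(),
                      beds_mean = numeric(), beds_sd = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-stratum network metric table
#'
#' Builds one network per (fiscal year, modality) stratum present in
#' `events` and tabulates node/edge counts, density and reciprocity.
#'
#' @param events data.frame of detected events across strata.
#' @param reciprocity_convention `"dyadic"` (default) or `"edgewise"`.
#' @return list with `metrics` (data.frame: `fiscal_year`, `modality`, `n`,
#'   `m`, `density`, `reciprocity`) and `networks` (named list of
#'   `shared_use_network`s keyed `"<modality>_<fy>"`).
#' @export
network_metrics <- function(events, reciprocity_convention = "dyadic") {
  strata <- unique(data.frame(modality = events$modality,
                              fiscal_year = events$fiscal_year,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$modality, strata$fiscal_year), , drop = FALSE]
  nets <- list()
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    m <- strata$modality[i]; y <- strata$fiscal_year[i]
    net <- build_network(events[events$modality == m &
                                  events$fiscal_year == y, , drop = FALSE])
    nets[[paste0(m, "_", y)]] <- net
    rows[[i]] <- data.frame(
      fiscal_year = y, modality = m, n = net$n, m_edges = net$m,
      density = suppressWarnings(network_density(net)),
      reciprocity = suppressWarnings(
        network_reciprocity(net, reciprocity_convention)),
      stringsAsFactors = FALSE)
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiscal_year = integer(), modality = character(),
               n = integer(), m_edges = integer(), density = numeric(),
               reciprocity = numeric(), stringsAsFactors = FALSE)
  rownames(metrics) <- NULL
  list(metrics = metrics, networks = nets)
}

#' Run the full shared-use analysis pipeline
#'
#' Executes the five stages — extract the study population, detect
#' shared-use events, build per-stratum referral networks, detect
#' communities, and tabulate annual summaries — and optionally writes all
#' outputs (CSV + GraphML) under `out_dir`. The configuration is a list (or
#' a YAML file path) with elements:
#' \describe{
#'   \item{input}{list with `visits`, `enrollments`, `facilities` CSV paths
#'     — or instead}
#'   \item{generator}{list of [generator_config()] arguments for a synthetic
#'     run}
#'   \item{study_start, study_end}{study window (default FY2016-FY2019)}
#'   \item{detection}{list of [detection_params()] arguments}
#'   \item{network}{list: `seed`, `resolution`,
#'     `reciprocity_convention`}
#' }
#' Reruns with the same configuration and seed are byte-identical.
#'
#' @param config list or YAML file path.
#' @param out_dir optional output directory.
#' @return invisibly, a list: `claims`, `exclusions`, `events`, `volume`,
#'   `facility`, `metrics`, `networks`, `communities`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- do.call(detection_params, config$detection %||% list())
  netcfg <- config$network %||% list()
  study_start <- as.Date(config$study_start %||% "2016-04-01")
  study_end <- as.Date(config$study_end %||% "2020-03-31")

  # stage 1: load / generate and extract the study population
  if (!is.null(config$generator)) {
    gen <- generate_claims(do.call(generator_config, config$generator))
    claims <- gen$claims
    message("stage 1 [extract]: generated ", nrow(claims$visits),
            " visit rows for ", nrow(claims$enrollments), " patients")
  } else if (!is.null(config$input)) {
    claims <- read_claims(config$input$visits, config$input$enrollments,
                          config$input$facilities)
    message("stage 1 [extract]: read ", nrow(claims$visits), " visit rows")
  } else {
    stop_shareduse("pipeline config needs either 'input' or 'generator'",
                   class = "shareduse_config_error")
  }
  claims <- filter_population(claims, study_start, study_end)
  excl <- attr(claims, "exclusions")
  message("stage 1 [extract]: retained ",
          length(unique(claims$enrollments$patient_id)), " patients (",
          excl$coverage_gap, " coverage-gap, ", excl$no_exam,
          " no-exam exclusions)")

  # stage 2: shared-use detection per stratum
  fys <- fiscal_year(study_start):fiscal_year(study_end - 1)
  events <- detect_all_strata(claims, modalities = c("CT", "MRI"),
                              fiscal_years = fys, params = params)
  message("stage 2 [detect]: ", nrow(events), " shared-use events")

  # stages 3-4: networks, metrics, communities
  nm <- network_metrics(events,
                        netcfg$reciprocity_convention %||% "dyadic")
  message("stage 3 [network]: ", length(nm$networks), " strata networks")
  communities <- list()
  comm_rows <- list()
  for (key in names(nm$networks)) {
    part <- louvain_communities(nm$networks[[key]],
                                seed = netcfg$seed %||% 0L,
                                resolution = netcfg$resolution %||% 1.0)
    communities[[key]] <- part
    if (length(part$membership)) {
      comm_rows[[key]] <- data.frame(
        modality = nm$networks[[key]]$modality,
        fiscal_year = nm$networks[[key]]$fiscal_year,
        facility_id = names(part$membership),
        community = unname(part$membership),
        Q = part$Q, stringsAsFactors = FALSE)
    }
  }
  comm_df <- if (length(comm_rows)) do.call(rbind, comm_rows) else
    data.frame(modality = character(), fiscal_year = integer(),
               facility_id = character(), community = integer(),
               Q = numeric(), stringsAsFactors = FALSE)
  rownames(comm_df) <- NULL
  message("stage 4 [communities]: ",
          sum(vapply(communities,
                     function(p) length(unique(p$membership)), 0L)),
          " communities across strata")

  # stage 5: annual summary tables
  volume <- volume_summary(claims, events)
  facility <- facility_summary(claims, events)
  message("stage 5 [report]: ", nrow(volume), " volume rows, ",
          nrow(facility), " facility rows")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ev_out <- events
    ev_out$exam_date <- format(ev_out$exam_date, "%Y-%m-%d")
    data.table::fwrite(ev_out, file.path(out_dir, "events.csv"))
    data.table::fwrite(volume, file.path(out_dir, "volume_summary.csv"))
    data.table::fwrite(facility, file.path(out_dir, "facility_summary.csv"))
    data.table::fwrite(nm$metrics, file.path(out_dir, "network_metrics.csv"))
    data.table::fwrite(comm_df, file.path(out_dir, "communities.csv"))
    for (key in names(nm$networks)) {
      export_network(nm$networks[[key]],
                     file.path(out_dir, paste0("network_", key, ".graphml")),
                     format = "graphml", partition = communities[[key]])
    }
  }

  invisible(list(claims = claims, exclusions = excl, events = events,
                 volume = volume, facility = facility,
                 metrics = nm$metrics, networks = nm$networks,
                 communities = communities))
}
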