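#!/usr/bin/env Rscript

# Stage 1: simulate a scaled-down synthetic prefecture.
#
# The real claims (a prefectural National Health Insurance / Late-Stage
# Elderly receipt database) are not shareable, so the analysis runs on
# synthetic claims with a planted shared-use network: 60 facilities in 4
# collaborative communities, FY2016-FY2019, with noise visits and a few
# injected rule violations. Ground truth (planted events, violations,
# community labels) is written alongside for the downstream checks.

library(shareduse)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- list(
  n_facilities = 60L, n_patients = 1L, n_communities = 4L,
  within_community_prob = 0.25, between_community_prob = 0.01,
  events_per_edge = 2L, reciprocity_fraction = 0.15,
  noise_visit_rate = 3, violation_mix = c(cond1 = 5L, cond2 = 5L,
                                          cond3 = 5L),
  seed = 20160401L)
n_ep <- sum(plant_network(do.call(generator_config, base))$n_events) +
  sum(base$violation_mix)
base$n_patients <- n_ep + 60L  # noise-only patients round out the cohort
cfg <- do.call(generator_config, base)

gen <- generate_claims(cfg)
print(gen$claims)

write_claims(gen$claims, out)
truth <- gen$truth
ev <- truth$events
ev$exam_date <- format(ev$exam_date, "%Y-%m-%d")
data.table::fwrite(ev, file.path(out, "truth_events.csv"))
ne <- truth$non_events
ne$exam_date <- format(ne$exam_date, "%Y-%m-%d")
data.table::fwrite(ne, file.path(out, "truth_non_events.csv"))
data.table::fwrite(data.frame(facility_id = names(truth$community_of),
                              community = unname(truth$community_of)),
                   file.path(out, "truth_communities.csv"))

cat(sprintf(
  "simulated %d visit rows, %d patients, %d facilities\n",
  nrow(gen$claims$visits), nrow(gen$claims$enrollments),
  nrow(gen$claims$facilities)))
cat(sprintf("planted %d shared-use events on %d directed edges; %d rule",
            nrow(truth$events), nrow(truth$edges), nrow(truth$non_events)),
    "violations injected\n")
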