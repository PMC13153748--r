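test_that("Condition 1 isolates an exam within +/-91 days at its facility", {
  # no other exam at T: vacuously isolated
  expect_true(condition1_isolated(toy_exam(), toy_episode_claims()))
  # a second imaging exam of the *other* modality 50 days later blocks it
  cl <- toy_episode_claims(visit_row("P1", "T", day(150), "MRI"))
  expect_false(condition1_isolated(toy_exam(), cl))
  # a second CT 100 days later (gap > 91) does not
  cl <- toy_episode_claims(visit_row("P1", "T", day(200), "CT"))
  expect_true(condition1_isolated(toy_exam(), cl))
  # brute-force confirmation: every 91-day window containing day 100 holds
  # exactly one exam
  exam_days <- c(100, 200)
  counts <- vapply((100 - 91):100, function(w0) {
    sum(exam_days >= w0 & exam_days <= w0 + 91)
  }, 0L)
  expect_true(all(counts == 1L))
  # exams at a different facility never affect Condition 1
  cl <- toy_episode_claims(visit_row("P1", "U", day(110), "CT"))
  expect_true(condition1_isolated(toy_exam(), cl))
})

test_that("qualifying sources need a bracketing pair within 182 days and no source-side imaging", {
  cand <- qualifying_sources(toy_exam(), toy_episode_claims())
  expect_identical(cand$facility_id, "S")
  expect_identical(cand$window_start, day(70))
  expect_identical(cand$window_end, day(130))
  expect_identical(cand$visit_count, 2L)
  expect_identical(cand$nearest_gap, 30L)
  # exhaustive pair enumeration agrees there is exactly that one window
  dates <- c(70, 130)
  pairs <- expand.grid(u = dates, v = dates)
  ok <- with(pairs, u < v & u <= 100 & 100 <= v & v - u <= 182)
  expect_identical(sum(ok), 1L)

  # span > 182: not qualifying
  v <- rbind(visit_row("P1", "S", day(70)), visit_row("P1", "S", day(300)),
             visit_row("P1", "T", day(100), "CT"))
  expect_identical(nrow(qualifying_sources(toy_exam(), make_claims(v))), 0L)
  # exam not bracketed: not qualifying
  v <- rbind(visit_row("P1", "S", day(120)), visit_row("P1", "S", day(150)),
             visit_row("P1", "T", day(100), "CT"))
  expect_identical(nrow(qualifying_sources(toy_exam(), make_claims(v))), 0L)
  # an imaging exam at the source inside the window disqualifies it
  v <- rbind(visit_row("P1", "S", day(70)), visit_row("P1", "S", day(130)),
             visit_row("P1", "S", day(90), "MRI"),
             visit_row("P1", "T", day(100), "CT"))
  expect_identical(nrow(qualifying_sources(toy_exam(), make_claims(v))), 0L)
  # single visit is not "multiple visits"
  v <- rbind(visit_row("P1", "S", day(100)),
             visit_row("P1", "T", day(100), "CT"))
  expect_identical(nrow(qualifying_sources(toy_exam(), make_claims(v))), 0L)
  # tightest bracket is reported when several qualify
  v <- rbind(visit_row("P1", "S", day(10)), visit_row("P1", "S", day(80)),
             visit_row("P1", "S", day(120)), visit_row("P1", "S", day(170)),
             visit_row("P1", "T", day(100), "CT"))
  cand <- qualifying_sources(toy_exam(), make_claims(v))
  expect_identical(cand$window_start, day(80))
  expect_identical(cand$window_end, day(120))
  expect_identical(cand$visit_count, 2L)
})

test_that("source selection prefers nearest gap, then visit count, then id", {
  cand <- data.frame(facility_id = c("S1", "S2"),
                     visit_count = c(2L, 2L), nearest_gap = c(5L, 20L))
  expect_identical(select_source(cand), "S1")
  cand$nearest_gap <- c(10L, 10L); cand$visit_count <- c(3L, 2L)
  expect_identical(select_source(cand), "S1")
  cand <- data.frame(facility_id = c("B", "A"), visit_count = 2L,
                     nearest_gap = 10L)
  expect_identical(select_source(cand), "A")
  expect_identical(select_source(cand[0, ]), NA_character_)
})

test_that("the toy episode yields exactly one event; a nearby second exam kills it", {
  ev <- detect_shared_use(toy_episode_claims(), "CT", 2016)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$source_facility_id, "S")
  expect_identical(ev$target_facility_id, "T")
  expect_identical(ev$exam_date, day(100))
  expect_identical(ev$fiscal_year, 2016L)
  # oracle agrees
  expect_identical(brute_force_oracle(toy_episode_claims(), "CT", 2016), ev)

  cl <- toy_episode_claims(visit_row("P1", "T", day(140), "CT"))
  expect_identical(nrow(detect_shared_use(cl, "CT", 2016)), 0L)
  expect_identical(nrow(brute_force_oracle(cl, "CT", 2016)), 0L)
  # empty claims
  empty <- make_claims(visit_row("P", "A", day(1))[0, , drop = FALSE],
                       enrollments = data.frame(patient_id = character(),
                                                start_date = day(0)[0],
                                                end_date = day(0)[0]),
                       facilities = data.frame(facility_id = "A",
                                               bed_count = 0L))
  expect_identical(nrow(detect_shared_use(empty, "CT", 2016)), 0L)
})

test_that("detection output is invariant to input row order", {
  g <- generate_claims(random_generator_config(3L))
  cl <- g$claims
  ev1 <- detect_shared_use(cl, "CT", 2017)
  set.seed(99)
  shuffled <- cl
  perm <- sample(nrow(cl$visits))
  shuffled$visits <- cl$visits[perm, , drop = FALSE]
  rownames(shuffled$visits) <- NULL
  ev2 <- detect_shared_use(shuffled, "CT", 2017)
  expect_identical(event_key(ev1), event_key(ev2))
})

test_that("window monotonicity: shrinking isolation relaxes, shrinking continuity restricts", {
  for (s in c(1L, 6L)) {
    g <- generate_claims(random_generator_config(s))
    cl <- g$claims
    for (m in c("CT", "MRI")) {
      base <- detect_shared_use(cl, m, 2018,
                                detection_params(91, 182, "all"))
      # smaller isolation window relaxes Condition 1: superset of events
      wide <- detect_shared_use(cl, m, 2018,
                                detection_params(45, 182, "all"))
      expect_true(all(event_key(base) %in% event_key(wide)))
      # smaller continuity window restricts Conditions 2-3: subset
      narrow <- detect_shared_use(cl, m, 2018,
                                  detection_params(91, 120, "all"))
      expect_true(all(event_key(narrow) %in% event_key(base)))
    }
  }
})

test_that("policy nearest yields at most one event per exam; policy all at least as many", {
  g <- generate_claims(random_generator_config(4L))
  for (m in c("CT", "MRI")) for (y in 2016:2019) {
    near <- detect_shared_use(g$claims, m, y)
    all_ev <- detect_shared_use(g$claims, m, y,
                                detection_params(multi_source_policy = "all"))
    exam_id <- paste(near$patient_id, near$target_facility_id,
                     near$exam_date)
    expect_false(any(duplicated(exam_id)))
    expect_true(all(event_key(near) %in% event_key(all_ev)))
    expect_false(any(near$source_facility_id == near$target_facility_id))
  }
})

test_that("fast detector and brute-force oracle agree on noisy generated claims", {
  for (s in 10:19) {
    g <- generate_claims(random_generator_config(s))
    for (m in c("CT", "MRI")) for (y in 2016:2019) {
      expect_identical(detect_shared_use(g$claims, m, y),
                       brute_force_oracle(g$claims, m, y),
                       info = sprintf("seed %d %s FY%d", s, m, y))
    }
  }
})
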