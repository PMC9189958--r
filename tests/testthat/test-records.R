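test_that("vocabulary counts distinct persons and filters rare codes", {
  persons <- make_persons(3)
  ev <- rbind(make_events("t001", "A"), make_events("t001", "A", month = 5L),
              make_events("t002", "A"), make_events("t003", "B"))
  co <- new_cohort(persons, ev)
  v <- build_vocabulary(co, min_persons = 2L)
  expect_named(v$index, "A")
  expect_equal(unname(v$counts["A"]), 2L)  # repeats within a person count once
  v1 <- build_vocabulary(co, min_persons = 1L)
  expect_setequal(names(v1$index), c("A", "B"))
  expect_error(build_vocabulary(co, min_persons = 5L), "empty vocabulary")
})

test_that("vocabulary indices are contiguous from 1 in lexicographic order", {
  persons <- make_persons(2)
  ev <- make_events(c("t001", "t002", "t001"), c("Z9", "B2", "A1"))
  v <- build_vocabulary(new_cohort(persons, ev), 1L)
  expect_equal(v$index, c(A1 = 1L, B2 = 2L, Z9 = 3L))
})

test_that("vocabulary is monotone in the rarity threshold", {
  cfg <- sim_preset("linear", n_persons = 150, seed = 7)
  co <- generate_histories(cfg)$cohort
  prev <- names(build_vocabulary(co, 1L)$index)
  for (mp in c(3L, 10L, 25L)) {
    v <- tryCatch(build_vocabulary(co, mp), error = function(e) NULL)
    cur <- if (is.null(v)) character(0) else names(v$index)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("vocabulary matches an independent two-pass person-set scan", {
  cfg <- sim_preset("linear", n_persons = 2000, seed = 7)
  co <- generate_histories(cfg)$cohort
  v <- build_vocabulary(co, min_persons = 30L)
  # oracle: explicit per-code person sets
  sets <- split(co$events$person_id, co$events$code)
  keep <- names(sets)[vapply(sets, function(s) length(unique(s)), 0L) >= 30L]
  expect_setequal(names(v$index), keep)
})

test_that("encode_history computes gaps, drops unknown codes, keeps replicas", {
  persons <- make_persons(1)
  v <- build_vocabulary(
    new_cohort(make_persons(1), make_events("t001", c("A", "B"), month = c(0L, 1L))), 1L)
  ev <- make_events("t001", c("A", "B", "B"), month = c(3L, 7L, 7L))
  h <- encode_history(ev, v)
  expect_equal(h$delta, c(0L, 4L, 0L))
  # out-of-vocabulary event dropped before gap computation
  ev2 <- make_events("t001", c("A", "X", "B"), month = c(2L, 5L, 9L))
  h2 <- encode_history(ev2, v)
  expect_equal(h2$delta, c(0L, 7L))
  expect_equal(length(h2$token), 2L)
  # replicas of a multi-month hospitalization are all retained
  ev3 <- make_events("t001", rep("A", 3L), month = c(10L, 11L, 12L))
  h3 <- encode_history(ev3, v)
  expect_equal(h3$token, rep(v$index[["A"]], 3L))
  expect_equal(h3$delta, c(0L, 1L, 1L))
  # empty retained sequence is legal
  h4 <- encode_history(make_events("t001", "X"), v)
  expect_length(h4$token, 0L)
  expect_length(h4$delta, 0L)
})

test_that("encoded gaps are non-negative and never longer than raw events", {
  cfg <- sim_preset("linear", n_persons = 60, seed = 3)
  co <- generate_histories(cfg)$cohort
  v <- build_vocabulary(co, 5L)
  hs <- encode_cohort(co, v)
  raw <- table(factor(co$events$person_id, levels = co$persons$person_id))
  for (i in seq_along(hs)) {
    expect_lte(length(hs[[i]]$token), as.integer(raw[i]))
    expect_true(all(hs[[i]]$delta >= 0L))
    if (length(hs[[i]]$delta) > 0) expect_identical(hs[[i]]$delta[1L], 0L)
  }
})

test_that("covariate vector is zero exactly at the reference person", {
  persons <- make_persons(4)
  ctr <- fit_centering(persons)
  for (set in c("full", "reduced")) {
    X <- covariate_matrix(reference_person(ctr), ctr, set)
    expect_equal(unname(X[1L, ]), rep(0, ncol(X)))
  }
  expect_length(covariate_matrix(persons, ctr, "reduced")[1L, ],
                2L + length(ethnicity_levels()) - 1L)
})

test_that("interaction entries are exact products of their factors", {
  p <- make_persons(1, age = 60)
  p$bp_lowering <- TRUE
  ctr <- list(mean_age = 50, dep_ref = 3, ethnicity_ref = "European", sex = "F")
  X <- covariate_matrix(p, ctr, "full")
  expect_equal(unname(X[1L, "age"]), 10)
  expect_equal(unname(X[1L, "bp_lowering"]), 1)
  expect_equal(unname(X[1L, "age_x_bp_lowering"]), 10)
  p$diabetes <- TRUE
  X <- covariate_matrix(p, ctr, "full")
  expect_equal(unname(X[1L, "age_x_diabetes"]), 10)
  expect_equal(unname(X[1L, "bp_lowering_x_diabetes"]), 1)
  expect_error(covariate_matrix(transform(p, deprivation = 7), ctr, "full"),
               "deprivation")
})

test_that("cohort files round-trip exactly including event order", {
  cfg <- sim_preset("linear", n_persons = 40, seed = 9)
  co <- simulate_cohort(cfg)$cohort
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$persons, co$persons)
  expect_equal(co2$events, co$events)
  expect_equal(co2$lookback_months, co$lookback_months)
  # identical downstream vocabulary
  expect_equal(build_vocabulary(co2, 3L)$index, build_vocabulary(co, 3L)$index)
})

test_that("malformed cohort files are rejected with row-level messages", {
  persons <- make_persons(2, follow_up = c(100L, 200L), event = c(TRUE, FALSE))
  co <- new_cohort(persons, make_events("t001", "A"))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        colClasses = c(person_id = "character"))
  ev$month[1] <- -1L
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "row 1.*month", ignore.case = TRUE)
  ev$month[1] <- 0L
  ev$code_type[1] <- "mystery"
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "unknown code_type")
})
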