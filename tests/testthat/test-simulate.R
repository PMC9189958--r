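test_that("generation is reproducible and respects zero intensity", {
  cfg <- sim_preset("linear", n_persons = 80, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$persons, b$cohort$persons)
  expect_identical(a$cohort$events, b$cohort$events)
  expect_identical(a$truth$eta, b$truth$eta)
  cfg0 <- sim_preset("linear", n_persons = 30, seed = 5,
                     events_per_person_month = 0, redundancy_strength = 0)
  expect_identical(nrow(generate_histories(cfg0)$cohort$events), 0L)
})

test_that("earlier persons are unchanged when the cohort grows", {
  small <- generate_histories(sim_preset("linear", n_persons = 25, seed = 5))$cohort
  big <- generate_histories(sim_preset("linear", n_persons = 60, seed = 5))$cohort
  expect_identical(big$persons[1:25, ], small$persons)
})

test_that("event counts match the Poisson intensity", {
  cfg <- sim_preset("linear", n_persons = 2000, seed = 13,
                    redundancy_strength = 0)
  co <- generate_histories(cfg)$cohort
  mean_ev <- nrow(co$events) / 2000
  mu <- 60 * cfg$events_per_person_month
  se <- sqrt(mu / 2000)
  expect_lt(abs(mean_ev - mu), 3 * se)
})

test_that("no competing hazards and a vanishing baseline censor everyone at 5 years", {
  cfg <- sim_preset("linear", n_persons = 50, seed = 2,
                    baseline_hazard = 1e-12, noncvd_death_hazard = 0,
                    emigration_hazard = 0)
  co <- simulate_cohort(cfg)$cohort
  expect_true(all(!co$persons$cvd_event))
  expect_true(all(co$persons$follow_up_days == 1826L))
})

test_that("null-effect event fraction matches the exponential closed form", {
  cfg <- sim_preset("linear", n_persons = 20000, seed = 17,
                    covariate_effects = c(age = 0),
                    noncvd_death_hazard = 0, emigration_hazard = 0)
  co <- simulate_cohort(cfg)$cohort
  p_true <- 1 - exp(-1826 * cfg$baseline_hazard)
  p_hat <- mean(co$persons$cvd_event)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("a planted code doubles the true hazard of an otherwise identical person", {
  persons <- make_persons(2)
  ev <- make_events("t002", "D005", month = 59L)
  co <- new_cohort(persons, ev)
  cfg <- sim_preset("planted_code", n_persons = 2, seed = 1)
  eta <- true_eta(co, cfg)
  expect_equal(exp(eta[2] - eta[1]), 2)
  # recency weighting shrinks the boost for older listings
  cfg12 <- sim_preset("planted_code", n_persons = 2, seed = 1,
                      recency_timescale = 12)
  ev_old <- make_events("t002", "D005", month = 35L)
  eta12 <- true_eta(new_cohort(persons, ev_old), cfg12)
  expect_equal(eta12[2] - eta12[1], log(2) * exp(-(59 - 35) / 12))
})

test_that("event fraction is monotone in the baseline hazard", {
  fr <- vapply(c(1e-5, 3e-5, 9e-5), function(l0) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_preset("linear", n_persons = 400, seed = 20 + s,
                        baseline_hazard = l0)
      mean(simulate_cohort(cfg)$cohort$persons$cvd_event)
    }, 0))
  }, 0)
  expect_true(all(diff(fr) > 0))
})

test_that("with all effects zero the true risk score has no discrimination", {
  cfg <- sim_preset("linear", n_persons = 20000, seed = 23,
                    covariate_effects = c(age = 0))
  sim <- simulate_cohort(cfg)
  expect_equal(var(sim$truth$eta), 0)
  # score must be non-constant for C; use an independent random score
  set.seed(23)
  C <- harrells_c(rnorm(20000), sim$cohort$persons$follow_up_days,
                  sim$cohort$persons$cvd_event)
  expect_lt(abs(C - 0.5), 0.02)
})

test_that("Kaplan-Meier of null simulated times matches the exponential curve", {
  cfg <- sim_preset("linear", n_persons = 20000, seed = 29,
                    covariate_effects = c(age = 0),
                    noncvd_death_hazard = 0, emigration_hazard = 0)
  co <- simulate_cohort(cfg)$cohort
  fit <- survival::survfit(survival::Surv(follow_up_days, cvd_event) ~ 1,
                           data = co$persons)
  for (t in c(300, 900, 1500)) {
    i <- max(which(fit$time <= t))
    expect_lt(abs(fit$surv[i] - exp(-cfg$baseline_hazard * t)), 0.01)
  }
})
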