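test_that("Breslow baseline matches hand-computed sums", {
  # single event, all scores at the reference: increment 1/n
  bl <- breslow_baseline(rep(0, 8), time = c(5, rep(10, 7)),
                         event = c(TRUE, rep(FALSE, 7)), f_ref = 0)
  expect_equal(bl$cumhaz, 1 / 8)
  # 4-person toy set: times 2*, 3, 5*, 7 with relative risks 1, 2, 1, 2
  f <- c(0, log(2), 0, log(2))
  bl2 <- breslow_baseline(f, time = c(2, 3, 5, 7),
                          event = c(TRUE, FALSE, TRUE, FALSE), f_ref = 0)
  # hand evaluation: at t=2 the risk set is everyone (1+2+1+2 = 6);
  # at t=5 it is persons 3 and 4 (1+2 = 3)
  expect_equal(bl2$times, c(2, 5))
  expect_equal(bl2$cumhaz, c(1 / 6, 1 / 6 + 1 / 3))
  # step function: flat beyond the last event time, S(0) = 1
  expect_equal(baseline_survival(bl2, 0), 1)
  expect_equal(baseline_survival(bl2, 1826), exp(-0.5))
  expect_equal(baseline_survival(bl2, 5), baseline_survival(bl2, 1000))
  expect_error(breslow_baseline(f, c(2, 3, 5, 7), rep(FALSE, 4)), "no events")
})

test_that("five-year risk follows the power rule and is monotone in the score", {
  bl <- list(times = 100, cumhaz = -log(0.99), surv = 0.99, f_ref = 0)
  class(bl) <- "seqrisk_baseline"
  expect_equal(five_year_risk(0, bl), 1 - 0.99)
  expect_equal(five_year_risk(log(2), bl), 1 - 0.99^2)
  f <- seq(-3, 3, length.out = 30)
  expect_true(all(diff(five_year_risk(f, bl)) > 0))
  expect_true(all(five_year_risk(rnorm(50, 0, 5), bl) >= 0 &
                  five_year_risk(rnorm(50, 0, 5), bl) <= 1))
})

test_that("risks are invariant to the arbitrary reference constant", {
  set.seed(8)
  f <- rnorm(60)
  tm <- sample.int(1000L, 60L, replace = TRUE)
  ev <- runif(60) < 0.5
  bl0 <- breslow_baseline(f, tm, ev, f_ref = 0)
  bl1 <- breslow_baseline(f, tm, ev, f_ref = 2.5)
  r0 <- five_year_risk(f, bl0)
  r1 <- five_year_risk(f, bl1)
  expect_equal(r0, r1)
})

test_that("the local-HR harness applied to a Cox model is exact", {
  cfg <- sim_preset("linear", n_persons = 2500, seed = 53)
  co <- simulate_cohort(cfg)$cohort
  cx <- fit_cox(co)
  perts <- list(list(type = "covariate", name = "diabetes", value = TRUE,
                     label = "diabetes"),
                list(type = "covariate", name = "ethnicity", value = "Maori",
                     label = "eth"))
  hr <- local_hr(list(cx, cx), perts, sex = "F")
  expect_equal(hr$hr[1], unname(exp(cx$coefficients["diabetes"])))
  expect_equal(hr$hr[2], unname(exp(cx$coefficients["ethnicityMaori"])))
  expect_equal(hr$ci_low, hr$hr)   # identical replicates collapse the CI
  expect_equal(hr$ci_high, hr$hr)
  expect_error(local_hr(list(cx), perts), "K >= 2")
})

test_that("identity perturbations give local HR exactly 1", {
  cfg0 <- sim_preset("linear", n_persons = 300, seed = 59)
  co <- simulate_cohort(cfg0)$cohort
  reps <- list(tiny_ensemble(co, seed = 1L), tiny_ensemble(co, seed = 2L))
  hr <- local_hr(reps, list(list(type = "covariate", name = "diabetes",
                                 value = FALSE, label = "noop")), sex = "F")
  expect_identical(hr$hr, 1)
  expect_identical(c(hr$ci_low, hr$ci_high), c(1, 1))
})

test_that("constant replicate shifts produce a degenerate CI at the shift", {
  shift_model <- function(d) list(
    predict = function(persons, events, lookback)
      rep(d * (nrow(events) > 0), nrow(persons)),
    centering = list(mean_age = 50, dep_ref = 3, ethnicity_ref = "European",
                     sex = "F"))
  reps <- list(shift_model(log(2)), shift_model(log(2)), shift_model(log(2)))
  hr <- local_hr(reps, list(list(type = "code", code = "X1",
                                 code_type = "primary_dx", label = "X1")))
  expect_equal(hr$hr, 2)
  expect_equal(c(hr$ci_low, hr$ci_high), c(2, 2))
  expect_equal(hr$K, 3L)
})

test_that("local HRs are invariant to a constant offset within a replicate", {
  cfg0 <- sim_preset("linear", n_persons = 300, seed = 61)
  co <- simulate_cohort(cfg0)$cohort
  ens <- tiny_ensemble(co, seed = 3L)
  off <- list(predict = function(persons, events, lookback)
                as.numeric(predict_log_risk(ens, new_cohort(persons, events, lookback))) + 4.2,
              centering = ens$centering)
  pert <- list(list(type = "covariate", name = "bp_lowering", value = TRUE,
                    label = "bp"))
  hr_raw <- local_hr(list(ens, ens), pert, sex = "F")
  hr_off <- local_hr(list(off, off), pert, sex = "F")
  expect_equal(hr_off$hr, hr_raw$hr)
})
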