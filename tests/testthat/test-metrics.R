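test_that("concordance equals the exhaustive all-pairs oracle", {
  set.seed(101)
  for (k in 1:25) {
    inst <- random_survival_instance(sample(20:120, 1L))
    if (!any(inst$event)) inst$event[1] <- TRUE
    expect_equal(harrells_c(inst$f, inst$time, inst$event),
                 brute_force_c(inst$f, inst$time, inst$event),
                 tolerance = 1e-12)
  }
})

test_that("concordance hits its boundary cases", {
  tm <- c(1, 2, 3, 4, 5)
  ev <- rep(TRUE, 5)
  expect_equal(harrells_c(5:1, tm, ev), 1)        # perfect ordering
  expect_equal(harrells_c(rep(2, 5), tm, ev), 0.5) # all prediction ties
  expect_error(harrells_c(1, 5, FALSE), "no comparable pairs")
})

test_that("D and explained variation behave as a rank-based statistic", {
  set.seed(7)
  f <- rnorm(300)
  tm <- rexp(300, exp(f) * 0.01)
  ev <- runif(300) < 0.8
  a <- royston_d_r2(f, tm, ev)
  b <- royston_d_r2(exp(f), tm, ev)  # strictly increasing transform
  expect_equal(a$D, b$D, tolerance = 1e-10)
  kappa <- sqrt(8 / pi)
  expect_equal(a$R2, (a$D^2 / kappa^2) / (pi^2 / 6 + a$D^2 / kappa^2),
               tolerance = 1e-12)
  cst <- royston_d_r2(rep(1, 300), tm, ev)
  expect_equal(cst$D, 0)
  expect_equal(cst$R2, 0)
  expect_true(cst$constant)
})

test_that("permuted predictions carry no discrimination", {
  set.seed(9)
  cfg <- sim_preset("linear", n_persons = 10000, seed = 67)
  co <- simulate_cohort(cfg)$cohort
  eta <- true_eta(co, cfg)
  f_perm <- sample(eta)
  C <- harrells_c(f_perm, co$persons$follow_up_days, co$persons$cvd_event)
  expect_lt(abs(C - 0.5), 0.02)
  r2 <- royston_d_r2(f_perm, co$persons$follow_up_days,
                     co$persons$cvd_event)$R2
  expect_lt(r2, 0.01)
})

test_that("Brier score matches perfect and coin-flip forecasters without censoring", {
  tm <- c(10, 20, 30, 40)
  ev <- c(TRUE, TRUE, TRUE, TRUE)
  grid <- c(15, 25, 35)
  S_perfect <- t(vapply(tm, function(ti) as.numeric(grid < ti), numeric(3)))
  ib <- integrated_brier(S_perfect, grid, tm, ev)
  expect_equal(ib$bs, rep(0, 3))
  expect_equal(ib$ibs, 0)
  ib5 <- integrated_brier(0.5, grid, tm, ev)
  expect_equal(ib5$bs, rep(0.25, 3))
  expect_equal(ib5$ibs, 0.25)
})

test_that("IPCW Brier matches a fully hand-expanded sum on a censored toy set", {
  tm <- c(2, 4, 5, 7, 9)
  ev <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  grid <- c(4, 6)
  set.seed(3)
  S <- matrix(runif(10), 5, 2)
  # censoring KM: censorings at t=4 (4 at risk) and t=9 (1 at risk)
  # G(t) = 1 for t < 4; 3/4 for 4 <= t < 9;  G(2-) = 1, G(4-) = 1, G(5-) = 3/4
  bs4 <- (S[1, 1]^2 / 1 +                       # event at 2 <= 4
          0 +                                   # censored at 4 drops out
          (1 - S[3, 1])^2 / (3 / 4) +           # still at risk at 4
          (1 - S[4, 1])^2 / (3 / 4) +
          (1 - S[5, 1])^2 / (3 / 4)) / 5
  bs6 <- (S[1, 2]^2 / 1 +
          0 +
          S[3, 2]^2 / (3 / 4) +                 # event at 5 <= 6, G(5-)
          (1 - S[4, 2])^2 / (3 / 4) +
          (1 - S[5, 2])^2 / (3 / 4)) / 5
  ib <- integrated_brier(S, grid, tm, ev)
  expect_equal(ib$bs, c(bs4, bs6), tolerance = 1e-12)
  expect_equal(ib$ibs, (bs4 + bs6) / 2, tolerance = 1e-12)
})

test_that("decile tables partition the cohort and conserve events", {
  set.seed(5)
  n <- 500
  risk <- runif(n)
  tm <- sample.int(1826L, n, replace = TRUE)
  ev <- runif(n) < risk * 0.5
  tab <- decile_table(risk, tm, ev)
  expect_equal(sum(tab$n), n)
  expect_true(max(tab$n) - min(tab$n) <= 1)
  expect_equal(sum(tab$event_share), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$mean_predicted) > 0))
  # degenerate separation: all events in the top decile
  risk2 <- seq(0, 1, length.out = 100)
  ev2 <- risk2 > 0.95
  tab2 <- decile_table(risk2, rep(1000L, 100), ev2, observed = "raw")
  expect_equal(tab2$event_share, c(rep(0, 9), 1))
})

test_that("stratified metrics agree with manual subsetting and partition the cohort", {
  cfg <- sim_preset("linear", n_persons = 3000, seed = 71)
  co <- simulate_cohort(cfg)$cohort
  f <- true_eta(co, cfg)
  tab <- stratified_metrics(f, co$persons, "age_band")
  expect_equal(sum(tab$n), nrow(co$persons))  # age bands partition 30-74
  i <- co$persons$age >= 45 & co$persons$age < 60
  expect_equal(tab$C[tab$stratum == "[45,60)"],
               harrells_c(f[i], co$persons$follow_up_days[i],
                          co$persons$cvd_event[i]))
  whole <- stratified_metrics(f, co$persons, factor(rep("all", 3000)))
  expect_equal(whole$C, harrells_c(f, co$persons$follow_up_days,
                                   co$persons$cvd_event))
})

test_that("the Kaplan-Meier forecaster beats the coin flip on rare-event cohorts", {
  cfg <- sim_preset("linear", n_persons = 2000, seed = 73)
  co <- simulate_cohort(cfg)$cohort
  tm <- co$persons$follow_up_days
  ev <- co$persons$cvd_event
  grid <- brier_grid(tm, ev, max_points = 50L)
  km <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  s_km <- vapply(grid, function(t) {
    i <- findInterval(t, km$time)
    c(1, km$surv)[i + 1L]
  }, 0)
  S <- matrix(s_km, nrow = length(tm), ncol = length(grid), byrow = TRUE)
  expect_lt(integrated_brier(S, grid, tm, ev)$ibs,
            integrated_brier(0.5, grid, tm, ev)$ibs)
})
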