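#' Harrell's concordance statistic for censored data
#'
#' A pair (i, j) is comparable when `t_i < t_j` and person i had the event,
#' or `t_i = t_j` with exactly one event; it is concordant when the person
#' with the earlier event has the higher score, and score ties count 1/2.
#' `C = (concordant + ties/2) / comparable`.
#'
#' The implementation loops only over event persons with vectorized
#' comparisons, O(events x n); it is checked against an exhaustive all-pairs
#' enumeration in the test-suite.
#'
#' @param f scores (higher = predicted earlier event).
#' @param time,event follow-up days and event indicators.
#' @return C in `[0, 1]`.
#' @export
harrells_c <- function(f, time, event) {
  event <- as.logical(event)
  n <- length(f)
  if (length(time) != n || length(event) != n) stop("length mismatch")
  conc <- 0; ties <- 0; comp <- 0
  for (i in which(event)) {
    later <- time > time[i] | (time == time[i] & !event)
    later[i] <- FALSE
    comp <- comp + sum(later)
    conc <- conc + sum(f[i] > f[later])
    ties <- ties + sum(f[i] == f[later])
  }
  if (comp == 0) stop("no comparable pairs")
  (conc + 0.5 * ties) / comp
}

#' Royston-Sauerbrei D statistic and explained variation
#'
#' Scores are rank-transformed to scaled rankits: `z_i = qnorm((rank_i -
#' 3/8) / (n + 1/4)) / kappa` with `kappa = sqrt(8 / pi)` (Blom's constant);
#' D is the Cox partial-likelihood coefficient of this single covariate, the
#' log hazard ratio between median-split prognostic groups. The explained
#' variation is `R2 = (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)`. Both
#' are invariant under strictly increasing transforms of the scores.
#'
#' @param f scores.
#' @param time,event follow-up days and event indicators.
#' @return List with `D`, `R2`, `se` (standard error of D) and `constant`
#'   (TRUE when all scores are identical, in which case D = 0 is returned
#'   with a flag rather than an error).
#' @export
royston_d_r2 <- function(f, time, event) {
  event <- as.logical(event)
  if (sum(event) < 1L) stop("no events")
  if (length(unique(f)) == 1L)
    return(list(D = 0, R2 = 0, se = NA_real_, constant = TRUE))
  n <- length(f)
  kappa <- sqrt(8 / pi)
  r <- rank(f, ties.method = "average")
  zstar <- stats::qnorm((r - 3 / 8) / (n + 1 / 4)) / kappa
  fit <- survival::coxph(survival::Surv(time, event) ~ zstar,
                         ties = "efron")
  D <- unname(stats::coef(fit))
  R2 <- (D^2 / kappa^2) / (pi^2 / 6 + D^2 / kappa^2)
  list(D = D, R2 = R2, se = sqrt(stats::vcov(fit)[1L, 1L]), constant = FALSE)
}

# Kaplan-Meier of the censoring distribution (events treated as censored
# observations), evaluated right-continuously and at left limits
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, !as.logical(event)) ~ 1)
  steps <- fit$time[fit$n.event > 0]
  surv <- fit$surv[fit$n.event > 0]
  at <- function(t) c(1, surv)[findInterval(t, steps) + 1L]
  at_left <- function(t) c(1, surv)[findInterval(t - 1e-9, steps) + 1L]
  list(at = at, at_left = at_left)
}

#' Default evaluation grid for the integrated Brier score
#'
#' All distinct event times up to the horizon, thinned by quantiles to at
#' most `max_points`.
#'
#' @param time,event follow-up days and event indicators.
#' @param horizon upper limit in days.
#' @param max_points grid-size cap.
#' @return Sorted numeric vector of times.
#' @export
brier_grid <- function(time, event, horizon = 1826, max_points = 200L) {
  ut <- sort(unique(time[as.logical(event) & time <= horizon]))
  if (length(ut) > max_points)
    ut <- unique(stats::quantile(ut, probs = seq(0, 1, length.out = max_points),
                                 type = 1, names = FALSE))
  ut
}

#' Integrated Brier score with censoring weights
#'
#' Graf's inverse-probability-of-censoring weighting:
#' `BS(t) = n^-1 sum_i [ S_i(t)^2 1{t_i <= t, e_i = 1} / G(t_i-) +
#' (1 - S_i(t))^2 1{t_i > t} / G(t) ]` where `G` is the Kaplan-Meier
#' estimate of the censoring distribution (left limits for the event-
#' weighted terms), integrated by the trapezoidal rule over the grid and
#' divided by the grid span.
#'
#' @param surv matrix of predicted survival probabilities, persons x grid
#'   (see [predicted_survival()]), or a single constant.
#' @param grid evaluation times.
#' @param time,event follow-up days and event indicators.
#' @param cens_km optional censoring distribution from a *training* sample
#'   (list with `at`, `at_left`); defaults to estimating it on `time`,
#'   `event`.
#' @return List with `ibs` and the per-time `bs` curve.
#' @export
integrated_brier <- function(surv, grid, time, event, cens_km = NULL) {
  event <- as.logical(event)
  n <- length(time)
  if (length(surv) == 1L) surv <- matrix(surv, n, length(grid))
  if (is.null(cens_km)) cens_km <- censoring_km(time, event)
  g_left <- cens_km$at_left(time)
  bs <- numeric(length(grid))
  for (j in seq_along(grid)) {
    t <- grid[j]
    gt <- cens_km$at(t)
    had_event <- time <= t & event
    at_risk <- time > t
    if (any(had_event & g_left == 0))
      stop("censoring survival is 0 at required time ",
           max(time[had_event & g_left == 0]))
    if (any(at_risk) && gt == 0)
      stop("censoring survival is 0 at required time ", t)
    term1 <- sum(surv[had_event, j]^2 / g_left[had_event])
    term2 <- if (any(at_risk)) sum((1 - surv[at_risk, j])^2) / gt else 0
    bs[j] <- (term1 + term2) / n
  }
  ibs <- if (length(grid) == 1L) bs else {
    w <- diff(grid)
    sum(w * (bs[-1L] + bs[-length(bs)]) / 2) / (max(grid) - min(grid))
  }
  list(ibs = ibs, bs = bs, grid = grid)
}

#' Decile calibration and discrimination table
#'
#' Persons are split into deciles of predicted 5-year risk (ties broken by
#' stable input order; decile sizes differ by at most one). Per decile:
#' mean predicted risk, the observed 5-year event proportion — by default
#' `1 -` the within-decile Kaplan-Meier survival at the horizon, which
#' adjusts for censoring; raw event fraction available via `observed =
#' "raw"` — and the decile's share of all observed events (shares sum to 1).
#'
#' @param risk predicted 5-year risks.
#' @param time,event follow-up days and event indicators.
#' @param horizon horizon in days.
#' @param observed `"km"` or `"raw"`.
#' @return data.frame with columns `decile`, `n`, `mean_predicted`,
#'   `observed`, `events`, `event_share`.
#' @export
decile_table <- function(risk, time, event, horizon = 1826,
                         observed = c("km", "raw")) {
  observed <- match.arg(observed)
  event <- as.logical(event)
  n <- length(risk)
  if (n < 10L) stop("need at least 10 persons for deciles")
  ord <- order(risk)  # stable: ties keep input order
  sizes <- diff(round(seq(0, n, length.out = 11L)))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(10L), times = sizes)
  total_events <- sum(event)
  rows <- lapply(seq_len(10L), function(g) {
    i <- grp == g
    obs <- if (observed == "raw") mean(event[i]) else {
      fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
      s <- c(1, fit$surv)[findInterval(horizon, fit$time) + 1L]
      1 - s
    }
    data.frame(decile = g, n = sum(i), mean_predicted = mean(risk[i]),
               observed = obs, events = sum(event[i]),
               event_share = if (total_events > 0) sum(event[i]) / total_events
                             else NA_real_)
  })
  do.call(rbind, rows)
}

#' Full metric report for one prediction vector
#'
#' Computes Harrell's C, the D statistic and explained variation, and (when
#' a baseline is supplied) the IPCW integrated Brier score, on one test set.
#'
#' @param f scores (log relative risks).
#' @param time,event follow-up days and event indicators.
#' @param baseline optional `seqrisk_baseline` fitted on training data, for
#'   the Brier score.
#' @param cens_km optional training-sample censoring distribution.
#' @param horizon horizon in days.
#' @return Named list with `C`, `D`, `R2`, `IBS` (NA without a baseline).
#' @export
metric_report <- function(f, time, event, baseline = NULL, cens_km = NULL,
                          horizon = 1826) {
  dr <- royston_d_r2(f, time, event)
  ibs <- NA_real_
  if (!is.null(baseline)) {
    grid <- brier_grid(time, event, horizon)
    S <- predicted_survival(f, baseline, grid)
    ibs <- integrated_brier(S, grid, time, event, cens_km)$ibs
  }
  list(C = harrells_c(f, time, event), D = dr$D, R2 = dr$R2, IBS = ibs)
}

#' Metrics within population strata
#'
#' Applies the metric machinery within each stratum of a grouping: 15-year
#' age bands ([30,45), [45,60), [60,75)), ethnicity, deprivation quintile,
#' dispensing of preventive medications, or any user factor. Strata with no
#' events are skipped with a warning.
#'
#' @param f scores.
#' @param persons persons table aligned with `f`.
#' @param strata `"age_band"`, `"ethnicity"`, `"deprivation"`,
#'   `"medications"`, or a factor of length `nrow(persons)`.
#' @return data.frame of per-stratum metrics (`stratum`, `n`, `events`, `C`,
#'   `D`, `R2`).
#' @export
stratified_metrics <- function(f, persons, strata = "age_band") {
  g <- if (is.character(strata) && length(strata) == 1L) {
    switch(strata,
           age_band = cut(persons$age, c(30, 45, 60, 75), right = FALSE,
                          labels = c("[30,45)", "[45,60)", "[60,75)"),
                          include.lowest = TRUE),
           ethnicity = factor(persons$ethnicity, ethnicity_levels()),
           deprivation = factor(persons$deprivation, 1:5),
           medications = factor(ifelse(persons$bp_lowering |
                                         persons$lipid_lowering |
                                         persons$antiplatelet_anticoagulant,
                                       "dispensed", "none")),
           stop("unknown strata spec: ", strata))
  } else factor(strata)
  rows <- list()
  for (lev in levels(g)) {
    i <- which(g == lev)
    if (length(i) == 0L) next
    ev <- sum(persons$cvd_event[i])
    if (ev < 1L) {
      warning("stratum '", lev, "' has no events; skipped")
      next
    }
    m <- tryCatch(metric_report(f[i], persons$follow_up_days[i],
                                persons$cvd_event[i]),
                  error = function(e) NULL)
    if (is.null(m)) { warning("stratum '", lev, "' skipped"); next }
    rows[[length(rows) + 1L]] <-
      data.frame(stratum = lev, n = length(i), events = ev,
                 C = m$C, D = m$D, R2 = m$R2, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Calibration and discrimination dot charts
#'
#' Base-graphics renderings of the decile table: predicted vs observed
#' 5-year risk with the identity line, and the share of observed events per
#' risk decile.
#'
#' @param tab a [decile_table()] result.
#' @param which `"calibration"` or `"discrimination"`.
#' @param ... passed to [plot()].
#' @return Invisibly, `tab`.
#' @export
plot_deciles <- function(tab, which = c("calibration", "discrimination"), ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    lim <- range(0, tab$mean_predicted, tab$observed)
    graphics::plot(tab$mean_predicted, tab$observed, xlim = lim, ylim = lim,
                   xlab = "mean predicted 5-year risk",
                   ylab = "observed 5-year risk", pch = 19, ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    graphics::plot(tab$decile, tab$event_share, type = "h", lwd = 3,
                   xlab = "decile of predicted risk",
                   ylab = "share of observed events", ...)
    graphics::points(tab$decile, tab$event_share, pch = 19)
  }
  invisible(tab)
}
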