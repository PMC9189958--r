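#' Breslow baseline survival at the reference person
#'
#' Step-function estimate of the reference person's cumulative hazard from a
#' fitted stratum's scores and outcomes:
#' `Lambda_ref(t) = sum over event times t_j <= t of d_j / sum_{i in R(t_j)}
#' exp(f_i - f_ref)` (Breslow tie handling), with `S_ref(t) =
#' exp(-Lambda_ref(t))`. Works identically for the Cox model (`f` = linear
#' predictor) and the network ensemble (`f` = mean log relative risk).
#' Beyond the last event time `S_ref` stays at its last value.
#'
#' @param f scores (log relative risks) of the fitted stratum.
#' @param time,event follow-up days and event indicators.
#' @param f_ref the model's score for the reference person.
#' @return An object of class `seqrisk_baseline`: event-time grid, cumulative
#'   hazard and survival steps, and `f_ref`.
#' @export
breslow_baseline <- function(f, time, event, f_ref = 0) {
  event <- as.logical(event)
  if (!any(event)) stop("no events: cannot estimate baseline survival")
  w <- exp(f - f_ref)
  ut <- sort(unique(time[event]))
  # risk-set weight sums at each event time, computed from the tail cumsum
  ot <- order(time)
  tsort <- time[ot]
  wsort <- w[ot]
  tail_w <- rev(cumsum(rev(wsort)))
  denom <- tail_w[findInterval(ut - 0.5, tsort) + 1L]
  d <- as.vector(table(factor(time[event], levels = ut)))
  cumhaz <- cumsum(d / denom)
  structure(list(times = ut, cumhaz = cumhaz, surv = exp(-cumhaz),
                 f_ref = f_ref),
            class = "seqrisk_baseline")
}

#' Evaluate baseline survival at arbitrary times
#'
#' @param baseline a `seqrisk_baseline`.
#' @param t times (days).
#' @return `S_ref(t)`, right-continuous step function with `S_ref(0) = 1`.
#' @export
baseline_survival <- function(baseline, t) {
  i <- findInterval(t, baseline$times)
  c(1, baseline$surv)[i + 1L]
}

#' Absolute 5-year risk from a score and the baseline
#'
#' `risk_i = 1 - S_ref(horizon) ^ exp(f_i - f_ref)`; strictly increasing in
#' `f_i` and always in `[0, 1]`.
#'
#' @param f scores.
#' @param baseline a `seqrisk_baseline` fitted on the same model/stratum.
#' @param horizon prediction horizon in days.
#' @return Numeric vector of absolute risks.
#' @export
five_year_risk <- function(f, baseline, horizon = 1826) {
  s0 <- baseline_survival(baseline, horizon)
  1 - s0^exp(f - baseline$f_ref)
}

#' Predicted survival curves on a time grid
#'
#' `S_i(t) = S_ref(t) ^ exp(f_i - f_ref)` for each person and grid time;
#' input to the integrated Brier score.
#'
#' @param f scores.
#' @param baseline a `seqrisk_baseline`.
#' @param grid times (days).
#' @return Matrix `length(f)` x `length(grid)`.
#' @export
predicted_survival <- function(f, baseline, grid) {
  s0 <- baseline_survival(baseline, grid)
  outer(exp(f - baseline$f_ref), s0, function(r, s) s^r)
}

# apply one perturbation to a one-person cohort (reference person)
perturb_person <- function(persons, events, perturbation, lookback_months) {
  if (perturbation$type == "covariate") {
    persons[[perturbation$name]] <- perturbation$value
  } else if (perturbation$type == "code") {
    events <- rbind(events,
                    data.frame(person_id = persons$person_id,
                               code = perturbation$code,
                               code_type = perturbation$code_type,
                               month = lookback_months - 1L,
                               stringsAsFactors = FALSE))
  } else stop("unknown perturbation type: ", perturbation$type)
  list(persons = persons, events = events)
}

empty_events <- function() {
  data.frame(person_id = character(0), code = character(0),
             code_type = character(0), month = integer(0),
             stringsAsFactors = FALSE)
}

# a prediction closure for one replicate: person table + events -> f
replicate_predictor <- function(model) {
  if (inherits(model, "seqrisk_cox")) {
    list(predict = function(persons, events, lookback) {
      predict_lp(model, persons)
    }, centering = model$centering)
  } else if (inherits(model, "seqrisk_ensemble")) {
    list(predict = function(persons, events, lookback) {
      co <- new_cohort(persons, events, lookback)
      as.numeric(predict_log_risk(model, co))
    }, centering = model$centering)
  } else if (is.list(model) && !is.null(model$predict)) {
    model
  } else stop("unsupported model for local-HR estimation")
}

#' Perturbation-based local hazard ratios
#'
#' For each of K replicate models (networks retrained from different random
#' initializations, or a Cox fit), the reference person of the model's
#' centering context is perturbed — a covariate set to a new value, or a
#' single coded event appended at the index month — and the local hazard
#' ratio of replicate k is `HR_k = exp(f_k(perturbed) - f_k(reference))`.
#' Continuous predictors (`age`, `deprivation`) are reported as per-unit
#' local HRs `exp(f(v + 1) - f(v))` averaged over a grid of observed values.
#' The report gives the mean over replicates with a percentile 2.5/97.5
#' confidence interval.
#'
#' Applied to a Cox model, a unit binary perturbation returns exactly
#' `exp(beta_j)` in every replicate (a closed-form check of the harness).
#'
#' @param replicates list of K >= 2 fitted models (`seqrisk_ensemble`
#'   members should be wrapped as single-member ensembles, see
#'   [ensemble_replicates()]).
#' @param perturbations list of perturbation specs: `list(type =
#'   "covariate", name =, value =)`, `list(type = "code", code =, code_type
#'   =)`, or `list(type = "continuous", name = "age", grid =)`.
#' @param sex stratum label for the reference person.
#' @param lookback_months lookback window of the cohort dialect.
#' @return data.frame with columns `predictor`, `hr`, `ci_low`, `ci_high`,
#'   `K`.
#' @export
local_hr <- function(replicates, perturbations, sex = "F",
                     lookback_months = 60L) {
  K <- length(replicates)
  if (K < 2L) stop("K >= 2 replicates required for a confidence interval")
  preds <- lapply(replicates, replicate_predictor)
  out <- vector("list", length(perturbations))
  for (j in seq_along(perturbations)) {
    pert <- perturbations[[j]]
    hrs <- numeric(K)
    for (k in seq_len(K)) {
      pk <- preds[[k]]
      ref <- reference_person(pk$centering, sex)
      if (identical(pert$type, "continuous")) {
        grid <- pert$grid
        if (is.null(grid)) grid <- seq(30, 73, by = 1)
        base <- ref[rep(1L, length(grid)), , drop = FALSE]
        base$person_id <- sprintf("__g%03d__", seq_along(grid))
        up <- base
        base[[pert$name]] <- grid
        up[[pert$name]] <- grid + 1
        f0 <- pk$predict(base, empty_events(), lookback_months)
        f1 <- pk$predict(up, empty_events(), lookback_months)
        hrs[k] <- mean(exp(f1 - f0))
      } else {
        f0 <- pk$predict(ref, empty_events(), lookback_months)
        pp <- perturb_person(ref, empty_events(), pert, lookback_months)
        f1 <- pk$predict(pp$persons, pp$events, lookback_months)
        hrs[k] <- exp(f1 - f0)
      }
    }
    label <- if (!is.null(pert$label)) pert$label
             else if (identical(pert$type, "code")) pert$code
             else pert$name
    ci <- unname(stats::quantile(hrs, c(0.025, 0.975), type = 7))
    out[[j]] <- data.frame(predictor = label, hr = mean(hrs),
                           ci_low = ci[1L], ci_high = ci[2L], K = K,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Train K replicate networks for local-HR inference
#'
#' Trains `K` single-member ensembles on the full stratum with distinct
#' derived seeds (the desk-scale analogue of retraining the network many
#' times) and returns them as a replicate list for [local_hr()].
#'
#' @param cohort a `seqrisk_cohort` stratum with outcomes.
#' @param config a `seqrisk_model_config` (its `ensemble_size` is ignored).
#' @param K number of replicates.
#' @param min_persons rarity threshold for the shared vocabulary.
#' @return List of K `seqrisk_ensemble` objects with one member each.
#' @export
ensemble_replicates <- function(cohort, config, K = 10L, min_persons = 1L) {
  vocab <- build_vocabulary(cohort, min_persons)
  centering <- fit_centering(cohort$persons)
  lapply(seq_len(K), function(k) {
    cfg <- config
    cfg$ensemble_size <- 1L
    cfg$seed <- as.integer((config$seed * 53 + k * 101) %% 2147483646) + 1L
    train_ensemble(cohort, cfg, vocab = vocab, centering = centering)
  })
}

#' Standard perturbation set for the pre-specified predictors
#'
#' The covariate perturbations mirroring the published hazard-ratio table
#' layout: per-year age, per-quintile deprivation, each non-reference
#' ethnicity, and each binary flag; optionally individual codes.
#'
#' @param codes optional character vector of codes to add as single-event
#'   perturbations (each tagged `primary_dx` unless it starts with "M", then
#'   `medication`).
#' @return List of perturbation specs for [local_hr()].
#' @export
standard_perturbations <- function(codes = character(0)) {
  p <- list(list(type = "continuous", name = "age", label = "age_per_year"),
            list(type = "continuous", name = "deprivation", grid = 1:4,
                 label = "deprivation_per_quintile"))
  for (e in ethnicity_levels()[-1L])
    p[[length(p) + 1L]] <- list(type = "covariate", name = "ethnicity",
                                value = e, label = paste0("ethnicity_", e))
  for (fl in flag_columns())
    p[[length(p) + 1L]] <- list(type = "covariate", name = fl, value = TRUE,
                                label = fl)
  for (cd in codes)
    p[[length(p) + 1L]] <- list(type = "code", code = cd,
                                code_type = if (startsWith(cd, "M"))
                                  "medication" else "primary_dx",
                                label = cd)
  p
}
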