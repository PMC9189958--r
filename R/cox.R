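#' Fit the sex-specific Cox proportional-hazards comparator
#'
#' Fits a Cox model by maximum partial likelihood on the pre-specified
#' covariate layout (see [covariate_matrix()]) for one sex stratum, the
#' traditional comparator to the sequence model. The fit is delegated to
#' [survival::coxph()] (Newton-Raphson with step halving); Efron tie
#' correction is the default since day-resolution follow-up produces ties.
#' Standard errors come from the inverse observed information.
#'
#' @param cohort a `seqrisk_cohort` restricted to one sex stratum, with
#'   outcomes set.
#' @param predictor_set `"full"` (covariates + six interactions) or
#'   `"reduced"` (age, deprivation, ethnicity only).
#' @param ties `"efron"` or `"breslow"`.
#' @param centering optional centering context; defaults to fitting one on
#'   this stratum via [fit_centering()].
#' @return An object of class `seqrisk_cox`: coefficients (log-hazard units;
#'   `exp(coef)` are adjusted hazard ratios), standard errors, covariance,
#'   centering context, stratum sex label, convergence diagnostics.
#' @export
fit_cox <- function(cohort, predictor_set = c("full", "reduced"),
                    ties = c("efron", "breslow"), centering = NULL) {
  predictor_set <- match.arg(predictor_set)
  ties <- match.arg(ties)
  persons <- cohort$persons
  if (any(is.na(persons$follow_up_days)))
    stop("cohort has unset outcomes; run simulate_outcomes() first")
  n_events <- sum(persons$cvd_event)
  if (n_events < 1L) stop("no events in stratum: cannot fit Cox model")
  if (is.null(centering)) centering <- fit_centering(persons)
  X <- covariate_matrix(persons, centering, predictor_set)
  # constant columns (e.g. a flag nobody in a small stratum carries) are
  # inestimable and dropped; genuine collinearity among varying columns is
  # an error
  constant <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no varying covariates in stratum")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
  }
  y <- survival::Surv(persons$follow_up_days, persons$cvd_event)
  fit <- survival::coxph(y ~ X, ties = ties,
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-9))
  beta <- stats::setNames(unname(stats::coef(fit)), colnames(X))
  if (anyNA(beta)) {
    # columns the fitter finds numerically redundant in this stratum
    warning("dropping inestimable covariate column(s): ",
            paste(names(beta)[is.na(beta)], collapse = ", "))
    X <- X[, !is.na(beta), drop = FALSE]
    fit <- survival::coxph(y ~ X, ties = ties,
                           control = survival::coxph.control(iter.max = 100,
                                                             eps = 1e-9))
    beta <- stats::setNames(unname(stats::coef(fit)), colnames(X))
  }
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  # score vector at the solution, for the convergence diagnostic
  grad <- tryCatch(colSums(survival::residuals(fit, type = "score")),
                   error = function(e) rep(NA_real_, length(beta)))
  structure(list(coefficients = beta,
                 se = sqrt(diag(V)), vcov = V,
                 centering = centering, predictor_set = predictor_set,
                 ties = ties, sex = centering$sex,
                 n = nrow(persons), n_events = n_events,
                 iterations = fit$iter,
                 gradient_norm = max(abs(grad)),
                 loglik = fit$loglik[2L]),
            class = "seqrisk_cox")
}

#' @export
print.seqrisk_cox <- function(x, ...) {
  cat(sprintf("seqrisk Cox model (%s predictors, %s ties, sex %s): %d persons, %d events\n",
              x$predictor_set, x$ties, x$sex, x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, HR = exp(x$coefficients), se = x$se,
                    z = x$coefficients / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Linear predictor of a fitted Cox model
#'
#' `eta_i = x_i' beta` with covariates built from the model's own centering
#' context, so `eta = 0` at the reference person.
#'
#' @param model a `seqrisk_cox`.
#' @param persons persons table (or a `seqrisk_cohort`).
#' @return Numeric vector of log-hazard offsets.
#' @export
predict_lp <- function(model, persons) {
  if (inherits(persons, "seqrisk_cohort")) persons <- persons$persons
  X <- covariate_matrix(persons, model$centering, model$predictor_set)
  as.vector(X[, names(model$coefficients), drop = FALSE] %*% model$coefficients)
}

#' Serialize / restore a Cox model as plain JSON
#'
#' @param model a `seqrisk_cox`.
#' @param path output file.
#' @return `path` (write) or the restored model (read), invisibly.
#' @export
write_cox <- function(model, path) {
  obj <- model[c("coefficients", "se", "centering", "predictor_set", "ties",
                 "sex", "n", "n_events", "iterations", "loglik")]
  obj$coefficients <- as.list(obj$coefficients)
  obj$se <- as.list(obj$se)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cox
#' @export
read_cox <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$se <- unlist(obj$se)
  obj$vcov <- NULL
  structure(obj, class = "seqrisk_cox")
}
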