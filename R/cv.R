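#' Stratified 5x2 cross-validation splits
#'
#' Five replications; each shuffles the stratum and splits it into two
#' halves stratified by event status (event counts in the two halves differ
#' by at most one). Each half serves once as the training set and once as
#' the test set.
#'
#' @param event event indicator vector.
#' @param seed integer seed; fixed seed gives identical splits.
#' @return List of 5 integer vectors of fold labels (1 or 2) per person.
#' @export
split_5x2 <- function(event, seed = 1L) {
  event <- as.logical(event)
  set.seed(as.integer(seed))
  lapply(seq_len(5L), function(r) {
    fold <- integer(length(event))
    for (grp in list(which(event), which(!event))) {
      grp <- grp[sample.int(length(grp))]
      half <- floor(length(grp) / 2L)
      extra <- length(grp) - 2L * half
      fold[grp] <- c(rep(1L, half + (extra > 0 && r %% 2L == 1L)),
                     rep(2L, length(grp) - half - (extra > 0 && r %% 2L == 1L)))
    }
    fold
  })
}

fit_model_spec <- function(spec, train_cohort) {
  if (identical(spec$type, "cox")) {
    fit_cox(train_cohort,
            predictor_set = if (is.null(spec$predictor_set)) "full"
                            else spec$predictor_set,
            ties = if (is.null(spec$ties)) "efron" else spec$ties)
  } else if (identical(spec$type, "deep")) {
    train_ensemble(train_cohort, spec$config,
                   min_persons = if (is.null(spec$min_persons)) 1L
                                 else spec$min_persons)
  } else stop("unknown model spec type: ", spec$type)
}

predict_model <- function(model, cohort) {
  if (inherits(model, "seqrisk_cox")) predict_lp(model, cohort$persons)
  else as.numeric(predict_log_risk(model, cohort))
}

#' Run stratified 5x2 cross-validated model comparison
#'
#' For each replication and fold, both model specifications are fitted on
#' the same training half — vocabulary, centering context, Breslow baseline
#' and the censoring distribution used for Brier weighting are all computed
#' from the training half only — and evaluated on the same test half with
#' Harrell's C, the D statistic, explained variation and the integrated
#' Brier score.
#'
#' @param cohort a `seqrisk_cohort` stratum with outcomes.
#' @param spec_a,spec_b model specs: `list(type = "cox", predictor_set =,
#'   ties =)` or `list(type = "deep", config = <model_config>, min_persons
#'   =)`.
#' @param seed split seed.
#' @param horizon Brier/risk horizon in days.
#' @return An object of class `seqrisk_cv`: `metrics` (long data.frame:
#'   replication, fold, model, C, D, R2, IBS), per-metric 5x2 difference
#'   matrices (`A - B`), and the combined F test per metric.
#' @export
run_5x2_cv <- function(cohort, spec_a, spec_b, seed = 1L, horizon = 1826) {
  splits <- split_5x2(cohort$persons$cvd_event, seed)
  rows <- list()
  for (r in seq_len(5L)) {
    for (j in 1:2) {
      train <- subset_cohort(cohort, which(splits[[r]] == j))
      test <- subset_cohort(cohort, which(splits[[r]] != j))
      if (sum(train$persons$cvd_event) == 0L ||
          sum(test$persons$cvd_event) == 0L)
        stop("a 5x2 half has zero events; enlarge the stratum")
      cens <- censoring_km(train$persons$follow_up_days,
                           train$persons$cvd_event)
      for (m in c("A", "B")) {
        spec <- if (m == "A") spec_a else spec_b
        fit <- fit_model_spec(spec, train)
        f_tr <- predict_model(fit, train)
        f_te <- predict_model(fit, test)
        bl <- breslow_baseline(f_tr, train$persons$follow_up_days,
                               train$persons$cvd_event, f_ref = 0)
        met <- metric_report(f_te, test$persons$follow_up_days,
                             test$persons$cvd_event, baseline = bl,
                             cens_km = cens, horizon = horizon)
        rows[[length(rows) + 1L]] <-
          data.frame(replication = r, fold = j, model = m,
                     C = met$C, D = met$D, R2 = met$R2, IBS = met$IBS)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  diffs <- list()
  ftests <- list()
  for (met in c("C", "D", "R2", "IBS")) {
    d <- matrix(NA_real_, 5L, 2L)
    for (r in seq_len(5L)) for (j in 1:2) {
      a <- metrics[metrics$replication == r & metrics$fold == j &
                     metrics$model == "A", met]
      b <- metrics[metrics$replication == r & metrics$fold == j &
                     metrics$model == "B", met]
      d[r, j] <- a - b
    }
    diffs[[met]] <- d
    ftests[[met]] <- tryCatch(combined_f_test(d), error = function(e)
      list(F = NA_real_, p = NA_real_, error = conditionMessage(e)))
  }
  structure(list(metrics = metrics, diffs = diffs, ftests = ftests,
                 seed = seed),
            class = "seqrisk_cv")
}

#' @export
print.seqrisk_cv <- function(x, ...) {
  cat("seqrisk 5x2 cross-validated comparison (model A vs model B)\n")
  for (met in names(x$diffs)) {
    mA <- mean(x$metrics[x$metrics$model == "A", met])
    mB <- mean(x$metrics[x$metrics$model == "B", met])
    ft <- x$ftests[[met]]
    cat(sprintf("  %-4s A %.4f  B %.4f  diff %+.4f  F = %.3f, p = %.4f\n",
                met, mA, mB, mA - mB, ft$F, ft$p))
  }
  invisible(x)
}

#' Cross-validated metric summary with t-based intervals
#'
#' Mean over the 10 fold values with a t-distribution 95% interval, per
#' metric and model.
#'
#' @param cv a `seqrisk_cv`.
#' @return data.frame with columns `model`, `metric`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
cv_summary <- function(cv) {
  rows <- list()
  for (m in c("A", "B")) for (met in c("C", "D", "R2", "IBS")) {
    v <- cv$metrics[cv$metrics$model == m, met]
    se <- stats::sd(v) / sqrt(length(v))
    q <- stats::qt(0.975, length(v) - 1L)
    rows[[length(rows) + 1L]] <-
      data.frame(model = m, metric = met, mean = mean(v),
                 ci_low = mean(v) - q * se, ci_high = mean(v) + q * se)
  }
  do.call(rbind, rows)
}

#' Combined 5x2 F test
#'
#' For the 5x2 difference matrix `d`, with per-replication mean `dbar_r` and
#' `s2_r = (d_r1 - dbar_r)^2 + (d_r2 - dbar_r)^2`:
#' `F = sum(d^2) / (2 * sum(s2_r))`, referred to the F distribution with
#' (10, 5) degrees of freedom.
#'
#' @param d numeric 5x2 matrix of per-fold performance differences.
#' @return List with `F` and `p`. All-zero differences return `F = 0, p = 1`
#'   by convention; zero variance with non-zero differences is an error.
#' @export
combined_f_test <- function(d) {
  if (!is.matrix(d) || nrow(d) != 5L || ncol(d) != 2L)
    stop("d must be a 5x2 matrix")
  dbar <- rowMeans(d)
  s2 <- (d[, 1L] - dbar)^2 + (d[, 2L] - dbar)^2
  num <- sum(d^2)
  if (num == 0) return(list(F = 0, p = 1))
  if (sum(s2) == 0) stop("degenerate variance: zero within-replication variance")
  F <- num / (2 * sum(s2))
  list(F = F, p = stats::pf(F, 10, 5, lower.tail = FALSE))
}
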