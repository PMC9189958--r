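#' Coded-event types
#'
#' The five recognised code types for events in a person's history: primary
#' diagnosis, secondary diagnosis, external cause of injury,
#' procedure/operation, and dispensed medication. Integer type indices used
#' by the network follow this order (1-5); 0 is reserved for padding.
#'
#' @return Character vector of the five code-type labels.
#' @export
code_types <- function() {
  c("primary_dx", "secondary_dx", "external_cause", "procedure", "medication")
}

#' Ethnicity levels
#'
#' Categorical ethnicity levels used throughout the package; the first level
#' is the reference and is omitted from covariate one-hot encoding.
#'
#' @return Character vector of levels, reference first.
#' @export
ethnicity_levels <- function() {
  c("European", "Maori", "Pacific", "Indian", "Other")
}

person_columns <- function() {
  c("person_id", "sex", "age", "ethnicity", "deprivation", "diabetes",
    "atrial_fibrillation", "bp_lowering", "lipid_lowering",
    "antiplatelet_anticoagulant", "follow_up_days", "cvd_event")
}

flag_columns <- function() {
  c("diabetes", "atrial_fibrillation", "bp_lowering", "lipid_lowering",
    "antiplatelet_anticoagulant")
}

#' Construct a cohort of longitudinal person records
#'
#' A cohort couples one row per person (baseline covariates and the
#' right-censored outcome) with a long table of coded events, each carrying a
#' code, a code type and a calendar-month index within the lookback window
#' (0 = earliest month, `lookback_months - 1` = index-date month). Events are
#' sorted non-decreasing by month within person, preserving input order among
#' ties.
#'
#' @param persons data.frame with columns `person_id`, `sex` ("F"/"M"), `age`
#'   (years, 30-74), `ethnicity` (see [ethnicity_levels()]), `deprivation`
#'   (quintile 1-5), logical flags `diabetes`, `atrial_fibrillation`,
#'   `bp_lowering`, `lipid_lowering`, `antiplatelet_anticoagulant`, and
#'   outcome columns `follow_up_days` (1-1826, may be NA before outcome
#'   simulation) and `cvd_event` (logical; TRUE = first CVD event at
#'   `follow_up_days`, FALSE = censored).
#' @param events data.frame with columns `person_id`, `code`, `code_type`
#'   (one of [code_types()]) and `month` (integer in `[0, lookback_months)`).
#' @param lookback_months length of the lookback window in months.
#' @return An object of class `seqrisk_cohort`: a list with elements
#'   `persons`, `events`, `lookback_months`.
#' @export
new_cohort <- function(persons, events, lookback_months = 60L) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  validate_persons(persons)
  validate_events(events, lookback_months, persons$person_id)
  ord <- order(match(events$person_id, persons$person_id), events$month)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(persons = persons, events = events,
                 lookback_months = as.integer(lookback_months)),
            class = "seqrisk_cohort")
}

validate_persons <- function(persons, file = NULL) {
  missing_cols <- setdiff(person_columns(), names(persons))
  if (length(missing_cols) > 0L)
    stop("persons table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(persons) == 0L) stop("cohort is empty: persons table has no rows")
  if (anyDuplicated(persons$person_id))
    stop("duplicated person_id in persons table")
  bad_row <- function(cond, field) {
    i <- which(cond)[1L]
    stop(sprintf("invalid persons row %d%s: field '%s' = %s", i,
                 if (is.null(file)) "" else paste0(" of ", file), field,
                 format(persons[[field]][i])))
  }
  if (any(!persons$sex %in% c("F", "M"))) bad_row(!persons$sex %in% c("F", "M"), "sex")
  if (any(!is.finite(persons$age) | persons$age < 30 | persons$age > 74))
    bad_row(!is.finite(persons$age) | persons$age < 30 | persons$age > 74, "age")
  if (any(!persons$ethnicity %in% ethnicity_levels()))
    bad_row(!persons$ethnicity %in% ethnicity_levels(), "ethnicity")
  if (any(!persons$deprivation %in% 1:5))
    bad_row(!persons$deprivation %in% 1:5, "deprivation")
  fu <- persons$follow_up_days
  ok_fu <- is.na(fu) | (is.finite(fu) & fu >= 1 & fu <= 1826 & fu == round(fu))
  if (any(!ok_fu)) bad_row(!ok_fu, "follow_up_days")
  invisible(persons)
}

validate_events <- function(events, lookback_months, known_ids, file = NULL) {
  needed <- c("person_id", "code", "code_type", "month")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0L)
    stop("events table lacks column(s): ", paste(missing_cols, collapse = ", "))
  where <- if (is.null(file)) "" else paste0(" of ", file)
  bad_type <- which(!events$code_type %in% code_types())
  if (length(bad_type) > 0L)
    stop(sprintf("invalid events row %d%s: unknown code_type '%s'",
                 bad_type[1L], where, events$code_type[bad_type[1L]]))
  m <- events$month
  bad_m <- which(!is.finite(m) | m < 0 | m >= lookback_months | m != round(m))
  if (length(bad_m) > 0L)
    stop(sprintf("invalid events row %d%s: field 'month' = %s (must be an integer in [0, %d])",
                 bad_m[1L], where, format(m[bad_m[1L]]), lookback_months - 1L))
  unknown <- which(!events$person_id %in% known_ids)
  if (length(unknown) > 0L)
    stop(sprintf("invalid events row %d%s: person_id '%s' not in persons table",
                 unknown[1L], where, events$person_id[unknown[1L]]))
  invisible(events)
}

#' @export
print.seqrisk_cohort <- function(x, ...) {
  n_ev <- sum(x$persons$cvd_event %in% TRUE)
  cat(sprintf("seqrisk cohort: %d persons (%d F / %d M), %d coded events, %d CVD events\n",
              nrow(x$persons), sum(x$persons$sex == "F"),
              sum(x$persons$sex == "M"), nrow(x$events), n_ev))
  invisible(x)
}

#' Restrict a cohort to one sex stratum
#'
#' All modelling in the package is sex-stratified: models are fitted
#' independently per stratum and sex never enters the covariate vector.
#'
#' @param cohort a `seqrisk_cohort`.
#' @param sex `"F"` or `"M"`.
#' @return The sub-cohort of persons with the requested sex.
#' @export
cohort_stratum <- function(cohort, sex) {
  sex <- match.arg(sex, c("F", "M"))
  keep <- cohort$persons$sex == sex
  if (!any(keep)) stop("no persons with sex ", sex, " in cohort")
  subset_cohort(cohort, which(keep))
}

#' Subset a cohort by person row indices
#'
#' @param cohort a `seqrisk_cohort`.
#' @param idx integer row indices into `cohort$persons`.
#' @return The sub-cohort (event rows restricted to the kept persons).
#' @export
subset_cohort <- function(cohort, idx) {
  persons <- cohort$persons[idx, , drop = FALSE]
  rownames(persons) <- NULL
  events <- cohort$events[cohort$events$person_id %in% persons$person_id, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(persons = persons, events = events,
                 lookback_months = cohort$lookback_months),
            class = "seqrisk_cohort")
}

#' Build the code vocabulary with a rarity filter
#'
#' Codes are counted by *distinct-person* support (each person counts once per
#' code however many times they list it); codes supported by fewer than
#' `min_persons` people are excluded. Retained codes get contiguous integer
#' indices from 1 in lexicographic code order; index 0 is reserved for
#' padding.
#'
#' @param cohort a `seqrisk_cohort`.
#' @param min_persons minimum distinct-person support for a code to be kept
#'   (the analysis of the national cohort used 500; desk-scale cohorts use a
#'   proportionally smaller value).
#' @return An object of class `seqrisk_vocab`: list with `index` (named
#'   integer vector code -> index), `counts` (distinct-person support of the
#'   retained codes), `min_persons`.
#' @export
build_vocabulary <- function(cohort, min_persons = 1L) {
  if (!inherits(cohort, "seqrisk_cohort")) stop("cohort must be a seqrisk_cohort")
  if (nrow(cohort$persons) == 0L) stop("invalid input: empty cohort")
  if (min_persons < 1L) stop("min_persons must be >= 1")
  ev <- cohort$events
  if (nrow(ev) > 0L) {
    pc <- unique(ev[, c("code", "person_id")])
    counts <- table(pc$code)
    keep <- counts[counts >= min_persons]
  } else {
    keep <- integer(0)
  }
  if (length(keep) == 0L)
    stop("empty vocabulary: no code has distinct-person support >= ", min_persons)
  codes <- sort(names(keep))
  index <- stats::setNames(seq_along(codes), codes)
  counts <- as.integer(keep[codes])
  names(counts) <- codes
  structure(list(index = index, counts = counts,
                 min_persons = as.integer(min_persons)),
            class = "seqrisk_vocab")
}

#' @export
print.seqrisk_vocab <- function(x, ...) {
  cat(sprintf("seqrisk vocabulary: %d codes (distinct-person support >= %d)\n",
              length(x$index), x$min_persons))
  invisible(x)
}

#' Encode one person's coded history for the network
#'
#' Events whose code is absent from the vocabulary are dropped first; the
#' months-between-events gaps (delta-t) are then recomputed over the retained
#' events, so delta-t describes the sequence the network actually sees.
#' The first retained event has delta-t 0. An empty retained sequence is
#' legal and yields length-0 vectors.
#'
#' @param events data.frame of one person's events, sorted non-decreasing by
#'   month (as stored in a `seqrisk_cohort`).
#' @param vocab a `seqrisk_vocab`.
#' @return List with equal-length integer vectors `token` (vocabulary
#'   indices), `type` (code-type indices 1-5 per [code_types()]) and `delta`
#'   (months since the previous retained event).
#' @export
encode_history <- function(events, vocab) {
  tok <- unname(vocab$index[events$code])
  keep <- !is.na(tok)
  tok <- tok[keep]
  typ <- match(events$code_type[keep], code_types())
  mon <- events$month[keep]
  n <- length(tok)
  delta <- if (n == 0L) integer(0) else c(0L, diff(as.integer(mon)))
  list(token = as.integer(tok), type = as.integer(typ), delta = as.integer(delta))
}

#' Encode every person in a cohort
#'
#' @param cohort a `seqrisk_cohort`.
#' @param vocab a `seqrisk_vocab`.
#' @param max_len keep at most this many events per person, retaining the most
#'   recent ones (bounds memory for very long histories).
#' @return Named list (by `person_id`) of [encode_history()] results, in
#'   `cohort$persons` row order.
#' @export
encode_cohort <- function(cohort, vocab, max_len = 500L) {
  ids <- cohort$persons$person_id
  ev_split <- split(seq_len(nrow(cohort$events)), cohort$events$person_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  empty <- list(token = integer(0), type = integer(0), delta = integer(0))
  for (i in seq_along(ids)) {
    rows <- ev_split[[ids[i]]]
    if (is.null(rows)) {
      out[[i]] <- empty
    } else {
      h <- encode_history(cohort$events[rows, , drop = FALSE], vocab)
      if (length(h$token) > max_len) {
        # keep the most recent events; the kept range is contiguous so the
        # within-range gaps are unchanged and only the first resets to 0
        keep <- seq.int(length(h$token) - max_len + 1L, length(h$token))
        h <- list(token = h$token[keep], type = h$type[keep], delta = h$delta[keep])
        h$delta[1L] <- 0L
      }
      out[[i]] <- h
    }
  }
  out
}

#' Fit the covariate centering context on a training stratum
#'
#' Age is centred at the stratum mean; deprivation at the third quintile;
#' ethnicity at its reference level. The context is fitted on training data
#' of the matching sex stratum only, and travels with every fitted model.
#'
#' @param persons persons table of the training stratum.
#' @return List with `mean_age`, `dep_ref` (3), `ethnicity_ref`, `sex`.
#' @export
fit_centering <- function(persons) {
  sex <- unique(persons$sex)
  list(mean_age = mean(persons$age), dep_ref = 3,
       ethnicity_ref = ethnicity_levels()[1L],
       sex = if (length(sex) == 1L) sex else "mixed")
}

covariate_names <- function(predictor_set = c("full", "reduced")) {
  predictor_set <- match.arg(predictor_set)
  eth <- paste0("ethnicity", ethnicity_levels()[-1L])
  base <- c("age", "deprivation", eth)
  if (predictor_set == "reduced") return(base)
  c(base, flag_columns(),
    "age_x_bp_lowering", "age_x_diabetes", "age_x_atrial_fibrillation",
    "bp_lowering_x_diabetes", "antiplatelet_anticoagulant_x_diabetes",
    "bp_lowering_x_lipid_lowering")
}

#' Build the pre-specified covariate matrix
#'
#' Layout (full predictor set): centred age; centred deprivation quintile;
#' ethnicity one-hot with the reference level omitted; the five binary
#' history/medication flags; then the six first-order interactions
#' age x blood-pressure-lowering, age x diabetes, age x atrial fibrillation,
#' blood-pressure-lowering x diabetes, antiplatelet/anticoagulant x diabetes,
#' blood-pressure-lowering x lipid-lowering. Interaction entries are the exact
#' products of their factor entries. The reduced predictor set (used in the
#' ablation experiment) keeps only centred age, centred deprivation and the
#' ethnicity one-hot. A person at the stratum mean age, quintile 3, reference
#' ethnicity with all flags FALSE maps to the all-zero vector.
#'
#' @param persons persons table (one or more rows).
#' @param centering centering context from [fit_centering()].
#' @param predictor_set `"full"` or `"reduced"`.
#' @return Numeric matrix, one row per person, with stable column names.
#' @export
covariate_matrix <- function(persons, centering, predictor_set = c("full", "reduced")) {
  predictor_set <- match.arg(predictor_set)
  if (any(!persons$deprivation %in% 1:5))
    stop("invalid input: deprivation outside 1-5")
  age <- persons$age - centering$mean_age
  dep <- persons$deprivation - centering$dep_ref
  eth <- vapply(ethnicity_levels()[-1L],
                function(l) as.numeric(persons$ethnicity == l),
                numeric(nrow(persons)))
  if (nrow(persons) == 1L) eth <- matrix(eth, nrow = 1L)
  X <- cbind(age = age, deprivation = dep, eth)
  if (predictor_set == "full") {
    fl <- vapply(flag_columns(), function(f) as.numeric(persons[[f]]),
                 numeric(nrow(persons)))
    if (nrow(persons) == 1L) fl <- matrix(fl, nrow = 1L,
                                          dimnames = list(NULL, flag_columns()))
    X <- cbind(X, fl,
               age * fl[, "bp_lowering"], age * fl[, "diabetes"],
               age * fl[, "atrial_fibrillation"],
               fl[, "bp_lowering"] * fl[, "diabetes"],
               fl[, "antiplatelet_anticoagulant"] * fl[, "diabetes"],
               fl[, "bp_lowering"] * fl[, "lipid_lowering"])
  }
  colnames(X) <- covariate_names(predictor_set)
  X
}

#' The reference person of a centering context
#'
#' Mean age, third deprivation quintile, reference ethnicity, all flags
#' FALSE, empty coded history. Absolute risks and local hazard ratios are
#' anchored at this person.
#'
#' @param centering centering context from [fit_centering()].
#' @param sex sex label for the record (defaults to the context's stratum).
#' @return A one-row persons data.frame (with an empty events attribute
#'   convention: the reference person has no coded events).
#' @export
reference_person <- function(centering, sex = NULL) {
  data.frame(person_id = "__reference__",
             sex = if (is.null(sex)) centering$sex else sex,
             age = centering$mean_age,
             ethnicity = centering$ethnicity_ref,
             deprivation = centering$dep_ref,
             diabetes = FALSE, atrial_fibrillation = FALSE,
             bp_lowering = FALSE, lipid_lowering = FALSE,
             antiplatelet_anticoagulant = FALSE,
             follow_up_days = NA_integer_, cvd_event = NA,
             stringsAsFactors = FALSE)
}

#' Write a cohort to a directory of plain text files
#'
#' The on-disk dialect is two comma-separated UTF-8 files with header rows:
#' `persons.csv` (one row per person; logical flags as 0/1) and `events.csv`
#' (one row per code listing: `person_id, code, code_type, month`), plus a
#' flat key-value `manifest.txt` recording `lookback_months`.
#'
#' @param cohort a `seqrisk_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$persons
  for (f in c(flag_columns(), "cvd_event")) p[[f]] <- as.integer(p[[f]])
  utils::write.csv(p, file.path(dir, "persons.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("lookback_months: ", cohort$lookback_months),
               "format: seqrisk-cohort-v1"),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Malformed rows are rejected with an error naming the file, row and field.
#'
#' @param dir directory containing `persons.csv`, `events.csv` and
#'   `manifest.txt`.
#' @return A `seqrisk_cohort`.
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "persons.csv")
  efile <- file.path(dir, "events.csv")
  if (!file.exists(pfile)) stop("missing ", pfile)
  if (!file.exists(efile)) stop("missing ", efile)
  lookback <- 60L
  mfile <- file.path(dir, "manifest.txt")
  if (file.exists(mfile)) {
    ln <- grep("^lookback_months:", readLines(mfile), value = TRUE)
    if (length(ln) == 1L) lookback <- as.integer(sub("^lookback_months: *", "", ln))
  }
  persons <- utils::read.csv(pfile, stringsAsFactors = FALSE,
                             colClasses = c(person_id = "character",
                                            sex = "character",
                                            ethnicity = "character"))
  for (f in c(flag_columns(), "cvd_event")) persons[[f]] <- persons[[f]] == 1
  if (all(is.na(persons$follow_up_days))) persons$cvd_event <- NA
  events <- utils::read.csv(efile, stringsAsFactors = FALSE,
                            colClasses = c(person_id = "character",
                                           code = "character"))
  validate_persons(persons, file = pfile)
  validate_events(events, lookback, persons$person_id, file = efile)
  new_cohort(persons, events, lookback)
}
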