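# Shared fixtures and independent oracles for the test-suite.

# hand-built persons table; flags default FALSE, outcomes settable
make_persons <- function(n, sex = "F", age = 50, ethnicity = "European",
                         deprivation = 3, follow_up = NA_integer_,
                         event = NA) {
  data.frame(person_id = sprintf("t%03d", seq_len(n)), sex = sex, age = age,
             ethnicity = ethnicity, deprivation = deprivation,
             diabetes = FALSE, atrial_fibrillation = FALSE,
             bp_lowering = FALSE, lipid_lowering = FALSE,
             antiplatelet_anticoagulant = FALSE,
             follow_up_days = follow_up, cvd_event = event,
             stringsAsFactors = FALSE)
}

make_events <- function(person_id, code, code_type = "primary_dx", month = 0L) {
  data.frame(person_id = person_id, code = code, code_type = code_type,
             month = as.integer(month), stringsAsFactors = FALSE)
}

no_events <- function() {
  data.frame(person_id = character(0), code = character(0),
             code_type = character(0), month = integer(0),
             stringsAsFactors = FALSE)
}

# exhaustive all-pairs concordance oracle (the definition, O(n^2))
brute_force_c <- function(f, time, event) {
  n <- length(f)
  conc <- 0; ties <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- NULL
    if (time[i] < time[j] && event[i]) a <- c(i, j)
    else if (time[j] < time[i] && event[j]) a <- c(j, i)
    else if (time[i] == time[j] && xor(event[i], event[j]))
      a <- if (event[i]) c(i, j) else c(j, i)
    if (is.null(a)) next
    comp <- comp + 1
    if (f[a[1]] > f[a[2]]) conc <- conc + 1
    else if (f[a[1]] == f[a[2]]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / comp
}

# random censored instance for metric oracle checks
random_survival_instance <- function(n, tie_prob = 0.3) {
  time <- sample.int(20L, n, replace = TRUE)
  if (tie_prob == 0) time <- sample.int(1000L, n)
  event <- runif(n) < 0.6
  f <- round(rnorm(n), if (runif(1) < 0.5) 1 else 4)
  list(f = f, time = time, event = event)
}

# tiny trained ensemble for plumbing tests
tiny_ensemble <- function(cohort, seed = 1L, members = 1L) {
  cfg <- model_config(embedding_dim = 2L, epochs = 1L, ensemble_size = members,
                      batch_cases = 16L, learning_rate = 0.01, seed = seed)
  train_ensemble(cohort, cfg, min_persons = 1L)
}
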