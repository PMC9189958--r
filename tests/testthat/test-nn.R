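test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  cfg <- model_config(embedding_dim = 3L, dropout = 0, seed = 1L)
  params <- nn_init_params(cfg, 7L, 4L)
  hs <- list(list(token = c(1L, 3L, 7L), type = c(1L, 5L, 2L), delta = c(0L, 2L, 5L)),
             list(token = c(2L, 2L), type = c(4L, 3L), delta = c(0L, 0L)),
             list(token = integer(0), type = integer(0), delta = integer(0)),
             list(token = 5L, type = 2L, delta = 0L))
  X <- matrix(rnorm(16), 4L, 4L)
  batch <- nn_batch(hs, X)
  fw <- nn_forward(params, batch, cfg, training = TRUE)
  df <- c(0.7, -1.2, 0.4, 0.9)
  g <- nn_backward(params, fw$cache, df, cfg)
  loss <- function(p) sum(df * nn_forward(p, batch, cfg)$f)
  eps <- 1e-6
  for (nm in names(params)) {
    pa <- params[[nm]]
    for (i in sample(length(pa), min(4L, length(pa)))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss(p1) - loss(p2)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("a zero-parameter network is constant and equals the output bias", {
  cfg <- model_config(embedding_dim = 3L, seed = 1L)
  set.seed(1)
  params <- nn_init_params(cfg, 5L, 4L)
  params <- lapply(params, function(p) p * 0)
  params$head.b2 <- 0.7
  hs <- list(list(token = c(1L, 2L), type = c(1L, 2L), delta = c(0L, 3L)),
             list(token = integer(0), type = integer(0), delta = integer(0)))
  f <- nn_forward(params, nn_batch(hs, matrix(rnorm(8), 2L)), cfg)$f
  expect_identical(f, c(0.7, 0.7))
})

test_that("evaluation mode is deterministic and the empty history gives the zero-context head value", {
  cfg <- model_config(embedding_dim = 4L, seed = 2L)
  set.seed(2)
  params <- nn_init_params(cfg, 9L, 3L)
  hist1 <- list(token = c(3L, 9L), type = c(1L, 4L), delta = c(0L, 7L))
  xcov <- c(1.5, -0.5, 2)
  f1 <- forward_log_risk(params, hist1, xcov, cfg)
  f2 <- forward_log_risk(params, hist1, xcov, cfg)
  expect_identical(f1, f2)
  # empty history: context is exactly zero, so f equals the head applied to
  # (0-context, covariates)
  empty <- list(token = integer(0), type = integer(0), delta = integer(0))
  f0 <- forward_log_risk(params, empty, xcov, cfg)
  M <- 2L * (cfg$embedding_dim + 1L) + 3L
  z0 <- c(rep(0, M - 3L), xcov)
  a1 <- drop(z0 %*% params$head.W1) + params$head.b1
  h1 <- ifelse(a1 > 0, a1, exp(pmin(a1, 0)) - 1)
  expect_equal(f0, sum(h1 * params$head.w2) + params$head.b2)
})

test_that("attention weights are a probability distribution over real events", {
  cfg <- model_config(embedding_dim = 3L, seed = 4L)
  set.seed(4)
  params <- nn_init_params(cfg, 6L, 2L)
  params$att_q <- rnorm(2L * (cfg$embedding_dim + 1L))  # non-trivial query
  hs <- list(list(token = c(1L, 4L, 6L), type = c(1L, 2L, 5L), delta = c(0L, 1L, 2L)),
             list(token = 2L, type = 3L, delta = 0L),
             list(token = integer(0), type = integer(0), delta = integer(0)))
  batch <- nn_batch(hs, matrix(0, 3L, 2L))
  fw <- nn_forward(params, batch, cfg)
  expect_true(all(fw$alpha >= 0))
  expect_equal(rowSums(fw$alpha), c(1, 1, 0))
  expect_true(all(fw$alpha[1L, ] > 0))
  expect_equal(fw$alpha[2L, 1L], 1)
})

test_that("pair loss matches its closed form and saturates", {
  expect_equal(partial_likelihood_loss(1, 1), log(2))
  expect_lt(partial_likelihood_loss(20, 0), 1e-8)
  expect_equal(partial_likelihood_loss(c(0, log(3)), c(0, 0)),
               (log(2) + log(1 + 1 / 3)) / 2)
  expect_error(partial_likelihood_loss(1:3, 1:2), "mismatch")
  # invariance to a common shift of all scores
  f1 <- rnorm(5); f2 <- rnorm(5)
  expect_equal(partial_likelihood_loss(f1, f2),
               partial_likelihood_loss(f1 + 13.7, f2 + 13.7))
})

test_that("sampled controls are always in the case's risk set", {
  set.seed(11)
  tm <- sample.int(1000L, 200L, replace = TRUE)
  ev <- runif(200) < 0.4
  for (rep in 1:10) {
    batches <- sample_case_control_epoch(tm, ev, batch_cases = 32L)
    for (b in batches) {
      expect_true(all(tm[b$controls] >= tm[b$cases]))
      expect_true(all(b$controls != b$cases))
    }
  }
  # all cases appear once per epoch
  batches <- sample_case_control_epoch(tm, ev, batch_cases = 32L)
  expect_setequal(unlist(lapply(batches, `[[`, "cases")), which(ev))
})

test_that("a case with an empty risk set is skipped with a warning", {
  tm <- c(10L, 5L, 3L)
  ev <- c(TRUE, TRUE, FALSE)
  set.seed(1)
  expect_warning(b <- sample_case_control_epoch(tm, ev, 8L), "empty risk set")
  expect_false(1L %in% unlist(lapply(b, `[[`, "cases")))
  expect_error(sample_case_control_epoch(c(5L, 1L), c(FALSE, FALSE), 8L),
               "no events")
})

test_that("batch sampling is reproducible under a fixed seed", {
  tm <- sample.int(500L, 100L, replace = TRUE)
  ev <- seq_len(100L) %% 3L == 0L
  set.seed(99); a <- sample_case_control_epoch(tm, ev, 16L)
  set.seed(99); b <- sample_case_control_epoch(tm, ev, 16L)
  expect_identical(a, b)
})

test_that("training reduces the loss and is fully reproducible", {
  cfg0 <- sim_preset("linear", n_persons = 600, seed = 47)
  co <- simulate_cohort(cfg0)$cohort
  mcfg <- model_config(embedding_dim = 3L, epochs = 4L, ensemble_size = 2L,
                       batch_cases = 32L, learning_rate = 0.02, seed = 7L)
  ens <- train_ensemble(co, mcfg, min_persons = 10L)
  for (tr in ens$loss_traces) expect_lt(tr[length(tr)], tr[1L])
  f1 <- predict_log_risk(ens, co)
  ens2 <- train_ensemble(co, mcfg, min_persons = 10L)
  expect_identical(as.numeric(predict_log_risk(ens2, co)), as.numeric(f1))
  # order contract: permuting persons permutes predictions
  idx <- sample(nrow(co$persons))
  f_perm <- predict_log_risk(ens, subset_cohort(co, idx))
  expect_equal(as.numeric(f_perm), as.numeric(f1)[idx])
})

test_that("ensemble predictions are the arithmetic mean of member outputs", {
  cfg <- model_config(embedding_dim = 2L, seed = 5L, ensemble_size = 2L)
  set.seed(5)
  n_cov <- ncol(covariate_matrix(make_persons(1),
                                 fit_centering(make_persons(1)), "full"))
  m1 <- lapply(nn_init_params(cfg, 4L, n_cov), function(p) p * 0)
  m2 <- m1
  m1$head.b2 <- 1.2
  m2$head.b2 <- -0.4
  vocab <- structure(list(index = stats::setNames(1:4, c("A", "B", "C", "D")),
                          counts = rep(1L, 4L), min_persons = 1L),
                     class = "seqrisk_vocab")
  ens <- structure(list(members = list(m1, m2), config = cfg, vocab = vocab,
                        centering = list(mean_age = 50, dep_ref = 3,
                                         ethnicity_ref = "European", sex = "F"),
                        loss_traces = list()),
                   class = "seqrisk_ensemble")
  co <- new_cohort(make_persons(3), no_events())
  f <- predict_log_risk(ens, co)
  expect_equal(as.numeric(f), rep((1.2 - 0.4) / 2, 3))
  expect_equal(dim(attr(f, "members")), c(3L, 2L))
})
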