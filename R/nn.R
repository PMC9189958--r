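#' Network configuration
#'
#' Architecture and training hyperparameters of the recurrent relative-risk
#' network. The published configuration is the default: three stacked
#' bidirectional gated recurrent unit (GRU) layers with 10% inter-layer
#' dropout and hidden size equal to the input size, dot-product attention
#' pooling, a size-preserving fully connected layer with exponential linear
#' unit (ELU) activation mapping to a scalar log relative risk; training by
#' Adam (learning rate 0.001, betas 0.9/0.999) on the Cox partial likelihood
#' with 256-case mini-batches matched 1:1 to risk-set controls, stopped
#' after 10 epochs; ensembles of 10 independently initialized members whose
#' log-risk predictions are averaged.
#'
#' @param embedding_dim dimension shared by code and type embeddings.
#' @param gru_layers number of stacked bidirectional recurrent layers.
#' @param bidirectional process sequences in both directions (outputs of the
#'   two directions are concatenated at each position).
#' @param dropout inter-layer dropout fraction, training only.
#' @param learning_rate,adam_betas Adam optimizer settings.
#' @param lr_decay fraction of the learning rate linearly decayed away by the
#'   final epoch (0 = constant rate).
#' @param batch_cases cases per mini-batch.
#' @param epochs training epochs (each iterates over all cases).
#' @param ensemble_size number of independently initialized members.
#' @param max_sequence_length histories longer than this keep only their most
#'   recent events.
#' @param seed base seed; member k derives its own stream from `(seed, k)`.
#' @param predictor_set `"full"` or `"reduced"` pre-specified covariates.
#' @return A `seqrisk_model_config` list.
#' @export
model_config <- function(embedding_dim = 16L, gru_layers = 3L,
                         bidirectional = TRUE, dropout = 0.10,
                         learning_rate = 0.001, adam_betas = c(0.9, 0.999),
                         lr_decay = 0,
                         batch_cases = 256L, epochs = 10L,
                         ensemble_size = 10L, max_sequence_length = 500L,
                         seed = 1L, predictor_set = "full") {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (embedding_dim < 1L) stop("embedding_dim must be >= 1")
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 gru_layers = as.integer(gru_layers),
                 bidirectional = isTRUE(bidirectional),
                 dropout = dropout, learning_rate = learning_rate,
                 adam_betas = adam_betas, lr_decay = lr_decay,
                 batch_cases = as.integer(batch_cases),
                 epochs = as.integer(epochs),
                 ensemble_size = as.integer(ensemble_size),
                 max_sequence_length = as.integer(max_sequence_length),
                 seed = as.integer(seed),
                 predictor_set = match.arg(predictor_set, c("full", "reduced"))),
            class = "seqrisk_model_config")
}

#' Desk-scale network configuration
#'
#' The published training configuration was sized for two million people and
#' tens of thousands of events; cohorts of a few thousand persons need
#' proportionally adapted optimization to reach the same regime. This helper
#' returns the configuration used by the package's own experiments: a small
#' network (embedding dimension 4), 64-case batches, 20 epochs with the
#' learning rate decaying linearly from 0.006 to about 0.001, and 5-member
#' ensembles. Chosen by monitoring held-out loss the same way the original
#' 10-epoch rule was chosen; see the methods vignette.
#'
#' @param seed base seed.
#' @param ... overrides passed to [model_config()].
#' @return A `seqrisk_model_config`.
#' @export
desk_model_config <- function(seed = 1L, ...) {
  args <- list(embedding_dim = 4L, epochs = 20L, ensemble_size = 5L,
               batch_cases = 64L, learning_rate = 0.006, lr_decay = 0.85,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# ---- parameter container ------------------------------------------------
# params is a flat named list of numeric matrices/vectors:
#   emb_code ((V+1) x d, row 1 = padding), emb_type (6 x d, row 1 = padding),
#   L<l><f|b>.Wi (in_l x 3H), .Wh (H x 3H), .bi, .bh (3H),
#   att_q (2H), head.W1 (M x M), head.b1 (M), head.w2 (M), head.b2 (1)
# with H = embedding_dim + 1 (per direction), M = 2H + n_covariates.

nn_dims <- function(config, n_vocab, n_cov) {
  d <- config$embedding_dim
  H <- d + 1L
  ndir <- if (config$bidirectional) 2L else 1L
  list(d = d, H = H, ndir = ndir, out = ndir * H, M = ndir * H + n_cov,
       n_vocab = n_vocab, n_cov = n_cov)
}

#' Initialize one network member
#'
#' Embeddings are drawn N(0, 0.3^2); recurrent and dense weights uniform on
#' +/- 1/sqrt(fan-in). Gate biases start open (reset-gate bias +1,
#' update-gate bias -1) and the attention query starts at zero (uniform
#' attention), so early training behaves like a bag-of-codes model and
#' gradients reach the embeddings first-order. Uses the current RNG stream.
#'
#' @param config a `seqrisk_model_config`.
#' @param n_vocab vocabulary size (token indices 1..n_vocab; 0 = padding).
#' @param n_cov length of the covariate vector.
#' @return Flat named list of parameter arrays.
#' @export
nn_init_params <- function(config, n_vocab, n_cov) {
  dm <- nn_dims(config, n_vocab, n_cov)
  H <- dm$H
  u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
  p <- list(emb_code = matrix(stats::rnorm((n_vocab + 1L) * dm$d, 0, 0.3),
                              n_vocab + 1L, dm$d),
            emb_type = matrix(stats::rnorm(6L * dm$d, 0, 0.3), 6L, dm$d))
  p$emb_code[1L, ] <- 0
  p$emb_type[1L, ] <- 0
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  for (l in seq_len(config$gru_layers)) {
    d_in <- if (l == 1L) H else dm$out
    for (dir in dirs) {
      key <- sprintf("L%d%s", l, dir)
      p[[paste0(key, ".Wi")]] <- u(d_in, 3L * H, H)
      p[[paste0(key, ".Wh")]] <- u(H, 3L * H, H)
      bi <- stats::runif(3L * H, -1, 1) / sqrt(H)
      bi[seq_len(H)] <- bi[seq_len(H)] + 1        # reset gate open
      bi[H + seq_len(H)] <- bi[H + seq_len(H)] - 1 # update gate favours input
      p[[paste0(key, ".bi")]] <- bi
      p[[paste0(key, ".bh")]] <- stats::runif(3L * H, -1, 1) / sqrt(H)
    }
  }
  p$att_q <- numeric(dm$out)
  # identity-plus-noise start for the size-preserving layer: the head then
  # begins as a near-linear model of context and covariates
  p$head.W1 <- diag(dm$M) + u(dm$M, dm$M, dm$M) / 2
  p$head.b1 <- stats::runif(dm$M, -1, 1) / sqrt(dm$M)
  p$head.w2 <- stats::runif(dm$M, -1, 1) / sqrt(dm$M)
  p$head.b2 <- 0
  p
}

#' Pack encoded histories and covariates into a padded batch
#'
#' @param histories list of [encode_history()] results.
#' @param X covariate matrix, one row per history.
#' @return List with integer matrices `tok`, `typ`, numeric `dt` (months-gap
#'   scaled by the 60-month lookback, keeping the recurrent gates in their
#'   responsive range), 0/1 `mask` (all B x T, right-padded) and `X`.
#' @export
nn_batch <- function(histories, X) {
  B <- length(histories)
  lens <- vapply(histories, function(h) length(h$token), integer(1))
  T_ <- max(1L, max(lens))
  tok <- matrix(0L, B, T_)
  typ <- matrix(0L, B, T_)
  dt <- matrix(0, B, T_)
  mask <- matrix(0, B, T_)
  for (b in seq_len(B)) {
    n <- lens[b]
    if (n == 0L) next
    tok[b, seq_len(n)] <- histories[[b]]$token
    typ[b, seq_len(n)] <- histories[[b]]$type
    dt[b, seq_len(n)] <- histories[[b]]$delta
    mask[b, seq_len(n)] <- 1
  }
  list(tok = tok, typ = typ, dt = dt / 60, mask = mask,
       X = matrix(as.numeric(X), nrow = B))
}

mat3 <- function(a) { d <- dim(a); dim(a) <- c(d[1L] * d[2L], d[3L]); a }
arr3 <- function(m, B, T_, D) { dim(m) <- c(B, T_, D); m }

# one direction of one GRU layer over a padded batch; masked (padded)
# positions carry the hidden state through unchanged in both passes.
# The time loop runs in compiled code (src/gru.cpp); rows of the flattened
# matrices index (person, time) pairs person-fastest.
gru_forward <- function(Xa, mask, Wi, Wh, bi, bh, reverse, keep_cache) {
  B <- dim(Xa)[1L]; T_ <- dim(Xa)[2L]; H <- nrow(Wh)
  Xp <- mat3(Xa) %*% Wi
  Xp <- Xp + rep(bi, each = B * T_)
  res <- gru_fwd_cpp(Xp, c(mask), Wh, bh, reverse, B, T_, keep_cache)
  cache <- NULL
  if (keep_cache) {
    cache <- res[c("r", "z", "n", "ahn", "hprev")]
    cache$X_m <- mat3(Xa)
  }
  list(out = arr3(res$out, B, T_, H), cache = cache)
}

gru_backward <- function(dH, cache, mask, Wi, Wh, reverse) {
  B <- dim(dH)[1L]; T_ <- dim(dH)[2L]; H <- nrow(Wh)
  res <- gru_bwd_cpp(mat3(dH), cache$r, cache$z, cache$n, cache$ahn,
                     cache$hprev, c(mask), Wh, reverse, B, T_)
  list(dX = arr3(res$dXp %*% t(Wi), B, T_, nrow(Wi)),
       gWi = crossprod(cache$X_m, res$dXp), gWh = res$gWh,
       gbi = colSums(res$dXp), gbh = drop(res$gbh))
}

#' Forward pass: log relative risk of a batch
#'
#' Computation, in order: (1) per event, code embedding plus type embedding,
#' concatenated with the scalar months-gap delta-t; (2) the stacked
#' (bi)directional gated recurrent layers, direction outputs concatenated at
#' each position, inter-layer dropout when `training`; (3) dot-product
#' attention pooling with a learned query vector, softmax over unpadded
#' positions (an empty history yields the zero context vector); (4) context
#' concatenated with the covariate vector; (5) size-preserving dense layer
#' with ELU activation; (6) dense map to the scalar log relative risk.
#' Evaluation mode (`training = FALSE`) is deterministic.
#'
#' @param params parameter list from [nn_init_params()].
#' @param batch a batch from [nn_batch()].
#' @param config a `seqrisk_model_config`.
#' @param training enable dropout (uses the current RNG stream) and keep the
#'   caches needed by [nn_backward()].
#' @return List with `f` (numeric length-B vector) and `cache` (NULL unless
#'   `training`).
#' @export
nn_forward <- function(params, batch, config, training = FALSE) {
  B <- nrow(batch$tok); T_ <- ncol(batch$tok)
  dm <- nn_dims(config, nrow(params$emb_code) - 1L, ncol(batch$X))
  H <- dm$H
  E <- params$emb_code[c(batch$tok) + 1L, , drop = FALSE] +
       params$emb_type[c(batch$typ) + 1L, , drop = FALSE]
  X0 <- arr3(cbind(E, c(batch$dt)), B, T_, H)
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  layers <- vector("list", config$gru_layers)
  drop_masks <- vector("list", config$gru_layers)
  Xl <- X0
  for (l in seq_len(config$gru_layers)) {
    outs <- vector("list", length(dirs))
    caches <- vector("list", length(dirs))
    for (k in seq_along(dirs)) {
      g <- gru_forward(Xl, batch$mask,
                       params[[sprintf("L%d%s.Wi", l, dirs[k])]],
                       params[[sprintf("L%d%s.Wh", l, dirs[k])]],
                       params[[sprintf("L%d%s.bi", l, dirs[k])]],
                       params[[sprintf("L%d%s.bh", l, dirs[k])]],
                       reverse = dirs[k] == "b", keep_cache = training)
      outs[[k]] <- g$out
      caches[[k]] <- g$cache
    }
    O <- array(0, c(B, T_, dm$out))
    O[, , seq_len(H)] <- outs[[1L]]
    if (length(dirs) == 2L) O[, , H + seq_len(H)] <- outs[[2L]]
    layers[[l]] <- list(input = Xl, caches = caches)
    if (training && config$dropout > 0 && l < config$gru_layers) {
      dmask <- array((stats::runif(B * T_ * dm$out) >= config$dropout) /
                       (1 - config$dropout), c(B, T_, dm$out))
      O <- O * dmask
      drop_masks[[l]] <- dmask
    }
    Xl <- O
  }
  O <- Xl
  # attention pooling over unpadded positions
  s <- matrix(mat3(O) %*% params$att_q, B, T_)
  s[batch$mask == 0] <- -Inf
  smax <- apply(s, 1L, max)
  smax[!is.finite(smax)] <- 0
  a <- exp(s - smax)
  a[batch$mask == 0] <- 0
  den <- rowSums(a)
  den[den == 0] <- 1
  alpha <- a / den
  ctx <- matrix(0, B, dm$out)
  for (t in seq_len(T_)) ctx <- ctx + alpha[, t] * matrix(O[, t, ], B)
  z0 <- cbind(ctx, batch$X)
  a1 <- z0 %*% params$head.W1 + rep(params$head.b1, each = B)
  h1 <- ifelse(a1 > 0, a1, exp(pmin(a1, 0)) - 1)
  f <- drop(h1 %*% params$head.w2) + params$head.b2
  cache <- NULL
  if (training)
    cache <- list(batch = batch, layers = layers, drop_masks = drop_masks,
                  O = O, alpha = alpha, ctx = ctx, z0 = z0, a1 = a1, h1 = h1,
                  dm = dm)
  list(f = f, cache = cache, alpha = alpha)
}

#' Backward pass: parameter gradients
#'
#' Backpropagation through the head, attention pooling, the stacked
#' (bi)directional recurrent layers and the embeddings, for a batch forward
#' pass run with `training = TRUE`.
#'
#' @param params parameter list.
#' @param cache cache returned by [nn_forward()].
#' @param df gradient of the loss with respect to each `f` (length B).
#' @param config a `seqrisk_model_config`.
#' @return Named list of gradients matching `params`.
#' @export
nn_backward <- function(params, cache, df, config) {
  batch <- cache$batch; dm <- cache$dm
  B <- nrow(batch$tok); T_ <- ncol(batch$tok); H <- dm$H
  g <- list()
  # head
  dh1 <- df %o% params$head.w2
  da1 <- dh1 * ifelse(cache$a1 > 0, 1, cache$h1 + 1)
  g$head.w2 <- drop(crossprod(cache$h1, df))
  g$head.b2 <- sum(df)
  g$head.W1 <- crossprod(cache$z0, da1)
  g$head.b1 <- colSums(da1)
  dz0 <- da1 %*% t(params$head.W1)
  dctx <- dz0[, seq_len(dm$out), drop = FALSE]
  # attention
  alpha <- cache$alpha
  O <- cache$O
  dO <- array(0, c(B, T_, dm$out))
  dalpha <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    Ot <- matrix(O[, t, ], B)
    dO[, t, ] <- alpha[, t] * dctx
    dalpha[, t] <- rowSums(dctx * Ot)
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  g$att_q <- drop(crossprod(mat3(O), c(ds)))
  dO <- arr3(mat3(dO) + c(ds) %o% params$att_q, B, T_, dm$out)
  # recurrent stack
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  dXl <- dO
  for (l in rev(seq_len(config$gru_layers))) {
    if (!is.null(cache$drop_masks[[l]])) dXl <- dXl * cache$drop_masks[[l]]
    lay <- cache$layers[[l]]
    dX_in <- NULL
    for (k in seq_along(dirs)) {
      idx <- if (k == 1L) seq_len(H) else H + seq_len(H)
      bk <- gru_backward(dXl[, , idx, drop = FALSE], lay$caches[[k]],
                         batch$mask,
                         params[[sprintf("L%d%s.Wi", l, dirs[k])]],
                         params[[sprintf("L%d%s.Wh", l, dirs[k])]],
                         reverse = dirs[k] == "b")
      g[[sprintf("L%d%s.Wi", l, dirs[k])]] <- bk$gWi
      g[[sprintf("L%d%s.Wh", l, dirs[k])]] <- bk$gWh
      g[[sprintf("L%d%s.bi", l, dirs[k])]] <- bk$gbi
      g[[sprintf("L%d%s.bh", l, dirs[k])]] <- bk$gbh
      dX_in <- if (is.null(dX_in)) bk$dX else dX_in + bk$dX
    }
    dXl <- dX_in
  }
  # embeddings: masked positions received zero gradient through the masked
  # recurrence and attention, so plain accumulation is exact
  dE <- mat3(dXl)[, seq_len(dm$d), drop = FALSE]
  g$emb_code <- matrix(0, dm$n_vocab + 1L, dm$d)
  g$emb_type <- matrix(0, 6L, dm$d)
  agg <- rowsum(dE, c(batch$tok) + 1L)
  g$emb_code[as.integer(rownames(agg)), ] <- agg
  agg <- rowsum(dE, c(batch$typ) + 1L)
  g$emb_type[as.integer(rownames(agg)), ] <- agg
  g$emb_code[1L, ] <- 0
  g$emb_type[1L, ] <- 0
  g
}

#' Log relative risk of a single person under one member
#'
#' Convenience wrapper around [nn_forward()] in evaluation mode.
#'
#' @param params one member's parameters.
#' @param history an [encode_history()] result.
#' @param covariates covariate vector (as from [covariate_matrix()]).
#' @param config a `seqrisk_model_config`.
#' @return Scalar log relative risk.
#' @export
forward_log_risk <- function(params, history, covariates, config) {
  b <- nn_batch(list(history), matrix(covariates, nrow = 1L))
  nn_forward(params, b, config, training = FALSE)$f
}

#' Sampled-risk-set partial likelihood loss
#'
#' For each case/control pair the loss is `log(1 + exp(-(f_case -
#' f_control)))`, the negative log Cox partial likelihood of a sampled risk
#' set of size two; the mean over pairs is returned. Invariant to adding a
#' constant to all scores.
#'
#' @param f_cases,f_controls equal-length score vectors for matched pairs.
#' @return Mean pair loss.
#' @export
partial_likelihood_loss <- function(f_cases, f_controls) {
  if (length(f_cases) != length(f_controls))
    stop("case/control length mismatch")
  d <- f_cases - f_controls
  mean(ifelse(d > 0, log1p(exp(-d)), -d + log1p(exp(d))))
}

#' Case-control mini-batches for one training epoch
#'
#' An epoch iterates over all cases (persons with an event) in shuffled
#' order, chunked into batches of `batch_cases` (final partial batch kept).
#' Each case's control is drawn uniformly from the persons, other than the
#' case, still at risk at the case's event time (`follow_up >= follow_up of
#' the case`); controls are redrawn independently per epoch and may recur.
#' Cases with an empty risk set are skipped with a warning. Uses the current
#' RNG stream.
#'
#' @param time,event follow-up days and event indicator vectors.
#' @param batch_cases cases per batch.
#' @return List of batches, each a list with integer `cases` and `controls`.
#' @export
sample_case_control_epoch <- function(time, event, batch_cases = 256L) {
  cases <- which(as.logical(event))
  if (length(cases) == 0L) stop("no events: cannot sample case-control batches")
  n <- length(time)
  ts <- sort(time)
  ord_asc <- order(time)
  cases <- cases[sample.int(length(cases))]
  controls <- integer(length(cases))
  keep <- logical(length(cases))
  for (j in seq_along(cases)) {
    i <- cases[j]
    # positions with time >= t_i in ascending order
    lo <- findInterval(time[i] - 0.5, ts) + 1L
    k <- n - lo + 1L
    if (k <= 1L && (k == 0L || ord_asc[lo] == i)) {
      warning("case with empty risk set skipped (person index ", i, ")")
      next
    }
    repeat {
      cand <- ord_asc[lo - 1L + sample.int(k, 1L)]
      if (cand != i) break
    }
    controls[j] <- cand
    keep[j] <- TRUE
  }
  cases <- cases[keep]
  controls <- controls[keep]
  if (length(cases) == 0L) stop("all cases had empty risk sets")
  starts <- seq(1L, length(cases), by = batch_cases)
  lapply(starts, function(s) {
    idx <- s:min(s + batch_cases - 1L, length(cases))
    list(cases = cases[idx], controls = controls[idx])
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gnm
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gnm * gnm
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

train_member <- function(histories, X, time, event, config, member_seed) {
  set.seed(member_seed)
  n_vocab_rows <- attr(histories, "n_vocab")
  params <- nn_init_params(config, n_vocab_rows, ncol(X))
  state <- adam_init(params)
  trace <- numeric(config$epochs)
  decay <- if (is.null(config$lr_decay)) 0 else config$lr_decay
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate *
      (1 - decay * (ep - 1) / max(1L, config$epochs - 1L))
    batches <- sample_case_control_epoch(time, event, config$batch_cases)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      bt <- batches[[bi]]
      idx <- c(bt$cases, bt$controls)
      m <- length(bt$cases)
      batch <- nn_batch(histories[idx], X[idx, , drop = FALSE])
      fw <- nn_forward(params, batch, config, training = TRUE)
      d <- fw$f[seq_len(m)] - fw$f[m + seq_len(m)]
      losses[bi] <- mean(ifelse(d > 0, log1p(exp(-d)), -d + log1p(exp(d))))
      if (!is.finite(losses[bi]))
        stop("non-finite training loss at epoch ", ep, ", batch ", bi)
      sig <- stats::plogis(-d) / m
      df <- c(-sig, sig)
      grads <- nn_backward(params, fw$cache, df, config)
      upd <- adam_step(params, grads, state, lr_ep, config$adam_betas)
      params <- upd$params
      state <- upd$state
    }
    trace[ep] <- mean(losses)
  }
  list(params = params, loss_trace = trace)
}

#' Train an ensemble of relative-risk networks on one stratum
#'
#' Fits the vocabulary and centering context on this stratum (unless
#' supplied, e.g. by a cross-validation driver that fitted them on the
#' training half only), encodes every history, then trains
#' `config$ensemble_size` members independently: Adam on the sampled
#' risk-set partial likelihood over case-control mini-batches for exactly
#' `config$epochs` epochs, dropout active during training only. Members
#' differ only in their derived initialization/batch seeds.
#'
#' @param cohort a `seqrisk_cohort` stratum with outcomes set.
#' @param config a `seqrisk_model_config`.
#' @param vocab,centering optional pre-fitted vocabulary / centering context.
#' @param min_persons rarity threshold when fitting the vocabulary here.
#' @return An object of class `seqrisk_ensemble`: `members` (parameter
#'   lists), `config`, `vocab`, `centering`, per-member `loss_traces`.
#' @export
train_ensemble <- function(cohort, config, vocab = NULL, centering = NULL,
                           min_persons = 1L) {
  persons <- cohort$persons
  if (any(is.na(persons$follow_up_days)))
    stop("cohort has unset outcomes; run simulate_outcomes() first")
  if (is.null(vocab)) vocab <- build_vocabulary(cohort, min_persons)
  if (is.null(centering)) centering <- fit_centering(persons)
  histories <- encode_cohort(cohort, vocab, config$max_sequence_length)
  attr(histories, "n_vocab") <- length(vocab$index)
  X <- covariate_matrix(persons, centering, config$predictor_set)
  members <- vector("list", config$ensemble_size)
  traces <- vector("list", config$ensemble_size)
  for (k in seq_len(config$ensemble_size)) {
    seed_k <- as.integer(((config$seed %% 1000000) * 1009 + k * 9973) %% 2147483646) + 1L
    fit <- train_member(histories, X, persons$follow_up_days,
                        persons$cvd_event, config, seed_k)
    members[[k]] <- fit$params
    traces[[k]] <- fit$loss_trace
  }
  structure(list(members = members, config = config, vocab = vocab,
                 centering = centering, loss_traces = traces),
            class = "seqrisk_ensemble")
}

#' @export
print.seqrisk_ensemble <- function(x, ...) {
  cat(sprintf("seqrisk ensemble: %d member(s), embedding dim %d, %d GRU layer(s), vocab %d, %s predictors\n",
              length(x$members), x$config$embedding_dim, x$config$gru_layers,
              length(x$vocab$index), x$config$predictor_set))
  invisible(x)
}

#' Ensemble log relative risk for a cohort
#'
#' Encodes the persons under the ensemble's vocabulary and centering
#' context, evaluates every member in deterministic evaluation mode, and
#' returns the member mean (and per-member matrix), order-preserving over
#' the input.
#'
#' @param ensemble a `seqrisk_ensemble`.
#' @param cohort a `seqrisk_cohort` (outcomes not required).
#' @param chunk persons per forward batch (memory bound).
#' @return Numeric vector of mean log relative risks, with the per-member
#'   matrix in attribute `"members"`.
#' @export
predict_log_risk <- function(ensemble, cohort, chunk = 1024L) {
  histories <- encode_cohort(cohort, ensemble$vocab,
                             ensemble$config$max_sequence_length)
  X <- covariate_matrix(cohort$persons, ensemble$centering,
                        ensemble$config$predictor_set)
  n <- length(histories)
  fk <- matrix(0, n, length(ensemble$members))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    batch <- nn_batch(histories[idx], X[idx, , drop = FALSE])
    for (k in seq_along(ensemble$members))
      fk[idx, k] <- nn_forward(ensemble$members[[k]], batch,
                               ensemble$config, training = FALSE)$f
  }
  f <- rowMeans(fk)
  attr(f, "members") <- fk
  f
}
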