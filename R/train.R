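# Reverse-mode gradients, Adam, and the early-stopped training loop.

# loss value without the clip warning (used inside the training loop)
loss_value_quiet <- function(h, width, at_risk, event, n_subjects) {
  sum(at_risk * (exp(pmin(h, 30)) * width - h * event)) / n_subjects
}

# gradients of sum(dh * h) w.r.t. every parameter, given the forward cache
net_gradients <- function(ex, net, dh, fw) {
  spec <- net$spec
  p <- net$params
  g <- list()
  dB <- fw$Trow * dh
  dTrow <- fw$B * dh
  dTm <- rowsum(dTrow, fw$idx)          # groups 1..M in sorted order
  # trunk
  g$tr_Wo <- crossprod(fw$T1, dTm)
  g$tr_bo <- colSums(dTm)
  dT1 <- (dTm %*% t(p$tr_Wo)) * (fw$T1 > 0)
  g$tr_W1 <- crossprod(fw$S0, dT1)
  g$tr_b1 <- colSums(dT1)
  # branch
  br <- fw$branch
  if (spec$branch == "fnn") {
    top <- if (is.null(br$A2)) br$A1 else br$A2
    g$br_Wo <- crossprod(top, dB)
    g$br_bo <- colSums(dB)
    dtop <- dB %*% t(p$br_Wo)
    if (!is.null(br$A2)) {
      d2 <- dtop * (br$A2 > 0)
      g$br_W2 <- crossprod(br$A1, d2)
      g$br_b2 <- colSums(d2)
      d1 <- (d2 %*% t(p$br_W2)) * (br$A1 > 0)
    } else {
      d1 <- dtop * (br$A1 > 0)
    }
    g$br_W1 <- crossprod(br$A0, d1)
    g$br_b1 <- colSums(d1)
  } else {
    N <- nrow(ex$X); Fl <- spec$cnn_filters; K <- spec$kernel_size
    g$br_Wo <- crossprod(br$D1, dB)
    g$br_bo <- colSums(dB)
    dD1 <- (dB %*% t(p$br_Wo)) * (br$D1 > 0)
    g$br_W1 <- crossprod(br$D0, dD1)
    g$br_b1 <- colSums(dD1)
    dD0 <- dD1 %*% t(p$br_W1)
    dflat <- dD0[, seq_len(spec$L2 * Fl), drop = FALSE]
    dP2 <- dflat; dim(dP2) <- c(N, spec$L2, Fl)
    dA2a <- maxpool_bwd(dP2, br$pool2)
    dA2 <- dA2a; dim(dA2) <- c(N * spec$L1, Fl)
    dA2 <- dA2 * (br$A2 > 0)
    g$cv_W2 <- crossprod(br$col2, dA2)
    g$cv_b2 <- colSums(dA2)
    dcol2 <- dA2 %*% t(p$cv_W2)
    dP1 <- col2im(dcol2, N, spec$L1, Fl, K)
    dA1a <- maxpool_bwd(dP1, br$pool1)
    dA1 <- dA1a; dim(dA1) <- c(N * spec$m, Fl)
    dA1 <- dA1 * (br$A1 > 0)
    g$cv_W1 <- crossprod(br$col1, dA1)
    g$cv_b1 <- colSums(dA1)
  }
  if (spec$dot_bias) g$b0 <- sum(dh)
  g[names(p)]
}

adam_init <- function(params) {
  zero <- lapply(params, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training hyperparameters
#'
#' Defaults follow common practice for this estimator: Adam with learning
#' rate 0.001, minibatches of 500 expanded rows, early stopping on the
#' validation loss with patience 10 epochs (`patience = 0` stops at the
#' first non-improving epoch), and a safety cap of 500 epochs.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size in expanded rows; each batch's loss is
#'   scaled by the number of distinct subjects contributing rows to it, so
#'   minibatch gradients target the subject-scaled objective.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param min_delta Minimum decrease of the validation loss that counts as
#'   an improvement.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return A list of class `svo_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 500L,
                         max_epochs = 500L, patience = 10L, min_delta = 0,
                         seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "svo_train_config")
}

# core loop: returns the checkpoint-best network and the per-epoch log
svo_train <- function(ex_train, ex_val, spec, config) {
  n_train <- length(ex_train$ids)
  n_val <- length(ex_val$ids)
  tr <- expanded_rows(ex_train, which(ex_train$at_risk == 1))
  va <- expanded_rows(ex_val, which(ex_val$at_risk == 1))
  N <- nrow(tr$X)
  set.seed(config$seed)
  net <- init_network(spec)
  state <- adam_init(net$params)
  best_val <- Inf
  best_params <- net$params
  best_epoch <- 0L
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(N)
    starts <- seq(1L, N, by = config$batch_size)
    tl_sum <- 0; tl_n <- 0L
    for (s0 in starts) {
      bidx <- perm[s0:min(s0 + config$batch_size - 1L, N)]
      exb <- expanded_rows(tr, bidx)
      fw <- operator_fwd_cache(exb, net)
      nb <- length(unique(exb$subject))
      dh <- loss_gradient(fw$h, exb$width, 1, exb$event, nb)
      tl_sum <- tl_sum + loss_value_quiet(fw$h, exb$width, 1, exb$event, nb)
      tl_n <- tl_n + 1L
      g <- net_gradients(exb, net, dh, fw)
      upd <- adam_step(net$params, g, state, config$learning_rate)
      net$params <- upd$params
      state <- upd$state
    }
    hv <- operator_forward(va, net)
    vloss <- loss_value_quiet(hv, va$width, 1, va$event, n_val)
    if (!is.finite(vloss))
      stop(sprintf("validation loss diverged (non-finite) at epoch %d; try a smaller learning rate", epoch))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl_sum / tl_n,
                                 val_loss = vloss))
    if (config$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      tl_sum / tl_n, vloss))
    if (vloss < best_val - config$min_delta) {
      best_val <- vloss
      best_params <- net$params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  net$params <- best_params
  list(net = net, log = log, best_epoch = best_epoch, best_val = best_val)
}

#' Grid search over training and architecture hyperparameters
#'
#' Fits every combination in `param_grid` on the training set (early
#' stopping on the validation set) and scores each fitted model by its
#' discretized loss on an independent test set; the combination with the
#' smallest test loss wins, with ties broken toward the fewest trainable
#' parameters (then first listed).
#'
#' @param train,val,test Three disjoint lists of [subject_record()]s.
#' @param grid A [time_grid()].
#' @param param_grid Named list of candidate vectors; recognised names are
#'   the arguments of [network_spec()] and [train_config()] (e.g.
#'   `learning_rate`, `batch_size`, `dense_nodes`, `cnn_filters`,
#'   `pool_size`).
#' @param branch Branch type for all candidates.
#' @param seed Base seed; candidate k trains with a derived seed.
#' @param ... Fixed arguments passed to [survonet()].
#' @return List with `best` (the winning parameter row), `scores` (the
#'   full table with test losses and parameter counts) and `fit` (the
#'   refitted winner).
#' @export
tune_survonet <- function(train, val, test, grid, param_grid,
                          branch = "fnn", seed = 1L, ...) {
  combos <- expand.grid(param_grid, stringsAsFactors = FALSE)
  stopifnot(nrow(combos) >= 1L)
  ex_test <- expand_records(test, grid)
  scores <- numeric(nrow(combos))
  npars <- integer(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    args <- c(list(data = train, grid = grid, validation = val,
                   branch = branch, seed = subject_seed(seed, k)),
              as.list(combos[k, , drop = FALSE]), list(...))
    fit <- do.call(survonet, args)
    h <- operator_forward(ex_test, fit$net)
    scores[k] <- loss_value_quiet(h, ex_test$width, ex_test$at_risk,
                                  ex_test$event, length(ex_test$ids))
    npars[k] <- n_parameters(fit$net)
  }
  ord <- order(scores, npars)
  best_k <- ord[1L]
  args <- c(list(data = train, grid = grid, validation = val,
                 branch = branch, seed = subject_seed(seed, best_k)),
            as.list(combos[best_k, , drop = FALSE]), list(...))
  list(best = combos[best_k, , drop = FALSE],
       scores = cbind(combos, test_loss = scores, n_parameters = npars),
       fit = do.call(survonet, args))
}

#' Select the sensor-grid size m across replicate datasets
#'
#' For each of `n_datasets` replicate simulated datasets, fits the model
#' at every candidate `m` (the covariate paths are re-sampled at each
#' sensor layout) and records the `m` minimising the validation loss; the
#' selected `m` is the median of the per-dataset optima.
#'
#' @param config A [sim_config()]; `config$n` subjects are used for
#'   training and an equally sized independent set for validation.
#' @param m_candidates Candidate interval counts.
#' @param n_datasets Number of replicate datasets.
#' @param seed Base seed.
#' @param ... Arguments passed to [survonet()].
#' @return List with `per_dataset` (data frame of optima) and `m` (the
#'   median, rounded to the nearest candidate).
#' @export
tune_m <- function(config, m_candidates, n_datasets = 10L, seed = 1L, ...) {
  opts <- integer(n_datasets)
  losses <- matrix(NA_real_, n_datasets, length(m_candidates))
  for (r in seq_len(n_datasets)) {
    cfg_tr <- config; cfg_tr$seed <- subject_seed(seed, 2L * r)
    cfg_va <- config; cfg_va$seed <- subject_seed(seed, 2L * r + 1L)
    for (k in seq_along(m_candidates)) {
      g <- time_grid(config$tau, m_candidates[k])
      dtr <- simulate_survdata(cfg_tr, g, keep_truth = FALSE)
      dva <- simulate_survdata(cfg_va, g, keep_truth = FALSE)
      fit <- survonet(dtr$records, g, validation = dva$records,
                      seed = subject_seed(seed, 1000L + r), ...)
      losses[r, k] <- fit$best_val_loss
    }
    opts[r] <- m_candidates[which.min(losses[r, ])]
  }
  med <- stats::median(opts)
  m_sel <- m_candidates[which.min(abs(m_candidates - med))]
  list(per_dataset = data.frame(dataset = seq_len(n_datasets),
                                best_m = opts),
       losses = losses, m = m_sel)
}
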