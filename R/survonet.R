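#' Fit a deep-operator-network conditional hazard model
#'
#' Estimates the conditional survival function given entire histories of
#' external time-varying covariates.  The log conditional hazard
#' `h[x~(s)](s)` is modelled by an operator network ([network_spec()]):
#' each subject is expanded into `m` person-period rows with future sensor
#' values masked to zero ([expand_records()]), and the network is trained
#' with Adam to minimise the discretized negative full log-likelihood
#' ([discretized_loss()]), stopping when the validation loss no longer
#' decreases and returning the parameters with the best validation loss
#' seen.
#'
#' @param data List of [subject_record()] objects (e.g. from
#'   [read_long_format()] or [simulate_survdata()]).
#' @param grid A [time_grid()]; its `m` must match the records' sensor
#'   count.
#' @param validation Either a fraction in (0, 1) of `data` to hold out
#'   for early stopping, or an independent list of records.
#' @param branch,dense_nodes,fnn_hidden_layers,cnn_filters,kernel_size,pool_size,latent_p,dot_bias
#'   Architecture settings, see [network_spec()].
#' @param learning_rate,batch_size,max_epochs,patience,min_delta Training
#'   settings, see [train_config()].
#' @param seed Seed for the validation split, weight initialization and
#'   batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `survonet` with components `net` (the
#'   fitted operator network), `grid`, `log` (per-epoch train/validation
#'   loss), `best_epoch`, `best_val_loss`, and the training records.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `simulate`, `logLik`.
#' @examples
#' cfg <- sim_config(n = 60, seed = 3)
#' g <- time_grid(100, 10)
#' d <- simulate_survdata(cfg, g, keep_truth = FALSE)
#' fit <- survonet(d$records, g, dense_nodes = 8, max_epochs = 3,
#'                 batch_size = 100, seed = 1)
#' S <- predict(fit, d$records[1:2])
#' @export
survonet <- function(data, grid, validation = 0.2,
                     branch = c("fnn", "cnn"),
                     dense_nodes = 64L, fnn_hidden_layers = 2L,
                     cnn_filters = 16L, kernel_size = 3L, pool_size = 4L,
                     latent_p = 10L, dot_bias = TRUE,
                     learning_rate = 1e-3, batch_size = 500L,
                     max_epochs = 500L, patience = 10L, min_delta = 0,
                     seed = 1L, verbose = FALSE) {
  branch <- match.arg(branch)
  stopifnot(is_svo_grid(grid), length(data) >= 2L)
  cl <- match.call()
  if (is.numeric(validation) && length(validation) == 1L) {
    stopifnot(validation > 0, validation < 1)
    set.seed(subject_seed(seed, 777L))
    n_val <- max(1L, round(validation * length(data)))
    vidx <- sample(length(data), n_val)
    records_val <- data[vidx]
    records_train <- data[-vidx]
  } else {
    records_train <- data
    records_val <- validation
  }
  check_records(records_train, grid)
  check_records(records_val, grid)
  spec <- network_spec(branch = branch, m = grid$m,
                       channels = ncol(records_train[[1L]]$x),
                       q = length(records_train[[1L]]$z),
                       dense_nodes = dense_nodes,
                       fnn_hidden_layers = fnn_hidden_layers,
                       cnn_filters = cnn_filters, kernel_size = kernel_size,
                       pool_size = pool_size, latent_p = latent_p,
                       dot_bias = dot_bias)
  tcfg <- train_config(learning_rate = learning_rate,
                       batch_size = batch_size, max_epochs = max_epochs,
                       patience = patience, min_delta = min_delta,
                       seed = seed, verbose = verbose)
  ex_train <- expand_records(records_train, grid)
  ex_val <- expand_records(records_val, grid)
  res <- svo_train(ex_train, ex_val, spec, tcfg)
  structure(list(call = cl, net = res$net, grid = grid, spec = spec,
                 log = res$log, best_epoch = res$best_epoch,
                 best_val_loss = res$best_val,
                 records_train = records_train, records_val = records_val,
                 train_config = tcfg),
            class = "survonet")
}

#' @export
print.survonet <- function(x, ...) {
  cat("Deep operator network conditional hazard model\n")
  cat(sprintf("  branch: %s; sensors: m = %d on [0, %g]; latent p = %d\n",
              toupper(x$spec$branch), x$grid$m, x$grid$tau, x$spec$latent_p))
  cat(sprintf("  subjects: %d train (%d events), %d validation\n",
              length(x$records_train),
              sum(vapply(x$records_train, `[[`, numeric(1), "delta")),
              length(x$records_val)))
  cat(sprintf("  epochs run: %d; best validation loss %.5f at epoch %d\n",
              nrow(x$log), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.survonet <- function(object, ...) {
  out <- list(fit = object,
              n_parameters = n_parameters(object$net),
              n_train = length(object$records_train),
              n_events = sum(vapply(object$records_train, `[[`,
                                    numeric(1), "delta")),
              epochs = nrow(object$log),
              best_epoch = object$best_epoch,
              best_val_loss = object$best_val_loss,
              final_train_loss = utils::tail(object$log$train_loss, 1L))
  class(out) <- "summary.survonet"
  out
}

#' @export
print.summary.survonet <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  trainable parameters: %d\n", x$n_parameters))
  cat(sprintf("  final mean train loss: %.5f\n", x$final_train_loss))
  invisible(x)
}

#' @export
coef.survonet <- function(object, ...) {
  unlist(object$net$params)
}

#' Predicted survival curves or log-hazards
#'
#' @param object A fitted [survonet()] model.
#' @param newdata List of [subject_record()]s (default: the training
#'   records).  Outcomes in `newdata` are ignored; the full covariate
#'   history of each record is used.
#' @param type `"survival"` for curves `S(t_k | history)` on the grid
#'   points `t_0 ... t_m`, `"loghazard"` for `h` at the interval left
#'   endpoints.
#' @param times Optional times at which to evaluate the (step) survival
#'   curves instead of the grid points.
#' @param ... Unused.
#' @return A numeric matrix with one row per record; columns are grid
#'   points (or `times`), stored in the `"times"` attribute.
#' @export
predict.survonet <- function(object, newdata = NULL,
                             type = c("survival", "loghazard"),
                             times = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$records_train
  if (inherits(newdata, "svo_record")) newdata <- list(newdata)
  check_records(newdata, object$grid)
  if (type == "loghazard") {
    ex <- expand_records(lapply(newdata, unrisk), object$grid)
    h <- matrix(operator_forward(ex, object$net),
                nrow = length(newdata), byrow = TRUE)
    dimnames(h) <- list(vapply(newdata, `[[`, character(1), "id"), NULL)
    attr(h, "times") <- object$grid$sensors
    return(h)
  }
  S <- predict_survival_matrix(newdata, object$net, object$grid)
  rownames(S) <- vapply(newdata, `[[`, character(1), "id")
  if (!is.null(times)) {
    S <- t(apply(S, 1L, function(row)
      surv_step_at(object$grid$points, row, times)))
    attr(S, "times") <- times
  } else {
    attr(S, "times") <- object$grid$points
  }
  S
}

#' @export
plot.survonet <- function(x, newdata = NULL, col = NULL, lty = 1,
                          xlab = "time", ylab = "S(t | history)", ...) {
  S <- predict.survonet(x, newdata)
  tt <- attr(S, "times")
  if (is.null(col)) col <- seq_len(nrow(S))
  graphics::matplot(tt, t(S), type = "s", col = col, lty = lty,
                    ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Martingale residuals of the fitted hazard
#'
#' `delta_i - Lambda_hat(y_i | history_i)`, with the cumulative hazard
#' read off the discretized survival curve.
#'
#' @param object A fitted [survonet()] model.
#' @param ... Unused.
#' @return Named numeric vector over the training records.
#' @export
residuals.survonet <- function(object, ...) {
  recs <- object$records_train
  S <- predict.survonet(object, recs)
  y <- vapply(recs, `[[`, numeric(1), "y")
  delta <- vapply(recs, `[[`, numeric(1), "delta")
  Lam <- vapply(seq_along(recs), function(i)
    -log(surv_step_at(object$grid$points, S[i, ], y[i])), numeric(1))
  stats::setNames(delta - Lam, vapply(recs, `[[`, character(1), "id"))
}

#' Simulate failure times from the fitted hazard
#'
#' Inverse-CDF sampling on the fitted discretized survival curves: for a
#' uniform draw `U`, the sampled time is the largest grid point with
#' `S_hat(t) >= U`, and draws with `U < S_hat(tau)` return `tau`
#' (follow-up cap).
#'
#' @param object A fitted [survonet()] model.
#' @param nsim Number of draws per record.
#' @param seed Optional seed.
#' @param newdata Records to simulate for (default: training records).
#' @param ... Unused.
#' @return Matrix `length(newdata) x nsim` of sampled times.
#' @export
simulate.survonet <- function(object, nsim = 1, seed = NULL,
                              newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$records_train
  S <- predict.survonet(object, newdata)
  tt <- attr(S, "times")
  out <- matrix(NA_real_, nrow(S), nsim,
                dimnames = list(rownames(S), NULL))
  for (i in seq_len(nrow(S))) {
    u <- stats::runif(nsim)
    out[i, ] <- vapply(u, function(ui) {
      ok <- S[i, ] >= ui
      if (!any(ok)) tt[1L] else tt[max(which(ok))]
    }, numeric(1))
  }
  out
}

#' @export
logLik.survonet <- function(object, ...) {
  ex <- expand_records(object$records_train, object$grid)
  h <- operator_forward(ex, object$net)
  val <- -length(ex$ids) *
    loss_value_quiet(h, ex$width, ex$at_risk, ex$event, length(ex$ids))
  structure(val, df = n_parameters(object$net),
            nobs = length(ex$ids), class = "logLik")
}
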