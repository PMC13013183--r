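#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning a step function
#' representation.  To estimate the censoring-time survival `G`, pass the
#' flipped indicators `1 - delta`.
#'
#' @param times Non-negative observed times.
#' @param indicators Event indicators (1 = the modelled endpoint).
#' @return Object of class `svo_km` with fields `time` and `surv`
#'   (right-continuous step values at the observed times).
#' @export
kaplan_meier <- function(times, indicators) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(all(times >= 0), length(times) == length(indicators))
  fit <- survival::survfit(survival::Surv(times, indicators) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "svo_km")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km An `svo_km` object.
#' @param t Times at which to evaluate.
#' @param left If `TRUE`, return the left limit `S(t-)` (the value just
#'   before `t`), the convention used for the event-term weight
#'   `G(Y_i-)` in the censoring-weighted Brier score.
#' @return Numeric vector of survival values (1 before the first jump).
#' @export
km_eval <- function(km, t, left = FALSE) {
  vals <- c(1, km$surv)
  idx <- findInterval(t, km$time, left.open = left)
  vals[idx + 1L]
}

#' @export
print.svo_km <- function(x, ...) {
  cat(sprintf("<svo_km> product-limit estimate on %d time point(s)\n",
              length(x$time)))
  invisible(x)
}

#' Censoring-weighted Brier score at one time point
#'
#' \deqn{BS(t) = \frac{1}{n}\sum_i \Big\{
#'   \frac{\hat S(t|x_i)^2 I(Y_i \le t, \Delta_i = 1)}{\hat G(Y_i-)} +
#'   \frac{[1 - \hat S(t|x_i)]^2 I(Y_i > t)}{\hat G(t)} \Big\}.}
#' Subjects censored at or before `t` contribute nothing.  On fully
#' uncensored data with `G = 1` this is the mean squared error between
#' `S_hat(t)` and `I(Y_i > t)`.
#'
#' @param t Evaluation time.
#' @param s_hat Predicted survival probabilities `S_hat(t | x_i)`.
#' @param y,delta Observed times and event indicators.
#' @param G An `svo_km` censoring-survival estimate (from
#'   [kaplan_meier()] with flipped indicators), or `NULL` for no
#'   weighting (`G = 1`).
#' @return The scalar Brier score.
#' @export
brier_score <- function(t, s_hat, y, delta, G = NULL) {
  stopifnot(length(s_hat) == length(y), length(delta) == length(y))
  w_event <- as.numeric(y <= t & delta == 1)
  w_alive <- as.numeric(y > t)
  if (is.null(G)) {
    g_event <- rep(1, length(y))
    g_alive <- 1
  } else {
    g_event <- km_eval(G, y, left = TRUE)
    g_alive <- km_eval(G, t)
  }
  if (any(w_event == 1 & g_event <= 0) || (any(w_alive == 1) && all(g_alive <= 0)))
    stop("censoring survival estimate is 0 where an inverse weight is needed; use a smaller upper evaluation time (Y_max)")
  mean(w_event * s_hat^2 / ifelse(g_event > 0, g_event, 1) +
         w_alive * (1 - s_hat)^2 / ifelse(g_alive > 0, g_alive, 1))
}

#' Integrated Brier score over a time mesh
#'
#' Trapezoidal integral of `BS(t)` over `[y_min, y_max]`, divided by the
#' range.
#'
#' @param times Mesh times (increasing).
#' @param bs Brier-score values at `times`.
#' @param y_min,y_max Integration range (defaults: range of `times`).
#' @return The scalar IBS.
#' @export
integrated_brier <- function(times, bs, y_min = min(times),
                             y_max = max(times)) {
  stopifnot(length(times) == length(bs), !is.unsorted(times))
  if (y_max <= y_min) stop("degenerate integration range: y_min >= y_max")
  keep <- times >= y_min & times <= y_max
  tt <- times[keep]; bb <- bs[keep]
  if (length(tt) < 2L) stop("need at least two mesh points inside the range")
  sum(diff(tt) * (utils::head(bb, -1L) + utils::tail(bb, -1L)) / 2) /
    (y_max - y_min)
}

#' K-fold cross-validated integrated Brier score
#'
#' Randomly partitions the subjects into `K` folds.  For each fold `k`
#' the model is fitted on the remaining data (with an inner 90/10
#' train/validation split for early stopping), predictions are made for
#' the held-out fold, and `BS^(k)(t)` is computed on the mesh of distinct
#' observed times of the fold with censoring weights `G_hat^(-k)` from
#' the training folds; `IBS` is the mean of the per-fold integrated
#' scores.  Folds without any event are skipped with a warning.
#'
#' @param records List of [subject_record()]s.
#' @param grid A [time_grid()].
#' @param K Number of folds (default 5).
#' @param seed Seed for the fold assignment and inner splits.
#' @param model_builder Function `(train_records, val_records, grid)`
#'   returning an object whose `predict(object, newdata, times = mesh)`
#'   yields a survival-probability matrix; defaults to [survonet()] with
#'   the extra `...` arguments.
#' @param inner_val Fraction of each training portion held out for early
#'   stopping.
#' @param ... Passed to [survonet()] when `model_builder` is `NULL`.
#' @return Object of class `svo_brier`: per-fold meshes, `BS` curves and
#'   IBS values, the fold assignment, and the mean `ibs`.
#' @export
cross_validated_ibs <- function(records, grid, K = 5L, seed = 1L,
                                model_builder = NULL, inner_val = 0.1,
                                ...) {
  n <- length(records)
  stopifnot(K >= 2L, n >= K)
  dots <- list(...)
  if (is.null(model_builder))
    model_builder <- function(train_records, val_records, grid) {
      do.call(survonet, c(list(data = train_records, grid = grid,
                               validation = val_records), dots))
    }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(K), n))
  per_fold <- vector("list", K)
  ibs_k <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    test <- records[fold == k]
    rest <- records[fold != k]
    y_test <- vapply(test, `[[`, numeric(1), "y")
    d_test <- vapply(test, `[[`, numeric(1), "delta")
    if (sum(d_test) == 0) {
      warning(sprintf("fold %d has no events; skipped", k))
      next
    }
    set.seed(subject_seed(seed, k))
    vidx <- sample(length(rest), max(1L, round(inner_val * length(rest))))
    fit <- model_builder(rest[-vidx], rest[vidx], grid)
    mesh <- sort(unique(y_test))
    S <- predict(fit, newdata = test, times = mesh)
    y_rest <- vapply(rest, `[[`, numeric(1), "y")
    d_rest <- vapply(rest, `[[`, numeric(1), "delta")
    G <- kaplan_meier(y_rest, 1 - d_rest)
    bs <- vapply(seq_along(mesh), function(j)
      brier_score(mesh[j], S[, j], y_test, d_test, G), numeric(1))
    # a degenerate mesh (e.g. leave-one-out folds) has no range to
    # integrate over; the time average collapses to the single BS value
    ibs_k[k] <- if (length(mesh) >= 2L) integrated_brier(mesh, bs) else bs[1L]
    per_fold[[k]] <- list(mesh = mesh, bs = bs, ibs = ibs_k[k])
  }
  structure(list(folds = fold, per_fold = per_fold, ibs_per_fold = ibs_k,
                 ibs = mean(ibs_k, na.rm = TRUE), K = K),
            class = "svo_brier")
}

#' @export
print.svo_brier <- function(x, ...) {
  cat(sprintf("<svo_brier> %d-fold cross-validated IBS = %.4f\n", x$K, x$ibs))
  cat("  per fold:", paste(sprintf("%.4f", x$ibs_per_fold), collapse = " "),
      "\n")
  invisible(x)
}

# default evaluation covariate sets: draws from the generator's law
draw_eval_sets <- function(n_sets, seed) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i)
    list(alphas = stats::runif(5L), z = stats::rbinom(1L, 1L, 0.5),
         w = stats::rnorm(1L)))
}

#' Replicate simulation study of estimated conditional survival curves
#'
#' Repeats the full pipeline `N` times: simulate an independent training
#' and validation dataset, fit the operator network, and predict the
#' conditional survival curves for a fixed collection of evaluation
#' covariate sets.  Returns the pointwise mean and empirical 5%/95%
#' quantile band across replications together with the oracle truth.
#'
#' @param config A [sim_config()] giving the generator conditions; the
#'   training and validation sets each have `config$n` subjects.
#' @param grid A [time_grid()] for the sensor layout.
#' @param N Number of replications.
#' @param eval_sets List of covariate sets, each a list with `alphas`
#'   (5-vector), `z`, `w`; default: four sets drawn from the generator's
#'   covariate law with a seed derived from `seed`.
#' @param seed Base seed; replication r uses derived substream seeds.
#' @param ... Passed to [survonet()] (architecture and training options).
#' @return Object of class `svo_ensemble`: `times` (grid points),
#'   `truth`, `mean`, `lower`, `upper` (matrices, one column per
#'   covariate set), and `curves` (array `N x (m+1) x n_sets`).
#' @export
replicate_study <- function(config, grid, N = 20L, eval_sets = NULL,
                            seed = 1L, ...) {
  if (is.null(eval_sets))
    eval_sets <- draw_eval_sets(4L, subject_seed(seed, 424242L))
  n_sets <- length(eval_sets)
  fine <- fine_times(config)
  sensor_idx <- findInterval(grid$sensors + 1e-9, fine)
  eval_records <- lapply(seq_len(n_sets), function(i) {
    s <- eval_sets[[i]]
    tp <- oracle_survival(config, s$alphas, s$z, s$w)
    subject_record(id = paste0("eval", i), y = NA, delta = NA,
                   x = matrix(tp$x[sensor_idx], ncol = 1L,
                              dimnames = list(NULL, "x")),
                   z = c(z = s$z, w = s$w))
  })
  truth <- vapply(seq_len(n_sets), function(i) {
    s <- eval_sets[[i]]
    tp <- oracle_survival(config, s$alphas, s$z, s$w)
    truepath_surv_at(tp, grid$points)
  }, numeric(grid$m + 1L))
  curves <- array(NA_real_, c(N, grid$m + 1L, n_sets))
  for (r in seq_len(N)) {
    cfg_tr <- config; cfg_tr$seed <- subject_seed(seed, 2L * r)
    cfg_va <- config; cfg_va$seed <- subject_seed(seed, 2L * r + 1L)
    dtr <- simulate_survdata(cfg_tr, grid, keep_truth = FALSE)
    dva <- simulate_survdata(cfg_va, grid, keep_truth = FALSE)
    fit <- survonet(dtr$records, grid, validation = dva$records,
                    seed = subject_seed(seed, 5000L + r), ...)
    S <- predict(fit, eval_records)
    for (i in seq_len(n_sets)) curves[r, , i] <- S[i, ]
  }
  mean_c <- apply(curves, c(2L, 3L), mean)
  lower <- apply(curves, c(2L, 3L), stats::quantile, probs = 0.05)
  upper <- apply(curves, c(2L, 3L), stats::quantile, probs = 0.95)
  structure(list(times = grid$points, truth = truth, mean = mean_c,
                 lower = lower, upper = upper, curves = curves,
                 eval_sets = eval_sets, N = N),
            class = "svo_ensemble")
}

#' @export
print.svo_ensemble <- function(x, ...) {
  cat(sprintf("<svo_ensemble> %d replications, %d covariate set(s), %d grid points\n",
              x$N, dim(x$curves)[3L], length(x$times)))
  err <- apply(abs(x$mean - x$truth), 2L, max)
  cat("  sup-norm of (mean estimate - truth) per set:",
      paste(sprintf("%.3f", err), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.svo_ensemble <- function(x, set = 1L, xlab = "time",
                              ylab = "S(t | history)", ...) {
  tt <- x$times
  graphics::plot(tt, x$truth[, set], type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(tt, rev(tt)), c(x$lower[, set], rev(x$upper[, set])),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(tt, x$truth[, set], lwd = 2)
  graphics::lines(tt, x$mean[, set], col = "orange", lwd = 2)
  invisible(x)
}
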