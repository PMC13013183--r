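test_that("the product-limit estimator matches hand computations", {
  # no events: survival stays at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_eval(km0, c(0.5, 2.5, 10)), c(1, 1, 1))
  # all events at 1, 2, 3: 2/3, 1/3, 0
  km1 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_eval(km1, 1), 2 / 3)
  expect_equal(km_eval(km1, 2), 1 / 3)
  expect_equal(km_eval(km1, 3), 0)
  # hand product-limit on 4 points: a censored observation after the last
  # event adds no drop to the curve
  km2 <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 0))
  expect_equal(km_eval(km2, c(1, 2, 3, 4, 10)),
               c(3 / 4, 1 / 2, 1 / 4, 1 / 4, 1 / 4))
  # left limits at jump points
  expect_equal(km_eval(km1, 2, left = TRUE), 2 / 3)
  expect_equal(km_eval(km1, 1, left = TRUE), 1)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("the Brier score matches its formula", {
  # perfect forecasts on uncensored data score zero
  y <- c(1, 3, 5); delta <- c(1, 1, 1)
  t0 <- 2
  s_perfect <- as.numeric(y > t0)
  expect_equal(brier_score(t0, s_perfect, y, delta), 0)
  # the coin-flip predictor scores 1/4 at every time
  for (tt in c(0.5, 2, 4))
    expect_equal(brier_score(tt, rep(0.5, 3), y, delta), 0.25)
  # uncensored: reduces exactly to mean squared error
  set.seed(2)
  s_hat <- stats::runif(3)
  expect_equal(brier_score(t0, s_hat, y, delta),
               mean((s_hat - (y > t0))^2))
  # hand-worked censored example: y = (2, 4, 6), delta = (1, 0, 1), t = 5.
  # censoring KM (indicators 1-delta): one censoring event at time 4 with
  # risk set {subjects 2, 3}, so G(t) = 1 for t < 4 and 1/2 for t >= 4.
  # subject 1: event before t: S1^2 / G(2-) = 0.3^2 / 1
  # subject 2: censored before t: contributes 0
  # subject 3: alive at t: (1 - S3)^2 / G(5) = 0.3^2 / (1/2)
  G <- kaplan_meier(c(2, 4, 6), c(0, 1, 0))
  s_hat <- c(0.3, 0.9, 0.7)
  hand <- (0.3^2 / 1 + 0 + (1 - 0.7)^2 / (1 / 2)) / 3
  expect_equal(brier_score(5, s_hat, c(2, 4, 6), c(1, 0, 1), G), hand,
               tolerance = 1e-12)
})

test_that("the integrated Brier score is a trapezoidal time average", {
  tt <- c(0, 2, 5, 9)
  expect_equal(integrated_brier(tt, rep(0.2, 4)), 0.2)
  # linear from 0 to b integrates to b/2
  expect_equal(integrated_brier(c(0, 10), c(0, 0.3)), 0.15)
  # mesh refinement changes a smooth integrand very little
  f <- function(t) 0.1 + 0.05 * sin(t / 3)
  t1 <- seq(0, 10, length.out = 51)
  t2 <- seq(0, 10, length.out = 101)
  expect_lt(abs(integrated_brier(t1, f(t1)) - integrated_brier(t2, f(t2))),
            1e-3)
  expect_error(integrated_brier(c(1, 2), c(0, 0), y_min = 2, y_max = 2),
               "degenerate")
})

test_that("cross-validated IBS follows the fold protocol", {
  g <- time_grid(10, 4)
  set.seed(31)
  recs <- lapply(1:12, function(i)
    subject_record(i, y = stats::runif(1, 1, 10), delta = 1,
                   x = stats::rnorm(4), z = numeric(0)))
  # trivial constant model: S(t) = exp(-0.1 t), no fitting
  const_builder <- function(train_records, val_records, grid) {
    structure(list(grid = grid), class = "const_model")
  }
  assign("predict.const_model",
         function(object, newdata, times, ...) {
           matrix(exp(-0.1 * rep(times, each = length(newdata))),
                  nrow = length(newdata))
         }, envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  res <- cross_validated_ibs(recs, g, K = 4, seed = 1,
                             model_builder = const_builder)
  expect_true(is.finite(res$ibs))
  expect_equal(res$ibs, mean(res$ibs_per_fold))
  # every subject lands in exactly one test fold
  expect_equal(sort(unique(res$folds)), 1:4)
  expect_length(res$folds, 12L)
  # leave-one-out on a 5-subject toy still runs
  res2 <- cross_validated_ibs(recs[1:5], g, K = 5, seed = 2,
                              model_builder = const_builder)
  expect_true(is.finite(res2$ibs))
})

test_that("folds without events are skipped with a warning", {
  g <- time_grid(10, 4)
  set.seed(8)
  recs <- lapply(1:8, function(i)
    subject_record(i, y = stats::runif(1, 1, 10),
                   delta = as.numeric(i <= 4), x = stats::rnorm(4),
                   z = numeric(0)))
  const_builder <- function(train_records, val_records, grid) {
    structure(list(grid = grid), class = "const_model2")
  }
  assign("predict.const_model2",
         function(object, newdata, times, ...)
           matrix(0.5, length(newdata), length(times)),
         envir = globalenv())
  on.exit(rm("predict.const_model2", envir = globalenv()), add = TRUE)
  # leave-one-out folds around the censored subjects have no events
  w <- testthat::capture_warnings(
    res <- cross_validated_ibs(recs, g, K = 8, seed = 3,
                               model_builder = const_builder))
  expect_true(any(grepl("no events", w)))
  expect_true(any(is.na(res$ibs_per_fold)))
  expect_true(is.finite(res$ibs))
})

test_that("replicate ensembles have ordered bands that collapse at N = 1", {
  cfg <- sim_config(n = 40, seed = 2)
  g <- time_grid(100, 10)
  ens <- replicate_study(cfg, g, N = 1, seed = 5, dense_nodes = 8,
                         latent_p = 4, batch_size = 100, max_epochs = 3)
  expect_equal(ens$mean, ens$lower)
  expect_equal(ens$mean, ens$upper)
  ens2 <- replicate_study(cfg, g, N = 3, seed = 5, dense_nodes = 8,
                          latent_p = 4, batch_size = 100, max_epochs = 3)
  expect_true(all(ens2$lower <= ens2$upper))
  expect_equal(dim(ens2$curves), c(3L, 11L, 4L))
  # oracle truth beats the coin-flip predictor in Brier terms
  cfg_b <- sim_config(n = 60, seed = 4)
  d <- simulate_survdata(cfg_b, g)
  y <- vapply(d$records, `[[`, numeric(1), "y")
  delta <- vapply(d$records, `[[`, numeric(1), "delta")
  mesh <- sort(unique(y))
  mesh <- mesh[mesh < max(mesh)]
  G <- kaplan_meier(y, 1 - delta)
  bs_true <- vapply(mesh, function(t0) {
    s <- vapply(d$truth, function(tp) survonet:::truepath_surv_at(tp, t0),
                numeric(1))
    brier_score(t0, s, y, delta, G)
  }, numeric(1))
  bs_half <- vapply(mesh, function(t0)
    brier_score(t0, rep(0.5, length(y)), y, delta, G), numeric(1))
  expect_lt(integrated_brier(mesh, bs_true), integrated_brier(mesh, bs_half))
})
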