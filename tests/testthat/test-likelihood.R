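test_that("loss evaluates hand-computable cases", {
  g <- time_grid(8, 4)
  # censored at tau with h = 0: every interval at risk, loss = sum of widths
  ex <- expand_subject(subject_record(1, y = 8, delta = 0, x = rep(0, 4)), g)
  expect_equal(discretized_loss(rep(0, 4), ex$width, ex$at_risk, ex$event, 1),
               8)
  # event in the first interval with h = c: loss = e^c w_1 - c
  ex2 <- expand_subject(subject_record(1, y = 1, delta = 1, x = rep(0, 4)), g)
  for (c0 in c(-1, 0, 0.5)) {
    expect_equal(discretized_loss(rep(c0, 4), ex2$width, ex2$at_risk,
                                  ex2$event, 1),
                 exp(c0) * 2 - c0)
  }
  # its minimizer is -log(w_1), found numerically
  opt <- stats::optimize(function(c0)
    discretized_loss(rep(c0, 4), ex2$width, ex2$at_risk, ex2$event, 1),
    c(-5, 5))
  expect_equal(opt$minimum, -log(2), tolerance = 1e-4)
  # an uncensored subject contributes exactly one -h delta term
  expect_equal(sum(ex2$event), 1)
})

test_that("loss errors on non-finite h and warns on clipping", {
  g <- time_grid(4, 4)
  ex <- expand_subject(subject_record(1, 4, 1, rep(0, 4)), g)
  expect_error(discretized_loss(c(0, NaN, 0, 0), ex$width, ex$at_risk,
                                ex$event, 1), "row\\(s\\) 2")
  expect_warning(discretized_loss(c(0, 40, 0, 0), ex$width, ex$at_risk,
                                  ex$event, 1), "clipped")
})

test_that("-n times the loss equals the grid Riemann log-likelihood", {
  # independently coded Riemann-sum likelihood on the same partition
  grid_loglik <- function(recs, g, hmat) {
    ll <- 0
    for (i in seq_along(recs)) {
      y <- recs[[i]]$y; delta <- recs[[i]]$delta
      for (j in seq_len(g$m)) {
        if (g$points[j] <= y) {
          ll <- ll - exp(hmat[i, j]) * g$widths[j]
          if (delta == 1 && g$points[j + 1] > y)
            ll <- ll + hmat[i, j]
        }
      }
    }
    ll
  }
  set.seed(77)
  for (rep in 1:50) {
    m <- sample(3:10, 1)
    pts <- c(0, sort(stats::runif(m - 1, 0, 10)), 10)
    g <- time_grid(points = pts)
    n <- sample(2:6, 1)
    recs <- make_records(n, g, seed = 1000 + rep)
    ex <- expand_records(recs, g)
    h <- stats::rnorm(n * m)
    hmat <- matrix(h, n, m, byrow = TRUE)
    loss <- discretized_loss(h, ex$width, ex$at_risk, ex$event, n)
    expect_equal(-n * loss, grid_loglik(recs, g, hmat), tolerance = 1e-12)
  }
})

test_that("the discretized loss converges to the continuous likelihood", {
  # smooth log-hazard depending on time only
  hfun <- function(t, record) -2 + 0.5 * sin(t / 2)
  g0 <- time_grid(10, 5)
  recs <- make_records(5, g0, seed = 12)
  ell <- exact_log_likelihood(recs, hfun, quadrature_step = 1e-3)
  gaps <- sapply(c(50, 1000), function(m) {
    g <- time_grid(10, m)
    recs_m <- lapply(recs, function(r) {
      r$x <- matrix(0, m, 1, dimnames = list(NULL, "x1")); r
    })
    ex <- expand_records(recs_m, g)
    h <- hfun(ex$t_left)
    abs(-length(recs) *
          discretized_loss(h, ex$width, ex$at_risk, ex$event, length(recs)) -
          ell) / abs(ell)
  })
  expect_lt(gaps[2], 0.01)
  expect_lt(gaps[2], gaps[1])
})

test_that("the quadrature likelihood matches the exponential closed form", {
  g <- time_grid(10, 5)
  lam <- 0.4
  recs <- make_records(6, g, seed = 3)
  recs <- lapply(recs, function(r) { r$delta <- 1; r })
  ell <- exact_log_likelihood(recs, function(t, r) log(lam),
                              quadrature_step = 1e-4)
  y <- vapply(recs, `[[`, numeric(1), "y")
  expect_equal(ell, sum(log(lam) - lam * y), tolerance = 1e-9)
})

test_that("the loss gradient in h matches finite differences", {
  g <- time_grid(10, 6)
  recs <- make_records(4, g, seed = 8)
  ex <- expand_records(recs, g)
  set.seed(9)
  h <- stats::rnorm(24)
  gr <- loss_gradient(h, ex$width, ex$at_risk, ex$event, 4)
  eps <- 1e-6
  for (k in seq_along(h)) {
    hp <- h; hp[k] <- h[k] + eps
    hm <- h; hm[k] <- h[k] - eps
    fd <- (discretized_loss(hp, ex$width, ex$at_risk, ex$event, 4) -
             discretized_loss(hm, ex$width, ex$at_risk, ex$event, 4)) / (2 * eps)
    expect_lt(abs(fd - gr[k]) / max(1e-8, abs(fd), abs(gr[k])), 1e-5)
  }
})

test_that("minimizing over a constant h recovers the occurrence/exposure rate", {
  g <- time_grid(10, 7)
  recs <- make_records(40, g, seed = 19)
  ex <- expand_records(recs, g)
  events <- sum(ex$event)
  exposure <- sum(ex$at_risk * ex$width)
  target <- log(events / exposure)
  # Newton iteration on the analytic gradient of the loss in c
  c0 <- 0
  for (it in 1:50) {
    gr <- sum(loss_gradient(rep(c0, length(ex$width)), ex$width,
                            ex$at_risk, ex$event, 40))
    hess <- sum(ex$at_risk * exp(c0) * ex$width) / 40
    c0 <- c0 - gr / hess
  }
  expect_equal(c0, target, tolerance = 1e-8)
})
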