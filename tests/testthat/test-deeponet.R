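test_that("zero parameters give zero branch/trunk and h equal to the dot bias", {
  spec <- network_spec("fnn", m = 6, q = 1, dense_nodes = 4, latent_p = 3)
  net <- init_network(spec, seed = 1)
  net$params <- lapply(net$params, function(p) p * 0)
  net$params$b0 <- 1.7
  expect_equal(unname(branch_forward(rnorm(6), 0.5, net)),
               matrix(0, 1, 3))
  expect_equal(unname(trunk_forward(c(0.2, 0.9), net, tau = 1)),
               matrix(0, 2, 3))
  g <- time_grid(6, 6)
  ex <- expand_subject(subject_record(1, 3, 1, rnorm(6), c(z = 0.5)), g)
  expect_equal(operator_forward(ex, net), rep(1.7, 6))
})

test_that("the operator reproduces the single-hidden-layer dot-product form", {
  # hand-set weights, n = 2 hidden nodes, p = 2, m = 3 sensors:
  # G(u)(y) = sum_k [ sum_i c_ik relu(sum_j xi_ij u_j + theta_i) ]
  #               * relu(w_k y + zeta_k)
  xi <- matrix(c(0.5, -0.3, 0.2,
                 0.1, 0.4, -0.6), nrow = 2, byrow = TRUE)
  theta <- c(0.1, -0.2)
  cmat <- matrix(c(1.0, -0.5,
                   0.3, 0.8), nrow = 2, byrow = TRUE)  # c[i, k]
  w <- c(0.7, -1.2)
  zeta <- c(0.05, 0.6)
  oracle <- function(u, y) {
    tot <- 0
    for (k in 1:2) {
      gk <- 0
      for (i in 1:2)
        gk <- gk + cmat[i, k] * max(0, sum(xi[i, ] * u) + theta[i])
      tot <- tot + gk * max(0, w[k] * y + zeta[k])
    }
    tot
  }
  spec <- network_spec("fnn", m = 3, q = 0, dense_nodes = 2,
                       fnn_hidden_layers = 1, latent_p = 2, dot_bias = FALSE)
  net <- init_network(spec, seed = 1)
  net$params$br_W1 <- t(xi)
  net$params$br_b1 <- theta
  net$params$br_Wo <- cmat
  net$params$br_bo <- c(0, 0)
  net$params$tr_W1 <- matrix(w, 1)
  net$params$tr_b1 <- zeta
  net$params$tr_Wo <- diag(2)
  net$params$tr_bo <- c(0, 0)
  g <- time_grid(1, 3)   # tau = 1 so trunk normalization is the identity
  r <- subject_record(1, NA, NA, x = c(0.9, -0.4, 1.3), z = numeric(0))
  ex <- expand_subject(r, g)
  h <- operator_forward(ex, net)
  masked <- list(c(0.9, 0, 0), c(0.9, -0.4, 0), c(0.9, -0.4, 1.3))
  for (j in 1:3)
    expect_equal(h[j], oracle(masked[[j]], g$points[j]))
})

test_that("the trunk computes relu(w y + zeta) through its linear head", {
  spec <- network_spec("fnn", m = 3, q = 0, dense_nodes = 2, latent_p = 2)
  net <- init_network(spec, seed = 2)
  net$params$tr_W1 <- matrix(c(2, -1), 1)
  net$params$tr_b1 <- c(-0.5, 0.8)
  net$params$tr_Wo <- diag(2)
  net$params$tr_bo <- c(0, 0)
  for (y in c(0.1, 0.4, 0.95)) {
    expect_equal(unname(trunk_forward(y, net, tau = 1)[1, ]),
                 c(max(0, 2 * y - 0.5), max(0, -y + 0.8)))
  }
  # distinct times give distinct outputs under random weights
  net2 <- rand_net("fnn", m = 3, q = 0, seed = 5)
  expect_false(isTRUE(all.equal(trunk_forward(0.2, net2, 1),
                                trunk_forward(0.7, net2, 1))))
})

test_that("future sensors cannot influence the operator output", {
  g <- time_grid(12, 12)
  for (br in c("fnn", "cnn")) {
    net <- rand_net(br, m = 12, q = 2, seed = 8, pool_size = 2)
    r <- make_records(1, g, seed = 21)[[1]]
    h0 <- operator_forward(expand_subject(r, g), net)
    for (rep in 1:20) {
      set.seed(100 + rep)
      j <- sample(1:11, 1)                       # interval whose output we watch
      k <- if (j < 11) sample(j:11, 1) else 11   # 0-based sensor index >= j
      r2 <- r
      r2$x[k + 1, 1] <- r2$x[k + 1, 1] + stats::rnorm(1, sd = 10)
      h2 <- operator_forward(expand_subject(r2, g), net)
      expect_identical(h2[j], h0[j])
    }
  }
})

test_that("causal convolution keeps internal features aligned to the past", {
  m <- 16L
  net <- rand_net("cnn", m = m, q = 2, seed = 13, pool_size = 2)
  x <- stats::rnorm(m)
  z <- c(0.3, -0.8)
  d0 <- branch_forward(x, z, net, details = TRUE)
  for (k in c(4L, 9L, 14L)) {   # 1-based sensor position being perturbed
    x2 <- x
    x2[k] <- x2[k] + 5
    d2 <- branch_forward(x2, z, net, details = TRUE)
    # conv features strictly before the perturbed position are untouched
    expect_identical(d2$conv1[, seq_len(k - 1L), , drop = FALSE],
                     d0$conv1[, seq_len(k - 1L), , drop = FALSE])
    # pooled blocks that end before the perturbation are untouched
    nb <- (k - 1L) %/% net$spec$pool_size
    if (nb >= 1L)
      expect_identical(d2$pool1$out[, seq_len(nb), , drop = FALSE],
                       d0$pool1$out[, seq_len(nb), , drop = FALSE])
  }
})

test_that("predicted curves are valid survival functions", {
  g <- time_grid(10, 8)
  r <- make_records(1, g, seed = 2)[[1]]
  for (br in c("fnn", "cnn")) {
    for (s in 1:10) {
      net <- rand_net(br, m = 8, q = 2, seed = s, pool_size = 2)
      cv <- predict_survival(r, net, g)
      expect_equal(cv$surv[1], 1)
      expect_true(all(diff(cv$surv) <= 0))
      expect_true(all(cv$surv >= 0 & cv$surv <= 1))
      h <- operator_forward(expand_subject(r, g), net)
      ch <- c(0, cumsum(exp(h) * g$widths))
      expect_true(all(cv$surv[ch < 700] > 0))
    }
  }
})

test_that("a constant log-hazard output yields the exponential curve", {
  g <- time_grid(10, 5)
  spec <- network_spec("fnn", m = 5, q = 0, dense_nodes = 4, latent_p = 3)
  net <- init_network(spec, seed = 1)
  net$params <- lapply(net$params, function(p) p * 0)
  net$params$b0 <- log(0.3)
  r <- subject_record(1, NA, NA, rnorm(5), numeric(0))
  cv <- predict_survival(r, net, g)
  expect_equal(cv$surv, exp(-0.3 * g$points))
})

test_that("analytic network gradients match finite differences", {
  g <- time_grid(10, 8)
  recs <- make_records(4, g, seed = 31)
  ex <- expand_records(recs, g)
  for (br in c("fnn", "cnn")) {
    net <- rand_net(br, m = 8, q = 2, seed = 17, pool_size = 2)
    lossfun <- function(nn) {
      h <- operator_forward(ex, nn)
      survonet:::loss_value_quiet(h, ex$width, ex$at_risk, ex$event, 4)
    }
    fw <- survonet:::operator_fwd_cache(ex, net)
    dh <- loss_gradient(fw$h, ex$width, ex$at_risk, ex$event, 4)
    gr <- survonet:::net_gradients(ex, net, dh, fw)
    eps <- 1e-6
    set.seed(55)
    for (nm in names(net$params)) {
      idx <- seq_along(net$params[[nm]])
      if (length(idx) > 10) idx <- sample(idx, 10)
      for (k in idx) {
        np <- net
        np$params[[nm]][k] <- np$params[[nm]][k] + eps
        lp <- lossfun(np)
        np$params[[nm]][k] <- np$params[[nm]][k] - 2 * eps
        lm <- lossfun(np)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - gr[[nm]][k]) /
                    max(1e-6, abs(fd), abs(gr[[nm]][k])), 1e-4)
      }
    }
  }
})
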