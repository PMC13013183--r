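# shared fixture builders (all data generated in code)

# random records on an m-sensor grid
make_records <- function(n, grid, seed = 1, q = 2L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    y <- stats::runif(1, 0, grid$tau)
    z <- if (q > 0) {
      zz <- c(z = stats::rbinom(1, 1, 0.5), w = stats::rnorm(1))
      zz[seq_len(q)]
    } else numeric(0)
    subject_record(i, y = y, delta = stats::rbinom(1, 1, 0.7),
                   x = stats::rnorm(grid$m), z = z)
  })
}

# records from a constant-hazard (exponential) population, x == 0, no z
make_const_records <- function(n, grid, rate, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    Ti <- stats::rexp(1, rate)
    subject_record(i, y = min(Ti, grid$tau),
                   delta = as.numeric(Ti <= grid$tau),
                   x = rep(0, grid$m), z = numeric(0))
  })
}

# small randomly initialized network with biases jittered off zero
rand_net <- function(branch, m, q = 2L, seed = 1, dense_nodes = 6L,
                     cnn_filters = 3L, pool_size = 2L, latent_p = 4L, ...) {
  spec <- network_spec(branch, m = m, channels = 1L, q = q,
                       dense_nodes = dense_nodes, cnn_filters = cnn_filters,
                       pool_size = pool_size, latent_p = latent_p, ...)
  net <- init_network(spec, seed = seed)
  net$params <- lapply(net$params, function(p) p + stats::rnorm(length(p), sd = 0.2))
  net
}
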