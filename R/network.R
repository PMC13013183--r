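#' Operator-network architecture specification
#'
#' The log conditional hazard `h[x~(s)](s)` is represented by an unstacked
#' deep operator network: a branch net encodes the masked covariate
#' history sampled at the `m` sensors (plus time-invariant covariates) and
#' a trunk net encodes the evaluation time `s`; both end in `latent_p`
#' nodes whose dot product (plus an optional scalar bias) is the output.
#' The branch is either a feed-forward net with `fnn_hidden_layers` dense
#' ReLU layers (time-invariant covariates concatenated directly to the
#' history), or a 1-D convolutional net with two blocks of causal
#' convolution + max pooling whose flattened features are concatenated
#' with the time-invariant covariates before one dense ReLU layer.  The
#' trunk is a single dense ReLU layer.  All hidden activations are ReLU
#' and the output is linear, so `h` is unconstrained.
#'
#' Causal (left) padding makes every convolution output position depend
#' only on current and earlier sensors, so the masked future zeros can
#' never leak information; for the FNN the masking itself guarantees this
#' because a zeroed input contributes nothing to the first dense layer.
#'
#' @param branch `"fnn"` or `"cnn"`.
#' @param m Number of sensors (must match the time grid).
#' @param channels Number of time-varying covariate channels.
#' @param q Number of time-invariant covariates.
#' @param dense_nodes Width of each dense hidden layer (branch and trunk).
#' @param fnn_hidden_layers 1 or 2 dense hidden layers for the FNN branch.
#' @param cnn_filters Filters per convolution layer.
#' @param kernel_size Convolution kernel width.
#' @param pool_size Max-pool window (stride equal to the window).
#' @param latent_p Dimension of the dot-product combination.
#' @param dot_bias Include a scalar bias added after the dot product.
#' @return An object of class `svo_spec`.
#' @export
network_spec <- function(branch = c("fnn", "cnn"), m, channels = 1L, q = 0L,
                         dense_nodes = 64L, fnn_hidden_layers = 2L,
                         cnn_filters = 16L, kernel_size = 3L,
                         pool_size = 4L, latent_p = 10L, dot_bias = TRUE) {
  branch <- match.arg(branch)
  stopifnot(m >= 1, channels >= 1, q >= 0, dense_nodes >= 1,
            fnn_hidden_layers %in% 1:2, cnn_filters >= 1,
            kernel_size >= 1, pool_size >= 1, latent_p >= 1)
  spec <- list(branch = branch, m = as.integer(m),
               channels = as.integer(channels), q = as.integer(q),
               dense_nodes = as.integer(dense_nodes),
               fnn_hidden_layers = as.integer(fnn_hidden_layers),
               cnn_filters = as.integer(cnn_filters),
               kernel_size = as.integer(kernel_size),
               pool_size = as.integer(pool_size),
               latent_p = as.integer(latent_p),
               dot_bias = isTRUE(dot_bias))
  if (branch == "cnn") {
    L1 <- spec$m %/% spec$pool_size
    L2 <- L1 %/% spec$pool_size
    if (L2 < 1L)
      stop(sprintf("pool_size %d too large for m = %d (two pooled blocks leave no features)",
                   spec$pool_size, spec$m))
    spec$L1 <- L1
    spec$L2 <- L2
  }
  structure(spec, class = "svo_spec")
}

#' @export
print.svo_spec <- function(x, ...) {
  cat(sprintf("<svo_spec> %s branch, m=%d sensors x %d channel(s), q=%d, p=%d\n",
              toupper(x$branch), x$m, x$channels, x$q, x$latent_p))
  invisible(x)
}

relu <- function(a) a * (a > 0)

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

#' Initialize operator-network parameters
#'
#' Fan-in-scaled random normal weights, zero biases; draws come from the
#' current R RNG stream (seed it for reproducibility).
#'
#' @param spec A [network_spec()].
#' @param seed Optional seed set before drawing.
#' @return An object of class `svo_net`: list with `spec` and the flat
#'   named parameter list `params`.
#' @export
init_network <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  nh <- spec$dense_nodes
  if (spec$branch == "fnn") {
    din <- spec$m * spec$channels + spec$q
    p$br_W1 <- he_init(din, nh); p$br_b1 <- numeric(nh)
    if (spec$fnn_hidden_layers == 2L) {
      p$br_W2 <- he_init(nh, nh); p$br_b2 <- numeric(nh)
    }
    p$br_Wo <- he_init(nh, spec$latent_p); p$br_bo <- numeric(spec$latent_p)
  } else {
    K <- spec$kernel_size; Fl <- spec$cnn_filters
    p$cv_W1 <- he_init(K * spec$channels, Fl); p$cv_b1 <- numeric(Fl)
    p$cv_W2 <- he_init(K * Fl, Fl); p$cv_b2 <- numeric(Fl)
    p$br_W1 <- he_init(spec$L2 * Fl + spec$q, nh); p$br_b1 <- numeric(nh)
    p$br_Wo <- he_init(nh, spec$latent_p); p$br_bo <- numeric(spec$latent_p)
  }
  p$tr_W1 <- he_init(1L, nh); p$tr_b1 <- numeric(nh)
  p$tr_Wo <- he_init(nh, spec$latent_p); p$tr_bo <- numeric(spec$latent_p)
  if (spec$dot_bias) p$b0 <- 0
  structure(list(spec = spec, params = p), class = "svo_net")
}

#' @export
print.svo_net <- function(x, ...) {
  cat(sprintf("<svo_net> %s branch, %d parameters\n", toupper(x$spec$branch),
              n_parameters(x)))
  invisible(x)
}

n_parameters <- function(net) sum(vapply(net$params, length, integer(1)))

add_bias <- function(A, b) sweep(A, 2L, b, `+`)

# --- causal Conv1D helpers -------------------------------------------------
# X3: array (N, L, C).  Output position t sees input positions
# t-K+1 ... t (left zero padding), so features are causal in t.

im2col <- function(X3, K) {
  N <- dim(X3)[1L]; L <- dim(X3)[2L]; C <- dim(X3)[3L]
  out <- matrix(0, N * L, K * C)
  for (c in seq_len(C)) for (dk in seq_len(K)) {
    src <- seq_len(L) - K + dk
    ok <- src >= 1L
    block <- matrix(0, N, L)
    block[, ok] <- X3[, src[ok], c]
    out[, (c - 1L) * K + dk] <- block
  }
  out
}

col2im <- function(dCol, N, L, C, K) {
  dX3 <- array(0, c(N, L, C))
  for (c in seq_len(C)) for (dk in seq_len(K)) {
    block <- matrix(dCol[, (c - 1L) * K + dk], N, L)
    src <- seq_len(L) - K + dk
    ok <- src >= 1L
    dX3[, src[ok], c] <- dX3[, src[ok], c] + block[, ok]
  }
  dX3
}

maxpool_fwd <- function(A, P) {
  N <- dim(A)[1L]; L <- dim(A)[2L]; Fl <- dim(A)[3L]; Lp <- L %/% P
  A2 <- A[, seq_len(P * Lp), , drop = FALSE]
  dim(A2) <- c(N, P, Lp, Fl)
  maxv <- A2[, 1L, , , drop = FALSE]
  dim(maxv) <- c(N, Lp, Fl)
  arg <- array(1L, c(N, Lp, Fl))
  if (P > 1L) for (pp in 2:P) {
    cand <- A2[, pp, , , drop = FALSE]
    dim(cand) <- c(N, Lp, Fl)
    upd <- cand > maxv
    maxv[upd] <- cand[upd]
    arg[upd] <- pp
  }
  list(out = maxv, arg = arg, L = L, P = P)
}

maxpool_bwd <- function(dOut, pool) {
  N <- dim(dOut)[1L]; Lp <- dim(dOut)[2L]; Fl <- dim(dOut)[3L]
  dA <- array(0, c(N, pool$L, Fl))
  for (pp in seq_len(pool$P)) {
    sel <- (pool$arg == pp) * dOut
    dA[, (seq_len(Lp) - 1L) * pool$P + pp, ] <-
      dA[, (seq_len(Lp) - 1L) * pool$P + pp, ] + sel
  }
  dA
}

# --- branch ----------------------------------------------------------------

#' Branch-net forward pass
#'
#' Encodes masked covariate histories (and time-invariant covariates) into
#' the `latent_p`-dimensional branch output.
#'
#' @param X Masked-history matrix, `N x (m * channels)` (sensor-major per
#'   channel), or a single numeric vector of that length.
#' @param Z Time-invariant covariate matrix `N x q` (or vector / NULL).
#' @param net An [init_network()] object.
#' @param details If `TRUE`, also return the internal feature maps
#'   (convolution/pooling activations for the CNN, dense activations for
#'   the FNN), used e.g. to verify the causality contract.
#' @return `N x latent_p` matrix, or a list with `out` and the internals.
#' @export
branch_forward <- function(X, Z = NULL, net, details = FALSE) {
  spec <- net$spec
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  N <- nrow(X)
  if (is.null(Z)) Z <- matrix(0, N, 0L)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = N)
  fw <- if (spec$branch == "fnn") fnn_branch_fwd(X, Z, net)
        else cnn_branch_fwd(X, Z, net)
  if (details) fw else fw$out
}

fnn_branch_fwd <- function(X, Z, net) {
  p <- net$params
  A0 <- cbind(X, Z)
  A1 <- relu(add_bias(A0 %*% p$br_W1, p$br_b1))
  if (net$spec$fnn_hidden_layers == 2L) {
    A2 <- relu(add_bias(A1 %*% p$br_W2, p$br_b2))
  } else A2 <- NULL
  top <- if (is.null(A2)) A1 else A2
  out <- add_bias(top %*% p$br_Wo, p$br_bo)
  list(out = out, A0 = A0, A1 = A1, A2 = A2)
}

cnn_branch_fwd <- function(X, Z, net) {
  spec <- net$spec; p <- net$params
  N <- nrow(X); m <- spec$m; C <- spec$channels
  K <- spec$kernel_size; Fl <- spec$cnn_filters; P <- spec$pool_size
  X3 <- X
  dim(X3) <- c(N, m, C)
  col1 <- im2col(X3, K)
  A1 <- relu(add_bias(col1 %*% p$cv_W1, p$cv_b1))
  A1a <- A1; dim(A1a) <- c(N, m, Fl)
  pool1 <- maxpool_fwd(A1a, P)
  col2 <- im2col(pool1$out, K)
  A2 <- relu(add_bias(col2 %*% p$cv_W2, p$cv_b2))
  A2a <- A2; dim(A2a) <- c(N, spec$L1, Fl)
  pool2 <- maxpool_fwd(A2a, P)
  flat <- pool2$out
  dim(flat) <- c(N, spec$L2 * Fl)
  D0 <- cbind(flat, Z)
  D1 <- relu(add_bias(D0 %*% p$br_W1, p$br_b1))
  out <- add_bias(D1 %*% p$br_Wo, p$br_bo)
  list(out = out, col1 = col1, A1 = A1, conv1 = A1a, pool1 = pool1,
       col2 = col2, A2 = A2, conv2 = A2a, pool2 = pool2, D0 = D0, D1 = D1)
}

#' Trunk-net forward pass
#'
#' One dense ReLU layer followed by a linear map to `latent_p` outputs.
#' Time is normalized to `s / tau` before entering the trunk for
#' conditioning; the likelihood always consumes interval widths on the
#' original time scale.
#'
#' @param s Numeric vector of evaluation times.
#' @param net An [init_network()] object.
#' @param tau Time-scale normalizer (upper end of the grid).
#' @return `length(s) x latent_p` matrix.
#' @export
trunk_forward <- function(s, net, tau = 1) {
  p <- net$params
  S0 <- matrix(s / tau, ncol = 1L)
  T1 <- relu(add_bias(S0 %*% p$tr_W1, p$tr_b1))
  add_bias(T1 %*% p$tr_Wo, p$tr_bo)
}

#' Log-hazard output of the operator network
#'
#' Computes `h = <branch(history, z), trunk(s)> + b0` for every row of an
#' expanded dataset.  The trunk is evaluated at each row's interval left
#' endpoint `t_{j-1}`, the time at which the rectangle rule of the
#' discretized likelihood needs the hazard.
#'
#' @param expanded An [expand_records()] object (or single-subject
#'   [expand_subject()]).
#' @param net An [init_network()] object.
#' @return Numeric vector of log-hazard values, one per row.
#' @export
operator_forward <- function(expanded, net) {
  fw <- operator_fwd_cache(expanded, net)
  fw$h
}

operator_fwd_cache <- function(expanded, net, details = FALSE) {
  ut <- sort(unique(expanded$t_left))
  idx <- match(expanded$t_left, ut)
  p <- net$params
  S0 <- matrix(ut / expanded$grid$tau, ncol = 1L)
  T1 <- relu(add_bias(S0 %*% p$tr_W1, p$tr_b1))
  Tm <- add_bias(T1 %*% p$tr_Wo, p$tr_bo)
  bf <- branch_forward(expanded$X, expanded$Z, net, details = TRUE)
  Trow <- Tm[idx, , drop = FALSE]
  h <- rowSums(bf$out * Trow)
  if (net$spec$dot_bias) h <- h + p$b0
  list(h = h, B = bf$out, branch = bf, Trow = Trow, Tm = Tm, T1 = T1,
       S0 = S0, idx = idx)
}

#' Predicted conditional survival curve
#'
#' Discretizes `S(t) = exp(-int_0^t e^h ds)` with the left-endpoint
#' rectangle rule on the grid:
#' `S(t_k) = exp(-sum_{j<=k} e^{h_j} (t_j - t_{j-1}))`, with `S(0) = 1`.
#' The result is a valid survival curve (non-increasing, in (0, 1]) for
#' any parameter values.
#'
#' @param record A [subject_record()] (its `y`/`delta` are ignored).
#' @param net An [init_network()] object.
#' @param grid A [time_grid()].
#' @return Data frame of class `svo_curve` with columns `time`
#'   (`t_0 ... t_m`) and `surv`.
#' @export
predict_survival <- function(record, net, grid) {
  ex <- expand_subject(unrisk(record), grid)
  h <- operator_forward(ex, net)
  s <- exp(-cumsum(exp(h) * grid$widths))
  structure(data.frame(time = grid$points, surv = c(1, s)),
            class = c("svo_curve", "data.frame"))
}

# strip the outcome so all m rows carry full histories regardless of y
unrisk <- function(record) {
  record$y <- NA_real_
  record$delta <- NA_real_
  record
}

# survival matrix (n x (m+1)) for a list of records
predict_survival_matrix <- function(records, net, grid) {
  ex <- expand_records(lapply(records, unrisk), grid)
  h <- operator_forward(ex, net)
  eh <- matrix(exp(h) * ex$width, nrow = grid$m)  # column per subject
  S <- rbind(1, exp(-apply(eh, 2L, cumsum)))
  t(S)
}

# step-function evaluation of grid survival curves at arbitrary times
surv_step_at <- function(times_grid, S_row, at) {
  idx <- findInterval(at + 1e-12, times_grid)
  idx[idx < 1L] <- 1L
  S_row[idx]
}
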