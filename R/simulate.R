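#' Configuration of the cumulative-effect survival simulator
#'
#' The simulator draws, for each subject, a smooth time-varying covariate
#' path built from a five-term Fourier basis with independent Uniform(0,1)
#' coefficients on a fine grid of `[0, tau]`, a Bernoulli(0.5)
#' time-invariant covariate `z` and a Normal(0,1) time-invariant covariate
#' `w`, and generates failure times from the hazard
#' \deqn{\lambda(t) = b0 \exp\{w + z + c1 \sum_{s \le t} x(s)\Delta s
#'   + c2 \sum_{s \le t} x(s)^2 z \Delta s\},}
#' whose covariate effects are cumulative rather than instantaneous, so
#' proportional-hazards fits with instantaneous effects are misspecified
#' on these data.  Censoring is an exponential draw truncated at a cap.
#'
#' @param n Number of subjects.
#' @param tau Upper end of the follow-up window (time units).
#' @param fine_step Fine-grid step `Delta s` used for path construction
#'   and the cumulative-hazard Riemann sums.
#' @param baseline_const Multiplicative baseline hazard constant `b0`.
#' @param effect_lin Coefficient `c1` of the cumulative linear term.
#' @param effect_quad Coefficient `c2` of the cumulative quadratic term
#'   interacted with `z`.
#' @param censor_mean Mean of the exponential censoring draw; `Inf`
#'   disables random censoring.  The default 50 gives roughly 20%
#'   censoring; 18 gives roughly 40%.
#' @param censor_cap Administrative cap applied to the censoring draw.
#' @param seed Master seed; each subject uses a deterministically derived
#'   substream so earlier subjects are unchanged when `n` grows.
#' @return An object of class `svo_sim_config` (a validated list).
#' @seealso [simulate_survdata()]
#' @export
sim_config <- function(n = 2000, tau = 100, fine_step = 0.1,
                       baseline_const = 0.05, effect_lin = 0.01,
                       effect_quad = 0.01, censor_mean = 50,
                       censor_cap = 99, seed = 1L) {
  stopifnot(n >= 1, tau > 0, fine_step > 0,
            baseline_const > 0, effect_lin >= 0, effect_quad >= 0,
            censor_mean > 0, censor_cap > 0)
  k <- tau / fine_step
  if (abs(k - round(k)) > 1e-8)
    stop("fine_step must divide tau")
  structure(list(n = as.integer(n), tau = tau, fine_step = fine_step,
                 baseline_const = baseline_const, effect_lin = effect_lin,
                 effect_quad = effect_quad, censor_mean = censor_mean,
                 censor_cap = censor_cap, seed = as.integer(seed)),
            class = "svo_sim_config")
}

fine_times <- function(config) {
  seq(0, config$tau, by = config$fine_step)
}

# deterministic per-subject substream seed below 2^31
subject_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 69621) %% 2147483647)
}

#' Fourier-basis covariate path
#'
#' Evaluates
#' `x(t) = a1 + a2 sin(2 pi t / tau) + a3 cos(2 pi t / tau) +
#'  a4 sin(4 pi t / tau) + a5 cos(4 pi t / tau)`
#' at the given times.  Downstream the sampled path is treated as a
#' left-continuous step function on the fine grid.
#'
#' @param alphas Numeric vector of the 5 basis coefficients.
#' @param times Evaluation times.
#' @param tau Period of the basis.
#' @return Numeric vector of path values.
#' @export
sample_covariate_path <- function(alphas, times, tau) {
  stopifnot(length(alphas) == 5L, tau > 0)
  u <- 2 * pi * times / tau
  alphas[1L] + alphas[2L] * sin(u) + alphas[3L] * cos(u) +
    alphas[4L] * sin(2 * u) + alphas[5L] * cos(2 * u)
}

#' Cumulative-effect conditional hazard on the fine grid
#'
#' @param x Covariate path values on the fine grid.
#' @param z,w Time-invariant covariate values.
#' @param config A [sim_config()].
#' @return Hazard values `lambda(t)` at every fine-grid time, using
#'   running sums over grid points `s <= t` (the `s = 0` term included).
#' @export
hazard_path <- function(x, z, w, config) {
  ds <- config$fine_step
  cum_lin <- cumsum(x) * ds
  cum_quad <- cumsum(x^2) * ds * z
  config$baseline_const *
    exp(w + z + config$effect_lin * cum_lin + config$effect_quad * cum_quad)
}

#' Cumulative hazard and survival from a fine-grid hazard
#'
#' `Lambda(t) = Delta s * sum_{s <= t} lambda(s)` and
#' `S(t) = exp(-Lambda(t))`.  Because the `s = 0` term is included,
#' `S(0) < 1` by an `O(Delta s)` amount; the failure sampler documents the
#' resulting boundary convention.
#'
#' @param hazard Positive hazard values on the fine grid.
#' @param config A [sim_config()].
#' @return List with `cumhaz` and `surv` on the same grid.
#' @export
survival_from_hazard <- function(hazard, config) {
  stopifnot(all(hazard > 0))
  cumhaz <- cumsum(hazard) * config$fine_step
  list(cumhaz = cumhaz, surv = exp(-cumhaz))
}

#' Inverse-CDF failure-time draw on the fine grid
#'
#' Returns `T = sup{t : S(t) >= U}` over the fine grid.  If `S` exceeds
#' `U` everywhere the draw is `tau`; if even the first grid point falls
#' below `U` (possible because `S(0) < 1`) the supremum is over an empty
#' set and the conventional value 0 is returned.
#'
#' @param surv Non-increasing survival values on the fine grid.
#' @param u A Uniform(0,1) draw.
#' @param times The fine-grid times.
#' @return The sampled failure time.
#' @export
sample_failure_time <- function(surv, u, times) {
  ok <- surv >= u
  if (!any(ok)) return(0)
  times[max(which(ok))]
}

#' Truncated-exponential censoring draw
#'
#' `C = min(Exp(mean = censor_mean), censor_cap)`, so
#' `P(C = cap) = exp(-cap / mean)`.
#'
#' @param config A [sim_config()].
#' @return A single censoring time.
#' @export
sample_censoring <- function(config) {
  if (!is.finite(config$censor_mean)) return(config$censor_cap)
  min(stats::rexp(1L, rate = 1 / config$censor_mean), config$censor_cap)
}

#' Oracle conditional survival curve for one covariate set
#'
#' Builds the true path, hazard, cumulative hazard and survival curve on
#' the fine grid for a given covariate set, without any sampling.
#'
#' @param config A [sim_config()].
#' @param alphas 5-vector of Fourier coefficients (or `NULL` if `x` given).
#' @param z,w Time-invariant covariates.
#' @param x Optional explicit covariate path on the fine grid.
#' @return A list of class `svo_truepath`: `times`, `x`, `z`, `w`,
#'   `hazard`, `cumhaz`, `surv`.
#' @export
oracle_survival <- function(config, alphas = NULL, z, w, x = NULL) {
  times <- fine_times(config)
  if (is.null(x)) x <- sample_covariate_path(alphas, times, config$tau)
  stopifnot(length(x) == length(times))
  hz <- hazard_path(x, z, w, config)
  ss <- survival_from_hazard(hz, config)
  structure(list(times = times, x = x, z = z, w = w, alphas = alphas,
                 hazard = hz, cumhaz = ss$cumhaz, surv = ss$surv),
            class = "svo_truepath")
}

#' Simulate a survival dataset with cumulative covariate effects
#'
#' Draws `n` subjects from the generator described in [sim_config()],
#' subsamples each covariate path at the `m` coarse sensors of `grid`
#' (taking the fine-grid value at the nearest fine time at or before each
#' sensor time, the left-continuity convention), and returns both the
#' observed records and the per-subject oracle truth.
#'
#' @param config A [sim_config()].
#' @param grid A [time_grid()] on `[0, tau]` giving the sensor layout.
#' @param keep_truth If `TRUE` (default) the full fine-grid oracle paths
#'   are returned alongside the records.
#' @return List with `records` (list of [subject_record()]), `truth`
#'   (list of `svo_truepath`, or `NULL`), and `config`, `grid`.
#' @examples
#' cfg <- sim_config(n = 5, seed = 42)
#' d <- simulate_survdata(cfg, time_grid(100, 10))
#' sapply(d$records, function(r) r$y)
#' @export
simulate_survdata <- function(config, grid, keep_truth = TRUE) {
  stopifnot(is_svo_grid(grid), abs(grid$tau - config$tau) < 1e-8)
  times <- fine_times(config)
  # index of the nearest fine time at or before each sensor time
  sensor_idx <- findInterval(grid$sensors + 1e-9, times)
  records <- vector("list", config$n)
  truth <- if (keep_truth) vector("list", config$n) else NULL
  for (i in seq_len(config$n)) {
    set.seed(subject_seed(config$seed, i))
    alphas <- stats::runif(5L)
    z <- stats::rbinom(1L, 1L, 0.5)
    w <- stats::rnorm(1L)
    u <- stats::runif(1L)
    tp <- oracle_survival(config, alphas, z, w)
    Ti <- sample_failure_time(tp$surv, u, times)
    Ci <- sample_censoring(config)
    y <- min(Ti, Ci)
    delta <- as.numeric(Ti <= Ci)
    records[[i]] <- subject_record(
      id = i, y = y, delta = delta,
      x = matrix(tp$x[sensor_idx], ncol = 1L, dimnames = list(NULL, "x")),
      z = c(z = z, w = w), grid = grid)
    if (keep_truth) truth[[i]] <- tp
  }
  list(records = records, truth = truth, config = config, grid = grid)
}

# true survival of one subject evaluated at arbitrary times (step function)
truepath_surv_at <- function(tp, at) {
  idx <- findInterval(at + 1e-9, tp$times)
  out <- numeric(length(at))
  out[idx >= 1] <- tp$surv[idx[idx >= 1]]
  out[at <= 0] <- if (tp$times[1] == 0) tp$surv[1] else 1
  out
}
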