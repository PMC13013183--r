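#' Discretized negative log-likelihood loss
#'
#' The training objective
#' \deqn{loss(h) = \frac{1}{n}\sum_i \sum_j I(t_{j-1} \le y_i)
#'   \{ e^{h_{ij}} (t_j - t_{j-1}) - h_{ij}\,\delta_{ij} \},}
#' a left-endpoint discretization of the negative full log-likelihood for
#' right-censored data, scaled by the number of subjects (not the number
#' of expanded rows).  `delta_ij` is nonzero only in the interval
#' containing an observed event.
#'
#' As an overflow guard, the exponential uses `h` clipped at +30 when
#' computing the loss value (with a warning); gradients use the unclipped
#' value wherever it is finite.
#'
#' @param h Per-row log-hazard values (from [operator_forward()]).
#' @param width Per-row interval widths `t_j - t_{j-1}`.
#' @param at_risk Per-row at-risk indicators `I(t_{j-1} <= y_i)`.
#' @param event Per-row event indicators `delta_ij`.
#' @param n_subjects Scaling denominator (number of subjects `n`).
#' @return The scalar loss.
#' @export
discretized_loss <- function(h, width, at_risk, event, n_subjects) {
  stopifnot(length(width) == length(h), length(at_risk) == length(h),
            length(event) == length(h), n_subjects >= 1)
  bad <- which(!is.finite(h))
  if (length(bad))
    stop("non-finite log-hazard value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  hc <- h
  if (any(at_risk > 0 & h > 30)) {
    warning("log-hazard values above 30 clipped in the loss value")
    hc <- pmin(h, 30)
  }
  sum(at_risk * (exp(hc) * width - h * event)) / n_subjects
}

#' Gradient of the discretized loss with respect to the log-hazard
#'
#' `d loss / d h_ij = I(t_{j-1} <= y_i) (e^{h_ij} (t_j - t_{j-1}) -
#' delta_ij) / n`.
#'
#' @inheritParams discretized_loss
#' @return Numeric vector of per-row derivatives.
#' @export
loss_gradient <- function(h, width, at_risk, event, n_subjects) {
  eh <- exp(h)
  eh[!is.finite(eh)] <- exp(30)  # overflow fallback, matches the loss guard
  at_risk * (eh * width - event) / n_subjects
}

loss_from_expanded <- function(ex, h, n_subjects = length(ex$ids)) {
  discretized_loss(h, ex$width, ex$at_risk, ex$event, n_subjects)
}

#' Continuous full log-likelihood (quadrature oracle)
#'
#' Evaluates the censored-data full log-likelihood
#' \deqn{\ell_n = \sum_i \{ h(y_i, \tilde x_i(y_i))\,\delta_i -
#'   \int_0^{y_i} e^{h(t, \tilde x_i(t))} dt \}}
#' with the integral computed by a left-rectangle rule on a fine
#' quadrature grid (the last, partial rectangle has width `y_i - t_k`).
#' Intended as an independent check of the discretized loss, not as a
#' training objective.
#'
#' @param records List of [subject_record()] objects with observed `y`,
#'   `delta`.
#' @param h_function Function `(t, record) -> log-hazard` evaluable at any
#'   time.
#' @param quadrature_step Step of the quadrature grid.
#' @return The scalar log-likelihood.
#' @export
exact_log_likelihood <- function(records, h_function, quadrature_step) {
  stopifnot(quadrature_step > 0)
  total <- 0
  for (r in records) {
    term <- if (r$delta == 1) h_function(r$y, r) else 0
    if (r$y > 0) {
      pts <- seq(0, r$y, by = quadrature_step)
      if (pts[length(pts)] < r$y) pts <- c(pts, r$y)
      lefts <- pts[-length(pts)]
      widths <- diff(pts)
      hv <- vapply(lefts, h_function, numeric(1), r)
      term <- term - sum(exp(hv) * widths)
    }
    total <- total + term
  }
  total
}
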