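#' Partition of the follow-up window
#'
#' Builds the partition `0 = t_0 < t_1 < ... < t_m = tau` on which
#' covariate histories are sampled ("sensors" at `t_0 ... t_{m-1}`) and on
#' which the discretized likelihood and survival curves are evaluated.
#' By default the partition is even; an arbitrary strictly increasing
#' vector of cut points is also accepted because the discretized loss only
#' uses the interval widths `t_j - t_{j-1}`.
#'
#' @param tau Positive upper bound of the supported follow-up window,
#'   typically the largest observed failure time.
#' @param m Number of intervals.
#' @param points Optional numeric vector of `m + 1` cut points starting at
#'   0 and ending at `tau`; overrides the even partition.
#' @return An object of class `svo_grid`: a list with elements `tau`, `m`,
#'   `points` (length `m + 1`), `widths` (length `m`) and `sensors`
#'   (the `m` sensor times `t_0 ... t_{m-1}`).
#' @examples
#' g <- time_grid(100, 4)
#' g$points  # 0 25 50 75 100
#' @export
time_grid <- function(tau, m, points = NULL) {
  if (is.null(points)) {
    stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
              is.numeric(m), length(m) == 1L, m >= 1, m == round(m))
    m <- as.integer(m)
    points <- seq(0, tau, length.out = m + 1L)
    points[m + 1L] <- tau
  } else {
    points <- as.numeric(points)
    m <- length(points) - 1L
    tau <- points[m + 1L]
  }
  if (points[1L] != 0)
    stop("grid must start at t_0 = 0")
  if (any(diff(points) <= 0))
    stop("grid points must be strictly increasing")
  structure(list(tau = tau, m = m, points = points,
                 widths = diff(points), sensors = points[seq_len(m)]),
            class = "svo_grid")
}

#' @export
print.svo_grid <- function(x, ...) {
  cat(sprintf("<svo_grid> m = %d intervals on [0, %g]%s\n", x$m, x$tau,
              if (length(unique(signif(x$widths, 10))) == 1L)
                sprintf(", even width %g", x$widths[1L]) else ", uneven"))
  invisible(x)
}

is_svo_grid <- function(x) inherits(x, "svo_grid")
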