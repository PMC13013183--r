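#' Person-period expansion with future-value masking
#'
#' Expands each subject into `m` rows, one per interval `(t_{j-1}, t_j]`.
#' Row `j` carries the covariate history sampled at the sensors
#' `t_0, ..., t_{j-1}` with all later sensor values masked to exact zeros,
#' the at-risk indicator `I(t_{j-1} <= y)` and the interval event
#' indicator `I(t_{j-1} <= y) I(t_j > y) delta`, which is nonzero only in
#' the interval containing the event.  The log-hazard is evaluated at the
#' interval's left endpoint `t_{j-1}`, matching the rectangle rule of the
#' discretized likelihood.
#'
#' @param record A [subject_record()].
#' @param grid A [time_grid()] whose `m` matches the record's sensor count.
#' @return An `svo_expanded` object for the single subject; see
#'   [expand_records()] for the layout.
#' @export
expand_subject <- function(record, grid) {
  expand_records(list(record), grid)
}

#' Expand a set of subject records into the masked training table
#'
#' @param records List of [subject_record()] objects.
#' @param grid A [time_grid()].
#' @return An object of class `svo_expanded`: a list with `grid`,
#'   per-subject `ids`, `y`, `delta`; and per-row (length `n * m`)
#'   `subject` (index into `ids`), `j` (interval number), `t_left`,
#'   `t_right`, `width`, `at_risk`, `event`; plus the masked history
#'   matrix `X` (`n*m` rows, `m * C` columns, sensor-major within
#'   channel) and the time-invariant matrix `Z` (`n*m` x `q`).
#' @export
expand_records <- function(records, grid) {
  check_records(records, grid)
  m <- grid$m
  n <- length(records)
  C <- ncol(records[[1L]]$x)
  q <- length(records[[1L]]$z)
  ids <- vapply(records, `[[`, character(1), "id")
  y <- vapply(records, `[[`, numeric(1), "y")
  delta <- vapply(records, `[[`, numeric(1), "delta")
  too_big <- !is.na(y) & y > grid$tau
  if (any(too_big)) {
    warning(sprintf("%d subject(s) have y > tau = %g; clamped to tau",
                    sum(too_big), grid$tau))
    y[too_big] <- grid$tau
  }

  # lower-triangular-with-diagonal mask: row j keeps sensors 1..j (t_0..t_{j-1})
  keep <- matrix(0, m, m)
  keep[lower.tri(keep, diag = TRUE)] <- 1

  X <- matrix(0, n * m, m * C)
  Z <- matrix(0, n * m, q)
  if (q) colnames(Z) <- invariant_names(records)
  colnames(X) <- as.vector(vapply(channel_names(records), function(ch)
    paste0(ch, "_s", seq_len(m) - 1L), character(m)))
  for (i in seq_len(n)) {
    rows <- (i - 1L) * m + seq_len(m)
    for (c in seq_len(C))
      X[rows, (c - 1L) * m + seq_len(m)] <-
        keep * rep(records[[i]]$x[, c], each = m)
    if (q) Z[rows, ] <- matrix(records[[i]]$z, m, q, byrow = TRUE)
  }

  t_left <- rep(grid$points[seq_len(m)], n)
  t_right <- rep(grid$points[-1L], n)
  width <- rep(grid$widths, n)
  yrow <- rep(y, each = m)
  drow <- rep(delta, each = m)
  at_risk <- as.numeric(!is.na(yrow) & t_left <= yrow)
  event <- at_risk * as.numeric(!is.na(yrow) & t_right > yrow) *
    ifelse(is.na(drow), 0, drow)

  structure(list(grid = grid, ids = ids, y = y, delta = delta,
                 subject = rep(seq_len(n), each = m),
                 j = rep(seq_len(m), n),
                 t_left = t_left, t_right = t_right, width = width,
                 at_risk = at_risk, event = event,
                 X = X, Z = Z, m = m, channels = C),
            class = "svo_expanded")
}

#' @export
print.svo_expanded <- function(x, ...) {
  cat(sprintf("<svo_expanded> %d subjects x %d intervals = %d rows, %d channel(s), %d invariant\n",
              length(x$ids), x$m, nrow(x$X), x$channels, ncol(x$Z)))
  invisible(x)
}

#' @export
as.data.frame.svo_expanded <- function(x, ...) {
  data.frame(id = x$ids[x$subject], j = x$j, t_left = x$t_left,
             t_right = x$t_right, width = x$width,
             at_risk = x$at_risk, event = x$event,
             x$X, x$Z, check.names = FALSE)
}

# subset rows of an expanded dataset (keeps per-subject vectors intact)
expanded_rows <- function(ex, idx) {
  ex$subject <- ex$subject[idx]
  ex$j <- ex$j[idx]
  ex$t_left <- ex$t_left[idx]
  ex$t_right <- ex$t_right[idx]
  ex$width <- ex$width[idx]
  ex$at_risk <- ex$at_risk[idx]
  ex$event <- ex$event[idx]
  ex$X <- ex$X[idx, , drop = FALSE]
  ex$Z <- ex$Z[idx, , drop = FALSE]
  ex
}
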