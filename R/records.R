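#' A single subject's survival record
#'
#' Bundles the observed time `y = min(T, C)`, the event indicator
#' `delta = I(T <= C)`, the time-varying covariate values sampled at the
#' grid sensors `t_0 ... t_{m-1}`, and any time-invariant covariates.
#'
#' @param id Subject identifier (scalar, coerced to character).
#' @param y Observed time in `[0, tau]`.  May be `NA` for prediction-only
#'   records (no likelihood contribution).
#' @param delta Event indicator, 0 (censored) or 1 (event); `NA` allowed
#'   alongside `NA` `y`.
#' @param x Time-varying covariate values at the `m` sensors: a numeric
#'   vector (one channel) or an `m x C` matrix with one column per channel.
#' @param z Named numeric vector of time-invariant covariates (may be
#'   length 0).
#' @param grid Optional [time_grid()] used to validate dimensions and
#'   clamp `y` to `[0, tau]` (values above `tau` are clamped with a
#'   warning, values below 0 are an error).
#' @return An object of class `svo_record`.
#' @export
subject_record <- function(id, y, delta, x, z = numeric(0), grid = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  z <- unlist(z)
  if (length(z) && is.null(names(z)))
    names(z) <- paste0("z", seq_along(z))
  if (!is.na(y) && y < 0) stop("observed time y must be non-negative")
  if (!is.na(delta) && !delta %in% c(0, 1)) stop("delta must be 0 or 1")
  if (!is.null(grid)) {
    if (nrow(x) != grid$m)
      stop(sprintf("subject %s: %d sensor values per channel, grid needs m = %d",
                   as.character(id), nrow(x), grid$m))
    if (!is.na(y) && y > grid$tau) {
      warning(sprintf("subject %s: y = %g exceeds tau = %g, clamped",
                      as.character(id), y, grid$tau))
      y <- grid$tau
    }
  }
  structure(list(id = as.character(id), y = as.numeric(y),
                 delta = as.numeric(delta), x = x, z = z),
            class = "svo_record")
}

#' @export
print.svo_record <- function(x, ...) {
  cat(sprintf("<svo_record> id=%s y=%g delta=%g, %d sensors x %d channel(s), %d invariant\n",
              x$id, x$y, x$delta, nrow(x$x), ncol(x$x), length(x$z)))
  invisible(x)
}

channel_names <- function(records) colnames(records[[1L]]$x)
invariant_names <- function(records) names(records[[1L]]$z)

check_records <- function(records, grid) {
  stopifnot(length(records) > 0L)
  ch <- channel_names(records)
  zn <- invariant_names(records)
  for (r in records) {
    if (!inherits(r, "svo_record")) stop("all elements must be svo_record")
    if (nrow(r$x) != grid$m)
      stop(sprintf("subject %s has %d sensor rows, grid needs m = %d",
                   r$id, nrow(r$x), grid$m))
    if (!identical(colnames(r$x), ch) || !identical(names(r$z), zn))
      stop(sprintf("subject %s has inconsistent covariate names", r$id))
  }
  invisible(records)
}

#' Forward-fill missing interim covariate values
#'
#' Replaces each `NA` in a time-ordered series by the most recent observed
#' value at an earlier sensor, the convention used for sparsely observed
#' longitudinal covariates.  A missing baseline (first) value cannot be
#' filled and is an error: subjects with missing baseline measurements
#' should be excluded before analysis.
#'
#' @param series Numeric vector in sensor-time order, possibly with `NA`s.
#' @return The filled numeric vector.
#' @examples
#' forward_fill(c(5, NA, 7, NA))  # 5 5 7 7
#' @export
forward_fill <- function(series) {
  series <- as.numeric(series)
  if (length(series) == 0L) return(series)
  if (is.na(series[1L]))
    stop("baseline (first) value is missing; cannot forward-fill")
  idx <- cummax(ifelse(is.na(series), 0L, seq_along(series)))
  series[idx]
}

#' Read subject records from a long-format file
#'
#' The long format has one row per subject per sensor time, with columns
#' `id`, `time`, one column per time-varying channel, `y`, `delta`, and
#' one column per time-invariant covariate (constant within subject).
#' Channel and invariant columns are identified by position (between
#' `time` and `y`, and after `delta`) unless given explicitly.
#'
#' @param path CSV (`.csv`) or TSV file with a header.
#' @param channels,invariant Optional character vectors naming the
#'   time-varying and time-invariant covariate columns.
#' @param impute If `TRUE`, missing (empty) channel cells are
#'   forward-filled per subject via [forward_fill()].
#' @return A list of [subject_record()] objects (empty list for an empty
#'   file) with attribute `sensor_times`, the common sensor time vector.
#' @seealso [write_long_format()]
#' @export
read_long_format <- function(path, channels = NULL, invariant = NULL,
                             impute = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) return(list())
  need <- c("id", "time", "y", "delta")
  if (!all(need %in% names(df)))
    stop("long format requires columns: ", paste(need, collapse = ", "))
  cols <- names(df)
  if (is.null(channels))
    channels <- cols[seq(match("time", cols) + 1L, match("y", cols) - 1L)]
  if (is.null(invariant)) {
    after <- seq_len(ncol(df)) > match("delta", cols)
    invariant <- cols[after]
  }
  ids <- unique(df$id)
  times0 <- sort(unique(df$time))
  bad <- character(0)
  for (i in ids) {
    ti <- sort(df$time[df$id == i])
    if (length(ti) != length(times0) || any(ti != times0))
      bad <- c(bad, as.character(i))
  }
  if (length(bad))
    stop("non-rectangular sensor sets for subject(s): ",
         paste(bad, collapse = ", "))
  records <- lapply(ids, function(i) {
    sub <- df[df$id == i, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    x <- as.matrix(sub[, channels, drop = FALSE])
    if (impute) x <- apply(x, 2L, forward_fill)
    if (is.null(dim(x))) x <- matrix(x, ncol = length(channels),
                                     dimnames = list(NULL, channels))
    z <- unlist(sub[1L, invariant, drop = TRUE])
    if (length(invariant)) names(z) <- invariant
    subject_record(i, sub$y[1L], sub$delta[1L], x,
                   if (length(invariant)) z else numeric(0))
  })
  attr(records, "sensor_times") <- times0
  records
}

#' Write subject records to a long-format file
#'
#' @param records List of [subject_record()] objects sharing a schema.
#' @param path Output CSV/TSV path (separator chosen by extension).
#' @param grid [time_grid()] supplying the sensor times written to the
#'   `time` column.
#' @seealso [read_long_format()]
#' @export
write_long_format <- function(records, path, grid) {
  check_records(records, grid)
  ch <- channel_names(records)
  zn <- invariant_names(records)
  blocks <- lapply(records, function(r) {
    out <- data.frame(id = r$id, time = grid$sensors,
                      check.names = FALSE)
    for (k in seq_along(ch)) out[[ch[k]]] <- r$x[, k]
    out$y <- r$y
    out$delta <- r$delta
    for (k in seq_along(zn)) out[[zn[k]]] <- r$z[[k]]
    out
  })
  df <- do.call(rbind, blocks)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
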