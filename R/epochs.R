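#' Per-subject condition-average ERP container
#'
#' Holds a subject x condition x sensor x time array of ERP amplitudes (uV)
#' together with its time axis, sensor ids, condition labels and subject
#' metadata. Time is in ms relative to stimulus onset; sample i covers the
#' half-open interval [t_i, t_i + 1000/sample_rate ms).
#'
#' @param values 4-d numeric array: subject x condition x sensor x time.
#' @param time_ms numeric vector of sample onset times (ms), strictly
#'   increasing with a uniform step.
#' @param sensors character vector of sensor ids.
#' @param conditions character vector of condition labels.
#' @param subjects character or integer vector of subject ids.
#' @param sample_rate sampling rate in Hz.
#' @param baseline_ms length-2 numeric, the baseline window (ms), contained
#'   in the epoch window.
#' @param subject_info optional tibble of per-subject metadata (must contain
#'   a `subject` column), e.g. between-subject group assignment.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(values, time_ms, sensors, conditions, subjects,
                      sample_rate, baseline_ms = c(-200, 0),
                      subject_info = NULL) {
  stopifnot(
    is.array(values), length(dim(values)) == 4,
    dim(values)[1] == length(subjects),
    dim(values)[2] == length(conditions),
    dim(values)[3] == length(sensors),
    dim(values)[4] == length(time_ms)
  )
  if (length(time_ms) > 1) {
    dt <- diff(time_ms)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
      stop("time axis must be strictly increasing and uniform")
    }
    if (abs(dt[1] - 1000 / sample_rate) > 1e-6) {
      stop("time step does not match sample rate")
    }
  }
  ep_win <- c(time_ms[1], time_ms[length(time_ms)] + 1000 / sample_rate)
  if (baseline_ms[1] < ep_win[1] || baseline_ms[2] > ep_win[2]) {
    stop("baseline window must lie within the epoch window")
  }
  dimnames(values) <- list(as.character(subjects), conditions, sensors, NULL)
  structure(
    list(
      values = values, time_ms = time_ms, sensors = sensors,
      conditions = conditions, subjects = as.character(subjects),
      sample_rate = sample_rate, baseline_ms = baseline_ms,
      subject_info = subject_info
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d subjects x %d conditions x %d sensors x %d samples (%g Hz)\n",
    length(x$subjects), length(x$conditions), length(x$sensors),
    length(x$time_ms), x$sample_rate
  ))
  cat(sprintf(
    "epoch [%g, %g) ms, baseline [%g, %g) ms\nconditions: %s\n",
    x$time_ms[1], x$time_ms[length(x$time_ms)] + 1000 / x$sample_rate,
    x$baseline_ms[1], x$baseline_ms[2],
    paste(x$conditions, collapse = ", ")
  ))
  invisible(x)
}

#' Long-format view of an epoch set
#'
#' @param x an `epoch_set`.
#' @param ... unused.
#' @return a tibble with columns subject, condition, sensor, time_ms,
#'   amplitude (uV).
#' @method tidy epoch_set
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    subject = rep(x$subjects, times = prod(d[2:4])),
    condition = rep(rep(x$conditions, each = d[1]), times = prod(d[3:4])),
    sensor = rep(rep(x$sensors, each = prod(d[1:2])), times = d[4]),
    time_ms = rep(x$time_ms, each = prod(d[1:3])),
    amplitude = as.vector(x$values)
  )
}

# indices of samples whose onsets fall in the half-open window [a, b)
.window_idx <- function(time_ms, window) {
  which(time_ms >= window[1] - 1e-9 & time_ms < window[2] - 1e-9)
}

#' Baseline-correct every epoch
#'
#' Subtracts, per subject/condition/sensor, the mean amplitude over the
#' baseline window from the whole epoch, so that the post-correction
#' baseline mean is zero. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param window length-2 numeric (ms), half-open; defaults to the set's
#'   stored baseline window.
#' @return a baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = epochs$baseline_ms) {
  idx <- .window_idx(epochs$time_ms, window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  ep_win <- c(epochs$time_ms[1],
              epochs$time_ms[length(epochs$time_ms)] + 1000 / epochs$sample_rate)
  if (window[1] < ep_win[1] - 1e-9 || window[2] > ep_win[2] + 1e-9) {
    stop("baseline window outside the epoch window")
  }
  bl <- apply(epochs$values[, , , idx, drop = FALSE], 1:3, mean)
  epochs$values <- epochs$values - as.vector(bl) # recycles over time (last dim)
  epochs$baseline_ms <- window
  epochs
}

#' Trial-level epoch container
#'
#' Single-trial sensor x time epochs with a per-trial metadata table
#' (subject, condition, ...). Produced by [gen_trial_epochs()] and consumed
#' by [average_by_condition()].
#'
#' @param values 3-d array: trial x sensor x time.
#' @param info tibble with one row per trial; must contain `subject` and
#'   `condition` columns.
#' @inheritParams epoch_set
#' @return an object of class `trial_epochs`.
#' @export
trial_epochs <- function(values, info, time_ms, sensors, sample_rate,
                         baseline_ms = c(-200, 0)) {
  stopifnot(
    is.array(values), length(dim(values)) == 3,
    dim(values)[1] == nrow(info),
    dim(values)[2] == length(sensors),
    dim(values)[3] == length(time_ms),
    all(c("subject", "condition") %in% names(info))
  )
  structure(
    list(
      values = values, info = tibble::as_tibble(info), time_ms = time_ms,
      sensors = sensors, sample_rate = sample_rate, baseline_ms = baseline_ms
    ),
    class = "trial_epochs"
  )
}

#' Average single trials into per-subject condition ERPs
#'
#' Arithmetic mean over trials within each subject x condition cell. Every
#' subject must contribute at least one trial to every condition; an empty
#' cell is an error naming the subject and cell. Trial counts per cell are
#' attached as attribute `"trial_counts"`.
#'
#' @param trials a [trial_epochs()] object.
#' @return an `epoch_set` of condition averages.
#' @export
average_by_condition <- function(trials) {
  subjects <- unique(trials$info$subject)
  conditions <- unique(trials$info$condition)
  ns <- length(subjects); nc <- length(conditions)
  out <- array(NA_real_, c(ns, nc, dim(trials$values)[2], dim(trials$values)[3]))
  counts <- matrix(0L, ns, nc, dimnames = list(subjects, conditions))
  for (si in seq_len(ns)) {
    for (ci in seq_len(nc)) {
      sel <- which(trials$info$subject == subjects[si] &
                     trials$info$condition == conditions[ci])
      if (length(sel) == 0) {
        stop(sprintf("no trials for subject '%s' in condition '%s'",
                     subjects[si], conditions[ci]))
      }
      counts[si, ci] <- length(sel)
      out[si, ci, , ] <- apply(trials$values[sel, , , drop = FALSE], 2:3, mean)
    }
  }
  es <- epoch_set(out, trials$time_ms, trials$sensors, conditions, subjects,
                  trials$sample_rate, trials$baseline_ms,
                  subject_info = dplyr::distinct(
                    trials$info, dplyr::across(dplyr::any_of(c("subject", "group")))
                  ))
  attr(es, "trial_counts") <- counts
  es
}

#' Subset an epoch set by sensors and/or time window
#'
#' Selection never changes amplitude values, only the index sets. The time
#' window is half-open `[start, end)` over sample onsets.
#'
#' @param epochs an `epoch_set`.
#' @param sensors character vector of sensor ids, a `sensor_layout`, or NULL.
#' @param window length-2 numeric window (ms) or NULL.
#' @param conditions character vector of condition labels or NULL.
#' @return the restricted `epoch_set`.
#' @export
subset_epochs <- function(epochs, sensors = NULL, window = NULL,
                          conditions = NULL) {
  si <- seq_along(epochs$sensors)
  if (!is.null(sensors)) {
    ids <- if (inherits(sensors, "sensor_layout")) sensors$ids else sensors
    stopifnot(all(ids %in% epochs$sensors))
    si <- match(ids, epochs$sensors)
  }
  ti <- seq_along(epochs$time_ms)
  if (!is.null(window)) {
    ti <- .window_idx(epochs$time_ms, window)
    if (length(ti) == 0) stop("time window contains no samples")
  }
  ci <- seq_along(epochs$conditions)
  if (!is.null(conditions)) {
    stopifnot(all(conditions %in% epochs$conditions))
    ci <- match(conditions, epochs$conditions)
  }
  bl <- epochs$baseline_ms
  tnew <- epochs$time_ms[ti]
  # keep a valid (possibly trivial) baseline record after cropping
  bl[1] <- max(bl[1], tnew[1])
  bl[2] <- min(bl[2], tnew[length(tnew)] + 1000 / epochs$sample_rate)
  if (bl[1] >= bl[2]) bl <- c(tnew[1], tnew[1])
  es <- epoch_set(
    epochs$values[, ci, si, ti, drop = FALSE], tnew,
    epochs$sensors[si], epochs$conditions[ci], epochs$subjects,
    epochs$sample_rate, bl, epochs$subject_info
  )
  es
}

#' Save / load an epoch set
#'
#' Serializes the container to RDS with a JSON sidecar describing its
#' layout (subjects, conditions, sensors, time axis, sample rate, baseline
#' window), so downstream stages and external tools can inspect the
#' metadata without loading the array.
#'
#' @param epochs an `epoch_set`.
#' @param path path of the `.rds` file to write.
#' @return `read_epochs` returns the `epoch_set`; `write_epochs` its path,
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(epochs, path)
  meta <- list(
    subjects = epochs$subjects, conditions = epochs$conditions,
    sensors = epochs$sensors, time_ms = epochs$time_ms,
    sample_rate_hz = epochs$sample_rate, baseline_ms = epochs$baseline_ms
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epoch_set"))
  x
}
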