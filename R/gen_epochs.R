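#' ERP epoch generator configuration
#'
#' Parameters of the synthetic ERP model: epochs are condition-average
#' waveforms equal to the sum of injected effect patches, a per-subject
#' random spatial offset, and spatially and temporally correlated Gaussian
#' noise.
#'
#' The noise model is deliberately minimal but non-trivial for spatial
#' clustering: white sensor noise is mixed through `spatial_smooth`
#' diffusion passes over the sensor adjacency graph (each pass averages a
#' sensor with its neighborhood mean), and samples follow an AR(1) process
#' along time with coefficient `ar`. The combined operator is rescaled so
#' the marginal SD of every sensor-sample equals `sd` exactly.
#'
#' @param n_sensors sensor count; must match the layout (default 129).
#' @param sample_rate sampling rate in Hz (default 250).
#' @param window epoch window in ms, half-open (default c(-200, 1200)).
#' @param baseline_ms baseline window in ms (default c(-200, 0)); must lie
#'   within `window`.
#' @param noise list with elements `sd` (marginal noise SD in uV at the
#'   condition-average level), `spatial_smooth` (number of graph diffusion
#'   passes), `ar` (temporal AR(1) coefficient in [0, 1)), `subject_sd`
#'   (SD of the per-subject spatial offset, constant over time and
#'   conditions, in uV).
#' @param effects list of [effect_patch()] objects.
#' @return an object of class `erp_config`.
#' @export
erp_config <- function(n_sensors = 129, sample_rate = 250,
                       window = c(-200, 1200), baseline_ms = c(-200, 0),
                       noise = list(), effects = list()) {
  noise <- utils::modifyList(
    list(sd = 1, spatial_smooth = 2L, ar = 0.5, subject_sd = 0.5), noise
  )
  stopifnot(
    noise$sd >= 0, noise$subject_sd >= 0,
    noise$ar >= 0, noise$ar < 1, noise$spatial_smooth >= 0,
    baseline_ms[1] >= window[1], baseline_ms[2] <= window[2]
  )
  structure(
    list(n_sensors = n_sensors, sample_rate = sample_rate, window = window,
         baseline_ms = baseline_ms, noise = noise, effects = effects),
    class = "erp_config"
  )
}

#' Ground-truth effect patch
#'
#' A sensor-time region with per-condition mean amplitudes, injected into
#' generated epochs. The sensor set is given explicitly or as a graph ball
#' (`center` id plus `radius` hops over the layout adjacency).
#'
#' @param window time window in ms, half-open, within the epoch window.
#' @param amplitude named numeric vector of mean amplitudes (uV) keyed by
#'   condition label; conditions not named get 0.
#' @param sensors character vector of sensor ids (or NULL).
#' @param center single sensor id (used with `radius` when `sensors` is NULL).
#' @param radius non-negative integer graph radius.
#' @param subject_sd SD (uV) of a per-subject amplitude deviation shared
#'   across conditions.
#' @param group optional between-subject group label; when set, the patch
#'   amplitudes apply only to subjects of that group (per the epoch set's
#'   subject metadata), which is how between-subject stimulation effects
#'   are injected.
#' @return an object of class `effect_patch`.
#' @export
effect_patch <- function(window, amplitude, sensors = NULL, center = NULL,
                         radius = 1L, subject_sd = 0, group = NULL) {
  if (is.null(sensors) && is.null(center)) {
    stop("either `sensors` or `center` must be given")
  }
  stopifnot(length(window) == 2, window[1] < window[2],
            !is.null(names(amplitude)), subject_sd >= 0)
  structure(
    list(window = window, amplitude = amplitude, sensors = sensors,
         center = center, radius = as.integer(radius), subject_sd = subject_sd,
         group = group),
    class = "effect_patch"
  )
}

# resolve a patch's sensor set against a layout (graph ball when implicit)
.patch_sensors <- function(patch, layout) {
  if (!is.null(patch$sensors)) {
    if (!all(patch$sensors %in% layout$ids)) stop("patch sensors outside the layout")
    return(patch$sensors)
  }
  c0 <- match(patch$center, layout$ids)
  if (is.na(c0)) stop("patch center sensor not in the layout")
  frontier <- c0; ball <- c0
  for (k in seq_len(patch$radius)) {
    frontier <- setdiff(unique(unlist(layout$neighbors[frontier])), ball)
    if (!length(frontier)) break
    ball <- c(ball, frontier)
  }
  layout$ids[sort(ball)]
}

# spatial mixing operator: `passes` diffusion steps, rows scaled to unit L2
# norm so white input keeps unit marginal variance
.spatial_operator <- function(layout, passes) {
  n <- length(layout$ids)
  M <- diag(n)
  if (passes > 0) {
    A <- matrix(0, n, n)
    if (nrow(layout$edges)) {
      A[layout$edges] <- 1
      A[layout$edges[, 2:1, drop = FALSE]] <- 1
    }
    deg <- pmax(rowSums(A), 1)
    S <- 0.5 * (diag(n) + A / deg)
    for (k in seq_len(passes)) M <- S %*% M
  }
  M / sqrt(rowSums(M^2))
}

# sensors x time noise: AR(1) along time, spatially mixed, unit marginal SD
.correlated_noise <- function(M, n_time, ar) {
  n <- nrow(M)
  W <- matrix(stats::rnorm(n * n_time), n, n_time)
  if (ar > 0 && n_time > 1) {
    X <- W
    X[, 1] <- W[, 1]
    sc <- sqrt(1 - ar^2)
    for (t in 2:n_time) X[, t] <- ar * X[, t - 1] + sc * W[, t]
    W <- X
  }
  M %*% W
}

#' Generate per-subject condition-average ERP epochs
#'
#' Produces an [epoch_set()] of per-subject, per-condition average ERPs with
#' known ground truth: injected patch amplitudes (plus per-subject patch
#' deviations), a per-subject spatially smooth offset, and correlated noise
#' per the [erp_config()]. The resolved ground truth (sensor ids and sample
#' windows per patch) is attached as attribute `"truth"`.
#'
#' @param cfg an [erp_config()].
#' @param design a [build_design()] result (supplies subjects and, for
#'   mixed designs, group membership), or NULL if `subjects` is given.
#' @param layout a [sensor_layout()] with `cfg$n_sensors` sensors.
#' @param seed integer seed.
#' @param conditions condition labels; defaults to the design's cells.
#' @param subjects optional explicit subject ids (overrides `design`).
#' @return an `epoch_set` with attribute `"truth"`.
#' @export
gen_epochs <- function(cfg, design = NULL, layout, seed = 1,
                       conditions = NULL, subjects = NULL) {
  stopifnot(inherits(cfg, "erp_config"), inherits(layout, "sensor_layout"))
  if (length(layout$ids) != cfg$n_sensors) {
    stop("layout sensor count does not match the config")
  }
  subject_info <- NULL
  if (is.null(subjects)) {
    stopifnot(inherits(design, "study_design"))
    subjects <- unique(design$encoding$subject)
    subject_info <- dplyr::distinct(design$encoding, subject, group)
    if (is.null(conditions)) conditions <- design$spec$cells
  }
  if (is.null(conditions)) stop("conditions must be given when no design is")
  set.seed(.child_rng(seed, "epochs"))

  dt <- 1000 / cfg$sample_rate
  time_ms <- seq(cfg$window[1], cfg$window[2] - dt, by = dt)
  ns <- length(subjects); nc <- length(conditions)
  nsen <- length(layout$ids); nt <- length(time_ms)

  patches <- lapply(cfg$effects, function(p) {
    ids <- .patch_sensors(p, layout)
    tidx <- .window_idx(time_ms, p$window)
    if (!length(tidx)) stop("patch window outside the epoch window")
    if (p$window[1] < cfg$window[1] || p$window[2] > cfg$window[2]) {
      stop("patch window outside the epoch window")
    }
    list(sensors = ids, sidx = match(ids, layout$ids), tidx = tidx,
         window = p$window, amplitude = p$amplitude, subject_sd = p$subject_sd,
         group = p$group)
  })
  subj_group <- if (!is.null(subject_info) && "group" %in% names(subject_info)) {
    subject_info$group[match(subjects, subject_info$subject)]
  } else {
    rep(NA_character_, length(subjects))
  }

  M <- .spatial_operator(layout, cfg$noise$spatial_smooth)
  values <- array(0, c(ns, nc, nsen, nt))
  # per-subject smooth spatial offset, constant over time and condition
  subj_off <- if (cfg$noise$subject_sd > 0) {
    (M %*% matrix(stats::rnorm(nsen * ns), nsen, ns)) * cfg$noise$subject_sd
  } else {
    matrix(0, nsen, ns)
  }
  # per-subject patch amplitude deviations (shared across conditions)
  patch_dev <- vapply(patches, function(p) stats::rnorm(ns, 0, p$subject_sd),
                      numeric(ns))
  if (length(patches) && ns == 1) patch_dev <- matrix(patch_dev, nrow = 1)

  for (si in seq_len(ns)) {
    for (ci in seq_len(nc)) {
      e <- if (cfg$noise$sd > 0) {
        .correlated_noise(M, nt, cfg$noise$ar) * cfg$noise$sd
      } else {
        matrix(0, nsen, nt)
      }
      e <- e + subj_off[, si]
      for (pi in seq_along(patches)) {
        p <- patches[[pi]]
        if (!is.null(p$group) && !identical(subj_group[si], p$group)) next
        amp <- if (conditions[ci] %in% names(p$amplitude)) {
          p$amplitude[[conditions[ci]]]
        } else 0
        if (amp != 0 || p$subject_sd > 0) {
          e[p$sidx, p$tidx] <- e[p$sidx, p$tidx] + amp + patch_dev[si, pi]
        }
      }
      values[si, ci, , ] <- e
    }
  }
  es <- epoch_set(values, time_ms, layout$ids, conditions, subjects,
                  cfg$sample_rate, cfg$baseline_ms, subject_info)
  attr(es, "truth") <- patches
  es
}

#' Generate single-trial epochs
#'
#' Trial-level counterpart of [gen_epochs()] for testing trial averaging:
#' each trial is patch effects (per its condition) plus correlated noise of
#' marginal SD `cfg$noise$sd` (interpreted here as per-trial noise).
#'
#' @param cfg an [erp_config()].
#' @param layout a [sensor_layout()].
#' @param info tibble with one row per trial: columns `subject`, `condition`.
#' @param seed integer seed.
#' @return a [trial_epochs()] object.
#' @export
gen_trial_epochs <- function(cfg, layout, info, seed = 1) {
  stopifnot(inherits(cfg, "erp_config"), all(c("subject", "condition") %in% names(info)))
  set.seed(.child_rng(seed, "epochs"))
  dt <- 1000 / cfg$sample_rate
  time_ms <- seq(cfg$window[1], cfg$window[2] - dt, by = dt)
  nsen <- length(layout$ids); nt <- length(time_ms)
  patches <- lapply(cfg$effects, function(p) {
    list(sidx = match(.patch_sensors(p, layout), layout$ids),
         tidx = .window_idx(time_ms, p$window), amplitude = p$amplitude)
  })
  M <- .spatial_operator(layout, cfg$noise$spatial_smooth)
  values <- array(0, c(nrow(info), nsen, nt))
  for (k in seq_len(nrow(info))) {
    e <- if (cfg$noise$sd > 0) {
      .correlated_noise(M, nt, cfg$noise$ar) * cfg$noise$sd
    } else {
      matrix(0, nsen, nt)
    }
    for (p in patches) {
      amp <- if (info$condition[k] %in% names(p$amplitude)) {
        p$amplitude[[info$condition[k]]]
      } else 0
      if (amp != 0) e[p$sidx, p$tidx] <- e[p$sidx, p$tidx] + amp
    }
    values[k, , ] <- e
  }
  trial_epochs(values, info, time_ms, layout$ids, cfg$sample_rate,
               cfg$baseline_ms)
}
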