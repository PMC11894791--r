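#' Specify an ERP condition effect for the permutation test
#'
#' Maps a named effect onto the condition labels of an [epoch_set()]. The
#' effect is always reduced to one contrast per subject:
#'
#' * `paired`: difference `a - b` between two within-subject conditions;
#'   tested with a one-sample t (F = t^2), df (1, n-1).
#' * `interaction_within`: difference of differences
#'   `(a1 - a2) - (b1 - b2)` for a 2 x 2 within design; one-sample t.
#' * `interaction_mixed`: within-subject difference `a - b` compared
#'   across two between-subject groups (pooled-variance two-sample t),
#'   df (1, n1 + n2 - 2).
#' * `three_way_mixed`: within-subject double difference compared across
#'   groups (two-sample t).
#'
#' @param name effect label carried through results.
#' @param type one of "paired", "interaction_within", "interaction_mixed",
#'   "three_way_mixed".
#' @param cells for `paired`/`interaction_mixed`: character vector
#'   `c(a, b)`; for `interaction_within`/`three_way_mixed`: list
#'   `list(a = c(a1, a2), b = c(b1, b2))`.
#' @param group_col name of the grouping column in the epoch set's
#'   `subject_info` (between-subject designs only).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(name, type = c("paired", "interaction_within",
                                       "interaction_mixed", "three_way_mixed"),
                        cells, group_col = "group") {
  type <- match.arg(type)
  if (type %in% c("paired", "interaction_mixed")) {
    stopifnot(is.character(cells), length(cells) == 2)
  } else {
    stopifnot(is.list(cells), length(cells) == 2,
              lengths(cells) == c(2, 2))
  }
  structure(list(name = name, type = type, cells = cells,
                 group_col = group_col),
            class = "effect_spec")
}

# n_subjects x (sensors*time) matrix of per-subject effect contrasts,
# plus the between-subject grouping factor where the design has one
subject_contrasts <- function(epochs, effect) {
  cl <- function(cond) {
    if (!cond %in% epochs$conditions) stop("condition not in epochs: ", cond)
    m <- epochs$values[, match(cond, epochs$conditions), , , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3, 4)]
    matrix(m, nrow = dim(m)[1])
  }
  X <- switch(effect$type,
    paired = ,
    interaction_mixed = cl(effect$cells[1]) - cl(effect$cells[2]),
    interaction_within = ,
    three_way_mixed = (cl(effect$cells$a[1]) - cl(effect$cells$a[2])) -
      (cl(effect$cells$b[1]) - cl(effect$cells$b[2]))
  )
  groups <- NULL
  if (effect$type %in% c("interaction_mixed", "three_way_mixed")) {
    si <- epochs$subject_info
    if (is.null(si) || !effect$group_col %in% names(si)) {
      stop("between-subject effect needs a '", effect$group_col,
           "' column in subject_info")
    }
    groups <- factor(si[[effect$group_col]][match(epochs$subjects, si$subject)])
    if (nlevels(groups) != 2) stop("grouping must have exactly 2 levels")
  }
  list(X = X, groups = groups)
}

# cap for infinite F from zero-variance contrasts; capped points flagged
.F_CAP <- 1e12

.f_within <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  f <- n * m^2 / v
  f[v <= 0 & m == 0] <- 0
  capped <- is.infinite(f) | (v <= 0 & m != 0)
  f[capped] <- .F_CAP
  list(f = f, df = c(1, n - 1), capped = any(capped))
}

.f_between <- function(X, groups) {
  g <- levels(groups)
  i1 <- groups == g[1]; i2 <- groups == g[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  ss1 <- colSums(X[i1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[i2, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  f <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  f[sp2 <= 0 & m1 == m2] <- 0
  capped <- is.infinite(f) | (sp2 <= 0 & m1 != m2)
  f[capped] <- .F_CAP
  list(f = f, df = c(1, n1 + n2 - 2), capped = any(capped))
}

#' Pointwise F map for an effect
#'
#' Computes the forming-step F statistic at every sensor-time point of a
#' condition-average [epoch_set()], per the design mapping in
#' [effect_spec()]. Points with zero contrast variance but a nonzero mean
#' (infinite F) are capped at a large sentinel and flagged via attribute
#' `"capped"`.
#'
#' @param epochs a condition-average `epoch_set`.
#' @param effect an [effect_spec()].
#' @return an object of class `fmap`: F matrix (sensor x time), numerator /
#'   denominator df, pointwise p-values, sensor ids and time axis.
#' @export
pointwise_f <- function(epochs, effect) {
  sc <- subject_contrasts(epochs, effect)
  n <- nrow(sc$X)
  if (is.null(sc$groups)) {
    if (n < 2) stop("need at least 2 subjects")
    st <- .f_within(sc$X)
  } else {
    if (min(table(sc$groups)) < 2) stop("need at least 2 subjects per group")
    st <- .f_between(sc$X, sc$groups)
  }
  fm <- matrix(st$f, length(epochs$sensors), length(epochs$time_ms))
  rownames(fm) <- epochs$sensors
  structure(
    list(f = fm, df = st$df,
         p = matrix(stats::pf(st$f, st$df[1], st$df[2], lower.tail = FALSE),
                    nrow(fm), ncol(fm)),
         sensors = epochs$sensors, time_ms = epochs$time_ms,
         sample_rate = epochs$sample_rate, effect = effect$name,
         capped = st$capped),
    class = "fmap"
  )
}

#' @export
print.fmap <- function(x, ...) {
  cat(sprintf("<fmap> effect '%s': %d sensors x %d samples, df (%g, %g), max F = %.2f\n",
              x$effect, nrow(x$f), ncol(x$f), x$df[1], x$df[2], max(x$f)))
  invisible(x)
}

.neighbors_of <- function(adjacency, sensors) {
  if (inherits(adjacency, "sensor_layout")) {
    if (!identical(adjacency$ids, sensors)) {
      if (!all(sensors %in% adjacency$ids)) {
        stop("adjacency does not cover the F-map sensors")
      }
      adjacency <- layout_roi(adjacency, sensors)
    }
    adjacency$neighbors
  } else {
    stopifnot(is.list(adjacency), length(adjacency) == length(sensors))
    adjacency
  }
}

#' Form spatiotemporal clusters from an F map
#'
#' Two-part forming criterion: (1) per sensor, keep only supra-threshold
#' runs (`p < forming_alpha`) of at least `min_run` consecutive samples;
#' (2) link surviving sensor-time points that share a sensor at adjacent
#' samples or share a sample at neighboring sensors, and take connected
#' components. Each component's mass is the sum of its F values. Clusters
#' are sorted by descending mass (ties: earliest onset, lowest sensor).
#'
#' @param fmap a [pointwise_f()] result.
#' @param adjacency a [sensor_layout()] covering the F-map sensors, or a
#'   list of integer neighbor vectors aligned with them.
#' @param forming_alpha pointwise forming threshold (default 0.05).
#' @param min_run minimum run length in samples (default 5, i.e. 20 ms at
#'   250 Hz).
#' @return tibble with one row per cluster: `cluster`, `mass`, `n_points`,
#'   `sensors` (list column of ids), `t_start`/`t_end` (ms, half-open
#'   spanning window), `duration_ms`. The sensor x time label matrix is
#'   attached as attribute `"labels"`.
#' @export
form_clusters <- function(fmap, adjacency, forming_alpha = 0.05, min_run = 5) {
  if (min_run < 1) stop("min_run must be >= 1")
  if (forming_alpha <= 0 || forming_alpha >= 1) stop("forming_alpha must be in (0, 1)")
  nb <- .neighbors_of(adjacency, fmap$sensors)
  thresh <- stats::qf(1 - forming_alpha, fmap$df[1], fmap$df[2])
  res <- form_clusters_cpp(fmap$f, thresh, as.integer(min_run), nb)
  .clusters_tibble(res, fmap)
}

.clusters_tibble <- function(res, fmap) {
  labels <- res$labels
  dt <- 1000 / fmap$sample_rate
  k <- length(res$mass)
  rows <- lapply(seq_len(k), function(i) {
    pts <- which(labels == i, arr.ind = TRUE)
    tibble::tibble(
      cluster = i,
      mass = res$mass[i],
      n_points = res$n_points[i],
      sensors = list(fmap$sensors[sort(unique(pts[, 1]))]),
      t_start = fmap$time_ms[min(pts[, 2])],
      t_end = fmap$time_ms[max(pts[, 2])] + dt
    )
  })
  out <- if (k) dplyr::bind_rows(rows) else tibble::tibble(
    cluster = integer(), mass = numeric(), n_points = integer(),
    sensors = list(), t_start = numeric(), t_end = numeric()
  )
  out$duration_ms <- out$t_end - out$t_start
  attr(out, "labels") <- labels
  out
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Monte-Carlo resampling under the null: purely within-subject effects are
#' re-signed independently per subject (sign flips of the per-subject
#' contrast, exact exchangeability for 2-level factors); between-subject
#' effects are re-assigned by permuting group labels across subjects while
#' keeping group sizes. For each permutation the F map is recomputed,
#' clusters are formed with the same forming criterion, and the maximum
#' cluster mass (0 if none) is recorded. The critical mass is the 95th
#' percentile of that sample.
#'
#' @inheritParams form_clusters
#' @param epochs a condition-average [epoch_set()].
#' @param effect an [effect_spec()].
#' @param n_perm number of permutations (default 1000, minimum 100 unless
#'   `exhaustive`).
#' @param seed integer seed.
#' @param exhaustive if TRUE (within-subject effects only), enumerate all
#'   2^n sign patterns instead of sampling; `n_perm` is ignored.
#' @return list with `null_max` (numeric vector), `critical` (95th
#'   percentile), `n_perm`, `seed`, `scheme`.
#' @export
perm_null <- function(epochs, effect, adjacency, n_perm = 1000, seed = 1,
                      forming_alpha = 0.05, min_run = 5, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100) stop("n_perm must be >= 100")
  sc <- subject_contrasts(epochs, effect)
  n <- nrow(sc$X)
  nb <- .neighbors_of(adjacency, epochs$sensors)
  nsen <- length(epochs$sensors); nt <- length(epochs$time_ms)
  set.seed(.child_rng(seed, "perm"))

  if (is.null(sc$groups)) {
    df <- c(1, n - 1)
    thresh <- stats::qf(1 - forming_alpha, df[1], df[2])
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
    }
    n_perm <- nrow(signs)
    ss <- colSums(sc$X^2) # invariant under sign flips
    null_max <- numeric(n_perm)
    chunk <- 64L
    for (start in seq(1, n_perm, by = chunk)) {
      idx <- start:min(start + chunk - 1, n_perm)
      Mn <- signs[idx, , drop = FALSE] %*% sc$X / n
      M2 <- Mn^2
      Fp <- n * M2 / ((rep(ss, each = length(idx)) - n * M2) / (n - 1))
      Fp[is.nan(Fp)] <- 0          # zero mean over zero variance
      Fp[is.infinite(Fp)] <- .F_CAP
      for (r in seq_along(idx)) {
        fm <- matrix(Fp[r, ], nsen, nt)
        null_max[idx[r]] <- max_cluster_mass_cpp(fm, thresh, as.integer(min_run), nb)
      }
    }
    scheme <- "within-subject sign flips of the effect contrast"
  } else {
    df <- c(1, n - 2)
    thresh <- stats::qf(1 - forming_alpha, df[1], df[2])
    null_max <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      g <- sample(sc$groups)
      st <- .f_between(sc$X, g)
      fm <- matrix(st$f, nsen, nt)
      null_max[r] <- max_cluster_mass_cpp(fm, thresh, as.integer(min_run), nb)
    }
    scheme <- "between-subject group-label permutation (sizes preserved)"
  }
  list(null_max = null_max,
       critical = unname(stats::quantile(null_max, 0.95)),
       n_perm = n_perm, seed = seed, scheme = scheme)
}

#' Two-step cluster-based permutation test
#'
#' Runs the full procedure: pointwise F map, cluster forming (pointwise
#' `p < forming_alpha` sustained for at least `min_run` samples, linked
#' over the sensor adjacency), and the Monte-Carlo max-mass null. An
#' empirical cluster is significant when its mass exceeds the critical
#' mass (the null's 95th percentile); each cluster also gets the
#' permutation p-value `(1 + #\{null >= mass\}) / (1 + n_perm)`.
#'
#' @inheritParams perm_null
#' @return an object of class `perm_result`: `clusters` tibble (with
#'   `p_value` and `significant` columns), `critical`, `null_max`, the F
#'   map, and the run metadata (effect, scheme, n_perm, seed,
#'   forming_alpha, min_run).
#' @export
#' @examples
#' lay <- sensor_layout(16)
#' cfg <- erp_config(n_sensors = 16, window = c(0, 200),
#'                   noise = list(sd = 0.5, subject_sd = 0),
#'                   effects = list(effect_patch(
#'                     window = c(80, 160), amplitude = c(a = 3),
#'                     center = "E001", radius = 2)))
#' ep <- gen_epochs(cfg, layout = lay, seed = 2, conditions = c("a", "b"),
#'                  subjects = sprintf("P%02d", 1:10))
#' res <- cluster_test(ep, effect_spec("ab", "paired", c("a", "b")),
#'                     lay, n_perm = 200, seed = 3)
#' res$clusters[1, c("mass", "p_value", "significant")]
cluster_test <- function(epochs, effect, adjacency, n_perm = 1000, seed = 1,
                         forming_alpha = 0.05, min_run = 5) {
  fmap <- pointwise_f(epochs, effect)
  clusters <- form_clusters(fmap, adjacency, forming_alpha, min_run)
  null <- perm_null(epochs, effect, adjacency, n_perm = n_perm, seed = seed,
                    forming_alpha = forming_alpha, min_run = min_run)
  clusters$p_value <- vapply(
    clusters$mass,
    function(m) (1 + sum(null$null_max >= m)) / (1 + null$n_perm),
    numeric(1)
  )
  clusters$significant <- clusters$mass > null$critical
  structure(
    list(clusters = clusters, critical = null$critical,
         null_max = null$null_max, fmap = fmap,
         effect = effect, scheme = null$scheme, n_perm = null$n_perm,
         seed = seed, forming_alpha = forming_alpha, min_run = min_run),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> effect '%s': %d cluster(s), %d significant (critical mass %.2f, %d permutations)\n",
    x$effect$name, nrow(x$clusters), sum(x$clusters$significant),
    x$critical, x$n_perm
  ))
  if (nrow(x$clusters)) {
    print(dplyr::select(x$clusters, -dplyr::any_of("sensors")), ...)
  }
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x a `perm_result`.
#' @param ... unused.
#' @return `tidy`: the cluster tibble (one row per cluster); `glance`: a
#'   one-row tibble with critical mass, cluster counts and run metadata.
#' @method tidy perm_result
#' @export
tidy.perm_result <- function(x, ...) x$clusters

#' @rdname tidy.perm_result
#' @method glance perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(
    effect = x$effect$name, n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    critical_mass = x$critical, n_perm = x$n_perm, seed = x$seed,
    forming_alpha = x$forming_alpha, min_run = x$min_run,
    scheme = x$scheme
  )
}

#' Per-subject mean amplitude over a cluster
#'
#' Averages epoch amplitudes over a cluster's sensor set and time window,
#' per subject and condition, for follow-up tests.
#'
#' @param epochs an [epoch_set()].
#' @param cluster a one-row cluster tibble (from a `perm_result`) or a list
#'   with elements `sensors` (ids) and `t_start`/`t_end` (ms).
#' @param conditions conditions to include (default: all in `epochs`).
#' @return tibble: subject, condition, amplitude (uV).
#' @export
cluster_mean_amplitude <- function(epochs, cluster, conditions = NULL) {
  sens <- if (is.list(cluster$sensors)) cluster$sensors[[1]] else cluster$sensors
  win <- c(cluster$t_start, cluster$t_end)
  if (!length(intersect(sens, epochs$sensors))) stop("cluster sensors not in epochs")
  sub <- subset_epochs(epochs, sensors = intersect(sens, epochs$sensors),
                       window = win, conditions = conditions)
  amp <- apply(sub$values, 1:2, mean)
  tibble::tibble(
    subject = rep(sub$subjects, times = length(sub$conditions)),
    condition = rep(sub$conditions, each = length(sub$subjects)),
    amplitude = as.vector(amp)
  )
}

#' Export a permutation-test result as JSON
#'
#' Writes clusters (sensor lists, half-open windows in ms, masses,
#' p-values), the critical mass and the full run metadata, so downstream
#' follow-up statistics are traceable to a seed and scheme.
#'
#' @param result a `perm_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_perm_result <- function(result, path) {
  obj <- list(
    effect = result$effect$name,
    clusters = purrr::pmap(result$clusters, function(cluster, mass, n_points,
                                                     sensors, t_start, t_end,
                                                     duration_ms, p_value,
                                                     significant, ...) {
      list(cluster = cluster, mass = mass, n_points = n_points,
           sensors = sensors, window_ms = c(t_start, t_end),
           p_value = p_value, significant = significant)
    }),
    critical_mass = result$critical, n_perm = result$n_perm,
    seed = result$seed, forming_alpha = result$forming_alpha,
    min_run = result$min_run, permutation_scheme = result$scheme
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
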