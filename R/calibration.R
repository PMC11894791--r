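#' Family-wise error calibration of the cluster permutation test
#'
#' Generates replicate null datasets (2 x 2 within-subject design, no
#' condition effects, spatially smoothed AR(1) Gaussian noise over a graph
#' layout), runs the full two-step interaction cluster test on each, and
#' returns the fraction of datasets with at least one significant cluster.
#' Under the exchangeable null this fraction should not exceed the nominal
#' 0.05 beyond Monte-Carlo error.
#'
#' @param n_datasets number of replicate null datasets.
#' @param n_subjects subjects per dataset (default 16).
#' @param n_sensors sensors in the synthetic layout (default 32).
#' @param n_samples epoch samples at 250 Hz (default 64).
#' @param n_perm permutations per test (default 500).
#' @param seed root seed; dataset r uses seed + r.
#' @param forming_alpha,min_run forming criterion (defaults 0.05, 5).
#' @return a list: `rate` (proportion with >= 1 significant cluster),
#'   `hits` (logical per dataset), and the simulation settings.
#' @export
fwer_simulation <- function(n_datasets = 200, n_subjects = 16, n_sensors = 32,
                            n_samples = 64, n_perm = 500, seed = 1,
                            forming_alpha = 0.05, min_run = 5) {
  lay <- sensor_layout(n_sensors)
  cells <- c("a1", "a2", "b1", "b2")
  eff <- effect_spec("null interaction", "interaction_within",
                     list(a = c("a1", "a2"), b = c("b1", "b2")))
  cfg <- erp_config(
    n_sensors = n_sensors, window = c(0, n_samples * 4), baseline_ms = c(0, 0),
    noise = list(sd = 1, spatial_smooth = 2L, ar = 0.5, subject_sd = 0.5)
  )
  hits <- logical(n_datasets)
  for (r in seq_len(n_datasets)) {
    ep <- gen_epochs(cfg, layout = lay, seed = seed + r, conditions = cells,
                     subjects = sprintf("S%03d", seq_len(n_subjects)))
    res <- cluster_test(ep, eff, lay, n_perm = n_perm, seed = seed + r,
                        forming_alpha = forming_alpha, min_run = min_run)
    hits[r] <- any(res$clusters$significant)
  }
  list(rate = mean(hits), hits = hits, n_datasets = n_datasets,
       n_subjects = n_subjects, n_sensors = n_sensors,
       n_samples = n_samples, n_perm = n_perm, seed = seed)
}

#' Cluster-recovery calibration with known ground truth
#'
#' Injects a 2 x 2 interaction patch at a configurable per-subject
#' contrast-to-noise ratio, runs the interaction cluster test, and scores
#' the spatiotemporal Jaccard overlap between the most massive significant
#' cluster and the injected patch, per replicate.
#'
#' @param n_replicates replicate datasets.
#' @param n_subjects subjects (default 26).
#' @param cnr per-subject contrast-to-noise ratio of the injected
#'   interaction (default 1): the patch amplitude is `cnr * 2 * sd` since
#'   the double-difference contrast of unit-variance cells has SD 2.
#' @inheritParams fwer_simulation
#' @return list: `success_rate` (fraction of replicates with a significant
#'   cluster at Jaccard >= 0.5), `jaccard` per replicate, settings.
#' @export
recovery_simulation <- function(n_replicates = 20, n_subjects = 26,
                                n_sensors = 32, n_samples = 64, cnr = 1,
                                n_perm = 200, seed = 1) {
  lay <- sensor_layout(n_sensors)
  cells <- c("a1", "a2", "b1", "b2")
  eff <- effect_spec("interaction", "interaction_within",
                     list(a = c("a1", "a2"), b = c("b1", "b2")))
  center <- lay$ids[1]
  patch_window <- c(80, 160)
  cfg <- erp_config(
    n_sensors = n_sensors, window = c(0, n_samples * 4), baseline_ms = c(0, 0),
    noise = list(sd = 1, spatial_smooth = 2L, ar = 0.5, subject_sd = 0.5),
    effects = list(effect_patch(window = patch_window,
                                amplitude = c(a1 = cnr * 2),
                                center = center, radius = 2))
  )
  jac <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    ep <- gen_epochs(cfg, layout = lay, seed = seed + r, conditions = cells,
                     subjects = sprintf("S%03d", seq_len(n_subjects)))
    res <- cluster_test(ep, eff, lay, n_perm = n_perm, seed = seed + r)
    sig <- res$clusters[res$clusters$significant, , drop = FALSE]
    if (nrow(sig) == 0) { jac[r] <- 0; next }
    labels <- attr(res$clusters, "labels")
    truth <- attr(ep, "truth")[[1]]
    mask <- matrix(FALSE, length(lay$ids), length(ep$time_ms))
    mask[truth$sidx, truth$tidx] <- TRUE
    got <- labels == sig$cluster[1]
    jac[r] <- sum(got & mask) / sum(got | mask)
  }
  list(success_rate = mean(jac >= 0.5), jaccard = jac,
       n_replicates = n_replicates, n_subjects = n_subjects, cnr = cnr,
       n_perm = n_perm, seed = seed)
}
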