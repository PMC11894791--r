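test_that("zero effects and zero noise give all-zero epochs", {
  lay <- sensor_layout(8)
  cfg <- erp_config(n_sensors = 8, window = c(0, 100), baseline_ms = c(0, 0),
                    noise = list(sd = 0, subject_sd = 0))
  ep <- gen_epochs(cfg, layout = lay, seed = 1, conditions = c("a", "b"),
                   subjects = c("S1", "S2"))
  expect_equal(max(abs(ep$values)), 0)
})

test_that("a noise-free patch appears exactly where injected", {
  lay <- make_line_layout(6)
  cfg <- erp_config(n_sensors = 6, window = c(0, 100), baseline_ms = c(0, 0),
                    noise = list(sd = 0, subject_sd = 0),
                    effects = list(effect_patch(
                      window = c(20, 60), amplitude = c(a = 2.5),
                      sensors = c("E002", "E003"))))
  ep <- gen_epochs(cfg, layout = lay, seed = 1, conditions = c("a", "b"),
                   subjects = c("S1", "S2"))
  dif <- ep$values[1, 1, , ] - ep$values[1, 2, , ]
  inside <- dif[2:3, 6:15]
  expect_equal(unname(inside), matrix(2.5, 2, 10))
  dif[2:3, 6:15] <- 0
  expect_equal(max(abs(dif)), 0)
  # truth metadata resolves sensors and window
  truth <- attr(ep, "truth")[[1]]
  expect_equal(truth$sensors, c("E002", "E003"))
  expect_equal(truth$window, c(20, 60))
})

test_that("marginal noise SD matches the configured value", {
  lay <- sensor_layout(8)
  cfg <- erp_config(n_sensors = 8, window = c(0, 100), baseline_ms = c(0, 0),
                    noise = list(sd = 1.7, spatial_smooth = 2, ar = 0.5,
                                 subject_sd = 0))
  info <- tibble::tibble(subject = "S1", condition = "a")[rep(1, 4000), ]
  tr <- gen_trial_epochs(cfg, lay, info, seed = 6)
  emp_sd <- apply(tr$values, 2:3, sd)
  # law of large numbers: every per-sample SD within 5% of the target
  expect_lt(max(abs(emp_sd - 1.7) / 1.7), 0.05)
})

test_that("spatial smoothing and AR(1) leave the advertised correlations", {
  lay <- sensor_layout(16)
  cfg <- erp_config(n_sensors = 16, window = c(0, 400), baseline_ms = c(0, 0),
                    noise = list(sd = 1, spatial_smooth = 2, ar = 0.6,
                                 subject_sd = 0))
  info <- tibble::tibble(subject = "S1", condition = "a")[rep(1, 400), ]
  tr <- gen_trial_epochs(cfg, lay, info, seed = 7)
  # lag-1 temporal autocorrelation near the configured coefficient
  x <- tr$values[, 1, ]
  r1 <- cor(as.vector(x[, -1]), as.vector(x[, -ncol(x)]))
  expect_lt(abs(r1 - 0.6), 0.05)
  # neighboring sensors correlate more than distant ones
  nb <- lay$neighbors[[1]][1]
  far <- which.max(as.matrix(dist(lay$positions))[1, ])
  s1 <- as.vector(tr$values[, 1, ]); s2 <- as.vector(tr$values[, nb, ])
  s3 <- as.vector(tr$values[, far, ])
  expect_gt(cor(s1, s2), cor(s1, s3) + 0.2)
})

test_that("patch validation and determinism hold", {
  lay <- sensor_layout(8)
  bad <- erp_config(n_sensors = 8, window = c(0, 100), baseline_ms = c(0, 0),
                    effects = list(effect_patch(window = c(150, 200),
                                                amplitude = c(a = 1),
                                                sensors = "E001")))
  expect_error(gen_epochs(bad, layout = lay, seed = 1, conditions = "a",
                          subjects = c("S1", "S2")), "outside the epoch")
  bad2 <- erp_config(n_sensors = 8, window = c(0, 100), baseline_ms = c(0, 0),
                     effects = list(effect_patch(window = c(0, 50),
                                                 amplitude = c(a = 1),
                                                 sensors = "E999")))
  expect_error(gen_epochs(bad2, layout = lay, seed = 1, conditions = "a",
                          subjects = c("S1", "S2")), "outside the layout")
  cfg <- erp_config(n_sensors = 8, window = c(0, 100), baseline_ms = c(0, 0))
  e1 <- gen_epochs(cfg, layout = lay, seed = 3, conditions = c("a", "b"),
                   subjects = c("S1", "S2"))
  e2 <- gen_epochs(cfg, layout = lay, seed = 3, conditions = c("a", "b"),
                   subjects = c("S1", "S2"))
  expect_identical(e1$values, e2$values)
})

test_that("group-restricted patches only reach that group's subjects", {
  lay <- make_line_layout(4)
  cfg <- erp_config(n_sensors = 4, window = c(0, 100), baseline_ms = c(0, 0),
                    noise = list(sd = 0, subject_sd = 0),
                    effects = list(effect_patch(
                      window = c(0, 100), amplitude = c(a = 1),
                      sensors = "E001", group = "g1")))
  # without group metadata no subject matches the restriction
  ep <- gen_epochs(cfg, layout = lay, seed = 1, conditions = "a",
                   subjects = c("S1", "S2"))
  expect_equal(max(abs(ep$values)), 0)
  # with a mixed design, only the matching group's subjects carry the patch
  cfg2 <- erp_config(n_sensors = 4, window = c(0, 100), baseline_ms = c(0, 0),
                     noise = list(sd = 0, subject_sd = 0),
                     effects = list(effect_patch(
                       window = c(0, 100), amplitude = c(neutral.on = 1),
                       sensors = "E001", group = "taVNS")))
  d <- build_design(2, n_subjects = 4, seed = 1)
  ep2 <- gen_epochs(cfg2, d, lay, seed = 1)
  grp <- d$encoding$group[match(ep2$subjects, d$encoding$subject)]
  ci <- match("neutral.on", ep2$conditions)
  for (si in seq_along(ep2$subjects)) {
    expected <- if (grp[si] == "taVNS") 1 else 0
    expect_equal(unique(as.vector(ep2$values[si, ci, 1, ])), expected)
  }
})
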