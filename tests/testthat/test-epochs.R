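test_that("baseline correction zeroes the baseline mean and is idempotent", {
  set.seed(1)
  v <- array(7, c(2, 2, 3, 100))
  ep <- epoch_set(v, seq(-200, 196, by = 4), sprintf("E%03d", 1:3),
                  c("a", "b"), c("S1", "S2"), 250)
  bc <- baseline_correct(ep, c(-200, 0))
  expect_equal(max(abs(bc$values)), 0)

  # baseline mean 2 plus a post-stimulus bump: bump preserved, shifted by -2
  v2 <- array(2, c(1, 1, 1, 100))
  v2[1, 1, 1, 60:70] <- 2 + 5
  ep2 <- epoch_set(v2, seq(-200, 196, by = 4), "E001", "a", "S1", 250)
  bc2 <- baseline_correct(ep2, c(-200, 0))
  expect_equal(bc2$values[1, 1, 1, 60:70], rep(5, 11))
  expect_equal(bc2$values[1, 1, 1, 1:50], rep(0, 50))

  v3 <- array(rnorm(2 * 2 * 4 * 100), c(2, 2, 4, 100))
  ep3 <- epoch_set(v3, seq(-200, 196, by = 4), sprintf("E%03d", 1:4),
                   c("a", "b"), c("S1", "S2"), 250)
  bc3 <- baseline_correct(ep3, c(-200, 0))
  bl_means <- apply(bc3$values[, , , 1:50, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(bl_means)), 1e-9)
  expect_equal(baseline_correct(bc3, c(-200, 0))$values, bc3$values,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep3, c(-400, 0)), "outside")
})

test_that("condition averaging equals the direct mean and flags empty cells", {
  set.seed(2)
  info <- tibble::tibble(subject = rep(c("S1", "S2"), each = 6),
                         condition = rep(c("a", "b", "a", "b"), each = 3))
  v <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
  tr <- trial_epochs(v, info, seq(0, 36, by = 4), c("E001", "E002"), 250,
                     baseline_ms = c(0, 0))
  av <- average_by_condition(tr)
  sel <- which(info$subject == "S1" & info$condition == "b")
  expect_equal(av$values[1, match("b", av$conditions), , ],
               apply(v[sel, , ], 2:3, mean), ignore_attr = TRUE)
  expect_equal(attr(av, "trial_counts")["S2", "a"], 3L, ignore_attr = TRUE)

  # two trials v and -v average to zero
  v2 <- array(0, c(2, 1, 4)); v2[1, , ] <- 1:4; v2[2, , ] <- -(1:4)
  tr2 <- trial_epochs(v2,
                      tibble::tibble(subject = c("S1", "S1"),
                                     condition = c("a", "a")),
                      seq(0, 12, by = 4), "E001", 250, baseline_ms = c(0, 0))
  expect_equal(max(abs(average_by_condition(tr2)$values)), 0)

  bad <- trial_epochs(v[1:6, , , drop = FALSE], info[c(1:3, 10:12), ],
                      seq(0, 36, by = 4), c("E001", "E002"), 250,
                      baseline_ms = c(0, 0))
  expect_error(average_by_condition(bad), "S1.*'b'")
})

test_that("averaging and baseline correction commute (linearity)", {
  set.seed(3)
  info <- tibble::tibble(subject = rep("S1", 4), condition = rep(c("a", "b"), 2))
  v <- array(rnorm(4 * 2 * 50), c(4, 2, 50))
  tmpl <- trial_epochs(v, info, seq(-100, 96, by = 4), c("E001", "E002"), 250,
                       baseline_ms = c(-100, 0))
  path1 <- baseline_correct(average_by_condition(tmpl), c(-100, 0))
  # correct each trial first, then average
  v_bc <- v
  bl_idx <- which(tmpl$time_ms >= -100 & tmpl$time_ms < 0)
  for (k in 1:4) v_bc[k, , ] <- v[k, , ] - rowMeans(v[k, , bl_idx])
  path2 <- average_by_condition(
    trial_epochs(v_bc, info, tmpl$time_ms, tmpl$sensors, 250, c(-100, 0))
  )
  expect_equal(path1$values, path2$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("subsetting changes index sets but never values", {
  set.seed(4)
  v <- array(rnorm(2 * 2 * 6 * 40), c(2, 2, 6, 40))
  ep <- epoch_set(v, seq(0, 156, by = 4), sprintf("E%03d", 1:6), c("a", "b"),
                  c("S1", "S2"), 250, baseline_ms = c(0, 0))
  sub <- subset_epochs(ep, sensors = c("E002", "E005"), window = c(40, 80))
  expect_equal(sub$values[1, 1, 1, ], ep$values[1, 1, 2, 11:20],
               ignore_attr = TRUE)
  expect_equal(sub$values[2, 2, 2, ], ep$values[2, 2, 5, 11:20],
               ignore_attr = TRUE)
  expect_error(subset_epochs(ep, sensors = "E099"))
})
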