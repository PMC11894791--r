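make_paired_noise <- function(n_subj, ns, nt, seed, effect = 0,
                              patch = NULL) {
  set.seed(seed)
  v <- array(rnorm(n_subj * 2 * ns * nt), c(n_subj, 2, ns, nt))
  if (!is.null(patch)) {
    v[, 1, patch$sensors, patch$samples] <-
      v[, 1, patch$sensors, patch$samples] + effect
  }
  make_epochs(v, c("a", "b"), sprintf("S%02d", seq_len(n_subj)))
}

test_that("all-zero contrasts give an all-zero null and critical mass 0", {
  v <- array(0, c(4, 2, 3, 20))
  v[, , 2, ] <- 5 # same in both conditions: contrast still zero
  ep <- make_epochs(v, c("a", "b"), sprintf("S%d", 1:4))
  nb <- list(2L, c(1L, 3L), 2L)
  null <- perm_null(ep, effect_spec("ab", "paired", c("a", "b")), nb,
                    n_perm = 100, seed = 1)
  expect_equal(null$null_max, rep(0, 100))
  expect_equal(null$critical, 0)
})

test_that("the permutation null is reproducible given the seed", {
  ep <- make_paired_noise(6, 4, 16, seed = 2)
  nb <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  es <- effect_spec("ab", "paired", c("a", "b"))
  # permissive forming so null masses are mostly nonzero
  n1 <- perm_null(ep, es, nb, n_perm = 120, seed = 5,
                  forming_alpha = 0.3, min_run = 2)
  n2 <- perm_null(ep, es, nb, n_perm = 120, seed = 5,
                  forming_alpha = 0.3, min_run = 2)
  expect_identical(n1$null_max, n2$null_max)
  n3 <- perm_null(ep, es, nb, n_perm = 120, seed = 6,
                  forming_alpha = 0.3, min_run = 2)
  expect_false(identical(n1$null_max, n3$null_max))
})

test_that("exhaustive sign-flip null equals independent enumeration (n=4)", {
  ep <- make_paired_noise(4, 1, 8, seed = 3)
  nb <- list(integer(0))
  es <- effect_spec("ab", "paired", c("a", "b"))
  got <- perm_null(ep, es, nb, seed = 1, exhaustive = TRUE,
                   forming_alpha = 0.2, min_run = 2)
  expect_equal(got$n_perm, 16)
  X <- ep$values[, 1, , ] - ep$values[, 2, , ]
  X <- matrix(X, nrow = 4)
  thr <- qf(0.8, 1, 3)
  want <- oracle_exhaustive_null(X, 1, 8, thr, 2, nb)
  expect_equal(sort(got$null_max), sort(want), tolerance = 1e-9)
})

test_that("an injected patch is detected and localized", {
  patch <- list(sensors = 1:2, samples = 11:25)
  ep <- make_paired_noise(12, 4, 40, seed = 4, effect = 2.5, patch = patch)
  nb <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  res <- cluster_test(ep, effect_spec("ab", "paired", c("a", "b")), nb,
                      n_perm = 300, seed = 7)
  expect_gte(sum(res$clusters$significant), 1)
  top <- res$clusters[1, ]
  labels <- attr(res$clusters, "labels")
  got_pts <- which(labels == top$cluster)
  truth_mask <- matrix(FALSE, 4, 40)
  truth_mask[patch$sensors, patch$samples] <- TRUE
  truth_pts <- which(truth_mask)
  jac <- length(intersect(got_pts, truth_pts)) /
    length(union(got_pts, truth_pts))
  expect_gte(jac, 0.5)
  # permutation p-values bounded away from 0 by the +1 correction
  expect_gte(min(res$clusters$p_value), 1 / (1 + res$n_perm))
  expect_true(all(res$clusters$p_value <= 1))
})

test_that("cluster masses are invariant to adding a constant everywhere", {
  ep <- make_paired_noise(8, 3, 24, seed = 5, effect = 1.5,
                          patch = list(sensors = 1:2, samples = 5:14))
  nb <- list(2L, c(1L, 3L), 2L)
  es <- effect_spec("ab", "paired", c("a", "b"))
  r1 <- cluster_test(ep, es, nb, n_perm = 150, seed = 2)
  ep2 <- ep
  ep2$values <- ep$values + 42
  r2 <- cluster_test(ep2, es, nb, n_perm = 150, seed = 2)
  expect_equal(r1$clusters$mass, r2$clusters$mass, tolerance = 1e-9)
  expect_equal(r1$null_max, r2$null_max, tolerance = 1e-9)
})

test_that("between-group permutation detects a group-dependent contrast", {
  set.seed(6)
  n <- 16; ns <- 4; nt <- 24
  v <- array(rnorm(n * 2 * ns * nt), c(n, 2, ns, nt))
  grp <- rep(c("g1", "g2"), each = n / 2)
  v[grp == "g1", 1, 1:2, 5:16] <- v[grp == "g1", 1, 1:2, 5:16] + 2.5
  ep <- make_epochs(v, c("a", "b"), sprintf("S%02d", 1:n))
  ep$subject_info <- tibble::tibble(subject = ep$subjects, group = grp)
  nb <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  res <- cluster_test(ep, effect_spec("mix", "interaction_mixed", c("a", "b")),
                      nb, n_perm = 300, seed = 8)
  expect_gte(sum(res$clusters$significant), 1)
  expect_match(res$scheme, "group-label")
})

test_that("identical seeds give byte-identical full test results", {
  ep <- make_paired_noise(6, 3, 20, seed = 9)
  nb <- list(2L, c(1L, 3L), 2L)
  es <- effect_spec("ab", "paired", c("a", "b"))
  r1 <- cluster_test(ep, es, nb, n_perm = 120, seed = 3)
  r2 <- cluster_test(ep, es, nb, n_perm = 120, seed = 3)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max, r2$null_max)
})

test_that("cluster-averaged amplitudes equal an independently masked mean", {
  set.seed(10)
  v <- array(rnorm(3 * 2 * 4 * 30), c(3, 2, 4, 30))
  ep <- make_epochs(v, c("a", "b"), c("S1", "S2", "S3"))
  cl <- list(sensors = c("E002", "E004"), t_start = ep$time_ms[6],
             t_end = ep$time_ms[15] + 4)
  amp <- cluster_mean_amplitude(ep, cl)
  want <- mean(v[2, 1, c(2, 4), 6:15])
  got <- amp$amplitude[amp$subject == "S2" & amp$condition == "a"]
  expect_equal(got, want, tolerance = 1e-12)
  # constant epochs give the constant back
  epc <- make_epochs(array(3.3, c(2, 2, 4, 30)), c("a", "b"), c("S1", "S2"))
  ampc <- cluster_mean_amplitude(epc, cl)
  expect_equal(unique(ampc$amplitude), 3.3)
})
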