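mk_table <- function(df) {
  df$dialect <- "six_point"
  tibble::as_tibble(df)
}

test_that("rates handle the all-hits / no-FA corner and the count identity", {
  tab <- mk_table(data.frame(
    subject = "S1",
    truth = rep(c("old", "new"), each = 10),
    response = rep(c("old", "new"), each = 10),
    confidence = rep(c(6L, 1L), each = 10)
  ))
  ov <- memory_rates(tab, memory_class = "overall")
  rc <- memory_rates(tab, memory_class = "recollection")
  fa <- memory_rates(tab, memory_class = "familiarity")
  expect_equal(c(ov$hit_rate, ov$fa_rate), c(1, 0))
  expect_equal(c(rc$hit_rate, rc$fa_rate), c(1, 0))
  expect_equal(c(fa$hit_rate, fa$fa_rate), c(0, 0))
})

test_that("recollection + familiarity counts equal overall counts exactly", {
  d <- build_design(2, n_subjects = 8, seed = 11)
  b <- gen_recognition(d, behavior_config("six_point", R = 0.3), seed = 11)
  strata <- c("subject", "category")
  ov <- memory_rates(b, strata, "overall")
  rc <- memory_rates(b, strata, "recollection")
  fm <- memory_rates(b, strata, "familiarity")
  expect_equal(rc$hits + fm$hits, ov$hits)
  expect_equal(rc$fas + fm$fas, ov$fas)
  idx <- memory_indices(b, strata)
  wide <- tidyr::pivot_wider(idx[, c(strata, "memory_class", "pr")],
                             names_from = memory_class, values_from = pr)
  expect_equal(wide$recollection + wide$familiarity, wide$overall,
               tolerance = 1e-12)
})

test_that("generator-implied rates match their closed forms", {
  # recollection mass R at the top anchor plus Gaussian familiarity bins
  R <- 0.4; dfam <- 1.2
  d <- build_design(2, n_subjects = 42, seed = 12)
  b <- gen_recognition(d, behavior_config("six_point", R = R, d_fam = dfam),
                       seed = 12)
  crit <- behavior_config("six_point")$criteria
  ov <- memory_rates(b, strata = character(0), memory_class = "overall")
  rc <- memory_rates(b, strata = character(0), memory_class = "recollection")
  n_old <- ov$n_old
  p_hit <- R + (1 - R) * pnorm(dfam - crit[3])
  p_rec <- R + (1 - R) * pnorm(dfam - crit[5])
  expect_lt(abs(ov$hit_rate - p_hit), 3 * sqrt(p_hit * (1 - p_hit) / n_old))
  expect_lt(abs(rc$hit_rate - p_rec), 3 * sqrt(p_rec * (1 - p_rec) / n_old))
})

test_that("Pr and d-prime match their defining formulas", {
  expect_equal(pr_index(0.9, 0.32), 0.58)
  expect_equal(pr_index(0.4, 0.4), 0)
  expect_equal(pr_index(1, 0), 1)
  expect_equal(d_prime(0.5, 0.5, 50, 50), 0)
  expect_equal(d_prime(0.841345, 0.158655, 1000, 1000), 2, tolerance = 1e-4)
  # extreme-rate correction: 1/(2N) at both ends
  expect_equal(d_prime(1, 0, 30, 30), 2 * qnorm(59 / 60), tolerance = 1e-10)
  # antisymmetry and monotonicity
  expect_equal(d_prime(0.8, 0.3, 40, 40), -d_prime(0.3, 0.8, 40, 40))
  expect_gt(d_prime(0.85, 0.3, 40, 40), d_prime(0.8, 0.3, 40, 40))
  expect_lt(d_prime(0.8, 0.35, 40, 40), d_prime(0.8, 0.3, 40, 40))
})

test_that("familiarity-only d-prime recovers the configured strength", {
  # with R = 0 the estimator sees pure familiarity: d' -> d_fam
  d <- build_design(2, n_subjects = 42, seed = 13)
  b <- gen_recognition(d, behavior_config("six_point", R = 0, d_fam = 1.5),
                       seed = 13)
  ov <- memory_rates(b, strata = character(0), memory_class = "overall")
  dp <- d_prime(ov$hit_rate, ov$fa_rate, ov$n_old, ov$n_new)
  expect_lt(abs(dp - 1.5), 0.1)
})

test_that("performance-based exclusion drops exactly the Pr <= 0 subjects", {
  d <- build_design(2, n_subjects = 65, seed = 14)
  b <- gen_recognition(d, behavior_config("six_point", R = 0.25, d_fam = 1.1),
                       seed = 14)
  # force six subjects below chance by inverting their responses
  bad <- sprintf("S%03d", 1:6)
  flip <- b$subject %in% bad
  b$response[flip] <- ifelse(b$truth[flip] == "old", "new", "old")
  b$confidence[flip] <- ifelse(b$response[flip] == "old", 6L, 1L)
  out <- exclude_poor_performers(b)
  rep <- exclusion_report(out)
  expect_equal(sort(rep$subject), bad)
  expect_equal(length(unique(out$subject)), 59)
  expect_true(all(rep$pr <= 0))
  # a clean table passes through unchanged
  ok <- b[!flip, ]
  out2 <- exclude_poor_performers(ok)
  expect_equal(nrow(out2), nrow(ok))
  expect_equal(nrow(exclusion_report(out2)), 0)
  # degenerate: everyone excluded
  allbad <- b[flip, ]
  expect_error(exclude_poor_performers(allbad), "all subjects")
})

test_that("unstable strata are flagged but still computed", {
  tab <- mk_table(data.frame(
    subject = "S1",
    truth = rep(c("old", "new"), each = 6),
    response = c(rep("old", 2), rep("new", 4), rep("new", 6)),
    confidence = c(6L, 5L, rep(1L, 10))
  ))
  r <- memory_rates(tab, memory_class = "recollection")
  expect_true(r$unstable)
  expect_equal(r$hits, 1)
})

test_that("memory indices survive a TSV round trip", {
  d <- build_design(2, n_subjects = 3, seed = 15)
  b <- gen_recognition(d, behavior_config("six_point"), seed = 15)
  idx <- memory_indices(b, c("subject", "category"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_memory_indices(idx, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(idx))
  expect_equal(back$pr, idx$pr, tolerance = 1e-12)
})
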