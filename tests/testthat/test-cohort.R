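test_that("a one-realization cohort equals a single engine run", {
  p <- model_params(N0 = 300, L = 25, T_end = 80)
  coh <- run_cohort(p, "random", strategies = "ctmtd", n_realizations = 1,
                    base_seed = 77)
  sim <- simulate_tumor(p, lattice = seed_cells(p, "random", seed = 77),
                        strategy = "ctmtd", seed = 77)
  expect_equal(coh$mean_traj$ctmtd$N, sim$ts$N)
  expect_equal(coh$outcomes$ttp,
               if (sim$outcome$censored) 80 else sim$outcome$ttp)
})

test_that("cohorts are reproducible and mean trajectories are true means", {
  p <- model_params(N0 = 250, L = 25, T_end = 60)
  a <- run_cohort(p, "random", strategies = "ctmtd", n_realizations = 4,
                  base_seed = 5)
  b <- run_cohort(p, "random", strategies = "ctmtd", n_realizations = 4,
                  base_seed = 5)
  expect_identical(a$mean_traj, b$mean_traj)
  expect_identical(a$outcomes, b$outcomes)
  # oracle recomputation of the mean from the long per-realization table
  long <- a$timeseries
  manual <- tapply(long$N, long$day, mean)
  expect_equal(as.numeric(manual[as.character(0:60)]), a$mean_traj$ctmtd$N)
})

test_that("seed pairing gives identical trajectories until dose divergence", {
  p <- model_params(N0 = 400, L = 30, T_end = 200, f0 = 15)
  coh <- run_cohort(p, "random", strategies = c("ctmtd", "at"),
                    n_realizations = 2, base_seed = 3)
  for (i in 1:2) {
    ct <- coh$timeseries[coh$timeseries$strategy == "ctmtd" &
                           coh$timeseries$realization == i, ]
    at <- coh$timeseries[coh$timeseries$strategy == "at" &
                           coh$timeseries$realization == i, ]
    div <- which(ct$dose != at$dose)
    if (length(div) == 0) {
      expect_equal(at$N, ct$N)
    } else {
      expect_equal(at$N[seq_len(div[1] - 1L)], ct$N[seq_len(div[1] - 1L)])
    }
  }
  # time-gain identity on the paired outcomes
  expect_equal(coh$tg$tg, coh$tg$ttp_at - coh$tg$ttp_ct)
})

test_that("Welch t-test matches the textbook formula and stars are stable", {
  a <- c(12.1, 14.3, 11.8, 13.9, 12.7)
  b <- c(15.2, 16.8, 14.9, 17.3, 16.1)
  got <- two_sample_ttest(a, b)
  # independent manual Welch computation
  se <- sqrt(stats::var(a) / 5 + stats::var(b) / 5)
  tman <- (mean(a) - mean(b)) / se
  dfman <- se^4 / ((stats::var(a) / 5)^2 / 4 + (stats::var(b) / 5)^2 / 4)
  pman <- 2 * stats::pt(-abs(tman), dfman)
  expect_equal(got$statistic, tman, tolerance = 1e-9)
  expect_equal(got$p.value, pman, tolerance = 1e-9)
  expect_error(two_sample_ttest(1, 1:4), "at least two")

  # identical samples degenerate gracefully
  same <- two_sample_ttest(rep(2, 4), rep(2, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$stars, "n.s.")

  expect_equal(stars_label(0.0005), "***")
  expect_equal(stars_label(0.005), "**")
  expect_equal(stars_label(0.04), "*")
  expect_equal(stars_label(0.2), "n.s.")

  # pooled-variance switch agrees with stats::t.test(var.equal = TRUE)
  pooled <- two_sample_ttest(a, b, var.equal = TRUE)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$p.value, ref$p.value)
})

test_that("experiment presets cover the documented grid", {
  ps <- experiment_presets()
  expect_true(all(c("base-clumped", "base-random", "base-uniform",
                    "clumped-n7000-f1", "migration-m2", "caf-FSq",
                    "caf-FC-a4", "capacity-K2") %in% names(ps)))
  expect_equal(experiment_preset("migration-m2")$params$m, 0.054)
  expect_equal(experiment_preset("capacity-K2")$params$K, 2L)
  expect_equal(experiment_preset("caf-FSp")$caf_layout, "FSp")
  expect_equal(experiment_preset("clumped-n7000-f1")$params$N0, 7000L)
  expect_error(experiment_preset("nope"), "unknown preset")
})

test_that("cohort CSV writers produce the documented columns", {
  p <- model_params(N0 = 200, L = 20, T_end = 30)
  coh <- run_cohort(p, "random", strategies = c("ctmtd", "at"),
                    n_realizations = 2, base_seed = 1,
                    record_neighborhood = TRUE)
  d <- withr_like_tempdir()
  write_outcomes(coh, file.path(d, "outcomes.csv"))
  oc <- utils::read.csv(file.path(d, "outcomes.csv"))
  expect_named(oc, c("seed", "strategy", "ttp", "censored", "cycles", "tr50"))
  expect_equal(nrow(oc), 4)
  write_timeseries(coh, file.path(d, "timeseries.csv"))
  ts <- utils::read.csv(file.path(d, "timeseries.csv"))
  expect_true(all(c("day", "S", "R", "N", "dose", "realization", "strategy")
                  %in% names(ts)))
  write_neighborhood(coh, file.path(d, "neighborhood.csv"))
  nb <- utils::read.csv(file.path(d, "neighborhood.csv"))
  expect_true(all(c("day", "realization", "focal_kind", "mean_NE", "mean_NS",
                    "mean_NR") %in% names(nb)))
  write_summary(coh, file.path(d, "summary.csv"))
  sm <- utils::read.csv(file.path(d, "summary.csv"))
  expect_true(all(c("strategy", "mean_ttp", "tg_mean", "ttest_p") %in% names(sm)))
  unlink(d, recursive = TRUE)
})
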