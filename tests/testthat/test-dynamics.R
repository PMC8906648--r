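# The daily decision tree for an isolated cell (always free space) reduces to
# four branch probabilities; branch_probs() enumerates them independently of
# the kernel. With the default rates and dose 1 an isolated S-cell is removed
# with probability r_S*delta_D + d_T = 0.02835 per day and divides
# successfully with probability r_S*(1 - delta_D) = 0.00675.

test_that("single-cell branch probabilities match the analytic enumeration", {
  p <- model_params()
  bp <- branch_probs(p, "S", dose = 1)
  expect_equal(bp$drug_death + bp$natural_death, 0.02835, tolerance = 1e-12)
  expect_equal(bp$division, 0.00675, tolerance = 1e-12)
  # R-cells never drug-die
  bpR <- branch_probs(p, "R", dose = 1)
  expect_equal(bpR$drug_death, 0)
  # dose 0 removes the drug branch for S too
  expect_equal(branch_probs(p, "S", dose = 0)$drug_death, 0)

  # Monte Carlo over >= 1e5 isolated-cell days within the binomial 99% CI
  p <- model_params()
  lat <- isolated_lattice(L = 300, spacing = 3, kind = "S")
  ncell <- lattice_counts(lat)[["N"]]
  removed <- 0; divided <- 0; trials <- 0
  s <- 0L
  while (trials < 1e5) {
    s <- s + 1L
    step <- advance(lat, dose = 1, p, seed = s)
    tally <- step$tally
    removed <- removed + tally[["deaths_natural"]] + tally[["deaths_drug"]]
    divided <- divided + tally[["births_S"]]
    trials <- trials + ncell
  }
  z <- stats::qnorm(0.995)
  ci <- function(prob) z * sqrt(prob * (1 - prob) / trials)
  expect_lt(abs(removed / trials - 0.02835), ci(0.02835))
  expect_lt(abs(divided / trials - 0.00675), ci(0.00675))
})

test_that("daily tallies satisfy the conservation identity", {
  p <- model_params(N0 = 500, L = 40, m = 0.054, T_end = 60)
  sim <- simulate_tumor(p, strategy = "at", seed = 5, r_pattern = "random")
  dN <- diff(sim$ts$N)
  with(sim$tallies, expect_equal(
    dN, births_S + births_R - deaths_natural - deaths_drug))
  # migration moves cells but never changes counts; blocked divisions neither
  expect_gt(sum(sim$tallies$migrations), 0)
})

test_that("zero migration probability never migrates", {
  p <- model_params(N0 = 400, L = 30, m = 0, T_end = 30)
  sim <- simulate_tumor(p, strategy = "ctmtd", seed = 1, r_pattern = "random")
  expect_equal(sum(sim$tallies$migrations), 0)
})

test_that("resistant cells are immune to the drug", {
  # d_T = 0 so the only removals would be drug deaths; R must not decline
  p <- validate_params(within_list(model_params(N0 = 300, L = 30, T_end = 80),
                                   d_T = 0))
  lat <- seed_cells(p, "random", seed = 2)
  sim <- simulate_tumor(p, lattice = lat, strategy = "ctmtd", seed = 2)
  expect_true(all(diff(sim$ts$R) >= 0))
  # while S-cells do drug-die
  expect_gt(sum(sim$tallies$deaths_drug), 0)
})

test_that("fully blocked divisions leave the lattice unchanged", {
  # r_R = 1, d_T = 0, m = 0: every cell attempts division every day; a full
  # lattice can only block
  p <- validate_params(within_list(model_params(N0 = 25, L = 5, T_end = 1),
                                   r_R = 1, r_S = 0.5, d_T = 0, m = 0,
                                   f0 = 100, alpha = 1))
  nR <- matrix(1L, 5, 5)
  lat <- new_lattice(matrix(0L, 5, 5), nR, K = 1)
  step <- advance(lat, dose = 1, p, seed = 3)
  expect_equal(step$tally[["blocked_divisions"]], 25)
  expect_identical(step$lattice$nR, nR)
})

test_that("CAF sites double the division-event probability when alpha = 2", {
  p <- validate_params(within_list(model_params(), alpha = 2, m = 0))
  lat_caf <- isolated_lattice(L = 150, kind = "R", caf_all = TRUE)
  lat_nof <- isolated_lattice(L = 150, kind = "R", caf_all = FALSE)
  ncell <- lattice_counts(lat_caf)[["N"]]
  births <- c(caf = 0, nof = 0); trials <- 0
  for (s in 1:15) {
    births[["caf"]] <- births[["caf"]] +
      advance(lat_caf, 0, p, seed = s)$tally[["births_R"]]
    births[["nof"]] <- births[["nof"]] +
      advance(lat_nof, 0, p, seed = 1000 + s)$tally[["births_R"]]
    trials <- trials + ncell
  }
  # analytic division probabilities: alpha*r_R vs r_R (free space guaranteed)
  pr_caf <- 2 * p$r_R; pr_nof <- p$r_R
  z <- stats::qnorm(0.9995)
  expect_lt(abs(births[["caf"]] / trials - pr_caf),
            z * sqrt(pr_caf * (1 - pr_caf) / trials))
  expect_lt(abs(births[["nof"]] / trials - pr_nof),
            z * sqrt(pr_nof * (1 - pr_nof) / trials))
})

test_that("sparse populations grow at r_j - d_T without drug", {
  # mean-field limit: expected per-day growth rate of type j is r_j - d_T
  p <- model_params(N0 = 400, L = 200, f0 = 0, T_end = 40)
  rates <- vapply(1:30, function(s) {
    sim <- simulate_tumor(p, strategy = "none", seed = s, r_pattern = "random")
    unname(coef(lm(log(N) ~ day, sim$ts))[2])
  }, numeric(1))
  expected <- log(1 + p$r_S - p$d_T)
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("sparse sensitive populations decline under full dose", {
  # net drift r_S(1 - delta_D) - r_S*delta_D - d_T = -0.0216 < 0
  p <- model_params()
  drift <- with(p, r_S * (1 - delta_D) - r_S * delta_D - d_T)
  expect_equal(drift, -0.0216, tolerance = 1e-12)
  p2 <- model_params(N0 = 500, L = 100, f0 = 0, T_end = 150)
  sim <- simulate_tumor(p2, strategy = "ctmtd", seed = 8, r_pattern = "random")
  expect_lt(sim$ts$N[151], sim$ts$N[1] * exp(drift * 150) * 2)
  expect_lt(sim$ts$N[151], 0.25 * sim$ts$N[1])
})

test_that("one-step state distribution matches exhaustive enumeration", {
  # 3x3 lattice, an S and an R cell side by side, dose 1, migration on:
  # enumerate every branch of the decision tree exactly, then compare
  # Monte Carlo frequencies from the kernel
  nS <- matrix(0L, 3, 3); nR <- matrix(0L, 3, 3)
  nS[2, 2] <- 1L; nR[2, 3] <- 1L # S at (2,2), R at (3,2)
  lat <- new_lattice(nS, nR, K = 1)
  p <- validate_params(within_list(model_params(N0 = 2, L = 3),
                                   m = 0.2, r_S = 0.3, r_R = 0.25,
                                   d_T = 0.1, delta_D = 0.6))
  for (variant in c(FALSE, TRUE)) {
    exact <- enumerate_step(lat, dose = 1, p, drug_after_space = variant)
    expect_equal(sum(exact), 1, tolerance = 1e-12)
    n <- 2e5
    reps <- latticeAT:::.abm_step_replicates(
      latticeAT:::engine_lesion(lat, p, 1), dose = 1, n = n,
      drug_check_after_space = variant, seed = 12345)
    keys <- replicate_keys(reps)
    z <- stats::qnorm(0.9995) # simultaneous across ~30 states
    for (k in names(exact)) {
      if (exact[[k]] < 5e-4) next
      phat <- mean(keys == k)
      expect_lt(abs(phat - exact[[k]]),
                z * sqrt(exact[[k]] * (1 - exact[[k]]) / n) + 1e-9)
    }
    # and every observed state was enumerated
    expect_true(all(unique(keys) %in% names(exact)))
  }
})

test_that("drug-check ordering variants differ exactly as specified", {
  # a boxed-in S-cell (no free neighbour) can drug-die under the flow-chart
  # order but not under the text order
  nS <- matrix(0L, 3, 3); nR <- matrix(0L, 3, 3)
  nS[2, 2] <- 1L
  nR[1, 2] <- nR[3, 2] <- nR[2, 1] <- nR[2, 3] <- 1L
  lat <- new_lattice(nS, nR, K = 1)
  p <- validate_params(within_list(model_params(N0 = 5, L = 3),
                                   r_S = 0.9, r_R = 0, d_T = 0, m = 0,
                                   delta_D = 1, alpha = 1))
  # flow-chart order: S divides-attempts w.p. 0.9 and always drug-dies
  flow <- enumerate_step(lat, 1, p, drug_after_space = FALSE)
  text <- enumerate_step(lat, 1, p, drug_after_space = TRUE)
  key_dead <- paste(c(0L * nS, nR), collapse = ",")
  key_alive <- paste(c(nS, nR), collapse = ",")
  expect_equal(unname(flow[key_dead]), 0.9, tolerance = 1e-12)
  expect_equal(unname(flow[key_alive]), 0.1, tolerance = 1e-12)
  expect_equal(unname(text[key_alive]), 1, tolerance = 1e-12) # blocked first
  # kernel agrees with both enumerations
  for (variant in c(FALSE, TRUE)) {
    reps <- latticeAT:::.abm_step_replicates(
      latticeAT:::engine_lesion(lat, p, 1), dose = 1, n = 2e4,
      drug_check_after_space = variant, seed = 7)
    dead <- mean(replicate_keys(reps) == key_dead)
    expect_equal(dead, if (variant) 0 else 0.9, tolerance = 0.02)
  }
})

test_that("runs are bit-reproducible given a seed", {
  p <- model_params(N0 = 300, L = 30, T_end = 40, m = 0.027)
  a <- simulate_tumor(p, strategy = "at", seed = 17, r_pattern = "clumped",
                      clump_side = 12)
  b <- simulate_tumor(p, strategy = "at", seed = 17, r_pattern = "clumped",
                      clump_side = 12)
  expect_identical(a$ts, b$ts)
  expect_identical(a$final$nR, b$final$nR)
  c2 <- simulate_tumor(p, strategy = "at", seed = 18, r_pattern = "clumped",
                       clump_side = 12)
  expect_false(identical(a$ts$N, c2$ts$N))
})
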