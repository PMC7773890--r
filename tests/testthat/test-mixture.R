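test_that("mixture log-likelihood matches closed forms", {
  # single 0-degree error, all-target, kappa = 2: log vM(0; 0, 2)
  expect_equal(mixture_loglik(0, NULL, pT = 1, pN = 0, pU = 0, kappa = 2),
               2 - log(2 * pi * besselI(2, 0)), tolerance = 1e-12)
  # pure-guess component: n * log(1 / (2 pi)) regardless of the errors
  e <- c(-45, 3, 88, 0, 12.5)
  expect_equal(mixture_loglik(e, NULL, pT = 0, pN = 0, pU = 1, kappa = 5),
               5 * log(1 / (2 * pi)), tolerance = 1e-12)
})

test_that("mixture log-likelihood matches per-trial direct evaluation", {
  errors <- c(5, -30, 70)
  offsets <- rbind(c(40, -60), c(-20, 85), c(10, -45))
  got <- mixture_loglik(errors, offsets, pT = 0.6, pN = 0.3, pU = 0.1,
                        kappa = 4)
  want <- oracle_mixture_loglik(errors, offsets, 0.6, 0.3, 0.1, 4)
  expect_equal(got, want, tolerance = 1e-10)
  # invalid simplex rejected
  expect_error(mixture_loglik(errors, offsets, 0.7, 0.3, 0.1, 4), "sum to 1")
  expect_error(mixture_loglik(errors, NULL, 0.6, 0.3, 0.1, 4), "offsets")
})

test_that("the two-factor fit satisfies pU + pT = 1", {
  sched <- make_schedule(6, 6, 1, 3, "1O", seed = 21)
  prof <- group_profile(pT = 0.85, pN = 0, pU = 0.15, kappa_mix = 8)
  resp <- simulate_behavior(sched, prof, seed = 22)
  fit <- fit_mixture(resp, n_factors = 2, n_starts = 5, seed = 23)
  expect_s3_class(fit, "mixture_fit")
  expect_equal(fit$pT + fit$pU, 1, tolerance = 1e-9)
  expect_equal(fit$pN, 0)
})

test_that("degenerate all-zero errors drive pT to 1 and kappa to its cap", {
  resp <- data.frame(error = rep(0, 60))
  fit <- fit_mixture(resp, n_factors = 2, n_starts = 3, seed = 24)
  expect_gt(fit$pT, 0.999)
  expect_equal(fit$kappa, 200)
})

test_that("EM recovers generating parameters and beats a grid-search oracle", {
  sched <- make_schedule(6, 6, 3, 139, "3O", seed = 25)[1:5000, ]
  class(sched) <- c("trial_schedule", "data.frame")
  attr(sched, "set_size") <- 3L
  prof <- group_profile(pT = 0.80, pN = 0.15, pU = 0.05, kappa_mix = 10)
  resp <- simulate_behavior(sched, prof, seed = 26)
  fit <- fit_mixture(resp, n_factors = 3, n_starts = 10, seed = 27)

  expect_lt(abs(fit$pT - 0.80), 0.03)
  expect_lt(abs(fit$pN - 0.15), 0.03)
  expect_lt(abs(fit$pU - 0.05), 0.03)
  expect_lt(abs(fit$kappa - 10) / 10, 0.15)

  # oracle: coarse lattice over the simplex and kappa, maximizing the
  # likelihood directly, refined locally with a finer lattice
  offs <- nontarget_offsets(resp)
  grid_best <- -Inf; arg <- NULL
  for (pT in seq(0.70, 0.90, by = 0.02)) {
    for (pN in seq(0.05, 0.25, by = 0.02)) {
      if (pT + pN > 1) next
      for (k in seq(6, 14, by = 1)) {
        ll <- mixture_loglik(resp$error, offs, pT, pN, 1 - pT - pN, k)
        if (ll > grid_best) { grid_best <- ll; arg <- c(pT, pN, k) }
      }
    }
  }
  for (pT in seq(arg[1] - 0.02, arg[1] + 0.02, by = 0.005)) {
    for (pN in seq(arg[2] - 0.02, arg[2] + 0.02, by = 0.005)) {
      if (pT + pN > 1 || pN < 0) next
      for (k in seq(arg[3] - 1, arg[3] + 1, by = 0.1)) {
        ll <- mixture_loglik(resp$error, offs, pT, pN, 1 - pT - pN, k)
        if (ll > grid_best) grid_best <- ll
      }
    }
  }
  expect_gte(fit$loglik, grid_best - 0.05)
  # fitted likelihood is at least the likelihood at the generating truth
  ll_truth <- mixture_loglik(resp$error, offs, 0.80, 0.15, 0.05, 10)
  expect_gte(fit$loglik, ll_truth)
})

test_that("EM log-likelihood never decreases across iterations", {
  sched <- make_schedule(6, 6, 3, 3, "3O", seed = 28)
  prof <- group_profile(pT = 0.6, pN = 0.25, pU = 0.15, kappa_mix = 6)
  resp <- simulate_behavior(sched, prof, seed = 29)
  fit <- fit_mixture(resp, n_factors = 3, n_starts = 6, seed = 30)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
})

test_that("three-factor fitting without offsets is a configuration error", {
  resp <- data.frame(error = rnorm(50, 0, 10),
                     offset_1 = NA_real_, offset_2 = NA_real_)
  expect_error(fit_mixture(resp, n_factors = 3, seed = 31), "offsets")
})

test_that("swap-error group classification follows both grouping rules", {
  expect_equal(classify_groups(c(0.01, 0.20, 0.08), "extreme_thresholds"),
               c("low", "high", "unclassified"))
  expect_warning(classify_groups(c(0, 0), "median_split"), "degenerate")
  split <- suppressWarnings(classify_groups(c(0, 0), "median_split"))
  expect_equal(as.character(split), c("low", "low"))
  expect_true(attr(split, "degenerate"))
  # 27 values, 14 at or below the median: 14 low vs 13 high
  set.seed(32)
  vals <- c(runif(14, 0, 0.04), runif(13, 0.06, 0.40))
  g <- classify_groups(vals, "median_split")
  expect_equal(sum(g == "low"), 14)
  expect_equal(sum(g == "high"), 13)
  expect_error(classify_groups(numeric(0)), "nonempty")
  expect_error(classify_groups(c(0.2, 1.4)), "\\[0, 1\\]")
})
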