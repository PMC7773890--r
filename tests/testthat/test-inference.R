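make_ctf_matrix <- function(n_subj, alpha, noise = 0, seed = 1) {
  set.seed(seed)
  x <- seq(-90, 89)
  base <- exp(6 * (cos(2 * pi * x / 180) - 1))
  t(vapply(seq_len(n_subj),
           function(i) alpha * base + rnorm(180, 0, noise),
           numeric(180)))
}

test_that("amplitude bootstrap gives p = 0 / p = 1 in the extreme cases", {
  strong <- make_ctf_matrix(8, alpha = 2)
  res <- bootstrap_amplitude_p(strong, n_iters = 200, seed = 1)
  expect_equal(res$p, 0)
  expect_length(res$values, 200)
  flipped <- bootstrap_amplitude_p(-strong, n_iters = 200, seed = 1)
  expect_equal(flipped$p, 1)
  expect_error(bootstrap_amplitude_p(strong[1, , drop = FALSE]), "2 subjects")
})

test_that("bootstrap p-values are seed-reproducible and order-invariant", {
  M <- make_ctf_matrix(10, alpha = 0.05, noise = 0.3, seed = 2)
  r1 <- bootstrap_amplitude_p(M, n_iters = 300, seed = 7)
  r2 <- bootstrap_amplitude_p(M, n_iters = 300, seed = 7)
  expect_identical(r1$values, r2$values)
  perm <- sample(10)
  r3 <- bootstrap_amplitude_p(M[perm, ], n_iters = 300, seed = 7)
  expect_identical(r1$values, r3$values)
  # and the same for the group-difference test
  N <- make_ctf_matrix(9, alpha = 0.1, noise = 0.3, seed = 3)
  d1 <- bootstrap_group_difference(M, N, n_iters = 300, seed = 8)
  d2 <- bootstrap_group_difference(M[perm, ], N[sample(9), ],
                                   n_iters = 300, seed = 8)
  expect_identical(d1$values, d2$values)
})

test_that("identical groups give a difference p near one half", {
  M <- make_ctf_matrix(10, alpha = 0.5, noise = 0.5, seed = 4)
  res <- bootstrap_group_difference(M, M, n_iters = 500, seed = 9)
  se <- sqrt(0.25 / 500)
  expect_lt(abs(res$p - 0.5), 3 * se)
  # clearly separated groups: p = 0
  strong <- make_ctf_matrix(8, alpha = 1)
  flat <- matrix(0, 8, 180)
  expect_equal(bootstrap_group_difference(strong, flat, n_iters = 200,
                                          seed = 10)$p, 0)
})

test_that("recall specificity is the exact amplitude difference", {
  M <- make_ctf_matrix(6, alpha = 1.2, noise = 0.1, seed = 5)
  s_same <- recall_specificity(M, M)
  expect_equal(s_same$difference, rep(0, 6))
  flat <- matrix(0.2, 6, 180)
  s <- recall_specificity(M, flat)
  expect_equal(s$difference, s$probed_amp - s$nonprobed_amp)
  expect_equal(s$nonprobed_amp, rep(0, 6))
  expect_error(recall_specificity(M, flat[1:3, ]), "align")
})

test_that("specificity varies only through the non-probed selection seed", {
  sched <- make_schedule(6, 6, 3, 1, "3O", seed = 11)
  sel_a <- select_nonprobed(sched, seed = 1)
  sel_b <- select_nonprobed(sched, seed = 2)
  expect_false(all(sel_a == sel_b))
  # both selections stay within the two non-probed items, so enumerating
  # the per-trial choices brackets any seeded outcome
  for (sel in list(sel_a, sel_b)) {
    expect_true(all(sel != sched$probed_index & sel %in% 1:3))
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up rule", {
  single <- fdr_bh(0.03)
  expect_equal(single$p_adjusted, 0.03)
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$p_adjusted, c(0.04, 0.04, 0.04, 0.04))
  none <- fdr_bh(rep(1, 5))
  expect_false(any(none$reject))
  # monotone in the raw p-values
  set.seed(12)
  p <- runif(30)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("within-subject correlation is exact for affine relations", {
  subject <- rep(1:6, each = 3)
  x <- rnorm(18)
  y_up <- x + rep(rnorm(6, 0, 5), each = 3)       # subject offsets
  r_up <- within_subject_correlation(x, y_up, subject)
  expect_equal(r_up$r, 1, tolerance = 1e-12)
  y_dn <- -x + rep(rnorm(6, 0, 5), each = 3)
  expect_equal(within_subject_correlation(x, y_dn, subject)$r, -1,
               tolerance = 1e-12)
  # degrees of freedom: N(k-1) - 1 for balanced designs
  expect_equal(r_up$df, 6 * (3 - 1) - 1)
})

test_that("within-subject correlation matches an explicit ANCOVA fit", {
  set.seed(13)
  subject <- rep(1:8, each = 3)
  x <- rnorm(24); y <- 0.5 * x + rnorm(24, 0, 1) +
    rep(rnorm(8, 0, 3), each = 3)
  got <- within_subject_correlation(x, y, subject)
  fit <- stats::lm(y ~ factor(subject) + x)
  aov_p <- stats::anova(fit)["x", "Pr(>F)"]
  expect_equal(got$p, aov_p, tolerance = 1e-10)
  slope_sign <- sign(stats::coef(fit)[["x"]])
  expect_equal(sign(got$r), slope_sign)
})

test_that("within-subject correlation null calibration is honest", {
  set.seed(14)
  rejections <- 0
  for (i in 1:100) {
    subject <- rep(1:8, each = 3)
    res <- within_subject_correlation(rnorm(24), rnorm(24), subject)
    if (res$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 100, 0.02)
  expect_lte(rejections / 100, 0.09)
})

test_that("rank correlations report squared coefficients", {
  x <- c(0.3, 1.1, 2.4, 3.9, 5.2)
  lin <- rank_correlation(x, 2 * x, "pearson")
  expect_equal(lin$R2, 1, tolerance = 1e-12)
  mono <- rank_correlation(x, exp(x), "spearman")
  expect_equal(mono$R2, 1, tolerance = 1e-12)
  expect_lt(rank_correlation(x, exp(x), "pearson")$R2, 1)
  # hand value: ranks 1,2,3,4 vs 1,2,4,3 -> rho = 1 - 6*2/(4*15) = 0.8
  sp <- rank_correlation(c(1, 2, 3, 4), c(1, 2, 4, 3), "spearman")
  expect_equal(sp$r, 0.8, tolerance = 1e-12)
  expect_equal(sp$R2, 0.64, tolerance = 1e-12)
  expect_error(rank_correlation(x, rep(1, 5)), "constant")
  expect_error(rank_correlation(1:3, 1:3), "length")
})

test_that("the Shapiro-Wilk gate recommends Spearman for skewed data", {
  set.seed(15)
  normal <- rnorm(30)
  skewed <- exp(rnorm(30, 0, 1.5))
  expect_equal(recommend_correlation_method(normal, rnorm(30)), "pearson")
  expect_equal(recommend_correlation_method(normal, skewed), "spearman")
})
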