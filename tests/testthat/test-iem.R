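test_that("channel bases have the designed count, unit peaks and zero antipodes", {
  b9 <- make_basis(9, 180)
  b6 <- make_basis(6, 180)
  expect_equal(b9$k, 9L)
  expect_equal(b6$k, 6L)
  expect_equal(b9$centers, seq(0, 160, by = 20))
  for (b in list(b9, b6, make_basis(6, 360))) {
    R <- basis_response(b, b$centers)
    expect_equal(diag(R), rep(1, b$k))            # own center drives 1
    anti <- basis_response(b, b$centers + b$period / 2)
    expect_equal(diag(anti), rep(0, b$k))         # antipode drives 0
    expect_true(all(R >= 0 & R <= 1))
  }
  expect_error(make_basis(1, 180), "k >= 2")
  expect_error(make_basis(6, 180, exponent = 0), "exponent")
})

test_that("basis responses respect the circular topology", {
  b <- make_basis(6, 180)
  # 180 degrees away on the orientation circle is the same orientation
  expect_equal(basis_response(b, 0), basis_response(b, 180))
  expect_equal(basis_response(b, 25), basis_response(b, 205))
})

test_that("baseline removal matches hand arithmetic and orthogonalizes", {
  # columns symmetric about 0: the mean pattern is zero, input unchanged
  B0 <- cbind(c(1, -2), c(-1, 2))
  expect_equal(remove_baseline(B0), B0)
  # hand example with a unit-norm mean pattern
  B <- rbind(c(1, 1), c(0, 0))
  expect_equal(remove_baseline(B), matrix(0, 2, 2))
  # projection property on random matrices: m' result = 0
  set.seed(51)
  for (i in 1:20) {
    M <- matrix(rnorm(35), 5, 7)
    out <- remove_baseline(M)
    m <- rowMeans(M)
    expect_equal(as.numeric(t(m) %*% out), rep(0, 7), tolerance = 1e-12)
  }
  expect_error(remove_baseline(matrix(numeric(0), 0, 0)), "empty")
})

test_that("weight training reproduces identity and scaling cases", {
  C1 <- basis_response(make_basis(6, 180), seq(2, 178, length.out = 30))
  W1 <- train_iem(C1, C1)
  expect_equal(W1$W, diag(6), tolerance = 1e-10)
  W2 <- train_iem(2 * C1, C1)
  expect_equal(W2$W, 2 * diag(6), tolerance = 1e-10)
})

test_that("weight training equals per-voxel least squares on random problems", {
  set.seed(52)
  C1 <- matrix(rnorm(9 * 81), 9, 81)
  B1 <- matrix(rnorm(50 * 81), 50, 81)
  W <- train_iem(B1, C1)$W
  for (v in c(1, 17, 50)) {
    ls <- stats::lm.fit(t(C1), B1[v, ])$coefficients
    expect_equal(unname(W[v, ]), unname(ls), tolerance = 1e-10)
  }
  # least-squares property: no weight perturbation improves the fit
  sse <- norm(B1 - W %*% C1, "F")^2
  for (i in 1:5) {
    Wp <- W + matrix(rnorm(length(W), 0, 0.01), nrow(W))
    expect_gt(norm(B1 - Wp %*% C1, "F")^2, sse)
  }
})

test_that("inversion is exact on the range of W", {
  set.seed(53)
  W <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(invert_iem(diag(5), diag(5)), diag(5))
  c_true <- matrix(runif(6 * 10), 6, 10)
  expect_equal(invert_iem(W, W %*% c_true), c_true, tolerance = 1e-10)
  # train -> invert round trip
  C1 <- matrix(runif(6 * 50), 6, 50)
  B1 <- W %*% C1
  What <- train_iem(B1, C1)
  expect_equal(invert_iem(What, B1), C1, tolerance = 1e-8)
  expect_error(invert_iem(matrix(1, 3, 5), matrix(1, 3, 2)), "voxels")
})

test_that("degenerate channel designs raise informative errors", {
  C1 <- matrix(1, 4, 20)             # identical channels: singular
  B1 <- matrix(rnorm(80), 4, 20)
  expect_error(train_iem(B1, C1), "ill-conditioned")
  expect_error(train_iem(B1[, 1:3], C1[, 1:3]), "training trials")
})

test_that("reconstructions are 180 points and peak at zero when matched", {
  prof <- noiseless_profile(probed_gain = 1, nonprobed_gain = 0)
  sub <- small_subject_dataset(prof, n_voxels = 60, noise_sd = 0, seed = 54)
  ct <- reconstruct_ctf(sub$dat, sub$bases$ori, 10, "1O", "3O",
                        "orientation", n_shift_iters = 30, seed = 55)
  expect_s3_class(ct, "ctf")
  expect_length(ct$values, 180)
  expect_equal(ct$offsets, seq(-90, 89))
  expect_equal(ct$offsets[which.max(ct$values)], 0)
  # location feature: full-circle axis at 2-degree steps, still 180 points
  cl <- reconstruct_ctf(sub$dat, sub$bases$loc, 10, "1O", "3O", "location",
                        n_shift_iters = 30, seed = 56)
  expect_length(cl$values, 180)
  expect_equal(cl$offsets, seq(-180, 178, by = 2))
  expect_equal(cl$offsets[which.max(cl$values)], 0)
})

test_that("reconstruction is invariant to voxel order", {
  prof <- group_profile(pT = 0.9, pN = 0.05, pU = 0.05)
  sub <- small_subject_dataset(prof, n_voxels = 40, noise_sd = 0.3,
                               seed = 57)
  ct1 <- reconstruct_ctf(sub$dat, sub$bases$ori, 10, "1O", "3O",
                         "orientation", n_shift_iters = 30, seed = 58)
  perm <- sample(40)
  dat2 <- sub$dat
  dat2$signal <- dat2$signal[perm, ]
  ct2 <- reconstruct_ctf(dat2, sub$bases$ori, 10, "1O", "3O",
                         "orientation", n_shift_iters = 30, seed = 58)
  expect_equal(ct1$values, ct2$values, tolerance = 1e-9)
})

test_that("rotating every feature by one channel spacing leaves the CTF unchanged", {
  prof <- noiseless_profile(probed_gain = 1, nonprobed_gain = 0)
  sub <- small_subject_dataset(prof, n_voxels = 60, noise_sd = 0, seed = 59)
  ct1 <- reconstruct_ctf(sub$dat, sub$bases$ori, 10, "1O", "3O",
                         "orientation", n_shift_iters = 30, seed = 60)

  rot <- function(sched) {
    for (col in c("sample_1", "sample_2", "sample_3",
                  "base_1", "base_2", "base_3")) {
      sched[[col]] <- (sched[[col]] + 30) %% 180
    }
    sched
  }
  s3r <- rot(sub$s3); s1r <- rot(sub$s1)
  b <- sub$bases
  # channel-permuted weights: rotating every feature by one spacing while
  # shifting each voxel's tuning by one channel reproduces the identical
  # voxel time series, so only the recentering bookkeeping is exercised
  w0 <- small_subject_dataset(prof, n_voxels = 60, noise_sd = 0,
                              seed = 59)$dat$truth
  w_rot <- list(w_ori = w0$w_ori[, c(6, 1:5)], w_loc = w0$w_loc)
  d3 <- simulate_bold(s3r, prof, 60, b$ori, b$loc, noise_sd = 0,
                      seed = 59 + 2L, weights = w_rot)
  d1 <- simulate_bold(s1r, prof, 60, b$ori, b$loc, noise_sd = 0,
                      seed = 59 + 3L, weights = w_rot)
  ct2 <- reconstruct_ctf(concat_datasets(d3, d1), b$ori, 10, "1O", "3O",
                         "orientation", n_shift_iters = 30, seed = 60)
  expect_equal(ct1$values, ct2$values, tolerance = 1e-9)
})

test_that("per-location splits reproduce 81/9 from 90-trial pools", {
  splits <- ctxbind:::make_splits(1:90, same_cond = TRUE, train_frac = 0.9,
                                  n_splits = 5)
  for (sp in splits) {
    expect_length(sp$train, 81)
    expect_length(sp$test, 9)
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("too few training trials per location is an error", {
  prof <- group_profile(pT = 0.9, pN = 0.05, pU = 0.05)
  sub <- small_subject_dataset(prof, n_voxels = 30, noise_sd = 0.2,
                               seed = 61, repeats_1O = 2)
  # demand more channels than the 12 per-location training trials support
  b12 <- make_basis(18, 180)
  expect_error(
    reconstruct_ctf(sub$dat, b12, 10, "1O", "3O", "orientation",
                    n_shift_iters = 30, seed = 62),
    "training trials")
})

test_that("non-probed item selection never picks the probed item", {
  sched <- make_schedule(6, 6, 3, 2, "3O", seed = 63)
  sel <- select_nonprobed(sched, seed = 64)
  expect_true(all(sel != sched$probed_index))
  expect_true(all(sel %in% 1:3))
  expect_identical(sel, select_nonprobed(sched, seed = 64))
})
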