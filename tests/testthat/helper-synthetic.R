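# shared builders for the synthetic-data tests

exp2_bases <- function() {
  list(ori = make_basis(6, 180), loc = make_basis(6, 360))
}

# a small experiment-2-like subject: 36 3O test trials, 72 1O training
# trials, shared ground-truth weights, both blocks concatenated
small_subject_dataset <- function(profile, n_voxels = 100, noise_sd = 0.5,
                                  seed = 1L, repeats_1O = 2) {
  b <- exp2_bases()
  s3 <- make_schedule(6, 6, 3, 1, "3O", seed = seed)
  s1 <- make_schedule(6, 6, 1, repeats_1O, "1O", seed = seed + 1L)
  d3 <- simulate_bold(s3, profile, n_voxels, b$ori, b$loc,
                      noise_sd = noise_sd, seed = seed + 2L)
  d1 <- simulate_bold(s1, profile, n_voxels, b$ori, b$loc,
                      noise_sd = noise_sd, seed = seed + 3L,
                      weights = d3$truth)
  list(dat = concat_datasets(d3, d1), s3 = s3, s1 = s1, bases = b)
}

noiseless_profile <- function(...) {
  group_profile(pT = 1, pN = 0, pU = 0, kappa_mix = Inf, ...)
}

# independent direct evaluation of the mixture likelihood, one trial at a
# time, used as the oracle for mixture_loglik
oracle_mixture_loglik <- function(errors, offsets, pT, pN, pU, kappa) {
  dvm <- function(dev) {
    th <- 2 * dev * pi / 180
    exp(kappa * cos(th)) / (2 * pi * besselI(kappa, 0))
  }
  total <- 0
  for (i in seq_along(errors)) {
    d <- pT * dvm(errors[i]) + pU / (2 * pi)
    if (pN > 0) {
      d <- d + pN * mean(dvm(errors[i] - offsets[i, ]))
    }
    total <- total + log(d)
  }
  total
}
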