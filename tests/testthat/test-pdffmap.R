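test_that("the relaxation correction reduces to identity in the limit", {
  W <- array(2, c(2, 2, 2)); F <- array(1, c(2, 2, 2))
  sp <- species_relaxation(10, 10, 30.8, 30.8)
  m <- correct_proton_density(W, F, flip_deg = 90, tr_ms = 1e4, te_ref_ms = 0, sp)
  expect_equal(m$m_w, W, tolerance = 1e-12)
  expect_equal(m$m_f, F, tolerance = 1e-12)
  # e^(TE/T2*) factor alone: W=1, alpha=90, TR>>T1, TE=3.08, T2*=30.8
  m2 <- correct_proton_density(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)),
                               90, 1e7, 3.08, species_relaxation(1, 1, 30.8, 30.8))
  expect_equal(m2$m_w[1], exp(0.1), tolerance = 1e-9)
  expect_equal(round(m2$m_w[1], 5), 1.10517)
  expect_error(correct_proton_density(W, F, 0, 30, 3.08, sp), "flip")
})

test_that("the correction inverts the simulator's steady-state amplitudes", {
  tr <- small_truth(seed = 41)
  p <- acquisition_params()
  W <- spgr_amp(tr$W0, p$te_ms[1], p$tr_ms, p$flip_deg, tr$t1w_ms, tr$t2sw_ms)
  F <- spgr_amp(tr$F0, p$te_ms[1], p$tr_ms, p$flip_deg, tr$t1f_ms, tr$t2sf_ms)
  sp <- species_relaxation(tr$t1w_ms, tr$t1f_ms, tr$t2sw_ms, tr$t2sf_ms)
  m <- correct_proton_density(W, F, p$flip_deg, p$tr_ms, p$te_ms[1], sp)
  tis <- !tr$background & tr$W0 > 0
  ratio <- m$m_w[tis] / tr$W0[tis]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # the global constant is the sin(alpha) saturation factor inverse: here 1
  expect_equal(mean(ratio), 1, tolerance = 1e-9)
})

test_that("PDFF arithmetic, masking and clipping follow the definition", {
  d <- c(2, 2, 1)
  mk <- array(TRUE, d)
  p <- compute_pdff(array(c(1, 0.5, 0.2, 0), d), array(c(0, 0.5, 0.8, 0), d), mk)
  expect_equal(as.vector(p$values), c(0, 50, 80, 0))
  mk2 <- array(c(TRUE, TRUE, FALSE, TRUE), d)
  p2 <- compute_pdff(array(1, d), array(1, d), mk2)
  expect_true(is.na(p2$values[1, 2, 1]))
  expect_equal(p2$values[1, 1, 1], 50)
  p3 <- compute_pdff(array(-1, d), array(1, d), mk)
  expect_equal(p3$n_clipped, 4)
  expect_equal(as.vector(p3$values), rep(100, 4))
  expect_error(compute_pdff(array(1, d), array(1, c(3, 2, 1)), mk), "grid")
})

test_that("noise SD estimation matches the sample SD with sanity checks", {
  v <- array(rep(c(1, 2, 3, 4, 5), 30), c(10, 5, 3))
  expect_equal(estimate_noise_sd(v, 1:150), sd(rep(c(1, 2, 3, 4, 5), 30)))
  # sample SD with the n-1 denominator: sd(1..5) = 1.5811
  expect_equal(round(sd(v[1:5]), 4), 1.5811)
  expect_equal(suppressWarnings(estimate_noise_sd(v, 1:10)), sd(v[1:10]))
  expect_equal(suppressWarnings(estimate_noise_sd(array(7, c(5, 5, 5)), 1:125)), 0)
  expect_error(estimate_noise_sd(v, 1:5 * 0), "fewer than 10")
  expect_warning(estimate_noise_sd(v, 1:50), "fewer than 100")
  set.seed(1)
  vs <- array(abs(rnorm(1000, 100, 1)), c(10, 10, 10))
  expect_warning(estimate_noise_sd(vs, 1:1000), "object signal")
})

test_that("tissue mask thresholding, refinement and user edits behave", {
  d <- c(3, 3, 1)
  e <- array(0.1 / sqrt(3), c(d, 3))
  e[2, 2, 1, ] <- 10 / sqrt(3)
  mk <- build_tissue_mask(e, sigma = 0.1, k = 3, refine = FALSE)
  expect_equal(sum(mk$mask), 1)
  expect_true(mk$mask[2, 2, 1])
  # threshold monotonicity on the pre-refinement mask
  set.seed(5)
  e2 <- array(abs(rnorm(5 * 5 * 5 * 3)), c(5, 5, 5, 3))
  ks <- c(0.5, 1, 2, 4)
  counts <- sapply(ks, function(k)
    sum(build_tissue_mask(e2, sigma = 0.5, k = k, refine = FALSE)$initial))
  expect_true(all(diff(counts) <= 0))
  # user mask forces voxels in and out after refinement
  um <- array(0L, d)
  um[1, 1, 1] <- 1L
  um[2, 2, 1] <- -1L
  mk2 <- build_tissue_mask(e, sigma = 0.1, k = 3, user_mask = um)
  expect_true(mk2$mask[1, 1, 1])
  expect_false(mk2$mask[2, 2, 1])
  expect_warning(build_tissue_mask(e, sigma = 0, k = 3), "positive")
})

test_that("the phantom mask captures the true tissue extent under noise", {
  tr <- make_truth(phantom_config(dim = c(32, 32, 32), seed = 51))
  p <- acquisition_params(n_coils = 4, seed = 51)
  lvl <- tissue_signal_level(tr, p)
  sim <- simulate_wf_echoes(tr, within_params(p, noise_sd = lvl / 20))
  cc <- combine_coils(sim, "reference")
  comb <- sqrt(apply(cc$magnitude^2, c(1, 2, 3), sum))
  bg_roi <- which(array(seq_len(32^3), tr$dim) <= 5 * 32 * 32 & tr$background)
  sigma <- suppressWarnings(estimate_noise_sd(comb, bg_roi))
  mu <- mean(comb[bg_roi])
  mk <- build_tissue_mask(cc$magnitude, sigma, k = 3, mu = mu)
  n_true <- sum(!tr$background)
  expect_lt(abs(sum(mk$mask) - n_true) / n_true, 0.02)
})

test_that("the histogram mixture recovers a known two-component blend", {
  set.seed(42)
  n <- 2e5
  x <- pmin(pmax(c(rnorm(0.8 * n, 20, 5), rnorm(0.2 * n, 90, 3)), 0), 100)
  m <- fit_histogram_gmm(x)
  expect_equal(sum(m$weight), 1, tolerance = 1e-9)
  expect_equal(length(m$counts), 1000)
  expect_lt(abs(m$mean[m$water] - 20), 0.15)
  expect_lt(abs(m$sd[m$water] - 5), 0.15)
  expect_lt(abs(m$mean[m$fat] - 90), 0.15)
  expect_true(m$mean[m$water] < m$mean[m$fat])
  expect_true(m$t_c > m$mean[m$water] && m$t_c <= 100)
  # order invariance: the histogram is permutation-invariant
  m2 <- fit_histogram_gmm(sample(x))
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$sd, m$sd)
  # degenerate input: all values equal
  m0 <- fit_histogram_gmm(rep(0, 1e4))
  expect_equal(length(m0$mean), 1)
  expect_lt(m0$mean, 0.1)
  expect_error(fit_histogram_gmm(rnorm(100, 50, 5)), "masked voxels")
})

test_that("mixture fit agrees with an unbinned EM reference on samples", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(9)
  x <- pmin(pmax(c(rnorm(4e4, 25, 6), rnorm(1e4, 85, 4)), 0), 100)
  m <- fit_histogram_gmm(x, components = 2)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu_ref <- ref$parameters$mean
  sd_ref <- sqrt(ref$parameters$variance$sigmasq)
  ord <- order(mu_ref)
  expect_equal(sort(m$mean), unname(mu_ref[ord]), tolerance = 0.05)
  expect_equal(m$sd[order(m$mean)], unname(sd_ref[ord]), tolerance = 0.05)
})

test_that("threshold selection snaps the 99.99% point up to a bin edge", {
  mk_model <- function(mu, sd) {
    structure(list(edges = seq(0, 100, by = 0.1), mean = mu, sd = sd,
                   weight = 1, water = 1), class = "histogram_model")
  }
  expect_equal(select_thresholds(mk_model(0, 1))$t_c, 3.8)
  expect_equal(select_thresholds(mk_model(21, 5))$t_c, 39.6)
  expect_equal(select_thresholds(mk_model(21, 0))$t_c, 21.0)
  expect_warning(th <- select_thresholds(mk_model(95, 3)), "clamped")
  expect_equal(th$t_c, 100)
  expect_equal(select_thresholds(mk_model(10, 2))$t_d, 50)
  # T_C matches a direct numeric inversion of the water CDF at 0.9999
  mu <- 17.3; sd <- 4.7
  inv <- uniroot(function(x) pnorm(x, mu, sd) - 0.9999, c(mu, mu + 10 * sd),
                 tol = 1e-10)$root
  t_c <- select_thresholds(mk_model(mu, sd))$t_c
  expect_lte(abs(t_c - inv), 0.1 + 1e-9)
})
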