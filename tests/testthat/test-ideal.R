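tau3 <- c(0, 0.23, 0.46)
fF <- -1361

test_that("a pure-water signal is solved exactly", {
  s <- solve_voxel(c(2, 2, 2) + 0i, tau3, 0)
  expect_equal(s$W, 2, tolerance = 1e-12)
  expect_equal(s$F, 0, tolerance = 1e-12)
  expect_equal(s$psi, 0, tolerance = 1e-9)
  expect_lt(s$residual, 1e-24)
  # all-zero signal: defined degenerate result
  z <- solve_voxel(c(0, 0, 0) + 0i, tau3, psi_init = 12)
  expect_equal(c(z$W, z$F, z$residual), c(0, 0, 0))
  expect_equal(z$psi, 12)
})

test_that("forward-simulated voxels are recovered to solver precision", {
  cases <- list(c(0.7, 0.3, 100), c(0.2, 0.8, -350), c(1, 0, 600),
                c(0.5, 0.5, 0), c(0.05, 0.95, 40))
  for (cs in cases) {
    sig <- fwd_wf_voxel(cs[1], cs[2], cs[3], tau3, fF)
    sol <- solve_voxel(sig, tau3, 0, ideal_settings(tol_hz = 1e-6, max_iter = 80))
    expect_equal(sol$W, cs[1], tolerance = 1e-6)
    expect_equal(sol$F, cs[2], tolerance = 1e-6)
    expect_equal(sol$psi, cs[3], tolerance = 1e-4)
  }
  # complex reference phase is absorbed: magnitudes unchanged
  sig <- fwd_wf_voxel(0.7, 0.3, 100, tau3, fF, phase0 = 1.3)
  sol <- solve_voxel(sig, tau3, 0, ideal_settings(tol_hz = 1e-6))
  expect_equal(sol$W, 0.7, tolerance = 1e-6)
  expect_equal(sol$F, 0.3, tolerance = 1e-6)
})

test_that("pure species admit an exact exchanged solution at psi - f_F", {
  # water at psi reinterpreted as fat at psi - f_F (and vice versa):
  # both fit with zero residual, equal to 1e-9; roles exchange
  for (cs in list(c(1, 0, 100), c(0, 1, -50))) {
    sig <- fwd_wf_voxel(cs[1], cs[2], cs[3], tau3, fF)
    a <- amp_solve_at_psi(sig, tau3, cs[3], fF)
    b <- amp_solve_at_psi(sig, tau3, cs[3] - sign(cs[1] - cs[2]) * fF, fF)
    expect_lt(abs(a$rss - b$rss), 1e-9)
    expect_lt(a$rss, 1e-18)
    expect_equal(Mod(b$rho[2]), cs[1], tolerance = 1e-9)  # roles exchanged
    expect_equal(Mod(b$rho[1]), cs[2], tolerance = 1e-9)
  }
  # mixed voxels: the exchanged candidate has strictly positive residual
  sig <- fwd_wf_voxel(0.7, 0.3, 100, tau3, fF)
  swap <- amp_solve_at_psi(sig, tau3, 100 - fF, fF)
  expect_gt(swap$rss, 1e-3)
})

test_that("the brute-force oracle is a global minimizer agreeing with the solver", {
  set.seed(101)
  n <- 100
  W <- runif(n); F <- runif(n); psi <- runif(n, -600, 600)
  S <- sapply(seq_len(n), function(i) fwd_wf_voxel(W[i], F[i], psi[i], tau3, fF))
  st <- ideal_settings(tol_hz = 1e-6, max_iter = 80)
  br <- brute_force_oracle(S, tau3, st, step_hz = 0.5, psi_init = 0)
  for (i in seq_len(n)) {
    sv <- solve_voxel(S[, i], tau3, 0, st)
    expect_lte(br$residual[i], sv$residual + 1e-9)
    # capture range: psi_true within +-|f_F|/2 of init -> agreement
    expect_lt(abs(br$psi[i] - sv$psi), 0.5 + 1e-9)
  }
  expect_lt(max(abs(br$psi - psi)), 0.5)
  expect_lt(max(abs(br$W - W)), 2e-3)
  # pure water voxel: psi at the grid point nearest 0, F ~ 0
  bw <- brute_force_oracle(fwd_wf_voxel(1, 0, 0.2, tau3, fF), tau3, st,
                           step_hz = 0.5)
  expect_lt(abs(bw$psi), 0.5)
  expect_lt(bw$F, 1e-3)
  expect_error(brute_force_oracle(S[, 1], tau3, st, step_hz = 2), "step")
})

test_that("scale equivariance and residual descent hold", {
  sig <- fwd_wf_voxel(0.6, 0.4, 250, tau3, fF)
  st <- ideal_settings(tol_hz = 1e-6)
  s1 <- solve_voxel(sig, tau3, 0, st)
  s2 <- solve_voxel(3.5 * sig, tau3, 0, st)
  expect_equal(s2$W / s1$W, 3.5, tolerance = 1e-9)
  expect_equal(s2$F / s1$F, 3.5, tolerance = 1e-9)
  expect_equal(s2$psi, s1$psi, tolerance = 1e-6)
  # residual at the returned solution never exceeds the init residual
  set.seed(202)
  for (i in 1:25) {
    sg <- fwd_wf_voxel(runif(1), runif(1), runif(1, -2000, 2000), tau3, fF) +
      complex(real = rnorm(3, 0, 0.05), imaginary = rnorm(3, 0, 0.05))
    p0 <- runif(1, -2000, 2000)
    sol <- solve_voxel(sg, tau3, p0)
    init <- amp_solve_at_psi(sg, tau3, p0, fF)
    expect_lte(sol$residual, init$rss + 1e-12)
  }
})

test_that("hierarchical solve recovers a +-600 Hz ramp without swaps", {
  cfg <- phantom_config(dim = c(16, 16, 16), seed = 31,
                        psi_coeff = c(c0 = 0, cx = 1200, cy = 0, cz = 0, cxx = 0))
  tr <- make_truth(cfg)
  mi <- simulate_wf_echoes(tr, acquisition_params(n_coils = 1, seed = 31))
  cc <- reference_to_first_echo(combine_coils(mi, "sum"))
  dec <- solve_volume_hierarchical(cc, ideal_settings())
  tis <- !tr$background
  expect_lt(max(abs(dec$psi - tr$psi)[tis]), 1)
  expect_true(all(dec$W >= 0) && all(dec$F >= 0))
  expect_true(all(dec$residual >= 0))
  # field map reported in the principal aliasing interval
  halfp <- 1000 / (2 * 0.23)
  expect_true(all(dec$psi >= -halfp & dec$psi < halfp))
})

test_that("an all-background volume decomposes to zero without error", {
  d <- c(8, 8, 8)
  cplx <- array(0i, c(d, 3))
  cc <- structure(list(magnitude = array(0, c(d, 3)), phase = array(0, c(d, 3)),
                       te_ms = c(3.08, 3.31, 3.54), spacing = c(1, 1, 1),
                       phase_mode = "sum", rel_phase = array(0, c(d, 3)),
                       cplx = cplx, tau_ms = tau3), class = "combined_echoes")
  dec <- solve_volume_hierarchical(cc, ideal_settings())
  expect_true(all(dec$W == 0) && all(dec$F == 0))
})

test_that("a uniform high-fat slab yields a spatially smooth field map", {
  cfg <- phantom_config(dim = c(16, 16, 16), seed = 33, ff_myocardium = 90,
                        ff_rim = 90, ff_cavity = 90, ff_patches = c(90),
                        psi_coeff = c(c0 = 300, cx = 400, cy = 0, cz = 0, cxx = 0))
  tr <- make_truth(cfg)
  mi <- simulate_wf_echoes(tr, acquisition_params(n_coils = 1, seed = 33))
  cc <- reference_to_first_echo(combine_coils(mi, "sum"))
  dec <- solve_volume_hierarchical(cc, ideal_settings())
  interior <- cardiofat3d:::erode3(!tr$background, 1L)
  med <- cardiofat3d:::median_filter3(dec$psi, 1L)
  expect_lt(max(abs(dec$psi - med)[interior]), abs(fF) / 2)
})

test_that("hierarchical estimates match the oracle on model-consistent volumes", {
  # constant-amplitude voxels (no echo-train decay): the continuous
  # global minimizer is the generating parameter set
  tr <- small_truth(seed = 35)
  d <- tr$dim
  cplx <- array(0i, c(d, 3))
  for (n in 1:3) {
    cplx[, , , n] <- (tr$W0 + tr$F0 * exp(1i * 2 * pi * fF * tau3[n] / 1000)) *
      exp(1i * 2 * pi * tr$psi * tau3[n] / 1000)
  }
  cc <- structure(list(magnitude = abs(cplx), phase = array(Arg(cplx), dim(cplx)),
                       te_ms = c(3.08, 3.31, 3.54), spacing = tr$spacing_mm,
                       phase_mode = "sum",
                       rel_phase = array(0, dim(cplx)), cplx = cplx,
                       tau_ms = tau3), class = "combined_echoes")
  dec <- solve_volume_hierarchical(cc, ideal_settings(tol_hz = 1e-3))
  tis <- which(!tr$background)
  set.seed(36)
  pick <- sample(tis, 100)
  S <- t(matrix(cplx, prod(d), 3))[, pick, drop = FALSE]
  br <- brute_force_oracle(S, tau3, ideal_settings(), step_hz = 0.5)
  expect_lt(max(abs(br$psi - dec$psi[pick])), 1)
  expect_lt(max(abs(br$W - dec$W[pick]) / pmax(dec$W[pick], 1e-3)), 1e-3)
  expect_lt(max(abs(br$F - dec$F[pick]) / pmax(dec$F[pick], 1e-3)), 1e-3)
})
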