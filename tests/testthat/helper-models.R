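## Shared forward models used as independent oracles: everything here is
## closed-form arithmetic, independent of the solver code paths.

## constant-amplitude water-fat voxel signal (the solver's model)
fwd_wf_voxel <- function(W, F, psi_hz, tau_ms, fat_offset_hz = -1361,
                         phase0 = 0) {
  (W + F * exp(1i * 2 * pi * fat_offset_hz * tau_ms / 1000)) *
    exp(1i * 2 * pi * psi_hz * tau_ms / 1000) * exp(1i * phase0)
}

## linear amplitude solve at fixed psi: independent re-implementation
## (normal equations written out) used to evaluate candidate solutions
amp_solve_at_psi <- function(signal, tau_ms, psi_hz, fat_offset_hz = -1361) {
  th <- 2 * pi * fat_offset_hz * tau_ms / 1000
  B <- cbind(rep(1 + 0i, length(tau_ms)), exp(1i * th))
  shat <- signal * exp(-1i * 2 * pi * psi_hz * tau_ms / 1000)
  rho <- qr.solve(B, shat)
  resid <- shat - B %*% rho
  list(rho = rho, rss = sum(Mod(resid)^2))
}

## spoiled-gradient-echo steady-state amplitude (closed form)
spgr_amp <- function(X0, t_ms, tr_ms, flip_deg, t1_ms, t2s_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  X0 * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-t_ms / t2s_ms)
}

## small default phantom used across tests
small_truth <- function(seed = 1L, dim = c(16L, 16L, 16L), ...) {
  make_truth(phantom_config(dim = dim, seed = seed, ...))
}

## mean per-coil echo-1 tissue magnitude, to convert SNR -> noise SD
tissue_signal_level <- function(truth, params) {
  m <- simulate_wf_echoes(truth, within_params(params, noise_sd = 0))
  mean(Mod(m$data[, , , , 1])[!truth$background])
}

within_params <- function(p, ...) {
  upd <- list(...)
  for (nm in names(upd)) p[[nm]] <- upd[[nm]]
  p
}
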