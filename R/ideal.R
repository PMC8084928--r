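## Water-fat-field-map decomposition (IDEAL) for 3-echo complex images.
##
## Per voxel, the signal model after referencing to the first echo is
##
##   s_n = (rho_w + rho_f exp(i 2 pi f_F tau_n)) exp(i 2 pi psi tau_n),
##
## with complex species amplitudes rho_w, rho_f (the echo-1 reference
## phase is unrecoverable and is absorbed by them), field offset psi in
## Hz and effective echo times tau_n in ms (tau_1 = 0). The field map is
## the only nonlinear parameter: for fixed psi the amplitudes are a
## linear least-squares solve, and psi is updated by Gauss-Newton on the
## projected (variable-projection) residual, with step halving so the
## residual never increases. A coarse-to-fine hierarchy anchors psi at
## low resolution to keep the field map on the smooth, swap-free branch.

#' Solver settings for the IDEAL decomposition
#'
#' @param fat_offset_hz water-fat frequency offset in Hz (fat below
#'   water; phase convention `exp(+i 2 pi f_F t)`). Default -1361 Hz,
#'   i.e. -3.4 ppm at a 400.2 MHz proton frequency (9.4 T).
#' @param max_iter maximum Gauss-Newton iterations per voxel.
#' @param tol_hz convergence tolerance on the field-map update (Hz).
#' @param coarsest smallest grid extent of the hierarchy (>= 4).
#' @param median_radius radius of the 3D median filter applied to the
#'   coarse field map before upsampling.
#' @param coarse_grid_step_hz step of the global field-map grid search
#'   run at the coarsest level (the few coarse voxels are cheap to scan
#'   over one full aliasing period); the grid minimizer seeds the
#'   Gauss-Newton refinement, anchoring uniform high-fat regions on the
#'   non-swapped branch. Ties go to the value nearest 0.
#' @return a list of class `ideal_settings`.
#' @export
ideal_settings <- function(fat_offset_hz = -1361, max_iter = 30L,
                           tol_hz = 0.1, coarsest = 4L, median_radius = 1L,
                           coarse_grid_step_hz = 10) {
  if (tol_hz <= 0) stop("tol_hz must be > 0", call. = FALSE)
  if (coarsest < 4L) stop("coarsest size must be >= 4", call. = FALSE)
  structure(list(fat_offset_hz = fat_offset_hz, max_iter = as.integer(max_iter),
                 tol_hz = tol_hz, coarsest = as.integer(coarsest),
                 median_radius = as.integer(median_radius),
                 coarse_grid_step_hz = coarse_grid_step_hz),
            class = "ideal_settings")
}

## fat basis matrix: columns span {water, fat} phasors at tau (ms)
ideal_basis <- function(tau_ms, fat_offset_hz) {
  th <- 2 * pi * fat_offset_hz * tau_ms / 1000
  B <- cbind(rep(1 + 0i, length(tau_ms)), exp(1i * th))
  Minv <- solve(Conj(t(B)) %*% B) %*% Conj(t(B))   # pseudo-inverse, 2 x n
  list(B = B, Minv = Minv, Q = diag(length(tau_ms)) - B %*% Minv)
}

## demodulate and solve the linear amplitude problem for all voxels
## S: n_echo x n_vox complex; psi: n_vox (Hz)
ideal_amplitudes <- function(S, psi, tau_ms, basis) {
  ph <- exp(-1i * 2 * pi * (tau_ms / 1000) %o% psi)
  Shat <- S * ph
  P <- basis$Minv %*% Shat
  R <- Shat - basis$B %*% P
  list(P = P, R = R, rss = colSums(Mod(R)^2))
}

## vectorized Gauss-Newton over voxels (variable projection in psi)
ideal_gauss_newton <- function(S, tau_ms, psi_init, settings) {
  basis <- ideal_basis(tau_ms, settings$fat_offset_hz)
  n <- ncol(S)
  psi <- psi_init
  st <- ideal_amplitudes(S, psi, tau_ms, basis)
  rss0 <- st$rss
  iters <- rep(0L, n)
  converged <- rep(FALSE, n)
  zero_sig <- colSums(Mod(S)^2) == 0
  converged[zero_sig] <- TRUE
  for (it in seq_len(settings$max_iter)) {
    act <- !converged
    if (!any(act)) break
    Model <- basis$B %*% st$P
    G <- (1i * 2 * pi * tau_ms / 1000) * Model
    QG <- basis$Q %*% G
    QR <- basis$Q %*% st$R
    den <- colSums(Mod(QG)^2)
    dpsi <- ifelse(den > 0, Re(colSums(Conj(QG) * QR)) / den, 0)
    dpsi[!act] <- 0
    psi_new <- psi + dpsi
    st_new <- ideal_amplitudes(S, psi_new, tau_ms, basis)
    # step halving where the residual got worse
    worse <- act & st_new$rss > st$rss + 1e-15
    half <- 0L
    while (any(worse) && half < 10L) {
      dpsi[worse] <- dpsi[worse] / 2
      psi_new[worse] <- psi[worse] + dpsi[worse]
      st2 <- ideal_amplitudes(S[, worse, drop = FALSE], psi_new[worse],
                              tau_ms, basis)
      st_new$rss[worse] <- st2$rss
      st_new$P[, worse] <- st2$P
      st_new$R[, worse] <- st2$R
      worse <- act & st_new$rss > st$rss + 1e-15
      half <- half + 1L
    }
    if (any(worse)) {             # keep previous iterate where no descent
      dpsi[worse] <- 0
      psi_new[worse] <- psi[worse]
      stk <- ideal_amplitudes(S[, worse, drop = FALSE], psi[worse], tau_ms, basis)
      st_new$rss[worse] <- stk$rss
      st_new$P[, worse] <- stk$P
      st_new$R[, worse] <- stk$R
    }
    iters[act] <- it
    newly <- act & abs(dpsi) < settings$tol_hz
    converged[newly] <- TRUE
    psi <- psi_new
    st <- st_new
  }
  # safeguard: never return worse than the initialization
  regress <- st$rss > rss0 + 1e-15
  if (any(regress)) {
    psi[regress] <- psi_init[regress]
    stk <- ideal_amplitudes(S[, regress, drop = FALSE], psi[regress], tau_ms, basis)
    st$rss[regress] <- stk$rss
    st$P[, regress] <- stk$P
  }
  psi[zero_sig] <- psi_init[zero_sig]
  st$P[, zero_sig] <- 0
  st$rss[zero_sig] <- 0
  list(W = Mod(st$P[1, ]), F = Mod(st$P[2, ]), psi = psi, rss = st$rss,
       iterations = iters, converged = converged)
}

#' Solve the water-fat model for a single voxel
#'
#' Alternates a linear least-squares solve for the complex water/fat
#' amplitudes with a linearized (Gauss-Newton) field-map update until the
#' update falls below `tol_hz` or `max_iter` is reached. An all-zero
#' signal returns W = F = 0, `psi = psi_init`, residual 0.
#'
#' @param signal complex vector, one value per echo (>= 3).
#' @param tau_ms effective echo times in ms; `tau_ms[1]` must be 0.
#' @param psi_init starting field-map value, Hz.
#' @param settings an [ideal_settings()] object.
#' @return list with `W`, `F` (amplitude magnitudes), `psi` (Hz, wrapped
#'   to the principal aliasing interval), `residual` (sum of squared
#'   misfit), `iterations`, `converged`.
#' @export
solve_voxel <- function(signal, tau_ms, psi_init = 0,
                        settings = ideal_settings()) {
  if (length(signal) < 3L) stop("need >= 3 echoes", call. = FALSE)
  if (tau_ms[1] != 0) stop("tau_ms[1] must be 0 (echo-1 referenced)", call. = FALSE)
  S <- matrix(as.complex(signal), ncol = 1)
  sol <- ideal_gauss_newton(S, tau_ms, psi_init, settings)
  period <- 1000 / (tau_ms[2] - tau_ms[1])
  list(W = sol$W, F = sol$F, psi = wrap_freq(sol$psi, period),
       residual = sol$rss, iterations = sol$iterations,
       converged = sol$converged)
}

#' Global brute-force water-fat solution over a field-map grid
#'
#' Independent oracle: for every psi on a regular grid spanning one full
#' aliasing period, solves the linear amplitude problem and returns the
#' global residual minimizer. Ties (within 1e-9 relative) go to the psi
#' closest to `psi_init`.
#'
#' @param signal complex vector (one voxel) or `n_echo x n_vox` matrix.
#' @param tau_ms effective echo times ms (`tau_ms[1] == 0`).
#' @param settings an [ideal_settings()] (fat offset is used).
#' @param step_hz grid step, must be <= 1 Hz.
#' @param psi_init tie-break reference (Hz).
#' @param refine polish the grid minimum with a derivative-free 1D
#'   minimization of the residual over `best +- step` (golden section /
#'   parabolic, [stats::optimize()]), so the oracle attains the
#'   continuous minimum rather than the nearest grid point.
#' @return list of vectors `W`, `F`, `psi`, `residual`.
#' @export
brute_force_oracle <- function(signal, tau_ms, settings = ideal_settings(),
                               step_hz = 0.5, psi_init = 0, refine = TRUE) {
  if (step_hz > 1) stop("grid step must be <= 1 Hz", call. = FALSE)
  S <- if (is.matrix(signal)) signal else matrix(as.complex(signal), ncol = 1)
  basis <- ideal_basis(tau_ms, settings$fat_offset_hz)
  period <- 1000 / (tau_ms[2] - tau_ms[1])
  grid <- seq(-period / 2, period / 2, by = step_hz)
  n <- ncol(S)
  scale <- pmax(colSums(Mod(S)^2), 1)
  best <- list(rss = rep(Inf, n), psi = rep(0, n),
               W = rep(0, n), F = rep(0, n))
  for (g in grid) {
    st <- ideal_amplitudes(S, rep(g, n), tau_ms, basis)
    better <- st$rss < best$rss - 1e-9 * scale
    tie <- !better & st$rss <= best$rss + 1e-9 * scale &
      abs(g - psi_init) < abs(best$psi - psi_init)
    upd <- better | tie
    if (any(upd)) {
      best$rss[upd] <- st$rss[upd]
      best$psi[upd] <- g
      best$W[upd] <- Mod(st$P[1, upd])
      best$F[upd] <- Mod(st$P[2, upd])
    }
  }
  if (refine) {
    for (v in seq_len(n)) {
      sv <- S[, v, drop = FALSE]
      rss_at <- function(p) ideal_amplitudes(sv, p, tau_ms, basis)$rss
      op <- stats::optimize(rss_at, best$psi[v] + c(-step_hz, step_hz),
                            tol = 1e-10)
      if (op$objective <= best$rss[v]) {
        st <- ideal_amplitudes(sv, op$minimum, tau_ms, basis)
        best$psi[v] <- op$minimum
        best$rss[v] <- st$rss
        best$W[v] <- Mod(st$P[1, 1])
        best$F[v] <- Mod(st$P[2, 1])
      }
    }
  }
  list(W = best$W, F = best$F, psi = best$psi, residual = best$rss)
}

## residual-minimizing psi over a regular grid spanning one aliasing
## period (vectorized over voxels); ties prefer psi nearest 0
coarse_grid_search <- function(S, tau_ms, settings) {
  basis <- ideal_basis(tau_ms, settings$fat_offset_hz)
  period <- 1000 / (tau_ms[2] - tau_ms[1])
  grid <- seq(-period / 2, period / 2, by = settings$coarse_grid_step_hz)
  n <- ncol(S)
  scale <- pmax(colSums(Mod(S)^2), 1)
  best_rss <- rep(Inf, n)
  best_psi <- rep(0, n)
  for (g in grid) {
    st <- ideal_amplitudes(S, rep(g, n), tau_ms, basis)
    better <- st$rss < best_rss - 1e-9 * scale
    tie <- !better & st$rss <= best_rss + 1e-9 * scale & abs(g) < abs(best_psi)
    upd <- better | tie
    if (any(upd)) {
      best_rss[upd] <- st$rss[upd]
      best_psi[upd] <- g
    }
  }
  best_psi
}

#' Hierarchical water-fat-field-map decomposition of a combined volume
#'
#' Builds a dyadic pyramid by complex block-averaging each echo image
#' (factor 2 per level) down to the coarsest grid, anchors the field map
#' there with a global grid search over one aliasing period followed by
#' Gauss-Newton refinement, and at every finer level median-filters the
#' coarser field map, upsamples it trilinearly and uses it as the
#' per-voxel initialization. Grids
#' smaller than 8 in any axis are solved in a single level.
#'
#' @param combined a `combined_echoes` object that has been through
#'   [reference_to_first_echo()].
#' @param settings an [ideal_settings()] object.
#' @return object of class `wf_decomposition`: 3D arrays `W`, `F`
#'   (amplitude magnitudes), `psi` (field map Hz, principal interval),
#'   `residual`, `iterations`, logical `converged`, plus `tau_ms`,
#'   `spacing` and a `quality` summary (non-converged voxel count).
#' @export
solve_volume_hierarchical <- function(combined, settings = ideal_settings()) {
  if (is.null(combined$cplx)) {
    stop("run reference_to_first_echo() before the decomposition", call. = FALSE)
  }
  cplx <- combined$cplx
  d <- dim(cplx)[1:3]
  ne <- dim(cplx)[4]
  tau <- combined$tau_ms
  # pyramid of complex echo volumes (level 1 = native)
  levels <- list(cplx)
  dd <- d
  while (min(dd) >= 8L && all(dd %% 2L == 0L) && min(dd) / 2L >= settings$coarsest) {
    prev <- levels[[length(levels)]]
    dd <- dd %/% 2L
    nxt <- array(0i, c(dd, ne))
    for (n in seq_len(ne)) nxt[, , , n] <- block_average(prev[, , , n], 2L)
    levels[[length(levels) + 1L]] <- nxt
  }
  nl <- length(levels)
  psi <- NULL
  for (lv in rev(seq_len(nl))) {
    vol <- levels[[lv]]
    dl <- dim(vol)[1:3]
    S <- t(matrix(vol, prod(dl), ne))        # n_echo x n_vox
    if (is.null(psi)) {
      # coarsest level: global grid search over one aliasing period
      # (ties -> psi nearest 0), then Gauss-Newton refinement
      grid_init <- coarse_grid_search(S, tau, settings)
      sol <- ideal_gauss_newton(S, tau, grid_init, settings)
    } else {
      init <- upsample_trilinear(psi, dl)
      sol <- ideal_gauss_newton(S, tau, as.vector(init), settings)
    }
    psi <- array(sol$psi, dl)
    if (lv > 1L && settings$median_radius >= 1L) {
      psi <- median_filter3(psi, settings$median_radius)
    }
  }
  period <- 1000 / (tau[2] - tau[1])
  out <- list(
    W = array(sol$W, d), F = array(sol$F, d),
    psi = array(wrap_freq(sol$psi, period), d),
    residual = array(sol$rss, d),
    iterations = array(sol$iterations, d),
    converged = array(sol$converged, d),
    tau_ms = tau, te_ms = combined$te_ms, spacing = combined$spacing,
    quality = list(n_voxels = prod(d),
                   n_nonconverged = sum(!sol$converged),
                   levels = nl)
  )
  class(out) <- "wf_decomposition"
  out
}

#' @export
print.wf_decomposition <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("<wf_decomposition> %dx%dx%d, %d pyramid level(s), %d/%d non-converged voxels\n",
              d[1], d[2], d[3], x$quality$levels,
              x$quality$n_nonconverged, x$quality$n_voxels))
  invisible(x)
}

#' Write a water-fat decomposition as NIfTI volumes
#'
#' Writes `water.nii.gz`, `fat.nii.gz`, `fieldmap_hz.nii.gz` and
#' `residual.nii.gz` into `dir`.
#'
#' @param decomp a `wf_decomposition`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- decomp$spacing
  write_nifti_volume(decomp$W, file.path(dir, "water.nii.gz"), sp)
  write_nifti_volume(decomp$F, file.path(dir, "fat.nii.gz"), sp)
  write_nifti_volume(decomp$psi, file.path(dir, "fieldmap_hz.nii.gz"), sp)
  write_nifti_volume(decomp$residual, file.path(dir, "residual.nii.gz"), sp)
  invisible(dir)
}
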