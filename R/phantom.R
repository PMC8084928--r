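## Digital heart phantom with full ground truth.
##
## Concentric-ellipsoid geometry emulating an ex vivo heart immersed in a
## signal-free medium: a zero-signal background, an epicardial fat rim,
## myocardium with a low fat fraction, and ellipsoidal fibro-fatty
## infiltration patches at intermediate fat fractions. The forward model
## generates every acquisition the pipeline consumes: per-coil complex
## spoiled-gradient-echo echoes (water-fat imaging), magnetization
## transfer on/off magnitude pairs on a coarser grid, and
## saturation-recovery / multi-gradient-echo relaxometry series.

#' Phantom configuration
#'
#' @param dim grid size, length 3, each >= 8.
#' @param spacing_mm voxel spacing in mm.
#' @param ff_myocardium,ff_rim fat fractions (%) of myocardium and of the
#'   epicardial fat rim.
#' @param ff_cavity fat fraction (%) of the ventricular cavity content
#'   (near-pure water by default).
#' @param ff_patches fat fractions (%) of the fibro-fatty infiltration
#'   patches placed inside the myocardium.
#' @param mtr_myocardium,mtr_rim,mtr_fibrosis true magnetization-transfer
#'   ratios (%) of normal myocardium, fat, and fibrotic patches. Fat
#'   shows essentially no transfer (ratio near 100); fibrosis is modelled
#'   as a distinct ratio on patches co-located with the fatty
#'   infiltrations.
#' @param proton_density total proton density of tissue (arbitrary units).
#' @param t1w_ms,t1f_ms,t2sw_ms,t2sf_ms species relaxation times (ms) for
#'   water and fat protons. Defaults are plausible for fixed, Gd-doped
#'   tissue and are configurable; they are inputs of the simulation, not
#'   measured values.
#' @param psi_coeff field-map polynomial coefficients, Hz: `c0` constant,
#'   `cx`, `cy`, `cz` linear terms across the volume (full-width span),
#'   `cxx` quadratic in x. The resulting map is spatially smooth.
#' @param n_coils number of receive coils simulated.
#' @param seed integer seed making every generated volume reproducible.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(32L, 32L, 32L), spacing_mm = c(0.2, 0.2, 0.2),
                           ff_myocardium = 5, ff_rim = 90, ff_cavity = 1,
                           ff_patches = c(45, 55, 70),
                           mtr_myocardium = 60, mtr_rim = 98, mtr_fibrosis = 85,
                           proton_density = 1,
                           t1w_ms = 250, t1f_ms = 150,
                           t2sw_ms = 20, t2sf_ms = 15,
                           psi_coeff = c(c0 = 0, cx = 200, cy = 120, cz = 80, cxx = 40),
                           n_coils = 4L, seed = 1L) {
  dim <- as.integer(dim)
  if (any(dim < 8L)) stop("grid dimension < 8 in some axis (hierarchy needs >= 2 levels)", call. = FALSE)
  structure(as.list(environment()), class = "phantom_config")
}

#' Acquisition parameters for the water-fat simulation
#'
#' @param tr_ms repetition time, ms.
#' @param te_ms echo times, ms, strictly increasing, >= 3 values.
#' @param flip_deg flip angle in degrees, in (0, 90].
#' @param fat_offset_hz water-fat frequency offset (Hz); fat resonates
#'   below water, phase convention `exp(+i 2 pi f_F t)`.
#' @param n_coils number of receive coils.
#' @param noise_sd complex Gaussian noise SD per channel (per real and
#'   imaginary component), in signal units.
#' @param seed RNG seed.
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(tr_ms = 30, te_ms = c(3.08, 3.31, 3.54),
                               flip_deg = 17, fat_offset_hz = -1361,
                               n_coils = 4L, noise_sd = 0, seed = 1L) {
  if (length(te_ms) < 3L) stop("need >= 3 echoes for water-fat simulation", call. = FALSE)
  if (any(diff(te_ms) <= 0)) stop("echo times must be strictly increasing", call. = FALSE)
  if (flip_deg <= 0 || flip_deg > 90) stop("flip angle must be in (0, 90]", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "acquisition_params")
}

## normalized coordinates in [-1, 1] per axis
norm_coords <- function(dim) {
  ax <- function(n) if (n > 1) (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2) else 0
  list(x = ax(dim[1]), y = ax(dim[2]), z = ax(dim[3]))
}

## ellipsoid membership: ((x-c1)/r1)^2 + ... <= 1, in normalized coords
ellipsoid_mask <- function(dim, center, radii) {
  co <- norm_coords(dim)
  dx2 <- ((co$x - center[1]) / radii[1])^2
  dy2 <- ((co$y - center[2]) / radii[2])^2
  dz2 <- ((co$z - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a ground-truth heart phantom
#'
#' Deterministic for a fixed config (the seed controls patch placement
#' jitter). Geometry: outer ellipsoid = epicardial fat rim; a concentric
#' inner ellipsoid = myocardium (low fat fraction) containing a central
#' cavity; fibro-fatty patches are small ellipsoids inside the
#' myocardial shell. Everything outside the outer ellipsoid is
#' zero-signal background.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom_truth` with fields `dim`,
#'   `spacing_mm`, `W0`, `F0` (proton-density maps, >= 0), `ff_true`
#'   (percent, `100*F0/(W0+F0)` where tissue), `t1w_ms`, `t1f_ms`,
#'   `t2sw_ms`, `t2sf_ms`, `psi` (Hz), `mtr_true` (%), `coils` (complex
#'   4D `[x,y,z,coil]`), `background` (logical), `compartments`
#'   (integer: 0 background, 1 myocardium, 2 fat rim, 3 cavity,
#'   4+ patches).
#' @export
make_truth <- function(config = phantom_config()) {
  if (any(config$dim < 8L)) stop("grid dimension < 8", call. = FALSE)
  set.seed(derive_seed(config$seed, 11L))
  d <- config$dim
  outer_m <- ellipsoid_mask(d, c(0, 0, 0), c(0.92, 0.88, 0.90))
  myo_m   <- ellipsoid_mask(d, c(0, 0, 0), c(0.68, 0.64, 0.66))
  cav_m   <- ellipsoid_mask(d, c(0.05, 0, 0), c(0.30, 0.26, 0.28))
  comp <- array(0L, d)
  comp[outer_m] <- 2L                 # fat rim
  comp[myo_m] <- 1L                   # myocardium
  comp[cav_m & myo_m] <- 3L           # cavity (fluid, water-like)
  # fibro-fatty patches in the myocardial shell, jittered placement
  n_patch <- length(config$ff_patches)
  patch_ff <- config$ff_patches
  base_centers <- list(c(0.45, 0.25, 0.0), c(-0.35, -0.35, 0.25), c(0.0, 0.45, -0.3))
  for (p in seq_len(n_patch)) {
    ctr <- base_centers[[(p - 1L) %% length(base_centers) + 1L]] +
      stats::runif(3, -0.04, 0.04)
    pm <- ellipsoid_mask(d, ctr, c(0.16, 0.15, 0.17))
    sel <- pm & comp == 1L
    comp[sel] <- 3L + p
  }
  ff <- array(0, d)
  ff[comp == 1L] <- config$ff_myocardium
  ff[comp == 2L] <- config$ff_rim
  ff[comp == 3L] <- config$ff_cavity
  for (p in seq_len(n_patch)) ff[comp == 3L + p] <- patch_ff[p]
  tissue <- comp > 0L
  W0 <- array(0, d); F0 <- array(0, d)
  W0[tissue] <- config$proton_density * (1 - ff[tissue] / 100)
  F0[tissue] <- config$proton_density * (ff[tissue] / 100)
  ff_true <- array(0, d)
  ff_true[tissue] <- 100 * F0[tissue] / (W0[tissue] + F0[tissue])
  mtr <- array(0, d)
  mtr[comp == 1L] <- config$mtr_myocardium
  mtr[comp == 2L] <- config$mtr_rim
  mtr[comp == 3L] <- config$mtr_myocardium
  for (p in seq_len(n_patch)) mtr[comp == 3L + p] <- config$mtr_fibrosis
  # smooth polynomial field map (Hz); coefficients span the full width
  co <- norm_coords(d)
  pc <- config$psi_coeff
  pc <- pc[c("c0", "cx", "cy", "cz", "cxx")]
  pc[is.na(pc)] <- 0
  psi <- pc[1] +
    outer(outer(pc[2] * co$x / 2, pc[3] * co$y / 2, "+"), pc[4] * co$z / 2, "+") +
    outer(outer(pc[5] * (co$x^2) / 2, rep(0, d[2]), "+"), rep(0, d[3]), "+")
  # smooth complex coil sensitivities: gaussian magnitude lobes at the
  # volume corners with coil-specific constant phases
  nc <- as.integer(config$n_coils)
  coils <- array(0i, c(d, nc))
  corner <- rbind(c(1, 1, 1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, 1),
                  c(1, 1, -1), c(-1, -1, -1))
  for (cix in seq_len(nc)) {
    cc <- corner[(cix - 1L) %% nrow(corner) + 1L, ] * 0.9
    r2 <- outer(outer((co$x - cc[1])^2, (co$y - cc[2])^2, "+"), (co$z - cc[3])^2, "+")
    m <- 0.4 + exp(-r2 / 1.8)
    phs <- 2 * pi * (cix - 1) / nc
    coils[, , , cix] <- m * exp(1i * phs)
  }
  structure(list(
    dim = d, spacing_mm = config$spacing_mm,
    W0 = W0, F0 = F0, ff_true = ff_true,
    t1w_ms = config$t1w_ms, t1f_ms = config$t1f_ms,
    t2sw_ms = config$t2sw_ms, t2sf_ms = config$t2sf_ms,
    psi = psi, mtr_true = mtr, coils = coils,
    background = !tissue, compartments = comp,
    config = config
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s @ %s mm, %d coils, %d tissue voxels\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              dim(x$coils)[4], sum(!x$background)))
  invisible(x)
}

## spoiled-gradient-echo steady-state amplitude for species X at echo t
spgr_amplitude <- function(X0, t_ms, tr_ms, flip_deg, t1_ms, t2s_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  X0 * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-t_ms / t2s_ms)
}

#' Simulate per-coil complex water-fat echoes from a phantom
#'
#' Forward model per coil c and echo n:
#' `s = C_c (A_w(t_n) + A_f(t_n) exp(i 2 pi f_F t_n)) exp(i 2 pi psi t_n) + eps`,
#' with spoiled-gradient-echo steady-state amplitudes
#' `A_x(t) = X0 sin(a) (1 - E1x) / (1 - cos(a) E1x) exp(-t / T2*_x)`,
#' `E1x = exp(-TR / T1x)`, and complex Gaussian noise of the configured
#' SD per channel (seeded).
#'
#' @param truth a [make_truth()] result.
#' @param params an [acquisition_params()]; its `n_coils` must not exceed
#'   the number of simulated coil maps.
#' @return a [multi_echo_image()].
#' @export
simulate_wf_echoes <- function(truth, params = acquisition_params()) {
  d <- truth$dim
  if (params$noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  nc <- as.integer(params$n_coils)
  if (nc > dim(truth$coils)[4]) {
    stop("params$n_coils exceeds the phantom's simulated coil maps", call. = FALSE)
  }
  ne <- length(params$te_ms)
  set.seed(derive_seed(params$seed, 23L))
  out <- array(0i, c(d, nc, ne))
  ph_fat <- exp(1i * 2 * pi * params$fat_offset_hz * params$te_ms / 1000)
  for (n in seq_len(ne)) {
    t_n <- params$te_ms[n]
    Aw <- spgr_amplitude(truth$W0, t_n, params$tr_ms, params$flip_deg,
                         truth$t1w_ms, truth$t2sw_ms)
    Af <- spgr_amplitude(truth$F0, t_n, params$tr_ms, params$flip_deg,
                         truth$t1f_ms, truth$t2sf_ms)
    base <- (Aw + Af * ph_fat[n]) * exp(1i * 2 * pi * truth$psi * t_n / 1000)
    for (cix in seq_len(nc)) {
      s <- truth$coils[, , , cix] * base
      if (params$noise_sd > 0) {
        s <- s + complex(real = stats::rnorm(prod(d), 0, params$noise_sd),
                         imaginary = stats::rnorm(prod(d), 0, params$noise_sd))
      }
      out[, , , cix, n] <- s
    }
  }
  multi_echo_image(out, params$te_ms, truth$spacing_mm)
}

#' Simulate a magnetization-transfer on/off magnitude pair
#'
#' Both volumes live on a grid coarser by `factor` (block-averaged
#' truth). `MT_off` is the block-averaged total proton density
#' `W0 + F0`; `MT_on = MT_off * mtr/100` with `mtr` the block-averaged
#' true ratio; seeded Gaussian noise is added to the magnitudes. The MT
#' preparation is simulated at the ratio level, not at spin level: the
#' downstream pipeline only consumes the on/off ratio.
#'
#' @param truth a [make_truth()] result.
#' @param noise_sd magnitude noise SD.
#' @param factor integer downsampling factor; must divide the grid.
#' @param seed RNG seed.
#' @return list with magnitude arrays `mt_on`, `mt_off`, the coarse-grid
#'   `mtr_true`, `spacing_mm` of the coarse grid and `factor`.
#' @export
simulate_mt_pair <- function(truth, noise_sd = 0, factor = 2L, seed = 1L) {
  d <- truth$dim
  factor <- as.integer(factor)
  if (any(d %% factor != 0L)) {
    stop(sprintf("factor %d does not divide grid %s", factor,
                 paste(d, collapse = "x")), call. = FALSE)
  }
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  set.seed(derive_seed(seed, 37L))
  off <- block_average(truth$W0 + truth$F0, factor)
  mtr_c <- block_average(truth$mtr_true, factor)
  on <- off * mtr_c / 100
  if (noise_sd > 0) {
    on <- on + array(stats::rnorm(length(on), 0, noise_sd), dim(on))
    off <- off + array(stats::rnorm(length(off), 0, noise_sd), dim(off))
  }
  list(mt_on = on, mt_off = off, mtr_true = mtr_c,
       spacing_mm = truth$spacing_mm * factor, factor = factor)
}

#' Simulate saturation-recovery and multi-gradient-echo relaxometry series
#'
#' Saturation recovery: `S(TR) = k S0 (1 - exp(-TR/T1))`; multi-gradient
#' echo: `S(TE) = k S0 exp(-TE/T2*)`. Each voxel carries one effective
#' T1 and T2*, the fat-fraction-weighted harmonic blend of the species
#' values (arithmetic mixing of rates), because the downstream fits are
#' mono-exponential. `k S0 = W0 + F0`.
#'
#' @param truth a [make_truth()] result.
#' @param tr_list_ms saturation-recovery repetition times, ms.
#' @param te_list_ms gradient-echo times, ms (default 8 echoes from 4 ms,
#'   5 ms spacing).
#' @param noise_sd magnitude noise SD.
#' @param seed RNG seed.
#' @return list with 4D arrays `satrec` `[x,y,z,TR]` and `mge`
#'   `[x,y,z,TE]`, the generating `t1_eff`, `t2s_eff`, `ks0` maps and the
#'   time lists.
#' @export
simulate_relaxometry_series <- function(truth,
                                        tr_list_ms = c(200, 400, 800, 1500, 5000, 10000),
                                        te_list_ms = seq(4, by = 5, length.out = 8),
                                        noise_sd = 0, seed = 1L) {
  if (length(tr_list_ms) == 0L || length(te_list_ms) == 0L) {
    stop("TR/TE lists must be non-empty", call. = FALSE)
  }
  set.seed(derive_seed(seed, 53L))
  d <- truth$dim
  tot <- truth$W0 + truth$F0
  wfrac <- ifelse(tot > 0, truth$W0 / tot, 0)
  ffrac <- 1 - wfrac
  t1_eff <- ifelse(tot > 0,
                   1 / (wfrac / truth$t1w_ms + ffrac / truth$t1f_ms), NA_real_)
  t2s_eff <- ifelse(tot > 0,
                    1 / (wfrac / truth$t2sw_ms + ffrac / truth$t2sf_ms), NA_real_)
  satrec <- array(0, c(d, length(tr_list_ms)))
  for (i in seq_along(tr_list_ms)) {
    s <- ifelse(tot > 0, tot * (1 - exp(-tr_list_ms[i] / t1_eff)), 0)
    if (noise_sd > 0) s <- s + array(stats::rnorm(prod(d), 0, noise_sd), d)
    satrec[, , , i] <- s
  }
  mge <- array(0, c(d, length(te_list_ms)))
  for (i in seq_along(te_list_ms)) {
    s <- ifelse(tot > 0, tot * exp(-te_list_ms[i] / t2s_eff), 0)
    if (noise_sd > 0) s <- s + array(stats::rnorm(prod(d), 0, noise_sd), d)
    mge[, , , i] <- s
  }
  list(satrec = satrec, mge = mge,
       t1_eff = array(t1_eff, d), t2s_eff = array(t2s_eff, d),
       ks0 = tot, tr_list_ms = tr_list_ms, te_list_ms = te_list_ms)
}

#' Write a phantom and its simulated acquisitions to disk
#'
#' Writes all volumes as NIfTI (complex echoes as `_real`/`_imag` pairs)
#' plus a JSON sidecar with the ground-truth scalars and the echoed
#' configuration.
#'
#' @param truth a [make_truth()] result.
#' @param params an [acquisition_params()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(truth, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- truth$spacing_mm
  write_nifti_volume(truth$W0, file.path(dir, "truth_w0.nii.gz"), sp)
  write_nifti_volume(truth$F0, file.path(dir, "truth_f0.nii.gz"), sp)
  write_nifti_volume(truth$ff_true, file.path(dir, "truth_ff.nii.gz"), sp)
  write_nifti_volume(truth$psi, file.path(dir, "truth_psi_hz.nii.gz"), sp)
  write_nifti_volume(truth$mtr_true, file.path(dir, "truth_mtr.nii.gz"), sp)
  multi <- simulate_wf_echoes(truth, params)
  d <- dim(multi$data)
  for (cix in seq_len(d[4])) for (n in seq_len(d[5])) {
    write_complex_nifti(multi$data[, , , cix, n],
                        file.path(dir, sprintf("echo_c%02d_e%d", cix, n)), sp)
  }
  side <- list(
    dim = truth$dim, spacing_mm = sp,
    te_ms = params$te_ms, tr_ms = params$tr_ms, flip_deg = params$flip_deg,
    fat_offset_hz = params$fat_offset_hz, n_coils = params$n_coils,
    noise_sd = params$noise_sd, seed = params$seed,
    t1w_ms = truth$t1w_ms, t1f_ms = truth$t1f_ms,
    t2sw_ms = truth$t2sw_ms, t2sf_ms = truth$t2sf_ms
  )
  write_json_sidecar(side, file.path(dir, "phantom.json"))
  invisible(dir)
}
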