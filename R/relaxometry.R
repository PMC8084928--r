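## Pixel-wise T1 (saturation recovery) and T2* (multi-gradient-echo)
## mapping. Fits are per-voxel nonlinear least squares (Levenberg-
## Marquardt); voxels below the signal floor, with degenerate series or
## non-converging fits are flagged invalid, never silently zeroed.
## Magnitude (Rician) noise bias is not corrected.

## normalize series input (vector / matrix / 3D+time 4D array) to an
## n_vox x n_pts matrix plus the original spatial dim
series_matrix <- function(series, n_pts) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  d <- dim(series)
  if (length(d) == 2L) {
    if (d[2] != n_pts) stop("series columns must match time points", call. = FALSE)
    list(m = series, sdim = c(d[1], 1L, 1L))
  } else if (length(d) == 4L) {
    if (d[4] != n_pts) stop("4th dimension must match time points", call. = FALSE)
    list(m = matrix(series, prod(d[1:3]), d[4]), sdim = d[1:3])
  } else {
    stop("series must be a vector, n_vox x n_pts matrix, or [x,y,z,t] array",
         call. = FALSE)
  }
}

relaxation_maps <- function(est, sdim, what) {
  shape <- function(v) array(v, sdim)
  structure(list(
    t1 = if (what == "t1") shape(est$tau) else NULL,
    t2star = if (what == "t2star") shape(est$tau) else NULL,
    ks0 = shape(est$ks0),
    residual = shape(est$resid),
    valid = shape(est$valid),
    what = what
  ), class = "relaxation_maps")
}

#' @export
print.relaxation_maps <- function(x, ...) {
  cat(sprintf("<relaxation_maps> %s map, %d/%d valid voxels\n",
              toupper(x$what), sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Fit a T1 map from a saturation-recovery series
#'
#' Per-voxel Levenberg-Marquardt fit of `S(TR) = k S0 (1 - exp(-TR/T1))`.
#' Initialization: `k S0` from the maximum signal; T1 from the first TR
#' reaching half of the maximum, divided by `log(2)`. Voxels whose peak
#' signal is below `signal_floor`, whose series is degenerate (no
#' recovery contrast), or whose fit fails to converge are flagged
#' invalid.
#'
#' @param series saturation-recovery magnitudes: vector (one voxel),
#'   `n_vox x n_TR` matrix, or `[x,y,z,TR]` array.
#' @param tr_ms repetition times in ms, strictly increasing, >= 3 values.
#' @param signal_floor validity floor on the per-voxel maximum signal
#'   (e.g. 3x the background noise SD).
#' @return a `relaxation_maps` object with `t1`, `ks0`, `residual`
#'   (residual norm) and logical `valid`.
#' @export
fit_t1_map <- function(series, tr_ms, signal_floor = 0) {
  if (length(tr_ms) < 3L) stop("need >= 3 TR points", call. = FALSE)
  if (any(diff(tr_ms) <= 0)) stop("TRs must be strictly increasing", call. = FALSE)
  sm <- series_matrix(series, length(tr_ms))
  n <- nrow(sm$m)
  est <- list(tau = rep(NA_real_, n), ks0 = rep(NA_real_, n),
              resid = rep(NA_real_, n), valid = rep(FALSE, n))
  for (v in seq_len(n)) {
    y <- sm$m[v, ]
    ymax <- max(y)
    if (!is.finite(ymax) || ymax <= signal_floor) next
    if (diff(range(y)) <= 1e-12 * max(abs(ymax), 1)) next  # constant series
    half_idx <- which(y >= ymax / 2)[1]
    t1_init <- max(tr_ms[half_idx] / log(2), tr_ms[1] / 10)
    dat <- data.frame(tr = tr_ms, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ k * (1 - exp(-tr / t1)), data = dat,
                        start = list(k = ymax, t1 = t1_init),
                        lower = c(k = 0, t1 = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (!all(is.finite(cf)) || cf["t1"] <= 0) next
    est$tau[v] <- cf[["t1"]]
    est$ks0[v] <- cf[["k"]]
    est$resid[v] <- sqrt(sum(stats::resid(fit)^2))
    est$valid[v] <- TRUE
  }
  relaxation_maps(est, sm$sdim, "t1")
}

#' Fit a T2* map from a multi-gradient-echo series
#'
#' Per-voxel fit of `S(TE) = k S0 exp(-TE/T2*)`: log-linear regression on
#' the positive signals for initialization, then Levenberg-Marquardt
#' refinement. Voxels with fewer than two positive signals, a peak below
#' `signal_floor`, or a non-converging fit are flagged invalid.
#'
#' @param series gradient-echo magnitudes (same shapes as
#'   [fit_t1_map()]).
#' @param te_ms echo times in ms, strictly increasing, >= 3 values.
#' @param signal_floor validity floor on the per-voxel maximum signal.
#' @return a `relaxation_maps` object with `t2star`, `ks0`, `residual`,
#'   `valid`.
#' @export
fit_t2star_map <- function(series, te_ms, signal_floor = 0) {
  if (length(te_ms) < 3L) stop("need >= 3 echoes", call. = FALSE)
  if (any(diff(te_ms) <= 0)) stop("TEs must be strictly increasing", call. = FALSE)
  sm <- series_matrix(series, length(te_ms))
  n <- nrow(sm$m)
  est <- list(tau = rep(NA_real_, n), ks0 = rep(NA_real_, n),
              resid = rep(NA_real_, n), valid = rep(FALSE, n))
  for (v in seq_len(n)) {
    y <- sm$m[v, ]
    if (!all(is.finite(y)) || max(y) <= signal_floor) next
    pos <- y > 0
    if (sum(pos) < 2L) next            # all (or nearly all) excluded
    ll <- stats::lm.fit(cbind(1, te_ms[pos]), log(y[pos]))
    slope <- unname(ll$coefficients[2])
    t2_init <- if (is.finite(slope) && slope < 0) -1 / slope else max(te_ms)
    k_init <- unname(exp(ll$coefficients[1]))
    if (!is.finite(k_init)) k_init <- max(y)
    dat <- data.frame(te = te_ms, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ k * exp(-te / t2), data = dat,
                        start = list(k = k_init, t2 = t2_init),
                        lower = c(k = 0, t2 = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (!all(is.finite(cf)) || cf["t2"] <= 0) next
    est$tau[v] <- cf[["t2"]]
    est$ks0[v] <- cf[["k"]]
    est$resid[v] <- sqrt(sum(stats::resid(fit)^2))
    est$valid[v] <- TRUE
  }
  relaxation_maps(est, sm$sdim, "t2star")
}

#' Mean of a map over a region of interest
#'
#' Arithmetic mean over the valid ROI voxels; invalid voxels (NA, or
#' flagged by `valid`) are excluded and the count actually used is
#' reported.
#'
#' @param map numeric array (e.g. `$t1` of a `relaxation_maps`).
#' @param roi integer vector of voxel indices into `map`, or a logical
#'   array of the same dimension.
#' @param valid optional logical array marking valid voxels.
#' @param name ROI name used in error messages.
#' @return list with `mean` and `n_used`.
#' @export
roi_mean <- function(map, roi, valid = NULL, name = "ROI") {
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) == 0L) stop(sprintf("%s is empty", name), call. = FALSE)
  if (any(idx < 1L | idx > length(map))) {
    stop(sprintf("%s has voxels outside the grid", name), call. = FALSE)
  }
  vals <- map[idx]
  ok <- is.finite(vals)
  if (!is.null(valid)) ok <- ok & valid[idx]
  if (!any(ok)) stop(sprintf("%s contains no valid voxels", name), call. = FALSE)
  list(mean = mean(vals[ok]), n_used = sum(ok))
}

#' Species relaxation scalars used by the proton-density correction
#'
#' @param t1w_ms,t1f_ms,t2sw_ms,t2sf_ms ROI-mean relaxation times (ms)
#'   of cardiac tissue (w) and pericardial fat (f); all must be finite
#'   and positive.
#' @return list of class `species_relaxation`.
#' @export
species_relaxation <- function(t1w_ms, t1f_ms, t2sw_ms, t2sf_ms) {
  v <- c(t1w_ms, t1f_ms, t2sw_ms, t2sf_ms)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("species relaxation times must be finite and positive", call. = FALSE)
  }
  structure(list(t1w_ms = t1w_ms, t1f_ms = t1f_ms,
                 t2sw_ms = t2sw_ms, t2sf_ms = t2sf_ms),
            class = "species_relaxation")
}
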