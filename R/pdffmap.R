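## Proton-density fat-fraction mapping.
##
## The water/fat amplitudes from the decomposition are steady-state
## spoiled-gradient-echo signals; the relaxation correction inverts the
## flip-angle/TR/T1 saturation factor and the T2* decay at the reference
## echo time to recover quantities proportional to proton density:
##
##   M_x = X (1 - cos(a) E1x) / (sin(a) (1 - E1x)) exp(+TE_ref / T2*_x)
##
## PDFF = 100 * M_f / (M_w + M_f). The tissue mask thresholds the root
## sum of squares of the echo magnitudes at k times the noise SD, and the
## water/fat thresholds come from a 4-component Gaussian mixture fitted
## to the 1000-bin PDFF histogram.

#' Relaxation correction of water/fat amplitudes to proton densities
#'
#' @param W,F water and fat amplitude volumes (same grid).
#' @param flip_deg flip angle, degrees; must be nonzero.
#' @param tr_ms repetition time, ms.
#' @param te_ref_ms reference echo time, ms. The solver's amplitudes are
#'   referenced to the first echo, so the first acquisition echo time is
#'   the consistent choice.
#' @param species a [species_relaxation()].
#' @return list with `m_w` and `m_f` volumes.
#' @export
correct_proton_density <- function(W, F, flip_deg, tr_ms, te_ref_ms, species) {
  if (!inherits(species, "species_relaxation")) {
    stop("species must be a species_relaxation object", call. = FALSE)
  }
  a <- flip_deg * pi / 180
  if (sin(a) == 0) stop("flip angle 0 makes the correction undefined", call. = FALSE)
  stopifnot_grid(W, F, "W/F volumes")
  corr <- function(t1, t2s) {
    e1 <- exp(-tr_ms / t1)
    (1 - cos(a) * e1) / (sin(a) * (1 - e1)) * exp(te_ref_ms / t2s)
  }
  list(m_w = W * corr(species$t1w_ms, species$t2sw_ms),
       m_f = F * corr(species$t1f_ms, species$t2sf_ms))
}

#' Compute the proton-density fat-fraction map
#'
#' `PDFF = 100 * M_f / (M_w + M_f)` on masked voxels. Negative inputs are
#' clipped to 0 (count logged); voxels with `M_w + M_f = 0` get 0;
#' voxels outside the mask carry `NA`.
#'
#' @param m_w,m_f proton-density volumes from [correct_proton_density()].
#' @param mask a [build_tissue_mask()] result, or a logical array.
#' @param te_ref_ms reference echo time recorded in the map metadata.
#' @return object of class `pdff_map`: `values` (%, `NA` outside the
#'   mask), `mask`, `te_ref_ms`, `n_clipped`, `n_zero_denominator`.
#' @export
compute_pdff <- function(m_w, m_f, mask, te_ref_ms = NA_real_) {
  stopifnot_grid(m_w, m_f, "M_w/M_f volumes")
  mk <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  stopifnot_grid(m_w, mk, "volume and mask")
  n_clip <- sum(m_w < 0) + sum(m_f < 0)
  m_w <- pmax(m_w, 0)
  m_f <- pmax(m_f, 0)
  tot <- m_w + m_f
  pdff <- array(0, dim(m_w))
  nz <- tot > 0
  pdff[nz] <- 100 * m_f[nz] / tot[nz]
  n_zero <- sum(!nz & mk)
  pdff[!mk] <- NA_real_
  structure(list(values = pdff, mask = mk, te_ref_ms = te_ref_ms,
                 n_clipped = n_clip, n_zero_denominator = n_zero),
            class = "pdff_map")
}

#' @export
print.pdff_map <- function(x, ...) {
  cat(sprintf("<pdff_map> %s, %d masked voxels, TE_ref %.3g ms\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask), x$te_ref_ms))
  invisible(x)
}

#' Estimate the noise standard deviation from a background ROI
#'
#' Sample SD (n-1 denominator) of the magnitude values in an ROI placed
#' outside the object. No Rician correction is applied. Warns if the ROI
#' looks like it contains signal (mean > 5x SD) or has fewer than 100
#' voxels; fewer than 10 voxels is an error.
#'
#' @param magnitude magnitude volume.
#' @param roi voxel indices (integer vector) or logical array selecting
#'   the noise ROI.
#' @return the estimated SD (scalar).
#' @export
estimate_noise_sd <- function(magnitude, roi) {
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) < 10L) stop("noise ROI has fewer than 10 voxels", call. = FALSE)
  if (length(idx) < 100L) warning("noise ROI has fewer than 100 voxels")
  vals <- magnitude[idx]
  s <- stats::sd(vals)
  if (s > 0 && mean(vals) > 5 * s) {
    warning("noise ROI mean > 5x its SD; the ROI may contain object signal")
  }
  s
}

#' Build the tissue mask from the combined echo magnitudes
#'
#' The root sum of squares of the echo magnitudes is thresholded at
#' `mu + k * sigma`; the initial mask is then refined deterministically
#' by a morphological closing (radius 1) and retention of the largest
#' 26-connected component. An optional user mask applies manual edits:
#' `+1` forces voxels in, `-1` forces them out, `0` leaves the automatic
#' result. All steps are logged in the returned provenance.
#'
#' `mu` defaults to 0, the plain `k * sigma` rule. A combined
#' (sum-of-squares over coils and echoes) magnitude image has a
#' chi-distributed background whose mean exceeds a few multiples of its
#' SD, so for such images the threshold must be referenced to the
#' background level: pass the noise-ROI mean of the combined image as
#' `mu`.
#'
#' @param echo_magnitudes per-echo magnitude volumes: a 4D
#'   `[x,y,z,echo]` array or list of 3D arrays.
#' @param sigma noise SD (from [estimate_noise_sd()]); `sigma = 0` with
#'   `k > 0` degenerates to "all strictly positive voxels" (warned).
#' @param k threshold multiplier (default 3).
#' @param mu background level of the combined image (default 0).
#' @param user_mask optional integer array in `{-1, 0, 1}`.
#' @param refine set `FALSE` to keep the raw threshold mask.
#' @return object of class `tissue_mask`: logical `mask`, `sigma`, `k`,
#'   `mu`, the pre-refinement mask `initial`, and a provenance `log`.
#' @export
build_tissue_mask <- function(echo_magnitudes, sigma, k = 3, mu = 0,
                              user_mask = NULL, refine = TRUE) {
  if (is.list(echo_magnitudes)) {
    echo_magnitudes <- array(unlist(echo_magnitudes),
                             c(dim(echo_magnitudes[[1]]), length(echo_magnitudes)))
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  combined <- sqrt(apply(echo_magnitudes^2, c(1, 2, 3), sum))
  if (sigma == 0 && k > 0) {
    warning("sigma = 0: mask keeps all strictly positive voxels")
  }
  initial <- combined > mu + k * sigma
  log <- c(sprintf("threshold: combined > %g + %g * %g", mu, k, sigma),
           sprintf("initial voxels: %d", sum(initial)))
  mask <- initial
  if (refine && any(mask)) {
    mask <- closing3(mask, 1L)
    log <- c(log, sprintf("closing radius 1: %d", sum(mask)))
    mask <- largest_component26(mask)
    log <- c(log, sprintf("largest 26-connected component: %d", sum(mask)))
  }
  if (!is.null(user_mask)) {
    stopifnot_grid(combined, user_mask, "mask and user mask")
    mask <- (mask | user_mask > 0) & !(user_mask < 0)
    log <- c(log, sprintf("user edits: +%d / -%d voxels",
                          sum(user_mask > 0), sum(user_mask < 0)))
  }
  structure(list(mask = mask, sigma = sigma, k = k, mu = mu,
                 initial = initial, log = log), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d voxels (k = %g, sigma = %.4g)\n",
              sum(x$mask), x$k, x$sigma))
  invisible(x)
}

## weighted EM for a K-component univariate Gaussian mixture on binned
## data (bin centers weighted by counts); returns parameters and loglik
gmm_em_binned <- function(centers, counts, mu, sd, weight,
                          max_iter = 500L, tol = 1e-8) {
  K <- length(mu)
  n <- sum(counts)
  ll_old <- -Inf
  iter <- 0L
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) weight[k] * stats::dnorm(centers, mu[k], sd[k]),
                   numeric(length(centers)))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(counts * log(tot))
    resp <- dens / tot
    nk <- colSums(counts * resp)
    weight <- nk / n
    mu <- colSums(counts * resp * centers) / nk
    sd <- sqrt(pmax(colSums(counts * resp *
                              (centers - rep(mu, each = length(centers)))^2) / nk,
                    1e-300))
    iter <- it
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd, weight = weight, loglik = ll, iterations = iter)
}

#' Fit a Gaussian mixture to the masked PDFF histogram
#'
#' Pools the masked PDFF values into a 1000-bin histogram on \[0, 100\]
#' and fits a `components`-component Gaussian mixture by weighted
#' expectation-maximization on the bin centers (counts as weights).
#' Initialization: the water mean at the global histogram mode; the fat
#' mean at the second-highest local maximum at least 10 percentage
#' points away; the remaining means spread evenly between the water and
#' fat means (the partial-volume region the residual components are
#' meant to absorb); equal weights; all SDs at a quarter of the sample
#' SD. Components collapsing below one bin width are pruned and the
#' mixture refitted with one component fewer. The water component is the
#' one whose fitted mean is nearest the initialization mode. The EM is
#' deterministic; `seed` is kept for interface stability and any future
#' randomized restart.
#'
#' @param pdff a [compute_pdff()] result (or numeric vector of PDFF
#'   values in percent).
#' @param mask optional mask overriding the map's own.
#' @param bins number of histogram bins (default 1000).
#' @param components number of Gaussian components (default 4).
#' @param seed unused by the deterministic EM; recorded.
#' @param min_voxels minimum masked voxel count.
#' @return object of class `histogram_model`: `edges`, `counts`,
#'   `weight`, `mean`, `sd` (per component), `water`, `fat` (component
#'   indices), `t_c`, `t_d`, `loglik`, `pruned`.
#' @export
fit_histogram_gmm <- function(pdff, mask = NULL, bins = 1000L, components = 4L,
                              seed = 1L, min_voxels = 1e4) {
  if (inherits(pdff, "pdff_map")) {
    mk <- if (is.null(mask)) pdff$mask else (if (inherits(mask, "tissue_mask")) mask$mask else mask)
    vals <- pdff$values[mk]
  } else {
    vals <- as.numeric(pdff)
    if (!is.null(mask)) vals <- vals[if (is.logical(mask)) mask else as.logical(mask)]
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_voxels) {
    stop(sprintf("need >= %g masked voxels, got %d", min_voxels, length(vals)),
         call. = FALSE)
  }
  vals <- pmin(pmax(vals, 0), 100)
  edges <- seq(0, 100, length.out = bins + 1)
  bw <- 100 / bins
  bin_of <- pmin(pmax(ceiling(vals / bw), 1L), bins)
  bin_of[vals == 0] <- 1L
  counts <- tabulate(bin_of, bins)
  centers <- edges[-1] - bw / 2
  # degenerate input: effectively a single spike
  nz <- which(counts > 0)
  mode_center <- centers[which.max(counts)]
  sample_mu <- sum(counts * centers) / sum(counts)
  sample_sd <- sqrt(sum(counts * (centers - sample_mu)^2) / sum(counts))
  if (length(nz) == 1L || sample_sd < bw) {
    model <- list(mu = mode_center, sd = bw / 2, weight = 1,
                  loglik = NA_real_, iterations = 0L)
    return(histogram_model(edges, counts, model, water = 1L, fat = NA_integer_,
                           pruned = components - 1L, seed = seed))
  }
  # init: water at the mode; fat at the 2nd-highest local max >= 10 away
  fat0 <- NA_real_
  for (i in order(counts, decreasing = TRUE)) {
    if (abs(centers[i] - mode_center) >= 10) { fat0 <- centers[i]; break }
  }
  if (is.na(fat0)) fat0 <- min(mode_center + 50, 100 - bw / 2)
  K <- as.integer(components)
  n_spare <- K - 2L
  spare <- if (n_spare > 0) {
    mode_center + (fat0 - mode_center) * seq_len(n_spare) / (n_spare + 1)
  } else numeric(0)
  mu0 <- c(mode_center, fat0, spare)
  sd0 <- rep(sample_sd / 4, K)
  w0 <- rep(1 / K, K)
  pruned <- 0L
  repeat {
    fit <- gmm_em_binned(centers, counts, mu0, sd0, w0)
    bad <- fit$sd < bw
    if (!any(bad) || length(fit$mu) <= 1L) break
    keep <- !bad
    pruned <- pruned + sum(bad)
    mu0 <- fit$mu[keep]; sd0 <- pmax(fit$sd[keep], bw); w0 <- fit$weight[keep]
    w0 <- w0 / sum(w0)
  }
  water <- which.min(abs(fit$mu - mode_center))
  means_rank <- order(abs(fit$mu - fat0))
  fat <- means_rank[means_rank != water][1]
  histogram_model(edges, counts, fit, water, fat, pruned, seed)
}

histogram_model <- function(edges, counts, fit, water, fat, pruned, seed) {
  m <- structure(list(edges = edges, counts = counts,
                      weight = fit$weight, mean = fit$mu, sd = fit$sd,
                      water = water, fat = fat,
                      loglik = fit$loglik, iterations = fit$iterations,
                      pruned = pruned, seed = seed,
                      t_c = NA_real_, t_d = 50),
                 class = "histogram_model")
  th <- select_thresholds(m)
  m$t_c <- th$t_c
  m
}

#' @export
print.histogram_model <- function(x, ...) {
  cat(sprintf("<histogram_model> %d component(s); water: mean %.2f%% sd %.2f%%; T_C = %.2f%%, T_D = %g%%\n",
              length(x$mean), x$mean[x$water], x$sd[x$water], x$t_c, x$t_d))
  invisible(x)
}

#' Water/fat classification thresholds from the histogram model
#'
#' `T_C` is the smallest histogram bin upper edge at or above the
#' 99.99% point of the fitted water Gaussian,
#' `mu_w + qnorm(0.9999) * sd_w` (z = 3.71902); values beyond 100 are
#' clamped with a warning. `T_D` is the fixed 50% Dixon threshold.
#'
#' @param model a `histogram_model`.
#' @return list with `t_c` and `t_d` (percent).
#' @export
select_thresholds <- function(model) {
  mu <- model$mean[model$water]
  sd <- model$sd[model$water]
  if (!is.finite(mu)) stop("no valid water component", call. = FALSE)
  z <- stats::qnorm(0.9999)
  x <- mu + z * sd
  uppers <- model$edges[-1]
  if (x > max(uppers)) {
    warning("99.99% point exceeds 100%; T_C clamped to 100")
    t_c <- 100
  } else {
    t_c <- uppers[which(uppers >= x - 1e-12)[1]]
  }
  list(t_c = t_c, t_d = 50)
}

#' Write PDFF artifacts
#'
#' Writes `pdff.nii.gz` (NA outside the mask stored as -1),
#' `mask.nii.gz`, the histogram model as JSON and the histogram as CSV.
#'
#' @param pdff a `pdff_map`.
#' @param model a `histogram_model` (optional).
#' @param dir output directory.
#' @param spacing voxel spacing mm.
#' @return `dir`, invisibly.
#' @export
write_pdff <- function(pdff, model = NULL, dir, spacing = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- pdff$values
  v[is.na(v)] <- -1
  write_nifti_volume(v, file.path(dir, "pdff.nii.gz"), spacing)
  write_nifti_volume(array(as.numeric(pdff$mask), dim(pdff$mask)),
                     file.path(dir, "mask.nii.gz"), spacing)
  if (!is.null(model)) {
    write_json_sidecar(list(weight = model$weight, mean = model$mean,
                            sd = model$sd, water = model$water,
                            fat = model$fat, t_c = model$t_c, t_d = model$t_d,
                            pruned = model$pruned),
                       file.path(dir, "histogram_model.json"))
    utils::write.csv(data.frame(lower = model$edges[-length(model$edges)],
                                upper = model$edges[-1],
                                count = model$counts),
                     file.path(dir, "histogram.csv"), row.names = FALSE)
  }
  invisible(dir)
}
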