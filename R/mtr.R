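## Magnetization transfer ratio mapping.
##
## MT volumes are acquired on a grid twice as coarse as the water-fat
## data; they are interpolated onto the fine grid by zero-filling the
## centered k-space before the inverse Fourier transform (band-limited
## sinc interpolation), then divided: MTR = 100 * MT_on / MT_off where
## MT_off exceeds the noise floor.

## Destination indices and weights for padding one axis of a centered
## spectrum from length n to length m = f*n. Frequencies 0..n/2-1 keep
## their slots, negative frequencies move to the tail, and for even n the
## Nyquist coefficient (signed frequency n/2 == -n/2) is split half and
## half between +n/2 and -(n/2) so real inputs stay real.
zf_axis_map <- function(n, m) {
  src <- integer(0); dst <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    k <- i - 1L
    if (n %% 2L == 0L && k == n %/% 2L) {
      src <- c(src, i, i)
      dst <- c(dst, n %/% 2L + 1L, m - n %/% 2L + 1L)
      w <- c(w, 0.5, 0.5)
    } else {
      ks <- if (k <= n %/% 2L) k else k - n
      j <- if (ks >= 0L) ks + 1L else m + ks + 1L
      src <- c(src, i); dst <- c(dst, j); w <- c(w, 1)
    }
  }
  list(src = src, dst = dst, w = w)
}

#' Upsample a volume by zero-filling its k-space
#'
#' Fourier transforms the volume, symmetrically zero-pads the centered
#' spectrum to `factor` times the size per axis (splitting the Nyquist
#' bin evenly for even lengths), inverse transforms, and rescales so a
#' constant volume maps to the same constant. The output samples at the
#' original lattice positions equal the input values exactly.
#'
#' @param vol real 3D array.
#' @param factor integer upsampling factor >= 1.
#' @return real 3D array of dimension `factor * dim(vol)`, with the
#'   maximum imaginary residual of the inverse transform attached as
#'   attribute `max_imag`.
#' @export
zero_fill_upsample <- function(vol, factor = 2L) {
  if (factor != round(factor) || factor < 1) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) {
    out <- vol
    attr(out, "max_imag") <- 0
    return(out)
  }
  d <- dim(vol)
  m <- d * factor
  K <- stats::fft(vol)
  maps <- lapply(seq_len(3), function(ax) zf_axis_map(d[ax], m[ax]))
  # pad axis by axis: apply the index/weight map along one dimension
  pad_axis <- function(arr, ax, map, newlen) {
    dd <- dim(arr)
    dd_out <- dd; dd_out[ax] <- newlen
    out <- array(0i, dd_out)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    o <- array(0i, c(newlen, dim(a)[2], dim(a)[3]))
    for (t in seq_along(map$src)) {
      o[map$dst[t], , ] <- o[map$dst[t], , ] + map$w[t] * a[map$src[t], , ]
    }
    aperm(o, order(perm))
  }
  P <- K
  for (ax in 1:3) P <- pad_axis(P, ax, maps[[ax]], m[ax])
  out_c <- stats::fft(P, inverse = TRUE) / prod(d)   # preserves the DC level
  out <- Re(out_c)
  attr(out, "max_imag") <- max(abs(Im(out_c)))
  out
}

#' Compute the magnetization transfer ratio map
#'
#' `MTR = 100 * MT_on / MT_off` where `MT_off` exceeds the noise floor;
#' other voxels are flagged invalid (`NA`), never zero-filled. Values
#' above 100% are retained (noise can produce them).
#'
#' @param mt_on,mt_off magnitude volumes on a shared grid (after any
#'   upsampling).
#' @param noise_floor validity floor on `MT_off`; the natural choice is
#'   3x the background SD of `MT_off`, the same rule family as the
#'   tissue mask.
#' @return object of class `mtr_map`: `values` (%), logical `valid`,
#'   `noise_floor`.
#' @export
compute_mtr <- function(mt_on, mt_off, noise_floor) {
  stopifnot_grid(mt_on, mt_off, "MT_on/MT_off volumes")
  valid <- mt_off > noise_floor
  if (!any(valid)) {
    stop("no voxel has MT_off above the noise floor; grids or floor misconfigured",
         call. = FALSE)
  }
  values <- array(NA_real_, dim(mt_on))
  values[valid] <- 100 * mt_on[valid] / mt_off[valid]
  structure(list(values = values, valid = valid, noise_floor = noise_floor),
            class = "mtr_map")
}

#' @export
print.mtr_map <- function(x, ...) {
  cat(sprintf("<mtr_map> %s, %d valid voxels (floor %.4g)\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid), x$noise_floor))
  invisible(x)
}

#' Write MTR artifacts
#'
#' Writes `mtr.nii.gz` (NA stored as -1) and `mtr_valid.nii.gz`.
#'
#' @param mtr an `mtr_map`.
#' @param dir output directory.
#' @param spacing voxel spacing mm.
#' @return `dir`, invisibly.
#' @export
write_mtr <- function(mtr, dir, spacing = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- mtr$values
  v[is.na(v)] <- -1
  write_nifti_volume(v, file.path(dir, "mtr.nii.gz"), spacing)
  write_nifti_volume(array(as.numeric(mtr$valid), dim(mtr$valid)),
                     file.path(dir, "mtr_valid.nii.gz"), spacing)
  invisible(dir)
}
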