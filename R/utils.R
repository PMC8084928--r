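## Small shared numerics: phase wrapping, block pyramids, 3D filters and
## morphology used by the field-map hierarchy and the tissue mask.

#' Wrap angles to the principal interval (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return wrapped angles, same shape.
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

## wrap a frequency (Hz) into the half-open principal interval
## [-period/2, +period/2)
wrap_freq <- function(x, period) {
  ((x + period / 2) %% period) - period / 2
}

stopifnot_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a)[1:3], dim(b)[1:3])) {
    stop(sprintf("%s do not share a grid: %s vs %s", what,
                 paste(dim(a)[1:3], collapse = "x"),
                 paste(dim(b)[1:3], collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Block-average a 3D volume by an integer factor
#'
#' Averages non-overlapping `f x f x f` cells; works for real and complex
#' volumes. Every dimension must be divisible by `f`.
#'
#' @param vol 3D array (numeric or complex).
#' @param f integer downsampling factor.
#' @return 3D array of dimension `dim(vol)/f`.
#' @export
block_average <- function(vol, f = 2L) {
  f <- as.integer(f)
  d <- dim(vol)
  if (length(d) != 3L) stop("block_average expects a 3D array", call. = FALSE)
  if (f == 1L) return(vol)
  if (any(d %% f != 0L)) {
    stop(sprintf("factor %d does not divide grid %s", f,
                 paste(d, collapse = "x")), call. = FALSE)
  }
  dd <- d %/% f
  a <- array(vol, c(f, dd[1], f, dd[2], f, dd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dd)
}

## Trilinear upsampling of a coarse cell-centered grid onto a finer
## cell-centered grid (dim_out >= dim(vol)); edge cells are clamped.
upsample_trilinear <- function(vol, dim_out) {
  d <- dim(vol)
  # fine-voxel centers expressed in coarse voxel index coordinates
  ax <- function(n_in, n_out) {
    s <- n_in / n_out
    (seq_len(n_out) - 0.5) * s + 0.5
  }
  gx <- ax(d[1], dim_out[1]); gy <- ax(d[2], dim_out[2]); gz <- ax(d[3], dim_out[3])
  lo <- function(g, n) pmin(pmax(floor(g), 1L), n - 1L)
  x0 <- lo(gx, d[1]); y0 <- lo(gy, d[2]); z0 <- lo(gz, d[3])
  fx <- pmin(pmax(gx - x0, 0), 1); fy <- pmin(pmax(gy - y0, 0), 1); fz <- pmin(pmax(gz - z0, 0), 1)
  if (d[1] == 1L) { x0 <- rep(1L, dim_out[1]); fx <- rep(0, dim_out[1]) }
  if (d[2] == 1L) { y0 <- rep(1L, dim_out[2]); fy <- rep(0, dim_out[2]) }
  if (d[3] == 1L) { z0 <- rep(1L, dim_out[3]); fz <- rep(0, dim_out[3]) }
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  out <- array(0, dim_out)
  # accumulate the 8 corner contributions with outer-product weights
  corners <- list(
    list(x0, y0, z0, (1 - fx), (1 - fy), (1 - fz)),
    list(x1, y0, z0, fx,       (1 - fy), (1 - fz)),
    list(x0, y1, z0, (1 - fx), fy,       (1 - fz)),
    list(x1, y1, z0, fx,       fy,       (1 - fz)),
    list(x0, y0, z1, (1 - fx), (1 - fy), fz),
    list(x1, y0, z1, fx,       (1 - fy), fz),
    list(x0, y1, z1, (1 - fx), fy,       fz),
    list(x1, y1, z1, fx,       fy,       fz)
  )
  for (cn in corners) {
    w <- outer(outer(cn[[4]], cn[[5]]), cn[[6]])
    out <- out + w * vol[cn[[1]], cn[[2]], cn[[3]], drop = FALSE]
  }
  out
}

## all integer offset triples with |di|,|dj|,|dk| <= r (including 0,0,0)
neighbor_offsets <- function(r = 1L) {
  as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
}

## shift a 3D array by an offset, replicating edge values
shift3 <- function(vol, off) {
  d <- dim(vol)
  ix <- pmin(pmax(seq_len(d[1]) - off[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - off[2], 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) - off[3], 1L), d[3])
  vol[ix, iy, iz, drop = FALSE]
}

## 3D median filter over the (2r+1)^3 neighborhood (edges replicated)
median_filter3 <- function(vol, r = 1L) {
  if (r < 1L) return(vol)
  offs <- neighbor_offsets(r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) as.vector(shift3(vol, offs[i, ])),
                  numeric(length(vol)))
  out <- matrixStats_rowMedians(stack)
  array(out, dim(vol))
}

## row-wise median without extra dependencies
matrixStats_rowMedians <- function(m) {
  apply(m, 1, stats::median)
}

## binary dilation/erosion with a (2r+1)^3 box structuring element
dilate3 <- function(mask, r = 1L) {
  offs <- neighbor_offsets(r)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out | shift3_pad(mask, offs[i, ], FALSE)
  out
}

erode3 <- function(mask, r = 1L) {
  offs <- neighbor_offsets(r)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) out <- out & shift3_pad(mask, offs[i, ], FALSE)
  out
}

## shift with constant padding (for morphology; edge replication would
## artificially extend structures across the volume boundary)
shift3_pad <- function(vol, off, fill) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- function(n, o) {
    from <- max(1L, 1L - o); to <- min(n, n - o)
    if (from > to) return(NULL)
    list(src = from:to, dst = (from + o):(to + o))
  }
  sx <- src(d[1], off[1]); sy <- src(d[2], off[2]); sz <- src(d[3], off[3])
  if (is.null(sx) || is.null(sy) || is.null(sz)) return(out)
  out[sx$dst, sy$dst, sz$dst] <- vol[sx$src, sy$src, sz$src]
  out
}

## morphological closing (dilate then erode), box element of radius r
closing3 <- function(mask, r = 1L) {
  erode3(dilate3(mask, r), r)
}

## label 26-connected components by iterative minimum-label propagation;
## returns an integer array (0 = background) relabelled to 1..n
label_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- neighbor_offsets(1L)
  repeat {
    nxt <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift3_pad(lab, offs[i, ], 0)
      upd <- mask & sh > 0 & (nxt == 0 | sh < nxt)
      nxt[upd] <- sh[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[] <- match(lab, c(0, u)) - 1L
  lab
}

## keep only the largest 26-connected component of a mask
largest_component26 <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components26(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

## deterministic sub-seed derivation (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629)
}
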