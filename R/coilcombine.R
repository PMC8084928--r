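## Coil combination for multi-coil, multi-echo complex acquisitions.
##
## Magnitude: root of the coil sum of squares. Phase: literal per-voxel
## summation of the coil phases (the acquisition protocol this package
## reproduces combined phase images by addition). Phase summation is only
## self-consistent for a single coil -- with n coils the echo-to-echo
## signal phase is multiplied by n -- so a `reference` mode is provided in
## which each coil is first phase-referenced to its own first echo; coil
## phases then cancel exactly for any coil count.

#' Multi-coil multi-echo complex image container
#'
#' @param data complex 5D array `[x, y, z, coil, echo]`.
#' @param te_ms echo times in ms, strictly increasing, length = n echoes.
#' @param spacing voxel spacing in mm.
#' @return object of class `multi_echo_image`.
#' @export
multi_echo_image <- function(data, te_ms, spacing = c(1, 1, 1)) {
  d <- dim(data)
  if (length(d) != 5L) stop("data must be [x,y,z,coil,echo]", call. = FALSE)
  if (d[5] != length(te_ms)) stop("length(te_ms) must match echo dimension", call. = FALSE)
  if (d[5] < 3L) stop("need >= 3 echoes", call. = FALSE)
  if (d[4] < 1L) stop("need >= 1 coil", call. = FALSE)
  if (any(diff(te_ms) <= 0)) stop("echo times must be strictly increasing", call. = FALSE)
  structure(list(data = data, te_ms = te_ms, spacing = spacing),
            class = "multi_echo_image")
}

#' @export
print.multi_echo_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_echo_image> %dx%dx%d, %d coil(s), %d echoes (TE %s ms)\n",
              d[1], d[2], d[3], d[4], d[5], paste(x$te_ms, collapse = "/")))
  invisible(x)
}

#' Combine coils into per-echo magnitude and phase volumes
#'
#' Magnitude is the root sum of squares over coils,
#' `sqrt(sum_c |s_c|^2)`. Phase depends on `phase`:
#' `"sum"` (default) wraps the per-voxel sum of the coil phases,
#' `wrap(sum_c arg(s_c))`; `"reference"` removes each coil's static phase
#' by referencing to its own first echo before complex summation,
#' `arg(sum_c s_{c,n} exp(-i arg(s_{c,1})))`, which is exact for any
#' number of coils when coil sensitivities do not vary across echoes.
#' Zero-magnitude voxels get phase 0 by convention.
#'
#' @param multi a [multi_echo_image()].
#' @param phase combination rule for the phase image.
#' @return object of class `combined_echoes` with per-echo `magnitude`
#'   and `phase` 4D arrays `[x,y,z,echo]`, echo times and spacing.
#' @export
combine_coils <- function(multi, phase = c("sum", "reference")) {
  phase <- match.arg(phase)
  s <- multi$data
  d <- dim(s)
  mag <- sqrt(apply(Mod(s)^2, c(1, 2, 3, 5), sum))
  if (phase == "sum") {
    ph <- wrap_phase(apply(Arg(s), c(1, 2, 3, 5), sum))
  } else {
    ref <- Arg(s[, , , , 1, drop = FALSE])         # [x,y,z,coil,1]
    ph <- array(0, d[c(1, 2, 3, 5)])
    for (n in seq_len(d[5])) {
      z <- s[, , , , n, drop = FALSE] * exp(-1i * ref)
      ph[, , , n] <- Arg(apply(z, c(1, 2, 3), sum))
    }
  }
  zero <- mag == 0
  ph[zero] <- 0
  structure(list(magnitude = mag, phase = ph, te_ms = multi$te_ms,
                 spacing = multi$spacing, phase_mode = phase),
            class = "combined_echoes")
}

#' Reference echo phases to the first (shortest) echo
#'
#' Computes the relative phase `wrap(phi_n - phi_1)` per voxel (echo 1 is
#' identically 0) and the complex echo images used by the water-fat
#' solver, `magnitude_n * exp(i (phi_n - phi_1))`, together with the
#' effective echo times `tau_n = t_n - t_1`.
#'
#' @param combined a `combined_echoes` object from [combine_coils()].
#' @return the input with `rel_phase` (4D), `cplx` (complex 4D) and
#'   `tau_ms` added.
#' @export
reference_to_first_echo <- function(combined) {
  ph <- combined$phase
  ne <- dim(ph)[4]
  rel <- array(0, dim(ph))
  for (n in seq_len(ne)) rel[, , , n] <- wrap_phase(ph[, , , n] - ph[, , , 1])
  rel[, , , 1] <- 0
  cplx <- array(complex(modulus = as.vector(combined$magnitude),
                        argument = as.vector(rel)), dim(ph))
  combined$rel_phase <- rel
  combined$cplx <- cplx
  combined$tau_ms <- combined$te_ms - combined$te_ms[1]
  combined
}

#' @export
print.combined_echoes <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<combined_echoes> %dx%dx%d, %d echoes, phase mode '%s'%s\n",
              d[1], d[2], d[3], d[4], x$phase_mode,
              if (!is.null(x$rel_phase)) ", referenced to echo 1" else ""))
  invisible(x)
}
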