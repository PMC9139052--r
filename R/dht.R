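# Discrete Hilbert transform featurization of PSSMs.
#
# The 1-D DHT is realized in the frequency domain: DFT, multiply by
# -j*sgn(frequency) (0 at DC and, for even length, at Nyquist -- the
# analytic-signal convention), inverse DFT, real part. The 2-D transform is
# separable: the 1-D transform applied along each axis. A protein's L x 20
# PSSM is zero-padded along the sequence axis, transformed, and summarized
# by the magnitude spectrum of its lowest sequence-frequency bins, giving a
# fixed 200-dimensional descriptor per protein and 400 per pair.

#' Frequency-domain signum multiplier for the discrete Hilbert transform
#'
#' For an N-point DFT (bins k = 0..N-1) returns the multiplier
#' `-1i * sgn(k)` with `sgn = +1` on positive-frequency bins (0 < k < N/2),
#' `-1` on negative-frequency bins (k > N/2), and `0` at DC and at the
#' Nyquist bin when N is even. Anti-symmetric under frequency negation;
#' magnitude 0 or 1.
#'
#' @param n Transform length, >= 2.
#' @return Complex vector of length `n`.
#' @export
signum_multiplier <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n) - 1L
  sgn <- numeric(n)
  sgn[k > 0 & k < n / 2] <- 1
  sgn[k > n / 2] <- -1
  complex(real = 0, imaginary = -sgn)
}

# Inverse DFT of a complex spectrum, real part, with a guard that the
# imaginary residue is numerically negligible rather than silently dropped.
ifft_real <- function(spectrum) {
  z <- stats::fft(spectrum, inverse = TRUE) / length(spectrum)
  resid <- max(abs(Im(z)))
  if (resid > 1e-10 * max(1, max(abs(Re(z))))) {
    rlang::abort(sprintf("imaginary residue %.3e after inverse transform", resid))
  }
  Re(z)
}

#' 1-D discrete Hilbert transform
#'
#' Maps `cos` components to `sin`: the DFT of the signal is multiplied by
#' [signum_multiplier()] and inverted. DC (and Nyquist, for even length)
#' components are annihilated, so applying the transform twice negates any
#' signal free of those components.
#'
#' @param x Real vector, length >= 2, finite entries.
#' @return Real vector of the same length.
#' @export
#' @examples
#' n <- 0:15
#' max(abs(dht_1d(cos(2 * pi * n / 16)) - sin(2 * pi * n / 16)))
dht_1d <- function(x) {
  if (length(x) < 2L) rlang::abort("`x` must have length >= 2")
  if (!all(is.finite(x))) rlang::abort("`x` must be finite")
  ifft_real(stats::fft(x) * signum_multiplier(length(x)))
}

#' Spatial-domain Hilbert kernel
#'
#' The periodic convolution kernel equivalent to [dht_1d()]: the inverse
#' DFT of the signum multiplier. Circular convolution of any length-N
#' signal with this kernel reproduces the frequency-route transform; it is
#' the discrete periodic realization of the classical odd `1/(a*pi)`-type
#' Hilbert kernel and serves as an independent cross-check oracle.
#'
#' @param n Kernel length, >= 2.
#' @return Real vector `p` of length `n`, zero-mean and anti-symmetric
#'   (`p[k] == -p[n - k]` in 0-based indexing).
#' @export
spatial_kernel_1d <- function(n) {
  stopifnot(n >= 2)
  ifft_real(signum_multiplier(n))
}

#' 2-D discrete Hilbert transform
#'
#' Separable transform of a real matrix: `mode = "rows"` applies [dht_1d()]
#' along each row, `"cols"` along each column, `"total"` (the featurization
#' default) both sequentially. Equivalent to multiplying the 2-D DFT by the
#' outer product of the per-axis signum multipliers.
#'
#' @param m Real matrix with both dimensions >= 2.
#' @param mode `"total"` (default), `"rows"`, or `"cols"`.
#' @return Real matrix of the same shape.
#' @export
dht_2d <- function(m, mode = c("total", "rows", "cols")) {
  mode <- match.arg(mode)
  if (!is.matrix(m) || !is.numeric(m)) rlang::abort("`m` must be a numeric matrix")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    rlang::abort("both dimensions of `m` must be >= 2")
  }
  if (!all(is.finite(m))) rlang::abort("`m` must be finite")
  out <- m
  if (mode %in% c("rows", "total")) {
    out <- t(apply(out, 1L, dht_1d))
  }
  if (mode %in% c("cols", "total")) {
    out <- apply(out, 2L, dht_1d)
  }
  out
}

#' Fixed-length DHT descriptor of one protein
#'
#' Featurizes a PSSM into exactly `block_rows * 20` values: the L x 20
#' score matrix is zero-padded (or truncated) along the sequence axis to
#' `pad_len` rows, transformed with the total-mode 2-D DHT, and the
#' magnitude spectrum (modulus of the 2-D DFT) of the transformed matrix is
#' taken. The `block_rows` lowest sequence-frequency rows across all 20
#' residue channels are returned, flattened row-major. Low-order
#' coefficients summarize the global conservation profile and are robust to
#' where along the sequence conserved stretches sit.
#'
#' @param pssm A [new_pssm()] object with at least 2 positions.
#' @param pad_len Sequence-axis length after zero-padding (default 512);
#'   longer sequences are truncated at `pad_len`.
#' @param block_rows Number of lowest sequence-frequency bins kept
#'   (default 10, giving a 200-dimensional descriptor).
#' @return Numeric vector of length `block_rows * 20`.
#' @export
protein_descriptor <- function(pssm, pad_len = 512, block_rows = 10) {
  stopifnot(inherits(pssm, "pssm"))
  L <- nrow(pssm)
  if (L < 2L) rlang::abort("PSSM must have at least 2 positions")
  stopifnot(pad_len >= 2, block_rows >= 1, block_rows <= pad_len)
  scores <- unclass(pssm)
  attr(scores, "protein_id") <- NULL
  if (L > pad_len) scores <- scores[seq_len(pad_len), , drop = FALSE]
  padded <- matrix(0, nrow = pad_len, ncol = 20L)
  padded[seq_len(nrow(scores)), ] <- scores
  transformed <- dht_2d(padded, mode = "total")
  spectrum <- Mod(stats::mvfft(t(stats::mvfft(t(transformed)))))
  block <- spectrum[seq_len(block_rows), , drop = FALSE]
  as.vector(t(block))
}

#' 400-dimensional descriptor of a protein pair
#'
#' Concatenation of the two per-protein descriptors, protein A first.
#'
#' @param pssm_a,pssm_b [new_pssm()] objects for the two proteins.
#' @inheritParams protein_descriptor
#' @return Named numeric vector of length `2 * block_rows * 20` (400 at the
#'   defaults), names `d0001`..`d0400`; attribute `pair_ids` holds the two
#'   protein ids.
#' @export
pair_descriptor <- function(pssm_a, pssm_b, pad_len = 512, block_rows = 10) {
  feats <- c(protein_descriptor(pssm_a, pad_len, block_rows),
             protein_descriptor(pssm_b, pad_len, block_rows))
  names(feats) <- sprintf("d%04d", seq_along(feats))
  attr(feats, "pair_ids") <- c(attr(pssm_a, "protein_id"),
                               attr(pssm_b, "protein_id"))
  feats
}
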