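# Analytic-signal phase/amplitude extraction. The analytic signal of a
# real narrowband series s(t) is z(t) = s(t) + i H[s(t)] with H the
# Hilbert transform; its argument is the instantaneous phase phi(t) and
# its modulus the instantaneous amplitude A(t), so that
# s(t) = A(t) cos(phi(t)).

#' Discrete analytic signal via FFT
#'
#' @param x real numeric vector.
#' @return Complex vector z with `Re(z) = x` and `Im(z) = H[x]`.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phases and amplitudes of regional signals
#'
#' Demeans each regional series (the analytic signal of a series with a
#' nonzero mean has a distorted phase), then takes the argument and
#' modulus of the FFT-based analytic signal. Apply [trim_borders()]
#' afterwards: the transform is least reliable at the series edges.
#'
#' @param ts a [regional_timeseries()], normally the output of
#'   [wavelet_bandpass()].
#' @return An object of class `analytic_phases`: list with `phases`
#'   (N x T radians, wrapped to (-pi, pi]), `amplitudes` (N x T, >= 0),
#'   `dt_sample`, `region_ids`, `trim` (samples already removed per edge,
#'   0 here).
#' @export
analytic_signal <- function(ts) {
  stopifnot(inherits(ts, "regional_timeseries"))
  x <- ts$data - rowMeans(ts$data)
  if (any(apply(x, 1L, function(r) all(r == 0))))
    stop("all-zero (constant) regional series: phase undefined")
  z <- t(apply(x, 1L, hilbert_analytic))
  phases <- Arg(z)
  # Arg() returns (-pi, pi]; keep that convention explicitly
  phases[phases <= -pi] <- pi
  structure(list(phases = phases, amplitudes = Mod(z),
                 dt_sample = ts$dt_sample, region_ids = ts$region_ids,
                 trim = 0L),
            class = "analytic_phases")
}

#' Discard edge samples of a phase set
#'
#' Removes the first and last `trim` samples of the phase and amplitude
#' matrices to avoid the border effect inherent to the Hilbert transform.
#' At a 1-s sampling interval the default removes 10 s per edge, e.g.
#' 410 retained simulation seconds become the 390 analyzed seconds.
#'
#' @param aps an `analytic_phases` object.
#' @param trim samples to drop from each edge (default 10).
#' @return The trimmed `analytic_phases` (cumulative `trim` recorded).
#' @export
trim_borders <- function(aps, trim = 10L) {
  stopifnot(inherits(aps, "analytic_phases"))
  trim <- as.integer(trim)
  if (trim < 0L) stop("trim must be non-negative")
  T <- ncol(aps$phases)
  if (trim > 0L && T <= 2L * trim)
    stop("series of length ", T, " too short to trim ", trim, " per edge")
  keep <- if (trim > 0L) (trim + 1L):(T - trim) else seq_len(T)
  aps$phases <- aps$phases[, keep, drop = FALSE]
  aps$amplitudes <- aps$amplitudes[, keep, drop = FALSE]
  aps$trim <- aps$trim + trim
  aps
}

#' @export
print.analytic_phases <- function(x, ...) {
  cat("analytic_phases:", nrow(x$phases), "regions x", ncol(x$phases),
      "samples @", x$dt_sample, "s (", x$trim, "samples trimmed per edge)\n")
  invisible(x)
}

#' Full empirical phase-extraction pipeline
#'
#' Convenience composition: wavelet band-pass at `level`, analytic signal,
#' border trim.
#'
#' @inheritParams wavelet_bandpass
#' @inheritParams trim_borders
#' @param trim samples to discard per edge after the Hilbert transform.
#' @return A trimmed `analytic_phases` object.
#' @export
extract_phases <- function(ts, level = 4, filter = "la8", trim = 10L) {
  trim_borders(analytic_signal(wavelet_bandpass(ts, level, filter)), trim)
}
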