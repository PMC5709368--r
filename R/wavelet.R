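# Maximal-overlap discrete wavelet transform (MODWT), pyramid algorithm
# with circular (periodic) boundary handling, and its multiresolution
# analysis. Implemented here because the transform is the band-pass step
# of the phase pipeline; filters follow the usual quadrature-mirror
# construction h_l = (-1)^l g_{L-1-l} with MODWT rescaling by 1/sqrt(2).

# Daubechies least-asymmetric scaling filter, length 8 ("LA(8)"/sym4).
.la8_scaling <- c(-0.075765714789273330, -0.029635527645998964,
                   0.497618667632014820,  0.803738751805916060,
                   0.297857795605276670, -0.099219543576847216,
                  -0.012603967262037833,  0.032223100604042702)

.wavelet_filters <- function(filter = "la8") {
  g <- switch(filter,
    la8  = .la8_scaling,
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet filter: ", filter))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# One circular filtering step at level j: y[t] = sum_l f[l] x[(t - 2^(j-1) l) mod T]
.modwt_filt <- function(x, f, j) {
  T <- length(x)
  y <- numeric(T)
  step <- 2^(j - 1L)
  t0 <- seq_len(T) - 1L
  for (l in seq_along(f)) {
    idx <- (t0 - (l - 1L) * step) %% T
    y <- y + f[l] * x[idx + 1L]
  }
  y
}

# Inverse step: x[t] = sum_l h[l] W[(t + 2^(j-1) l) mod T] + sum_l g[l] V[...]
.imodwt_step <- function(W, V, filt, j) {
  T <- length(V)
  x <- numeric(T)
  step <- 2^(j - 1L)
  t0 <- seq_len(T) - 1L
  for (l in seq_len(filt$L)) {
    idx <- ((t0 + (l - 1L) * step) %% T) + 1L
    x <- x + filt$h[l] * W[idx] + filt$g[l] * V[idx]
  }
  x
}

#' Maximal-overlap discrete wavelet transform of a single series
#'
#' @param x numeric vector, length T.
#' @param level decomposition depth J (requires T >= 2^J).
#' @param filter `"la8"` (Daubechies least-asymmetric, length 8; default)
#'   or `"haar"`.
#' @return List with `W` (T x J matrix of wavelet coefficients, one column
#'   per level) and `V` (level-J scaling coefficients).
#' @export
modwt <- function(x, level, filter = "la8") {
  if (anyNA(x)) stop("series contains missing values")
  T <- length(x)
  if (T < 2^level)
    stop("series of length ", T, " too short for level ", level)
  filt <- .wavelet_filters(filter)
  W <- matrix(0, T, level)
  V <- x
  for (j in seq_len(level)) {
    W[, j] <- .modwt_filt(V, filt$h, j)
    V <- .modwt_filt(V, filt$g, j)
  }
  list(W = W, V = V, level = level, filter = filter)
}

#' Multiresolution analysis: additive detail and smooth components
#'
#' Inverts the MODWT keeping one level at a time, yielding details
#' `D[, j]` and the smooth `S` such that `rowSums(D) + S` reconstructs the
#' input exactly (perfect-reconstruction property).
#'
#' @param x numeric vector.
#' @inheritParams modwt
#' @return List with `D` (T x J matrix of details) and `S` (smooth).
#' @export
modwt_mra <- function(x, level, filter = "la8") {
  dec <- modwt(x, level, filter)
  filt <- .wavelet_filters(filter)
  T <- length(x)
  zero <- numeric(T)
  D <- matrix(0, T, level)
  for (j in seq_len(level)) {
    comp <- .imodwt_step(dec$W[, j], zero, filt, j)
    if (j > 1L) for (jj in (j - 1L):1L)
      comp <- .imodwt_step(zero, comp, filt, jj)
    D[, j] <- comp
  }
  S <- dec$V
  for (jj in level:1L) S <- .imodwt_step(zero, S, filt, jj)
  list(D = D, S = S)
}

#' Nominal frequency band of a MODWT level
#'
#' Level j of the transform isolates the octave band
#' `[fs / 2^(j+1), fs / 2^j]`; at a 1-s sampling interval level 4 spans
#' 0.031-0.063 Hz, the slow BOLD band usually quoted as 0.03-0.06 Hz.
#'
#' @param fs sampling frequency in Hz.
#' @param level decomposition level j.
#' @return Named numeric vector `c(lower, upper)` in Hz.
#' @export
wavelet_band <- function(fs, level) {
  c(lower = fs / 2^(level + 1), upper = fs / 2^level)
}

#' Wavelet band-pass filter for regional time series
#'
#' Extracts, for every region, the MODWT detail at the requested level:
#' the narrowband component of the BOLD signal whose phase is subsequently
#' read off the Hilbert analytic signal. Output length equals input length
#' (the transform is undecimated).
#'
#' @param ts a [regional_timeseries()].
#' @param level decomposition level (default 4, the 0.03-0.06 Hz band at
#'   TR = 1 s).
#' @param filter wavelet filter name, see [modwt()].
#' @return A `regional_timeseries` of the band-passed signals, with
#'   attribute `"band_hz"` carrying the nominal band edges.
#' @export
wavelet_bandpass <- function(ts, level = 4, filter = "la8") {
  stopifnot(inherits(ts, "regional_timeseries"))
  T <- ncol(ts$data)
  if (T < 2^(level + 1))
    stop("need T >= ", 2^(level + 1), " samples for level ", level,
         " band-pass, got ", T)
  out <- t(apply(ts$data, 1L, function(x) modwt_mra(x, level, filter)$D[, level]))
  res <- regional_timeseries(out, dt_sample = ts$dt_sample,
                             region_ids = ts$region_ids)
  attr(res, "band_hz") <- wavelet_band(1 / ts$dt_sample, level)
  res
}
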