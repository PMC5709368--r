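# Synthetic study generator: modular connectomes with distance-like tract
# lengths, and BOLD-like narrowband signals whose per-network phase
# coherence is controlled by a von Mises concentration kappa. The closed
# form E[R] = I1(kappa)/I0(kappa) (ratio of modified Bessel functions)
# makes the generated coherence a usable ground truth for the whole
# phase-extraction + network-metrics pipeline.

#' Specification of a synthetic study
#'
#' Defaults emulate the empirical setting the analysis targets: a 90-region
#' parcellation with six resting-state networks of unequal size, tract
#' lengths averaging 57.3 mm with a 10-mm lower bound (short fibers are
#' discarded in tractography), 410 one-second samples of narrowband
#' (0.03-0.06 Hz) signal per region.
#'
#' @param n_regions number of regions.
#' @param network_sizes integer vector of network sizes (sum <=
#'   `n_regions`; the remainder stays unassigned).
#' @param network_labels labels, same length as `network_sizes`.
#' @param within_weight_mean,between_weight_mean mean connection weight
#'   inside/between modules (weights are truncated-normal, SD = mean / 4,
#'   floored at 0).
#' @param length_scale mean tract length in mm.
#' @param min_length lower bound on tract lengths in mm.
#' @param coupling_levels per-network von Mises concentration kappa >= 0
#'   (recycled; 0 = independent phases, large = identical phases).
#' @param offset_timescale correlation time (s) of each region's phase
#'   offset process.
#' @param noise_sd SD of additive Gaussian measurement noise (signal
#'   units; the noiseless signal has amplitude 1).
#' @param carrier_band numeric length-2, Hz; each network's carrier
#'   frequency is drawn uniformly in this band.
#' @param duration total signal duration in seconds.
#' @param dt_sample sampling interval in seconds.
#' @param seed integer; one global seed, split internally per stage so the
#'   connectome and the signals can be regenerated independently.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_regions = 90,
                       network_sizes = c(16, 12, 10, 12, 14, 8),
                       network_labels = c("DMN", "CEN", "SAL", "SMN",
                                          "VN", "AN"),
                       within_weight_mean = 1, between_weight_mean = 0.2,
                       length_scale = 57.3, min_length = 10,
                       coupling_levels = 2, offset_timescale = 60,
                       noise_sd = 0.2, carrier_band = c(0.03, 0.06),
                       duration = 410, dt_sample = 1, seed = 1L) {
  if (sum(network_sizes) > n_regions)
    stop("network_sizes exceed n_regions")
  if (length(network_labels) != length(network_sizes))
    stop("one label per network required")
  if (any(network_sizes < 2)) stop("networks need >= 2 regions")
  if (within_weight_mean < 0 || between_weight_mean < 0)
    stop("weight means must be non-negative")
  if (length_scale <= min_length || min_length < 0)
    stop("need 0 <= min_length < length_scale")
  if (any(coupling_levels < 0)) stop("coupling_levels must be >= 0")
  nyq <- 1 / (2 * dt_sample)
  if (carrier_band[1] <= 0 || carrier_band[2] >= nyq ||
      carrier_band[1] > carrier_band[2])
    stop("carrier_band must lie inside (0, Nyquist = ", nyq, " Hz)")
  if (duration <= 0 || dt_sample <= 0) stop("duration and dt_sample must be > 0")
  structure(list(n_regions = n_regions, network_sizes = network_sizes,
                 network_labels = network_labels,
                 within_weight_mean = within_weight_mean,
                 between_weight_mean = between_weight_mean,
                 length_scale = length_scale, min_length = min_length,
                 coupling_levels = rep_len(coupling_levels,
                                           length(network_sizes)),
                 offset_timescale = offset_timescale,
                 noise_sd = noise_sd, carrier_band = carrier_band,
                 duration = duration, dt_sample = dt_sample,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Expected order parameter of a von Mises phase ensemble
#'
#' The mean resultant length of a von Mises distribution with
#' concentration `kappa` is the Bessel-function ratio I1(kappa)/I0(kappa):
#' the synchrony a large network of such phases converges to.
#'
#' @param kappa concentration(s) >= 0.
#' @return numeric vector in [0, 1).
#' @export
bessel_ratio_synchrony <- function(kappa) {
  ifelse(kappa > 700,
         1 - 1 / (2 * pmax(kappa, 1)),  # asymptotic, avoids Bessel overflow
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Generate a modular structural connectome and matching partition
#'
#' Block-structured symmetric weights (within-module entries with mean
#' `within_weight_mean`, between-module with mean `between_weight_mean`,
#' truncated at 0), shifted-gamma tract lengths with mean `length_scale`
#' and lower bound `min_length` wherever a connection exists, zero
#' diagonals. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list with `connectome` ([structural_connectome()]) and
#'   `partition` ([network_partition()]).
#' @export
make_connectome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions
  ids <- sprintf("R%02d", seq_len(n))
  block <- rep(NA_character_, n)
  block[seq_len(sum(spec$network_sizes))] <-
    rep(spec$network_labels, spec$network_sizes)

  mean_w <- matrix(spec$between_weight_mean, n, n)
  same <- outer(block, block, function(a, b) !is.na(a) & !is.na(b) & a == b)
  mean_w[same] <- spec$within_weight_mean
  up <- upper.tri(mean_w)
  w <- matrix(0, n, n)
  w[up] <- pmax(0, stats::rnorm(sum(up), mean_w[up], mean_w[up] / 4))
  w <- w + t(w)

  len <- matrix(0, n, n)
  len[up] <- spec$min_length +
    stats::rgamma(sum(up), shape = 4,
                  scale = (spec$length_scale - spec$min_length) / 4)
  len <- len + t(len)
  len[w == 0] <- 0

  sc <- structural_connectome(w, len, region_ids = ids)
  assigned <- !is.na(block)
  part <- network_partition(stats::setNames(block[assigned], ids[assigned]),
                            ids)
  list(connectome = sc, partition = part)
}

# von Mises quantile function on a fixed grid; used to give the phase
# offsets an exact stationary von Mises marginal. For large kappa the
# N(0, 1/kappa) limit is used directly.
# The offset timescale must keep the phase-modulation bandwidth
# (~1/(2 pi timescale)) well inside the analysis band, otherwise a
# band-pass filter clips the modulation and inflates measured coherence.
.vm_quantile_fun <- function(kappa, grid_n = 4096L) {
  if (kappa == 0) return(function(p) (p - 0.5) * 2 * pi)
  if (kappa > 50) return(function(p) stats::qnorm(p) / sqrt(kappa))
  th <- seq(-pi, pi, length.out = grid_n)
  dens <- exp(kappa * (cos(th) - 1))
  cdf <- cumsum(c(0, (dens[-1] + dens[-grid_n]) / 2 * diff(th)))
  cdf <- cdf / cdf[grid_n]
  function(p) stats::approx(cdf, th, xout = p, ties = "ordered")$y
}

#' Generate phase-coupled BOLD-like signals with known synchrony
#'
#' Each network carries a common narrowband phase trajectory; each member
#' region follows it with a slowly varying offset whose stationary
#' distribution is von Mises with the network's `kappa` (obtained by a
#' probability-integral transform of a Gaussian Ornstein-Uhlenbeck
#' process, so paths are smooth and the marginal is exact). The signal is
#' `cos(phase) + noise`. Unassigned regions get independent carriers.
#'
#' @param spec a [synth_spec()].
#' @param partition the [network_partition()] from [make_connectome()].
#' @return list with `timeseries` ([regional_timeseries()]) and
#'   `ground_truth` (data.frame: `network`, `kappa`,
#'   `expected_synchrony` = I1(kappa)/I0(kappa)).
#' @export
make_phase_coupled_bold <- function(spec, partition) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(partition, "network_partition"))
  set.seed(spec$seed + 1000003L)
  nt <- as.integer(round(spec$duration / spec$dt_sample))
  tt <- (seq_len(nt) - 1L) * spec$dt_sample
  ids <- partition$region_ids
  x <- matrix(0, length(ids), nt, dimnames = list(ids, NULL))

  # discrete-time OU with unit stationary variance
  rho <- exp(-spec$dt_sample / spec$offset_timescale)
  innov_sd <- sqrt(1 - rho^2)
  ou_path <- function() {
    z <- numeric(nt)
    z[1] <- stats::rnorm(1)
    eps <- stats::rnorm(nt - 1L, sd = innov_sd)
    for (i in 2:nt) z[i] <- rho * z[i - 1L] + eps[i - 1L]
    z
  }

  for (j in seq_along(partition$networks)) {
    nw <- partition$networks[j]
    kappa <- spec$coupling_levels[j]
    mem <- network_members(partition, nw)
    f0 <- stats::runif(1, spec$carrier_band[1], spec$carrier_band[2])
    common <- 2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi)
    qf <- .vm_quantile_fun(kappa)
    for (m in mem) {
      delta <- qf(stats::pnorm(ou_path()))
      x[m, ] <- cos(common + delta)
    }
  }
  unassigned <- setdiff(ids, names(partition$assignment))
  for (m in unassigned) {
    f0 <- stats::runif(1, spec$carrier_band[1], spec$carrier_band[2])
    x[m, ] <- cos(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
  }
  if (spec$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd),
                    nrow(x), ncol(x))

  gt <- data.frame(network = partition$networks,
                   kappa = spec$coupling_levels,
                   expected_synchrony =
                     bessel_ratio_synchrony(spec$coupling_levels),
                   stringsAsFactors = FALSE)
  list(timeseries = regional_timeseries(x, spec$dt_sample, ids),
       ground_truth = gt)
}

#' Write a complete synthetic study to disk
#'
#' Emits the TSV files the loaders read (weights, lengths, partition,
#' time series) plus a JSON sidecar with the ground-truth synchrony.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_synthetic_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- make_connectome(spec)
  bold <- make_phase_coupled_bold(spec, con$partition)
  save_connectome(con$connectome, file.path(dir, "weights.tsv"),
                  file.path(dir, "lengths.tsv"))
  save_partition(con$partition, file.path(dir, "partition.tsv"))
  save_timeseries(bold$timeseries, file.path(dir, "bold.tsv"))
  jsonlite::write_json(bold$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(list(connectome = con$connectome, partition = con$partition,
                 timeseries = bold$timeseries,
                 ground_truth = bold$ground_truth))
}
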