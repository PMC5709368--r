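# Dynamic and functional-connectivity metrics of resting-state networks.
#
# The Kuramoto order parameter of a set of phases phi_n(t),
#   R(t) = | (1/N) sum_n exp(i phi_n(t)) |,
# summarizes the instantaneous coherence of a network: its time mean is
# the network's synchrony and its time SD its metastability. Functional
# connectivity is correlation-based: cohesion = mean pairwise Pearson r
# within a network, integration = mean r between a network's mean signal
# and the other networks' mean signals.

#' Order-parameter time series of a set of regions
#'
#' @param phases N x T numeric matrix of instantaneous phases in radians
#'   (rows named by region), or an `analytic_phases` object.
#' @param members character vector of member region ids, or integer row
#'   indices.
#' @param network optional network label stored on the result.
#' @return Object of class `order_parameter_series`: list with `values`
#'   (T reals in [0, 1]), `network`, `n_members`.
#' @export
order_parameter_series <- function(phases, members = NULL, network = NA_character_) {
  if (inherits(phases, "analytic_phases")) phases <- phases$phases
  if (is.null(members)) members <- seq_len(nrow(phases))
  if (!length(members)) stop("empty member set")
  if (is.character(members)) {
    missing <- setdiff(members, rownames(phases))
    if (length(missing)) stop("member region(s) absent from phase matrix: ",
                              paste(missing, collapse = ", "))
  }
  ph <- phases[members, , drop = FALSE]
  z <- colMeans(exp(1i * ph))
  structure(list(values = Mod(z), network = network, n_members = nrow(ph)),
            class = "order_parameter_series")
}

#' Synchrony: time mean of the order parameter
#' @param ops an `order_parameter_series`.
#' @return scalar in [0, 1].
#' @export
synchrony <- function(ops) {
  v <- if (inherits(ops, "order_parameter_series")) ops$values else ops
  if (length(v) < 2L) stop("need at least 2 time points")
  mean(v)
}

#' Metastability: time SD of the order parameter
#'
#' Population convention (divisor T): R(t) is treated as the complete
#' realization under analysis, not a sample from a longer one. A
#' [0, 1]-bounded series has SD at most 0.5.
#'
#' @param ops an `order_parameter_series`.
#' @return non-negative scalar, at most 0.5.
#' @export
metastability <- function(ops) {
  v <- if (inherits(ops, "order_parameter_series")) ops$values else ops
  if (length(v) < 2L) stop("need at least 2 time points")
  sqrt(mean((v - mean(v))^2))
}

#' Within-network functional connectivity (cohesion)
#'
#' Mean of the pairwise Pearson correlations among the member regions'
#' time series.
#'
#' @param ts a [regional_timeseries()].
#' @param members >= 2 member region ids (or row indices).
#' @return scalar in [-1, 1].
#' @export
within_network_fc <- function(ts, members) {
  x <- t(ts$data[members, , drop = FALSE])
  if (ncol(x) < 2L) stop("need >= 2 member regions")
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("zero-variance member series: correlation undefined")
  r <- stats::cor(x)
  mean(r[upper.tri(r)])
}

#' Mean time series of each network
#' @param ts a [regional_timeseries()].
#' @param partition a [network_partition()].
#' @return K x T matrix, one row per network.
#' @export
network_mean_series <- function(ts, partition) {
  t(vapply(partition$networks, function(nw)
    colMeans(ts$data[network_members(partition, nw), , drop = FALSE]),
    numeric(ncol(ts$data))))
}

#' Between-network functional connectivity (integration)
#'
#' Unweighted mean, over the other K - 1 networks, of the Pearson
#' correlation between this network's mean series and each other
#' network's mean series.
#'
#' @param ts a [regional_timeseries()].
#' @param partition a [network_partition()] with >= 2 networks.
#' @param network network label.
#' @return scalar in [-1, 1].
#' @export
between_network_fc <- function(ts, partition, network) {
  if (length(partition$networks) < 2L) stop("need >= 2 networks")
  ms <- network_mean_series(ts, partition)
  if (any(apply(ms, 1L, stats::sd) == 0))
    stop("zero-variance network mean series")
  r <- stats::cor(t(ms))
  others <- setdiff(partition$networks, network)
  if (length(others) == length(partition$networks))
    stop("unknown network label: ", network)
  mean(r[network, others])
}

#' Fisher z-transform of a correlation
#' @param r correlation(s) with |r| < 1.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| >= 1: Fisher z-transform undefined")
  atanh(r)
}

#' Phase-locking value matrix
#'
#' PLV[i, j] = | mean over t of exp(i (phi_i(t) - phi_j(t))) |: 1 for a
#' constant phase offset, near 0 for independent phases. An alternative,
#' phase-based definition of connectivity.
#'
#' @param aps an `analytic_phases` object (trimmed), or an N x T phase
#'   matrix in radians.
#' @return Symmetric N x N matrix in [0, 1] with unit diagonal.
#' @export
plv_matrix <- function(aps) {
  ph <- if (inherits(aps, "analytic_phases")) aps$phases else aps
  z <- exp(1i * ph)
  m <- (z %*% Conj(t(z))) / ncol(ph)
  plv <- Mod(m)
  plv <- (plv + t(plv)) / 2
  diag(plv) <- 1
  dimnames(plv) <- list(rownames(ph), rownames(ph))
  plv
}

#' Per-network dynamics and connectivity summary
#'
#' One tidy row per network: synchrony, metastability (from the trimmed
#' phases) and within-/between-network functional connectivity with their
#' Fisher-z transforms (from the band-passed series).
#'
#' @param aps an `analytic_phases` object.
#' @param ts the [regional_timeseries()] used for correlation-based FC
#'   (normally the band-passed series; pass `NULL` to skip FC columns).
#' @param partition a [network_partition()].
#' @return data.frame with columns `network`, `n_members`, `synchrony`,
#'   `metastability` and, when `ts` is given, `within_fc`, `between_fc`,
#'   `fisher_z_within`, `fisher_z_between`.
#' @export
network_summary <- function(aps, ts, partition) {
  rows <- lapply(partition$networks, function(nw) {
    mem <- network_members(partition, nw)
    ops <- order_parameter_series(aps, mem, network = nw)
    row <- data.frame(network = nw, n_members = length(mem),
                      synchrony = synchrony(ops),
                      metastability = metastability(ops),
                      stringsAsFactors = FALSE)
    if (!is.null(ts)) {
      row$within_fc <- within_network_fc(ts, mem)
      row$between_fc <- between_network_fc(ts, partition, nw)
      row$fisher_z_within <- fisher_z(row$within_fc)
      row$fisher_z_between <- fisher_z(row$between_fc)
    }
    row
  })
  do.call(rbind, rows)
}
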