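# End-to-end orchestration. A run configuration is a plain named list
# (buildable from JSON via jsonlite); every output data.frame can be
# written as tidy TSV. The exported functions are the package's
# command-surface: empirical-style analysis, simulation + fit study, and
# a fully synthetic demonstration study.

.cfg_default <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Empirical-style analysis of regional time series
#'
#' Wavelet band-pass -> Hilbert phases -> border trim -> per-network
#' synchrony, metastability and within-/between-network FC.
#'
#' @param ts a [regional_timeseries()].
#' @param partition a [network_partition()].
#' @param config optional named list with `wavelet_level` (4),
#'   `wavelet_filter` ("la8"), `trim_samples` (10).
#' @return data.frame as from [network_summary()], one row per network.
#' @export
run_empirical <- function(ts, partition, config = list()) {
  level <- .cfg_default(config, "wavelet_level", 4)
  filter <- .cfg_default(config, "wavelet_filter", "la8")
  trim <- .cfg_default(config, "trim_samples", 10L)
  band <- wavelet_bandpass(ts, level = level, filter = filter)
  aps <- trim_borders(analytic_signal(band), trim)
  # FC on the band-passed series restricted to the same retained window
  keep <- (trim + 1):(ncol(band$data) - trim)
  band_trimmed <- regional_timeseries(band$data[, keep, drop = FALSE],
                                      band$dt_sample, band$region_ids)
  network_summary(aps, band_trimmed, partition)
}

#' Simulation sweep plus model fit against empirical summaries
#'
#' Builds the conduction-delay model, sweeps the global coupling, and (when
#' empirical summaries are supplied) reports per-k absolute errors and the
#' optimal coupling per network.
#'
#' @param sc a [structural_connectome()].
#' @param partition a [network_partition()].
#' @param empirical optional data.frame with `network`, `synchrony`,
#'   `metastability` (e.g. from [run_empirical()], averaged over subjects).
#' @param config named list: `ks` (coupling grid, default 1:25),
#'   `tau_mean` (ms, default 6), `dt` (ms, default 0.1), `duration` (s,
#'   default 410), `transient` (s, default 20), `omega_mean` (Hz, 60),
#'   `omega_sd` (Hz, 1), `omega_dist` ("uniform"), `store_stride`
#'   (default: stored resolution <= 10 ms), `seed` (1).
#' @return list with `sweep` (per-k per-network summary), `delay_model`,
#'   and when `empirical` is given `errors` (per-k [fit_error()] table)
#'   and `optimal` (per-network k of maximal metastability with the error
#'   at that k).
#' @export
run_model_study <- function(sc, partition, empirical = NULL,
                            config = list()) {
  ks <- .cfg_default(config, "ks", 1:25)
  dt <- .cfg_default(config, "dt", 0.1)
  stride <- .cfg_default(config, "store_stride",
                         max(1L, as.integer(floor(10 / dt))))
  dm <- build_delay_model(sc, tau_mean = .cfg_default(config, "tau_mean", 6),
                          dt = dt)
  cfg <- sim_config(k = ks[1],
                    duration = .cfg_default(config, "duration", 410),
                    transient = .cfg_default(config, "transient", 20),
                    dt = dt,
                    omega_mean = .cfg_default(config, "omega_mean", 60),
                    omega_sd = .cfg_default(config, "omega_sd", 1),
                    omega_dist = .cfg_default(config, "omega_dist",
                                              "uniform"),
                    store_stride = stride,
                    seed = .cfg_default(config, "seed", 1L))
  sweep <- coupling_sweep(sc, dm, cfg, ks, partition)
  out <- list(sweep = sweep, delay_model = dm)
  if (!is.null(empirical)) {
    errors <- do.call(rbind, lapply(split(sweep, sweep$k), fit_error,
                                    emp = empirical))
    rownames(errors) <- NULL
    opt <- optimal_coupling(sweep, "max_metastability")
    i <- match(paste(opt$network, opt$k_opt),
               paste(errors$network, errors$k))
    opt$synchrony_error <- errors$synchrony_error[i]
    opt$metastability_error <- errors$metastability_error[i]
    out$errors <- errors
    out$optimal <- opt
  }
  out
}

#' Self-contained synthetic study
#'
#' Generates a modular connectome and phase-coupled signals, runs the
#' empirical-style arm, and relates the per-network dynamic metrics to
#' cohesion/integration and to the generator's ground truth.
#'
#' @param spec a [synth_spec()].
#' @param config passed to [run_empirical()].
#' @return list with `summary` (per-network metrics joined with the
#'   ground-truth kappa and expected synchrony), `connectome`,
#'   `partition`.
#' @export
run_synthetic_study <- function(spec = synth_spec(), config = list()) {
  con <- make_connectome(spec)
  bold <- make_phase_coupled_bold(spec, con$partition)
  summary <- run_empirical(bold$timeseries, con$partition, config)
  summary <- merge(summary, bold$ground_truth, by = "network", sort = FALSE)
  list(summary = summary, connectome = con$connectome,
       partition = con$partition)
}
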