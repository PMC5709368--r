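# Delay-coupled Kuramoto model on a structural connectome. Tract lengths
# are converted to conduction delays D = L / v, where the velocity v is
# set indirectly through the mean delay tau: v = mean(L over connected
# pairs) / tau. The simulator integrates
#   dtheta_n/dt = omega_n + k sum_p C_np sin(theta_p(t - D_np) - theta_n(t))
# with an explicit Euler scheme, random uniform initial phases, and
# backward free rotation for the pre-history.

#' Build the conduction-delay model from tract lengths
#'
#' @param sc a [structural_connectome()].
#' @param tau_mean desired mean delay tau in ms across connected pairs;
#'   `0` disables delays entirely.
#' @param dt integration step in ms used to discretize delays.
#' @return Object of class `delay_model`: `velocity` (mm/ms), `delays`
#'   (N x N ms), `delay_steps` (integer, round-to-nearest), `tau_mean`,
#'   `dt`, `mean_length` (mm over connected pairs).
#' @export
build_delay_model <- function(sc, tau_mean, dt) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (tau_mean < 0) stop("tau_mean must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  conn <- sc$weights > 0
  if (!any(conn)) stop("connectome has no connected pairs")
  mean_len <- mean(sc$lengths[conn])
  if (tau_mean == 0) {
    delays <- matrix(0, nrow(sc$weights), ncol(sc$weights))
    velocity <- Inf
  } else {
    velocity <- mean_len / tau_mean           # mm/ms == m/s
    delays <- sc$lengths / velocity
    delays[!conn] <- 0
  }
  structure(list(velocity = velocity, delays = delays,
                 delay_steps = matrix(as.integer(round(delays / dt)),
                                      nrow(delays), ncol(delays)),
                 tau_mean = tau_mean, dt = dt, mean_length = mean_len),
            class = "delay_model")
}

#' @export
print.delay_model <- function(x, ...) {
  cat("delay_model: v =", format(x$velocity, digits = 4),
      "mm/ms (mean tract length", format(x$mean_length, digits = 4),
      "mm, tau =", x$tau_mean, "ms), max delay",
      max(x$delays), "ms =", max(x$delay_steps), "steps @ dt =", x$dt, "ms\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param k global coupling strength (dimensionless; scales all weights).
#' @param duration total simulated time in seconds.
#' @param transient initial seconds discarded before storing phases.
#' @param dt Euler step in ms.
#' @param omega_mean,omega_sd mean and SD of the intrinsic frequencies in
#'   Hz (gamma-band 60 +/- 1 Hz by default; slow-oscillation runs use
#'   e.g. mean 0.045, SD 0.01 with `omega_dist = "normal"`).
#' @param omega_dist `"uniform"` (uniform on mean +/- sqrt(3) SD, i.e. the
#'   uniform with that mean/SD) or `"normal"`.
#' @param store_stride store every `store_stride`-th Euler step.
#' @param seed integer seed for initial phases and frequency draws.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(k, duration, transient = 0, dt = 0.1,
                       omega_mean = 60, omega_sd = 1,
                       omega_dist = c("uniform", "normal"),
                       store_stride = 1L, seed = 1L) {
  omega_dist <- match.arg(omega_dist)
  if (dt <= 0) stop("dt must be positive")
  if (duration <= transient) stop("duration must exceed transient")
  if (omega_sd < 0) stop("omega_sd must be non-negative")
  structure(list(k = k, duration = duration, transient = transient, dt = dt,
                 omega_mean = omega_mean, omega_sd = omega_sd,
                 omega_dist = omega_dist,
                 store_stride = as.integer(store_stride),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw intrinsic oscillator frequencies
#'
#' @param n number of oscillators.
#' @param cfg a [sim_config()] (uses `omega_mean`, `omega_sd`,
#'   `omega_dist`).
#' @return numeric vector of frequencies in Hz.
#' @export
draw_frequencies <- function(n, cfg) {
  switch(cfg$omega_dist,
    uniform = stats::runif(n, cfg$omega_mean - sqrt(3) * cfg$omega_sd,
                              cfg$omega_mean + sqrt(3) * cfg$omega_sd),
    normal  = stats::rnorm(n, cfg$omega_mean, cfg$omega_sd))
}

#' Run one delay-coupled Kuramoto simulation
#'
#' @param sc a [structural_connectome()].
#' @param dm a [build_delay_model()] result whose `dt` matches `cfg$dt`.
#' @param cfg a [sim_config()].
#' @param omega optional explicit vector of angular frequencies in rad/s
#'   (overrides the `cfg` frequency draw; useful for analytic test cases).
#' @param theta0 optional explicit initial phases in radians.
#' @return Object of class `simulated_phases`: `phases` (N x T_stored,
#'   radians, wrapped), `dt_effective` (seconds between stored samples),
#'   `config`, `region_ids`.
#' @export
simulate_kuramoto <- function(sc, dm, cfg, omega = NULL, theta0 = NULL) {
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(dm, "delay_model"), inherits(cfg, "sim_config"))
  if (abs(dm$dt - cfg$dt) > 1e-12)
    stop("delay model was discretized at dt = ", dm$dt,
         " ms but config requests ", cfg$dt, " ms")
  n <- nrow(sc$weights)
  set.seed(cfg$seed)
  if (is.null(theta0)) theta0 <- stats::runif(n, 0, 2 * pi)
  if (is.null(omega)) omega <- 2 * pi * draw_frequencies(n, cfg)
  dt_s <- cfg$dt / 1000
  n_steps <- as.integer(round(cfg$duration / dt_s))
  transient_steps <- as.integer(round(cfg$transient / dt_s))
  res <- .kuramoto_core(sc$weights, dm$delay_steps, omega, theta0,
                        cfg$k, dt_s, n_steps, transient_steps,
                        cfg$store_stride)
  phases <- res$phases[, seq_len(res$n_stored), drop = FALSE]
  rownames(phases) <- sc$region_ids
  structure(list(phases = phases,
                 dt_effective = dt_s * cfg$store_stride,
                 config = cfg, region_ids = sc$region_ids,
                 max_delay_steps = res$max_delay_steps),
            class = "simulated_phases")
}

#' @export
print.simulated_phases <- function(x, ...) {
  cat("simulated_phases:", nrow(x$phases), "oscillators x", ncol(x$phases),
      "stored samples @", x$dt_effective, "s (k =", x$config$k, ")\n")
  invisible(x)
}

#' Sweep the global coupling strength
#'
#' Simulates the whole connectome once per coupling value (same seed for
#' every k, so sweeps differ only through k) and summarizes synchrony and
#' metastability per network on the stored phases. Simulated phases feed
#' the order parameter directly, without wavelet/Hilbert re-processing.
#'
#' @param sc a [structural_connectome()].
#' @param dm a [build_delay_model()] result.
#' @param cfg_base a [sim_config()]; its `k` is replaced by each sweep
#'   value.
#' @param ks numeric vector of coupling strengths.
#' @param partition a [network_partition()], or `NULL` to treat the whole
#'   connectome as a single network `"global"`.
#' @return data.frame with columns `k`, `network`, `n_members`,
#'   `synchrony`, `metastability`.
#' @export
coupling_sweep <- function(sc, dm, cfg_base, ks, partition = NULL) {
  if (!length(ks)) stop("ks must be non-empty")
  nets <- if (is.null(partition)) list(global = sc$region_ids)
          else stats::setNames(lapply(partition$networks, network_members,
                                      partition = partition),
                               partition$networks)
  out <- lapply(ks, function(k) {
    cfg <- cfg_base; cfg$k <- k
    sim <- simulate_kuramoto(sc, dm, cfg)
    do.call(rbind, lapply(names(nets), function(nw) {
      ops <- order_parameter_series(sim$phases, nets[[nw]], network = nw)
      data.frame(k = k, network = nw, n_members = ops$n_members,
                 synchrony = synchrony(ops),
                 metastability = metastability(ops),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
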