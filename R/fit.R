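# Empirical-vs-simulated model fit: absolute differences in synchrony and
# metastability per network across the coupling sweep, and the optimal
# coupling per network.

#' Absolute fit error between simulated and empirical network summaries
#'
#' @param sim,emp data.frames with columns `network`, `synchrony`,
#'   `metastability` (one row per network; `sim` may also carry `k`).
#' @return data.frame with `network` (and `k` if present in `sim`),
#'   `synchrony_error`, `metastability_error` — the absolute differences.
#' @export
fit_error <- function(sim, emp) {
  if (!setequal(sim$network, emp$network))
    stop("network labels differ between simulated and empirical summaries")
  i <- match(sim$network, emp$network)
  out <- data.frame(network = sim$network,
                    synchrony_error = abs(sim$synchrony - emp$synchrony[i]),
                    metastability_error =
                      abs(sim$metastability - emp$metastability[i]),
                    stringsAsFactors = FALSE)
  if (!is.null(sim$k)) out <- cbind(k = sim$k, out)
  out
}

#' Optimal coupling strength per network
#'
#' Either the coupling of maximal simulated metastability (the working
#' point at which the model best reproduces empirical dynamics) or the
#' coupling minimizing the absolute fit error. Ties resolve to the
#' smallest k.
#'
#' @param sweep data.frame from [coupling_sweep()] (columns `k`,
#'   `network`, `synchrony`, `metastability`); for
#'   `criterion = "min_error"` it must carry error columns from
#'   [fit_error()].
#' @param criterion `"max_metastability"` (default) or `"min_error"`
#'   (sum of synchrony and metastability absolute errors).
#' @return data.frame with `network`, `k_opt`, and the criterion value at
#'   the optimum.
#' @export
optimal_coupling <- function(sweep,
                             criterion = c("max_metastability", "min_error")) {
  criterion <- match.arg(criterion)
  if (!nrow(sweep)) stop("empty sweep")
  rows <- lapply(split(sweep, sweep$network), function(df) {
    df <- df[order(df$k), , drop = FALSE]
    if (criterion == "max_metastability") {
      i <- which.max(df$metastability)  # which.max takes the first = smallest k
      data.frame(network = df$network[1], k_opt = df$k[i],
                 metastability = df$metastability[i],
                 stringsAsFactors = FALSE)
    } else {
      err <- df$synchrony_error + df$metastability_error
      i <- which.min(err)
      data.frame(network = df$network[1], k_opt = df$k[i], error = err[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
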