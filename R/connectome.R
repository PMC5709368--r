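#' Structural connectome container
#'
#' Bundles a weighted anatomical connectivity matrix (streamline-density
#' units), the companion tract-length matrix (mm) and, optionally, ROI
#' volumes (mm^3). Both matrices must be symmetric with zero diagonals, and
#' every structural connection must carry a positive tract length.
#'
#' @param weights N x N non-negative numeric matrix of connection weights.
#' @param lengths N x N non-negative numeric matrix of tract lengths in mm.
#' @param region_ids character vector of N region labels; defaults to the
#'   row names of `weights` or `"R1"..."RN"`.
#' @param volumes optional numeric vector of N strictly positive ROI
#'   volumes in mm^3.
#' @return An object of class `structural_connectome` with elements
#'   `weights`, `lengths`, `region_ids`, `volumes`.
#' @export
structural_connectome <- function(weights, lengths, region_ids = NULL,
                                  volumes = NULL) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  if (!identical(dim(weights), dim(lengths)))
    stop("weights and lengths must have identical dimensions")
  n <- nrow(weights)
  if (n < 2L || ncol(weights) != n)
    stop("connectome matrices must be square with N >= 2")
  if (is.null(region_ids)) {
    region_ids <- rownames(weights)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n || anyDuplicated(region_ids))
    stop("region_ids must be ", n, " unique labels")
  for (nm in c("weights", "lengths")) {
    m <- get(nm)
    if (anyNA(m) || any(!is.finite(m))) stop(nm, " contains non-finite values")
    if (any(m < 0)) stop(nm, " contains negative entries")
  }
  weights <- .symmetrize(weights, "weights")
  lengths <- .symmetrize(lengths, "lengths")
  diag(weights) <- 0
  diag(lengths) <- 0
  if (any(weights > 0 & lengths <= 0))
    stop("every positive weight requires a positive tract length")
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != n || anyNA(volumes) || any(volumes <= 0))
      stop("volumes must be ", n, " strictly positive values")
  }
  dimnames(weights) <- dimnames(lengths) <- list(region_ids, region_ids)
  structure(list(weights = weights, lengths = lengths,
                 region_ids = region_ids, volumes = volumes),
            class = "structural_connectome")
}

# Average (A + t(A))/2 when the relative asymmetry is within tolerance,
# refuse otherwise: silent averaging of a genuinely asymmetric matrix
# would hide an upstream error.
.symmetrize <- function(m, what, tol = 1e-8) {
  asym <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  if (asym > tol * scale)
    stop(what, " is asymmetric beyond tolerance (max |A - t(A)| = ",
         format(asym), ")")
  (m + t(m)) / 2
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- length(x$region_ids)
  cat("structural_connectome:", n, "regions,",
      sum(x$weights[upper.tri(x$weights)] > 0), "connections,",
      if (is.null(x$volumes)) "no volumes" else "with volumes", "\n")
  invisible(x)
}

#' Regional time-series container
#'
#' @param data N x T numeric matrix, one row per region.
#' @param dt_sample sampling interval in seconds (the TR for fMRI data).
#' @param region_ids character vector of N region labels.
#' @return An object of class `regional_timeseries`.
#' @export
regional_timeseries <- function(data, dt_sample, region_ids = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data)))
    stop("time series contain missing or non-finite values")
  if (ncol(data) < 32L)
    stop("need T >= 32 samples (minimum for level-4 wavelet decomposition), got ",
         ncol(data))
  if (!is.numeric(dt_sample) || length(dt_sample) != 1L || dt_sample <= 0)
    stop("dt_sample must be a positive scalar (seconds)")
  if (is.null(region_ids)) {
    region_ids <- rownames(data)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(data)))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(data) || anyDuplicated(region_ids))
    stop("region_ids must be ", nrow(data), " unique labels")
  rownames(data) <- region_ids
  structure(list(data = data, dt_sample = dt_sample, region_ids = region_ids),
            class = "regional_timeseries")
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat("regional_timeseries:", nrow(x$data), "regions x", ncol(x$data),
      "samples @", x$dt_sample, "s\n")
  invisible(x)
}

#' Region-to-network partition
#'
#' Maps region ids to resting-state network labels (e.g. DMN, CEN, SAL,
#' SMN, VN, AN). Regions absent from `assignment` are unassigned; every
#' network must have at least two member regions.
#'
#' @param assignment named character vector: names are region ids, values
#'   are network labels.
#' @param region_ids full ordered parcellation; every assigned region must
#'   occur here.
#' @return An object of class `network_partition` with `assignment`,
#'   `networks` (ordered unique labels) and `region_ids`.
#' @export
network_partition <- function(assignment, region_ids) {
  region_ids <- as.character(region_ids)
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("assignment must be a named vector (region id -> network label)")
  dup <- duplicated(names(assignment))
  if (any(dup)) {
    agree <- vapply(unique(names(assignment)[dup]), function(id)
      length(unique(assignment[names(assignment) == id])) == 1L, logical(1))
    if (!all(agree)) stop("conflicting network labels for region(s): ",
                          paste(unique(names(assignment)[dup])[!agree],
                                collapse = ", "))
    assignment <- assignment[!dup]
  }
  unknown <- setdiff(names(assignment), region_ids)
  if (length(unknown))
    stop("assigned region id(s) not in parcellation: ",
         paste(unknown, collapse = ", "))
  sizes <- table(assignment)
  if (any(sizes < 2L))
    stop("every network needs >= 2 member regions; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  structure(list(assignment = assignment,
                 networks = unique(unname(assignment)),
                 region_ids = region_ids),
            class = "network_partition")
}

#' Member region ids of one network
#' @param partition a `network_partition`.
#' @param network a network label.
#' @return character vector of member region ids, in parcellation order.
#' @export
network_members <- function(partition, network) {
  ids <- names(partition$assignment)[partition$assignment == network]
  if (!length(ids)) stop("unknown network label: ", network)
  partition$region_ids[partition$region_ids %in% ids]
}

#' @export
print.network_partition <- function(x, ...) {
  cat("network_partition:", length(x$networks), "networks over",
      length(x$assignment), "of", length(x$region_ids), "regions\n")
  print(table(x$assignment))
  invisible(x)
}

## ------------------------------------------------------------------ I/O

.read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1)
  as.matrix(df)
}

.write_matrix <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load a structural connectome from delimited text
#'
#' Reads headered TSV matrices (first column = region id). Region order in
#' the weights file is authoritative; the lengths (and volumes) files must
#' use the same order.
#'
#' @param weights_path,lengths_path paths to N x N TSV matrices.
#' @param volumes_path optional path to a two-column TSV
#'   (`region`, `volume`).
#' @return A [structural_connectome()].
#' @export
load_connectome <- function(weights_path, lengths_path, volumes_path = NULL) {
  w <- .read_matrix(weights_path)
  l <- .read_matrix(lengths_path)
  if (!identical(dim(w), dim(l)))
    stop("shape mismatch: weights ", nrow(w), "x", ncol(w),
         " vs lengths ", nrow(l), "x", ncol(l))
  if (!identical(rownames(w), rownames(l)))
    stop("region id mismatch between weights and lengths files")
  vols <- NULL
  if (!is.null(volumes_path)) {
    vt <- utils::read.table(volumes_path, header = TRUE, sep = "\t")
    vols <- vt[[2]][match(rownames(w), as.character(vt[[1]]))]
    if (anyNA(vols)) stop("volumes file is missing regions")
  }
  structural_connectome(w, l, region_ids = rownames(w), volumes = vols)
}

#' Write a structural connectome to delimited text
#' @param sc a `structural_connectome`.
#' @param weights_path,lengths_path,volumes_path output TSV paths
#'   (volumes written only when present and a path is given).
#' @return `sc`, invisibly.
#' @export
save_connectome <- function(sc, weights_path, lengths_path,
                            volumes_path = NULL) {
  .write_matrix(sc$weights, weights_path)
  .write_matrix(sc$lengths, lengths_path)
  if (!is.null(volumes_path) && !is.null(sc$volumes))
    utils::write.table(
      data.frame(region = sc$region_ids, volume = sc$volumes),
      volumes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sc)
}

#' Load regional time series from delimited text
#'
#' @param path TSV with a header of region ids; stored regions x time
#'   (`orientation = "regions_x_time"`, default) or time x regions.
#' @param dt_sample sampling interval in seconds.
#' @param orientation one of `"regions_x_time"`, `"time_x_regions"`.
#' @return A [regional_timeseries()].
#' @export
load_timeseries <- function(path, dt_sample,
                            orientation = c("regions_x_time",
                                            "time_x_regions")) {
  orientation <- match.arg(orientation)
  m <- .read_matrix(path)
  if (orientation == "time_x_regions") m <- t(m)
  regional_timeseries(m, dt_sample = dt_sample, region_ids = rownames(m))
}

#' Write regional time series to delimited text (regions x time)
#' @param ts a `regional_timeseries`.
#' @param path output TSV path.
#' @return `ts`, invisibly.
#' @export
save_timeseries <- function(ts, path) {
  m <- ts$data
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  .write_matrix(m, path)
  invisible(ts)
}

#' Load a region-to-network partition table
#' @param path two-column TSV (`region`, `network`) with header.
#' @param region_ids the full parcellation (e.g. `sc$region_ids`).
#' @return A [network_partition()].
#' @export
load_partition <- function(path, region_ids) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  network_partition(stats::setNames(df[[2]], df[[1]]), region_ids)
}

#' Write a partition table
#' @param partition a `network_partition`.
#' @param path output TSV path.
#' @return `partition`, invisibly.
#' @export
save_partition <- function(partition, path) {
  ids <- partition$region_ids[partition$region_ids %in%
                                names(partition$assignment)]
  utils::write.table(
    data.frame(region = ids, network = unname(partition$assignment[ids])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(partition)
}

## --------------------------------------------------------- transformations

#' Normalize connection weights by ROI volume
#'
#' Divides each weight by the arithmetic mean of the two connected ROI
#' volumes, correcting for the tendency of larger regions to accumulate
#' more streamlines. The mean (rather than sum or product) keeps the
#' operation symmetric and the units interpretable as streamlines per unit
#' volume.
#'
#' @param sc a `structural_connectome` with volumes.
#' @return A `structural_connectome` with rescaled weights.
#' @export
normalize_weights_by_volume <- function(sc) {
  if (is.null(sc$volumes)) stop("connectome has no ROI volumes")
  v <- sc$volumes
  pairmean <- (outer(v, v, "+")) / 2
  w <- sc$weights / pairmean
  diag(w) <- 0
  structural_connectome(w, sc$lengths, region_ids = sc$region_ids,
                        volumes = v)
}

#' Group-average a list of structural connectomes
#'
#' Element-wise mean of the weight and length matrices across subjects,
#' producing the group connectome that constrains the simulator.
#'
#' @param scs non-empty list of `structural_connectome` objects sharing
#'   the same region ordering.
#' @return The group-averaged `structural_connectome` (volumes dropped).
#' @export
group_average_connectomes <- function(scs) {
  if (!length(scs)) stop("need at least one connectome")
  ids <- scs[[1]]$region_ids
  for (sc in scs)
    if (!identical(sc$region_ids, ids))
      stop("connectomes have mismatched region orderings")
  w <- Reduce(`+`, lapply(scs, `[[`, "weights")) / length(scs)
  l <- Reduce(`+`, lapply(scs, `[[`, "lengths")) / length(scs)
  structural_connectome(w, l, region_ids = ids)
}
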