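#' Detect per-node seizure onsets from the slow permittivity variable
#'
#' Operationalizes "the time when z starts increasing": for each node a
#' baseline mean and standard deviation are computed over the window
#' `[warmup - baseline_window, warmup]`; the onset is the first time after
#' `warmup` at which the (lightly smoothed) z series exceeds
#' `mean + max(eps_abs, k_sigma * sd)` and keeps non-decreasing for the
#' persistence window. Nodes that never cross report `NA`.
#'
#' @param z an `epileptor_trajectory`, or a samples x nodes matrix (a plain
#'   vector is treated as a single node) of z values.
#' @param times sampling times; taken from the trajectory when omitted.
#' @param warmup end of the transient to ignore (defaults to the
#'   trajectory's `warmup`, else 15).
#' @param baseline_window length of the baseline window ending at `warmup`
#'   (default 10 time units).
#' @param k_sigma baseline-noise multiple for the threshold (default 5).
#' @param eps_abs absolute floor of the threshold (default 0.05).
#' @param persistence time for which the smoothed series must stay
#'   non-decreasing after the crossing (default 1 time unit).
#' @param smooth_samples width (samples) of the centered moving average used
#'   before the monotonicity check (default 11).
#' @return Named numeric vector of onset times, `NA` where no onset.
#' @export
detect_onsets <- function(z, times = NULL, warmup = NULL,
                          baseline_window = 10, k_sigma = 5, eps_abs = 0.05,
                          persistence = 1, smooth_samples = 11) {
  if (inherits(z, "epileptor_trajectory")) {
    if (is.null(times)) times <- z$times
    if (is.null(warmup)) warmup <- z$params$warmup
    z <- z$z
  }
  if (is.null(warmup)) warmup <- 15
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (is.null(times)) stop("supply sampling times", call. = FALSE)
  if (!all(is.finite(z))) stop("z series must be finite", call. = FALSE)
  base_ix <- which(times >= warmup - baseline_window & times <= warmup)
  if (length(base_ix) < 10)
    stop("degenerate baseline window (fewer than 10 samples)", call. = FALSE)
  post_ix <- which(times > warmup)
  dt_out <- stats::median(diff(times))
  n_persist <- max(1L, ceiling(persistence / dt_out))
  k <- min(smooth_samples, nrow(z))
  onsets <- vapply(seq_len(ncol(z)), function(i) {
    zi <- z[, i]
    zs <- smooth_ma(zi, k)
    mu <- mean(zi[base_ix])
    s <- stats::sd(zi[base_ix])
    thr <- mu + max(eps_abs, k_sigma * s)
    cand <- post_ix[zs[post_ix] > thr]
    for (t0 in cand) {
      hi <- min(length(zi), t0 + n_persist)
      if (all(diff(zs[t0:hi]) >= -1e-12)) return(times[t0])
    }
    NA_real_
  }, numeric(1))
  names(onsets) <- colnames(z)
  onsets
}

# centered moving average, edges padded with the edge values
smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  half <- floor(k / 2)
  k <- 2L * half + 1L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[half + seq_along(x)]
}

#' Time distance from seizure onset in the epileptogenic zone
#'
#' For each node `i`, `T_i` is 0 if `i` is in the EZ (and it seized),
#' `T_onset,i - T_onset,EZ` if the node was recruited, and `NA` for
#' non-recruited nodes. With a multi-node EZ the reference time is the
#' earliest EZ onset.
#'
#' @param onset_times per-node (possibly `NA`) onset times.
#' @param ez_nodes integer indices of the epileptogenic-zone node(s).
#' @return Numeric vector of time distances, `NA` where not recruited.
#' @export
time_distances <- function(onset_times, ez_nodes) {
  n <- length(onset_times)
  ez_nodes <- as.integer(ez_nodes)
  if (any(ez_nodes < 1 | ez_nodes > n))
    stop("ez_nodes out of range", call. = FALSE)
  ez_onsets <- onset_times[ez_nodes]
  if (all(is.na(ez_onsets)))
    stop("EZ never seized: no onset detected in any EZ node", call. = FALSE)
  t_ref <- min(ez_onsets, na.rm = TRUE)
  td <- onset_times - t_ref
  td[ez_nodes] <- ifelse(is.na(onset_times[ez_nodes]), NA_real_, 0)
  names(td) <- names(onset_times)
  td
}

#' Per-run onset table
#'
#' Combines onset detection, time distances and propagation classification
#' for one simulated seizure into a single summary object.
#'
#' @param traj an `epileptor_trajectory` (or a precomputed onset vector via
#'   `onsets`).
#' @param ez_nodes integer indices of the epileptogenic zone.
#' @param onsets optional precomputed per-node onset times, bypassing
#'   [detect_onsets()].
#' @param localized_max_regions,widespread_min_fraction classification
#'   settings, see [classify_propagation()].
#' @param ... further arguments passed to [detect_onsets()].
#' @return An object of class `onset_table`: a list with a per-node
#'   data frame (`node`, `label`, `onset_time`, `time_distance`,
#'   `recruited`), the EZ indices, `recruited_count`, `recruited_fraction`
#'   and `propagation_class`.
#' @export
onset_table <- function(traj, ez_nodes, onsets = NULL,
                        localized_max_regions = 2,
                        widespread_min_fraction = 0.5, ...) {
  if (is.null(onsets)) onsets <- detect_onsets(traj, ...)
  n <- length(onsets)
  ez_nodes <- as.integer(ez_nodes)
  td <- time_distances(onsets, ez_nodes)
  is_ez <- seq_len(n) %in% ez_nodes
  recruited <- !is.na(onsets) & !is_ez
  n_non_ez <- n - length(ez_nodes)
  frac <- if (n_non_ez > 0) sum(recruited) / n_non_ez else 0
  tab <- data.frame(
    node = seq_len(n),
    label = names(onsets) %||% paste0("node_", seq_len(n) - 1L),
    onset_time = unname(onsets),
    time_distance = unname(td),
    recruited = recruited,
    row.names = NULL
  )
  out <- structure(
    list(table = tab, ez_nodes = ez_nodes,
         recruited_count = sum(recruited), recruited_fraction = frac,
         propagation_class = NA_character_),
    class = "onset_table"
  )
  out$propagation_class <- classify_propagation(
    out, localized_max_regions = localized_max_regions,
    widespread_min_fraction = widespread_min_fraction)
  out
}

#' @export
print.onset_table <- function(x, ...) {
  cat(sprintf("<onset_table> EZ = {%s}; %d/%d non-EZ nodes recruited (%.1f%%): %s\n",
              paste(x$ez_nodes, collapse = ", "), x$recruited_count,
              nrow(x$table) - length(x$ez_nodes),
              100 * x$recruited_fraction, x$propagation_class))
  invisible(x)
}

#' Classify seizure propagation as localized, widespread or partial
#'
#' A run is `localized` when at most `localized_max_regions` non-EZ regions
#' were recruited, `widespread` when the recruited fraction reaches
#' `widespread_min_fraction` (a seizure reaching almost all brain areas),
#' and `partial` otherwise. The partial class is a safety valve: simulated
#' seizures empirically fall into the two extreme classes.
#'
#' @param x an `onset_table`, or a list with `recruited_count` and
#'   `recruited_fraction` entries.
#' @param localized_max_regions maximum recruited regions still counted as
#'   localized (default 2).
#' @param widespread_min_fraction minimum recruited fraction for the
#'   widespread class (default 0.5).
#' @return One of `"localized"`, `"widespread"`, `"partial"`.
#' @export
classify_propagation <- function(x, localized_max_regions = 2,
                                 widespread_min_fraction = 0.5) {
  if (x$recruited_count <= localized_max_regions) return("localized")
  if (x$recruited_fraction >= widespread_min_fraction) return("widespread")
  "partial"
}
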