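#' Sweep epileptogenic-zone locations across connectomes
#'
#' For each (connectome, EZ node) pair, runs one simulation with a
#' single-node epileptogenic zone (`x0 = x0_ez` there, `x0 = x0_pz`
#' elsewhere), detects onsets, classifies propagation and attaches the EZ's
#' graph measures. A simulation or detection failure flags the row instead
#' of aborting the sweep.
#'
#' @param connectomes a `connectome` or (optionally named) list of them.
#' @param ez_nodes integer vector of EZ node indices to sweep.
#' @param params an [epileptor_params()] template; the per-row seed is
#'   `params$seed + row index - 1`, recorded in the result.
#' @param x0_ez,x0_pz epileptogenicity of the EZ node and of all others
#'   (defaults -1.6 and -2.1).
#' @param ... passed to [onset_table()] (detection and classification
#'   settings).
#' @return A `sweep_result`: data frame with one row per (connectome, EZ):
#'   `connectome_id`, `ez_node`, `ez_label`, `seed`, `recruited_count`,
#'   `recruited_fraction`, `propagation_class`, `ez_max_out_weight`,
#'   `ez_out_degree`, `ez_eig_centrality`, `ez_avg_shortest_path` (the last
#'   three max-normalized within their connectome), and `failed`.
#' @export
ez_sweep <- function(connectomes, ez_nodes, params = epileptor_params(),
                     x0_ez = -1.6, x0_pz = -2.1, ...) {
  if (inherits(connectomes, "connectome")) connectomes <- list(connectomes)
  ids <- names(connectomes)
  if (is.null(ids))
    ids <- vapply(seq_along(connectomes), function(k)
      attr(connectomes[[k]], "id") %||% sprintf("connectome_%d", k),
      character(1))
  rows <- list()
  irow <- 0L
  for (k in seq_along(connectomes)) {
    C <- connectomes[[k]]
    nm <- node_measures(C)
    n <- n_nodes(C)
    for (ez in ez_nodes) {
      irow <- irow + 1L
      seed_k <- params$seed + irow - 1L
      p <- params
      p$x0 <- rep(x0_pz, n)
      p$x0[ez] <- x0_ez
      p$seed <- seed_k
      res <- tryCatch({
        traj <- simulate_epileptor(C, p)
        ot <- onset_table(traj, ez_nodes = ez, ...)
        list(count = ot$recruited_count, frac = ot$recruited_fraction,
             class = ot$propagation_class, failed = FALSE)
      }, error = function(e) {
        list(count = NA_integer_, frac = NA_real_,
             class = NA_character_, failed = TRUE)
      })
      rows[[irow]] <- data.frame(
        connectome_id = ids[k], ez_node = ez, ez_label = C$labels[ez],
        seed = seed_k, recruited_count = res$count,
        recruited_fraction = res$frac, propagation_class = res$class,
        ez_max_out_weight = nm$max_out_weight[ez],
        ez_out_degree = nm$norm_out_degree[ez],
        ez_eig_centrality = nm$norm_eig_centrality[ez],
        ez_avg_shortest_path = nm$norm_avg_shortest_path[ez],
        failed = res$failed, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Estimate the propagation-regime weight thresholds from a sweep
#'
#' The upper threshold is the largest strongest-outgoing weight among EZs
#' that produced localized seizures; the lower threshold is the smallest
#' strongest-outgoing weight among EZs that produced widespread seizures.
#' Any EZ with weight above the upper value was widespread and any below
#' the lower value was localized, by construction; the interval between
#' them (when the lower lies below the upper) is the mixed regime. Partial
#' or failed rows are excluded with a warning.
#'
#' @param sweep a `sweep_result` from [ez_sweep()].
#' @return An object of class `threshold_estimate`: list with `w_upper`,
#'   `w_lower` (either `NA` when its regime is absent) and the per-class
#'   `counts`.
#' @export
estimate_weight_thresholds <- function(sweep) {
  sw <- sweep[!sweep$failed & !is.na(sweep$propagation_class), , drop = FALSE]
  if (any(sw$propagation_class == "partial")) {
    warning("excluding ", sum(sw$propagation_class == "partial"),
            " partial rows from threshold estimation")
    sw <- sw[sw$propagation_class != "partial", , drop = FALSE]
  }
  loc <- sw$ez_max_out_weight[sw$propagation_class == "localized"]
  wid <- sw$ez_max_out_weight[sw$propagation_class == "widespread"]
  structure(
    list(w_upper = if (length(loc)) max(loc) else NA_real_,
         w_lower = if (length(wid)) min(wid) else NA_real_,
         counts = table(factor(sw$propagation_class,
                               levels = c("localized", "partial",
                                          "widespread")))),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> w_upper = %s (max localized), w_lower = %s (min widespread)\n",
              format(x$w_upper), format(x$w_lower)))
  print(x$counts)
  invisible(x)
}

#' Evaluate structural interventions against seizure propagation
#'
#' Applies each intervention to the connectome, reruns the simulation and
#' onset detection with the same seed and EZ, and reports the recruited
#' fraction and propagation class next to the unmodified baseline (always
#' included as the first row).
#'
#' @param C a `connectome`.
#' @param ez EZ node index.
#' @param specs list of [intervention_spec()]s (possibly empty).
#' @param params an [epileptor_params()] template.
#' @param x0_ez,x0_pz epileptogenicity values as in [ez_sweep()].
#' @param ... passed to [onset_table()].
#' @return Data frame with one row per case (`baseline` first):
#'   `case`, `recruited_count`, `recruited_fraction`, `propagation_class`,
#'   `ez_max_out_weight` (after the intervention), `failed`.
#' @export
evaluate_interventions <- function(C, ez, specs = list(),
                                   params = epileptor_params(),
                                   x0_ez = -1.6, x0_pz = -2.1, ...) {
  validate_connectome(C)
  cases <- c(list(baseline = NULL), stats::setNames(
    specs, vapply(specs, function(s) s$label, character(1))))
  rows <- lapply(seq_along(cases), function(k) {
    Ck <- if (is.null(cases[[k]])) C else apply_intervention(C, cases[[k]])
    p <- params
    p$x0 <- rep(x0_pz, n_nodes(Ck))
    p$x0[ez] <- x0_ez
    res <- tryCatch({
      traj <- simulate_epileptor(Ck, p)
      ot <- onset_table(traj, ez_nodes = ez, ...)
      list(count = ot$recruited_count, frac = ot$recruited_fraction,
           class = ot$propagation_class, failed = FALSE)
    }, error = function(e) list(count = NA_integer_, frac = NA_real_,
                                class = NA_character_, failed = TRUE))
    data.frame(case = names(cases)[k], recruited_count = res$count,
               recruited_fraction = res$frac,
               propagation_class = res$class,
               ez_max_out_weight = max_outgoing_weight(Ck, ez),
               failed = res$failed, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Scan outgoing-weight reduction levels
#'
#' Applies [reduce_outgoing()] to the EZ at each reduction level on each
#' connectome, reruns simulation and detection, and reports the recruited
#' fraction per (connectome, level). The attribute
#' `minimal_confining_level` records the smallest level that yields a
#' localized seizure on every connectome (`NA` if none does).
#'
#' @param connectomes a `connectome` or list of them.
#' @param ez EZ node index.
#' @param levels reduction fractions to scan (default 0, 0.1, ..., 0.5).
#' @param params an [epileptor_params()] template.
#' @param x0_ez,x0_pz epileptogenicity values as in [ez_sweep()].
#' @param ... passed to [onset_table()].
#' @return Data frame with `connectome_id`, `level`, `recruited_count`,
#'   `recruited_fraction`, `propagation_class`, `failed`; attribute
#'   `minimal_confining_level`.
#' @export
reduction_scan <- function(connectomes, ez, levels = seq(0, 0.5, by = 0.1),
                           params = epileptor_params(),
                           x0_ez = -1.6, x0_pz = -2.1, ...) {
  if (any(levels < 0 | levels > 1))
    stop("levels must lie in [0, 1]", call. = FALSE)
  if (inherits(connectomes, "connectome")) connectomes <- list(connectomes)
  ids <- names(connectomes)
  if (is.null(ids))
    ids <- vapply(seq_along(connectomes), function(k)
      attr(connectomes[[k]], "id") %||% sprintf("connectome_%d", k),
      character(1))
  rows <- list()
  irow <- 0L
  for (k in seq_along(connectomes)) {
    for (lv in levels) {
      irow <- irow + 1L
      Ck <- if (lv == 0) connectomes[[k]] else
        reduce_outgoing(connectomes[[k]], ez, lv)
      p <- params
      p$x0 <- rep(x0_pz, n_nodes(Ck))
      p$x0[ez] <- x0_ez
      res <- tryCatch({
        traj <- simulate_epileptor(Ck, p)
        ot <- onset_table(traj, ez_nodes = ez, ...)
        list(count = ot$recruited_count, frac = ot$recruited_fraction,
             class = ot$propagation_class, failed = FALSE)
      }, error = function(e) list(count = NA_integer_, frac = NA_real_,
                                  class = NA_character_, failed = TRUE))
      rows[[irow]] <- data.frame(
        connectome_id = ids[k], level = lv, recruited_count = res$count,
        recruited_fraction = res$frac, propagation_class = res$class,
        failed = res$failed, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  ok <- !out$failed & !is.na(out$propagation_class)
  confining <- vapply(sort(unique(out$level)), function(lv) {
    sub <- out[ok & out$level == lv, , drop = FALSE]
    nrow(sub) == length(connectomes) &&
      all(sub$propagation_class == "localized")
  }, logical(1))
  lvls <- sort(unique(out$level))
  attr(out, "minimal_confining_level") <-
    if (any(confining)) min(lvls[confining]) else NA_real_
  out
}

#' Simulated functional connectivity
#'
#' Pearson correlation matrix of the per-node LFP proxy (`x2 - x1`) over
#' the post-warmup window. A node with (numerically) constant signal gets
#' zero correlations off the diagonal, with a warning.
#'
#' @param traj an `epileptor_trajectory`.
#' @param from start of the correlation window (defaults to the
#'   trajectory's warmup).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
functional_connectivity <- function(traj, from = NULL) {
  if (is.null(from)) from <- traj$params$warmup
  ix <- traj$times >= from
  if (!any(ix)) stop("empty post-warmup window", call. = FALSE)
  X <- traj$lfp[ix, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  flat <- sds < 1e-12
  FC <- diag(1, ncol(X))
  dimnames(FC) <- list(colnames(X), colnames(X))
  live <- which(!flat)
  if (length(live) >= 2) FC[live, live] <- stats::cor(X[, live, drop = FALSE])
  if (any(flat)) {
    warning("constant LFP on ", sum(flat),
            " node(s); their correlations are reported as 0")
  }
  diag(FC) <- 1
  FC
}

#' Similarity between two functional connectivity matrices
#'
#' Pearson correlation of the upper triangles (diagonal excluded) of two
#' equally sized square matrices — the summary used to judge how much of
#' the baseline functional organization an intervention preserves.
#'
#' @param A,B square numeric matrices of equal dimension.
#' @return Scalar correlation.
#' @export
fc_similarity <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("matrices must have identical dimensions", call. = FALSE)
  ut <- upper.tri(A)
  stats::cor(A[ut], B[ut])
}
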