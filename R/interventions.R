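#' Remove connectome edges with renormalization
#'
#' Sets the listed directed edges to zero and then renormalizes the whole
#' matrix so its global maximum weight is exactly one again — the in-silico
#' analogue of resecting specific fiber tracts while keeping the connectome
#' on its conventional max-normalized scale. `removal_norm = "sum"`
#' rescales to preserve the total connective strength instead, and
#' `"none"` skips rescaling.
#'
#' @param C a `connectome`.
#' @param edges an `m x 2` matrix or data frame of `(source, target)` node
#'   index pairs, or a length-2 vector for a single edge.
#' @param removal_norm `"max"` (default), `"sum"` or `"none"`.
#' @return A new `connectome`; the input is not modified.
#' @export
remove_edges <- function(C, edges, removal_norm = c("max", "sum", "none")) {
  removal_norm <- match.arg(removal_norm)
  validate_connectome(C)
  edges <- edge_matrix(edges, n_nodes(C))
  w <- C$weights
  total_before <- sum(w)
  # row-target storage: edge src -> dst lives at [dst, src]
  w[cbind(edges[, 2], edges[, 1])] <- 0
  if (removal_norm == "max") {
    m <- max(w)
    if (m == 0)
      stop("all positive edges removed; cannot renormalize", call. = FALSE)
    w <- w / m
  } else if (removal_norm == "sum") {
    s <- sum(w)
    if (s == 0)
      stop("all positive edges removed; cannot renormalize", call. = FALSE)
    w <- w * (total_before / s)
  }
  out <- C
  out$weights <- w
  validate_connectome(out)
}

edge_matrix <- function(edges, n) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  if (any(edges < 1 | edges > n)) stop("edge index out of range", call. = FALSE)
  if (any(edges[, 1] == edges[, 2]))
    stop("self-edges are not part of the connectome", call. = FALSE)
  edges
}

#' Reduce a node's outgoing weights, preserving total strength
#'
#' Multiplies all outgoing connections of `node` by `1 - p` and then
#' rescales the whole matrix so the grand total of weights equals its value
#' before the reduction — a macroscopic stand-in for suppressing the
#' hyperexcitability of an epileptogenic area (drug or neuromodulation)
#' while conserving overall connective strength.
#'
#' @param C a `connectome`.
#' @param node node index whose outgoing weights are reduced.
#' @param p reduction fraction in `[0, 1]`; `p = 0` is the identity,
#'   `p = 1` silences all output of the node.
#' @return A new `connectome`; the input is not modified.
#' @export
reduce_outgoing <- function(C, node, p) {
  validate_connectome(C)
  node <- as.integer(node)
  if (length(node) != 1 || node < 1 || node > n_nodes(C))
    stop("node index out of range", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
    stop("p must be a single fraction in [0, 1]", call. = FALSE)
  w <- C$weights
  total_before <- sum(w)
  w[, node] <- (1 - p) * w[, node]
  s <- sum(w)
  if (s == 0)
    stop("reduction left the connectome with zero total strength",
         call. = FALSE)
  w <- w * (total_before / s)
  out <- C
  out$weights <- w
  validate_connectome(out)
}

#' Intervention specification
#'
#' A small descriptor for one structural intervention, consumed by
#' [apply_intervention()] and [evaluate_interventions()].
#'
#' @param kind `"remove_edges"` or `"reduce_outgoing"`.
#' @param edges edge list for `remove_edges` (see [remove_edges()]).
#' @param node,p node index and reduction fraction for `reduce_outgoing`.
#' @param label optional human-readable label.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(kind = c("remove_edges", "reduce_outgoing"),
                              edges = NULL, node = NULL, p = NULL,
                              label = NULL) {
  kind <- match.arg(kind)
  if (kind == "remove_edges" && is.null(edges))
    stop("remove_edges needs an edge list", call. = FALSE)
  if (kind == "reduce_outgoing" && (is.null(node) || is.null(p)))
    stop("reduce_outgoing needs node and p", call. = FALSE)
  if (is.null(label)) {
    label <- if (kind == "remove_edges") {
      em <- if (is.null(dim(edges))) matrix(edges, ncol = 2, byrow = TRUE) else edges
      paste(apply(em, 1, function(e) sprintf("%d-x->%d", e[1], e[2])),
            collapse = ", ")
    } else {
      sprintf("reduce node %d by %d%%", node, round(100 * p))
    }
  }
  structure(list(kind = kind, edges = edges, node = node, p = p,
                 label = label),
            class = "intervention_spec")
}

#' Apply an intervention spec to a connectome
#'
#' @param C a `connectome`.
#' @param spec an [intervention_spec()].
#' @param ... passed to [remove_edges()] (e.g. `removal_norm`).
#' @return The modified `connectome`.
#' @export
apply_intervention <- function(C, spec, ...) {
  if (!inherits(spec, "intervention_spec"))
    stop("spec must be an intervention_spec", call. = FALSE)
  switch(spec$kind,
         remove_edges = remove_edges(C, spec$edges, ...),
         reduce_outgoing = reduce_outgoing(C, spec$node, spec$p))
}

#' Compare a connectome before and after an intervention
#'
#' Lists the individually changed entries (beyond any global rescaling),
#' reports per-node deltas of the strongest outgoing weight and eigenvector
#' centrality, and flags nodes whose strongest outgoing weight crossed the
#' supplied propagation-regime thresholds.
#'
#' @param before,after `connectome`s of identical shape.
#' @param w_lower,w_upper optional regime thresholds on the strongest
#'   outgoing weight (see [estimate_weight_thresholds()]).
#' @return A list with `rescale_factor` (the global ratio after/before over
#'   unchanged entries, `NA` if none), `changed` (data frame of entries that
#'   moved beyond the global rescaling), `node_deltas` (per-node data frame
#'   with before/after `max_out_weight` and `eig_centrality` and any
#'   threshold crossing).
#' @export
intervention_report <- function(before, after, w_lower = NULL,
                                w_upper = NULL) {
  validate_connectome(before)
  validate_connectome(after)
  wb <- before$weights
  wa <- after$weights
  if (!all(dim(wb) == dim(wa)))
    stop("connectomes have different shapes", call. = FALSE)
  pos <- wb > 0
  ratios <- wa[pos] / wb[pos]
  rescale <- if (any(pos)) as.numeric(names(sort(table(signif(ratios, 12)),
                                                 decreasing = TRUE))[1])
             else NA_real_
  rel_dev <- abs(wa - ifelse(is.na(rescale), 1, rescale) * wb)
  tol <- 1e-9 * max(wb, 1)
  ch <- which(rel_dev > tol & (wb > 0 | wa > 0), arr.ind = TRUE)
  changed <- data.frame(source = ch[, 2], target = ch[, 1],
                        before = wb[ch], after = wa[ch], row.names = NULL)
  n <- nrow(wb)
  mow_b <- max_outgoing_weight(before, seq_len(n))
  mow_a <- max_outgoing_weight(after, seq_len(n))
  ec_b <- eigenvector_centrality(before)
  ec_a <- eigenvector_centrality(after)
  nd <- data.frame(node = seq_len(n), label = before$labels,
                   max_out_weight_before = mow_b, max_out_weight_after = mow_a,
                   eig_centrality_before = ec_b, eig_centrality_after = ec_a,
                   row.names = NULL)
  if (!is.null(w_upper))
    nd$crossed_w_upper <- (mow_b > w_upper) & (mow_a <= w_upper)
  if (!is.null(w_lower))
    nd$crossed_w_lower <- (mow_b > w_lower) & (mow_a <= w_lower)
  list(rescale_factor = rescale, changed = changed, node_deltas = nd)
}
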