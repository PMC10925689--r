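#' Specification for a synthetic two-hemisphere connectome
#'
#' Describes a surrogate structural connectome with the statistical features
#' the propagation analysis relies on: two mirrored hemispheres, heavy-tailed
#' nonnegative background weights with the global maximum normalized to 1,
#' and a 3-node hippocampus-like focus subnetwork per hemisphere whose nodes
#' play the CA1/CA3/DG roles — strong connections within the focus triplet
#' and between the two hemispheres' triplets, plus moderate "gateway" edges
#' from the first and third focus node into the background (the entorhinal
#' cortex / subiculum analogues).
#'
#' The default `focus_out_weights` are the mouse hippocampal triplet pattern
#' (CA1 high, CA3 low, DG mid) placed so that it brackets the coupled
#' Epileptor's propagation band under the default model constants: the
#' high-weight node lies above the single-edge recruitment threshold, the
#' low-weight node below it, and the mid node near it (see the package
#' vignette for the calibration).
#'
#' @param n_per_hemisphere nodes per hemisphere (default 49, giving the
#'   98-node layout of the mirrored mouse atlas); at least 4.
#' @param background_weight_scale log-normal scale (median) of background
#'   weights before max-normalization (default 0.08).
#' @param background_sdlog log-normal shape of background weights
#'   (default 0.6).
#' @param density fraction of nonzero background edges (default 0.35;
#'   cross-hemisphere background edges are drawn at the same density but at
#'   half the weight).
#' @param focus_out_weights length-3 positive vector: the realized strongest
#'   outgoing weight of each focus node (high, low, mid roles; default
#'   `c(0.72, 0.36, 0.50)`).
#' @param focus_internal_weight weight of the secondary intra- and
#'   inter-hemispheric focus edges (default 0.4).
#' @param seed integer seed; generation is bit-reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_hemisphere = 49,
                           background_weight_scale = 0.08,
                           background_sdlog = 0.6,
                           density = 0.35,
                           focus_out_weights = c(0.72, 0.36, 0.50),
                           focus_internal_weight = 0.4,
                           seed = 1L) {
  if (n_per_hemisphere < 4)
    stop("n_per_hemisphere must be at least 4 (3 focus nodes + background)",
         call. = FALSE)
  if (density <= 0 || density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  if (length(focus_out_weights) != 3 || any(focus_out_weights <= 0))
    stop("focus_out_weights must be three positive reals", call. = FALSE)
  if (background_weight_scale <= 0 || focus_internal_weight <= 0)
    stop("weight parameters must be positive", call. = FALSE)
  structure(
    list(n_per_hemisphere = as.integer(n_per_hemisphere),
         background_weight_scale = background_weight_scale,
         background_sdlog = background_sdlog,
         density = density,
         focus_out_weights = focus_out_weights,
         focus_internal_weight = focus_internal_weight,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic mirrored connectome
#'
#' Builds one hemisphere — heavy-tailed log-normal background weights
#' thinned to the requested density, with the global background maximum
#' normalized to 1 — wires the focus triplet (see [synthetic_spec()]), and
#' mirrors it via [mirror_right_hemisphere()] so that R-R = L-L and
#' R-L = L-R exactly. Each focus node's realized strongest outgoing weight
#' equals its specified value exactly; weights above 1 are left as
#' specified.
#'
#' Focus wiring (per hemisphere; `w = focus_out_weights`,
#' `v = focus_internal_weight`, indices F1/F2/F3 in CA1/CA3/DG roles):
#' F1->F2 `w[1]`, F2->F1 `w[2]`, F3->F2 `w[3]`, F1->F3 and F3->F1 `v`,
#' F2->F3 `0.8 v`; cross-hemisphere F1->F2', F1->F3', F3->F2', F3->F3'
#' all `v`. F1 and F3 additionally send gateway edges (weight in
#' `[0.6v, 0.9v]`, 70% coverage) into the background; F2 keeps only weak
#' extra-focus output, mirroring a CA3 whose strong projections stay inside
#' the hippocampus. All focus edges are capped at 90% of the source's
#' specified strongest-outgoing weight so the realized maximum is exact.
#'
#' @param spec a [synthetic_spec()].
#' @return A `connectome` with `2 * n_per_hemisphere` nodes; focus triplets
#'   are annotated in `focus_nodes` and placed mid-hemisphere (nodes 73-75
#'   are the left triplet in the default 98-node layout).
#' @export
make_synthetic_connectome <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec", call. = FALSE)
  n <- spec$n_per_hemisphere
  w <- spec$focus_out_weights
  v <- spec$focus_internal_weight
  # focus triplet placed mid-hemisphere (left triplet lands at 73:75 when
  # n = 49, echoing the atlas indices of l CA1 / l CA3 / l DG)
  f <- min(n - 3L, 23L) + 1:3
  with_seed_local(spec$seed, {
    rl <- function(m) {
      mask <- matrix(stats::runif(n * n) < m, n, n)
      wts <- matrix(stats::rlnorm(n * n, meanlog = log(spec$background_weight_scale),
                                  sdlog = spec$background_sdlog), n, n)
      out <- ifelse(mask, wts, 0)
      out
    }
    W_rr <- rl(spec$density)
    diag(W_rr) <- 0
    W_rl <- 0.5 * rl(spec$density) # cross-hemisphere edges run weaker
    # focus outgoing columns are fully designed: clear background there,
    # then max-normalize the remaining background to 1
    W_rr[, f] <- 0
    W_rl[, f] <- 0
    m <- max(W_rr, W_rl)
    W_rr <- W_rr / m
    W_rl <- W_rl / m
    F1 <- f[1]; F2 <- f[2]; F3 <- f[3]
    # row = target, column = source
    W_rr[F2, F1] <- w[1]
    W_rr[F1, F2] <- w[2]
    W_rr[F2, F3] <- w[3]
    W_rr[F3, F1] <- min(v, 0.9 * w[1])
    W_rr[F1, F3] <- min(v, 0.9 * w[3])
    W_rr[F3, F2] <- min(0.8 * v, 0.9 * w[2])
    # cross-hemisphere focus edges: W_rl[j, i] = weight from left node i to
    # right node j; by mirror symmetry the same values serve right -> left
    W_rl[F2, F1] <- min(v, 0.9 * w[1])
    W_rl[F3, F1] <- min(v, 0.9 * w[1])
    W_rl[F2, F3] <- min(v, 0.9 * w[3])
    W_rl[F3, F3] <- min(v, 0.9 * w[3])
    # gateway edges into the background from the CA1- and DG-like nodes
    bg <- setdiff(seq_len(n), f)
    for (k in c(1, 3)) {
      src <- f[k]
      hit <- bg[stats::runif(length(bg)) < 0.7]
      W_rr[hit, src] <- stats::runif(length(hit), 0.6 * v, 0.9 * v) *
        min(1, 0.9 * w[k] / (0.9 * v))
    }
    # the CA3-like node keeps only weak extra-focus output
    hit2 <- bg[stats::runif(length(bg)) < 0.3]
    W_rr[hit2, F2] <- stats::runif(length(hit2), 0.02, 0.08) *
      min(1, 0.9 * w[2] / 0.08)
    labels_r <- paste0("r_", c(sprintf("bg_%02d", seq_len(n))))
    labels_r[f] <- c("r_focus_CA1like", "r_focus_CA3like", "r_focus_DGlike")
    C <- mirror_right_hemisphere(W_rr, W_rl, labels_r = labels_r,
                                 focus_r = f)
    attr(C, "id") <- sprintf("synthetic_seed%d", spec$seed)
    attr(C, "spec") <- spec
    C
  })
}

#' Synthetic slow-variable onset signals
#'
#' Builds per-node z-like test signals with known ground truth: flat
#' baseline plus Gaussian noise before each node's onset time, then a
#' linear ramp (slope well above the noise floor). Nodes with `NA` onset
#' stay at baseline throughout. Used to exercise the onset detector against
#' a constructed truth.
#'
#' @param n_nodes number of nodes.
#' @param onset_times per-node onset times (`NA` = never), within
#'   `[0, duration]`.
#' @param duration,dt signal length and sampling step (time units).
#' @param noise_sd Gaussian noise standard deviation (default 0.005).
#' @param slope ramp slope after onset (default 0.05 per time unit, well
#'   above the noise floor so the detector's crossing lag stays within a
#'   couple of time units).
#' @param baseline baseline level (default 2.9).
#' @param seed integer seed for the noise.
#' @return A list with `times` and the samples x nodes matrix `z`.
#' @export
make_onset_signal <- function(n_nodes, onset_times, duration = 300, dt = 0.5,
                              noise_sd = 0.005, slope = 0.05,
                              baseline = 2.9, seed = 1L) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  onset_times <- rep_len(onset_times, n_nodes)
  if (any(onset_times < 0 | onset_times > duration, na.rm = TRUE))
    stop("onset_times must lie within [0, duration]", call. = FALSE)
  times <- seq(0, duration, by = dt)
  z <- with_seed_local(seed, {
    noise <- matrix(stats::rnorm(length(times) * n_nodes, sd = noise_sd),
                    length(times), n_nodes)
    ramp <- vapply(seq_len(n_nodes), function(i) {
      if (is.na(onset_times[i])) return(numeric(length(times)))
      pmax(0, times - onset_times[i]) * slope
    }, numeric(length(times)))
    baseline + ramp + noise
  })
  colnames(z) <- paste0("node_", seq_len(n_nodes) - 1L)
  list(times = times, z = z)
}

#' Write the standard synthetic fixture suite
#'
#' Emits three deterministic connectome fixtures: (a) a 10-node toy for
#' graph-oracle tests, (b) a 20-node two-hemisphere connectome with the
#' focus triplet, and (c) a 98-node surrogate shaped like the mirrored
#' mouse atlas. Files are written with [write_connectome()] (matrix text
#' plus JSON sidecar) when `dir` is given.
#'
#' @param seed integer seed.
#' @param dir optional output directory; created if missing.
#' @return Named list of the three `connectome`s (`toy10`, `mirrored20`,
#'   `surrogate98`), invisibly when writing.
#' @export
make_fixture_suite <- function(seed = 1L, dir = NULL) {
  toy <- with_seed_local(seed, {
    W <- matrix(stats::runif(100), 10, 10) *
      (matrix(stats::runif(100), 10, 10) < 0.5)
    diag(W) <- 0
    W / max(W)
  })
  fixtures <- list(
    toy10 = connectome(toy),
    mirrored20 = make_synthetic_connectome(
      synthetic_spec(n_per_hemisphere = 10, seed = seed)),
    surrogate98 = make_synthetic_connectome(synthetic_spec(seed = seed))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(fixtures)) {
      write_connectome(fixtures[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
    return(invisible(fixtures))
  }
  fixtures
}
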