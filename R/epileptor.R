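#' Critical epileptogenicity of an isolated Epileptor
#'
#' Below this value of the excitability parameter `x0` a single, noise-free
#' Epileptor rests at a stable interictal fixed point; above it the fixed
#' point collides with the knee of the fast-subsystem nullcline (a
#' saddle-node bifurcation) and the node seizes spontaneously. Healthy
#' propagation-zone nodes are parameterized below this value (default -2.1),
#' epileptogenic-zone nodes above it (default -1.6). See
#' [find_critical_x0()] for a numerical location of the transition.
#' @export
CRITICAL_X0 <- -2.06

#' Epileptor network parameters
#'
#' Collects the model constants, per-node epileptogenicity and integration
#' settings for a network of coupled Epileptors. Time is measured in
#' dimensionless model units throughout; the slow permittivity variable `z`
#' evolves at rate `r` so a seizure cycle spans thousands of units.
#'
#' @param x0 per-node epileptogenicity vector (or scalar, recycled at
#'   simulation time). Epileptogenic-zone nodes are conventionally -1.6 and
#'   propagation-zone nodes -2.1, either side of [CRITICAL_X0].
#' @param I1,I2 drive currents of the fast and sharp-wave subsystems
#'   (defaults 3.1 and 0.45).
#' @param r slow permittivity rate (default 8e-5 per time unit).
#' @param K global coupling gain on the diffusive x1 coupling (default 0.2).
#' @param tau timescale of the y2 equation (default 10 time units).
#' @param sigma standard deviation of the additive Gaussian white noise
#'   applied to the x2 and y2 equations only (default 0.0025); `sigma = 0`
#'   gives a bit-reproducible deterministic run.
#' @param dt integration step (default 0.05 time units).
#' @param duration total simulated time (default 6000 units, enough for a
#'   full seizure cycle of an isolated epileptogenic node).
#' @param warmup initial transient excluded from onset detection
#'   (default 15 units).
#' @param dt_out sampling interval of the stored trajectory (default 0.5
#'   units; must be a multiple of `dt`).
#' @param seed integer seed governing initial-condition jitter and the
#'   integration noise.
#' @param ic_x0 epileptogenicity at which the shared interictal initial
#'   condition is evaluated (default -2.1, the propagation-zone value).
#' @param ic_jitter half-width of the seeded uniform perturbation applied to
#'   the initial state (default 1e-3).
#' @param coupling_in_slow logical; if `TRUE` (default) the diffusive
#'   coupling term is scaled by `r` inside the slow permittivity equation,
#'   so that sustained input from seizing neighbours shifts a node's
#'   effective epileptogenicity by `(K/4) * sum_j w_ji * (x1_j - x1_i)`.
#'   `FALSE` adds the coupling at the fast timescale instead, which makes
#'   recruitment insensitive to the weight magnitude (see the package
#'   vignette for why the slow-scaled form is the default).
#'
#' @return An object of class `epileptor_params`.
#' @export
epileptor_params <- function(x0 = -2.1, I1 = 3.1, I2 = 0.45, r = 8e-5,
                             K = 0.2, tau = 10, sigma = 0.0025,
                             dt = 0.05, duration = 6000, warmup = 15,
                             dt_out = 0.5, seed = 1L, ic_x0 = -2.1,
                             ic_jitter = 1e-3, coupling_in_slow = TRUE) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration <= warmup || warmup < 0)
    stop("need duration > warmup >= 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  stride <- round(dt_out / dt)
  if (stride < 1 || abs(stride * dt - dt_out) > 1e-9)
    stop("dt_out must be a positive multiple of dt", call. = FALSE)
  structure(
    list(x0 = x0, I1 = I1, I2 = I2, r = r, K = K, tau = tau, sigma = sigma,
         dt = dt, duration = duration, warmup = warmup, dt_out = dt_out,
         stride = as.integer(stride), seed = as.integer(seed), ic_x0 = ic_x0,
         ic_jitter = ic_jitter, coupling_in_slow = isTRUE(coupling_in_slow)),
    class = "epileptor_params"
  )
}

#' @export
print.epileptor_params <- function(x, ...) {
  cat(sprintf(paste0("<epileptor_params> I1=%.3g I2=%.3g r=%.3g K=%.3g tau=%.3g ",
                     "sigma=%.4g\n  dt=%.3g duration=%g warmup=%g dt_out=%.3g seed=%d\n"),
              x$I1, x$I2, x$r, x$K, x$tau, x$sigma,
              x$dt, x$duration, x$warmup, x$dt_out, x$seed))
  invisible(x)
}

#' Fast-subsystem nonlinearity f1
#'
#' Piecewise cubic/quadratic nonlinearity of the fast discharging subsystem:
#' `x1^3 - 3*x1^2` for `x1 < 0` and `(x2 - 0.6*(z - 4)^2) * x1` for
#' `x1 >= 0`. Both branches vanish at `x1 = 0`, so f1 is continuous there.
#'
#' @param x1,x2,z state variables (vectorized).
#' @return f1 evaluated elementwise.
#' @export
f1 <- function(x1, x2, z) {
  ifelse(x1 < 0, x1^3 - 3 * x1^2, (x2 - 0.6 * (z - 4)^2) * x1)
}

#' Sharp-wave subsystem nonlinearity f2
#'
#' Piecewise-linear rectifier: 0 for `x2 < -0.25`, `6 * (x2 + 0.25)`
#' otherwise.
#'
#' @param x2 state variable (vectorized).
#' @return f2 evaluated elementwise.
#' @export
f2 <- function(x2) {
  ifelse(x2 < -0.25, 0, 6 * (x2 + 0.25))
}

#' Deterministic right-hand side of the coupled Epileptor network
#'
#' Evaluates the drift of the six state variables for every node, including
#' the diffusive x1 coupling over each node's incoming connections:
#' node `i` receives `K * sum_j w(j->i) * (x1_i - x1_j)` (scaled by `r` when
#' `coupling_in_slow` is set) in its slow permittivity equation. Provided as
#' a plain R reference implementation; the integrator in [simulate_epileptor()]
#' uses a compiled equivalent.
#'
#' @param state numeric matrix 6 x N (rows x1, y1, z, x2, y2, g) or a
#'   length-6 vector for a single node.
#' @param params an [epileptor_params()] object; `params$x0` must have one
#'   entry per node (scalars are recycled).
#' @param C a `connectome` with N nodes, or `NULL` for uncoupled nodes.
#' @return A 6 x N matrix of time derivatives.
#' @export
network_rhs <- function(state, params, C = NULL) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 6)
  if (nrow(state) != 6) stop("state must be 6 x N", call. = FALSE)
  N <- ncol(state)
  x0 <- rep_len(params$x0, N)
  x1 <- state[1, ]; y1 <- state[2, ]; z <- state[3, ]
  x2 <- state[4, ]; y2 <- state[5, ]; g <- state[6, ]
  coup <- 0
  if (!is.null(C)) {
    if (n_nodes(C) != N) stop("connectome size does not match state", call. = FALSE)
    W <- C$weights
    coup <- unname(params$K * (rowSums(W) * x1 - drop(W %*% x1)))
    if (params$coupling_in_slow) coup <- params$r * coup
  }
  dz_lin <- 4 * (x1 - x0) - z - ifelse(z < 0, 0.1 * z^7, 0)
  rbind(
    y1 - f1(x1, x2, z) - z + params$I1,
    1 - 5 * x1^2 - y1,
    params$r * dz_lin + coup,
    -y2 + x2 - x2^3 + params$I2 + 0.002 * g - 0.3 * (z - 3.5),
    (1 / params$tau) * (-y2 + f2(x2)),
    -0.01 * (g - 0.1 * x1)
  )
}

#' Interictal fixed point of a single Epileptor
#'
#' Solves for the resting state of a node with epileptogenicity `x0`: the
#' intersection of the left (interictal) branch of the fast-subsystem
#' nullcline with the slow nullcline `z = 4 * (x1 - x0)`, then the
#' corresponding rest values of the sharp-wave subsystem and the low-pass
#' variable g. Used as the shared initial condition of all nodes.
#'
#' @param x0 epileptogenicity at which to evaluate the fixed point.
#' @param params an [epileptor_params()] object (for I2 and tau).
#' @return Named length-6 numeric vector (x1, y1, z, x2, y2, g).
#' @export
interictal_state <- function(x0 = -2.1, params = epileptor_params()) {
  # z-nullcline meets the fast nullcline z = -x1^3 - 2 x1^2 + 1 + I1
  gfun <- function(x1) -x1^3 - 2 * x1^2 + 1 + params$I1 - 4 * (x1 - x0)
  x1 <- stats::uniroot(gfun, c(-3, -0.5), tol = 1e-12)$root
  z <- 4 * (x1 - x0)
  y1 <- 1 - 5 * x1^2
  g <- 0.1 * x1
  cc <- params$I2 + 0.002 * g - 0.3 * (z - 3.5)
  hfun <- function(x2) -f2(x2) + x2 - x2^3 + cc
  x2 <- if (hfun(-0.25) * hfun(3) <= 0) {
    stats::uniroot(hfun, c(-0.25, 3), tol = 1e-12)$root
  } else {
    stats::uniroot(hfun, c(-3, -0.25), tol = 1e-12)$root
  }
  y2 <- f2(x2)
  c(x1 = x1, y1 = y1, z = z, x2 = x2, y2 = y2, g = g)
}

#' Simulate a network of coupled Epileptors
#'
#' Integrates the six-variable Epileptor equations on a connectome with a
#' stochastic Heun (predictor-corrector) scheme. Additive Gaussian noise of
#' standard deviation `sigma * sqrt(dt)` per step is applied to the x2 and
#' y2 updates only; with `sigma = 0` the run is deterministic and
#' bit-reproducible. All nodes start at the interictal fixed point evaluated
#' at `params$ic_x0`, perturbed by a seeded uniform jitter of half-width
#' `params$ic_jitter`.
#'
#' @param C a `connectome` (or `NULL` with `n` for uncoupled nodes).
#' @param params an [epileptor_params()] object; `params$x0` is recycled to
#'   the node count.
#' @param keep `"z"` (default) stores the slow variable and the LFP proxy
#'   `x2 - x1`; `"all"` additionally stores all six state variables.
#' @param n node count when `C` is `NULL`.
#' @param init optional 6 x N matrix of initial states, overriding the
#'   fixed-point default.
#' @return An object of class `epileptor_trajectory`: a list with `times`,
#'   matrices `z` and `lfp` (samples x nodes), optionally `states` (a named
#'   list of the six per-variable matrices), plus the parameters used and a
#'   provenance tag.
#' @export
simulate_epileptor <- function(C, params = epileptor_params(),
                               keep = c("z", "all"), n = NULL, init = NULL) {
  keep <- match.arg(keep)
  if (is.null(C)) {
    if (is.null(n)) stop("supply a connectome or a node count n", call. = FALSE)
    W <- matrix(0, n, n)
    cid <- sprintf("uncoupled_%d", n)
  } else {
    validate_connectome(C)
    W <- C$weights
    n <- nrow(W)
    cid <- attr(C, "id") %||% sprintf("connectome_%d", n)
  }
  x0 <- rep_len(params$x0, n)
  n_steps <- round(params$duration / params$dt)
  set.seed(params$seed)
  if (is.null(init)) {
    fp <- interictal_state(params$ic_x0, params)
    init <- matrix(fp, nrow = 6, ncol = n)
    if (params$ic_jitter > 0)
      init <- init + matrix(stats::runif(6 * n, -params$ic_jitter,
                                         params$ic_jitter), 6, n)
  } else {
    init <- as.matrix(init)
    if (nrow(init) != 6 || ncol(init) != n)
      stop("init must be a 6 x N matrix", call. = FALSE)
  }
  raw <- .heun_epileptor(W, x0, params$I1, params$I2, params$r, params$K,
                         params$tau, params$sigma, params$dt,
                         as.integer(n_steps), params$stride, init,
                         params$coupling_in_slow, keep == "all")
  labels <- if (is.null(C)) paste0("node_", seq_len(n) - 1L) else C$labels
  colnames(raw$z) <- labels
  colnames(raw$lfp) <- labels
  out <- list(times = raw$times, z = raw$z, lfp = raw$lfp,
              params = params, connectome_id = cid)
  if (keep == "all") {
    out$states <- lapply(raw[c("x1", "y1", "z", "x2", "y2", "g")],
                         `colnames<-`, labels)
  }
  structure(out, class = "epileptor_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epileptor_trajectory <- function(x, ...) {
  cat(sprintf("<epileptor_trajectory> %d nodes, %d samples over %g time units (dt_out=%g)\n",
              ncol(x$z), length(x$times), max(x$times), x$params$dt_out))
  invisible(x)
}

#' Locate the critical epileptogenicity by bisection
#'
#' Bisects the epileptogenicity parameter of a single noise-free Epileptor
#' between a known-seizing and a known-quiet value, classifying each run by
#' whether [detect_onsets()] finds a seizure onset within the horizon, and
#' returns the bracket midpoint once the bracket is narrower than twice the
#' requested tolerance. The result approximates the saddle-node value at
#' which spontaneous seizing appears (around [CRITICAL_X0]).
#'
#' @param tolerance half-width of the final bracket (default 0.01).
#' @param bracket known-seizing / known-quiet endpoints, default
#'   `c(-2.2, -1.6)` (order irrelevant).
#' @param horizon simulation length per probe, default 30000 time units;
#'   near the transition the passage time through the saddle-node ghost
#'   diverges, so short horizons bias the estimate upward.
#' @param dt integration step for the probes (default 0.05).
#' @param verbose print each probe's classification.
#' @return The estimated critical `x0` (scalar).
#' @export
find_critical_x0 <- function(tolerance = 0.01, bracket = c(-2.2, -1.6),
                             horizon = 30000, dt = 0.05, verbose = FALSE) {
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  seizes <- function(x0) {
    p <- epileptor_params(x0 = x0, sigma = 0, dt = dt, duration = horizon,
                          dt_out = 1, ic_jitter = 0)
    traj <- simulate_epileptor(NULL, p, n = 1L)
    on <- detect_onsets(traj)
    if (verbose)
      message(sprintf("x0 = %.5f -> %s", x0,
                      if (is.na(on[1])) "quiet" else "seizing"))
    !is.na(on[1])
  }
  lo <- min(bracket); hi <- max(bracket)
  if (seizes(lo) || !seizes(hi))
    stop("bracket endpoints classify identically; horizon too short or ",
         "bracket does not straddle the transition", call. = FALSE)
  while ((hi - lo) / 2 > tolerance) {
    mid <- (lo + hi) / 2
    if (seizes(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
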