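#' Shifted Hill function
#'
#' `H^s(x, T, n, lambda) = lambda + (1 - lambda) * T^n / (T^n + x^n)`: a
#' sigmoid decreasing from `H^s(0) = 1` to `lambda` as `x` grows, with
#' half-saturation `H^s(T) = (1 + lambda)/2`.  With `lambda = i < 1` it
#' models repression; an activating edge enters the production term as
#' `H^s(x, T, n, a)/a`, which increases from `1/a` to 1.
#'
#' @param x regulator concentration (vector ok).
#' @param T threshold (half-saturation) concentration.
#' @param n Hill coefficient.
#' @param lambda fold change.
#' @return Numeric vector.
#' @export
shifted_hill <- function(x, T, n, lambda) {
  lambda + (1 - lambda) / (1 + (x / T)^n)
}

## Per-row parameter bundle for vectorized evaluation of the RACIPE rhs.
.hill_prep <- function(network, params) {
  n <- nrow(params)
  fold <- .edge_mat(params, network, "fold")
  act <- network$edges$sign == "activation"
  lam <- fold
  lam[, act] <- 1 / fold[, act, drop = FALSE]
  list(P = .node_mat(params, network, "P"),
       G = .node_mat(params, network, "gamma"),
       theta = .edge_mat(params, network, "theta"),
       hn = .edge_mat(params, network, "n"),
       lam = lam, act = act,
       src = match(network$edges$source, network$nodes),
       tgt = match(network$edges$target, network$nodes),
       n = n)
}

## Production (P * prod of edge factors) for a state matrix X aligned with
## the prep rows; returns a matrix like X.
.hill_production <- function(prep, X) {
  prod <- prep$P
  for (e in seq_along(prep$src)) {
    Fh <- 1 / (1 + (X[, prep$src[e]] / prep$theta[, e])^prep$hn[, e])
    if (prep$act[e]) Fh <- 1 - Fh
    fac <- prep$lam[, e] + (1 - prep$lam[, e]) * Fh
    prod[, prep$tgt[e]] <- prod[, prep$tgt[e]] * fac
  }
  prod
}

#' Right-hand side of the shifted-Hill ODE system
#'
#' `dx_k/dt = P_k * prod_act H^s(x_j, theta, n, a)/a *
#' prod_rep H^s(x_j, theta, n, i) - gamma_k x_k`.
#'
#' @param network a [grn_network()].
#' @param params one row of a `racipe_params` table, or one row per row of
#'   `x`.
#' @param x state vector (node order) or matrix with one state per row.
#' @return Derivative, same shape as `x`.
#' @export
hill_rhs <- function(network, params, x) {
  .check_racipe(network, params)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (any(X < 0)) stop("negative state: concentrations must be >= 0")
  if (nrow(params) == 1L && nrow(X) > 1L)
    params <- params[rep(1L, nrow(X)), , drop = FALSE]
  prep <- .hill_prep(network, params)
  d <- .hill_production(prep, X) - prep$G * X
  if (vec) stats::setNames(drop(d), network$nodes) else d
}

#' Steady-state verification residual
#'
#' Root-mean-square of the derivative components,
#' `sqrt(sum_k (dx_k/dt)^2 / N)`, evaluated at `x`.  A state is accepted
#' as a verified steady state when the residual is below the tolerance
#' (default `1e-4`).
#'
#' @inheritParams hill_rhs
#' @return Numeric residual (one per row of `x`).
#' @export
verify_steady_state <- function(network, params, x) {
  d <- hill_rhs(network, params, x)
  if (is.null(dim(d))) sqrt(mean(d^2)) else sqrt(rowMeans(d^2))
}

#' Integrator and post-processing settings for the Hill ensemble
#'
#' The default integrator is fixed-step Euler, run for
#' `horizon_gamma / dt_gamma` steps with a per-set step
#' `dt = dt_gamma / min_k(gamma_k)`; that is, the resolution is
#' `dt_gamma` per unit of the set's slowest decay time and the horizon is
#' `horizon_gamma` such times.  `integrator = "adaptive"` switches to an
#' adaptive high-order solver (via \pkg{deSolve}) for accuracy checks.
#'
#' @param dt_gamma dimensionless Euler step (fraction of the slowest decay
#'   time).
#' @param horizon_gamma integration horizon in units of the slowest decay
#'   time.
#' @param merge_tol relative tolerance below which two final states are
#'   the same steady state.
#' @param max_states cap on distinct states per parameter set; reaching it
#'   with no verified state flags the set as cyclic.
#' @param verify_tol residual tolerance of [verify_steady_state()].
#' @param integrator `"euler"` or `"adaptive"`.
#' @return List of class `hill_settings`.
#' @export
hill_settings <- function(dt_gamma = 0.05, horizon_gamma = 200,
                          merge_tol = 1e-2, max_states = 10L,
                          verify_tol = 1e-4, integrator = "euler") {
  stopifnot(dt_gamma > 0, horizon_gamma > dt_gamma, merge_tol > 0)
  structure(list(dt_gamma = dt_gamma, horizon_gamma = horizon_gamma,
                 merge_tol = merge_tol, max_states = as.integer(max_states),
                 verify_tol = verify_tol,
                 integrator = match.arg(integrator, c("euler", "adaptive"))),
            class = "hill_settings")
}

#' Simulate a shifted-Hill ensemble to steady state
#'
#' Integrates the ODE system for every parameter set from many random
#' initial conditions, merges the final states of each set into distinct
#' states (relative tolerance `merge_tol`), verifies each against the
#' steady-state residual condition, and assigns each state a weight equal
#' to the fraction of initial conditions that converged to it.  A set
#' whose distinct final states reach `max_states` with none verified is
#' flagged cyclic (the states keep moving, as on a limit cycle).
#' Trajectories that become non-finite are dropped from the weight
#' normalization and counted per set.
#'
#' @param network a [grn_network()].
#' @param params a `racipe_params` table (M rows).
#' @param n_init initial conditions per parameter set.
#' @param ics optional list of IC matrices (one `n_init x N` matrix per
#'   set); by default drawn as in [sample_initial_conditions()].
#' @param settings a [hill_settings()].
#' @param seed optional seed for the initial conditions.
#' @return Object of class `hill_ensemble`: `states` (data frame with
#'   columns `set`, one per node, `weight`, `residual`, `verified`),
#'   `cyclic` (logical per set), `divergent` (count per set), plus the
#'   network and settings.
#' @examples
#' ts <- builtin_network("TS")
#' p <- sample_parameters(ts, sampling_config(n_sets = 5, seed = 3))
#' ens <- simulate_hill_ensemble(ts, p, n_init = 20, seed = 3)
#' ens
#' @export
simulate_hill_ensemble <- function(network, params, n_init = 100L,
                                   ics = NULL, settings = hill_settings(),
                                   seed = NULL) {
  .check_racipe(network, params)
  M <- nrow(params)
  N <- length(network$nodes)
  if (!is.null(seed)) set.seed(seed)
  n_init <- as.integer(n_init)
  idx <- rep(seq_len(M), each = n_init)
  big <- params[idx, , drop = FALSE]
  prep <- .hill_prep(network, big)
  if (is.null(ics)) {
    lvl <- .node_mat(params, network, "P") / .node_mat(params, network, "gamma")
    lo <- log(1e-2 * apply(lvl, 1, min))[idx]
    hi <- log(10 * apply(lvl, 1, max))[idx]
    X <- matrix(exp(stats::runif(length(idx) * N, lo, hi)), ncol = N)
  } else {
    stopifnot(length(ics) == M)
    X <- do.call(rbind, ics)
    stopifnot(nrow(X) == M * n_init, ncol(X) == N)
  }
  g_min <- apply(.node_mat(params, network, "gamma"), 1, min)
  if (settings$integrator == "euler") {
    dt <- (settings$dt_gamma / g_min)[idx]
    n_steps <- ceiling(settings$horizon_gamma / settings$dt_gamma)
    for (s in seq_len(n_steps))
      X <- X + dt * (.hill_production(prep, X) - prep$G * X)
  } else {
    if (!requireNamespace("deSolve", quietly = TRUE))
      stop("the adaptive integrator needs the deSolve package")
    horizon <- (settings$horizon_gamma / g_min)[idx]
    for (r in seq_len(nrow(X))) {
      pr <- params[idx[r], , drop = FALSE]
      f <- function(t, y, parms)
        list(as.numeric(hill_rhs(network, pr, pmax(y, 0))))
      sol <- deSolve::lsoda(X[r, ], c(0, horizon[r]), f, NULL,
                            rtol = 1e-8, atol = 1e-10)
      X[r, ] <- sol[nrow(sol), -1]
    }
  }
  ## merge final states per set, count divergent trajectories
  finite <- rowSums(is.finite(X)) == N
  states <- vector("list", M)
  divergent <- integer(M)
  for (m in seq_len(M)) {
    rows <- which(idx == m & finite)
    divergent[m] <- n_init - length(rows)
    if (!length(rows)) next
    xm <- X[rows, , drop = FALSE]
    reps <- xm[1, , drop = FALSE]
    cnt <- 1L
    if (nrow(xm) > 1L) for (r in 2:nrow(xm)) {
      d <- abs(sweep(reps, 2, xm[r, ])) / pmax(abs(reps), 1e-8)
      hit <- which(apply(d, 1, max) <= settings$merge_tol)
      if (length(hit)) cnt[hit[1]] <- cnt[hit[1]] + 1L
      else { reps <- rbind(reps, xm[r, ]); cnt <- c(cnt, 1L) }
    }
    states[[m]] <- cbind(set = m, reps, weight = cnt / length(rows))
  }
  st <- as.data.frame(do.call(rbind, states))
  names(st) <- c("set", network$nodes, "weight")
  res <- verify_steady_state(network,
                             params[st$set, , drop = FALSE],
                             as.matrix(st[, network$nodes, drop = FALSE]))
  st$residual <- res
  st$verified <- res < settings$verify_tol
  n_states <- tabulate(st$set, M)
  any_ver <- as.logical(tapply(st$verified, factor(st$set, seq_len(M)), any))
  any_ver[is.na(any_ver)] <- FALSE
  cyclic <- n_states >= settings$max_states & !any_ver
  structure(list(network = network, states = st, cyclic = cyclic,
                 divergent = divergent, settings = settings,
                 n_sets = M, n_init = n_init),
            class = "hill_ensemble")
}

#' @export
print.hill_ensemble <- function(x, ...) {
  cat("Hill ensemble:", x$n_sets, "parameter sets x", x$n_init,
      "initial conditions\n")
  cat("  distinct states:", nrow(x$states),
      sprintf("(%.1f%% verified)", 100 * mean(x$states$verified)), "\n")
  cat("  cyclic sets:", sum(x$cyclic),
      " divergent trajectories:", sum(x$divergent), "\n")
  invisible(x)
}

#' Discretize a steady-state table into attractor repertoires
#'
#' Pools all (state, weight) rows of an ensemble, computes per node the
#' weighted mean and weighted standard deviation of log2 expression
#' (weights are the basin fractions), converts each state to weighted
#' z-scores and binarizes: `z >= 0` is the high digit 1, `z < 0` the low
#' digit 0 (ties at exactly 0 — a measure-zero event — count as high).
#' The log2 transform puts the decades-wide expression scales of a random
#' ensemble on a common footing before standardization, as in standard
#' RACIPE processing; `log2 = FALSE` binarizes linear expression instead.
#'
#' Each parameter set is labelled by its canonical repertoire — the
#' sorted unique digit strings of its states joined by `"-"`, e.g.
#' `"01-10"` — and classified as monostable, bistable, tristable,
#' multistable, cyclic (per the `cyclic` flags) or unresolved (no usable
#' state).
#'
#' @param states data frame with columns `set`, one column per node, and
#'   `weight`.
#' @param network a [grn_network()].
#' @param n_sets number of parameter sets (sets absent from `states` are
#'   unresolved).
#' @param cyclic optional logical vector per set.
#' @param log2 binarize log2-transformed expression (default) or raw
#'   expression.
#' @return Data frame of class `hill_repertoires` with columns `set`,
#'   `repertoire`, `class`, `n_attractors`; attributes `node_stats`
#'   (weighted means/SDs on the binarization scale) and `state_labels`
#'   (per-state digit strings aligned with the rows of `states`).
#' @export
discretize_states <- function(states, network, n_sets = max(states$set),
                              cyclic = NULL, log2 = TRUE) {
  nodes <- network$nodes
  if (nrow(states) < 2L) stop("need at least two states to discretize")
  if (is.null(cyclic)) cyclic <- rep(FALSE, n_sets)
  w <- states$weight
  xm <- as.matrix(states[, nodes, drop = FALSE])
  if (log2) xm <- log2(xm)
  mu <- colSums(w * xm) / sum(w)
  sd <- sqrt(colSums(w * sweep(xm, 2, mu)^2) / sum(w))
  if (any(sd <= 0))
    stop("zero weighted standard deviation for node ",
         paste(nodes[sd <= 0], collapse = ", "))
  z <- sweep(sweep(xm, 2, mu), 2, sd, "/")
  digit <- ifelse(z >= 0, "1", "0")
  labels <- apply(digit, 1, paste, collapse = "")
  per_set <- split(labels, factor(states$set, seq_len(n_sets)))
  rep_str <- vapply(per_set, function(l)
    if (length(l)) canonical_repertoire(l) else NA_character_, character(1))
  n_att <- vapply(per_set, function(l) length(unique(l)), integer(1))
  cls <- ifelse(cyclic, "cyclic",
         ifelse(n_att == 0L, "unresolved",
         ifelse(n_att == 1L, "monostable",
         ifelse(n_att == 2L, "bistable",
         ifelse(n_att == 3L, "tristable", "multistable")))))
  rep_str[cyclic] <- "cyclic"
  out <- data.frame(set = seq_len(n_sets), repertoire = rep_str,
                    class = cls, n_attractors = n_att)
  attr(out, "node_stats") <- data.frame(node = nodes, mean = mu, sd = sd)
  attr(out, "state_labels") <- labels
  class(out) <- c("hill_repertoires", "data.frame")
  out
}

#' Discretize the verified steady states of a Hill ensemble
#'
#' Applies [discretize_states()] to the verified steady states of a
#' [simulate_hill_ensemble()] result, carrying the simulator's cyclic
#' flags through.
#'
#' @param ensemble a [simulate_hill_ensemble()] result.
#' @param log2 see [discretize_states()].
#' @return See [discretize_states()].
#' @export
discretize_ensemble <- function(ensemble, log2 = TRUE) {
  stopifnot(inherits(ensemble, "hill_ensemble"))
  st <- ensemble$states[ensemble$states$verified, , drop = FALSE]
  discretize_states(st, ensemble$network, n_sets = ensemble$n_sets,
                    cyclic = ensemble$cyclic, log2 = log2)
}
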