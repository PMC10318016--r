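#' Event-driven integration of a switching system
#'
#' Within a rectangular domain the switching flow is exactly
#' `x_i(t) = T_i + (x_i(0) - T_i) e^(-gamma_i t)` toward the domain's
#' target point, so the first wall-crossing time of every coordinate has a
#' closed form and the trajectory can be advanced from wall to wall
#' without discretization error.  The trajectory terminates at a stable
#' fixed point when the target lies inside the current domain, or is
#' classified as a cycle when a (domain, exit-wall) pair repeats.
#'
#' Because the networks handled here have no self-loops, the production
#' term of a coordinate is identical on both sides of any of its own
#' walls, so sliding (Filippov) motion cannot arise; the only ambiguity is
#' an exact tie between two crossing times, which is retried once from a
#' minutely perturbed initial condition and otherwise reported as
#' `"ambiguous"`.
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table (regular).
#' @param x0 initial state (strictly positive, off all thresholds).
#' @param max_transitions cap on wall crossings before giving up.
#' @param tie_tol relative tolerance for a crossing-time tie.
#' @return Object of class `switching_trajectory`: `classification`
#'   (`"FP"`, `"cycle"` or `"ambiguous"`), `label` (fixed-point domain
#'   label such as `"01"`, or `"cycle"`), `domains` (visited domain
#'   labels), `times` (entry times), `state` (final state), and for
#'   cycles `cycle_domains` (the repeating domain sequence).
#' @examples
#' ts <- builtin_network("TS")
#' q <- data.frame(gamma_A = 1, gamma_B = 1, L_B_A = 1, U_B_A = 3,
#'                 theta_B_A = 2, L_A_B = 1, U_A_B = 3, theta_A_B = 2)
#' integrate_event_driven(ts, q, c(A = 0.5, B = 2.5))$label  # "01"
#' @export
integrate_event_driven <- function(network, q, x0, max_transitions = 1000L,
                                   tie_tol = 1e-9) {
  .check_switching(network, q)
  model <- .sw_model(network, q[1, , drop = FALSE])
  run <- function(x, retried) {
    alpha <- .sw_domain_of(model, x)
    doms <- .alpha_label(alpha)
    times <- 0
    keys <- character(0)
    t_cur <- 0
    for (step in seq_len(max_transitions)) {
      lam <- .sw_lambda(model, alpha)
      targ <- lam / model$gamma
      t_i <- rep(Inf, model$N)
      wall <- dir <- rep(NA_real_, model$N)
      inside <- TRUE
      for (i in seq_len(model$N)) {
        iv <- .sw_interval(model, i, alpha[i])
        if (targ[i] > iv[2]) {
          inside <- FALSE; wall[i] <- iv[2]; dir[i] <- 1
        } else if (targ[i] < iv[1] && iv[1] > 0) {
          inside <- FALSE; wall[i] <- iv[1]; dir[i] <- -1
        } else next
        t_i[i] <- log((x[i] - targ[i]) / (wall[i] - targ[i])) / model$gamma[i]
      }
      if (inside)
        return(structure(list(classification = "FP",
                              label = .alpha_label(alpha),
                              domains = doms, times = times, state = x),
                         class = "switching_trajectory"))
      o <- order(t_i)
      if (length(o) > 1L && is.finite(t_i[o[2]]) &&
          (t_i[o[2]] - t_i[o[1]]) <= tie_tol * max(t_i[o[1]], 1e-12)) {
        if (retried)
          return(structure(list(classification = "ambiguous", label = NA,
                                domains = doms, times = times, state = x),
                           class = "switching_trajectory"))
        return(run(x0 * (1 + 1e-7 * seq_along(x0)), TRUE))
      }
      imin <- o[1]
      key <- paste0(.alpha_label(alpha), "|", imin, dir[imin])
      if (key %in% keys) {
        first <- match(key, keys)
        return(structure(list(classification = "cycle", label = "cycle",
                              domains = doms, times = times, state = x,
                              cycle_domains = doms[(first + 1):length(doms)]),
                         class = "switching_trajectory"))
      }
      keys <- c(keys, key)
      tmin <- t_i[imin]
      x <- targ + (x - targ) * exp(-model$gamma * tmin)
      x[imin] <- wall[imin]
      alpha[imin] <- alpha[imin] + dir[imin]
      t_cur <- t_cur + tmin
      doms <- c(doms, .alpha_label(alpha))
      times <- c(times, t_cur)
    }
    structure(list(classification = "ambiguous", label = NA,
                   domains = doms, times = times, state = x),
              class = "switching_trajectory")
  }
  run(as.numeric(x0), FALSE)
}

#' @export
print.switching_trajectory <- function(x, ...) {
  cat("Switching trajectory:", length(x$domains), "domain(s) visited ->",
      x$classification,
      if (x$classification == "FP") paste0("FP(", x$label, ")") else "",
      "\n")
  invisible(x)
}

#' Stable fixed points of a switching parameter set
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table.
#' @return List with `labels` (domain labels of the FP attractors) and
#'   `points` (matrix of their coordinates); empty when the only
#'   attractors are cycles.
#' @export
switching_fixed_points <- function(network, q) {
  stg <- build_stg(network, q)
  mg <- morse_graph(stg)
  fp <- mg$nodes$minimal & mg$nodes$annotation == "FP"
  labs <- mg$nodes$label[fp]
  dom <- match(labs, stg$labels)
  list(labels = labs,
       points = stg$targets[dom, , drop = FALSE])
}

#' Stable-state table of a switching ensemble
#'
#' For each switching parameter set, collects the exact coordinates of
#' its stable fixed points (the minimal FP nodes of the Morse graph, each
#' sitting at its domain's target point) into the same (set, state,
#' weight) table layout the Hill simulator produces, so the two ensembles
#' can be discretized and compared through the identical z-score pipeline
#' (see [discretize_states()]).  Within a set the fixed points get equal
#' weights.  Sets whose only attractor is a cycle contribute no rows and
#' are flagged cyclic.
#'
#' @param network a [grn_network()].
#' @param q rows of a `switching_params` table (regular).
#' @return List with `states` (data frame `set`, node columns, `weight`)
#'   and `cyclic` (logical per row of `q`).
#' @export
switching_state_table <- function(network, q) {
  .check_switching(network, q)
  M <- nrow(q)
  cyclic <- logical(M)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    stg <- build_stg(network, q[m, , drop = FALSE])
    mg <- morse_graph(stg)
    minimal <- mg$nodes[mg$nodes$minimal, , drop = FALSE]
    fp <- minimal$annotation == "FP"
    cyclic[m] <- any(!fp)
    if (any(fp)) {
      dom <- match(minimal$label[fp], stg$labels)
      pts <- stg$targets[dom, , drop = FALSE]
      rows[[m]] <- cbind(set = m, pts, weight = 1 / nrow(pts))
    }
  }
  st <- as.data.frame(do.call(rbind, rows))
  names(st) <- c("set", network$nodes, "weight")
  list(states = st, cyclic = cyclic)
}

#' Fixed-step Euler integration of a switching system
#'
#' The numerical counterpart of [integrate_event_driven()]: forward Euler
#' on the switching ODE with the production term evaluated at the current
#' state.  Used to measure how much error a fixed-step integration
#' contributes to basin estimation, relative to the exact event-driven
#' assignment.
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table.
#' @param x0 matrix of initial states (one per row) or a single state
#'   vector.
#' @param dt_gamma dimensionless step: the actual step is
#'   `dt_gamma / min(gamma)`.
#' @param horizon_gamma horizon in units of the slowest decay time.
#' @return Matrix of final states (or vector for vector input).
#' @export
integrate_switching_euler <- function(network, q, x0, dt_gamma = 0.05,
                                      horizon_gamma = 200) {
  .check_switching(network, q)
  model <- .sw_model(network, q[1, , drop = FALSE])
  vec <- is.null(dim(x0))
  X <- if (vec) matrix(x0, nrow = 1L) else as.matrix(x0)
  dt <- dt_gamma / min(model$gamma)
  n_steps <- ceiling(horizon_gamma / dt_gamma)
  gam <- rep(model$gamma, each = nrow(X))
  dim(gam) <- dim(X)
  for (s in seq_len(n_steps)) {
    lam <- matrix(1, nrow(X), model$N)
    if (any(!is.na(model$P0)))
      lam[, !is.na(model$P0)] <- rep(model$P0[!is.na(model$P0)],
                                     each = nrow(X))
    for (e in seq_along(model$src)) {
      above <- X[, model$src[e]] > model$theta[e]
      hi <- if (model$act[e]) above else !above
      lam[, model$tgt[e]] <- lam[, model$tgt[e]] *
        ifelse(hi, model$U[e], model$L[e])
    }
    X <- X + dt * (lam - gam * X)
  }
  if (vec) drop(X) else X
}

#' Classify states by nearest switching fixed point
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table.
#' @param x matrix of states (one per row).
#' @param tol relative matching tolerance.
#' @return Character vector of fixed-point labels, `NA` where no fixed
#'   point matches within tolerance.
#' @export
classify_switching_state <- function(network, q, x, tol = 1e-2) {
  fps <- switching_fixed_points(network, q)
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  out <- rep(NA_character_, nrow(x))
  if (!length(fps$labels)) return(out)
  for (j in seq_along(fps$labels)) {
    p <- fps$points[j, ]
    d <- abs(sweep(x, 2, p)) / pmax(abs(rep(p, each = nrow(x))), 1e-8)
    hit <- apply(d, 1, max) <= tol & is.na(out)
    out[hit] <- fps$labels[j]
  }
  out
}

## Extract the 2-node switching parameters in the x/y naming of the
## closed-form basin boundary formulas (x = first node, y = second).
.two_node_pars <- function(network, q) {
  if (length(network$nodes) != 2L)
    stop("separatrix formulas apply to two-node networks")
  n1 <- network$nodes[1]; n2 <- network$nodes[2]
  list(gx = q[[paste0("gamma_", n1)]], gy = q[[paste0("gamma_", n2)]],
       Lxy = q[[paste0("L_", n1, "_", n2)]],
       Uxy = q[[paste0("U_", n1, "_", n2)]],
       thxy = q[[paste0("theta_", n1, "_", n2)]],  # threshold on y
       Lyx = q[[paste0("L_", n2, "_", n1)]],
       Uyx = q[[paste0("U_", n2, "_", n1)]],
       thyx = q[[paste0("theta_", n2, "_", n1)]])  # threshold on x
}

## First-crossing time of x(t) = T + (x0 - T) exp(-g t) through `wall`.
.cross_time <- function(x0, targ, wall, g) log((x0 - targ) / (wall - targ)) / g

#' Analytic basin assignment for the bistable Toggle Switch
#'
#' For a mutual-repression pair in the bistable (central) parameter
#' region — `L_xy < gamma_x theta_yx < U_xy` and
#' `L_yx < gamma_y theta_xy < U_yx` — the two stable fixed points sit in
#' the off-diagonal domains (`FP(01)` where x is below its threshold and
#' y above; `FP(10)` conversely), and the basin boundary inside the two
#' diagonal domains is the locus of equal first-crossing times of the two
#' thresholds.  An initial condition is therefore assigned exactly: by
#' containment in the off-diagonal domains, and by comparing the two
#' closed-form crossing times in the diagonal ones.
#'
#' @param network the two-node mutual-repression network.
#' @param q one row of a `switching_params` table satisfying the
#'   bistability inequalities.
#' @param x0 state vector `c(x, y)` or matrix with one state per row.
#' @param tol relative tolerance below which the two crossing times are
#'   considered tied (`"ambiguous"`, the state lies on the separatrix).
#' @return Character vector: `"10"`, `"01"` or `"ambiguous"`.
#' @export
ts_separatrix_side <- function(network, q, x0, tol = 1e-12) {
  if (!all(network$edges$sign == "repression"))
    stop("ts_separatrix_side expects a mutual-repression (toggle) pair")
  p <- .two_node_pars(network, q[1, , drop = FALSE])
  if (!(p$Lxy < p$gx * p$thyx && p$gx * p$thyx < p$Uxy &&
        p$Lyx < p$gy * p$thxy && p$gy * p$thxy < p$Uyx))
    stop("bistability inequalities do not hold for this parameter set")
  X <- if (is.null(dim(x0))) matrix(x0, nrow = 1L) else as.matrix(x0)
  x <- X[, 1]; y <- X[, 2]
  out <- rep(NA_character_, nrow(X))
  lo_x <- x < p$thyx; lo_y <- y < p$thxy
  out[lo_x & !lo_y] <- "01"   # domain II contains FP(01)
  out[!lo_x & lo_y] <- "10"   # domain IV contains FP(10)
  side <- function(sel, lx, ly, first_cross_x) {
    ## time for x to cross theta_yx vs time for y to cross theta_xy
    tx <- .cross_time(x[sel], lx / p$gx, p$thyx, p$gx)
    ty <- .cross_time(y[sel], ly / p$gy, p$thxy, p$gy)
    lab <- ifelse(xor(tx < ty, !first_cross_x), "10", "01")
    lab[abs(tx - ty) <= tol * pmax(tx, ty)] <- "ambiguous"
    lab
  }
  ## both above their thresholds: decay toward the L/gamma target; y
  ## dropping below theta_xy first leads into domain IV, i.e. FP(10)
  d3 <- !lo_x & !lo_y
  out[d3] <- side(d3, p$Lxy, p$Lyx, first_cross_x = FALSE)
  ## both below: growth toward the U/gamma target; x rising through
  ## theta_yx first leads into domain IV, i.e. FP(10)
  d1 <- lo_x & lo_y
  out[d1] <- side(d1, p$Uxy, p$Uyx, first_cross_x = TRUE)
  out
}

#' Analytic basin assignment for the bistable Double Activation pair
#'
#' Mirror of [ts_separatrix_side()] for mutual activation: under the
#' bistability inequalities the stable fixed points are `FP(00)` (both
#' below threshold) and `FP(11)` (both above), each contained in its own
#' invariant domain, and the basin boundary crosses the two mixed
#' domains, where it is again the locus of equal threshold-crossing
#' times.
#'
#' @inheritParams ts_separatrix_side
#' @return Character vector: `"00"`, `"11"` or `"ambiguous"`.
#' @export
da_separatrix_side <- function(network, q, x0, tol = 1e-12) {
  if (!all(network$edges$sign == "activation"))
    stop("da_separatrix_side expects a mutual-activation pair")
  p <- .two_node_pars(network, q[1, , drop = FALSE])
  if (!(p$Lxy < p$gx * p$thyx && p$gx * p$thyx < p$Uxy &&
        p$Lyx < p$gy * p$thxy && p$gy * p$thxy < p$Uyx))
    stop("bistability inequalities do not hold for this parameter set")
  X <- if (is.null(dim(x0))) matrix(x0, nrow = 1L) else as.matrix(x0)
  x <- X[, 1]; y <- X[, 2]
  out <- rep(NA_character_, nrow(X))
  lo_x <- x < p$thyx; lo_y <- y < p$thxy
  out[lo_x & lo_y] <- "00"    # invariant: both productions stay low
  out[!lo_x & !lo_y] <- "11"  # invariant: both productions stay high
  ## domain II (x low, y high): x grows on U_xy, y decays on L_yx
  d2 <- lo_x & !lo_y
  if (any(d2)) {
    tx <- .cross_time(x[d2], p$Uxy / p$gx, p$thyx, p$gx)
    ty <- .cross_time(y[d2], p$Lyx / p$gy, p$thxy, p$gy)
    lab <- ifelse(tx < ty, "11", "00")  # x crosses first -> both high
    lab[abs(tx - ty) <= tol * pmax(tx, ty)] <- "ambiguous"
    out[d2] <- lab
  }
  ## domain IV (x high, y low): x decays on L_xy, y grows on U_yx
  d4 <- !lo_x & lo_y
  if (any(d4)) {
    tx <- .cross_time(x[d4], p$Lxy / p$gx, p$thyx, p$gx)
    ty <- .cross_time(y[d4], p$Uyx / p$gy, p$thxy, p$gy)
    lab <- ifelse(ty < tx, "11", "00")  # y crosses first -> both high
    lab[abs(tx - ty) <= tol * pmax(tx, ty)] <- "ambiguous"
    out[d4] <- lab
  }
  out
}

#' Basin fractions and basin strength
#'
#' Summarizes attractor assignments of a batch of initial conditions for
#' one parameter set: the fraction of initial conditions converging to
#' each attractor, and the scalar *basin strength*, the product of those
#' fractions.  A fully monostable set has strength 1; a k-stable set has
#' strength at most `(1/k)^k` (0.25 for bistability, at equal basins).
#' Ambiguous or unclassified initial conditions (`NA`) count toward the
#' denominator but toward no attractor, so the fractions sum to at most 1.
#'
#' @param labels character vector of attractor labels per initial
#'   condition, `NA` for unclassified ones.
#' @return Object of class `basin_report`: data frame `fractions`, scalar
#'   `strength`, counts.
#' @examples
#' basin_report(c("10", "10", "01", "10"))  # strength 0.75 * 0.25
#' @export
basin_report <- function(labels) {
  if (!length(labels)) stop("no classified initial conditions")
  n <- length(labels)
  tab <- table(labels, useNA = "no")
  frac <- as.numeric(tab) / n
  structure(list(fractions = data.frame(attractor = names(tab),
                                        fraction = frac),
                 strength = prod(frac),
                 n = n, n_unclassified = sum(is.na(labels))),
            class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  print(x$fractions, row.names = FALSE)
  cat("basin strength:", format(x$strength, digits = 4),
      " (", x$n_unclassified, "of", x$n, "unclassified )\n")
  invisible(x)
}
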