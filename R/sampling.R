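#' Sampling configuration for RACIPE-style parameter ensembles
#'
#' Bundles the uniform sampling ranges and ensemble sizes used by
#' [sample_parameters()].  The defaults follow the RACIPE conventions for
#' ranges estimated from BioNumbers: production uniform on (1, 100) (so the
#' ensemble median production rate is 50), degradation uniform on
#' (0.1, 1), a fold change uniform on (1, 100) for every edge — applied as
#' the activation fold `a = FC > 1` on activating edges and as the
#' repression fold `i = 1/FC < 1` on repressing edges — and Hill
#' coefficients uniform on (1, 6) by default.
#'
#' Thresholds follow the "half-functional" rule: for an edge with source
#' node *j*, the threshold is sampled uniformly on
#' `(0.02 * M_j, 1.98 * M_j)` where `M_j` is the Monte-Carlo median of the
#' steady-state level of *j* when each of *j*'s own regulations is active
#' with probability 1/2 (`(P/gamma) * prod (1/FC)^Bernoulli(0.5)`).  This
#' makes each regulation roughly equally likely to be on or off, and keeps
#' thresholds commensurate with the source's expression scale.
#'
#' @param production,degradation,fold_change,hill numeric length-2 ranges
#'   (lower < upper, all bounds positive).
#' @param n_sets ensemble size M.
#' @param n_init initial conditions per parameter set.
#' @param seed integer random seed governing the whole draw.
#' @param integer_hill logical; sample Hill coefficients as integers
#'   instead of continuous uniforms.
#' @param threshold_scale multipliers of the half-functional median
#'   defining the threshold range.
#' @param threshold_mc Monte-Carlo draws used to estimate each
#'   half-functional median.
#' @param regularity_tol tolerance of the post-translation regularity
#'   screen (see [regularity_screen()]).
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(production = c(1, 100),
                            degradation = c(0.1, 1),
                            fold_change = c(1, 100),
                            hill = c(1, 6),
                            n_sets = 5000L,
                            n_init = 100L,
                            seed = 1L,
                            integer_hill = FALSE,
                            threshold_scale = c(0.02, 1.98),
                            threshold_mc = 100000L,
                            regularity_tol = 1e-9) {
  rng <- list(production = production, degradation = degradation,
              fold_change = fold_change, hill = hill,
              threshold_scale = threshold_scale)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2] || r[1] <= 0)
      stop("invalid range for ", nm, ": bounds must be positive and ordered")
  }
  if (n_sets < 0L) stop("n_sets must be >= 0")
  structure(list(production = production, degradation = degradation,
                 fold_change = fold_change, hill = hill,
                 n_sets = as.integer(n_sets), n_init = as.integer(n_init),
                 seed = as.integer(seed), integer_hill = integer_hill,
                 threshold_scale = threshold_scale,
                 threshold_mc = as.integer(threshold_mc),
                 regularity_tol = regularity_tol),
            class = "sampling_config")
}

#' Read a sampling configuration from a key-value text file
#'
#' The file uses Debian-control (DCF) `key: value` lines; range-valued
#' keys take two comma-separated numbers.  Recognized keys are the
#' arguments of [sampling_config()], e.g.
#'
#' ```
#' production: 1, 100
#' hill: 10, 50
#' n_sets: 5000
#' seed: 7
#' integer_hill: FALSE
#' ```
#'
#' Unrecognized keys are an error; omitted keys keep their defaults.
#'
#' @param path file path.
#' @return A [sampling_config()].
#' @export
read_sampling_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- names(formals(sampling_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  parsed <- lapply(names(raw), function(k) {
    v <- trimws(strsplit(raw[[k]], ",")[[1]])
    if (k == "integer_hill") as.logical(v) else as.numeric(v)
  })
  names(parsed) <- names(raw)
  do.call(sampling_config, parsed)
}

## Half-functional median level per node: median of (P/gamma) with each
## incoming regulation active with probability 1/2.  Active repression and
## inactive activation both scale production by 1/FC.
.half_functional_medians <- function(network, config) {
  n_mc <- config$threshold_mc
  m <- n_inputs(network)
  med <- numeric(length(network$nodes))
  names(med) <- network$nodes
  for (j in seq_along(network$nodes)) {
    lvl <- stats::runif(n_mc, config$production[1], config$production[2]) /
      stats::runif(n_mc, config$degradation[1], config$degradation[2])
    if (m[j] > 0) for (e in seq_len(m[j])) {
      fc <- stats::runif(n_mc, config$fold_change[1], config$fold_change[2])
      on <- stats::runif(n_mc) < 0.5
      lvl <- lvl * ifelse(on, 1 / fc, 1)
    }
    med[j] <- stats::median(lvl)
  }
  med
}

.draw_params <- function(network, config, n, theta_med) {
  nodes <- network$nodes
  edges <- network$edges
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (v in nodes)
    out[[paste0("P_", v)]] <- stats::runif(n, config$production[1],
                                           config$production[2])
  for (v in nodes)
    out[[paste0("gamma_", v)]] <- stats::runif(n, config$degradation[1],
                                               config$degradation[2])
  ec <- function(p) .ecols(network, p)
  th <- ec("theta"); hn <- ec("n"); fl <- ec("fold")
  for (e in seq_len(nrow(edges))) {
    mj <- theta_med[edges$source[e]]
    out[[th[e]]] <- stats::runif(n, config$threshold_scale[1] * mj,
                                 config$threshold_scale[2] * mj)
    out[[hn[e]]] <- if (config$integer_hill)
      sample(seq(ceiling(config$hill[1]), floor(config$hill[2])), n,
             replace = TRUE)
    else stats::runif(n, config$hill[1], config$hill[2])
    fc <- stats::runif(n, config$fold_change[1], config$fold_change[2])
    out[[fl[e]]] <- if (edges$sign[e] == "activation") fc else 1 / fc
  }
  out
}

#' Sample a RACIPE-style parameter ensemble
#'
#' Draws `config$n_sets` kinetic parameter sets for `network` from the
#' uniform ranges in `config` (see [sampling_config()] for the
#' conventions), then applies the regularity screen required by the
#' switching formalism: a set whose translated switching parameters place
#' some production level exactly on a `gamma * theta` product (a
#' measure-zero event for continuous ranges) is resampled.
#'
#' @param network a [grn_network()].
#' @param config a [sampling_config()].
#' @return Data frame of class `racipe_params`, one row per parameter set,
#'   with columns `P_<node>`, `gamma_<node>`, `theta_<target>_<source>`,
#'   `n_<target>_<source>`, `fold_<target>_<source>`.  The number of
#'   resampled rows is recorded in attribute `"resampled"`.
#' @examples
#' ts <- builtin_network("TS")
#' p <- sample_parameters(ts, sampling_config(n_sets = 10, seed = 42))
#' round(p[1, 1:4], 2)
#' @export
sample_parameters <- function(network, config = sampling_config()) {
  stopifnot(inherits(network, "grn_network"))
  set.seed(config$seed)
  theta_med <- .half_functional_medians(network, config)
  out <- .draw_params(network, config, config$n_sets, theta_med)
  resampled <- 0L
  if (config$n_sets > 0L) {
    for (iter in 1:100) {
      ok <- regularity_screen(network, to_switching(network, out),
                              tol = config$regularity_tol)
      if (all(ok)) break
      resampled <- resampled + sum(!ok)
      out[!ok, ] <- .draw_params(network, config, sum(!ok), theta_med)
    }
    if (!all(ok)) stop("regularity screen kept failing after 100 rounds")
  }
  attr(out, "resampled") <- resampled
  attr(out, "theta_medians") <- theta_med
  class(out) <- c("racipe_params", "data.frame")
  out
}

#' Sample initial conditions for a parameter set
#'
#' Initial states are drawn log-uniformly over the envelope
#' `[1e-2 * min_k(P_k/gamma_k), 10 * max_k(P_k/gamma_k)]` of the parameter
#' set, which spans the attainable expression scales across several
#' decades so that every attractor basin receives initial conditions.
#'
#' @param network a [grn_network()].
#' @param params one or more rows of a `racipe_params` table.
#' @param count number of initial conditions per parameter set.
#' @param seed optional integer seed.
#' @return For a single-row `params`, a `count x N` matrix (columns in node
#'   order); otherwise a list of such matrices, one per row.
#' @export
sample_initial_conditions <- function(network, params, count, seed = NULL) {
  stopifnot(count >= 1)
  .check_racipe(network, params)
  if (!is.null(seed)) set.seed(seed)
  P <- .node_mat(params, network, "P")
  G <- .node_mat(params, network, "gamma")
  lvl <- P / G
  lo <- log(1e-2 * apply(lvl, 1, min))
  hi <- log(10 * apply(lvl, 1, max))
  N <- length(network$nodes)
  one <- function(r) {
    m <- matrix(exp(stats::runif(count * N, lo[r], hi[r])), count, N)
    colnames(m) <- network$nodes
    m
  }
  if (nrow(params) == 1L) one(1L) else lapply(seq_len(nrow(params)), one)
}

#' Regularity screen for switching parameters
#'
#' A switching parameter set is *regular* when no production level
#' `Lambda_i(alpha)` (over all on/off combinations of the node's inputs)
#' equals any of the node's `gamma_i * theta` products, and all thresholds
#' of a given source variable are distinct.  Only regular parameters have a
#' well-defined state transition graph.
#'
#' @param network a [grn_network()].
#' @param q rows of a `switching_params` table (see [to_switching()]).
#' @param tol absolute tolerance below which an inequality is considered
#'   violated.
#' @return Logical vector, one entry per row (`TRUE` = regular).  For
#'   failing rows, attribute `"reason"` names the offending inequality.
#' @examples
#' ts <- builtin_network("TS")
#' q <- data.frame(gamma_A = 1, gamma_B = 1, L_B_A = 1, U_B_A = 3,
#'                 theta_B_A = 2, L_A_B = 1, U_A_B = 2, theta_A_B = 2)
#' regularity_screen(ts, q)  # gamma_A * theta_A_B == U_A_B -> fails
#' @export
regularity_screen <- function(network, q, tol = 1e-9) {
  .check_switching(network, q)
  n <- nrow(q)
  pass <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    hit <- bad & pass
    reason[hit] <<- msg
    pass <- pass & !bad
    pass
  }
  nodes <- network$nodes
  edges <- network$edges
  thc <- .ecols(network, "theta")
  Lc <- .ecols(network, "L"); Uc <- .ecols(network, "U")
  for (i in seq_along(nodes)) {
    out_e <- which(edges$source == nodes[i])
    in_e <- which(edges$target == nodes[i])
    gam <- q[[paste0("gamma_", nodes[i])]]
    ## all attainable production levels of node i
    if (length(in_e)) {
      combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(in_e)))
      lams <- lapply(seq_len(nrow(combos)), function(ci) {
        v <- rep(1, n)
        for (j in seq_along(in_e)) {
          e <- in_e[j]
          v <- v * if (combos[ci, j]) q[[Uc[e]]] else q[[Lc[e]]]
        }
        v
      })
    } else lams <- list(q[[paste0("P_", nodes[i])]])
    for (e in out_e) {
      gt <- gam * q[[thc[e]]]
      for (lam in lams)
        pass <- flag(abs(gt - lam) <= tol,
                     paste0("gamma_", nodes[i], " * ", thc[e],
                            " coincides with a production level of ",
                            nodes[i]))
    }
    ## distinct thresholds of the same source variable
    if (length(out_e) > 1L) {
      cmb <- utils::combn(out_e, 2)
      for (cc in seq_len(ncol(cmb))) {
        d <- abs(q[[thc[cmb[1, cc]]]] - q[[thc[cmb[2, cc]]]])
        pass <- flag(d <= tol,
                     paste0("coincident thresholds ", thc[cmb[1, cc]],
                            " and ", thc[cmb[2, cc]]))
      }
    }
  }
  attr(pass, "reason") <- reason
  pass
}
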