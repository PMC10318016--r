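#' Translate RACIPE parameters to switching-system parameters
#'
#' The map `R` from a shifted-Hill (RACIPE) parameter set to the switching
#' (Glass) system it limits to as all Hill coefficients grow.  The basal
#' production rate of a node with `m_k` inputs is attributed evenly to its
#' input edges: every input edge `j -> k` gets the upper level
#' `U_kj = P_k^(1/m_k)`; the lower level is `U_kj / a_kj` on activating
#' edges and `U_kj * i_kj` on repressing edges.  Thresholds and decay
#' rates are common to the two formalisms and carried over unchanged, so
#' `P_k = prod_j U_kj` holds exactly and `0 < L < U` is guaranteed by
#' `a > 1`, `i < 1`.  The Hill coefficients are the one RACIPE parameter
#' with no switching counterpart (the switching system is their infinite
#' limit) and are dropped.
#'
#' Unregulated nodes (`m_k = 0`) keep their constant production `P_k` as a
#' `P_<node>` column: the translation is the identity on it.
#'
#' @param network a [grn_network()].
#' @param params rows of a `racipe_params` table.
#' @return Data frame of class `switching_params` with columns
#'   `gamma_<node>`, `L_<target>_<source>`, `U_<target>_<source>`,
#'   `theta_<target>_<source>` (plus `P_<node>` for unregulated nodes).
#' @examples
#' ts <- builtin_network("TS")
#' p <- sample_parameters(ts, sampling_config(n_sets = 3, seed = 7))
#' to_switching(ts, p)
#' @seealso [to_racipe()] for the inverse map `D` (`D o R` is the
#'   identity), [regularity_screen()].
#' @export
to_switching <- function(network, params) {
  .check_racipe(network, params)
  nodes <- network$nodes
  edges <- network$edges
  m <- n_inputs(network)
  out <- data.frame(row.names = seq_len(nrow(params)))
  for (v in nodes)
    out[[paste0("gamma_", v)]] <- params[[paste0("gamma_", v)]]
  for (v in nodes[m == 0L])
    out[[paste0("P_", v)]] <- params[[paste0("P_", v)]]
  Lc <- .ecols(network, "L"); Uc <- .ecols(network, "U")
  thc <- .ecols(network, "theta"); fc <- .ecols(network, "fold")
  for (e in seq_len(nrow(edges))) {
    k <- edges$target[e]
    U <- params[[paste0("P_", k)]]^(1 / m[k])
    fold <- params[[fc[e]]]
    out[[Uc[e]]] <- U
    out[[Lc[e]]] <- if (edges$sign[e] == "activation") U / fold else U * fold
    out[[thc[e]]] <- params[[thc[e]]]
  }
  class(out) <- c("switching_params", "data.frame")
  out
}

#' Translate switching-system parameters to RACIPE parameters
#'
#' The map `D`, inverse to [to_switching()] on its image: production rates
#' are recovered as `P_k = prod_j U_kj` and the folds as
#' `a_kj = P_k^(1/m_k) / L_kj` (activation) or
#' `i_kj = L_kj / P_k^(1/m_k)` (repression).  Because the switching system
#' is the infinite-Hill limit, the returned set carries no finite Hill
#' coefficient: the `n_*` columns are `Inf` and the result is flagged with
#' attribute `"switching_limit"`.
#'
#' `D o R` is the identity, but `R o D` is not: the map is undefined
#' wherever some `L_kj` equals `P_k^(1/m_k)` (the fold would be exactly 1,
#' which is not a valid RACIPE parameter), and a round trip through `D`
#' need not return to the same point of switching parameter space.
#'
#' @param network a [grn_network()].
#' @param q rows of a `switching_params` table.
#' @return Data frame of class `racipe_params` with `n_*` columns `Inf`
#'   and attribute `switching_limit = TRUE`.
#' @export
to_racipe <- function(network, q) {
  .check_switching(network, q)
  nodes <- network$nodes
  edges <- network$edges
  m <- n_inputs(network)
  out <- data.frame(row.names = seq_len(nrow(q)))
  P <- stats::setNames(vector("list", length(nodes)), nodes)
  Uc <- .ecols(network, "U")
  for (v in nodes) {
    ine <- which(edges$target == v)
    P[[v]] <- if (length(ine)) {
      pr <- rep(1, nrow(q))
      for (e in ine) pr <- pr * q[[Uc[e]]]
      pr
    } else q[[paste0("P_", v)]]
  }
  for (v in nodes) out[[paste0("P_", v)]] <- P[[v]]
  for (v in nodes) out[[paste0("gamma_", v)]] <- q[[paste0("gamma_", v)]]
  Lc <- .ecols(network, "L"); thc <- .ecols(network, "theta")
  nc <- .ecols(network, "n"); fc <- .ecols(network, "fold")
  for (e in seq_len(nrow(edges))) {
    k <- edges$target[e]
    root <- P[[k]]^(1 / m[k])
    L <- q[[Lc[e]]]
    if (any(L >= root))
      stop("translation to RACIPE undefined: L = P^(1/m) (fold change ",
           "would be 1) on edge ", edges$source[e], " -> ", edges$target[e])
    out[[thc[e]]] <- q[[thc[e]]]
    out[[nc[e]]] <- Inf
    out[[fc[e]]] <- if (edges$sign[e] == "activation") root / L else L / root
  }
  attr(out, "switching_limit") <- TRUE
  class(out) <- c("racipe_params", "data.frame")
  out
}

#' Link strength of a regulatory edge
#'
#' The nondimensional measure
#' `LS = P_source * n / (gamma_source * theta * fold)` of how strongly an
#' edge acts on its target: large when the source is abundant relative to
#' the edge's threshold and the regulation is steep and strong.  For
#' repressing edges `fold` is the repression fold `i < 1`.  The measure is
#' extended to activating edges by using `1/a` in place of `i`, so that a
#' stronger activation also gives a larger strength; this extension is a
#' package convention.
#'
#' @param network a [grn_network()].
#' @param params rows of a `racipe_params` table.
#' @param source,target node names identifying the edge.
#' @return Numeric vector of strengths (typically examined on a log
#'   scale).
#' @examples
#' ts <- builtin_network("TS")
#' p <- data.frame(P_A = 50, gamma_A = 0.5, P_B = 1, gamma_B = 1,
#'                 theta_B_A = 10, n_B_A = 2, fold_B_A = 0.5,
#'                 theta_A_B = 1, n_A_B = 1, fold_A_B = 0.5)
#' link_strength(ts, p, "A", "B")  # 50*2/(0.5*10*0.5) = 40
#' @export
link_strength <- function(network, params, source, target) {
  .check_racipe(network, params)
  e <- which(network$edges$source == source & network$edges$target == target)
  if (length(e) != 1L)
    stop("no edge ", source, " -> ", target, " in network")
  fold <- params[[.ecols(network, "fold")[e]]]
  if (network$edges$sign[e] == "activation") fold <- 1 / fold
  params[[paste0("P_", source)]] * params[[.ecols(network, "n")[e]]] /
    (params[[paste0("gamma_", source)]] * params[[.ecols(network, "theta")[e]]] * fold)
}
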