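## Internal helpers: parameter-table column conventions and fast access.
##
## RACIPE-style tables (class "racipe_params"), one row per parameter set:
##   P_<node>, gamma_<node>  per node
##   theta_<target>_<source>, n_<target>_<source>, fold_<target>_<source>
##     per edge, in network edge order; `fold` holds the activation fold
##     a > 1 on activating edges and the repression fold i < 1 on
##     repressing edges.
## Switching-system tables (class "switching_params"):
##   gamma_<node> per node, P_<node> for unregulated nodes only,
##   L_<t>_<s>, U_<t>_<s>, theta_<t>_<s> per edge.

.ecols <- function(network, prefix) {
  if (nrow(network$edges) == 0L) return(character(0))
  paste0(prefix, "_", network$edges$target, "_", network$edges$source)
}

.ncols <- function(network, prefix) paste0(prefix, "_", network$nodes)

.node_mat <- function(params, network, prefix) {
  m <- as.matrix(params[, .ncols(network, prefix), drop = FALSE])
  dimnames(m) <- list(NULL, network$nodes)
  m
}

.edge_mat <- function(params, network, prefix) {
  m <- as.matrix(params[, .ecols(network, prefix), drop = FALSE])
  dimnames(m) <- NULL
  m
}

.check_cols <- function(params, cols, what) {
  miss <- setdiff(cols, names(params))
  if (length(miss))
    stop("missing ", what, " column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

.check_racipe <- function(network, params) {
  .check_cols(params, c(.ncols(network, "P"), .ncols(network, "gamma"),
                        .ecols(network, "theta"), .ecols(network, "n"),
                        .ecols(network, "fold")), "RACIPE parameter")
}

.check_switching <- function(network, params) {
  m <- n_inputs(network)
  cols <- c(.ncols(network, "gamma"), .ecols(network, "L"),
            .ecols(network, "U"), .ecols(network, "theta"))
  if (any(m == 0L))
    cols <- c(cols, paste0("P_", network$nodes[m == 0L]))
  .check_cols(params, cols, "switching parameter")
}

## Per-set switching model used by the combinatorial and event-driven code.
## Thresholds of each source variable are sorted; each outgoing edge gets
## the rank of its threshold in that order, so a source at discrete level
## a is above the edge's threshold iff a >= rank.
.sw_model <- function(network, q) {
  q <- as.list(q)
  nodes <- network$nodes
  N <- length(nodes)
  edges <- network$edges
  src_i <- match(edges$source, nodes)
  tgt_i <- match(edges$target, nodes)
  theta <- unlist(q[.ecols(network, "theta")], use.names = FALSE)
  L <- unlist(q[.ecols(network, "L")], use.names = FALSE)
  U <- unlist(q[.ecols(network, "U")], use.names = FALSE)
  gamma <- unlist(q[.ncols(network, "gamma")], use.names = FALSE)
  lev <- tabulate(src_i, nbins = N)            # |T(i)| per node
  rank_e <- integer(nrow(edges))
  thr_sorted <- vector("list", N)              # sorted thresholds per node
  for (i in seq_len(N)) {
    out <- which(src_i == i)
    if (length(out)) {
      o <- order(theta[out])
      thr_sorted[[i]] <- theta[out][o]
      rank_e[out[o]] <- seq_along(out)
    } else thr_sorted[[i]] <- numeric(0)
  }
  P0 <- rep(NA_real_, N)                       # constants for unregulated nodes
  m_in <- tabulate(tgt_i, nbins = N)
  if (any(m_in == 0L)) {
    nm <- paste0("P_", nodes[m_in == 0L])
    P0[m_in == 0L] <- unlist(q[nm], use.names = FALSE)
  }
  list(N = N, nodes = nodes, src = src_i, tgt = tgt_i,
       act = edges$sign == "activation",
       theta = theta, L = L, U = U, gamma = gamma,
       lev = lev, rank = rank_e, thr = thr_sorted, P0 = P0,
       in_edges = lapply(seq_len(N), function(k) which(tgt_i == k)))
}

## Production term Lambda_k(alpha) for every node, one domain multi-index.
.sw_lambda <- function(model, alpha) {
  lam <- numeric(model$N)
  for (k in seq_len(model$N)) {
    ine <- model$in_edges[[k]]
    if (!length(ine)) { lam[k] <- model$P0[k]; next }
    v <- 1
    for (e in ine) {
      above <- alpha[model$src[e]] >= model$rank[e]
      on_high <- if (model$act[e]) above else !above
      v <- v * if (on_high) model$U[e] else model$L[e]
    }
    lam[k] <- v
  }
  lam
}

## Domain interval of coordinate i at discrete level a (open interval).
.sw_interval <- function(model, i, a) {
  thr <- model$thr[[i]]
  lo <- if (a == 0) 0 else thr[a]
  hi <- if (a == length(thr)) Inf else thr[a + 1]
  c(lo, hi)
}

## Multi-index for a continuous state (off-threshold assumed).
.sw_domain_of <- function(model, x) {
  vapply(seq_len(model$N),
         function(i) sum(x[i] > model$thr[[i]]), integer(1))
}

.alpha_label <- function(alpha) paste(alpha, collapse = "")

#' Canonical attractor-repertoire name
#'
#' Joins the unique, lexicographically sorted attractor labels with `"-"`,
#' e.g. `"01-10"` or `"002-020-200"`.
#'
#' @param labels character vector of per-attractor labels.
#' @return Single canonical string.
#' @export
canonical_repertoire <- function(labels) {
  paste(sort(unique(labels)), collapse = "-")
}
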