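#' Domain target point of a switching system
#'
#' Within each rectangular phase-space domain `D(alpha)` the switching flow
#' is linear and converges toward the target point
#' `T(alpha) = (Lambda_1(alpha)/gamma_1, ..., Lambda_n(alpha)/gamma_n)`,
#' where `Lambda_i` is the product over input edges of the upper or lower
#' level selected by whether each source sits above or below the edge's
#' threshold in `alpha`.
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table.
#' @param alpha integer multi-index, `alpha[i]` in `0:|T(i)|` (number of
#'   thresholds of variable `i` crossed).
#' @return Numeric vector, one coordinate per node.
#' @export
target_point <- function(network, q, alpha) {
  .check_switching(network, q)
  model <- .sw_model(network, q[1, , drop = FALSE])
  stopifnot(length(alpha) == model$N, all(alpha >= 0), all(alpha <= model$lev))
  stats::setNames(.sw_lambda(model, alpha) / model$gamma, network$nodes)
}

#' Build the state transition graph of a switching parameter set
#'
#' Phase space decomposes into `prod(|T(i)| + 1)` rectangular domains
#' bounded by the thresholds.  The STG has one node per domain; a domain
#' whose target point lies inside it gets a self-edge, and each wall
#' between adjacent domains carries exactly one directed edge, pointing in
#' the direction of the flow through that wall (upward iff the shared
#' coordinate's target lies above the wall threshold).
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table; must be regular (see
#'   [regularity_screen()]).
#' @return An object of class `stg`: list with `domains` (matrix of
#'   multi-indices), `labels`, `edges` (data frame `from`/`to` of domain
#'   indices, self-edges included) and the internal model.
#' @export
build_stg <- function(network, q) {
  .check_switching(network, q)
  model <- .sw_model(network, q[1, , drop = FALSE])
  lev <- model$lev
  grid <- as.matrix(expand.grid(lapply(lev, function(l) 0:l)))
  dimnames(grid) <- NULL
  n_dom <- nrow(grid)
  ## target points, one row per domain
  targ <- t(apply(grid, 1, function(a) .sw_lambda(model, a) / model$gamma))
  if (model$N == 1L) targ <- matrix(targ, ncol = 1L)
  from <- integer(0); to <- integer(0)
  idx <- function(alpha) { # row index of a multi-index in the grid
    i <- 1L; mult <- 1L
    for (d in seq_len(model$N)) {
      i <- i + alpha[d] * mult
      mult <- mult * (lev[d] + 1L)
    }
    i
  }
  for (r in seq_len(n_dom)) {
    a <- grid[r, ]
    inside <- TRUE
    for (i in seq_len(model$N)) {
      iv <- .sw_interval(model, i, a[i])
      ti <- targ[r, i]
      if (ti == iv[1] || ti == iv[2])
        stop("target point on a threshold: parameter set is not regular")
      if (ti < iv[1] || ti > iv[2]) inside <- FALSE
    }
    if (inside) { from <- c(from, r); to <- c(to, r) }
    ## walls to the domain above in each coordinate (lower wall handled
    ## by the neighbour below)
    for (i in seq_len(model$N)) {
      if (a[i] >= lev[i]) next
      b <- a; b[i] <- a[i] + 1L
      rb <- idx(b)
      wall <- model$thr[[i]][a[i] + 1L]
      ## Lambda_i is independent of alpha_i (no self-loops), so the
      ## target coordinate is the same on both sides of the wall
      if (targ[r, i] > wall) { from <- c(from, r); to <- c(to, rb) }
      else                   { from <- c(from, rb); to <- c(to, r) }
    }
  }
  structure(list(domains = grid,
                 labels = apply(grid, 1, paste, collapse = ""),
                 targets = targ,
                 edges = data.frame(from = from, to = to),
                 model = model, network = network),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph:", nrow(x$domains), "domains,",
      nrow(x$edges), "edges (incl.",
      sum(x$edges$from == x$edges$to), "self-edges)\n")
  invisible(x)
}

#' Morse graph and predicted attractor repertoire of an STG
#'
#' Collapses the STG to its recurrent strongly connected components,
#' partially ordered by reachability.  Minimal components (no other
#' recurrent component reachable) are the predicted attractors: a
#' singleton component is a stable fixed point annotated `FP(<domain>)`
#' and labelled by the domain's discrete coordinates (e.g. `"01"`); any
#' nontrivial recurrent component is annotated `"cycle"`.
#'
#' @param stg an object from [build_stg()].
#' @return Object of class `morse_graph`: data frame `nodes` (component,
#'   annotation, label, size, minimal), reachability `edges` among Morse
#'   nodes, and `repertoire`, the canonical sorted attractor repertoire
#'   string.
#' @export
morse_graph <- function(stg) {
  g <- igraph::make_graph(c(rbind(stg$edges$from, stg$edges$to)),
                          n = nrow(stg$domains), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership
  n_comp <- comp$no
  size <- tabulate(member, n_comp)
  has_self <- logical(n_comp)
  self <- stg$edges$from == stg$edges$to
  has_self[member[stg$edges$from[self]]] <- TRUE
  recurrent <- size > 1L | has_self
  ## condensation and reachability between components
  cg <- igraph::make_graph(c(rbind(member[stg$edges$from],
                                   member[stg$edges$to])),
                           n = n_comp, directed = TRUE)
  cg <- igraph::simplify(cg)
  d <- igraph::distances(cg, mode = "out")
  reach <- is.finite(d) & d > 0
  minimal <- recurrent & !apply(reach[, recurrent, drop = FALSE], 1,
                                function(z) any(z))
  rec_id <- which(recurrent)
  ann <- ifelse(size[rec_id] == 1L, "FP", "cycle")
  lab <- vapply(seq_along(rec_id), function(j) {
    if (ann[j] == "FP") stg$labels[which(member == rec_id[j])] else "cycle"
  }, character(1))
  nodes <- data.frame(component = rec_id, annotation = ann, label = lab,
                      size = size[rec_id], minimal = minimal[rec_id])
  er <- which(reach & outer(recurrent, recurrent, `&`), arr.ind = TRUE)
  edges <- data.frame(from = match(er[, 1], rec_id),
                      to = match(er[, 2], rec_id))
  structure(list(nodes = nodes, edges = edges,
                 repertoire = canonical_repertoire(lab[nodes$minimal]),
                 membership = member),
            class = "morse_graph")
}

#' @export
print.morse_graph <- function(x, ...) {
  cat("Morse graph:", nrow(x$nodes), "recurrent component(s)\n")
  ann <- ifelse(x$nodes$annotation == "FP",
                paste0("FP(", x$nodes$label, ")"), "cycle")
  cat(paste0("  ", ann, ifelse(x$nodes$minimal, "  [attractor]", "")),
      sep = "\n")
  cat("predicted repertoire:", x$repertoire, "\n")
  invisible(x)
}

#' Predicted attractor repertoire of switching parameter sets
#'
#' Convenience wrapper: builds the STG and Morse graph for each row of `q`
#' and returns the canonical predicted repertoire string.
#'
#' @param network a [grn_network()].
#' @param q rows of a `switching_params` table.
#' @return Character vector of canonical repertoires, one per row.
#' @export
switching_repertoire <- function(network, q) {
  .check_switching(network, q)
  vapply(seq_len(nrow(q)), function(r)
    morse_graph(build_stg(network, q[r, , drop = FALSE]))$repertoire,
    character(1))
}

## Per-node factor choice for single-input/single-output nodes, following
## the three-way split (0: gamma*theta < L < U, 1: L < gamma*theta < U,
## 2: L < U < gamma*theta).  Vectorized over rows of q.
.factor_choice <- function(network, q) {
  nodes <- network$nodes
  edges <- network$edges
  Lc <- .ecols(network, "L"); Uc <- .ecols(network, "U")
  thc <- .ecols(network, "theta")
  sapply(seq_along(nodes), function(i) {
    oe <- which(edges$source == nodes[i])
    ie <- which(edges$target == nodes[i])
    if (length(oe) != 1L || length(ie) != 1L)
      stop("factor choices need single-input/single-output nodes")
    gt <- q[[paste0("gamma_", nodes[i])]] * q[[thc[oe]]]
    ifelse(gt < q[[Lc[ie]]], 0L, ifelse(gt < q[[Uc[ie]]], 1L, 2L))
  })
}

#' Assign switching parameter sets to parameter-graph nodes
#'
#' For networks whose nodes all have exactly one input and one output
#' (Toggle Switch, Double Activation, Negative Feedback), each node
#' contributes a three-way factor choice comparing its `gamma * theta`
#' product with the lower/upper levels of its input edge.  The parameter
#' node index is the row-major combination of the factor choices over the
#' network's node order, `index = 3 * c_1 + c_2` for two-node networks:
#' indices run 0-8 and the central node — both factors in the middle
#' position `L < gamma*theta < U` — is index 4.
#'
#' @param network a [grn_network()] with single-input/single-output nodes.
#' @param q rows of a `switching_params` table.
#' @return Integer vector of 0-based parameter node indices.
#' @export
parameter_node <- function(network, q) {
  .check_switching(network, q)
  ch <- .factor_choice(network, q)
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1L)
  N <- length(network$nodes)
  idx <- rep(0L, nrow(ch))
  for (i in seq_len(N)) idx <- idx * 3L + ch[, i]
  idx
}

#' Inequality signature of a switching parameter set
#'
#' The complete list of inequalities that place a regular switching
#' parameter set in its parameter-space domain: for every node, the order
#' of its output thresholds, and for every output threshold and every
#' on/off combination of the node's inputs, whether the production level
#' `Lambda` exceeds `gamma * theta`.  All parameters with the same
#' signature share the same state transition graph.
#'
#' @param network a [grn_network()].
#' @param q one row of a `switching_params` table.
#' @return Object of class `dsgrn_signature`: list with `key` (canonical
#'   string), per-node inequality tables, and — for networks where all
#'   nodes have one input and one output — the 0-based `node` index of
#'   [parameter_node()].
#' @export
dsgrn_signature <- function(network, q) {
  .check_switching(network, q)
  q <- q[1, , drop = FALSE]
  nodes <- network$nodes
  edges <- network$edges
  Lc <- .ecols(network, "L"); Uc <- .ecols(network, "U")
  thc <- .ecols(network, "theta")
  per_node <- list()
  for (i in seq_along(nodes)) {
    oe <- which(edges$source == nodes[i])
    ie <- which(edges$target == nodes[i])
    if (length(oe) == 0L) next
    th <- vapply(oe, function(e) q[[thc[e]]], numeric(1))
    ord <- order(th)
    gam <- q[[paste0("gamma_", nodes[i])]]
    if (length(ie)) {
      combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(ie)))
      lam <- apply(combos, 1, function(hi) {
        v <- 1
        for (j in seq_along(ie))
          v <- v * if (hi[j]) q[[Uc[ie[j]]]] else q[[Lc[ie[j]]]]
        v
      })
      combo_lab <- apply(combos, 1, function(hi)
        paste(ifelse(hi, "U", "L"), collapse = ""))
    } else {
      lam <- q[[paste0("P_", nodes[i])]]
      combo_lab <- "const"
    }
    tab <- outer(lam, th[ord], function(l, t) l > gam * t)
    dimnames(tab) <- list(combo_lab,
                          paste0("theta_", edges$target[oe][ord], "_", nodes[i]))
    per_node[[nodes[i]]] <- list(threshold_order = oe[ord], greater = tab)
  }
  key <- paste(vapply(names(per_node), function(v) {
    s <- per_node[[v]]
    paste0(v, ":", paste(s$threshold_order, collapse = ","), ":",
           paste(as.integer(s$greater), collapse = ""))
  }, character(1)), collapse = ";")
  node <- tryCatch(parameter_node(network, q), error = function(e) NA_integer_)
  structure(list(key = key, per_node = per_node, node = node),
            class = "dsgrn_signature")
}

#' Enumerate the parameter graph of a single-input/single-output network
#'
#' For a network in which every node has exactly one input and one output,
#' the parameter graph is the product of per-node three-choice factor
#' graphs: `3^N` parameter nodes (9 for the two-node motifs), indexed
#' row-major over the node order with the factor choices ordered
#' `gamma*theta < L < U`, `L < gamma*theta < U`, `L < U < gamma*theta`.
#' Each parameter node is annotated with the Morse-graph attractor
#' repertoire computed from a representative parameter set satisfying its
#' inequalities; two parameter nodes are adjacent when they differ by a
#' single inequality (one factor choice moved one step).
#'
#' @param network a [grn_network()] with single-input/single-output nodes.
#' @return Object of class `parameter_graph`: data frame `nodes` (`index`,
#'   factor choices, `repertoire`, `n_attractors`), adjacency `edges`, and
#'   the network.
#' @examples
#' pg <- enumerate_parameter_graph(builtin_network("TS"))
#' pg$nodes[pg$nodes$index == 4, ]
#' @export
enumerate_parameter_graph <- function(network) {
  m_in <- n_inputs(network); m_out <- n_outputs(network)
  if (!all(m_in == 1L) || !all(m_out == 1L))
    stop("parameter graph enumeration supports only networks where every ",
         "node has exactly one input and one output")
  nodes <- network$nodes
  N <- length(nodes)
  ## row r holds the base-3 digits of index r - 1, node 1 most significant
  grid <- t(vapply(0:(3^N - 1), function(ix) {
    d <- integer(N)
    for (i in N:1) { d[i] <- ix %% 3L; ix <- ix %/% 3L }
    d
  }, integer(N)))
  ## representative parameters: L = 1, U = 3, gamma = 1; the output
  ## threshold of node i is 0.5, 2 or 4 according to its factor choice
  theta_rep <- c(0.5, 2, 4)
  rep_q <- function(choice) {
    q <- data.frame(row.names = 1L)
    for (v in nodes) q[[paste0("gamma_", v)]] <- 1
    for (e in seq_len(nrow(network$edges))) {
      src <- match(network$edges$source[e], nodes)
      q[[.ecols(network, "L")[e]]] <- 1
      q[[.ecols(network, "U")[e]]] <- 3
      q[[.ecols(network, "theta")[e]]] <- theta_rep[choice[src] + 1L]
    }
    q
  }
  reps <- character(nrow(grid)); natt <- integer(nrow(grid))
  morse <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    q <- rep_q(grid[r, ])
    stopifnot(parameter_node(network, q) == r - 1L)
    mg <- morse_graph(build_stg(network, q))
    reps[r] <- mg$repertoire
    natt[r] <- sum(mg$nodes$minimal)
    morse[[r]] <- mg
  }
  ## adjacency: one factor choice changed by one step
  dif <- as.matrix(stats::dist(grid, method = "manhattan"))
  adj <- which(dif == 1 & upper.tri(dif), arr.ind = TRUE)
  nodes_df <- data.frame(index = seq_len(nrow(grid)) - 1L, grid, reps, natt)
  names(nodes_df) <- c("index", paste0("choice_", nodes), "repertoire",
                       "n_attractors")
  structure(list(nodes = nodes_df,
                 edges = data.frame(from = adj[, 1] - 1L, to = adj[, 2] - 1L),
                 morse = morse, network = network),
            class = "parameter_graph")
}

#' @export
print.parameter_graph <- function(x, ...) {
  cat("DSGRN parameter graph:", nrow(x$nodes), "parameter nodes,",
      nrow(x$edges), "adjacencies\n")
  print(x$nodes[, c("index", "repertoire", "n_attractors")], row.names = FALSE)
  invisible(x)
}

#' Export a state transition graph or Morse graph as DOT
#'
#' @param x an `stg` or `morse_graph` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path) {
  arrows <- function(pre, e) {
    if (nrow(e) == 0L) character(0)
    else paste0("  ", pre, e$from, " -> ", pre, e$to, ";")
  }
  if (inherits(x, "stg")) {
    lines <- c("digraph STG {",
               paste0("  d", seq_len(nrow(x$domains)),
                      " [label=\"", x$labels, "\"];"),
               arrows("d", x$edges),
               "}")
  } else if (inherits(x, "morse_graph")) {
    ann <- ifelse(x$nodes$annotation == "FP",
                  paste0("FP(", x$nodes$label, ")"), "cycle")
    lines <- c("digraph Morse {",
               paste0("  m", seq_len(nrow(x$nodes)), " [label=\"", ann, "\"];"),
               arrows("m", x$edges),
               "}")
  } else stop("write_dot handles stg and morse_graph objects")
  writeLines(lines, path)
  invisible(path)
}
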