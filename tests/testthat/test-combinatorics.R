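test_that("target points take the closed product form", {
  ts <- builtin_network("TS")
  q <- ts_center_q(gx = 0.5, gy = 2, Lxy = 1, Uxy = 4, Lyx = 0.8, Uyx = 5)
  ## both nodes above threshold: both repressions active, targets L/gamma
  expect_equal(unname(target_point(ts, q, c(1, 1))),
               c(1 / 0.5, 0.8 / 2))
  expect_equal(unname(target_point(ts, q, c(0, 0))), c(4 / 0.5, 5 / 2))
  ## single-input activation with the source below the threshold: L/gamma
  nf <- builtin_network("NF")
  expect_equal(unname(target_point(nf, q, c(0, 0)))[2], 0.8 / 2)
  expect_equal(unname(target_point(nf, q, c(1, 0)))[2], 5 / 2)
})

test_that("toggle-triad target points match a brute-force factor enumeration", {
  tt <- builtin_network("TT")
  p <- sample_parameters(tt, sampling_config(n_sets = 4, seed = 43))
  qs <- to_switching(tt, p)
  nodes <- tt$nodes
  for (m in seq_len(4)) {
    q <- qs[m, , drop = FALSE]
    ## independent oracle: pick U/L per edge directly from the definition
    oracle <- function(alpha) {
      vapply(seq_along(nodes), function(k) {
        prod <- 1
        for (e in which(tt$edges$target == nodes[k])) {
          s <- tt$edges$source[e]
          si <- match(s, nodes)
          th <- q[[paste0("theta_", nodes[k], "_", s)]]
          ## source level alpha_s vs the rank of this threshold among the
          ## source's sorted outgoing thresholds
          out_th <- vapply(which(tt$edges$source == s), function(oe)
            q[[paste0("theta_", tt$edges$target[oe], "_", s)]], numeric(1))
          above <- alpha[si] >= rank(out_th)[match(th, out_th)]
          val <- if (above) q[[paste0("L_", nodes[k], "_", s)]]
                 else q[[paste0("U_", nodes[k], "_", s)]]  # repression
          prod <- prod * val
        }
        prod / q[[paste0("gamma_", nodes[k])]]
      }, numeric(1))
    }
    for (alpha in list(c(2, 0, 0), c(0, 2, 1), c(1, 1, 1), c(2, 2, 2)))
      expect_equal(unname(target_point(tt, q, alpha)), oracle(alpha))
  }
  ## the printed special case: alpha = (2,0,0) has both repressors of A off
  q1 <- qs[1, , drop = FALSE]
  expect_equal(unname(target_point(tt, q1, c(2, 0, 0)))[1],
               q1$U_A_B * q1$U_A_C / q1$gamma_A)
})

test_that("parameter node indexing follows the row-major three-way split", {
  ts <- builtin_network("TS")
  expect_identical(parameter_node(ts, ts_center_q()), 4L)
  ## gamma*theta below both input levels on A's factor, above on B's
  q <- ts_center_q()
  q$theta_B_A <- 0.5   # gamma_A theta_B_A < L_A_B
  q$theta_A_B <- 4     # gamma_B theta_A_B > U_B_A
  expect_identical(parameter_node(ts, q), 2L)
  sig <- dsgrn_signature(ts, q)
  expect_identical(sig$node, 2L)
  expect_true(is.character(sig$key) && nzchar(sig$key))
  ## homogeneous inequalities: joint scaling leaves the signature fixed
  q2 <- ts_center_q()
  for (v in names(q2)) if (!startsWith(v, "theta")) q2[[v]] <- 5 * q2[[v]]
  q2$theta_B_A <- 2; q2$theta_A_B <- 2  # thetas unscaled, gammas carry it
  expect_identical(parameter_node(ts, q2), parameter_node(ts, ts_center_q()))
})

test_that("two-node parameter graphs have the exact enumerated structure", {
  ts <- builtin_network("TS")
  pg <- enumerate_parameter_graph(ts)
  expect_identical(nrow(pg$nodes), 9L)
  expect_identical(sum(pg$nodes$n_attractors == 2), 1L)
  expect_identical(pg$nodes$repertoire[pg$nodes$index == 4], "01-10")
  expect_identical(enumerate_parameter_graph(builtin_network("DA"))$nodes$repertoire[5],
                   "00-11")
  expect_identical(enumerate_parameter_graph(builtin_network("NF"))$nodes$repertoire[5],
                   "cycle")
  ## 3x3 grid adjacency: corners degree 2, edge midpoints 3, center 4
  deg <- tabulate(c(pg$edges$from, pg$edges$to) + 1L, 9L)
  expect_identical(deg[c(1, 3, 7, 9)], rep(2L, 4))
  expect_identical(deg[c(2, 4, 6, 8)], rep(3L, 4))
  expect_identical(deg[5], 4L)
  expect_error(enumerate_parameter_graph(builtin_network("TT")),
               "one input and one output")
})

test_that("state transition graphs obey the wall rules", {
  ts <- builtin_network("TS")
  stg <- build_stg(ts, ts_center_q())
  expect_identical(nrow(stg$domains), 4L)
  self <- stg$edges$from == stg$edges$to
  ## the two off-diagonal domains hold the stable fixed points
  expect_setequal(stg$labels[stg$edges$from[self]], c("01", "10"))
  ## property checks over random regular parameter sets
  for (nm in c("TS", "DA", "NF")) {
    net <- builtin_network(nm)
    p <- sample_parameters(net, sampling_config(n_sets = 25, seed = 47))
    q <- to_switching(net, p)
    for (m in seq_len(nrow(q))) {
      stg <- build_stg(net, q[m, , drop = FALSE])
      self <- stg$edges$from == stg$edges$to
      ## each of the 4 interior walls carries exactly one directed edge
      expect_identical(sum(!self), 4L)
      walls <- apply(cbind(pmin(stg$edges$from[!self], stg$edges$to[!self]),
                           pmax(stg$edges$from[!self], stg$edges$to[!self])),
                     1, paste, collapse = "-")
      expect_false(anyDuplicated(walls) > 0)
      ## no stuck domains: self-edge or at least one outgoing edge
      out_deg <- tabulate(stg$edges$from, nrow(stg$domains))
      expect_true(all(out_deg >= 1L))
    }
  }
})

test_that("morse graphs are acyclic with attractors at minimal nodes", {
  nf <- builtin_network("NF")
  stg <- build_stg(nf, ts_center_q())
  mg <- morse_graph(stg)
  ## frustrated loop: a single recurrent component, a 4-domain cycle
  expect_identical(nrow(mg$nodes), 1L)
  expect_identical(mg$nodes$annotation, "cycle")
  expect_identical(mg$nodes$size, 4L)
  expect_identical(mg$repertoire, "cycle")
  ts <- builtin_network("TS")
  mg2 <- morse_graph(build_stg(ts, ts_center_q()))
  expect_identical(mg2$repertoire, "01-10")
  expect_true(all(mg2$nodes$minimal))
  ## reachability order has no two-cycles (antisymmetry)
  if (nrow(mg2$edges))
    expect_false(any(paste(mg2$edges$from, mg2$edges$to) %in%
                     paste(mg2$edges$to, mg2$edges$from)))
})

test_that("per-sample Morse repertoires agree with the enumerated graph", {
  total <- 0L
  for (nm in c("TS", "DA", "NF")) {
    net <- builtin_network(nm)
    pg <- enumerate_parameter_graph(net)
    p <- sample_parameters(net, sampling_config(n_sets = 334, seed = 53))
    q <- to_switching(net, p)
    nd <- parameter_node(net, q)
    reps <- switching_repertoire(net, q)
    expect_identical(reps, pg$nodes$repertoire[nd + 1L])
    total <- total + nrow(q)
  }
  expect_gte(total, 1000L)
})

test_that("every predicted fixed point is realized by the switching flow", {
  ## independent check: fine-step Euler integration of the switching ODE
  ## from a grid of initial conditions reaches exactly the predicted FPs
  for (nm in c("TS", "DA")) {
    net <- builtin_network(nm)
    p <- sample_parameters(net, sampling_config(n_sets = 3, seed = 59))
    q <- to_switching(net, p)
    for (m in seq_len(3)) {
      qm <- q[m, , drop = FALSE]
      fps <- switching_fixed_points(net, qm)
      grid <- expand.grid(x = exp(seq(log(0.05), log(200), length.out = 7)),
                          y = exp(seq(log(0.05), log(200), length.out = 7)))
      gmin <- min(qm$gamma_A, qm$gamma_B)
      finals <- t(apply(grid, 1, function(x0)
        naive_switching_euler(net, qm, x0, dt = 0.01 / gmin,
                              t_end = 25 / gmin)))
      ## each final state is near a predicted FP, and each FP is hit
      dmat <- vapply(seq_along(fps$labels), function(j)
        apply(abs(finals - rep(fps$points[j, ], each = nrow(finals))) /
                pmax(abs(rep(fps$points[j, ], each = nrow(finals))), 1e-6),
              1, max),
        numeric(nrow(finals)))
      dmat <- matrix(dmat, nrow = nrow(finals))
      nearest <- apply(dmat, 1, which.min)
      expect_true(all(apply(dmat, 1, min) < 0.05))
      expect_setequal(unique(nearest), seq_along(fps$labels))
    }
  }
})
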