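test_that("event-driven trajectories follow the exact wall-to-wall flow", {
  ts <- builtin_network("TS")
  q <- ts_center_q()
  ## start in an invariant off-diagonal domain: immediate fixed point
  tr <- integrate_event_driven(ts, q, c(0.5, 2.5))
  expect_identical(tr$classification, "FP")
  expect_identical(tr$label, "01")
  expect_identical(tr$domains, "01")
  ## start high-high: both decay toward (L/gamma); the coordinate with the
  ## shorter crossing time exits first (symmetric box, x closer to wall)
  tr2 <- integrate_event_driven(ts, q, c(2.2, 3.5))
  expect_identical(tr2$classification, "FP")
  expect_identical(tr2$label, "01")   # y crosses later, x first -> FP(01)
  expect_identical(tr2$domains[1], "11")
  ## times strictly increase and consecutive domains are wall-adjacent
  expect_true(all(diff(tr2$times) > 0))
  d <- do.call(rbind, lapply(strsplit(tr2$domains, ""), as.integer))
  if (nrow(d) > 1)
    expect_true(all(rowSums(abs(diff(d))) == 1L))
})

test_that("event-driven cycles reproduce the STG recurrent component", {
  nf <- builtin_network("NF")
  q <- ts_center_q()
  tr <- integrate_event_driven(nf, q, c(0.5, 0.7))
  expect_identical(tr$classification, "cycle")
  mg <- morse_graph(build_stg(nf, q))
  stg <- build_stg(nf, q)
  rec <- stg$labels[mg$membership == mg$nodes$component[1]]
  expect_setequal(unique(tr$cycle_domains), rec)
  expect_length(unique(tr$cycle_domains), 4L)
})

test_that("the analytic separatrix matches the crossing-time geometry", {
  ts <- builtin_network("TS")
  q <- ts_center_q()   # fully symmetric: the diagonal separates the basins
  expect_identical(ts_separatrix_side(ts, q, c(2.6, 2.4)), "10")
  expect_identical(ts_separatrix_side(ts, q, c(2.4, 2.6)), "01")
  expect_identical(ts_separatrix_side(ts, q, c(1.2, 1.1)), "10")
  expect_identical(ts_separatrix_side(ts, q, c(2.7, 2.7)), "ambiguous")
  ## off-diagonal domains classified by containment
  expect_identical(ts_separatrix_side(ts, q, c(0.3, 3)), "01")
  q_mono <- q; q_mono$theta_B_A <- 0.2
  expect_error(ts_separatrix_side(ts, q_mono, c(1, 1)), "bistability")
  da <- builtin_network("DA")
  expect_identical(da_separatrix_side(da, q, c(1, 1)), "00")
  expect_identical(da_separatrix_side(da, q, c(2.5, 2.5)), "11")
  ## domain II: x rises on U (crosses at ln 1.95), y decays on L (ln 1.9):
  ## y reaches its threshold first, into the low-low basin
  expect_identical(da_separatrix_side(da, q, c(1.05, 2.9)), "00")
  ## and with x closer to its wall the flow tips to high-high instead
  expect_identical(da_separatrix_side(da, q, c(1.5, 2.6)), "11")
})

test_that("separatrix assignment agrees with the event-driven oracle", {
  for (nm in c("TS", "DA")) {
    net <- builtin_network(nm)
    p <- sample_parameters(net, sampling_config(n_sets = 150, seed = 61))
    q <- to_switching(net, p)
    csets <- which(parameter_node(net, q) == 4)[1:25]
    side <- if (nm == "TS") ts_separatrix_side else da_separatrix_side
    for (m in csets) {
      qm <- q[m, , drop = FALSE]
      ic <- sample_initial_conditions(net, p[m, , drop = FALSE], 40,
                                      seed = m)
      lab_an <- side(net, qm, ic)
      lab_ev <- vapply(seq_len(nrow(ic)), function(r)
        integrate_event_driven(net, qm, ic[r, ])$label, character(1))
      keep <- lab_an != "ambiguous"
      expect_identical(lab_an[keep], lab_ev[keep])
    }
  }
})

test_that("the analytic basins are invariant under the flow", {
  ts <- builtin_network("TS")
  p <- sample_parameters(ts, sampling_config(n_sets = 60, seed = 67))
  q <- to_switching(ts, p)
  m <- which(parameter_node(ts, q) == 4)[1]
  qm <- q[m, , drop = FALSE]
  ## points in the diagonal domains, re-classified after one wall crossing
  ic <- sample_initial_conditions(ts, p[m, , drop = FALSE], 200, seed = 3)
  lab0 <- ts_separatrix_side(ts, qm, ic)
  for (r in which(lab0 != "ambiguous")[1:50]) {
    tr <- integrate_event_driven(ts, qm, ic[r, ], max_transitions = 1L)
    if (tr$classification == "FP") {
      expect_identical(tr$label, lab0[r])
    } else {
      expect_identical(ts_separatrix_side(ts, qm, tr$state), lab0[r])
    }
  }
})

test_that("Euler switching integration approaches the exact assignment", {
  ts <- builtin_network("TS")
  p <- sample_parameters(ts, sampling_config(n_sets = 150, seed = 71))
  q <- to_switching(ts, p)
  csets <- which(parameter_node(ts, q) == 4)[1:15]
  agree <- function(dt_gamma) {
    hits <- n <- 0
    for (m in csets) {
      qm <- q[m, , drop = FALSE]
      ic <- sample_initial_conditions(ts, p[m, , drop = FALSE], 50, seed = m)
      lab_an <- ts_separatrix_side(ts, qm, ic)
      fin <- integrate_switching_euler(ts, qm, ic, dt_gamma = dt_gamma)
      lab_eu <- classify_switching_state(ts, qm, fin)
      keep <- lab_an != "ambiguous" & !is.na(lab_eu)
      hits <- hits + sum(lab_an[keep] == lab_eu[keep])
      n <- n + sum(keep)
    }
    hits / n
  }
  a_default <- agree(0.05)
  expect_gt(a_default, 0.9)     # the printed step-induced error is ~5%
  a_fine <- agree(0.0125)
  expect_gte(a_fine, a_default - 0.005)  # refinement helps

  expect_gt(a_fine, 0.97)
})

test_that("basin strength is the product of converging fractions", {
  mono <- basin_report(rep("10", 40))
  expect_equal(mono$strength, 1)
  even <- basin_report(rep(c("01", "10"), each = 20))
  expect_equal(even$strength, 0.25)
  skew <- basin_report(c(rep("01", 36), rep("10", 4)))
  expect_equal(skew$strength, 0.9 * 0.1)
  ## unclassified initial conditions dilute the fractions
  part <- basin_report(c(rep("01", 30), rep(NA, 10)))
  expect_equal(part$strength, 0.75)
  expect_identical(part$n_unclassified, 10L)
  expect_error(basin_report(character(0)), "no classified")
})
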