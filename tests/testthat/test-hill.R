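test_that("shifted Hill function satisfies its defining identities", {
  expect_equal(shifted_hill(0, T = 3, n = 4, lambda = 0.2), 1)
  expect_equal(shifted_hill(3, T = 3, n = 7, lambda = 0.2), (1 + 0.2) / 2)
  expect_equal(shifted_hill(1e8, T = 3, n = 4, lambda = 0.2), 0.2,
               tolerance = 1e-6)
  ## activation effect H/a spans (1/a, 1)
  a <- 5
  eff <- shifted_hill(c(0, 1e8), T = 2, n = 3, lambda = a) / a
  expect_equal(eff, c(1 / a, 1), tolerance = 1e-6)
})

test_that("rhs and residual have their closed forms on a free node", {
  solo <- solo_network()
  p <- solo_params(P = 10, gamma = 0.5)
  xstar <- 10 / 0.5
  expect_equal(as.numeric(hill_rhs(solo, p, xstar)), 0)
  expect_equal(verify_steady_state(solo, p, xstar), 0)
  ## linear decay: residual of a delta-perturbed state is gamma * delta
  expect_equal(verify_steady_state(solo, p, xstar + 0.3), 0.5 * 0.3)
  expect_error(hill_rhs(solo, p, -1), "negative")
  ## ensemble on the free node finds the unique verified state P/gamma
  ens <- simulate_hill_ensemble(solo, p, n_init = 20, seed = 1)
  expect_identical(nrow(ens$states), 1L)
  expect_true(ens$states$verified)
  expect_equal(ens$states$A, xstar, tolerance = 1e-3)
})

test_that("ensemble weights sum to one per parameter set", {
  fix <- sampled_ts(n_sets = 40, seed = 31)
  ens <- simulate_hill_ensemble(fix$net, fix$params, n_init = 40, seed = 32)
  w <- tapply(ens$states$weight, ens$states$set, sum)
  expect_equal(as.numeric(w), rep(1, length(w)), tolerance = 1e-9)
  expect_true(all(ens$states$residual[ens$states$verified] < 1e-4))
})

test_that("halving the Euler step leaves verified states within merge tolerance", {
  fix <- sampled_ts(n_sets = 5, seed = 33)
  ic <- lapply(seq_len(5), function(m)
    sample_initial_conditions(fix$net, fix$params[m, ], 20, seed = m))
  e1 <- simulate_hill_ensemble(fix$net, fix$params, n_init = 20, ics = ic)
  e2 <- simulate_hill_ensemble(fix$net, fix$params, n_init = 20, ics = ic,
                               settings = hill_settings(dt_gamma = 0.025))
  expect_identical(nrow(e1$states), nrow(e2$states))
  for (m in seq_len(5)) {
    s1 <- as.matrix(e1$states[e1$states$set == m, c("A", "B")])
    s2 <- as.matrix(e2$states[e2$states$set == m, c("A", "B")])
    s1 <- s1[order(s1[, 1]), , drop = FALSE]
    s2 <- s2[order(s2[, 1]), , drop = FALSE]
    expect_lt(max(abs(s1 - s2) / pmax(abs(s1), 1e-8)), 1e-2)
  }
})

test_that("weighted z-scores standardize exactly and binarize symmetrically", {
  ts <- builtin_network("TS")
  ## two states mirrored about the mean get mirrored labels
  st <- data.frame(set = c(1L, 1L), A = c(10, 1), B = c(1, 10),
                   weight = c(0.5, 0.5))
  reps <- discretize_states(st, ts, n_sets = 1)
  expect_identical(sort(attr(reps, "state_labels")), c("01", "10"))
  expect_identical(reps$repertoire, "01-10")
  expect_identical(reps$class, "bistable")
  ## standardization identity on a sampled ensemble
  fix <- sampled_ts(n_sets = 60, seed = 35)
  ens <- simulate_hill_ensemble(fix$net, fix$params, n_init = 30, seed = 36)
  reps2 <- discretize_ensemble(ens)
  stats <- attr(reps2, "node_stats")
  ver <- ens$states[ens$states$verified, ]
  for (j in c("A", "B")) {
    z <- (log2(ver[[j]]) - stats$mean[stats$node == j]) /
      stats$sd[stats$node == j]
    expect_equal(sum(ver$weight * z) / sum(ver$weight), 0, tolerance = 1e-9)
    expect_equal(sum(ver$weight * z^2) / sum(ver$weight), 1, tolerance = 1e-9)
  }
})

test_that("toggle switch ensembles are dominated by one-high-one-low monostability", {
  fix <- sampled_ts(n_sets = 300, seed = 37)
  ens <- simulate_hill_ensemble(fix$net, fix$params, n_init = 50, seed = 38)
  reps <- discretize_ensemble(ens)
  cls <- table(reps$class)
  expect_identical(names(which.max(cls)), "monostable")
  mono <- reps$repertoire[reps$class == "monostable"]
  expect_gt(mean(mono %in% c("10", "01")), mean(mono %in% c("00", "11")))
})

test_that("steep central toggle-switch sets recover the switching bistability", {
  fix <- sampled_ts(n_sets = 300, seed = 39, hill = c(1, 10))
  nd <- parameter_node(fix$net, fix$q)
  sel <- which(nd == 4 & fix$params$n_B_A > 6 & fix$params$n_A_B > 6)[1:12]
  ens <- simulate_hill_ensemble(fix$net, fix$params[sel, ], n_init = 100,
                                seed = 40)
  reps <- discretize_ensemble(ens)
  ## cross-check against the switching prediction for the same sets
  expect_identical(switching_repertoire(fix$net, fix$q[sel, ]),
                   rep("01-10", length(sel)))
  expect_gt(mean(reps$n_attractors == 2), 0.7)
})

test_that("negative-feedback central sets at steep Hill are flagged cyclic", {
  nf <- builtin_network("NF")
  p <- sample_parameters(nf, sampling_config(n_sets = 120, seed = 41,
                                             hill = c(10, 50)))
  q <- to_switching(nf, p)
  sel <- which(parameter_node(nf, q) == 4)[1:25]
  ens <- simulate_hill_ensemble(nf, p[sel, ], n_init = 60, seed = 42)
  expect_gt(mean(ens$cyclic), 0.5)
  ## cyclic sets have many distinct states, none passing verification
  n_states <- tabulate(ens$states$set, length(sel))
  expect_true(all(n_states[ens$cyclic] >= 10L))
  if (sum(ens$states$verified) >= 2L) {
    reps <- discretize_ensemble(ens)
    expect_true(all(reps$repertoire[ens$cyclic] == "cyclic"))
    expect_true(all(reps$class[ens$cyclic] == "cyclic"))
  }
})
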