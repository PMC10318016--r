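## Symmetric bistable toggle-switch switching parameters (central node):
## gamma = 1, L = 1, U = 3, theta = 2 on both nodes.
ts_center_q <- function(gx = 1, gy = 1, Lxy = 1, Uxy = 3, thxy = 2,
                        Lyx = 1, Uyx = 3, thyx = 2) {
  data.frame(gamma_A = gx, gamma_B = gy,
             L_B_A = Lyx, U_B_A = Uyx, theta_B_A = thyx,
             L_A_B = Lxy, U_A_B = Uxy, theta_A_B = thxy)
}

## Same box for the other two-node motifs (edge names identical).
two_node_q <- ts_center_q

## Single node, no regulation: dx/dt = P - gamma x.
solo_network <- function() {
  grn_network(data.frame(source = character(0), target = character(0),
                         sign = character(0)), nodes = "A")
}

solo_params <- function(P = 10, gamma = 0.5) {
  data.frame(P_A = P, gamma_A = gamma)
}

## A small sampled TS ensemble shared by several expensive tests.
sampled_ts <- function(n_sets = 200, seed = 1, hill = c(1, 6)) {
  net <- builtin_network("TS")
  params <- sample_parameters(net, sampling_config(n_sets = n_sets,
                                                   seed = seed, hill = hill))
  list(net = net, params = params, q = to_switching(net, params))
}

## Independent fine-step Euler integrator for switching systems, written
## directly from the step-function definition; used as an oracle.
naive_switching_euler <- function(network, q, x0, dt = 0.002, t_end = 60) {
  nodes <- network$nodes
  x <- as.numeric(x0)
  gam <- vapply(nodes, function(v) q[[paste0("gamma_", v)]], numeric(1))
  for (s in seq_len(ceiling(t_end / dt))) {
    lam <- rep(1, length(nodes))
    for (e in seq_len(nrow(network$edges))) {
      src <- match(network$edges$source[e], nodes)
      tgt <- match(network$edges$target[e], nodes)
      th <- q[[paste0("theta_", network$edges$target[e], "_",
                      network$edges$source[e])]]
      L <- q[[paste0("L_", network$edges$target[e], "_",
                     network$edges$source[e])]]
      U <- q[[paste0("U_", network$edges$target[e], "_",
                     network$edges$source[e])]]
      on_high <- if (network$edges$sign[e] == "activation") x[src] > th
                 else x[src] < th
      lam[tgt] <- lam[tgt] * if (on_high) U else L
    }
    x <- x + dt * (lam - gam * x)
  }
  x
}
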