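#' Frequency distribution of attractor repertoires
#'
#' @param labels character vector of canonical repertoire labels (`NA`
#'   entries — unresolved parameter sets — are dropped).
#' @return Named numeric vector of frequencies summing to 1.
#' @export
repertoire_distribution <- function(labels) {
  if (inherits(labels, "hill_repertoires")) labels <- labels$repertoire
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labelled parameter sets")
  tab <- table(labels)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Jensen-Shannon divergence between two repertoire distributions
#'
#' Symmetric, zero iff the distributions coincide, and bounded by 1 in
#' the default base 2 (by `log(2)` in nats).  Distributions are aligned
#' on the union of their labels, absent labels counting as frequency 0.
#'
#' @param p,q named numeric frequency vectors (renormalized internally).
#' @param base logarithm base; 2 gives bits.
#' @return Scalar divergence.
#' @examples
#' jsd(c(a = 1), c(b = 1))  # disjoint support: 1 bit
#' @export
jsd <- function(p, q, base = 2) {
  labs <- union(names(p), names(q))
  pp <- stats::setNames(numeric(length(labs)), labs)
  qq <- pp
  pp[names(p)] <- p; qq[names(q)] <- q
  pp <- pp / sum(pp); qq <- qq / sum(qq)
  m <- (pp + qq) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (kl(pp) / 2 + kl(qq) / 2) / log(base)
}

#' Map binarized Hill labels to switching-level labels
#'
#' Hill-model attractors are binarized to digits 0/1 per node, while
#' switching-system fixed points are labelled by discrete levels
#' `0..|T(i)|` (the number of thresholds of node *i*).  The comparison
#' needs both on the same alphabet: digit 1 is mapped to the node's
#' maximum level and digit 0 stays 0, so for one-threshold networks
#' (Toggle Switch) the map is the identity, while for the Toggle Triad
#' (two thresholds per node) `"100"` becomes `"200"`.
#'
#' @param labels character vector of canonical repertoire strings (labels
#'   joined by `"-"`); `"cyclic"` and `NA` pass through.
#' @param network a [grn_network()].
#' @return Character vector of mapped canonical repertoires.
#' @export
repertoire_label_map <- function(labels, network) {
  lev <- n_outputs(network)
  map1 <- function(lab) {
    d <- strsplit(lab, "")[[1]]
    paste(ifelse(d == "1", as.character(lev), "0"), collapse = "")
  }
  vapply(labels, function(s) {
    if (is.na(s) || s == "cyclic") return(s)
    canonical_repertoire(vapply(strsplit(s, "-")[[1]], map1, character(1)))
  }, character(1), USE.NAMES = FALSE)
}

## repertoire labels out of a hill_repertoires object or plain vector
.rep_labels <- function(x) {
  if (inherits(x, "hill_repertoires")) x$repertoire else x
}

## align a named frequency vector onto a label universe
.align <- function(f, labs) {
  v <- stats::setNames(numeric(length(labs)), labs)
  v[names(f)] <- f
  v
}

#' Node-wise comparison of Hill repertoires with switching predictions
#'
#' Stratifies the simulated ensemble by DSGRN parameter node and compares
#' each stratum's Hill-model repertoire distribution with the switching
#' prediction for that node: the maximum absolute frequency discrepancy
#' and the Jensen-Shannon divergence per node.
#'
#' The reference may be given two ways.  Passing the discretized
#' switching ensemble (from [switching_state_table()] +
#' [discretize_states()]) compares the two formalisms through the
#' identical z-score binarization — the like-for-like comparison.
#' Passing an [enumerate_parameter_graph()] instead compares against each
#' node's threshold-coordinate repertoire (a point mass), with the Hill
#' labels lifted to switching levels via [repertoire_label_map()].
#'
#' @param network a [grn_network()] with an enumerable parameter graph.
#' @param repertoires a [discretize_ensemble()] result (or its
#'   `repertoire` column).
#' @param node_index 0-based parameter node per set, from
#'   [parameter_node()].
#' @param reference a `hill_repertoires` object for the switching
#'   ensemble, or a `parameter_graph`.
#' @return Object of class `nodewise_comparison`: `summary` data frame
#'   (node, sets, predicted modal reference label, modal Hill label,
#'   max_abs_diff, jsd), `distributions` per node, and `worst`, the
#'   largest max_abs_diff over occupied nodes.
#' @export
nodewise_comparison <- function(network, repertoires, node_index,
                                reference) {
  use_pg <- inherits(reference, "parameter_graph")
  labels <- .rep_labels(repertoires)
  if (use_pg) labels <- repertoire_label_map(labels, network)
  ref_labels <- if (use_pg) NULL else .rep_labels(reference)
  stopifnot(length(labels) == length(node_index))
  occupied <- sort(unique(node_index))
  dists <- list()
  rows <- lapply(occupied, function(nd) {
    lab <- labels[node_index == nd]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NULL)
    f <- repertoire_distribution(lab)
    ref <- if (use_pg) {
      stats::setNames(1, reference$nodes$repertoire[reference$nodes$index == nd])
    } else {
      rl <- ref_labels[node_index == nd]
      rl <- rl[!is.na(rl)]
      if (!length(rl)) return(NULL)
      repertoire_distribution(rl)
    }
    all_lab <- union(names(f), names(ref))
    fv <- .align(f, all_lab)
    pv <- .align(ref, all_lab)
    dists[[as.character(nd)]] <<- rbind(hill = fv, switching = pv)
    data.frame(node = nd, n_sets = length(lab),
               predicted = names(ref)[which.max(ref)],
               modal = names(f)[which.max(f)],
               max_abs_diff = max(abs(fv - pv)),
               jsd = jsd(fv, pv))
  })
  summary <- do.call(rbind, rows)
  structure(list(summary = summary, distributions = dists,
                 worst = max(summary$max_abs_diff)),
            class = "nodewise_comparison")
}

#' @export
print.nodewise_comparison <- function(x, ...) {
  cat("Node-wise Hill vs switching comparison\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("worst max|freq diff|:", format(x$worst, digits = 3), "\n")
  invisible(x)
}

#' Ensemble-level comparison and sampling-bias normalization
#'
#' Compares the pooled Hill-model repertoire distribution with the
#' DSGRN-uniform prediction (each parameter node weighted equally), shows
#' the occupancy histogram of parameter nodes under the sampling scheme,
#' and recomputes the ensemble distribution normalized for sampling bias:
#' every occupied parameter node contributes its own repertoire
#' distribution with equal weight, removing the over-representation of
#' heavily sampled nodes.
#'
#' @inheritParams nodewise_comparison
#' @return Object of class `ensemble_comparison` with `raw`, `normalized`
#'   and `dsgrn` distributions, `occupancy`, and the JSDs of raw and
#'   normalized distributions against the DSGRN-uniform one.
#' @export
ensemble_comparison <- function(network, repertoires, node_index,
                                reference) {
  use_pg <- inherits(reference, "parameter_graph")
  labels <- .rep_labels(repertoires)
  if (use_pg) labels <- repertoire_label_map(labels, network)
  raw <- repertoire_distribution(labels)
  occupied <- sort(unique(node_index))
  node_dist <- function(labs) {
    per <- lapply(occupied, function(nd) {
      l <- labs[node_index == nd]
      l <- l[!is.na(l)]
      if (length(l)) repertoire_distribution(l) else NULL
    })
    per <- Filter(Negate(is.null), per)
    all_lab <- sort(unique(unlist(lapply(per, names))))
    out <- stats::setNames(numeric(length(all_lab)), all_lab)
    for (d in per) out[names(d)] <- out[names(d)] + d / length(per)
    out
  }
  ## DSGRN-uniform reference: every parameter node weighted equally
  dsgrn <- if (use_pg) repertoire_distribution(reference$nodes$repertoire)
           else node_dist(.rep_labels(reference))
  occupancy <- stats::setNames(
    as.numeric(table(factor(node_index, occupied)) / length(node_index)),
    occupied)
  norm <- node_dist(labels)
  structure(list(raw = raw, normalized = norm, dsgrn = dsgrn,
                 occupancy = occupancy,
                 jsd_raw = jsd(raw, dsgrn),
                 jsd_normalized = jsd(norm, dsgrn)),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("Ensemble repertoire distributions (Hill | DSGRN-uniform)\n")
  labs <- union(names(x$raw), names(x$dsgrn))
  for (l in labs)
    cat(sprintf("  %-12s %6.3f | %6.3f\n", l,
                if (l %in% names(x$raw)) x$raw[[l]] else 0,
                if (l %in% names(x$dsgrn)) x$dsgrn[[l]] else 0))
  cat("JSD raw:", format(x$jsd_raw, digits = 3),
      " JSD normalized:", format(x$jsd_normalized, digits = 3), "\n")
  invisible(x)
}

#' PCA of monostable vs bistable parameter sets
#'
#' Principal component analysis of the raw (covariance, unscaled)
#' parameter matrix, run separately on the monostable and the bistable
#' parameter sets.  Unscaled PCA is deliberate: it lets the
#' large-variance parameters (production rates, thresholds) dominate the
#' leading loadings; set `scale. = TRUE` for the correlation-based
#' variant.
#'
#' @param params a `racipe_params` table.
#' @param classes character vector of stability classes per row (from
#'   [discretize_ensemble()]'s `class` column).
#' @param compare classes to analyse.
#' @param n_components number of leading components summarized.
#' @param scale. standardize columns first?
#' @param min_n minimum class size.
#' @return Object of class `pca_delineation`: per class the
#'   `stats::prcomp` fit, cumulative explained variance and leading
#'   loadings; `min_cumvar` is the smaller cumulative explained-variance
#'   fraction at `n_components`.
#' @export
pca_delineation <- function(params, classes,
                            compare = c("monostable", "bistable"),
                            n_components = 4L, scale. = FALSE,
                            min_n = 10L) {
  stopifnot(nrow(params) == length(classes))
  out <- list()
  for (cl in compare) {
    sub <- as.matrix(params[classes == cl, , drop = FALSE])
    if (nrow(sub) < min_n)
      stop("class '", cl, "' has fewer than ", min_n, " parameter sets")
    fit <- stats::prcomp(sub, center = TRUE, scale. = scale.)
    expl <- cumsum(fit$sdev^2) / sum(fit$sdev^2)
    k <- min(n_components, length(expl))
    out[[cl]] <- list(fit = fit, cum_explained = expl,
                      loadings = fit$rotation[, seq_len(k), drop = FALSE],
                      n = nrow(sub))
  }
  structure(list(classes = out,
                 n_components = n_components,
                 min_cumvar = min(vapply(out, function(z)
                   z$cum_explained[min(n_components,
                                       length(z$cum_explained))],
                   numeric(1)))),
            class = "pca_delineation")
}

#' @export
print.pca_delineation <- function(x, ...) {
  for (cl in names(x$classes)) {
    z <- x$classes[[cl]]
    cat(cl, " (n = ", z$n, "): cumulative variance PC1-",
        x$n_components, " = ",
        sprintf("%.1f%%", 100 * z$cum_explained[min(x$n_components,
                                                    length(z$cum_explained))]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Run the full Hill vs switching comparison pipeline
#'
#' End-to-end orchestration: sample a parameter ensemble, translate it to
#' switching parameters, assign parameter nodes (for networks with an
#' enumerable parameter graph) or compute per-sample Morse-graph
#' predictions, simulate the Hill ensemble, discretize, and assemble the
#' node-wise and ensemble-level comparison reports together with the
#' pooled Jensen-Shannon divergence between the Hill and switching
#' repertoire distributions.
#'
#' @param network a [grn_network()].
#' @param config a [sampling_config()].
#' @param settings a [hill_settings()].
#' @return Object of class `grn_comparison`: the ensemble, repertoires,
#'   translated parameters, node assignments (`NA` for networks without
#'   an enumerated graph), switching predictions, comparison reports and
#'   `jsd_pooled`.
#' @examples
#' \donttest{
#' cmp <- run_comparison(builtin_network("TS"),
#'                       sampling_config(n_sets = 200, n_init = 30, seed = 1))
#' cmp$nodewise
#' }
#' @export
run_comparison <- function(network, config = sampling_config(),
                           settings = hill_settings()) {
  params <- sample_parameters(network, config)
  q <- to_switching(network, params)
  single <- all(n_inputs(network) == 1L) && all(n_outputs(network) == 1L)
  pg <- if (single) enumerate_parameter_graph(network) else NULL
  node_index <- if (single) parameter_node(network, q)
                else rep(NA_integer_, nrow(q))
  sw <- switching_state_table(network, q)
  sw_reps <- discretize_states(sw$states, network, n_sets = nrow(q),
                               cyclic = sw$cyclic)
  ens <- simulate_hill_ensemble(network, params, n_init = config$n_init,
                                settings = settings)
  reps <- discretize_ensemble(ens)
  pooled <- jsd(repertoire_distribution(reps),
                repertoire_distribution(sw_reps))
  structure(list(network = network, params = params, switching = q,
                 node_index = node_index, switching_reps = sw_reps,
                 ensemble = ens, repertoires = reps,
                 nodewise = if (single)
                   nodewise_comparison(network, reps, node_index, sw_reps),
                 ensemble_cmp = if (single)
                   ensemble_comparison(network, reps, node_index, sw_reps),
                 pg = pg, jsd_pooled = pooled),
            class = "grn_comparison")
}

#' @export
print.grn_comparison <- function(x, ...) {
  cat("Hill vs switching comparison,", x$ensemble$n_sets,
      "parameter sets\n")
  cat("pooled JSD (Hill vs switching prediction):",
      format(x$jsd_pooled, digits = 3), "\n")
  if (!is.null(x$nodewise)) print(x$nodewise)
  invisible(x)
}

#' Jensen-Shannon divergence across Hill-coefficient ranges
#'
#' Repeats [run_comparison()] with Hill coefficients drawn from each of
#' the given ranges, holding every other draw fixed (same seed), and
#' returns the pooled Hill-vs-switching JSD per range.  As the range
#' climbs, the Hill model approaches its switching limit and the
#' divergence shrinks.
#'
#' @param network a [grn_network()].
#' @param config base [sampling_config()]; its `hill` entry is replaced
#'   by each range in turn.
#' @param hill_ranges list of length-2 ranges.
#' @param settings a [hill_settings()].
#' @return Data frame with the range bounds and the pooled JSD.
#' @export
jsd_hill_sweep <- function(network, config = sampling_config(),
                           hill_ranges = list(c(1, 10), c(10, 50),
                                              c(50, 100)),
                           settings = hill_settings()) {
  rows <- lapply(hill_ranges, function(r) {
    cfg <- config
    cfg$hill <- r
    cmp <- run_comparison(network, cfg, settings)
    data.frame(hill_min = r[1], hill_max = r[2], jsd = cmp$jsd_pooled)
  })
  do.call(rbind, rows)
}
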