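#' Construct a regulatory network
#'
#' A regulatory network is a signed directed graph: nodes are genes (or
#' transcription factors) and each edge is an activation or a repression of
#' the target's production by the source.  All simulation and
#' parameter-space machinery in this package consumes this object.
#'
#' Node order is significant: state vectors, parameter columns and discrete
#' attractor labels all follow it.  By default nodes are ordered by first
#' appearance in `edges` (source before target, row by row), matching the
#' order induced by reading a `.topo` file.
#'
#' Self-loops and duplicated (source, target) pairs are rejected: none of
#' the motifs this machinery targets contain them, and silently accepting
#' them would corrupt the domain bookkeeping of the switching formalism.
#'
#' @param edges data frame with columns `source`, `target`, `sign`; `sign`
#'   entries must be `"activation"` or `"repression"`.
#' @param nodes optional character vector fixing the node order; must
#'   contain every edge endpoint exactly once.
#' @return An object of class `grn_network` with elements `nodes`
#'   (character) and `edges` (data frame).
#' @examples
#' ts <- grn_network(data.frame(
#'   source = c("A", "B"), target = c("B", "A"),
#'   sign = "repression"))
#' ts
#' @seealso [builtin_network()], [read_topo()]
#' @export
grn_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges)))
    stop("`edges` must have columns source, target, sign")
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign   = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L && is.null(nodes))
    stop("no edges (declare `nodes` explicitly for an edgeless network)")
  bad <- !edges$sign %in% c("activation", "repression")
  if (any(bad))
    stop("unknown sign value(s): ", paste(unique(edges$sign[bad]), collapse = ", "))
  if (any(edges$source == edges$target))
    stop("self-loops are not supported")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge(s): ",
         paste(unique(sub("\r", " -> ", key[duplicated(key)])), collapse = ", "))
  appear <- unique(c(rbind(edges$source, edges$target)))
  if (is.null(nodes)) {
    nodes <- appear
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node names")
    if (!all(appear %in% nodes))
      stop("`nodes` must contain every edge endpoint")
  }
  structure(list(nodes = nodes, edges = edges), class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Regulatory network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  arrow <- ifelse(x$edges$sign == "activation", "->", "-|")
  cat(paste0("  ", x$edges$source, " ", arrow, " ", x$edges$target),
      sep = "\n")
  invisible(x)
}

#' Number of inputs and outputs per node
#'
#' @param network a [grn_network()].
#' @return Named integer vector in node order.
#' @export
n_inputs <- function(network) {
  vapply(network$nodes, function(v) sum(network$edges$target == v),
         integer(1))
}

#' @rdname n_inputs
#' @export
n_outputs <- function(network) {
  vapply(network$nodes, function(v) sum(network$edges$source == v),
         integer(1))
}

## sign tokens accepted in .topo files (RACIPE numeric codes and words)
.topo_sign <- function(tok) {
  tok <- tolower(tok)
  if (tok %in% c("1", "activate", "activates", "activation", "act")) return("activation")
  if (tok %in% c("2", "inhibit", "inhibits", "inhibition", "inh",
                 "repress", "represses", "repression")) return("repression")
  NA_character_
}

#' Read and write networks in the `.topo` edge-list format
#'
#' The `.topo` dialect is one edge per line, whitespace-separated columns
#' `Source Target Type`.  A single header line `Source Target Type` is
#' auto-detected and skipped.  The type token may be numeric (1 =
#' activation, 2 = inhibition, the RACIPE convention) or a word
#' (`activate`/`inhibit`); [write_topo()] always emits the numeric codes,
#' so a write/read round trip reproduces the edge set exactly.
#'
#' @param path file path.
#' @return [read_topo()] returns a [grn_network()]; [write_topo()] returns
#'   `path` invisibly.
#' @examples
#' read_topo(system.file("extdata", "TT.topo", package = "hillswitch"))
#' f <- tempfile(fileext = ".topo")
#' write_topo(builtin_network("TS"), f)
#' read_topo(f)
#' @export
read_topo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no edges in '", path, "'")
  first <- tolower(strsplit(trimws(lines[keep[1]]), "\\s+")[[1]])
  if (identical(first, c("source", "target", "type")))
    keep <- keep[-1]
  if (length(keep) == 0L) stop("no edges in '", path, "'")
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 3L)
      stop("malformed line ", i, " in '", path, "': expected 3 columns, got ",
           length(tok))
    sgn <- .topo_sign(tok[3])
    if (is.na(sgn))
      stop("malformed line ", i, " in '", path, "': unknown sign token '",
           tok[3], "'")
    data.frame(source = tok[1], target = tok[2], sign = sgn,
               stringsAsFactors = FALSE)
  })
  grn_network(do.call(rbind, rows))
}

#' @param network a [grn_network()].
#' @rdname read_topo
#' @export
write_topo <- function(network, path) {
  stopifnot(inherits(network, "grn_network"))
  code <- ifelse(network$edges$sign == "activation", 1L, 2L)
  writeLines(c("Source Target Type",
               paste(network$edges$source, network$edges$target, code)),
             path)
  invisible(path)
}

#' Built-in motif networks
#'
#' The two-, three- and four-node motifs used throughout:
#' \describe{
#'   \item{`TS`}{Toggle Switch — two nodes, mutual repression.}
#'   \item{`DA`}{Double Activation — two nodes, mutual activation.}
#'   \item{`NF`}{Negative Feedback loop — A activates B, B represses A.}
#'   \item{`TT`}{Toggle Triad — all six pairwise repressions among three
#'     nodes (a coupling of three toggle switches).}
#'   \item{`toggle_square`}{cyclic chain of four mutual-repression pairs
#'     (four nodes, eight edges).}
#' }
#'
#' @param name one of `"TS"`, `"DA"`, `"NF"`, `"TT"`, `"toggle_square"`.
#' @return A [grn_network()].
#' @examples
#' builtin_network("NF")
#' @export
builtin_network <- function(name) {
  pair <- function(a, b, sa, sb)
    data.frame(source = c(a, b), target = c(b, a), sign = c(sa, sb),
               stringsAsFactors = FALSE)
  switch(name,
    TS = grn_network(pair("A", "B", "repression", "repression")),
    DA = grn_network(pair("A", "B", "activation", "activation")),
    NF = grn_network(pair("A", "B", "activation", "repression")),
    TT = grn_network(data.frame(
      source = c("A", "B", "B", "C", "C", "A"),
      target = c("B", "A", "C", "B", "A", "C"),
      sign = "repression", stringsAsFactors = FALSE)),
    toggle_square = grn_network(data.frame(
      source = c("A", "B", "B", "C", "C", "D", "D", "A"),
      target = c("B", "A", "C", "B", "D", "C", "A", "D"),
      sign = "repression", stringsAsFactors = FALSE)),
    stop("unknown network '", name,
         "'; valid names: TS, DA, NF, TT, toggle_square")
  )
}
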