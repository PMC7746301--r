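#' Node order used throughout the package
#'
#' All matrices and state vectors use the fixed order
#' AMPK (a), PFK3 (k), APC-Cdh1 (c), OXPHOS (m), PPP (p), GLUTAMATE (g),
#' so printed tables line up across functions.
#'
#' @format Character vector of the six short node ids.
#' @export
node_order <- c("a", "k", "c", "m", "p", "g")

#' Display names for the six functional agents
#' @format Named character vector mapping short id to display name.
#' @export
node_display <- c(
  a = "AMPK", k = "PFK3", c = "APC^Cdh1",
  m = "OXPHOS", p = "PPP", g = "GLUTAMATE"
)

#' Construct a signed interaction network
#'
#' A signed directed graph over a set of functional agents, together with one
#' exogenous input node whose edges carry their own signs.  This is the purely
#' qualitative layer of the model: it knows who activates or inhibits whom,
#' but nothing about response-function shapes or parameters.
#'
#' @param nodes character vector of unique node ids, in the order used for all
#'   matrices and state vectors.
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1) and
#'   `label` (unique edge label, e.g. `"f1"`, `"h5"`).
#' @param input_node id of the exogenous driver (not a member of `nodes`).
#' @param input_edges data.frame with columns `target`, `sign`, `label` for
#'   edges from the input node into the network.
#' @param display optional named character vector of display names.
#'
#' @return An object of class `signed_network`.
#' @seealso [als_network()] for the built-in ALS instance.
#' @export
signed_network <- function(nodes, edges, input_node = "u",
                           input_edges = data.frame(target = character(),
                                                    sign = integer(),
                                                    label = character()),
                           display = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1)
  if (anyDuplicated(nodes)) stop("node ids must be unique")
  if (input_node %in% nodes) stop("input node must not be an internal node")
  edges <- as.data.frame(edges)
  req <- c("from", "to", "sign", "label")
  if (!all(req %in% names(edges))) {
    stop("edges needs columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) stop("edge references unknown node(s): ",
                        paste(unique(bad), collapse = ", "))
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  if (anyDuplicated(edges[, c("from", "to")])) {
    stop("duplicate (from, to) edge")
  }
  if (anyDuplicated(c(edges$label, input_edges$label))) {
    stop("edge labels must be unique")
  }
  input_edges <- as.data.frame(input_edges)
  if (nrow(input_edges)) {
    if (!all(c("target", "sign", "label") %in% names(input_edges))) {
      stop("input_edges needs columns: target, sign, label")
    }
    bad <- setdiff(input_edges$target, nodes)
    if (length(bad)) stop("input edge targets unknown node(s): ",
                          paste(bad, collapse = ", "))
    if (!all(input_edges$sign %in% c(-1L, 1L))) {
      stop("input edge signs must be +1 or -1")
    }
  }
  if (is.null(display)) {
    display <- stats::setNames(nodes, nodes)
  }
  structure(
    list(nodes = nodes, edges = edges, input_node = input_node,
         input_edges = input_edges, display = display),
    class = "signed_network"
  )
}

#' The built-in ALS loop network
#'
#' Six agents -- AMPK (a), PFK3 (k), APC-Cdh1 (c), OXPHOS (m), PPP (p),
#' GLUTAMATE (g) -- connected by nine signed edges forming three overlapping
#' positive feedback loops, plus the exogenous mutant-SOD1 input u acting
#' negatively on OXPHOS:
#'
#' \describe{
#'   \item{f1: a -> k (+)}{AMPK phosphorylates and activates PFK3.}
#'   \item{f2: p -> m (+)}{PPP-derived reducing power sustains OXPHOS.}
#'   \item{h1: g -> m (-)}{glutamate-driven calcium overload damages mitochondria.}
#'   \item{h2: g -> c (-)}{excitotoxic signalling inhibits APC-Cdh1.}
#'   \item{h3: p -> g (-)}{redox balance via PPP restrains glutamate build-up.}
#'   \item{h4: c -> k (-)}{APC-Cdh1 targets PFK3 for degradation.}
#'   \item{h5: k -> p (-)}{PFK3 shifts glucose from PPP to glycolysis.}
#'   \item{h6: m -> a (-)}{healthy OXPHOS keeps AMP low, hence AMPK off.}
#'   \item{h7: u -> m (-)}{misfolded mutant SOD1 impairs mitochondria.}
#' }
#'
#' @return A `signed_network`.
#' @export
als_network <- function() {
  edges <- data.frame(
    from  = c("a", "p", "g", "g", "p", "c", "k", "m"),
    to    = c("k", "m", "m", "c", "g", "k", "p", "a"),
    sign  = c(1L, 1L, -1L, -1L, -1L, -1L, -1L, -1L),
    label = c("f1", "f2", "h1", "h2", "h3", "h4", "h5", "h6"),
    stringsAsFactors = FALSE
  )
  input_edges <- data.frame(target = "m", sign = -1L, label = "h7",
                            stringsAsFactors = FALSE)
  signed_network(node_order, edges, input_node = "u",
                 input_edges = input_edges, display = node_display)
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "internal edges,",
      nrow(x$input_edges), "input edge(s)\n")
  cat("nodes:", paste(sprintf("%s (%s)", x$nodes, x$display[x$nodes]),
                      collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %-3s %s %s %s\n", e$label, e$from,
                if (e$sign > 0) "->(+)" else "->(-)", e$to))
  }
  for (i in seq_len(nrow(x$input_edges))) {
    e <- x$input_edges[i, ]
    cat(sprintf("  %-3s %s %s %s  [input]\n", e$label, x$input_node,
                if (e$sign > 0) "->(+)" else "->(-)", e$target))
  }
  invisible(x)
}

# remove one internal edge (by label) from a network
drop_edge <- function(network, label) {
  i <- which(network$edges$label == label)
  if (!length(i)) {
    stop("unknown edge label '", label, "'; valid labels: ",
         paste(network$edges$label, collapse = ", "))
  }
  network$edges <- network$edges[-i, , drop = FALSE]
  network
}
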