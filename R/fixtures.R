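#' The 10-node Krackhardt kite graph
#'
#' Standard 18-edge kite used as the worked example throughout the package.
#' Node labelling (0-based, stored as vertex names) is fixed so that the hub
#' node 3 has degree 6, node 8 degree 2, and the tail node 9 degree 1;
#' degrees of nodes 0..9 are 4, 4, 3, 6, 3, 5, 5, 3, 2, 1.
#'
#' @return an undirected \code{igraph} with 10 vertices named "0".."9".
#' @examples
#' g <- make_kite()
#' igraph::degree(g)
#' @export
make_kite <- function() {
  edges <- matrix(c(
    0, 1, 0, 2, 0, 3, 0, 5,
    1, 3, 1, 4, 1, 6,
    2, 3, 2, 5,
    3, 4, 3, 5, 3, 6,
    4, 6,
    5, 6, 5, 7,
    6, 7,
    7, 8,
    8, 9
  ), ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(edges + 1, directed = FALSE)
  igraph::V(g)$name <- as.character(0:9)
  g
}

#' Sample a connected Erdős–Rényi graph
#'
#' Draws \eqn{G(n, p)}; with \code{require_connected} the draw is rejected
#' and repeated until a connected sample appears (bounded retries).
#' Deterministic for a fixed seed.
#'
#' @param n number of nodes.
#' @param p edge probability in \code{[0, 1]}.
#' @param seed integer RNG seed.
#' @param require_connected reject disconnected samples?
#' @param max_tries retry budget for the rejection loop.
#' @return an undirected \code{igraph} with vertices named
#'   \code{"0".."n-1"}.
#' @export
make_er <- function(n, p, seed = 1, require_connected = TRUE,
                    max_tries = 1000) {
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    if (!require_connected || igraph::is_connected(g)) {
      igraph::V(g)$name <- as.character(0:(n - 1))
      return(g)
    }
  }
  stop(sprintf(
    "no connected G(%d, %g) sample found in %d tries; increase p or the retry budget",
    n, p, max_tries), call. = FALSE)
}

#' Read a graph from an edge list or GraphML file
#'
#' Edge lists are whitespace- or comma-separated two-column files of 0-based
#' integer node ids; GraphML is read via igraph.  The result is undirected
#' and simplified, with vertices named by their 0-based ids.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension: \code{.graphml} vs anything
#'   else), \code{"edgelist"} or \code{"graphml"}.
#' @return an undirected \code{igraph}.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1)
    }
    return(g)
  }
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) == 1) {  # comma-separated fallback
    tab <- utils::read.table(path, header = FALSE, sep = ",",
                             comment.char = "#", colClasses = "character")
  }
  if (ncol(tab) < 2) stop("edge list must have two columns", call. = FALSE)
  el <- cbind(as.integer(tab[[1]]), as.integer(tab[[2]]))
  if (anyNA(el)) stop("edge list entries must be integer node ids", call. = FALSE)
  n <- max(el) + 1L
  g <- igraph::graph_from_edgelist(el + 1L, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- as.character(0:(igraph::vcount(g) - 1))
  g
}
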