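#' Construct an indexed edge list
#'
#' The elementary carrier for a batch of undirected, weighted edges over a
#' dense 1-based vertex index space.  Edge lists feed [create_graph()] and
#' [add_version()]; label-level input is handled by [read_edge_list()] and
#' the builder, which translate labels to indices through a registry.
#'
#' @param from,to Integer vertex indices in `1:n_vertices`.  Each unordered
#'   pair may appear at most once; self-loops are permitted.
#' @param weight Numeric edge weights, recycled to the number of edges.
#'   Must be finite and non-negative.
#' @param n_vertices Upper bound of the vertex index space.  Vertices with
#'   no incident edges are legal (isolated) vertices.
#' @return An object of class `edge_list`: a list with integer vectors
#'   `from`, `to`, numeric `weight` and scalar `n_vertices`.
#' @examples
#' el <- edge_list(c(1, 1, 2), c(2, 3, 3), 1, n_vertices = 4)
#' n_edges(el)
#' @export
edge_list <- function(from = integer(), to = integer(), weight = 1,
                      n_vertices) {
  from <- as.integer(from)
  to <- as.integer(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same length", call. = FALSE)
  }
  weight <- rep_len(as.numeric(weight), length(from))
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 0L) {
    stop("`n_vertices` must be a single non-negative integer", call. = FALSE)
  }
  if (length(from)) {
    bad <- which(is.na(from) | is.na(to) | from < 1L | to < 1L |
                   from > n_vertices | to > n_vertices)
    if (length(bad)) {
      stop(sprintf("edge %d (%s, %s) is outside the vertex range 1..%d",
                   bad[1L], from[bad[1L]], to[bad[1L]], n_vertices),
           call. = FALSE)
    }
    if (any(!is.finite(weight))) {
      stop("edge weights must be finite", call. = FALSE)
    }
    key <- pair_key(from, to)
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("duplicate edge (%d, %d)", from[dup[1L]], to[dup[1L]]),
           call. = FALSE)
    }
  }
  structure(list(from = from, to = to, weight = weight,
                 n_vertices = n_vertices),
            class = "edge_list")
}

#' Number of edges in an edge list
#' @param el An [edge_list()].
#' @return Integer edge count.
#' @export
n_edges <- function(el) length(el$from)

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("<edge_list> %d edges over %d vertices\n",
              n_edges(x), x$n_vertices))
  invisible(x)
}

# Canonical key for an unordered vertex pair.
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

stopifnot_edge_list <- function(el) {
  if (!inherits(el, "edge_list")) {
    stop("expected an `edge_list` object", call. = FALSE)
  }
  invisible(el)
}
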