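#' Vertex label registry
#'
#' Maps vertex labels to dense 1-based indices and records each vertex's
#' kind (`"disease"`, `"protein"` or `"locus"`).  The registry is a mutable
#' environment shared by all layers of a heterogeneous build, so indices
#' assigned while reading one layer remain valid for all others.  Kinds are
#' immutable once assigned.
#'
#' @return An object of class `vertex_registry`.
#' @examples
#' reg <- vertex_registry()
#' registry_add(reg, c("HP:0001", "HP:0002"), "disease")
#' registry_index(reg, "HP:0002")
#' @export
vertex_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$labels <- character()
  reg$kind <- character()
  reg$map <- new.env(parent = emptyenv())
  class(reg) <- "vertex_registry"
  reg
}

#' @export
print.vertex_registry <- function(x, ...) {
  tab <- table(x$kind)
  cat(sprintf("<vertex_registry> %d vertices (%s)\n", length(x$labels),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Register labels of one kind
#'
#' Unknown labels are appended with fresh indices; labels already present
#' keep their index.  Registering a label under a different kind than it
#' was first seen with is an error.
#'
#' @param reg A [vertex_registry()].
#' @param labels Character vector of vertex labels.
#' @param kind One of `"disease"`, `"protein"`, `"locus"`.
#' @return (Invisibly) the integer indices of `labels`.
#' @export
registry_add <- function(reg, labels, kind) {
  kind <- match.arg(kind, c("disease", "protein", "locus"))
  labels <- as.character(labels)
  idx <- integer(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    j <- reg$map[[lab]]
    if (is.null(j)) {
      j <- length(reg$labels) + 1L
      reg$labels[[j]] <- lab
      reg$kind[[j]] <- kind
      assign(lab, j, envir = reg$map)
    } else if (reg$kind[[j]] != kind) {
      stop(sprintf("label '%s' already registered as %s, cannot re-type as %s",
                   lab, reg$kind[[j]], kind), call. = FALSE)
    }
    idx[i] <- j
  }
  invisible(idx)
}

#' Look up label indices
#'
#' @param reg A [vertex_registry()].
#' @param labels Character labels to resolve.
#' @param strict Error on unknown labels (default); otherwise `NA`.
#' @return Integer indices.
#' @export
registry_index <- function(reg, labels, strict = TRUE) {
  idx <- vapply(as.character(labels), function(lab) {
    j <- reg$map[[lab]]
    if (is.null(j)) NA_integer_ else j
  }, integer(1), USE.NAMES = FALSE)
  if (strict && anyNA(idx)) {
    stop(sprintf("unknown vertex label '%s'",
                 labels[which(is.na(idx))[1L]]), call. = FALSE)
  }
  idx
}

#' Number of registered vertices
#' @param reg A [vertex_registry()].
#' @return Integer count.
#' @export
registry_size <- function(reg) length(reg$labels)

#' Labels (and kinds) of registered vertices
#' @param reg A [vertex_registry()].
#' @param indices Optional integer indices; default all.
#' @return `registry_labels()`: character labels. `registry_kinds()`:
#'   character kinds.
#' @export
registry_labels <- function(reg, indices = NULL) {
  if (is.null(indices)) reg$labels else reg$labels[indices]
}

#' @rdname registry_labels
#' @export
registry_kinds <- function(reg, indices = NULL) {
  if (is.null(indices)) reg$kind else reg$kind[indices]
}
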