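# Query-time vertical extraction and horizontal composition of versions
# into standard CSR networks.

new_plain_csr <- function(adj, vertex_ids) {
  deg <- vapply(adj, function(x) length(x$v), integer(1))
  list(
    A = unlist(lapply(adj, `[[`, "w"), use.names = FALSE),
    JA = match(unlist(lapply(adj, `[[`, "v"), use.names = FALSE), vertex_ids),
    IA = cumsum(c(0L, deg)),
    vertex_ids = as.integer(vertex_ids)
  ) |> structure(class = "plain_csr")
}

#' Number of vertices of an extracted CSR network
#' @param csr A `plain_csr`.
#' @return Integer vertex count.
#' @export
csr_n_vertices <- function(csr) length(csr$IA) - 1L

#' @export
print.plain_csr <- function(x, ...) {
  cat(sprintf("<plain_csr> %d vertices, %d edges\n",
              csr_n_vertices(x), length(x$JA) / 2))
  invisible(x)
}

# Local adjacency of row i: list(v = local neighbor indices, w = weights).
csr_row <- function(csr, i) {
  r <- seq.int(csr$IA[i] + 1, length.out = csr$IA[i + 1] - csr$IA[i])
  list(v = csr$JA[r], w = csr$A[r])
}

#' Convert an extracted network to a sparse adjacency matrix
#'
#' @param csr A `plain_csr`.
#' @return A symmetric `Matrix::dgCMatrix` whose rows/columns follow the
#'   CSR's local vertex order (`csr$vertex_ids` maps back to the registry).
#' @export
as_sparse_matrix <- function(csr) {
  V <- csr_n_vertices(csr)
  deg <- diff(csr$IA)
  Matrix::sparseMatrix(
    i = rep.int(seq_len(V), deg), j = csr$JA, x = csr$A,
    dims = c(V, V)
  )
}

#' Edge frame of an extracted network
#'
#' Lists each undirected edge once (`source <= target` in index or label
#' order is not guaranteed; the pair is canonical by local index).
#'
#' @param csr A `plain_csr`.
#' @param registry Optional [vertex_registry()]; when given, global labels
#'   are reported instead of global indices.
#' @return A data.frame with `source`, `target`, `weight`.
#' @export
csr_edge_frame <- function(csr, registry = NULL) {
  V <- csr_n_vertices(csr)
  deg <- diff(csr$IA)
  row <- rep.int(seq_len(V), deg)
  keep <- row <= csr$JA
  src <- csr$vertex_ids[row[keep]]
  tgt <- csr$vertex_ids[csr$JA[keep]]
  w <- csr$A[keep]
  if (!is.null(registry)) {
    src <- registry_labels(registry, src)
    tgt <- registry_labels(registry, tgt)
  } else {
    src <- as.character(src); tgt <- as.character(tgt)
  }
  data.frame(source = src, target = tgt, weight = w, stringsAsFactors = FALSE)
}

# Restrict a plain_csr to the vertices reachable from `seeds` (local
# indices) by undirected breadth-first search; returns the pruned CSR and
# the remapped seed indices.
prune_unreachable <- function(csr, seeds) {
  V <- csr_n_vertices(csr)
  seen <- logical(V)
  queue <- unique(as.integer(seeds))
  seen[queue] <- TRUE
  while (length(queue)) {
    nxt <- unique(unlist(lapply(queue, function(i) csr_row(csr, i)$v),
                         use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- nxt
  }
  keep <- which(seen)
  local <- match(seq_len(V), keep)
  adj <- lapply(keep, function(i) {
    r <- csr_row(csr, i)
    list(v = csr$vertex_ids[r$v], w = r$w)
  })
  out <- new_plain_csr(adj, csr$vertex_ids[keep])
  list(csr = out, seeds = local[seeds])
}

#' Extract one stored version as a standard CSR network
#'
#' Vertical integration: materializes the cumulative network of a single
#' version-tree node in standard CSR form, so any CSR-based network
#' algorithm can run on it.  When seed vertices are given, the parts of
#' the network not reachable from any seed are removed.
#'
#' @param g A `versioned_csr`.
#' @param version Version id.
#' @param seeds Optional integer vertex indices (global) used for
#'   reachability pruning.
#' @return A `plain_csr`; `vertex_ids` maps local rows to global indices.
#' @export
extract_version <- function(g, version, seeds = NULL) {
  version <- check_version(g, version)
  adj <- version_adjacency(g, version)
  csr <- new_plain_csr(adj, seq_along(adj))
  if (is.null(seeds)) return(csr)
  seeds <- as.integer(seeds)
  if (any(seeds < 1L | seeds > length(adj))) {
    stop(sprintf("seed outside the version's vertex range 1..%d",
                 length(adj)), call. = FALSE)
  }
  prune_unreachable(csr, seeds)$csr
}

version_ancestors <- function(g, version) {
  path <- version
  while (g$parent[version] != version) {
    version <- g$parent[version]
    path <- c(path, version)
  }
  path
}

#' Partition vertices by row identity across versions
#'
#' Splits the vertex set into `S_p`, the vertices whose decompressed
#' augmented IA entries are bitwise identical across all listed versions
#' (so their adjacency can be gathered from any one version), and its
#' complement `S_n`.  The test is conservative: identical adjacency stored
#' at different offsets lands in `S_n`, which costs speed but never
#' correctness.  Vertices absent from at least one version are in `S_n`.
#'
#' @param g A `versioned_csr`.
#' @param version_ids One or more version ids.
#' @return A list with integer vectors `S_p` and `S_n` partitioning
#'   `1:max(n_vertices)` over the versions.
#' @export
partition_vertices <- function(g, version_ids) {
  ids <- check_version(g, version_ids)
  ias <- lapply(ids, function(d) decompress_ia(g, d))
  nv <- vapply(ids, function(d) g$n_vertices[d], integer(1))
  m <- min(nv); V <- max(nv)
  same <- rep(TRUE, m)
  if (length(ids) > 1L && m > 0L) {
    ref <- ias[[1L]][seq_len(m), , drop = FALSE]
    for (j in seq_along(ias)[-1L]) {
      same <- same &
        rowSums(ias[[j]][seq_len(m), , drop = FALSE] == ref) == 4L
    }
  }
  s_p <- which(same)
  list(S_p = s_p, S_n = setdiff(seq_len(V), s_p))
}

#' Compose sibling versions by edge union or intersection
#'
#' Horizontal integration: combines the edge sets of versions on distinct
#' branches of the version tree into one standard CSR network.  Vertices
#' in the identical partition (`S_p` of [partition_vertices()]) are
#' gathered in a single pass over one version; only the differing minority
#' is read from every version, so composing `b` highly overlapping
#' versions touches the edge arrays `O(bE)` times in the worst case and
#' close to once in the typical case.
#'
#' @param g A `versioned_csr`.
#' @param version_ids Two or more version ids on distinct branches (none
#'   may be an ancestor of another); a single id degenerates to
#'   [extract_version()].
#' @param mode `"union"` keeps an edge present in at least one version;
#'   `"intersection"` keeps an edge present in every version.
#' @param weight_reducer Function combining the weights of the versions
#'   that carry an edge; defaults to `max` for union and `min` for
#'   intersection.  Use a commutative/associative reducer so results are
#'   independent of version order.
#' @return A `plain_csr` over `1:max(n_vertices)` of the versions.
#' @export
compose_versions <- function(g, version_ids,
                             mode = c("union", "intersection"),
                             weight_reducer = NULL) {
  mode <- match.arg(mode)
  ids <- check_version(g, version_ids)
  if (anyDuplicated(ids)) ids <- unique(ids)
  if (length(ids) > 1L) {
    paths <- lapply(ids, function(d) version_ancestors(g, d))
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a != b && ids[a] %in% paths[[b]]) {
          stop(sprintf(
            "version %d is an ancestor of version %d; compose distinct branches",
            ids[a], ids[b]), call. = FALSE)
        }
      }
    }
  }
  if (is.null(weight_reducer)) {
    weight_reducer <- if (mode == "union") max else min
  }
  if (length(ids) == 1L) return(extract_version(g, ids))

  ias <- lapply(ids, function(d) decompress_ia(g, d))
  nv <- vapply(ids, function(d) g$n_vertices[d], integer(1))
  V <- max(nv)
  b <- length(ids)
  part <- partition_vertices(g, ids)
  in_sp <- rep(FALSE, V)
  in_sp[part$S_p] <- TRUE

  adj <- vector("list", V)
  empty <- list(v = integer(), w = numeric())
  for (vtx in seq_len(V)) {
    if (in_sp[vtx]) {
      adj[[vtx]] <- adjacency_of_entry(g, ias[[1L]][vtx, ])
      next
    }
    rows <- lapply(seq_len(b), function(j) {
      if (vtx <= nv[j]) adjacency_of_entry(g, ias[[j]][vtx, ]) else empty
    })
    allv <- unlist(lapply(rows, `[[`, "v"), use.names = FALSE)
    if (!length(allv)) { adj[[vtx]] <- empty; next }
    allw <- unlist(lapply(rows, `[[`, "w"), use.names = FALSE)
    grp <- split(allw, allv)
    if (mode == "intersection") {
      grp <- grp[lengths(grp) == b]
    }
    if (!length(grp)) { adj[[vtx]] <- empty; next }
    nb <- as.integer(names(grp))
    ord <- order(nb)
    adj[[vtx]] <- list(v = nb[ord],
                       w = vapply(grp, weight_reducer, numeric(1),
                                  USE.NAMES = FALSE)[ord])
  }
  new_plain_csr(adj, seq_len(V))
}

#' Specify an integrated-network query
#'
#' @param layers Network types to include, a non-empty prefix of
#'   `c("GD", "GA", "GP", "GL")` (ontology, associations, PPI, eQTL): the
#'   selected types must induce a path from the root of the version tree.
#' @param tissues Character tissue names to integrate over; required when
#'   `"GL"` is selected, optional for `"GP"` (no tissues means the generic
#'   PPI core only).
#' @param mode `"union"` (edge in at least one tissue) or
#'   `"intersection"` (edge in all tissues).
#' @param seeds Character vertex labels used as query seeds.
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(layers, tissues = character(), mode = "union",
                       seeds = character()) {
  all_layers <- c("GD", "GA", "GP", "GL")
  layers <- unique(toupper(layers))
  if (!length(layers) || !all(layers %in% all_layers)) {
    stop("`layers` must be a non-empty subset of GD, GA, GP, GL",
         call. = FALSE)
  }
  prefix <- all_layers[seq_len(max(match(layers, all_layers)))]
  if (!setequal(layers, prefix)) {
    stop(sprintf(
      "selected layers must induce a path in the version tree (expected %s)",
      paste(prefix, collapse = ", ")), call. = FALSE)
  }
  mode <- match.arg(mode, c("union", "intersection"))
  if ("GL" %in% layers && !length(tissues)) {
    stop("selecting the eQTL layer requires at least one tissue",
         call. = FALSE)
  }
  structure(list(layers = prefix, tissues = as.character(tissues),
                 mode = mode, seeds = as.character(seeds)),
            class = "query_spec")
}

#' Resolve a query into a composed network and seed indices
#'
#' Picks, for every tissue in the query, the version at the deepest layer
#' the query selects (the version tree integrates vertically along the
#' path implicitly), horizontally integrates those versions under the
#' query mode, and maps the seed labels to local row indices.  Generic
#' queries (no tissue-specific layer, or `"GP"` with no tissues) bypass
#' horizontal integration.  When seeds are given, the composed network is
#' pruned to the component(s) reachable from them.
#'
#' @param g A `versioned_csr` built by [build_version_tree()].
#' @param meta The builder's version metadata.
#' @param registry The builder's [vertex_registry()].
#' @param spec A [query_spec()].
#' @return A list with `csr` (`plain_csr`) and `seeds` (local indices into
#'   the csr, `NULL` when the query has no seeds).
#' @export
resolve_query <- function(g, meta, registry, spec) {
  if (!inherits(spec, "query_spec")) {
    stop("`spec` must be a `query_spec`", call. = FALSE)
  }
  deepest <- spec$layers[length(spec$layers)]
  if (length(spec$tissues)) {
    known <- unique(meta$tissue[!is.na(meta$tissue)])
    bad <- setdiff(spec$tissues, known)
    if (length(bad)) {
      stop(sprintf("unknown tissue '%s'", bad[1L]), call. = FALSE)
    }
  }
  if (deepest %in% c("GD", "GA") || !length(spec$tissues)) {
    vid <- switch(deepest,
                  GD = meta$version[meta$layer == "ontology"],
                  GA = meta$version[meta$layer == "association"],
                  GP = meta$version[meta$layer == "generic_ppi"],
                  stop("selecting the eQTL layer requires at least one tissue",
                       call. = FALSE))
    csr <- extract_version(g, vid)
  } else {
    layer <- if (deepest == "GP") "tissue_ppi" else "tissue_eqtl"
    vids <- vapply(spec$tissues, function(tn) {
      meta$version[meta$layer == layer & !is.na(meta$tissue) &
                     meta$tissue == tn]
    }, integer(1))
    csr <- compose_versions(g, vids, mode = spec$mode)
  }
  seeds <- NULL
  if (length(spec$seeds)) {
    gidx <- registry_index(registry, spec$seeds)
    loc <- match(gidx, csr$vertex_ids)
    if (anyNA(loc)) {
      stop(sprintf("seed '%s' is not a vertex of the composed network",
                   spec$seeds[which(is.na(loc))[1L]]), call. = FALSE)
    }
    pr <- prune_unreachable(csr, loc)
    csr <- pr$csr
    seeds <- pr$seeds
  }
  list(csr = csr, seeds = seeds)
}
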