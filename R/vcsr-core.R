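# Augmented IA row-type flags, stored in the two least-significant bits of
# e3.  Length payloads sharing e3 are stored shifted left by two bits.
IA_NORMAL <- 0
IA_SPLIT <- 1
IA_COMPRESSED <- 2

ia_flag <- function(e3) e3 %% 4
ia_payload <- function(e3) e3 %/% 4
ia_pack <- function(payload, flag) payload * 4 + flag

ia_matrix <- function(n) {
  matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, c("e0", "e1", "e2", "e3")))
}

#' Create a versioned CSR graph from a single edge list
#'
#' Builds the root version of a versioned compressed-sparse-row store.  The
#' root is a standard CSR matrix: a weight array `A`, a column-index array
#' `JA` (both of length twice the edge count, once per incident row) and one
#' augmented IA entry per vertex, every entry a normal row.  Further
#' versions are grown with [add_version()].
#'
#' @param edges An [edge_list()] with the root version's undirected edges.
#' @param h Key-frame compression-ratio threshold in `(0, 1]`.  When a new
#'   version's IA segment compresses against its key-frame to a ratio at or
#'   below `h` the compressed segment is stored; otherwise the version is
#'   stored uncompressed and becomes its own key-frame.
#' @return An object of class `versioned_csr`.
#' @seealso [add_version()], [neighbors()], [storage_stats()]
#' @examples
#' g <- create_graph(edge_list(c(1, 2), c(2, 3), 1, n_vertices = 3))
#' neighbors(g, 1, 2)
#' @export
create_graph <- function(edges, h = 0.5) {
  stopifnot_edge_list(edges)
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h > 1) {
    stop("`h` must be a single value in (0, 1]", call. = FALSE)
  }
  nv <- edges$n_vertices
  rows <- rowwise_incidence(edges)
  deg <- tabulate(rows$row, nbins = nv)
  ia <- ia_matrix(nv)
  ia[, "e0"] <- cumsum(c(0, deg))[seq_len(nv)]
  ia[, "e1"] <- deg
  g <- structure(list(
    A = rows$w,
    JA = rows$col,
    IA = ia,
    D = c(0, nv),
    K = 1L,
    parent = 1L,
    n_vertices = nv,
    h = h,
    counters = new.env(parent = emptyenv())
  ), class = "versioned_csr")
  g$counters$ja_reads <- 0
  g
}

# Expand an undirected edge list into per-row incidence sorted by
# (row, column): each edge contributes one entry to each endpoint's row,
# self-loops one entry to their single row.
rowwise_incidence <- function(edges) {
  u <- edges$from; v <- edges$to; w <- edges$weight
  loop <- u == v
  row <- c(u, v[!loop])
  col <- c(v, u[!loop])
  wt <- c(w, w[!loop])
  ord <- order(row, col)
  list(row = row[ord], col = col[ord], w = wt[ord])
}

#' Number of versions in a versioned graph
#' @param g A `versioned_csr`.
#' @return Integer count of stored versions.
#' @export
n_versions <- function(g) length(g$parent)

#' Per-version vertex counts
#' @param g A `versioned_csr`.
#' @param version Optional version id; when omitted the full vector is
#'   returned.
#' @return Integer vertex count(s).
#' @export
n_vertices <- function(g, version = NULL) {
  if (is.null(version)) g$n_vertices else g$n_vertices[check_version(g, version)]
}

check_version <- function(g, version) {
  version <- as.integer(version)
  if (any(is.na(version)) || any(version < 1L) || any(version > n_versions(g))) {
    stop(sprintf("unknown version id (graph has %d versions)", n_versions(g)),
         call. = FALSE)
  }
  version
}

# IA rows (1-based) belonging to a version's stored segment.
ia_segment_rows <- function(g, version) {
  if (g$D[version + 1] <= g$D[version]) return(integer())
  seq.int(g$D[version] + 1, g$D[version + 1])
}

#' @export
print.versioned_csr <- function(x, ...) {
  st <- storage_stats(x)
  cat(sprintf(paste0(
    "<versioned_csr> %d version(s), %d vertices in latest, h = %g\n",
    "  A/JA length %d, IA entries %d, %.0f bytes",
    " (separate CSR storage: %.0f bytes)\n"),
    n_versions(x), x$n_vertices[n_versions(x)], x$h,
    st$lenJA, st$lenIA, st$bytesTotal, st$perVersionSeparateBytes))
  invisible(x)
}

#' Decompress a version's augmented IA segment
#'
#' Resolves every compressed-row-set (C) entry of the stored segment into
#' the normal/split entries it references inside the version's key-frame
#' segment, yielding one entry per vertex.  By construction a key-frame
#' segment contains no C entries, so decompression is a single pass that
#' never chases references across multiple versions.
#'
#' @param g A `versioned_csr`.
#' @param version Version id.
#' @return A numeric matrix with columns `e0, e1, e2, e3` and one row per
#'   vertex of the version; no row has the compressed type.
#' @export
decompress_ia <- function(g, version) {
  version <- check_version(g, version)
  rows <- ia_segment_rows(g, version)
  seg <- g$IA[rows, , drop = FALSE]
  flags <- ia_flag(seg[, "e3"])
  if (!any(flags == IA_COMPRESSED)) {
    if (nrow(seg) != g$n_vertices[version]) {
      stop("corrupted IA segment: entry count does not match vertex count",
           call. = FALSE)
    }
    return(seg)
  }
  kf <- g$K[version]
  kf_lo <- g$D[kf] + 1
  kf_hi <- g$D[kf + 1]
  take <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (flags[i] == IA_COMPRESSED) {
      run <- seq.int(seg[i, "e0"] + 1, length.out = seg[i, "e1"])
      if (run[1L] < kf_lo || run[length(run)] > kf_hi) {
        stop("corrupted compressed row set: range outside key-frame segment",
             call. = FALSE)
      }
      take[[i]] <- run
    } else {
      take[[i]] <- rows[i]
    }
  }
  out <- g$IA[unlist(take), , drop = FALSE]
  if (any(ia_flag(out[, "e3"]) == IA_COMPRESSED)) {
    stop("corrupted compressed row set: reference to a compressed entry",
         call. = FALSE)
  }
  if (nrow(out) != g$n_vertices[version]) {
    stop("corrupted IA segment: entry count does not match vertex count",
         call. = FALSE)
  }
  out
}

# Adjacency of one decompressed IA entry: list(v = neighbor indices sorted,
# w = weights).  Segments are individually sorted; split rows are merged.
adjacency_of_entry <- function(g, entry) {
  flag <- ia_flag(entry[["e3"]])
  i1 <- seq.int(entry[["e0"]] + 1, length.out = entry[["e1"]])
  v <- g$JA[i1]
  w <- g$A[i1]
  nread <- entry[["e1"]]
  if (flag == IA_SPLIT) {
    len2 <- ia_payload(entry[["e3"]])
    i2 <- seq.int(entry[["e2"]] + 1, length.out = len2)
    v2 <- g$JA[i2]
    w2 <- g$A[i2]
    ord <- merge_order(v, v2)
    v <- c(v, v2)[ord]
    w <- c(w, w2)[ord]
    nread <- nread + len2
  }
  g$counters$ja_reads <- g$counters$ja_reads + nread
  list(v = v, w = w)
}

# Two-way merge order of two individually sorted integer vectors.
merge_order <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L) return(seq_len(nb) + na)
  if (nb == 0L) return(seq_len(na))
  out <- integer(na + nb)
  i <- 1L; j <- 1L; k <- 1L
  while (i <= na && j <= nb) {
    if (a[i] <= b[j]) { out[k] <- i; i <- i + 1L }
    else { out[k] <- na + j; j <- j + 1L }
    k <- k + 1L
  }
  if (i <= na) out[k:(na + nb)] <- i:na
  if (j <= nb) out[k:(na + nb)] <- na + (j:nb)
  out
}

#' Adjacency list of one vertex in one version
#'
#' Random access into the versioned store.  The lookup resolves at most one
#' compressed-row-set reference (into the version's key-frame segment) and
#' reads at most two contiguous ranges of `JA`, independent of the
#' version's depth in the tree.
#'
#' @param g A `versioned_csr`.
#' @param version Version id.
#' @param vertex Vertex index in `1:n_vertices(g, version)`.
#' @return A data.frame with columns `vertex` and `weight`, sorted by
#'   neighbor index and duplicate-free; zero rows for an isolated vertex.
#' @export
neighbors <- function(g, version, vertex) {
  version <- check_version(g, version)
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L ||
      vertex > g$n_vertices[version]) {
    stop(sprintf("vertex index out of range for version %d (1..%d)",
                 version, g$n_vertices[version]), call. = FALSE)
  }
  rows <- ia_segment_rows(g, version)
  seg <- g$IA[rows, , drop = FALSE]
  flags <- ia_flag(seg[, "e3"])
  spans <- ifelse(flags == IA_COMPRESSED, seg[, "e1"], 1)
  ends <- cumsum(spans)
  i <- which(ends >= vertex)[1L]
  if (is.na(i)) {
    stop("corrupted IA segment: vertex not covered", call. = FALSE)
  }
  if (flags[i] == IA_COMPRESSED) {
    offset <- vertex - (ends[i] - spans[i])   # 1-based position in the run
    target <- seg[i, "e0"] + offset
    kf <- g$K[version]
    if (target < g$D[kf] + 1 || target > g$D[kf + 1]) {
      stop("corrupted compressed row set: range outside key-frame segment",
           call. = FALSE)
    }
    entry <- g$IA[target, ]
    if (ia_flag(entry[["e3"]]) == IA_COMPRESSED) {
      stop("corrupted compressed row set: reference to a compressed entry",
           call. = FALSE)
    }
  } else {
    entry <- seg[i, ]
  }
  adj <- adjacency_of_entry(g, entry)
  data.frame(vertex = adj$v, weight = adj$w)
}

# Full adjacency of a version: list over vertices of list(v, w).
version_adjacency <- function(g, version) {
  ia <- decompress_ia(g, version)
  lapply(seq_len(nrow(ia)), function(i) adjacency_of_entry(g, ia[i, ]))
}

#' Compress an IA segment against a key-frame segment
#'
#' Replaces maximal runs of entries that are identical (all four fields) to
#' the entries at the same vertex positions of the key-frame segment with
#' single compressed-row-set (C) entries.  A C entry's `e0` is the 0-based
#' position of the run's first entry *within the key-frame segment* and
#' `e1` is the run length; [add_version()] rebases `e0` to an absolute IA
#' offset when storing.
#'
#' @param new_segment Numeric 4-column matrix of uncompressed entries (one
#'   per vertex of the new version).
#' @param keyframe_segment Numeric 4-column matrix with no compressed
#'   entries.
#' @return A list with `compressed` (4-column matrix) and `ratio`
#'   (`nrow(compressed) / nrow(new_segment)`, in `(0, 1]`).  Decompression
#'   of the result against the same key-frame segment is exact.
#' @export
compress_ia_segment <- function(new_segment, keyframe_segment) {
  stopifnot(is.matrix(new_segment), ncol(new_segment) == 4L,
            is.matrix(keyframe_segment), ncol(keyframe_segment) == 4L)
  if (any(ia_flag(new_segment[, 4L]) == IA_COMPRESSED)) {
    stop("`new_segment` must be uncompressed", call. = FALSE)
  }
  if (any(ia_flag(keyframe_segment[, 4L]) == IA_COMPRESSED)) {
    stop("`keyframe_segment` must not contain compressed entries",
         call. = FALSE)
  }
  n <- nrow(new_segment)
  if (n == 0L) {
    return(list(compressed = new_segment, ratio = 1))
  }
  m <- min(n, nrow(keyframe_segment))
  same <- rep(FALSE, n)
  if (m > 0L) {
    same[seq_len(m)] <-
      rowSums(new_segment[seq_len(m), , drop = FALSE] ==
                keyframe_segment[seq_len(m), , drop = FALSE]) == 4L
  }
  runs <- rle(same)
  pos <- 1L
  out <- vector("list", length(runs$lengths))
  for (j in seq_along(runs$lengths)) {
    len <- runs$lengths[j]
    if (runs$values[j]) {
      entry <- ia_matrix(1L)
      entry[1, "e0"] <- pos - 1L        # 0-based within keyframe segment
      entry[1, "e1"] <- len
      entry[1, "e3"] <- ia_pack(0, IA_COMPRESSED)
      out[[j]] <- entry
    } else {
      out[[j]] <- new_segment[seq.int(pos, length.out = len), , drop = FALSE]
    }
    pos <- pos + len
  }
  compressed <- do.call(rbind, out)
  colnames(compressed) <- c("e0", "e1", "e2", "e3")
  list(compressed = compressed, ratio = nrow(compressed) / n)
}

#' Add a child version to a versioned graph
#'
#' Appends a new version whose network is the parent's edge set plus
#' `new_edges`.  The parent's stored data are never modified: reads of any
#' existing version are identical before and after the call.  For each
#' vertex gaining edges, the update either splits a normal row (the new
#' edges become the second segment), splits a split row (the parent's
#' second segment is merged with the new edges into a fresh second
#' segment), or joins a split row into a single normal row.  The join is
#' taken when the prospective second segment would be at least as long as
#' the first (`e3 + t >= e1` for `t` new edges on that row), which bounds
#' the storage of a vertex gaining `r` edges over an `l`-version chain by
#' `O(r log l)` instead of the `Theta(r l)` cost of never joining.
#'
#' After the per-vertex updates, the new IA segment is compressed against
#' the parent's key-frame ([compress_ia_segment()]); if the achieved ratio
#' is at most `g$h` the compressed segment is stored and the key-frame is
#' inherited, otherwise the segment is stored uncompressed and the new
#' version becomes its own key-frame.
#'
#' @param g A `versioned_csr`.
#' @param parent Parent version id.
#' @param new_edges An [edge_list()] of edges to add.  `n_vertices` may
#'   exceed the parent's vertex count (the vertex set grows; new vertices
#'   start as empty normal rows) but may not shrink.  An edge already
#'   present in the parent version is an error: the store is additive and
#'   silent re-weighting would corrupt storage shared with other versions.
#' @param join Keep the default `TRUE` for normal use.  `FALSE` disables
#'   the split-row join rule (every update of a split row re-splits),
#'   exposing the quadratic storage growth the join rule exists to avoid;
#'   useful only for storage analysis.
#' @return The updated `versioned_csr`.  The id of the new version is
#'   `n_versions()` of the result; ids are assigned in insertion order.
#' @examples
#' g <- create_graph(edge_list(1, 2, 1, n_vertices = 3))
#' g <- add_version(g, 1, edge_list(2, 3, 1, n_vertices = 3))
#' neighbors(g, 2, 2)
#' @export
add_version <- function(g, parent, new_edges, join = TRUE) {
  parent <- check_version(g, parent)
  stopifnot_edge_list(new_edges)
  nv_parent <- g$n_vertices[parent]
  if (new_edges$n_vertices < nv_parent) {
    stop(sprintf(
      "vertex count may not shrink: parent version %d has %d vertices, new edge list declares %d",
      parent, nv_parent, new_edges$n_vertices), call. = FALSE)
  }
  nv_new <- new_edges$n_vertices
  pia <- decompress_ia(g, parent)

  new_seg <- ia_matrix(nv_new)
  new_seg[seq_len(nv_parent), ] <- pia
  if (nv_new > nv_parent) {
    new_seg[(nv_parent + 1):nv_new, "e0"] <- length(g$JA)
  }

  upd <- incident_map(new_edges)
  if (length(upd)) {
    # reject edges already present in the parent
    for (v in as.integer(names(upd))) {
      if (v > nv_parent) next
      existing <- adjacency_of_entry(g, pia[v, ])$v
      clash <- intersect(upd[[as.character(v)]]$v, existing)
      if (length(clash)) {
        stop(sprintf("edge (%d, %d) already exists in parent version %d",
                     v, clash[1L], parent), call. = FALSE)
      }
    }
  }

  ja_app <- list()
  a_app <- list()
  cur <- length(g$JA)                      # 0-based append cursor
  for (nm in names(upd)) {
    v <- as.integer(nm)
    nb <- upd[[nm]]
    t <- length(nb$v)
    entry <- new_seg[v, ]
    flag <- ia_flag(entry[["e3"]])
    if (flag == IA_NORMAL) {
      if (entry[["e1"]] == 0) {
        # empty row: the appended run simply becomes the row
        new_seg[v, ] <- c(cur, t, 0, ia_pack(0, IA_NORMAL))
        ja_app[[length(ja_app) + 1L]] <- nb$v
        a_app[[length(a_app) + 1L]] <- nb$w
        cur <- cur + t
      } else {
        # split a normal row: parent's list is segment 1, new edges segment 2
        new_seg[v, "e2"] <- cur
        new_seg[v, "e3"] <- ia_pack(t, IA_SPLIT)
        ja_app[[length(ja_app) + 1L]] <- nb$v
        a_app[[length(a_app) + 1L]] <- nb$w
        cur <- cur + t
      }
    } else {                               # split row
      len2 <- ia_payload(entry[["e3"]])
      i2 <- seq.int(entry[["e2"]] + 1, length.out = len2)
      s2v <- g$JA[i2]; s2w <- g$A[i2]
      if (join && (len2 + t) >= entry[["e1"]]) {
        # join to a normal row: segment 1 + segment 2 + new edges, one run
        i1 <- seq.int(entry[["e0"]] + 1, length.out = entry[["e1"]])
        allv <- c(g$JA[i1], s2v, nb$v)
        allw <- c(g$A[i1], s2w, nb$w)
        ord <- order(allv)
        new_seg[v, ] <- c(cur, length(allv), 0, ia_pack(0, IA_NORMAL))
        ja_app[[length(ja_app) + 1L]] <- allv[ord]
        a_app[[length(a_app) + 1L]] <- allw[ord]
        cur <- cur + length(allv)
      } else {
        # maintain the split: merge old segment 2 with the new edges
        mv <- c(s2v, nb$v); mw <- c(s2w, nb$w)
        ord <- order(mv)
        new_seg[v, "e2"] <- cur
        new_seg[v, "e3"] <- ia_pack(len2 + t, IA_SPLIT)
        ja_app[[length(ja_app) + 1L]] <- mv[ord]
        a_app[[length(a_app) + 1L]] <- mw[ord]
        cur <- cur + length(mv)
      }
    }
  }

  kf <- g$K[parent]
  kf_seg <- g$IA[ia_segment_rows(g, kf), , drop = FALSE]
  comp <- compress_ia_segment(new_seg, kf_seg)
  if (comp$ratio <= g$h) {
    seg_store <- comp$compressed
    is_c <- ia_flag(seg_store[, "e3"]) == IA_COMPRESSED
    seg_store[is_c, "e0"] <- seg_store[is_c, "e0"] + g$D[kf]  # rebase
    new_kf <- kf
  } else {
    seg_store <- new_seg
    new_kf <- n_versions(g) + 1L
  }

  g$JA <- c(g$JA, unlist(ja_app, use.names = FALSE))
  g$A <- c(g$A, unlist(a_app, use.names = FALSE))
  g$IA <- rbind(g$IA, seg_store)
  g$D <- c(g$D, g$D[length(g$D)] + nrow(seg_store))
  g$K <- c(g$K, new_kf)
  g$parent <- c(g$parent, parent)
  g$n_vertices <- c(g$n_vertices, nv_new)
  g
}

# Group an edge batch by incident vertex: named list (by vertex index) of
# list(v = sorted new neighbors, w = weights).
incident_map <- function(edges) {
  if (n_edges(edges) == 0L) return(list())
  loop <- edges$from == edges$to
  row <- c(edges$from, edges$to[!loop])
  col <- c(edges$to, edges$from[!loop])
  w <- c(edges$weight, edges$weight[!loop])
  ord <- order(row, col)
  row <- row[ord]; col <- col[ord]; w <- w[ord]
  idx <- split(seq_along(row), row)
  lapply(idx, function(i) list(v = col[i], w = w[i]))
}

#' Storage accounting for a versioned graph
#'
#' Reports the array lengths of the shared store and the bytes it occupies
#' under the container field widths (8-byte weights and indices, 32-byte
#' augmented IA entries), next to the bytes that storing every version as
#' its own standalone CSR matrix would need (per version: `2E` weights,
#' `2E` column indices and `V + 1` row offsets, 8 bytes each).
#'
#' @param g A `versioned_csr`.
#' @return A list with `lenA`, `lenJA`, `lenIA`, `bytesTotal` and
#'   `perVersionSeparateBytes`.
#' @export
storage_stats <- function(g) {
  sep <- 0
  for (d in seq_len(n_versions(g))) {
    ia <- decompress_ia(g, d)
    entries <- sum(ia[, "e1"]) +
      sum(ia_payload(ia[, "e3"])[ia_flag(ia[, "e3"]) == IA_SPLIT])
    sep <- sep + 8 * (2 * entries) + 8 * (g$n_vertices[d] + 1)
  }
  list(
    lenA = length(g$A),
    lenJA = length(g$JA),
    lenIA = nrow(g$IA),
    bytesTotal = 8 * length(g$A) + 8 * length(g$JA) + 32 * nrow(g$IA) +
      8 * (length(g$D) + 3 * n_versions(g)) + 8,
    perVersionSeparateBytes = sep
  )
}

#' Edge deletion is not supported
#'
#' The store is additive: versions are sequences of edge additions along
#' tree paths, and ancestral storage is shared with every descendant.
#' Removing an edge would require tombstones the row types cannot
#' express, so the operation is rejected rather than half-supported.
#'
#' @param g A `versioned_csr`.
#' @param ... Ignored.
#' @export
delete_edges <- function(g, ...) {
  stop(paste("edge deletion is not supported: the versioned store is",
             "additive; model removals as alternative branches instead"),
       call. = FALSE)
}

#' Read or reset the JA/A access counter
#'
#' The store counts every element read from the `JA`/`A` arrays (adjacency
#' fetches during extraction and composition).  The counter makes the
#' `O(bE)` composition bound observable: composing `b` versions touches the
#' edge arrays a bounded number of times.
#'
#' @param g A `versioned_csr`.
#' @param reset If `TRUE`, zero the counter after reading it.
#' @return The number of `JA` elements read since the last reset.
#' @export
access_counter <- function(g, reset = FALSE) {
  n <- g$counters$ja_reads
  if (reset) g$counters$ja_reads <- 0
  n
}
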