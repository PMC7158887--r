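# Brute-force oracles kept deliberately independent of the package
# internals: versions are plain cumulative edge data frames, adjacency is
# recomputed from scratch on every call.

okey <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")

oracle_root <- function(el) {
  list(list(
    edges = data.frame(u = el$from, v = el$to, w = el$weight),
    nv = el$n_vertices,
    parent = 1L
  ))
}

oracle_add <- function(o, parent, el) {
  p <- o[[parent]]
  o[[length(o) + 1L]] <- list(
    edges = rbind(p$edges,
                  data.frame(u = el$from, v = el$to, w = el$weight)),
    nv = max(p$nv, el$n_vertices),
    parent = parent
  )
  o
}

# Sorted (neighbor, weight) pairs of vertex `vert` in version `d`.
oracle_neighbors <- function(o, d, vert) {
  e <- o[[d]]$edges
  hit <- e$u == vert | e$v == vert
  nb <- ifelse(e$u[hit] == vert, e$v[hit], e$u[hit])
  w <- e$w[hit]
  ord <- order(nb)
  data.frame(vertex = as.integer(nb[ord]), weight = w[ord])
}

oracle_adjacency <- function(o, d) {
  e <- o[[d]]$edges
  nv <- o[[d]]$nv
  loop <- e$u == e$v
  row <- c(e$u, e$v[!loop]); col <- c(e$v, e$u[!loop]); w <- c(e$w, e$w[!loop])
  ord <- order(row, col)
  row <- row[ord]; col <- col[ord]; w <- w[ord]
  out <- rep(list(list(v = integer(), w = numeric())), nv)
  for (i in split(seq_along(row), row)) {
    out[[row[i[1L]]]] <- list(v = as.integer(col[i]), w = as.numeric(w[i]))
  }
  out
}

# connected ring with random chords, as a plain_csr
ring_csr <- function(n, chords = 0L) {
  u <- seq_len(n); v <- c(seq_len(n - 1L) + 1L, 1L)
  ex <- okey(u, v)
  if (chords > 0L) {
    p <- sample_pairs(n, chords, exclude = ex)
    u <- c(u, p$u); v <- c(v, p$v)
  }
  extract_version(create_graph(edge_list(u, v, 1, n_vertices = n)), 1)
}

oracle_edge_keys <- function(o, d) okey(o[[d]]$edges$u, o[[d]]$edges$v)

# Sample `m` distinct unordered pairs over 1..nv, excluding given keys.
sample_pairs <- function(nv, m, exclude = character()) {
  pairs <- utils::combn(nv, 2L)
  keys <- okey(pairs[1L, ], pairs[2L, ])
  ok <- which(!(keys %in% exclude))
  if (length(ok) < m) stop("not enough free pairs to sample")
  sel <- sample(ok, m)
  list(u = pairs[1L, sel], v = pairs[2L, sel])
}

# A random versioned tree plus its oracle.  Each non-root version picks a
# random parent and adds a random batch of edges absent from that parent;
# some versions also grow the vertex set.
random_tree <- function(n_versions = 5L, nv0 = 20L, m0 = 25L,
                        batch = c(1L, 8L), grow_prob = 0.3, h = 0.5) {
  p <- sample_pairs(nv0, m0)
  el <- edge_list(p$u, p$v, stats::runif(m0, 0.5, 2), n_vertices = nv0)
  g <- create_graph(el, h = h)
  o <- oracle_root(el)
  for (d in seq_len(n_versions - 1L)) {
    parent <- sample(length(o), 1L)
    nv <- o[[parent]]$nv
    if (stats::runif(1) < grow_prob) nv <- nv + sample(1:4, 1L)
    m <- sample(seq(batch[1L], batch[2L]), 1L)
    p <- sample_pairs(nv, m, exclude = oracle_edge_keys(o, parent))
    el <- edge_list(p$u, p$v, stats::runif(m, 0.5, 2), n_vertices = nv)
    g <- add_version(g, parent, el)
    o <- oracle_add(o, parent, el)
  }
  list(g = g, o = o)
}

expect_version_matches_oracle <- function(g, o, d) {
  got <- lapply(netvc:::version_adjacency(g, d), function(x) {
    list(v = as.integer(x$v), w = as.numeric(x$w))
  })
  expect_identical(got, oracle_adjacency(o, d))
}

# Dense reference solution of the restart equation (I - (1-a)W)x = a r.
dense_rwr_solve <- function(W, r, alpha) {
  Wd <- as.matrix(W)
  solve(diag(nrow(Wd)) - (1 - alpha) * Wd, alpha * r)
}
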