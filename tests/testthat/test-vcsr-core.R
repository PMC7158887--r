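test_that("root version reproduces standard CSR semantics", {
  # empty graph with one vertex
  g <- create_graph(edge_list(n_vertices = 1))
  expect_equal(nrow(g$IA), 1L)
  expect_equal(unname(g$IA[1, "e1"]), 0)
  expect_equal(length(g$A), 0L)
  expect_equal(nrow(neighbors(g, 1, 1)), 0L)

  # path graph 1-2-3: undirected storage is symmetric
  g <- create_graph(edge_list(c(1, 2), c(2, 3), 1, n_vertices = 3))
  expect_equal(length(g$JA), 4L)  # 2 * |E|
  nb <- neighbors(g, 1, 2)
  expect_equal(nb$vertex, c(1L, 3L))
  expect_equal(nb$weight, c(1, 1))

  # 50-vertex random graph against the brute-force adjacency oracle
  set.seed(101)
  p <- sample_pairs(50, 120)
  el <- edge_list(p$u, p$v, runif(120), n_vertices = 50)
  g <- create_graph(el)
  o <- oracle_root(el)
  expect_version_matches_oracle(g, o, 1L)
})

test_that("input validation names the offending edge", {
  expect_error(edge_list(c(1, 1), c(2, 2), 1, n_vertices = 3),
               "duplicate edge \\(1, 2\\)")
  expect_error(edge_list(1, 5, 1, n_vertices = 3), "outside the vertex range")
  expect_error(edge_list(1, 2, NaN, n_vertices = 3), "finite")
})

test_that("adding a child splits a normal row and leaves the parent intact", {
  # vertex 1 has degree 3 in the root; two edges are added to it
  el <- edge_list(c(1, 1, 1), c(2, 3, 4), 1, n_vertices = 6)
  g <- create_graph(el)
  before <- neighbors(g, 1, 1)
  g2 <- add_version(g, 1, edge_list(c(1, 1), c(5, 6), 1, n_vertices = 6))
  ia2 <- decompress_ia(g2, 2)
  expect_equal(unname(netvc:::ia_flag(ia2[1, "e3"])), netvc:::IA_SPLIT)
  expect_equal(unname(ia2[1, "e1"]), 3)                        # first segment length
  expect_equal(unname(netvc:::ia_payload(ia2[1, "e3"])), 2)    # second segment length
  expect_equal(neighbors(g2, 2, 1)$vertex, 2:6)
  expect_identical(neighbors(g2, 1, 1), before)
})

test_that("an empty edge batch yields an identity child", {
  set.seed(7)
  tr <- random_tree(n_versions = 3L)
  g <- tr$g
  nv <- n_vertices(g, 3)
  len_ia <- nrow(g$IA)
  g2 <- add_version(g, 3, edge_list(n_vertices = nv))
  for (v in seq_len(nv)) {
    expect_identical(neighbors(g2, 4, v), neighbors(g2, 3, v))
  }
  # fully shared segment compresses to a single C entry plus no edge data
  expect_lte(nrow(g2$IA) - len_ia, 2L)
  expect_equal(length(g2$JA), length(g$JA))
})

test_that("duplicating a parent edge or shrinking the vertex set errors", {
  g <- create_graph(edge_list(1, 2, 1, n_vertices = 3))
  expect_error(add_version(g, 1, edge_list(2, 1, 1, n_vertices = 3)),
               "already exists in parent")
  expect_error(add_version(g, 1, edge_list(n_vertices = 2)),
               "may not shrink")
  expect_error(add_version(g, 5, edge_list(n_vertices = 3)),
               "unknown version")
  expect_error(delete_edges(g), "not supported")
})

test_that("split rows merge their two sorted segments on read", {
  g <- create_graph(edge_list(c(1, 1), c(2, 6), 1, n_vertices = 10))
  g <- add_version(g, 1, edge_list(c(1, 1, 1), c(4, 7, 10), 2, n_vertices = 10))
  nb <- neighbors(g, 2, 1)
  expect_equal(nb$vertex, c(2L, 4L, 6L, 7L, 10L))
  expect_equal(nb$weight, c(1, 2, 1, 2, 2))
})

test_that("randomized version trees agree with the cumulative oracle", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- random_tree(n_versions = 6L, nv0 = 25L, m0 = 30L)
    for (d in seq_len(n_versions(tr$g))) {
      expect_version_matches_oracle(tr$g, tr$o, d)
    }
  }
})

test_that("ancestor versions are bit-stable under later additions", {
  set.seed(11)
  tr <- random_tree(n_versions = 4L)
  g <- tr$g
  snapA <- g$A; snapJA <- g$JA; snapIA <- g$IA; snapD <- g$D
  reads <- lapply(seq_len(4L), function(d) netvc:::version_adjacency(g, d))
  p <- sample_pairs(n_vertices(g, 4), 5, exclude = oracle_edge_keys(tr$o, 4))
  g2 <- add_version(g, 4, edge_list(p$u, p$v, 1,
                                    n_vertices = n_vertices(g, 4)))
  expect_identical(g2$A[seq_along(snapA)], snapA)
  expect_identical(g2$JA[seq_along(snapJA)], snapJA)
  expect_identical(g2$IA[seq_len(nrow(snapIA)), ], snapIA)
  expect_identical(g2$D[seq_along(snapD)], snapD)
  for (d in seq_len(4L)) {
    expect_identical(netvc:::version_adjacency(g2, d), reads[[d]])
  }
})

test_that("split/join keeps single-vertex storage near the logarithmic bound", {
  # chain of 8 versions, one new neighbor for vertex 1 each time
  build_chain <- function(l, join) {
    g <- create_graph(edge_list(1, 2, 1, n_vertices = l + 1))
    for (d in seq_len(l - 1L)) {
      g <- add_version(g, d, edge_list(1, d + 2L, 1, n_vertices = l + 1),
                       join = join)
    }
    g
  }
  count_row1 <- function(g) {
    tot <- 0
    prev_entries <- character()
    for (d in seq_len(n_versions(g))) {
      e <- decompress_ia(g, d)[1, ]
      key1 <- paste(e[["e0"]], e[["e1"]])
      tot <- tot + if (key1 %in% prev_entries) 0 else e[["e1"]]
      prev_entries <- c(prev_entries, key1)
      if (netvc:::ia_flag(e[["e3"]]) == netvc:::IA_SPLIT) {
        key2 <- paste("s", e[["e2"]], netvc:::ia_payload(e[["e3"]]))
        if (!(key2 %in% prev_entries)) {
          tot <- tot + netvc:::ia_payload(e[["e3"]])
          prev_entries <- c(prev_entries, key2)
        }
      }
    }
    tot
  }
  l <- 8L
  g <- build_chain(l, join = TRUE)
  # every version still reads the correct cumulative adjacency
  for (d in seq_len(l)) {
    expect_equal(neighbors(g, d, 1)$vertex, seq(2L, d + 1L))
  }
  expect_lte(count_row1(g), 4 * l * (1 + log2(l)))
  # never joining must store strictly more for the adversarial vertex
  g_nojoin <- build_chain(l, join = FALSE)
  expect_gt(count_row1(g_nojoin), count_row1(g))
})

test_that("access is depth-independent: at most two JA range reads", {
  set.seed(3)
  # a deep chain; the last version sits at depth 12
  g <- create_graph(edge_list(c(1, 2), c(2, 3), 1, n_vertices = 15))
  o <- oracle_root(edge_list(c(1, 2), c(2, 3), 1, n_vertices = 15))
  for (d in seq_len(12L)) {
    p <- sample_pairs(15, 1, exclude = oracle_edge_keys(o, d))
    el <- edge_list(p$u, p$v, 1, n_vertices = 15)
    g <- add_version(g, d, el)
    o <- oracle_add(o, d, el)
  }
  last <- n_versions(g)
  for (v in seq_len(15L)) {
    deg <- nrow(oracle_neighbors(o, last, v))
    access_counter(g, reset = TRUE)
    nb <- neighbors(g, last, v)
    # reads equal the row's stored entries: one or two contiguous ranges
    expect_equal(access_counter(g), deg)
    expect_equal(nrow(nb), deg)
  }
})

test_that("IA segment compression round-trips and reports its ratio", {
  set.seed(5)
  kf <- netvc:::ia_matrix(12L)
  kf[, "e0"] <- sample(100, 12)
  kf[, "e1"] <- sample(10, 12, replace = TRUE)

  # identical segment: one C entry spanning everything
  out <- compress_ia_segment(kf, kf)
  expect_equal(nrow(out$compressed), 1L)
  expect_equal(out$ratio, 1 / 12)
  expect_equal(unname(netvc:::ia_flag(out$compressed[1, "e3"])), netvc:::IA_COMPRESSED)
  expect_equal(out$compressed[1, c("e0", "e1")], c(e0 = 0, e1 = 12))

  # nothing shared: output equals input
  seg <- kf
  seg[, "e0"] <- seg[, "e0"] + 1000
  out <- compress_ia_segment(seg, kf)
  expect_identical(out$compressed, seg)
  expect_equal(out$ratio, 1)

  # planted shared runs round-trip through decompression
  seg <- kf
  seg[c(3, 7, 8), "e0"] <- seg[c(3, 7, 8), "e0"] + 500
  out <- compress_ia_segment(seg, kf)
  expect_lt(out$ratio, 1)
  rebuilt <- lapply(seq_len(nrow(out$compressed)), function(i) {
    e <- out$compressed[i, ]
    if (netvc:::ia_flag(e[["e3"]]) == netvc:::IA_COMPRESSED) {
      kf[seq.int(e[["e0"]] + 1, length.out = e[["e1"]]), , drop = FALSE]
    } else {
      out$compressed[i, , drop = FALSE]
    }
  })
  expect_equal(do.call(rbind, rebuilt), seg, ignore_attr = TRUE)
})

test_that("decompression of stored versions matches the uncompressed view", {
  set.seed(9)
  tr <- random_tree(n_versions = 6L)
  g <- tr$g
  for (d in seq_len(n_versions(g))) {
    ia <- decompress_ia(g, d)
    expect_true(all(netvc:::ia_flag(ia[, "e3"]) != netvc:::IA_COMPRESSED))
    expect_equal(nrow(ia), n_vertices(g, d))
    # key-frame segments are stored uncompressed
    kf <- g$K[d]
    kf_seg <- g$IA[netvc:::ia_segment_rows(g, kf), , drop = FALSE]
    expect_true(all(netvc:::ia_flag(kf_seg[, "e3"]) != netvc:::IA_COMPRESSED))
  }
})

test_that("storage accounting reflects array reuse across versions", {
  set.seed(13)
  p <- sample_pairs(30, 60)
  el <- edge_list(p$u, p$v, 1, n_vertices = 30)
  g <- create_graph(el)
  st1 <- storage_stats(g)
  expect_equal(st1$lenJA, 120L)
  # identical (empty-delta) children reuse all edge storage
  g <- add_version(g, 1, edge_list(n_vertices = 30))
  g <- add_version(g, 2, edge_list(n_vertices = 30))
  st3 <- storage_stats(g)
  expect_equal(st3$lenJA, st1$lenJA)
  expect_lt(st3$bytesTotal, st3$perVersionSeparateBytes)
})
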