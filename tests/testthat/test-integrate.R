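edge_keys_local <- function(csr) {
  df <- csr_edge_frame(csr)
  paste(pmin(df$source, df$target), pmax(df$source, df$target))
}

oracle_keys <- function(o, d) unique(oracle_edge_keys(o, d))

test_that("extraction reproduces a version's full edge set", {
  # single-version graph: extraction equals the root CSR
  set.seed(21)
  p <- sample_pairs(30, 50)
  el <- edge_list(p$u, p$v, runif(50), n_vertices = 30)
  g <- create_graph(el)
  csr <- extract_version(g, 1)
  expect_equal(csr$JA, g$JA)
  expect_equal(csr$A, g$A)
  expect_equal(diff(csr$IA), as.vector(g$IA[, "e1"]))

  # random 6-version tree: edge-set equality with the cumulative oracle
  tr <- random_tree(n_versions = 6L)
  for (d in seq_len(6L)) {
    got <- csr_edge_frame(extract_version(tr$g, d))
    keys <- paste(pmin(as.integer(got$source), as.integer(got$target)),
                  pmax(as.integer(got$source), as.integer(got$target)),
                  sep = "|")
    expect_setequal(keys, oracle_keys(tr$o, d))
  }
})

test_that("seed reachability pruning keeps exactly one component", {
  # two components: triangle {1,2,3} and edge {4,5}
  g <- create_graph(edge_list(c(1, 1, 2, 4), c(2, 3, 3, 5), 1,
                              n_vertices = 5))
  csr <- extract_version(g, 1, seeds = 4)
  expect_equal(csr$vertex_ids, c(4L, 5L))
  expect_equal(length(csr$JA), 2L)
  expect_error(extract_version(g, 1, seeds = 9), "outside the version")
})

test_that("vertex partition is sound: S_p rows are identical adjacency", {
  set.seed(31)
  # two children that each add edges only to vertex 7
  base <- create_graph(edge_list(c(1, 2, 7), c(2, 3, 1), 1, n_vertices = 8))
  g <- add_version(base, 1, edge_list(7, 4, 1, n_vertices = 8))
  g <- add_version(g, 1, edge_list(7, 5, 1, n_vertices = 8))
  part <- partition_vertices(g, c(2, 3))
  expect_true(all(setdiff(1:8, c(7, 4, 5)) %in% part$S_p))
  expect_true(7 %in% part$S_n)

  # single version: everything is in S_p
  part1 <- partition_vertices(g, 2)
  expect_equal(part1$S_p, 1:8)

  # random siblings: adjacency equality holds for every S_p vertex
  tr <- random_tree(n_versions = 7L)
  sib <- which(tr$g$parent == 1L)[-1L]
  if (length(sib) >= 2L) {
    part <- partition_vertices(tr$g, sib)
    for (v in part$S_p) {
      rows <- lapply(sib, function(d) neighbors(tr$g, d, v))
      for (j in seq_along(rows)[-1L]) expect_identical(rows[[j]], rows[[1L]])
    }
  }
})

test_that("composition equals brute-force edge-set union/intersection", {
  set.seed(55)
  for (rep in 1:4) {
    tr <- random_tree(n_versions = 6L, nv0 = 20L, m0 = 25L, grow_prob = 0)
    kids <- which(tr$g$parent == 1L)[-1L]
    if (length(kids) < 2L) next
    b <- min(length(kids), sample(2:4, 1))
    ids <- kids[seq_len(b)]
    key_sets <- lapply(ids, function(d) oracle_keys(tr$o, d))
    for (mode in c("union", "intersection")) {
      comp <- compose_versions(tr$g, ids, mode = mode)
      want <- Reduce(if (mode == "union") union else intersect, key_sets)
      got <- csr_edge_frame(comp)
      keys <- paste(pmin(as.integer(got$source), as.integer(got$target)),
                    pmax(as.integer(got$source), as.integer(got$target)),
                    sep = "|")
      expect_setequal(keys, want)
    }
  }
})

test_that("union contains intersection and single-id compose extracts", {
  set.seed(60)
  repeat {
    tr <- random_tree(n_versions = 6L, grow_prob = 0)
    kids <- which(tr$g$parent == 1L)[-1L]
    if (length(kids) >= 2L) break
  }
  ids <- kids[1:2]
  un <- edge_keys_local(compose_versions(tr$g, ids, "union"))
  ix <- edge_keys_local(compose_versions(tr$g, ids, "intersection"))
  expect_true(all(ix %in% un))
  one <- compose_versions(tr$g, ids[1])
  expect_identical(one, extract_version(tr$g, ids[1]))
  # composing a version with an identical sibling equals either one
  g2 <- add_version(tr$g, tr$g$parent[ids[1]],
                    edge_list(n_vertices = n_vertices(tr$g, ids[1])))
  # ancestor mixing is refused
  expect_error(compose_versions(tr$g, c(1, ids[1])), "ancestor")
})

test_that("composition is order-invariant and tissue-monotone", {
  fam <- generate_family(k = 4, n_diseases = 10, n_proteins = 50,
                         n_loci = 15, core_edges = 120, residual_edges = 10,
                         eqtl_edges = 15, association_edges = 12, seed = 8)
  built <- build_version_tree(fam)
  meta <- built$meta
  ids <- meta$version[meta$layer == "tissue_ppi"]
  for (mode in c("union", "intersection")) {
    a <- compose_versions(built$graph, ids[1:3], mode)
    b <- compose_versions(built$graph, rev(ids[1:3]), mode)
    expect_identical(a, b)
  }
  # growing T grows unions and shrinks intersections
  u2 <- edge_keys_local(compose_versions(built$graph, ids[1:2], "union"))
  u3 <- edge_keys_local(compose_versions(built$graph, ids[1:3], "union"))
  i2 <- edge_keys_local(compose_versions(built$graph, ids[1:2], "intersection"))
  i3 <- edge_keys_local(compose_versions(built$graph, ids[1:3], "intersection"))
  expect_true(all(u2 %in% u3))
  expect_true(all(i3 %in% i2))
})

test_that("composition touches the edge arrays O(bE) times", {
  fam <- generate_family(k = 3, n_diseases = 10, n_proteins = 60,
                         n_loci = 15, core_edges = 150, residual_edges = 8,
                         eqtl_edges = 15, association_edges = 12, seed = 9)
  built <- build_version_tree(fam)
  g <- built$graph
  ids <- built$meta$version[built$meta$layer == "tissue_ppi"]
  b <- length(ids)
  per_version <- vapply(ids, function(d) {
    ia <- decompress_ia(g, d)
    sum(ia[, "e1"]) + sum(netvc:::ia_payload(ia[, "e3"])[
      netvc:::ia_flag(ia[, "e3"]) == netvc:::IA_SPLIT])
  }, numeric(1))
  access_counter(g, reset = TRUE)
  compose_versions(g, ids, "union")
  reads <- access_counter(g)
  expect_lte(reads, (b + 1) * max(per_version))
  # the S_p optimization reads far less than b full passes
  expect_lt(reads, sum(per_version))
})

test_that("queries resolve to the expected composed networks", {
  fam <- generate_family(k = 3, n_diseases = 12, n_proteins = 50,
                         n_loci = 15, core_edges = 120, residual_edges = 10,
                         eqtl_edges = 15, association_edges = 12, seed = 10)
  built <- build_version_tree(fam)
  g <- built$graph; meta <- built$meta; reg <- built$registry

  # ontology-only query with one disease seed
  sp <- query_spec("GD", seeds = "D0003")
  res <- resolve_query(g, meta, reg, sp)
  expect_true(all(registry_kinds(reg, res$csr$vertex_ids) == "disease"))
  expect_equal(length(res$seeds), 1L)

  # single-tissue union equals plain extraction of that tissue version
  tn <- fam$tissue_names[2]
  sp <- query_spec(c("GD", "GA", "GP"), tissues = tn)
  res <- resolve_query(g, meta, reg, sp)
  vid <- meta$version[meta$layer == "tissue_ppi" & !is.na(meta$tissue) &
                        meta$tissue == tn]
  expect_identical(res$csr, extract_version(g, vid))

  # two-tissue intersection at the eQTL level matches the set oracle
  lab_keys <- function(df) paste(pmin(df$source, df$target),
                                 pmax(df$source, df$target))
  tns <- fam$tissue_names[1:2]
  sp <- query_spec(c("GD", "GA", "GP", "GL"), tissues = tns,
                   mode = "intersection")
  res <- resolve_query(g, meta, reg, sp)
  got <- lab_keys(csr_edge_frame(res$csr, reg))
  leaves <- lapply(tns, function(tn) {
    lab_keys(rbind(fam$ontology, fam$association,
                   fam$tissue_ppi[[tn]],
                   fam$tissue_eqtl[[tn]])[, c("source", "target")])
  })
  expect_setequal(got, Reduce(intersect, leaves))

  # invalid specifications
  expect_error(query_spec(c("GD", "GP")), "induce a path")
  expect_error(query_spec(c("GD", "GA", "GP", "GL")),
               "requires at least one tissue")
  expect_error(resolve_query(g, meta, reg, query_spec("GD", seeds = "nope")),
               "unknown vertex label")
  expect_error(resolve_query(g, meta, reg,
                             query_spec(c("GD", "GA", "GP"),
                                        tissues = "kidney")),
               "unknown tissue")
})
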