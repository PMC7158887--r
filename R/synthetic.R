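# Deterministic generators for layered tissue-specific network families.
# Everything is a pure function of its parameters: the RNG state is
# localized, so the same seed always yields byte-identical layers.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Sample `m` distinct unordered pairs (as a 2-column label matrix) from the
# cross space of `a` x `b` labels (bipartite) or within `a` (unipartite,
# no self-pairs), excluding `exclude` pair keys.
sample_label_pairs <- function(a, b = NULL, m, exclude = character()) {
  bipartite <- !is.null(b)
  total <- if (bipartite) length(a) * length(b)
           else length(a) * (length(a) - 1) / 2
  if (m > total - length(exclude)) {
    stop(sprintf("infeasible edge count: %d requested, %d pairs available",
                 m, total - length(exclude)), call. = FALSE)
  }
  picked <- character(0)
  out_u <- character(0); out_v <- character(0)
  # rejection sampling with a deterministic widening batch size
  need <- m
  while (need > 0L) {
    take <- max(need * 2L, 16L)
    if (bipartite) {
      u <- a[sample.int(length(a), take, replace = TRUE)]
      v <- b[sample.int(length(b), take, replace = TRUE)]
    } else {
      i <- sample.int(length(a), take, replace = TRUE)
      j <- sample.int(length(a) - 1L, take, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      u <- a[pmin(i, j)]; v <- a[pmax(i, j)]
    }
    key <- paste(pmin(u, v), pmax(u, v), sep = "\r")
    fresh <- !(key %in% c(exclude, picked)) & !duplicated(key)
    u <- u[fresh]; v <- v[fresh]; key <- key[fresh]
    n_take <- min(length(key), need)
    if (n_take > 0L) {
      sel <- seq_len(n_take)
      out_u <- c(out_u, u[sel]); out_v <- c(out_v, v[sel])
      picked <- c(picked, key[sel])
      need <- need - n_take
    }
  }
  data.frame(source = out_u, target = out_v, stringsAsFactors = FALSE)
}

#' Generate a synthetic layered tissue-specific network family
#'
#' Emulates the structural regime of real heterogeneous tissue atlases:
#' a rooted disease-ontology tree, a bipartite protein--disease association
#' layer, `k` tissue-specific PPI networks that share a large common core
#' plus a small per-tissue residual (by default the residual is 2% of the
#' core, mirroring the low per-tissue uniqueness of curated interactomes),
#' and `k` bipartite locus--protein eQTL layers.  Residual edges are drawn
#' partly from a pool shared between tissues, so an edge missing from the
#' core can still occur in several tissues, and partly from tissue-private
#' candidates.
#'
#' Generation is a pure function of the parameters: the same `seed` always
#' produces identical layers, and the caller's RNG state is untouched.
#'
#' @param k Number of tissues.
#' @param n_diseases,n_proteins,n_loci Vertex-set sizes per kind.
#' @param core_edges Number of PPI edges shared by every tissue.
#' @param residual_edges Number of extra PPI edges per tissue.
#' @param overlap_across_tissues Probability that a residual edge is drawn
#'   from the shared pool rather than the tissue-private candidates.
#' @param eqtl_edges Number of locus--protein edges per tissue.
#' @param association_edges Number of protein--disease association edges.
#' @param ontology_branching Branching factor of the disease-ontology tree.
#' @param seed Integer RNG seed.
#' @return A [layered_inputs()] bundle.
#' @examples
#' fam <- generate_family(k = 2, n_proteins = 40, n_diseases = 10,
#'                        n_loci = 12, core_edges = 60, residual_edges = 6,
#'                        eqtl_edges = 8, association_edges = 10, seed = 1)
#' @export
generate_family <- function(k = 4, n_diseases = 40, n_proteins = 200,
                            n_loci = 60, core_edges = 600,
                            residual_edges = 12,
                            overlap_across_tissues = 0.25,
                            eqtl_edges = 30, association_edges = 50,
                            ontology_branching = 3, seed = 1) {
  stopifnot(k >= 1, n_diseases >= 2, n_proteins >= 2, n_loci >= 1,
            core_edges >= 0, residual_edges >= 0, eqtl_edges >= 0,
            association_edges >= 0, ontology_branching >= 1,
            overlap_across_tissues >= 0, overlap_across_tissues <= 1)
  with_seed(seed, {
    diseases <- sprintf("D%04d", seq_len(n_diseases))
    proteins <- sprintf("P%05d", seq_len(n_proteins))
    loci <- sprintf("L%05d", seq_len(n_loci))
    tissues <- sprintf("tissue%02d", seq_len(k))

    # rooted ontology: node i attaches to ceiling((i - 1) / b), so deeper
    # vertices represent more specific phenotypes
    child <- seq(2L, n_diseases)
    parent <- pmax(1L, ceiling((child - 1L) / ontology_branching))
    ontology <- data.frame(source = diseases[parent],
                           target = diseases[child],
                           weight = 1, stringsAsFactors = FALSE)

    # one disjoint draw covers core, shared pool and per-tissue reserves,
    # with one weight per candidate edge so tissues agree on shared edges
    pool_size <- max(residual_edges, ceiling(residual_edges * k / 2))
    n_cand <- core_edges + pool_size + k * residual_edges
    cand <- sample_label_pairs(proteins, m = n_cand)
    cand$weight <- round(stats::runif(n_cand, 0.5, 1.5), 6)
    core <- cand[seq_len(core_edges), , drop = FALSE]
    pool <- cand[core_edges + seq_len(pool_size), , drop = FALSE]
    reserve <- cand[core_edges + pool_size + seq_len(k * residual_edges), ,
                    drop = FALSE]

    tissue_ppi <- list()
    for (i in seq_len(k)) {
      shared_n <- stats::rbinom(1L, residual_edges, overlap_across_tissues)
      shared <- pool[sample.int(nrow(pool), shared_n), , drop = FALSE]
      priv <- reserve[(i - 1L) * residual_edges + seq_len(residual_edges - shared_n), ,
                      drop = FALSE]
      tissue_ppi[[tissues[i]]] <- rbind(core, shared, priv)
    }

    # associations and eQTLs attach to proteins that occur in PPI layers,
    # since the protein vertex set is defined as the PPI union
    ppi_proteins <- sort(unique(unlist(lapply(tissue_ppi, function(df) {
      c(df$source, df$target)
    }), use.names = FALSE)))
    association <- sample_label_pairs(ppi_proteins, diseases,
                                      association_edges)
    association$weight <- 1

    tissue_eqtl <- list()
    for (i in seq_len(k)) {
      eq <- sample_label_pairs(loci, ppi_proteins, eqtl_edges)
      eq$weight <- round(stats::runif(eqtl_edges, 0.5, 1.5), 6)
      tissue_eqtl[[tissues[i]]] <- eq
    }

    layered_inputs(ontology, association, tissue_ppi, tissue_eqtl)
  })
}

#' A tiny hand-built two-version graph
#'
#' Five vertices; version 1 is the 4-edge network
#' `{(1,2), (1,3), (2,3), (3,4)}` and version 2 adds the single edge
#' `(2,5)`.  The fixture exercises the normal-to-split row transition and
#' the per-version IA segment layout, and is small enough to inspect by
#' hand.
#'
#' @param h Key-frame threshold, handed to [create_graph()].
#' @return A `versioned_csr` with two versions.
#' @examples
#' g <- two_version_fixture()
#' neighbors(g, 2, 2)
#' @export
two_version_fixture <- function(h = 0.5) {
  g <- create_graph(edge_list(c(1, 1, 2, 3), c(2, 3, 3, 4), 1,
                              n_vertices = 5), h = h)
  add_version(g, 1, edge_list(2, 5, 1, n_vertices = 5))
}
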