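# Label-level edge frames -------------------------------------------------

#' Canonicalize a label-level edge frame
#'
#' Layer inputs arrive as data frames with character columns `source`,
#' `target` and a numeric `weight`.  Canonicalization sorts by unordered
#' pair, collapses exact duplicate pairs (warning when weights agree,
#' error otherwise) and fills a missing weight column with 1.
#'
#' @param df A data.frame with at least `source` and `target` columns.
#' @return A canonical data.frame with columns `source`, `target`,
#'   `weight`.
#' @export
edge_frame <- function(df) {
  if (!all(c("source", "target") %in% names(df))) {
    stop("edge frame needs `source` and `target` columns", call. = FALSE)
  }
  src <- as.character(df$source)
  tgt <- as.character(df$target)
  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else rep(1, length(src))
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("edge weights must be finite and non-negative", call. = FALSE)
  }
  key <- paste(pmin(src, tgt), pmax(src, tgt), sep = "\r")
  if (anyDuplicated(key)) {
    split_w <- split(w, key)
    bad <- names(split_w)[vapply(split_w, function(x) length(unique(x)) > 1L,
                                 logical(1))]
    if (length(bad)) {
      pr <- strsplit(bad[1L], "\r", fixed = TRUE)[[1L]]
      stop(sprintf("duplicate edge (%s, %s) with conflicting weights",
                   pr[1L], pr[2L]), call. = FALSE)
    }
    warning(sprintf("%d duplicate edge(s) collapsed",
                    sum(duplicated(key))), call. = FALSE)
    keep <- !duplicated(key)
    src <- src[keep]; tgt <- tgt[keep]; w <- w[keep]; key <- key[keep]
  }
  ord <- order(key)
  data.frame(source = src[ord], target = tgt[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

frame_keys <- function(df) {
  paste(pmin(df$source, df$target), pmax(df$source, df$target), sep = "\r")
}

# Layered inputs ------------------------------------------------------------

#' Bundle the layers of a heterogeneous tissue-specific network family
#'
#' Collects the per-layer edge frames that the version-tree builder
#' consumes: a disease-ontology layer, a gene--disease association layer,
#' `k` tissue-specific PPI layers and `k` tissue-specific bipartite eQTL
#' layers.  Tissues are ordered by sorted name so version numbering is
#' deterministic.
#'
#' @param ontology Edge frame of disease--disease ontology relations.
#' @param association Edge frame of protein--disease associations.
#' @param tissue_ppi Named list (by tissue) of PPI edge frames.
#' @param tissue_eqtl Named list (by tissue) of locus--protein eQTL edge
#'   frames; names must match `tissue_ppi`.
#' @return An object of class `layered_inputs`.
#' @export
layered_inputs <- function(ontology, association, tissue_ppi, tissue_eqtl) {
  if (length(tissue_ppi) < 1L) {
    stop("at least one tissue-specific PPI network is required", call. = FALSE)
  }
  nms <- names(tissue_ppi)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("`tissue_ppi` must be a uniquely named list", call. = FALSE)
  }
  if (!setequal(nms, names(tissue_eqtl))) {
    stop("`tissue_eqtl` names must match `tissue_ppi` names", call. = FALSE)
  }
  ord <- order(nms)
  structure(list(
    ontology = edge_frame(ontology),
    association = edge_frame(association),
    tissue_ppi = lapply(tissue_ppi[ord], edge_frame),
    tissue_eqtl = lapply(tissue_eqtl[nms[ord]], edge_frame),
    tissue_names = nms[ord]
  ), class = "layered_inputs")
}

#' @export
print.layered_inputs <- function(x, ...) {
  cat(sprintf(
    "<layered_inputs> %d tissues; ontology %d edges, associations %d edges\n",
    length(x$tissue_names), nrow(x$ontology), nrow(x$association)))
  invisible(x)
}

# Core / residual decomposition ---------------------------------------------

#' Split tissue-specific PPI layers into a shared core and residuals
#'
#' The generic PPI core is the edge-set intersection over all `k`
#' tissue-specific PPI networks; each tissue's residual is its edge set
#' minus the core, so core plus residual reproduces every input layer
#' exactly.  Core edge weights are taken from the first tissue carrying
#' them (layers sharing an edge are expected to agree on its weight).
#'
#' @param tissue_ppi List of `k >= 1` canonical edge frames.
#' @return A list with `core` (edge frame) and `residuals` (list of edge
#'   frames parallel to the input).
#' @examples
#' a <- edge_frame(data.frame(source = c("p1", "p2"), target = c("p2", "p3")))
#' b <- edge_frame(data.frame(source = "p1", target = "p2"))
#' compute_generic_core(list(t1 = a, t2 = b))
#' @export
compute_generic_core <- function(tissue_ppi) {
  if (length(tissue_ppi) < 1L) {
    stop("need at least one tissue-specific network", call. = FALSE)
  }
  tissue_ppi <- lapply(tissue_ppi, edge_frame)
  keys <- lapply(tissue_ppi, frame_keys)
  core_keys <- Reduce(intersect, keys)
  core <- tissue_ppi[[1L]][keys[[1L]] %in% core_keys, , drop = FALSE]
  rownames(core) <- NULL
  residuals <- Map(function(df, k) {
    out <- df[!(k %in% core_keys), , drop = FALSE]
    rownames(out) <- NULL
    out
  }, tissue_ppi, keys)
  list(core = core, residuals = residuals)
}

# Version-tree assembly -----------------------------------------------------

layer_to_edge_list <- function(df, reg, n_vertices) {
  edge_list(registry_index(reg, df$source), registry_index(reg, df$target),
            df$weight, n_vertices = n_vertices)
}

check_bipartite <- function(df, reg, kinds_a, kinds_b, layer) {
  ka <- registry_kinds(reg, registry_index(reg, df$source, strict = FALSE))
  kb <- registry_kinds(reg, registry_index(reg, df$target, strict = FALSE))
  ok <- (ka %in% kinds_a & kb %in% kinds_b) | (ka %in% kinds_b & kb %in% kinds_a)
  if (any(!ok | is.na(ok))) {
    i <- which(!ok | is.na(ok))[1L]
    stop(sprintf("%s edge (%s, %s) does not connect %s and %s vertices",
                 layer, df$source[i], df$target[i],
                 paste(kinds_a, collapse = "/"), paste(kinds_b, collapse = "/")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the heterogeneous version tree from layered inputs
#'
#' Assembles the canonical tree: the root holds the disease ontology,
#' its child adds gene--disease associations, the next version adds the
#' generic PPI core (the intersection of all tissue-specific PPI layers),
#' one branch per tissue adds that tissue's residual PPI edges, and each
#' tissue branch gains a leaf adding the tissue's eQTL layer --
#' `3 + 2k` versions for `k` tissues.  Every tissue-PPI version therefore
#' reproduces ontology + associations + that tissue's full PPI network,
#' and every leaf additionally carries the tissue's eQTL edges.
#'
#' Disease labels are those of the ontology layer; protein labels are the
#' union of the PPI layers; locus labels are whatever eQTL endpoints are
#' neither.  Association edges must connect a protein and a disease, eQTL
#' edges a locus and a protein; anything else is a layer-typing error.
#'
#' @param inputs A [layered_inputs()] bundle.
#' @param registry Optional pre-filled [vertex_registry()]; created when
#'   omitted.
#' @param h Key-frame threshold handed to [create_graph()].
#' @return A list with `graph` (`versioned_csr`), `meta` (data.frame of
#'   per-version label, layer type and tissue) and `registry`.
#' @export
build_version_tree <- function(inputs, registry = NULL, h = 0.5) {
  if (!inherits(inputs, "layered_inputs")) {
    stop("`inputs` must be a `layered_inputs` object", call. = FALSE)
  }
  reg <- if (is.null(registry)) vertex_registry() else registry
  k <- length(inputs$tissue_names)

  disease_labels <- sort(unique(c(inputs$ontology$source,
                                  inputs$ontology$target)))
  registry_add(reg, disease_labels, "disease")
  protein_labels <- sort(unique(unlist(lapply(inputs$tissue_ppi, function(df) {
    c(df$source, df$target)
  }), use.names = FALSE)))
  protein_labels <- setdiff(protein_labels, disease_labels)
  registry_add(reg, protein_labels, "protein")

  check_bipartite(inputs$association, reg, "protein", "disease", "association")
  locus_labels <- sort(unique(unlist(lapply(inputs$tissue_eqtl, function(df) {
    setdiff(c(df$source, df$target), c(disease_labels, protein_labels))
  }), use.names = FALSE)))
  registry_add(reg, locus_labels, "locus")
  for (tn in inputs$tissue_names) {
    check_bipartite(inputs$tissue_eqtl[[tn]], reg, "locus", "protein",
                    sprintf("eQTL (%s)", tn))
  }

  nv_dis <- length(disease_labels)
  nv_prot <- nv_dis + length(protein_labels)
  nv_all <- registry_size(reg)

  dec <- compute_generic_core(inputs$tissue_ppi)

  g <- create_graph(layer_to_edge_list(inputs$ontology, reg, nv_dis), h = h)
  meta <- data.frame(version = 1L, label = "ontology", layer = "ontology",
                     tissue = NA_character_, stringsAsFactors = FALSE)
  g <- add_version(g, 1L, layer_to_edge_list(inputs$association, reg, nv_prot))
  meta <- rbind(meta, data.frame(version = 2L, label = "association",
                                 layer = "association", tissue = NA_character_))
  g <- add_version(g, 2L, layer_to_edge_list(dec$core, reg, nv_prot))
  meta <- rbind(meta, data.frame(version = 3L, label = "generic_ppi",
                                 layer = "generic_ppi", tissue = NA_character_))
  for (i in seq_len(k)) {
    tn <- inputs$tissue_names[i]
    g <- add_version(g, 3L, layer_to_edge_list(dec$residuals[[i]], reg, nv_prot))
    meta <- rbind(meta, data.frame(
      version = 3L + i, label = sprintf("ppi_%s", tn),
      layer = "tissue_ppi", tissue = tn))
  }
  for (i in seq_len(k)) {
    tn <- inputs$tissue_names[i]
    g <- add_version(g, 3L + i,
                     layer_to_edge_list(inputs$tissue_eqtl[[tn]], reg, nv_all))
    meta <- rbind(meta, data.frame(
      version = 3L + k + i, label = sprintf("eqtl_%s", tn),
      layer = "tissue_eqtl", tissue = tn))
  }
  rownames(meta) <- NULL
  list(graph = g, meta = meta, registry = reg)
}
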