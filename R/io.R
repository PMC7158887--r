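# Plain-text edge-list input, the binary container and result output.

#' Read a tab-separated edge list
#'
#' Accepts the common plain-text interchange form: one edge per line,
#' `source<TAB>target[<TAB>weight]`, UTF-8, `#` comment lines and blank
#' lines skipped, an optional header row (detected by a non-numeric third
#' field), missing weights defaulting to 1.  Duplicate unordered pairs are
#' collapsed with a warning when their weights agree and rejected
#' otherwise.
#'
#' @param path File path.
#' @return A canonical edge frame (see [edge_frame()]).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("edge list file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    return(edge_frame(data.frame(source = character(),
                                 target = character(), weight = numeric())))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop(sprintf("malformed line %d in %s: need at least 2 tab-separated fields",
                 keep[which(nf < 2L)[1L]], path), call. = FALSE)
  }
  first <- parts[[1L]]
  w1 <- suppressWarnings(as.numeric(first[3L]))
  is_header <- (length(first) >= 3L && is.na(w1) && !is.nan(w1)) ||
    identical(tolower(first[1:2]), c("source", "target"))
  if (is_header) {
    parts <- parts[-1L]
    keep <- keep[-1L]
    if (!length(parts)) {
      return(edge_frame(data.frame(source = character(),
                                   target = character(),
                                   weight = numeric())))
    }
  }
  src <- vapply(parts, `[[`, character(1), 1L)
  tgt <- vapply(parts, `[[`, character(1), 2L)
  wraw <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "1",
                 character(1))
  w <- suppressWarnings(as.numeric(wraw))
  if (anyNA(w) || any(!is.finite(w))) {
    stop(sprintf("malformed weight on line %d in %s: '%s'",
                 keep[which(is.na(w) | !is.finite(w))[1L]], path,
                 wraw[which(is.na(w) | !is.finite(w))[1L]]), call. = FALSE)
  }
  if (any(w < 0)) {
    stop(sprintf("negative weight on line %d in %s",
                 keep[which(w < 0)[1L]], path), call. = FALSE)
  }
  edge_frame(data.frame(source = src, target = tgt, weight = w,
                        stringsAsFactors = FALSE))
}

#' Write an edge frame as a tab-separated file
#'
#' @param df An edge frame (`source`, `target`, `weight`).
#' @param path Output file path.
#' @param header Write a header row (default `TRUE`).
#' @return (Invisibly) `path`.
#' @export
write_edge_list <- function(df, path, header = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

# Manifest ------------------------------------------------------------------

#' Read layered inputs described by a JSON manifest
#'
#' The manifest maps layer roles to edge-list files:
#' ```json
#' {"ontology": "gd.tsv", "association": "ga.tsv",
#'  "tissues": [{"name": "liver", "ppi": "liver_ppi.tsv",
#'               "eqtl": "liver_eqtl.tsv"}],
#'  "h": 0.5}
#' ```
#' Relative paths resolve against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A list with `inputs` ([layered_inputs()]) and `h`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("ontology", "association", "tissues")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop(sprintf("manifest is missing required field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  tissue_ppi <- list(); tissue_eqtl <- list()
  for (t in m$tissues) {
    tissue_ppi[[t$name]] <- read_edge_list(resolve(t$ppi))
    tissue_eqtl[[t$name]] <- read_edge_list(resolve(t$eqtl))
  }
  inputs <- layered_inputs(read_edge_list(resolve(m$ontology)),
                           read_edge_list(resolve(m$association)),
                           tissue_ppi, tissue_eqtl)
  list(inputs = inputs, h = if (is.null(m$h)) 0.5 else as.numeric(m$h))
}

# Binary container ----------------------------------------------------------
#
# Layout (little-endian throughout):
#   bytes 0..3   magic "VCSR" (ASCII)
#   u64          container format version (currently 1)
#   u64 x 4      nVersions, len(A), len(JA), len(IA)
#   f64 x len(A)         edge weights A
#   u64 x len(JA)        column indices JA (1-based vertex ids)
#   u64 x 4*len(IA)      augmented IA entries, row-major (e0, e1, e2, e3)
#   u64 x nVersions+1    D   (0-based IA segment offsets)
#   u64 x nVersions      K   (key-frame version per version)
#   u64 x nVersions      parent
#   u64 x nVersions      nVertices
#   f64          key-frame threshold h
# A JSON sidecar at "<path>.meta.json" carries version labels/layers and
# the vertex registry.

write_u64 <- function(con, x) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 2^53)) {
    stop("u64 field out of the exactly representable range", call. = FALSE)
  }
  lo <- x %% 2^32
  hi <- x %/% 2^32
  lo <- ifelse(lo >= 2^31, lo - 2^32, lo)
  hi <- ifelse(hi >= 2^31, hi - 2^32, hi)
  v <- as.integer(as.vector(rbind(lo, hi)))
  writeBin(v, con, size = 4L, endian = "little")
}

read_u64 <- function(con, n) {
  if (n == 0L) return(numeric())
  v <- readBin(con, "integer", n * 2L, size = 4L, endian = "little")
  if (length(v) != n * 2L) {
    stop("truncated container: unexpected end of file", call. = FALSE)
  }
  lo <- as.numeric(v[seq.int(1L, 2L * n, 2L)])
  hi <- as.numeric(v[seq.int(2L, 2L * n, 2L)])
  lo <- ifelse(lo < 0, lo + 2^32, lo)
  hi <- ifelse(hi < 0, hi + 2^32, hi)
  hi * 2^32 + lo
}

#' Save and load a versioned graph
#'
#' `save_graph()` writes the binary container (documented in the package
#' source) plus a JSON sidecar `<path>.meta.json` with the version
#' metadata and the vertex registry; `load_graph()` reverses it,
#' reproducing every array bit-exactly.
#'
#' @param g A `versioned_csr`.
#' @param path Container file path.
#' @param meta Optional version metadata data.frame (from
#'   [build_version_tree()]).
#' @param registry Optional [vertex_registry()].
#' @return `save_graph()`: (invisibly) `path`.  `load_graph()`: a list
#'   with `graph`, `meta` (or `NULL`) and `registry` (or `NULL`).
#' @export
save_graph <- function(g, path, meta = NULL, registry = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VCSR"), con)
  write_u64(con, 1)
  nver <- n_versions(g)
  write_u64(con, c(nver, length(g$A), length(g$JA), nrow(g$IA)))
  writeBin(as.numeric(g$A), con, size = 8L, endian = "little")
  write_u64(con, g$JA)
  write_u64(con, as.vector(t(g$IA)))
  write_u64(con, g$D)
  write_u64(con, g$K)
  write_u64(con, g$parent)
  write_u64(con, g$n_vertices)
  writeBin(as.numeric(g$h), con, size = 8L, endian = "little")
  side <- list(
    meta = meta,
    labels = if (is.null(registry)) NULL else registry_labels(registry),
    kinds = if (is.null(registry)) NULL else registry_kinds(registry)
  )
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("container not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "VCSR")) {
    stop("not a VCSR container: bad magic", call. = FALSE)
  }
  fmt <- read_u64(con, 1L)
  if (fmt != 1) {
    stop(sprintf("unsupported container format version %d", fmt),
         call. = FALSE)
  }
  hdr <- read_u64(con, 4L)
  nver <- hdr[1L]; lenA <- hdr[2L]; lenJA <- hdr[3L]; lenIA <- hdr[4L]
  A <- readBin(con, "numeric", lenA, size = 8L, endian = "little")
  if (length(A) != lenA) stop("truncated container", call. = FALSE)
  JA <- as.integer(read_u64(con, lenJA))
  IA <- matrix(read_u64(con, 4 * lenIA), ncol = 4L, byrow = TRUE,
               dimnames = list(NULL, c("e0", "e1", "e2", "e3")))
  D <- read_u64(con, nver + 1)
  K <- as.integer(read_u64(con, nver))
  parent <- as.integer(read_u64(con, nver))
  nv <- as.integer(read_u64(con, nver))
  h <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  g <- structure(list(A = A, JA = JA, IA = IA, D = D, K = K,
                      parent = parent, n_vertices = nv, h = h,
                      counters = new.env(parent = emptyenv())),
                 class = "versioned_csr")
  g$counters$ja_reads <- 0
  meta <- NULL; registry <- NULL
  side_path <- paste0(path, ".meta.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$meta) && length(side$meta)) {
      meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
      meta$version <- as.integer(meta$version)
      if (!"tissue" %in% names(meta)) meta$tissue <- NA_character_
      meta$tissue <- as.character(meta$tissue)
    }
    if (!is.null(side$labels) && length(side$labels)) {
      registry <- vertex_registry()
      labs <- as.character(side$labels)
      kds <- as.character(side$kinds)
      runs <- rle(kds)   # add in original order, one run of equal kind at a time
      pos <- 1L
      for (j in seq_along(runs$lengths)) {
        idx <- seq.int(pos, length.out = runs$lengths[j])
        registry_add(registry, labs[idx], runs$values[j])
        pos <- pos + runs$lengths[j]
      }
    }
  }
  list(graph = g, meta = meta, registry = registry)
}

#' Write a proximity ranking as TSV
#'
#' Columns `label`, `kind`, `score` (at least 12 significant digits) and
#' `rank`.
#'
#' @param ranking Ranking data.frame from [rank_vertices()].
#' @param path Output path.
#' @return (Invisibly) `path`.
#' @export
write_ranking <- function(ranking, path) {
  out <- ranking
  out$score <- formatC(out$score, digits = 15, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
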