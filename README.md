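# netvc

Versioned storage, composition and proximity querying of context-specific
biological networks in R.

## What problem it solves

Tissue-specific interactomes are families of heavily overlapping networks:
every tissue's protein–protein interaction (PPI) map shares most of its
edges with every other tissue's, all of them sit on a common disease
ontology and gene–disease association scaffold, and each tissue adds its
own eQTL (locus→gene) layer. Anyone building a network query service over
such a family faces two costs at once — storing many near-identical
networks, and materializing, at query time, whichever combination of them
(one tissue, a union over several, an intersection) the user asks for.

netvc stores the whole family in a single version-tree extension of the
compressed sparse row (CSR) format. Each version is the cumulative union
of edge batches along its root-to-node path; ancestral edge arrays are
shared, descendants only append. Per-version row descriptors are 4-tuples
typed *normal* (one JA range), *split* (two ranges, merged on read — so
row access never depends on tree depth), or *compressed row set*
(a pointer to a run of identical entries in a key-frame segment). A
split/join rule bounds the duplication caused by repeated edge additions
to `O(r log l)` per vertex over an `l`-version chain, and key-framing
(threshold `h`) keeps row-descriptor decompression single-hop.

Any stored version, or a query-time union/intersection over tissues, can
be extracted as a standard CSR network and queried with
random-walk-with-restart (RWR) proximity

```
x = (1 − α) W x + α r
```

with column-stochastic `W`, restart vector `r` over the seed set and
restart probability `α`. Two solvers are provided: plain power iteration
(error factor `1 − α` per step) and a Chebyshev semi-iteration whose
guaranteed factor `μ = 2(1−α) / (2 + √(2α − α²))` is strictly smaller —
about a 5× iteration advantage at `α = 0.05` on slow-mixing graphs.

## Worked example

```r
library(netvc)

# a synthetic 3-tissue family: ontology + associations + shared PPI core
# + per-tissue residual PPI and eQTL layers
fam   <- generate_family(k = 3, n_diseases = 20, n_proteins = 100,
                         n_loci = 30, core_edges = 300, residual_edges = 8,
                         eqtl_edges = 20, association_edges = 25, seed = 42)
built <- build_version_tree(fam)
built$graph
#> <versioned_csr> 9 version(s), 149 vertices in latest, h = 0.5
#>   A/JA length 974, IA entries 796, 41360 bytes (separate CSR storage: 91136 bytes)

head(built$meta)
#>   version        label       layer   tissue
#> 1       1     ontology    ontology     <NA>
#> 2       2  association association     <NA>
#> 3       3  generic_ppi generic_ppi     <NA>
#> 4       4 ppi_tissue01  tissue_ppi tissue01
#> 5       5 ppi_tissue02  tissue_ppi tissue02
#> 6       6 ppi_tissue03  tissue_ppi tissue03

# which diseases are closest to disease D0005, walking over the union of
# two tissues' PPI + eQTL networks?
sp  <- query_spec(c("GD", "GA", "GP", "GL"),
                  tissues = c("tissue01", "tissue02"),
                  mode = "union", seeds = "D0005")
out <- proximity_query(built$graph, built$meta, built$registry, sp,
                       alpha = 0.2, kinds = "disease")
out$proximity
#> <proximity_vector> chebyshev, 41 iteration(s), residual 9.215e-13
head(out$ranking, 5)
#>   label    kind      score rank
#> 1 D0005 disease 0.27360112    1
#> 2 D0002 disease 0.04045096    2
#> 3 D0016 disease 0.03499951    3
#> 4 D0015 disease 0.03320196    4
#> 5 D0014 disease 0.03126870    5
```

The seed ranks first (27% of the walk's mass under this fairly localized
`α`), followed by the ontology neighbours and the diseases reachable
through shared associated proteins. Storing the nine versions in one
structure takes 2.2× less space than nine separate CSR matrices here; the
advantage grows with the number of tissues and the size of the shared
core.

The same operations are available from a shell through `exec/netvc`
(subcommands `generate`, `build`, `add-version`, `extract`, `compose`,
`query`, `stats`); plain-text inputs are tab-separated edge lists plus a
JSON manifest, and built trees are saved in a small binary container
(byte layout documented in `R/io.R`) with a JSON sidecar for labels and
version metadata.

## Package layout

- `R/vcsr-core.R` — the versioned CSR structure: `create_graph()`,
  `add_version()`, `neighbors()`, `decompress_ia()`,
  `compress_ia_segment()`, `storage_stats()`
- `R/builder.R` — `compute_generic_core()`, `build_version_tree()`
- `R/integrate.R` — `extract_version()`, `partition_vertices()`,
  `compose_versions()`, `query_spec()`, `resolve_query()`
- `R/proximity.R` — `column_stochastic()`, `rwr_power()`,
  `rwr_chebyshev()`, `convergence_factor()`, `rank_vertices()`,
  `proximity_query()`
- `R/synthetic.R` — `generate_family()`, `two_version_fixture()`
- `R/io.R`, `R/cli.R`, `exec/netvc` — edge-list/manifest I/O, the binary
  container, the command-line interface
- `vignettes/versioned-networks.Rmd` — the methods vignette: data
  structure, query model, solvers, generator design and limitations
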