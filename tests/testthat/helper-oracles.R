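# Shared fixtures and independent oracles used across the suite.

# Hand-built five-domain tree used in worked examples.
toy_tree <- function() {
  read_lineage_table(c(
    "lineage",
    "root;cellular organisms;Bacteria;Proteobacteria;Escherichia coli",
    "root;cellular organisms;Bacteria;Proteobacteria;Salmonella enterica",
    "root;cellular organisms;Eukaryota;Fungi;Saccharomyces cerevisiae",
    "root;cellular organisms;Eukaryota;Metazoa",
    "root;cellular organisms;Archaea"))
}

# Brute-force ancestor-or-self set by naive parent chasing.
brute_ancestors <- function(tree, taxon) {
  out <- taxon
  while (taxon != tree$root) {
    taxon <- tree$parent[[taxon]]
    out <- c(out, taxon)
  }
  out
}

# Brute-force LCA: intersect ancestor-or-self sets, take the deepest.
brute_lca <- function(tree, taxa) {
  common <- Reduce(intersect, lapply(taxa, brute_ancestors, tree = tree))
  common[which.max(tree$depth[common])]
}

# Graph-search oracle for signed WTD built on igraph: shortest path on the
# undirected tree, depths from igraph distances, sign from root-path
# membership. Independent of the package's chain arithmetic.
igraph_wtd <- function(tree, expected, observed, weight_base = 2) {
  edges <- cbind(tree$parent[tree$nodes != tree$root],
                 tree$nodes[tree$nodes != tree$root])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (expected == observed) return(0)
  depth_of <- function(v) {
    as.numeric(igraph::distances(g, v = tree$root, to = v))
  }
  path <- igraph::shortest_paths(g, from = expected, to = observed)$vpath[[1]]
  nodes <- names(path)
  mag <- 0
  for (i in seq_len(length(nodes) - 1L)) {
    d <- min(depth_of(nodes[[i]]), depth_of(nodes[[i + 1L]]))
    mag <- mag + weight_base^(-d)
  }
  on_root_path <- expected %in% names(
    igraph::shortest_paths(g, from = tree$root, to = observed)$vpath[[1]])
  if (on_root_path) mag else -mag
}

# Oracle for the pathway-level selection rule, driven by igraph_wtd.
igraph_pathway_wtd <- function(tree, range, observed, weight_base = 2) {
  d <- vapply(range, igraph_wtd, numeric(1), tree = tree,
              observed = observed, weight_base = weight_base)
  if (any(d >= 0)) min(d[d >= 0]) else max(d)
}

# Sort-free classification oracle: class from the count of strictly smaller
# scored distances.
oracle_classes <- function(v) {
  n <- length(v)
  vapply(v, function(x) {
    r <- sum(v < x)
    if (r < floor(n / 4)) "High"
    else if (r < floor(n / 2)) "Medium"
    else "Low"
  }, character(1))
}

random_tree <- function(seed, n_leaves = 40, max_depth = 8) {
  make_taxonomy(seed, n_leaves, max_depth)
}

random_subset <- function(universe, p = 0.5) {
  universe[stats::runif(length(universe)) < p]
}
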