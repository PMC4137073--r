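# Taxonomic hierarchy model: a rooted tree with parent links, used as the
# substrate for lowest-common-ancestor queries and depth-weighted paths.

#' Construct a taxonomy tree
#'
#' A `taxonomy_tree` is a rooted tree over taxon identifiers with parent
#' links (the root is its own parent), display names, and optional rank
#' labels. It is the substrate for depth, ancestry, LCA and path queries.
#'
#' @param parent Named character vector mapping each taxon identifier to its
#'   parent identifier. Exactly one entry must map to itself (the root).
#' @param name Named character vector of display labels per identifier.
#'   Defaults to the identifiers themselves.
#' @param rank Named character vector of rank labels (e.g. `"genus"`);
#'   missing entries default to `"no rank"`.
#' @param synonyms Optional named character vector mapping alternative labels
#'   to taxon identifiers, consulted after primary names during resolution.
#' @return An object of class `taxonomy_tree` with precomputed node depths.
#' @export
taxonomy_tree <- function(parent, name = NULL, rank = NULL, synonyms = NULL) {
  ids <- names(parent)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop_schema("parent map must be a fully named character vector")
  }
  if (anyDuplicated(ids)) stop_schema("duplicate taxon identifiers in parent map")
  parent <- as.character(parent)
  names(parent) <- ids
  unknown <- setdiff(parent, ids)
  if (length(unknown) > 0L) {
    stop_schema("parent identifier(s) not present as nodes: %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  }
  root <- ids[parent == ids]
  if (length(root) != 1L) {
    stop_schema("tree must have exactly one self-parented root (found %d)",
                length(root))
  }

  depth <- compute_depths(parent, root)

  if (is.null(name)) name <- stats::setNames(ids, ids)
  name <- stats::setNames(as.character(name[ids]), ids)
  name[is.na(name)] <- ids[is.na(name)]
  if (is.null(rank)) rank <- stats::setNames(rep("no rank", length(ids)), ids)
  rank <- stats::setNames(as.character(rank[ids]), ids)
  rank[is.na(rank)] <- "no rank"

  # primary label index: label -> character vector of candidate ids
  label_index <- split(ids, name)

  structure(
    list(nodes = ids, parent = parent, name = name, rank = rank,
         root = root, depth = depth,
         label_index = label_index,
         synonym_index = if (is.null(synonyms)) list() else
           split(as.character(synonyms), names(synonyms))),
    class = "taxonomy_tree"
  )
}

# Level-by-level depth propagation; stalls indicate a cycle.
compute_depths <- function(parent, root) {
  ids <- names(parent)
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[root] <- 0L
  repeat {
    todo <- is.na(depth)
    if (!any(todo)) break
    ready <- todo & !is.na(depth[parent])
    if (!any(ready)) {
      stop_schema("cycle or unreachable node(s) detected: %s",
                  paste(utils::head(ids[todo], 5L), collapse = ", "))
    }
    depth[ready] <- depth[parent[ready]] + 1L
  }
  depth
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root '%s' (%s), max depth %d\n",
              length(x$nodes), x$root, x$name[[x$root]], max(x$depth)))
  invisible(x)
}

check_taxon <- function(tree, taxon) {
  if (length(taxon) != 1L || is.na(taxon) || !taxon %in% tree$nodes) {
    stop_lookup("unknown taxon identifier: '%s'", as.character(taxon)[1L])
  }
  taxon
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses the `nodes.dmp`/`names.dmp` dialect (fields separated by
#' `"\t|\t"`, lines terminated by `"\t|"`). Scientific names become primary
#' labels; synonym, equivalent-name and common-name entries are indexed as
#' secondary labels for name resolution.
#'
#' @param nodes_source,names_source File paths, connections, or character
#'   vectors of lines in the taxdump dialect.
#' @return A [taxonomy_tree()].
#' @export
read_ncbi_dump <- function(nodes_source, names_source) {
  parse_dmp <- function(source, min_fields, what) {
    lines <- read_source_lines(source)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      ln <- sub("\t\\|$", "", lines[[i]])
      fields <- strsplit(ln, "\t\\|\t")[[1L]]
      if (length(fields) < min_fields) {
        stop_schema("malformed %s line %d: expected >= %d fields, got %d",
                    what, i, min_fields, length(fields))
      }
      fields
    })
    rows
  }

  node_rows <- parse_dmp(nodes_source, 3L, "nodes.dmp")
  ids <- vapply(node_rows, `[[`, character(1), 1L)
  parents <- vapply(node_rows, `[[`, character(1), 2L)
  ranks <- vapply(node_rows, `[[`, character(1), 3L)
  if (anyDuplicated(ids)) stop_schema("duplicate tax_id in nodes source")
  unknown <- setdiff(parents, ids)
  if (length(unknown) > 0L) {
    stop_schema("node(s) with unknown parent tax_id: %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  }

  name_rows <- parse_dmp(names_source, 4L, "names.dmp")
  nm_id <- vapply(name_rows, `[[`, character(1), 1L)
  nm_txt <- vapply(name_rows, `[[`, character(1), 2L)
  nm_class <- vapply(name_rows, `[[`, character(1), 4L)

  sci <- nm_class == "scientific name"
  name <- stats::setNames(nm_txt[sci], nm_id[sci])
  syn_classes <- c("synonym", "equivalent name", "common name",
                   "genbank common name", "genbank synonym")
  syn_keep <- nm_class %in% syn_classes & nm_id %in% ids
  synonyms <- stats::setNames(nm_id[syn_keep], nm_txt[syn_keep])

  taxonomy_tree(parent = stats::setNames(parents, ids),
                name = name, rank = stats::setNames(ranks, ids),
                synonyms = synonyms)
}

#' Read a lineage table
#'
#' Fixture-friendly taxonomy dialect: a TSV with a `lineage` column whose
#' values are semicolon-separated label chains from root to tip. The tree is
#' the union of all chains; shared prefixes merge. Labels double as
#' identifiers, so a label recurring under a different parent is an error.
#'
#' @param source File path, connection, or character vector of lines.
#' @return A [taxonomy_tree()].
#' @export
read_lineage_table <- function(source) {
  df <- read_tsv_dialect(source, required = "lineage")
  chains <- lapply(df$lineage, split_semicolon)
  chains <- chains[lengths(chains) > 0L]
  if (length(chains) == 0L) stop_schema("lineage table contains no chains")

  roots <- unique(vapply(chains, `[[`, character(1), 1L))
  if (length(roots) != 1L) {
    stop_schema("all lineages must share one root; found: %s",
                paste(roots, collapse = ", "))
  }
  parent <- stats::setNames(roots, roots)
  for (chain in chains) {
    for (i in seq_along(chain)[-1L]) {
      lab <- chain[[i]]; par <- chain[[i - 1L]]
      if (lab %in% names(parent)) {
        if (parent[[lab]] != par) {
          stop_schema("conflicting parentage for '%s': '%s' vs '%s'",
                      lab, parent[[lab]], par)
        }
      } else {
        parent[[lab]] <- par
      }
    }
  }
  taxonomy_tree(parent)
}

#' Write a taxonomy tree as a lineage table
#'
#' Inverse of [read_lineage_table()]: one row per leaf, the semicolon-joined
#' root-first chain of node names.
#'
#' @param tree A [taxonomy_tree()].
#' @param path Output file path.
#' @export
write_lineage_table <- function(tree, path) {
  is_parent <- tree$nodes %in% tree$parent[tree$nodes != tree$root]
  leaves <- tree$nodes[!is_parent]
  if (length(leaves) == 0L) leaves <- tree$root
  lin <- vapply(leaves, function(lf) {
    paste(tree$name[ancestor_chain(tree, lf)], collapse = ";")
  }, character(1))
  write_tsv_dialect(data.frame(lineage = lin), path)
}

# Root-first chain of identifiers including the taxon itself.
ancestor_chain <- function(tree, taxon) {
  chain <- character(tree$depth[[taxon]] + 1L)
  node <- taxon
  for (i in rev(seq_along(chain))) {
    chain[[i]] <- node
    node <- tree$parent[[node]]
  }
  chain
}

# Ranks counted when depth is restricted to canonical levels.
CANONICAL_RANKS <- c("superkingdom", "domain", "kingdom", "phylum", "division",
                     "class", "order", "family", "genus", "species")

#' Depth of a taxon
#'
#' Number of edges from the root (depth 0) to the taxon. With
#' `ranked_only = TRUE` only ancestors carrying a canonical rank
#' (domain/kingdom/phylum/class/order/family/genus/species and synonyms)
#' are counted, a sensitivity-analysis alternative for taxonomies rich in
#' unranked internal nodes.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxon Taxon identifier.
#' @param ranked_only Count only canonically ranked ancestors.
#' @return Nonnegative integer depth.
#' @export
taxon_depth <- function(tree, taxon, ranked_only = FALSE) {
  check_taxon(tree, taxon)
  if (!ranked_only) return(unname(tree$depth[[taxon]]))
  chain <- ancestor_chain(tree, taxon)
  # ranked depth: canonically ranked nodes below the root on the chain
  sum(tree$rank[chain[-1L]] %in% CANONICAL_RANKS)
}

#' Lowest common ancestor
#'
#' Deepest node that is an ancestor-or-self of every taxon in `taxa`.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxa Nonempty character vector of taxon identifiers.
#' @return A single taxon identifier.
#' @export
taxon_lca <- function(tree, taxa) {
  if (length(taxa) == 0L) stop_domain("LCA of an empty taxon collection")
  for (t in unique(taxa)) check_taxon(tree, t)
  chains <- lapply(unique(taxa), ancestor_chain, tree = tree)
  k <- min(lengths(chains))
  lca <- tree$root
  for (i in seq_len(k)) {
    level <- vapply(chains, `[[`, character(1), i)
    if (all(level == level[[1L]])) lca <- level[[1L]] else break
  }
  lca
}

#' Ancestor-or-self test
#'
#' `TRUE` iff `a` lies on `b`'s chain to the root, or `a == b`.
#'
#' @param tree A [taxonomy_tree()].
#' @param a,b Taxon identifiers.
#' @export
is_ancestor <- function(tree, a, b) {
  check_taxon(tree, a); check_taxon(tree, b)
  if (a == b) return(TRUE)
  if (tree$depth[[a]] >= tree$depth[[b]]) return(FALSE)
  node <- b
  while (node != tree$root) {
    node <- tree$parent[[node]]
    if (node == a) return(TRUE)
  }
  FALSE
}

#' Path between two taxa through their LCA
#'
#' Returns the edges of the unique simple path from `a` up to `lca(a, b)`
#' and down to `b`. Every edge is reported as (parent, child) with the
#' parent the shallower node; the edge list is empty iff `a == b`.
#'
#' @param tree A [taxonomy_tree()].
#' @param a,b Taxon identifiers.
#' @return Data frame with columns `parent`, `child`, ordered from `a`'s
#'   side to `b`'s side.
#' @export
path_edges <- function(tree, a, b) {
  check_taxon(tree, a); check_taxon(tree, b)
  lca <- taxon_lca(tree, c(a, b))
  up <- character(0); down <- character(0)
  node <- a
  while (node != lca) { up <- c(up, node); node <- tree$parent[[node]] }
  node <- b
  while (node != lca) { down <- c(down, node); node <- tree$parent[[node]] }
  # ascending side: edges (parent(x), x) for x walking a -> lca
  parents <- c(if (length(up)) tree$parent[up] else character(0),
               if (length(down)) rev(tree$parent[down]) else character(0))
  children <- c(up, rev(down))
  data.frame(parent = unname(parents), child = unname(children),
             stringsAsFactors = FALSE)
}

#' Default high-level group anchors
#'
#' Maps anchor node labels to the high-level summary groups used when
#' collapsing expected taxonomic ranges: root, cellular organisms, archaea,
#' bacteria, eukaryotes, animals, fungi, plants (plus the catch-all
#' "other", and "prokaryotes" available for user-supplied anchors).
#'
#' @return Data frame with columns `label` and `group`.
#' @export
default_group_map <- function() {
  data.frame(
    label = c("root", "cellular organisms", "Bacteria", "Archaea",
              "Eukaryota", "Metazoa", "Fungi", "Viridiplantae"),
    group = c("root", "cellular organisms", "bacteria", "archaea",
              "eukaryotes", "animals", "fungi", "plants"),
    stringsAsFactors = FALSE
  )
}

#' Collapse a taxon to its high-level group
#'
#' Walks the taxon's ancestor-or-self chain tip-first and returns the group
#' of the deepest anchor label found in `group_map`; `"other"` if no anchor
#' (not even the root) matches.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxon Taxon identifier.
#' @param group_map Data frame with columns `label`, `group`; see
#'   [default_group_map()].
#' @return A group label.
#' @export
collapse_to_group <- function(tree, taxon, group_map = default_group_map()) {
  check_taxon(tree, taxon)
  chain <- ancestor_chain(tree, taxon)
  labels <- tree$name[chain]
  for (i in rev(seq_along(chain))) {
    hit <- match(labels[[i]], group_map$label)
    if (!is.na(hit)) return(group_map$group[[hit]])
  }
  "other"
}

#' Resolve taxon labels to identifiers
#'
#' Labels are matched first against identifiers, then primary (scientific)
#' names, then synonyms. A homonym (label naming several nodes) is resolved
#' by preferring the candidate whose ancestor chain contains `anchor`;
#' without an anchor, homonyms raise an ambiguity error. Labels matching
#' nothing are skipped with a warning; the number skipped is attached as
#' attribute `n_skipped`.
#'
#' @param tree A [taxonomy_tree()].
#' @param labels Character vector of names, synonyms or identifiers.
#' @param anchor Optional taxon identifier used to disambiguate homonyms.
#' @return Character vector of resolved identifiers (possibly shorter than
#'   `labels`), with attribute `n_skipped`.
#' @export
resolve_taxa <- function(tree, labels, anchor = NULL) {
  if (!is.null(anchor)) check_taxon(tree, anchor)
  resolved <- character(0)
  skipped <- character(0)
  for (lab in labels) {
    ids <- if (lab %in% tree$nodes) lab else
      c(tree$label_index[[lab]], tree$synonym_index[[lab]])
    ids <- unique(ids[!is.na(ids)])
    if (length(ids) == 0L) { skipped <- c(skipped, lab); next }
    if (length(ids) > 1L) {
      if (!is.null(anchor)) {
        ids <- ids[vapply(ids, function(i) is_ancestor(tree, anchor, i),
                          logical(1))]
      }
      if (length(ids) != 1L) {
        stop_domain("ambiguous taxon label '%s' (%d candidates); supply an anchor",
                    lab, max(length(ids), 2L))
      }
    }
    resolved <- c(resolved, ids)
  }
  if (length(skipped) > 0L) {
    warning(sprintf("skipped %d unresolvable taxon label(s): %s",
                    length(skipped),
                    paste(utils::head(unique(skipped), 5L), collapse = ", ")),
            call. = FALSE)
  }
  structure(resolved, n_skipped = length(skipped))
}
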