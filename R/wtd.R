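# Weighted taxonomic distance (WTD) between a pathway's observed CDS-LCA
# taxon and its expected taxonomic range(s), with per-sample disagreement
# classes.
#
# The distance walks the unique tree path between an expected taxon and the
# observed LCA, weighting each edge by weight_base^(-depth(parent)) with
# depth(root) = 0. Steps near the root thus dominate all steps below them
# (for weight_base >= 2 an edge at depth d outweighs the entire geometric
# tail at depths > d), and every distance magnitude is bounded by
# weight_base / (weight_base - 1) < 2 at the default base.

#' Depth-dependent edge weight
#'
#' Weight of a tree edge whose parent (shallower) endpoint sits at
#' `parent_depth`: `weight_base^(-parent_depth)`, so the root-level edge has
#' weight 1 and weights halve with each level at the default base 2.
#'
#' @param parent_depth Nonnegative integer depth of the edge's parent node.
#' @param weight_base Geometric base (> 1) of the weighting scheme.
#' @return Positive numeric weight.
#' @export
edge_weight <- function(parent_depth, weight_base = 2) {
  if (any(parent_depth < 0)) stop_domain("parent_depth must be nonnegative")
  if (weight_base <= 1) stop_domain("weight_base must exceed 1")
  weight_base^(-parent_depth)
}

#' Signed weighted taxonomic distance between two taxa
#'
#' Magnitude is the sum of [edge_weight()] over the edges of the unique path
#' between `expected` and `observed` (through their LCA). The sign encodes
#' containment: nonnegative iff `expected` is an ancestor-or-self of
#' `observed` (the observed lineage descends from the expected range),
#' negative when the observed lineage falls outside it.
#'
#' @param tree A [taxonomy_tree()].
#' @param expected,observed Taxon identifiers.
#' @param weight_base Geometric base of the edge weights.
#' @param ranked_only Restrict depths to canonically ranked nodes
#'   (see [taxon_depth()]).
#' @return Signed numeric distance; 0 iff `expected == observed`.
#' @export
signed_distance <- function(tree, expected, observed, weight_base = 2,
                            ranked_only = FALSE) {
  edges <- path_edges(tree, expected, observed)
  if (nrow(edges) == 0L) return(0)
  d <- vapply(edges$parent, taxon_depth, integer(1),
              tree = tree, ranked_only = ranked_only)
  mag <- sum(edge_weight(d, weight_base))
  if (is_ancestor(tree, expected, observed)) mag else -mag
}

#' Observed LCA taxon for a pathway's CDS annotations
#'
#' Resolves the per-CDS taxon labels against the tree (skipping
#' unresolvable labels with a warning) and returns their lowest common
#' ancestor.
#'
#' @param tree A [taxonomy_tree()].
#' @param cds_taxa Character vector of taxon labels, one per CDS.
#' @param anchor Optional disambiguation anchor for homonyms
#'   (see [resolve_taxa()]).
#' @return Taxon identifier of the LCA, with attribute `n_skipped`.
#' @export
observed_taxon_for_pathway <- function(tree, cds_taxa, anchor = NULL) {
  ids <- resolve_taxa(tree, cds_taxa, anchor = anchor)
  if (length(ids) == 0L) {
    stop_domain("no CDS taxon label could be resolved against the tree")
  }
  structure(taxon_lca(tree, ids), n_skipped = attr(ids, "n_skipped"))
}

#' Expected taxonomic range map
#'
#' Wraps a pathway -> taxa mapping after validating that every taxon
#' resolves in the working tree (unresolvable taxa are dropped with a
#' warning; a pathway losing its whole range is dropped and counted).
#'
#' @param ranges Named list: pathway identifier -> character vector of taxon
#'   labels or identifiers.
#' @param tree A [taxonomy_tree()] used for resolution.
#' @return An object of class `expected_range_map` (named list of resolved
#'   identifier vectors).
#' @export
expected_range_map <- function(ranges, tree) {
  if (is.null(names(ranges)) || any(!nzchar(names(ranges)))) {
    stop_schema("expected ranges must be a named list keyed by pathway")
  }
  out <- list()
  dropped <- character(0)
  for (p in names(ranges)) {
    ids <- suppressWarnings(resolve_taxa(tree, ranges[[p]]))
    if (length(ids) == 0L) dropped <- c(dropped, p) else out[[p]] <- unname(ids)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d pathway range(s) with no resolvable taxa: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  structure(out, class = "expected_range_map")
}

#' Read an expected-range file
#'
#' TSV dialect with columns `pathway_id` and `expected_taxa`
#' (semicolon-separated labels or identifiers).
#'
#' @param source File path, connection, or character lines.
#' @param tree A [taxonomy_tree()] for resolution.
#' @return An [expected_range_map()].
#' @export
read_expected_ranges <- function(source, tree) {
  df <- read_tsv_dialect(source, required = c("pathway_id", "expected_taxa"))
  if (anyDuplicated(df$pathway_id)) {
    stop_schema("duplicate pathway_id in expected-range file")
  }
  ranges <- stats::setNames(lapply(df$expected_taxa, split_semicolon),
                            df$pathway_id)
  expected_range_map(ranges, tree)
}

#' Write an expected-range map
#'
#' @param ranges An [expected_range_map()].
#' @param path Output TSV path.
#' @export
write_expected_ranges <- function(ranges, path) {
  df <- data.frame(
    pathway_id = names(ranges),
    expected_taxa = vapply(ranges, paste, character(1), collapse = ";")
  )
  write_tsv_dialect(df, path)
}

#' WTD of a pathway against its expected taxonomic range
#'
#' Computes [signed_distance()] from every taxon in the pathway's expected
#' range to the observed LCA, then reports the minimum nonnegative distance
#' if the observed taxon is contained in any expected clade, otherwise the
#' maximum (closest to zero) negative distance. Ties are broken toward the
#' lexicographically smallest expected-taxon name for determinism.
#'
#' @param tree A [taxonomy_tree()].
#' @param ranges An [expected_range_map()].
#' @param pathway Pathway identifier.
#' @param observed Observed LCA taxon identifier.
#' @param weight_base,ranked_only Passed to [signed_distance()].
#' @param missing_range Policy when `pathway` has no range: `"none"` returns
#'   an `NA` distance (the pathway cannot disagree and later receives the
#'   "None" class), `"skip"` returns `NULL`, `"error"` raises.
#' @return A one-row data frame with columns `pathway`, `observed_taxon`,
#'   `matched_expected`, `distance` (or `NULL` under `"skip"`).
#' @export
pathway_wtd <- function(tree, ranges, pathway, observed, weight_base = 2,
                        ranked_only = FALSE,
                        missing_range = c("none", "skip", "error")) {
  missing_range <- match.arg(missing_range)
  check_taxon(tree, observed)
  range <- ranges[[pathway]]
  if (is.null(range)) {
    if (missing_range == "error") {
      stop_domain("pathway '%s' missing from the expected-range map", pathway)
    }
    if (missing_range == "skip") return(NULL)
    return(data.frame(pathway = pathway, observed_taxon = observed,
                      matched_expected = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE))
  }
  d <- vapply(range, signed_distance, numeric(1), tree = tree,
              observed = observed, weight_base = weight_base,
              ranked_only = ranked_only)
  nonneg <- d >= 0
  cand <- if (any(nonneg)) which(nonneg & d == min(d[nonneg])) else
    which(d == max(d))
  if (length(cand) > 1L) {
    cand <- cand[order(tree$name[range[cand]], range[cand])][1L]
  }
  data.frame(pathway = pathway, observed_taxon = observed,
             matched_expected = range[[cand]], distance = unname(d[[cand]]),
             stringsAsFactors = FALSE)
}

#' Compute WTD results for every record of a pathway table
#'
#' For each (sample, pathway) record with CDS taxon annotations, derives the
#' observed LCA via [observed_taxon_for_pathway()] and scores it against the
#' expected range via [pathway_wtd()]. Records without CDS taxa are skipped
#' with a count in attribute `n_no_taxa`.
#'
#' @param table A [pathway_table()].
#' @param tree A [taxonomy_tree()].
#' @param ranges An [expected_range_map()].
#' @param ... Passed on to [pathway_wtd()].
#' @return Data frame with columns `sample`, `pathway_id`, `observed_lca`,
#'   `matched_expected`, `wtd`, `disagreement_class` (`NA` until
#'   [assign_disagreement_classes()] is applied).
#' @export
compute_wtd <- function(table, tree, ranges, ...) {
  rec <- table$records
  out <- vector("list", nrow(rec))
  n_no_taxa <- 0L
  for (i in seq_len(nrow(rec))) {
    taxa <- split_semicolon(rec$cds_taxa[[i]])
    if (length(taxa) == 0L) { n_no_taxa <- n_no_taxa + 1L; next }
    obs <- tryCatch(observed_taxon_for_pathway(tree, taxa),
                    epgdb_domain_error = function(e) NULL)
    if (is.null(obs)) { n_no_taxa <- n_no_taxa + 1L; next }
    row <- pathway_wtd(tree, ranges, rec$pathway_id[[i]], obs, ...)
    if (is.null(row)) next
    out[[i]] <- data.frame(sample = rec$sample[[i]],
                           pathway_id = row$pathway,
                           observed_lca = row$observed_taxon,
                           matched_expected = row$matched_expected,
                           wtd = row$distance,
                           disagreement_class = NA_character_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(sample = character(), pathway_id = character(),
                      observed_lca = character(),
                      matched_expected = character(), wtd = numeric(),
                      disagreement_class = character(),
                      stringsAsFactors = FALSE)
  }
  structure(res, n_no_taxa = n_no_taxa)
}

# Rank-quartile partition of the scored (disagreeing) distances of one
# sample. Sorted ascending (most negative first): the lowest floor(n/4)
# values are High, the next up to floor(n/2) are Medium, the remainder
# (strictly above the median) are Low. Ties take the class of the first
# occupied position of their value, so a run spanning a boundary gets the
# more severe class. With n = 1 no strictly-lower quartile exists and the
# single value is Low.
classify_scored <- function(v) {
  n <- length(v)
  if (n == 0L) return(character(0))
  n_high <- floor(n / 4)
  n_med <- floor(n / 2) - n_high
  by_pos <- rep("Low", n)
  if (n_high > 0L) by_pos[seq_len(n_high)] <- "High"
  if (n_med > 0L) by_pos[n_high + seq_len(n_med)] <- "Medium"
  s <- sort(v)
  by_pos[match(v, s)]
}

#' Assign taxonomic disagreement classes
#'
#' Per-sample quartile classification of WTD results: positive distances
#' (and, under the default zero policy, exact zeros and missing-range
#' records) are "None"; the remaining distances are partitioned by rank
#' into "Low" (above the median), "Medium" (second quartile) and "High"
#' (lowest quartile, the strongest candidates for spurious predictions).
#'
#' @param wtd_df Data frame from [compute_wtd()] (columns `sample`, `wtd`).
#' @param zero_is_none If `TRUE` (default) a distance of exactly 0 — the
#'   observed LCA equals an expected taxon — is perfect agreement and gets
#'   "None"; if `FALSE` zeros join the quartile partition.
#' @return `wtd_df` with `disagreement_class` filled in.
#' @export
assign_disagreement_classes <- function(wtd_df, zero_is_none = TRUE) {
  if (nrow(wtd_df) == 0L) return(wtd_df)
  wtd_df$disagreement_class <- "None"
  for (s in unique(wtd_df$sample)) {
    in_s <- wtd_df$sample == s
    v <- wtd_df$wtd[in_s]
    scored <- !is.na(v) & (v < 0 | (!zero_is_none & v == 0))
    cls <- rep("None", sum(in_s))
    cls[scored] <- classify_scored(v[scored])
    wtd_df$disagreement_class[in_s] <- cls
  }
  wtd_df
}

#' Summarize disagreement classes by high-level taxonomic group
#'
#' Collapses each result's matched expected taxon to its high-level group
#' (see [collapse_to_group()]) and tabulates (group, class) counts; counts
#' sum to the number of classified results. Results without a matched
#' expected taxon are tabulated under group `"other"`.
#'
#' @param wtd_df Classified data frame from [assign_disagreement_classes()].
#' @param tree A [taxonomy_tree()].
#' @param group_map See [default_group_map()].
#' @return Data frame with columns `group`, `disagreement_class`, `n`.
#' @export
summarize_by_group <- function(wtd_df, tree, group_map = default_group_map()) {
  if (nrow(wtd_df) == 0L) {
    return(data.frame(group = character(), disagreement_class = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  grp <- vapply(wtd_df$matched_expected, function(t) {
    if (is.na(t)) "other" else collapse_to_group(tree, t, group_map)
  }, character(1), USE.NAMES = FALSE)
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(wtd_df))),
    by = list(group = grp,
              disagreement_class = unname(wtd_df$disagreement_class)),
    FUN = sum)
  agg[order(agg$group, agg$disagreement_class), , drop = FALSE]
}
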