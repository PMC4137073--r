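# Weighted taxonomic distance: edge weights, signed distances, range
# selection, disagreement classes, group summaries.

test_that("edge weights follow the geometric depth scheme", {
  expect_identical(edge_weight(0), 1)
  expect_identical(edge_weight(3), 0.125)
  d <- 0:10
  expect_equal(edge_weight(d + 1) / edge_weight(d), rep(0.5, 11))
  expect_equal(edge_weight(2, weight_base = 10), 0.01)
  expect_error(edge_weight(-1), class = "epgdb_domain_error")
})

test_that("signed distance matches hand-computed path sums and the sign law", {
  tree <- read_lineage_table(c("lineage",
                               "root;cellular organisms;Bacteria",
                               "root;cellular organisms;Eukaryota;Fungi"))
  expect_identical(signed_distance(tree, "Fungi", "Fungi"), 0)
  expect_identical(signed_distance(tree, "root", "cellular organisms"), 1)
  # Bacteria -> up to cellular organisms (w 2^-1) -> down to Eukaryota
  # (w 2^-1) -> Fungi (w 2^-2), outside the expected clade: -1.25
  expect_identical(signed_distance(tree, "Bacteria", "Fungi"), -1.25)
  # containment gives the same magnitude with positive sign
  expect_identical(signed_distance(tree, "cellular organisms", "Fungi"),
                   0.5 + 0.25)
})

test_that("signed distance agrees with a graph-search oracle on random trees", {
  skip_if_not_installed("igraph")
  for (seed in 1:8) {
    tree <- random_tree(seed, n_leaves = 30, max_depth = 7)
    set.seed(seed + 500)
    for (i in 1:10) {
      a <- sample(tree$nodes, 1); b <- sample(tree$nodes, 1)
      expect_equal(signed_distance(tree, a, b), igraph_wtd(tree, a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("distance magnitudes are bounded and root steps dominate", {
  # dominance: within each descending segment of a path (at most one edge
  # per depth), an edge strictly outweighs all edges below it
  for (seed in 1:6) {
    tree <- random_tree(seed, n_leaves = 40, max_depth = 9)
    set.seed(seed)
    for (i in 1:20) {
      a <- sample(tree$nodes, 1); b <- sample(tree$nodes, 1)
      d <- signed_distance(tree, a, b)
      # a descending path is one geometric series (bound 2); a divergent
      # path stacks one series per side of the LCA (bound 4)
      expect_lt(abs(d), 4)
      if (d >= 0) expect_lt(d, 2)
      pe <- path_edges(tree, a, b)
      if (nrow(pe) >= 2L) {
        lca <- taxon_lca(tree, c(a, b))
        up_len <- tree$depth[[a]] - tree$depth[[lca]]
        side <- rep(c("up", "down"), c(up_len, nrow(pe) - up_len))
        w <- edge_weight(tree$depth[pe$parent])
        for (j in seq_len(nrow(pe) - 1L)) {
          deeper <- side == side[[j]] &
            tree$depth[pe$parent] > tree$depth[pe$parent][[j]]
          if (any(deeper)) expect_gt(w[[j]], sum(w[deeper]))
        }
      }
    }
  }
})

test_that("observed LCA skips unresolvable labels and errors when none resolve", {
  tree <- toy_tree()
  expect_identical(
    as.character(observed_taxon_for_pathway(tree, "Escherichia coli")),
    "Escherichia coli")
  expect_identical(
    as.character(observed_taxon_for_pathway(
      tree, c("Escherichia coli", "Salmonella enterica"))),
    "Proteobacteria")
  expect_warning(
    obs <- observed_taxon_for_pathway(
      tree, c("Escherichia coli", "not-a-taxon")),
    "skipped 1")
  expect_identical(as.character(obs), "Escherichia coli")
  expect_identical(attr(obs, "n_skipped"), 1L)
  expect_error(
    suppressWarnings(observed_taxon_for_pathway(tree, "not-a-taxon")),
    class = "epgdb_domain_error")
})

test_that("pathway_wtd selects min nonnegative else max negative, with ties", {
  tree <- toy_tree()
  ranges <- expected_range_map(list(
    exact = c("Fungi", "Bacteria"),
    rooted = "root",
    disjoint = c("Bacteria", "Archaea")), tree)

  r <- pathway_wtd(tree, ranges, "exact", "Fungi")
  expect_identical(r$distance, 0)
  expect_identical(r$matched_expected, "Fungi")

  # range {root}: full chain sum, always nonnegative
  r <- pathway_wtd(tree, ranges, "rooted", "Saccharomyces cerevisiae")
  expect_identical(r$distance, 1 + 0.5 + 0.25 + 0.125)

  # no expected ancestor: maximum (closest to zero) negative wins
  r <- pathway_wtd(tree, ranges, "disjoint", "Fungi")
  d_bact <- signed_distance(tree, "Bacteria", "Fungi")
  d_arch <- signed_distance(tree, "Archaea", "Fungi")
  expect_identical(r$distance, max(d_bact, d_arch))
  expect_true(r$distance < 0)

  # deterministic lexicographic tie-break between equal distances
  tie <- expected_range_map(list(p = c("Escherichia coli",
                                       "Salmonella enterica")), tree)
  r <- pathway_wtd(tree, tie, "p", "Fungi")
  expect_identical(r$matched_expected, "Escherichia coli")

  # missing range policies
  expect_true(is.na(pathway_wtd(tree, ranges, "absent", "Fungi")$distance))
  expect_null(pathway_wtd(tree, ranges, "absent", "Fungi",
                          missing_range = "skip"))
  expect_error(pathway_wtd(tree, ranges, "absent", "Fungi",
                           missing_range = "error"),
               class = "epgdb_domain_error")
})

test_that("pathway_wtd matches brute-force evaluation on random trees/ranges", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (seed in 1:10) {
    tree <- random_tree(seed, n_leaves = 35, max_depth = 8)
    range <- sample(tree$nodes, sample(2:5, 1))
    ranges <- expected_range_map(list(p = range), tree)
    obs <- sample(tree$nodes, 1)
    expect_equal(pathway_wtd(tree, ranges, "p", obs)$distance,
                 igraph_pathway_wtd(tree, range, obs), tolerance = 1e-12)
  }
})

test_that("containment in the range guarantees a nonnegative distance", {
  set.seed(7)
  for (seed in 1:10) {
    tree <- random_tree(seed)
    obs <- sample(tree$nodes, 1)
    anc <- brute_ancestors(tree, obs)
    range <- unique(c(sample(anc, 1), sample(tree$nodes, 3)))
    ranges <- expected_range_map(list(p = range), tree)
    expect_gte(pathway_wtd(tree, ranges, "p", obs)$distance, 0)
  }
})

test_that("disagreement classes reproduce the rank-quartile oracle", {
  # worked example: four negatives split High / Medium / Low-Low
  expect_identical(epgdbkit:::classify_scored(c(-0.4, -0.3, -0.2, -0.1)),
                   c("High", "Medium", "Low", "Low"))
  # a single negative has no strictly lower quartile: Low
  expect_identical(epgdbkit:::classify_scored(-0.5), "Low")

  set.seed(11)
  for (n in 1:50) {
    v <- -round(stats::runif(n), 2)  # rounding forces ties
    v <- v[v < 0]
    if (length(v) == 0L) next
    expect_identical(epgdbkit:::classify_scored(v), oracle_classes(v),
                     info = sprintf("n = %d", n))
  }
})

test_that("class assignment is per sample, exhaustive, and respects the zero policy", {
  df <- data.frame(
    sample = rep(c("A", "B"), c(6, 3)),
    pathway_id = paste0("p", 1:9),
    observed_lca = "x", matched_expected = "x",
    wtd = c(0.5, 0, -0.4, -0.3, -0.2, -0.1, 1, -1, NA),
    disagreement_class = NA_character_, stringsAsFactors = FALSE)
  cls <- assign_disagreement_classes(df)
  expect_false(anyNA(cls$disagreement_class))
  expect_identical(cls$disagreement_class[1:2], c("None", "None"))
  expect_identical(cls$disagreement_class[3:6],
                   c("High", "Medium", "Low", "Low"))
  # sample B: single negative -> Low; missing distance -> None
  expect_identical(cls$disagreement_class[7:9], c("None", "Low", "None"))
  # all-positive input is all None
  pos <- df[df$wtd > 0 & !is.na(df$wtd), ]
  expect_true(all(assign_disagreement_classes(pos)$disagreement_class == "None"))
  # literal zero policy pushes the zero into the quartile partition
  lit <- assign_disagreement_classes(df, zero_is_none = FALSE)
  expect_identical(lit$disagreement_class[2], "Low")
  expect_identical(nrow(assign_disagreement_classes(df[0, ])), 0L)
})

test_that("classes and signs are invariant to a positive rescaling of all weights", {
  # classes are rank statistics and signs are containment, so multiplying
  # every edge weight (hence every distance) by a positive constant must
  # change neither
  tree <- random_tree(21, n_leaves = 25, max_depth = 7)
  set.seed(22)
  obs <- sample(tree$nodes, 30, replace = TRUE)
  range <- lapply(1:30, function(i) sample(tree$nodes, 2))
  ranges <- expected_range_map(stats::setNames(range, paste0("p", 1:30)), tree)
  d <- vapply(1:30, function(i)
    pathway_wtd(tree, ranges, paste0("p", i), obs[[i]])$distance, numeric(1))
  classify <- function(w) {
    df <- data.frame(sample = "S", pathway_id = paste0("p", 1:30),
                     observed_lca = obs, matched_expected = "x", wtd = w,
                     disagreement_class = NA_character_)
    assign_disagreement_classes(df)$disagreement_class
  }
  for (c in c(0.1, 3, 1e6)) {
    expect_identical(classify(c * d), classify(d))
    expect_identical(sign(c * d), sign(d))
  }
})

test_that("group summaries count every classified result exactly once", {
  tree <- toy_tree()
  df <- data.frame(
    sample = "S", pathway_id = paste0("p", 1:4),
    observed_lca = "Fungi",
    matched_expected = c("Bacteria", "Fungi", "Archaea", NA),
    wtd = c(-0.5, 0, -1, NA),
    disagreement_class = c("Low", "None", "High", "None"),
    stringsAsFactors = FALSE)
  s <- summarize_by_group(df, tree)
  expect_identical(sum(s$n), 4L)
  expect_identical(s$n[s$group == "bacteria" & s$disagreement_class == "Low"], 1L)
  expect_identical(s$n[s$group == "other"], 1L)
  # marginal sums over groups equal per-class counts
  set.seed(5)
  big <- data.frame(
    sample = "S", pathway_id = paste0("q", 1:100),
    observed_lca = "Fungi",
    matched_expected = sample(tree$nodes, 100, replace = TRUE),
    wtd = stats::runif(100, -1, 1),
    disagreement_class = sample(c("None", "Low", "Medium", "High"), 100,
                                replace = TRUE),
    stringsAsFactors = FALSE)
  s <- summarize_by_group(big, tree)
  for (cl in unique(big$disagreement_class)) {
    expect_identical(sum(s$n[s$disagreement_class == cl]),
                     sum(big$disagreement_class == cl))
  }
  expect_identical(nrow(summarize_by_group(big[0, ], tree)), 0L)
})

test_that("expected-range files round-trip and validate against the tree", {
  tree <- toy_tree()
  path <- withr::local_tempfile(fileext = ".tsv")
  ranges <- expected_range_map(list(p1 = c("Bacteria", "Fungi"),
                                    p2 = "root"), tree)
  write_expected_ranges(ranges, path)
  back <- read_expected_ranges(path, tree)
  expect_identical(back$p1, ranges$p1)
  expect_identical(back$p2, ranges$p2)
  expect_warning(
    expected_range_map(list(p1 = "Bacteria", bad = "no-such"), tree),
    "dropped 1")
})
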