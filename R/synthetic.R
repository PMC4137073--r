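# Synthetic taxonomies, communities and pathway tables with the statistical
# structure of simulated-metagenome experiments: even versus skewed genome
# abundance (a dominant genome in 20-fold excess), a shared core of common
# pathways plus genome-specific accessory pathways, engineered split
# pathways divided between two genomes, and coverage subsampling of CDS
# observations with replacement.
#
# Every generator is a pure function of its seed and parameters: the global
# RNG state is saved and restored around each call.

# Random rooted tree grown with the caller's RNG state.
make_taxonomy_impl <- function(n_leaves, max_depth) {
  parent <- c(root = "root")
  levels <- list("root")
  counter <- 0L
  if (max_depth >= 2L) {
    for (l in seq_len(max_depth - 1L)) {
      m <- sample.int(max(2L, min(n_leaves, 5L)), 1L)
      ids <- paste0("n", counter + seq_len(m))
      counter <- counter + m
      pars <- levels[[l]][sample.int(length(levels[[l]]), m, replace = TRUE)]
      parent[ids] <- pars
      levels[[l + 1L]] <- ids
    }
  }
  internal_pool <- unlist(levels, use.names = FALSE)
  leaves <- paste0("t", seq_len(n_leaves))
  leaf_par <- internal_pool[sample.int(length(internal_pool), n_leaves,
                                       replace = TRUE)]
  parent[leaves] <- leaf_par
  # prune internal nodes that attracted no children
  repeat {
    ids <- names(parent)
    has_child <- ids %in% parent[ids != "root"]
    drop <- ids[!has_child & !(ids %in% leaves) & ids != "root"]
    if (length(drop) == 0L) break
    parent <- parent[setdiff(ids, drop)]
  }
  taxonomy_tree(parent)
}

#' Generate a random taxonomy tree
#'
#' Random rooted tree with exactly `n_leaves` leaves (labelled `t1`,
#' `t2`, ...) and depth at most `max_depth`, deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n_leaves Number of leaves (>= 1).
#' @param max_depth Maximum depth (>= 1).
#' @return A [taxonomy_tree()].
#' @export
make_taxonomy <- function(seed, n_leaves, max_depth) {
  if (n_leaves < 1L || max_depth < 1L) {
    stop_domain("n_leaves and max_depth must both be >= 1")
  }
  withr::with_seed(seed, make_taxonomy_impl(n_leaves, max_depth))
}

#' Generate a synthetic multi-genome community
#'
#' Builds a taxonomy with one leaf per genome (plus decoy leaves carrying no
#' genome, used as misassignment targets for expected ranges), assigns each
#' genome an abundance weight — genome 1 gets `skew`, all others 1, so
#' `skew = 1` reproduces an even community and `skew = 20` a community with
#' one dominant genome in 20-fold excess — and draws each genome's pathway
#' repertoire as a mix of a shared core (`shared_fraction`) and
#' genome-specific accessory pathways, giving pathway accumulation the
#' core-then-accessory structure of a collector's curve. Optionally emits
#' engineered split pathways whose reactions are divided between genomes 1
#' and 2 with a small overlap: neither genome encodes the full reaction
#' set, their union does, and both contribute CDS to (n-2)/n of the
#' reactions — ground-truth positives for distributed-pathway detection.
#'
#' @param seed Integer seed.
#' @param n_genomes Number of genomes (>= 2 if split pathways are emitted).
#' @param skew Abundance weight of genome 1 relative to the others.
#' @param pathways_per_genome Pathways per genome repertoire.
#' @param shared_fraction Fraction of each repertoire drawn from the core.
#' @param n_split_pathways Engineered split pathways (0 disables).
#' @param reactions_range Inclusive range of reactions per ordinary pathway.
#' @param multiplicity_range Inclusive range of per-reaction CDS copies.
#' @param max_depth Taxonomy depth.
#' @param n_decoy_leaves Extra leaves holding no genome.
#' @return Object of class `community_model`: list with `tree`, `genomes`
#'   (label, taxon, weight per genome), `pathway_defs` (pathway -> reaction
#'   identifiers), `coverage` (genome -> pathway -> named multiplicity
#'   vector), `true_pathways`, `split_pathways`.
#' @export
make_community <- function(seed, n_genomes = 10L, skew = 1,
                           pathways_per_genome = 40L, shared_fraction = 0.3,
                           n_split_pathways = 2L,
                           reactions_range = c(4L, 8L),
                           multiplicity_range = c(1L, 4L),
                           max_depth = 6L, n_decoy_leaves = 3L) {
  if (n_genomes < 1L || pathways_per_genome < 1L) {
    stop_domain("n_genomes and pathways_per_genome must be positive")
  }
  if (skew <= 0) stop_domain("skew must be positive")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop_domain("shared_fraction must be in [0, 1]")
  }
  if (n_split_pathways > 0L && n_genomes < 2L) {
    stop_domain("split pathways require at least two genomes")
  }
  withr::with_seed(seed, {
    tree <- make_taxonomy_impl(n_genomes + n_decoy_leaves, max_depth)
    leaves <- paste0("t", seq_len(n_genomes + n_decoy_leaves))
    genome_leaves <- leaves[sample.int(length(leaves), n_genomes)]
    genomes <- lapply(seq_len(n_genomes), function(i) {
      list(label = sprintf("G%d", i), taxon = genome_leaves[[i]],
           weight = if (i == 1L) skew else 1)
    })
    names(genomes) <- vapply(genomes, `[[`, character(1), "label")

    n_core <- round(shared_fraction * pathways_per_genome)
    core <- if (n_core > 0L) sprintf("PWY-CORE-%03d", seq_len(n_core)) else
      character(0)
    pathway_defs <- list()
    coverage <- stats::setNames(vector("list", n_genomes), names(genomes))

    rxn_count <- function() sample(reactions_range[1]:reactions_range[2], 1L)
    multiplicities <- function(rxns) {
      stats::setNames(sample(multiplicity_range[1]:multiplicity_range[2],
                             length(rxns), replace = TRUE), rxns)
    }
    define_pathway <- function(p) {
      if (is.null(pathway_defs[[p]])) {
        pathway_defs[[p]] <<- sprintf("RXN-%s-%02d", p, seq_len(rxn_count()))
      }
      pathway_defs[[p]]
    }

    for (g in names(genomes)) {
      acc_n <- pathways_per_genome - n_core
      acc <- if (acc_n > 0L) sprintf("PWY-%s-%03d", g, seq_len(acc_n)) else
        character(0)
      repertoire <- c(core, acc)
      coverage[[g]] <- stats::setNames(
        lapply(repertoire, function(p) multiplicities(define_pathway(p))),
        repertoire)
    }

    split <- character(0)
    if (n_split_pathways > 0L) {
      split <- sprintf("PWY-SPLIT-%02d", seq_len(n_split_pathways))
      for (p in split) {
        rxns <- sprintf("RXN-%s-%02d", p, seq_len(8L))
        pathway_defs[[p]] <- rxns
        # genome 1 misses the last reaction, genome 2 the first: neither is
        # complete, the union is, and both cover 6/8 = 0.75 of reactions
        coverage[["G1"]][[p]] <- multiplicities(rxns[-length(rxns)])
        coverage[["G2"]][[p]] <- multiplicities(rxns[-1L])
      }
    }

    model <- structure(list(tree = tree, genomes = genomes,
                            pathway_defs = pathway_defs, coverage = coverage,
                            true_pathways = sort(names(pathway_defs)),
                            split_pathways = split),
                       class = "community_model")
    model$population <- cds_population(model)
    model
  })
}

#' @export
print.community_model <- function(x, ...) {
  w <- vapply(x$genomes, `[[`, numeric(1), "weight")
  cat(sprintf("community_model: %d genomes (weights %s), %d pathways (%d split)\n",
              length(x$genomes),
              paste(format(w, trim = TRUE), collapse = ","),
              length(x$true_pathways), length(x$split_pathways)))
  invisible(x)
}

# Expanded CDS population: one row per CDS copy, draw weight = genome
# abundance. Cached on the model at construction.
cds_population <- function(model) {
  if (!is.null(model$population)) return(model$population)
  cols <- list(genome = character(0), taxon = character(0),
               pathway = character(0), reaction = character(0),
               weight = numeric(0))
  for (g in names(model$coverage)) {
    taxon <- model$genomes[[g]]$taxon
    weight <- model$genomes[[g]]$weight
    for (p in names(model$coverage[[g]])) {
      mult <- model$coverage[[g]][[p]]
      rxn <- rep(names(mult), mult)
      cols$genome <- c(cols$genome, rep(g, length(rxn)))
      cols$taxon <- c(cols$taxon, rep(taxon, length(rxn)))
      cols$pathway <- c(cols$pathway, rep(p, length(rxn)))
      cols$reaction <- c(cols$reaction, rxn)
      cols$weight <- c(cols$weight, rep(weight, length(rxn)))
    }
  }
  data.frame(cols, stringsAsFactors = FALSE)
}

#' Subsample a community into a pathway table
#'
#' Draws `round(fraction * total CDS)` coding-sequence observations (at
#' least one) from the community's CDS population, with replacement by
#' default, each CDS weighted by its genome's abundance. Observations are
#' aggregated into one pathway-table record per pathway, with `cds_taxa`
#' listing the source genome taxon of every draw and the sample's
#' `total_orfs` set to the number of draws.
#'
#' @param model A [make_community()] model.
#' @param fraction Sampling fraction in (0, 1] of the total CDS population.
#' @param seed Integer seed.
#' @param sample_id Sample label for the emitted records.
#' @param replacement Sample with replacement (the default, emulating
#'   redundant sequencing coverage).
#' @return A [pathway_table()].
#' @export
sample_pathway_table <- function(model, fraction, seed, sample_id = "S1",
                                 replacement = TRUE) {
  if (fraction <= 0 || fraction > 1) stop_domain("fraction must be in (0, 1]")
  pop <- cds_population(model)
  n_draws <- max(1L, as.integer(round(fraction * nrow(pop))))
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pop), n_draws, replace = replacement,
                      prob = pop$weight)
    by_pwy <- split(idx, pop$pathway[idx])
    pwys <- names(by_pwy)
    recs <- data.frame(
      sample = sample_id, pathway_id = pwys, pathway_name = pwys,
      n_reactions = vapply(model$pathway_defs[pwys], length, integer(1)),
      n_covered = vapply(by_pwy, function(i)
        length(unique(pop$reaction[i])), integer(1)),
      n_cds = lengths(by_pwy),
      cds_taxa = vapply(by_pwy, function(i)
        paste(pop$taxon[i], collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    pathway_table(recs, stats::setNames(n_draws, sample_id))
  })
}

# Fast path for recovery curves: which pathways receive >= 1 sampled CDS.
sampled_pathway_set <- function(model, fraction, seed,
                                pop = cds_population(model)) {
  n_draws <- max(1L, as.integer(round(fraction * nrow(pop))))
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pop), n_draws, replace = TRUE, prob = pop$weight)
    unique(pop$pathway[idx])
  })
}

#' Pathway recovery collector's curve
#'
#' Mean (and standard deviation over replicates) of the fraction of the
#' community's true pathways observed with at least one sampled CDS, at
#' each subsampling fraction. Common core pathways accumulate early and
#' rare accessory pathways late, so the mean curve is nondecreasing in the
#' sampling fraction.
#'
#' @param model A [make_community()] model.
#' @param fractions Ascending vector of sampling fractions.
#' @param replicates Replicate subsamples per fraction.
#' @param seed Integer seed (replicate seeds are derived from it).
#' @return Data frame with columns `fraction`, `mean_recovery`,
#'   `sd_recovery`.
#' @export
collector_curve <- function(model, fractions = c(1/20, 1/10, 3/20, 1/5,
                                                 2/5, 3/5, 4/5, 1),
                            replicates = 50L, seed = 1L) {
  if (is.unsorted(fractions)) stop_domain("fractions must be ascending")
  sub_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(fractions) * replicates),
           nrow = length(fractions)))
  n_true <- length(model$true_pathways)
  pop <- cds_population(model)
  rows <- lapply(seq_along(fractions), function(i) {
    rec <- vapply(seq_len(replicates), function(r) {
      drawn <- sampled_pathway_set(model, fractions[[i]], sub_seeds[i, r], pop)
      length(intersect(drawn, model$true_pathways)) / n_true
    }, numeric(1))
    data.frame(fraction = fractions[[i]], mean_recovery = mean(rec),
               sd_recovery = stats::sd(rec))
  })
  do.call(rbind, rows)
}

#' Generate expected taxonomic ranges with known ground truth
#'
#' For each pathway, the expected range is drawn from the ancestor-or-self
#' chain of the LCA of its carrier genomes, guaranteeing a nonnegative WTD
#' whatever subset of carriers is observed. A `misassignment_rate` fraction
#' of pathways instead receives decoy taxa from clades holding no carrier,
#' guaranteeing a negative WTD — known ground truth for sign tests.
#'
#' @param model A [make_community()] model (built with decoy leaves if
#'   `misassignment_rate > 0`).
#' @param seed Integer seed.
#' @param misassignment_rate Fraction of pathways given disjoint ranges.
#' @return An [expected_range_map()] with attribute `misassigned` listing
#'   the pathways given decoy ranges.
#' @export
make_expected_ranges <- function(model, seed, misassignment_rate = 0) {
  if (misassignment_rate < 0 || misassignment_rate > 1) {
    stop_domain("misassignment_rate must be in [0, 1]")
  }
  tree <- model$tree
  carrier_taxa <- function(p) {
    unique(vapply(names(model$coverage)[vapply(model$coverage, function(cv)
      p %in% names(cv), logical(1))],
      function(g) model$genomes[[g]]$taxon, character(1)))
  }
  all_carriers <- unique(vapply(model$genomes, `[[`, character(1), "taxon"))
  # nodes whose subtree holds no genome: safe decoy targets
  decoys <- tree$nodes[vapply(tree$nodes, function(n) {
    n != tree$root &&
      !any(vapply(all_carriers, function(ct)
        is_ancestor(tree, n, ct) || is_ancestor(tree, ct, n), logical(1)))
  }, logical(1))]
  if (misassignment_rate > 0 && length(decoys) == 0L) {
    stop_domain("no decoy clades available; rebuild the community with decoy leaves")
  }
  withr::with_seed(seed, {
    ranges <- list()
    misassigned <- character(0)
    for (p in model$true_pathways) {
      lca <- taxon_lca(tree, carrier_taxa(p))
      if (misassignment_rate > 0 && stats::runif(1) < misassignment_rate) {
        k <- min(length(decoys), sample(1:2, 1L))
        ranges[[p]] <- decoys[sample.int(length(decoys), k)]
        misassigned <- c(misassigned, p)
      } else {
        chain <- ancestor_chain(tree, lca)
        ranges[[p]] <- chain[[sample.int(length(chain), 1L)]]
      }
    }
    structure(expected_range_map(ranges, tree), misassigned = misassigned)
  })
}

#' Per-genome encoded pathway sets
#'
#' Pathways a genome encodes completely (every reaction of the definition
#' carries at least one CDS copy), the synthetic analogue of the pathway
#' set predicted from an individual genome.
#'
#' @param model A [make_community()] model.
#' @return Named list: genome label -> sorted pathway vector.
#' @export
genome_pathway_sets <- function(model) {
  lapply(model$coverage, function(cv) {
    full <- vapply(names(cv), function(p) {
      all(model$pathway_defs[[p]] %in% names(cv[[p]]))
    }, logical(1))
    sort(names(cv)[full])
  })
}

#' Combined pathway set for a genome subset
#'
#' Pathways whose full reaction set is covered by the union of the given
#' genomes' CDS — the synthetic analogue of predictions from a combined
#' multi-genome database.
#'
#' @param model A [make_community()] model.
#' @param genomes Character vector of genome labels.
#' @return Sorted pathway vector.
#' @export
combined_pathway_set <- function(model, genomes) {
  pws <- unique(unlist(lapply(model$coverage[genomes], names),
                       use.names = FALSE))
  full <- vapply(pws, function(p) {
    covered <- unique(unlist(lapply(model$coverage[genomes], function(cv)
      names(cv[[p]])), use.names = FALSE))
    all(model$pathway_defs[[p]] %in% covered)
  }, logical(1))
  sort(pws[full])
}

#' Per-reaction contributor map for a genome pair
#'
#' For each pathway carried by either member, maps every reaction of the
#' pathway definition to the pair members contributing at least one CDS —
#' the coverage evidence consumed by [plausibility_filter()].
#'
#' @param model A [make_community()] model.
#' @param pair Character vector of two genome labels.
#' @return Named list: pathway -> named list reaction -> contributing
#'   genome labels.
#' @export
reaction_coverage_map <- function(model, pair) {
  if (length(pair) != 2L) stop_domain("pair must name exactly two genomes")
  pws <- unique(unlist(lapply(model$coverage[pair], names), use.names = FALSE))
  out <- lapply(pws, function(p) {
    rxns <- model$pathway_defs[[p]]
    stats::setNames(lapply(rxns, function(r) {
      pair[vapply(pair, function(g) {
        cv <- model$coverage[[g]][[p]]
        !is.null(cv) && r %in% names(cv)
      }, logical(1))]
    }), rxns)
  })
  stats::setNames(out, pws)
}
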