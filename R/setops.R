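# Presence/absence set analyses across samples and genomes: k-way region
# reports, DNA/RNA fraction partitions, and distributed-pathway detection
# with a reaction-coverage plausibility filter.

#' K-way set regions
#'
#' Assigns every pathway in the union of `named_sets` to its exact
#' membership pattern (an ordered tuple of booleans over the sets, encoded
#' as a string of 0/1 in the given set order). All 2^k - 1 nonempty
#' patterns are reported, empty ones with empty pathway sets, so the
#' regions partition the union.
#'
#' @param named_sets Named list (2 to 6 entries) of pathway-identifier
#'   vectors, e.g. per-sample presence sets.
#' @return An object of class `set_region_report`: list with `regions`
#'   (named list pattern -> sorted pathway vector) and `set_names`.
#' @export
kway_regions <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2L || k > 6L) stop_domain("k-way analysis requires 2 to 6 sets")
  labels <- names(named_sets)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop_schema("sets must carry unique nonempty labels")
  }
  named_sets <- lapply(named_sets, unique)
  universe <- sort(unique(unlist(named_sets, use.names = FALSE)))
  membership <- vapply(named_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)

  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  keys <- apply(patterns, 1L, function(r) paste(as.integer(r), collapse = ""))
  keep <- keys != paste(rep("0", k), collapse = "")
  patterns <- patterns[keep, , drop = FALSE]
  keys <- keys[keep]
  ord <- order(keys)
  patterns <- patterns[ord, , drop = FALSE]
  keys <- keys[ord]

  obs_key <- if (length(universe) == 0L) character(0) else
    apply(membership, 1L, function(r) paste(as.integer(r), collapse = ""))
  regions <- stats::setNames(
    lapply(keys, function(kk) sort(universe[obs_key == kk])), keys)
  structure(list(regions = regions, set_names = labels),
            class = "set_region_report")
}

#' @export
print.set_region_report <- function(x, ...) {
  cat(sprintf("set_region_report over %d sets (%s): %d pathways in union\n",
              length(x$set_names), paste(x$set_names, collapse = ", "),
              sum(lengths(x$regions))))
  invisible(x)
}

#' Tabulate a set-region report
#'
#' @param report A [kway_regions()] result.
#' @return Data frame with columns `pattern`, `n`, `pathways`
#'   (semicolon-joined), sorted by pattern.
#' @export
region_table <- function(report) {
  data.frame(pattern = names(report$regions),
             n = unname(lengths(report$regions)),
             pathways = vapply(report$regions, paste, character(1),
                               collapse = ";"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition DNA and RNA pathway sets at one depth
#'
#' @param dna,rna Pathway-identifier vectors for the DNA (metagenome) and
#'   RNA (metatranscriptome) fraction of one sample/depth.
#' @return List with components `dna_only`, `shared`, `rna_only`, which
#'   partition `union(dna, rna)`.
#' @export
fraction_partition <- function(dna, rna) {
  dna <- unique(dna); rna <- unique(rna)
  list(dna_only = sort(setdiff(dna, rna)),
       shared = sort(intersect(dna, rna)),
       rna_only = sort(setdiff(rna, dna)))
}

#' Union fraction partitions across depths
#'
#' Component-wise union of per-depth [fraction_partition()] results. A
#' pathway classified differently at different depths appears in more than
#' one component, so component sizes may sum to more than the size of the
#' overall union — by design, matching per-depth classification.
#'
#' @param partitions Named list: depth -> [fraction_partition()] result.
#' @return List with components `dna_only`, `shared`, `rna_only`.
#' @export
union_fractions_over_depths <- function(partitions) {
  if (length(partitions) == 0L) stop_domain("at least one depth is required")
  comp <- function(name) sort(unique(unlist(lapply(partitions, `[[`, name),
                                            use.names = FALSE)))
  list(dna_only = comp("dna_only"), shared = comp("shared"),
       rna_only = comp("rna_only"))
}

#' Candidate distributed metabolic pathways
#'
#' Pathways predicted from a combined (multi-genome) dataset that are absent
#' from every individual genome's predictions — candidates for metabolism
#' completed only by combining reactions across genomes.
#'
#' @param combined Pathway set predicted from the combined genomes.
#' @param individuals List (>= 2) of pathway sets predicted from the
#'   individual genomes.
#' @return Sorted character vector of candidate pathway identifiers.
#' @export
distributed_candidates <- function(combined, individuals) {
  if (length(individuals) < 2L) {
    stop_domain("at least two individual pathway sets are required")
  }
  sort(setdiff(unique(combined),
               unique(unlist(individuals, use.names = FALSE))))
}

#' Plausibility filter for distributed-pathway candidates
#'
#' A candidate is plausible when sufficiently covered by both members of the
#' genome pair. Under the default per-reaction mode, a reaction counts only
#' if both genomes contribute at least one CDS to it, and the pathway is
#' plausible when the fraction of such reactions reaches `threshold`
#' (closed boundary: exactly 75% qualifies). The looser per-pathway mode
#' requires `threshold` of reactions covered by anyone plus each genome
#' contributing somewhere in the pathway.
#'
#' @param candidates Character vector of candidate pathway identifiers.
#' @param reaction_coverage Named list: pathway -> named list of reactions,
#'   each a character vector of contributing genome labels.
#' @param pair Character vector of the two genome labels.
#' @param threshold Minimum coverage fraction (default 0.75).
#' @param coverage_mode `"per_reaction"` (default) or `"per_pathway"`.
#' @return Data frame with columns `pathway`, `pair`, `coverage_both`,
#'   `plausible`. Candidates lacking coverage data are reported implausible
#'   with coverage `NA` and a warning.
#' @export
plausibility_filter <- function(candidates, reaction_coverage, pair,
                                threshold = 0.75,
                                coverage_mode = c("per_reaction",
                                                  "per_pathway")) {
  coverage_mode <- match.arg(coverage_mode)
  if (length(pair) != 2L) stop_domain("pair must name exactly two genomes")
  if (threshold < 0 || threshold > 1) stop_domain("threshold must be in [0, 1]")

  rows <- lapply(sort(unique(candidates)), function(p) {
    rxns <- reaction_coverage[[p]]
    if (is.null(rxns) || length(rxns) == 0L) {
      warning(sprintf("no reaction coverage for candidate '%s'; reported implausible", p),
              call. = FALSE)
      return(data.frame(pathway = p, pair = paste(pair, collapse = "+"),
                        coverage_both = NA_real_, plausible = FALSE,
                        stringsAsFactors = FALSE))
    }
    if (coverage_mode == "per_reaction") {
      both <- vapply(rxns, function(g) all(pair %in% g), logical(1))
      cov <- sum(both) / length(rxns)
      ok <- cov >= threshold
    } else {
      covered <- vapply(rxns, function(g) length(g) > 0L, logical(1))
      cov <- sum(covered) / length(rxns)
      contributors <- unique(unlist(rxns, use.names = FALSE))
      ok <- cov >= threshold && all(pair %in% contributors)
    }
    data.frame(pathway = p, pair = paste(pair, collapse = "+"),
               coverage_both = cov, plausible = ok, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(pathway = character(), pair = character(),
                      coverage_both = numeric(), plausible = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
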