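# Long-form pathway-prediction tables: the exchange format downstream of
# pathway inference. One record per (sample, pathway) carrying reaction and
# CDS counts plus optional per-CDS taxon annotations.

#' Construct a pathway table
#'
#' @param records Data frame with columns `sample`, `pathway_id`,
#'   `pathway_name` (optional), `n_reactions`, `n_covered`, `n_cds`,
#'   `cds_taxa` (optional; semicolon-separated taxon labels, one per CDS).
#' @param total_orfs Named numeric vector: total predicted ORFs per sample,
#'   the normalization denominator. May be `NULL` until normalization.
#' @return An object of class `pathway_table`.
#' @export
pathway_table <- function(records, total_orfs = NULL) {
  req <- c("sample", "pathway_id", "n_reactions", "n_covered", "n_cds")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0L) {
    stop_schema("pathway records missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (!"pathway_name" %in% names(records)) records$pathway_name <- records$pathway_id
  if (!"cds_taxa" %in% names(records)) records$cds_taxa <- ""
  records$cds_taxa[is.na(records$cds_taxa)] <- ""

  key <- paste(records$sample, records$pathway_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("sample", "pathway_id")][1L, ]
    stop_schema("duplicate (sample, pathway) record: (%s, %s)",
                dup$sample, dup$pathway_id)
  }
  for (col in c("n_reactions", "n_covered", "n_cds")) {
    records[[col]] <- as_count(records[[col]], col)
  }
  if (any(records$n_reactions < 1L)) {
    stop_schema("n_reactions must be positive for every record")
  }
  bad <- records$n_covered > records$n_reactions
  if (any(bad)) {
    stop_schema("n_covered exceeds n_reactions for (%s, %s)",
                records$sample[bad][1L], records$pathway_id[bad][1L])
  }
  has_taxa <- nzchar(records$cds_taxa)
  # label count = separator count + 1 (cheap; avoids splitting long strings)
  n_lab <- ifelse(has_taxa,
                  nchar(records$cds_taxa) -
                    nchar(gsub(";", "", records$cds_taxa, fixed = TRUE)) + 1L,
                  0L)
  mism <- has_taxa & n_lab != records$n_cds
  if (any(mism)) {
    stop_schema("cds_taxa count (%d) != n_cds (%d) for (%s, %s)",
                n_lab[mism][1L], records$n_cds[mism][1L],
                records$sample[mism][1L], records$pathway_id[mism][1L])
  }
  if (!is.null(total_orfs)) {
    total_orfs <- stats::setNames(as.numeric(total_orfs), names(total_orfs))
    if (any(total_orfs <= 0)) stop_schema("total_orfs must be positive")
  }
  rownames(records) <- NULL
  structure(list(records = records, total_orfs = total_orfs),
            class = "pathway_table")
}

#' @export
print.pathway_table <- function(x, ...) {
  cat(sprintf("pathway_table: %d records, %d sample(s), %d distinct pathway(s)\n",
              nrow(x$records), length(unique(x$records$sample)),
              length(unique(x$records$pathway_id))))
  invisible(x)
}

#' Read a pathway table
#'
#' TSV dialect modelled on long-form pathway exports from pathway/genome
#' databases: header row with `sample`, `pathway_id`, `n_reactions`,
#' `n_covered`, `n_cds` (plus optional `pathway_name`, `cds_taxa`), `#`
#' comment lines. Duplicate (sample, pathway) rows are a schema error.
#'
#' @param source File path, connection, or character lines.
#' @param totals_source Optional totals file (TSV `sample`, `total_orfs`).
#' @return A [pathway_table()].
#' @export
read_pathway_table <- function(source, totals_source = NULL) {
  df <- read_tsv_dialect(source, required = c("sample", "pathway_id",
                                              "n_reactions", "n_covered",
                                              "n_cds"))
  totals <- NULL
  if (!is.null(totals_source)) totals <- read_total_orfs(totals_source)
  pathway_table(df, totals)
}

#' Read a per-sample total-ORF file
#'
#' @param source TSV with columns `sample`, `total_orfs`.
#' @return Named numeric vector.
#' @export
read_total_orfs <- function(source) {
  df <- read_tsv_dialect(source, required = c("sample", "total_orfs"))
  stats::setNames(as.numeric(as_count(df$total_orfs, "total_orfs")), df$sample)
}

#' Write a pathway table (and optionally its totals)
#'
#' @param x A [pathway_table()].
#' @param path Output TSV path.
#' @param totals_path Optional output path for the totals TSV.
#' @export
write_pathway_table <- function(x, path, totals_path = NULL) {
  write_tsv_dialect(x$records[, c("sample", "pathway_id", "pathway_name",
                                  "n_reactions", "n_covered", "n_cds",
                                  "cds_taxa")], path)
  if (!is.null(totals_path) && !is.null(x$total_orfs)) {
    write_tsv_dialect(data.frame(sample = names(x$total_orfs),
                                 total_orfs = unname(x$total_orfs)),
                      totals_path)
  }
  invisible(path)
}

#' Quality-control filter on mapped CDS counts
#'
#' Keeps the records with at least `min_cds` mapped CDS sequences,
#' judged per sample: a pathway can survive in one sample and be removed
#' in another. The default of 10 removes the sparsely supported lower tail
#' of pathway annotations most likely to be spurious.
#'
#' @param x A [pathway_table()].
#' @param min_cds Minimum mapped CDS count to keep (default 10).
#' @return A filtered [pathway_table()].
#' @export
qc_filter <- function(x, min_cds = 10L) {
  if (min_cds < 1L) stop_domain("min_cds must be >= 1")
  keep <- x$records$n_cds >= min_cds
  pathway_table(x$records[keep, , drop = FALSE], x$total_orfs)
}

#' Normalize pathway CDS counts to relative ORF abundance
#'
#' Divides each record's CDS count by the sample's total predicted ORFs and
#' converts to a percentage, making abundances comparable across samples of
#' different sequencing effort.
#'
#' @param x A [pathway_table()] with `total_orfs` set for every sample.
#' @param denominator Optional named vector overriding `x$total_orfs`.
#' @return Data frame with columns `sample`, `pathway_id`, `rel_cds_pct`.
#' @export
normalize_counts <- function(x, denominator = NULL) {
  totals <- denominator %||% x$total_orfs
  if (is.null(totals)) {
    stop_domain("no total_orfs available; supply a totals file or denominator")
  }
  samples <- unique(x$records$sample)
  missing <- setdiff(samples, names(totals))
  if (length(missing) > 0L) {
    stop_domain("total_orfs missing for sample(s): %s",
                paste(missing, collapse = ", "))
  }
  if (any(totals[samples] <= 0)) stop_domain("total_orfs must be positive")
  data.frame(sample = x$records$sample,
             pathway_id = x$records$pathway_id,
             rel_cds_pct = 100 * x$records$n_cds /
               unname(totals[x$records$sample]),
             stringsAsFactors = FALSE)
}

#' Per-sample pathway presence sets
#'
#' @param x A [pathway_table()].
#' @return Named list: sample -> character vector of pathway identifiers
#'   present in that sample.
#' @export
presence_sets <- function(x) {
  if (nrow(x$records) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(x$records$pathway_id, x$records$sample), function(p) sort(unique(p)))
}
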