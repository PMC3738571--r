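# Reciprocal-best-hit orthology. A pipeline sequence q and a reference
# gene s form a best-reciprocal pair when s is q's best-scoring reference
# match and q is s's best-scoring pipeline match, both under an e-value
# ceiling (1e-10 by convention). The machinery is agnostic to where the
# hit tables came from: the built-in nucleotide aligner for synthetic
# runs, or imported protein-space searches for real data.

#' Best hit for each query in a hit table
#'
#' Minimum e-value wins; ties break by higher bit score, then
#' lexicographically smaller subject id, so the choice is deterministic.
#'
#' @param hits a hit data.frame.
#' @param max_evalue ceiling; hits above it are ignored.
#' @return one row per query with a qualifying hit.
#' @export
best_hit <- function(hits, max_evalue = 1e-10) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  h <- h[order(h$query_id, h$evalue, -h$bitscore, h$subject_id), ,
         drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Best reciprocal hits between a pipeline set and a reference set
#'
#' @param forward_hits hits of pipeline sequences against the reference.
#' @param reciprocal_hits hits of reference genes against the pipeline set.
#' @param max_evalue e-value ceiling applied to both directions.
#' @param ref_set_name label stored with each pair.
#' @return data.frame with query_id, subject_id, ref_set, forward_evalue,
#'   reciprocal_evalue; each query appears at most once.
#' @export
brbh <- function(forward_hits, reciprocal_hits, max_evalue = 1e-10,
                 ref_set_name = "ref") {
  fb <- best_hit(forward_hits, max_evalue)
  rb <- best_hit(reciprocal_hits, max_evalue)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      ref_set = character(), forward_evalue = numeric(),
                      reciprocal_evalue = numeric(), stringsAsFactors = FALSE)
  if (nrow(fb) == 0L || nrow(rb) == 0L) return(empty)
  rb_best <- stats::setNames(rb$subject_id, rb$query_id)
  mutual <- !is.na(rb_best[fb$subject_id]) &
    rb_best[fb$subject_id] == fb$query_id
  fb <- fb[mutual, , drop = FALSE]
  if (nrow(fb) == 0L) return(empty)
  rb_ev <- stats::setNames(rb$evalue, rb$query_id)
  out <- data.frame(query_id = fb$query_id, subject_id = fb$subject_id,
                    ref_set = ref_set_name, forward_evalue = fb$evalue,
                    reciprocal_evalue = unname(rb_ev[fb$subject_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of unique queries across several reciprocal-best-hit sets
#'
#' @param brbh_sets named list of [brbh()] tables.
#' @return list with `count` and the sorted `ids`.
#' @export
unique_hit_union <- function(brbh_sets) {
  stopifnot(length(brbh_sets) >= 1L)
  ids <- sort(unique(unlist(lapply(brbh_sets, function(b) b$query_id),
                            use.names = FALSE)))
  list(count = length(ids), ids = ids)
}

#' Four-set core-ortholog intersection lattice
#'
#' Partitions the union of queries from exactly four reciprocal-best-hit
#' sets into the 15 regions of the four-set Venn lattice, keyed by query
#' id only (a query matching different reference genes in different sets
#' still counts once per set). The core is the all-four region: the
#' operational core ortholog set shared by every reference.
#'
#' @param brbh_sets named list of exactly 4 [brbh()] tables.
#' @return list of class `core_set_report`: `regions` (named counts, names
#'   like `"A|C|D"` built from set names), `core_count`, `union_count`,
#'   `core_pct` and `core_ids`.
#' @export
core_intersection <- function(brbh_sets) {
  if (length(brbh_sets) != 4L) {
    stop("core_intersection needs exactly 4 reference sets, got ",
         length(brbh_sets))
  }
  nm <- names(brbh_sets)
  if (is.null(nm)) nm <- paste0("set", 1:4)
  members <- lapply(brbh_sets, function(b) unique(b$query_id))
  universe <- sort(unique(unlist(members, use.names = FALSE)))
  key <- vapply(universe, function(q) {
    paste(nm[vapply(members, function(m) q %in% m, logical(1))],
          collapse = "|")
  }, character(1))
  # all 15 non-empty subsets, fixed order
  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(nm, k, FUN = paste, collapse = "|", simplify = FALSE)
  }))
  regions <- stats::setNames(integer(length(subsets)), unlist(subsets))
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  core_key <- paste(nm, collapse = "|")
  core_ids <- universe[key == core_key]
  structure(list(regions = regions,
                 core_count = length(core_ids),
                 union_count = length(universe),
                 core_pct = if (length(universe))
                   100 * length(core_ids) / length(universe) else NA_real_,
                 core_ids = core_ids),
            class = "core_set_report")
}

#' Place pipeline sequences on a genetic map via reciprocal best hits
#'
#' Each query whose reciprocal-best partner is present in the map inherits
#' the partner's chromosome and centimorgan position; `bin_index` is
#' `floor(cM / bin_width_cM)`. Queries whose partner is absent from the
#' map are skipped with a warning and counted.
#'
#' @param brbh_pairs a [brbh()] table against the mapped gene set.
#' @param genetic_map data.frame from [read_genetic_map()].
#' @param bin_width_cM bin width in centimorgans.
#' @return data.frame query_id, gene_id, chromosome, position_cM,
#'   bin_index, with attribute `n_unplaced`.
#' @export
place_on_map <- function(brbh_pairs, genetic_map, bin_width_cM = 5) {
  stopifnot(bin_width_cM > 0)
  idx <- match(brbh_pairs$subject_id, genetic_map$gene_id)
  unplaced <- sum(is.na(idx))
  if (unplaced > 0L) {
    warning(unplaced, " quer", if (unplaced == 1L) "y" else "ies",
            " with partners absent from the genetic map were skipped")
  }
  keep <- !is.na(idx)
  out <- data.frame(
    query_id = brbh_pairs$query_id[keep],
    gene_id = genetic_map$gene_id[idx[keep]],
    chromosome = genetic_map$chromosome[idx[keep]],
    position_cM = genetic_map$cM[idx[keep]],
    stringsAsFactors = FALSE)
  out$bin_index <- as.integer(floor(out$position_cM / bin_width_cM))
  attr(out, "n_unplaced") <- unplaced
  out
}
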