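# NB-LRR resistance-gene mining. Two independent predictors are compared:
# (1) a two-stage domain cascade -- sequences with an NB-ARC domain hit at
# a strict domain e-value (0.1), then, *within* that set only, sequences
# that also carry an intracellular LRR-clan hit -- and (2) a lexical search
# of annotation terms for "nblrr" / "nb-lrr". Their narrow overlap is the
# interesting observable: diversifying selection makes this family poorly
# covered by homology-transferred annotation alone.

#' Read a domain-hit table
#'
#' TSV with columns seq_id, profile_name, profile_class, domain_evalue,
#' start, end, as produced by profile-search tools after column mapping.
#' `profile_class` must be one of `NB_ARC`, `LRR_clan`, `other`.
#'
#' @param path path to the TSV (with header).
#' @return a domain-hit data.frame.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("seq_id", "profile_name", "profile_class", "domain_evalue",
            "start", "end")
  if (!all(need %in% names(d))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[, need]
  stopifnot(all(d$profile_class %in% c("NB_ARC", "LRR_clan", "other")),
            all(d$domain_evalue >= 0), all(d$start < d$end))
  d
}

#' Read an annotation-term table
#'
#' TSV with header columns `seq_id` and `term` (one term per row); terms
#' are aggregated per sequence.
#'
#' @param path path to the TSV.
#' @return named list mapping seq_id to its character vector of terms.
#' @export
read_annotations <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE)
  if (!all(c("seq_id", "term") %in% names(a))) {
    stop("annotation table must have columns seq_id, term")
  }
  split(a$term, a$seq_id)
}

#' Select sequences with a qualifying domain hit
#'
#' @param hits a domain-hit data.frame.
#' @param profile_class the class to select on.
#' @param max_domain_evalue per-domain e-value threshold (default 0.1, the
#'   strict cutoff that removes most false profile matches).
#' @return sorted unique seq_ids with >= 1 qualifying hit.
#' @export
select_domain_hits <- function(hits, profile_class,
                               max_domain_evalue = 0.1) {
  sel <- hits$profile_class == profile_class &
    hits$domain_evalue <= max_domain_evalue
  sort(unique(hits$seq_id[sel]))
}

#' Two-stage NB-ARC / LRR domain cascade
#'
#' NB-ARC positives are selected first; the LRR-clan search then applies
#' only within that set, so the NB-LRR predictions are a subset of the
#' NB-ARC predictions by construction. A sequence carrying an LRR hit but
#' no NB-ARC hit is in neither set.
#'
#' @param all_hits a domain-hit data.frame carrying both classes.
#' @param max_domain_evalue per-domain e-value threshold for both stages.
#' @return list with `nbarc_ids` and `nblrr_ids` (subset of the former).
#' @export
nblrr_cascade <- function(all_hits, max_domain_evalue = 0.1) {
  nbarc <- select_domain_hits(all_hits, "NB_ARC", max_domain_evalue)
  lrr <- select_domain_hits(all_hits, "LRR_clan", max_domain_evalue)
  list(nbarc_ids = nbarc, nblrr_ids = intersect(lrr, nbarc))
}

#' Lexical NB-LRR search over annotation terms
#'
#' Case-insensitive substring match of "nblrr" or "nb-lrr" against every
#' term of every sequence.
#'
#' @param annotations named list mapping seq_id to term strings.
#' @return sorted seq_ids with a matching term.
#' @export
lexical_search <- function(annotations) {
  hit <- vapply(annotations, function(terms) {
    lt <- tolower(terms)
    any(grepl("nblrr", lt, fixed = TRUE) | grepl("nb-lrr", lt, fixed = TRUE))
  }, logical(1))
  sort(names(annotations)[hit])
}

#' Overlap of the cascade and lexical predictions
#'
#' @param cascade_ids,lexical_ids id vectors from the two predictors over
#'   the same sequence universe.
#' @return list with both, only_cascade, only_lexical counts and the
#'   shared ids; the three counts sum to the union size.
#' @export
compare_predictions <- function(cascade_ids, lexical_ids) {
  cascade_ids <- unique(cascade_ids)
  lexical_ids <- unique(lexical_ids)
  shared <- intersect(cascade_ids, lexical_ids)
  list(both = length(shared),
       only_cascade = length(setdiff(cascade_ids, lexical_ids)),
       only_lexical = length(setdiff(lexical_ids, cascade_ids)),
       shared_ids = sort(shared))
}

# ---- toy motif scanner -------------------------------------------------
# The production path consumes externally produced domain-hit tables; for
# synthetic runs a position-specific scanner over the planted motif
# consensus stands in for profile search. The reported "e-value" is the
# binomial tail probability of observing at least the window's match count
# by chance (base composition 1/4) times the number of windows scanned over
# the whole database -- the database-wide expected chance-hit count, as
# profile-search tools report it, so a strict threshold bounds the
# per-database false yield.

scan_one_motif <- function(seq, motif) {
  w <- nchar(motif)
  n <- nchar(seq)
  if (n < w) return(NULL)
  mch <- strsplit(motif, "")[[1]]
  sch <- strsplit(seq, "")[[1]]
  n_win <- n - w + 1L
  # match-count profile over all windows
  counts <- integer(n_win)
  for (k in seq_len(w)) {
    counts <- counts + (sch[k:(k + n_win - 1L)] == mch[k])
  }
  best <- which.max(counts)
  m <- counts[best]
  list(start = best, end = best + w - 1L, matches = m,
       evalue = n_win * stats::pbinom(m - 1L, w, 0.25, lower.tail = FALSE))
}

#' Scan sequences for planted domain motifs
#'
#' @param seqs a `seq_set`.
#' @param motifs named list of motif consensus strings; names are profile
#'   names.
#' @param classes named character vector mapping profile name to
#'   `profile_class`.
#' @return a domain-hit data.frame (best window per sequence per motif,
#'   with the e-value scaled to the whole scanned set).
#' @export
scan_domains <- function(seqs, motifs, classes) {
  rows <- list()
  n_db <- nrow(seqs)
  for (i in seq_len(nrow(seqs))) {
    for (nm in names(motifs)) {
      hit <- scan_one_motif(seqs$seq[i], motifs[[nm]])
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seqs$id[i], profile_name = nm,
        profile_class = unname(classes[[nm]]),
        domain_evalue = n_db * hit$evalue, start = hit$start, end = hit$end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), profile_name = character(),
                      profile_class = character(), domain_evalue = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Default motif set for the toy scanner
#' @return list with `motifs` and `classes` for [scan_domains()].
#' @export
default_rgene_motifs <- function() {
  list(motifs = list(NB_ARC_toy = NBARC_MOTIF, LRR_toy = LRR_MOTIF),
       classes = c(NB_ARC_toy = "NB_ARC", LRR_toy = "LRR_clan"))
}
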