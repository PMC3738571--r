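# The read-preprocessing cascade: a length filter followed by alignment
# screens against repeat, organelle and human contaminant libraries, with
# sequential accounting. Each stage sees only the survivors of the previous
# stage, and each stage's removal percentage is reported relative to the
# reads *entering* that stage (the sequential-denominator convention, the
# only one under which the published per-stage percentages for this kind of
# table are arithmetically self-consistent).

#' Define one screening rule
#'
#' @param name one of `"short_reads"`, `"triticeae_repeats"`, `"organelle"`,
#'   `"human_repeats"`.
#' @param library contaminant `seq_set` (empty for `short_reads`).
#' @param max_evalue,min_query_cov,min_identity alignment thresholds: a read
#'   is removed iff it has a hit with e-value at or below `max_evalue`,
#'   query coverage at least `min_query_cov` percent and identity at least
#'   `min_identity` percent. The conventional settings are 1e-6 with 85/85
#'   for transposon repeats and 1e-6 with 90/90 for organelle and human
#'   screens.
#' @param min_len minimum read length in nt (`short_reads` only): reads
#'   strictly shorter than `min_len` are removed, i.e. the default 46 drops
#'   reads of 45 nt and below.
#' @return a list of class `screen_rule`.
#' @export
screen_rule <- function(name, library = NULL, max_evalue = 1e-6,
                        min_query_cov = 85, min_identity = 85,
                        min_len = 46L) {
  name <- match.arg(name, c("short_reads", "triticeae_repeats", "organelle",
                            "human_repeats"))
  stopifnot(max_evalue > 0, min_query_cov >= 0, min_query_cov <= 100,
            min_identity >= 0, min_identity <= 100)
  if (name != "short_reads" && (is.null(library) || nrow(library) == 0L)) {
    stop("screen_rule '", name, "' needs a non-empty library")
  }
  structure(list(name = name, library = library, max_evalue = max_evalue,
                 min_query_cov = min_query_cov, min_identity = min_identity,
                 min_len = as.integer(min_len)), class = "screen_rule")
}

#' Remove short reads
#'
#' @param reads a `seq_set`.
#' @param min_len reads shorter than this survive removal only if their
#'   length is at least `min_len`; the default 46 removes reads of <= 45 nt.
#' @return list with `kept` and `removed` `seq_set`s partitioning the input.
#' @export
length_filter <- function(reads, min_len = 46L) {
  keep <- nchar(reads$seq) >= min_len
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Screen reads against a contaminant library
#'
#' A read is removed iff it has at least one alignment to the library
#' passing the rule's e-value, query-coverage and identity thresholds
#' simultaneously.
#'
#' @param reads a `seq_set`.
#' @param rule a [screen_rule()] with a non-empty library.
#' @param aligner_params [align_params()] for the similarity engine; its
#'   e-value ceiling is raised to the rule's threshold if tighter.
#' @return list with `kept` and `removed` `seq_set`s.
#' @export
screen_by_library <- function(reads, rule, aligner_params = align_params()) {
  stopifnot(inherits(rule, "screen_rule"), !is.null(rule$library))
  if (nrow(reads) == 0L) {
    return(list(kept = reads, removed = reads))
  }
  p <- aligner_params
  p$max_evalue <- max(p$max_evalue, rule$max_evalue)
  hits <- all_vs_all(reads, rule$library, p)
  bad_ids <- character()
  if (nrow(hits) > 0L) {
    pass <- hits$evalue <= rule$max_evalue &
      hits$q_cov >= rule$min_query_cov &
      hits$pct_identity >= rule$min_identity
    bad_ids <- unique(hits$query_id[pass])
  }
  keep <- !(reads$id %in% bad_ids)
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Run the full screening cascade
#'
#' Applies the rules in order, each stage consuming the previous stage's
#' survivors, and reports per-stage counts and percentages plus a per-read
#' disposition. Conservation (kept + removed = entering) is asserted at
#' every stage. A read matching several libraries is attributed to the
#' first stage that removes it.
#'
#' @param reads a `seq_set`.
#' @param rules list of [screen_rule()]s in cascade order.
#' @param aligner_params [align_params()] shared by all alignment screens.
#' @return a list of class `qc_report`: `stages` (data.frame stage,
#'   input_count, removed_count, removed_pct), `final_count`, `kept` (the
#'   surviving `seq_set`) and `disposition` (data.frame read_id, stage or
#'   `"kept"`).
#' @export
run_cascade <- function(reads, rules, aligner_params = align_params()) {
  current <- reads
  disposition <- stats::setNames(rep("kept", nrow(reads)), reads$id)
  stage_rows <- list()
  for (rule in rules) {
    entering <- nrow(current)
    res <- if (rule$name == "short_reads") {
      length_filter(current, rule$min_len)
    } else {
      screen_by_library(current, rule, aligner_params)
    }
    stopifnot(nrow(res$kept) + nrow(res$removed) == entering)
    disposition[res$removed$id] <- rule$name
    stage_rows[[length(stage_rows) + 1L]] <- data.frame(
      stage = rule$name, input_count = entering,
      removed_count = nrow(res$removed),
      removed_pct = round(100 * nrow(res$removed) / max(1L, entering), 2),
      stringsAsFactors = FALSE)
    current <- res$kept
  }
  stages <- if (length(stage_rows)) do.call(rbind, stage_rows) else
    data.frame(stage = character(), input_count = integer(),
               removed_count = integer(), removed_pct = numeric(),
               stringsAsFactors = FALSE)
  structure(list(stages = stages, input_count = nrow(reads),
                 final_count = nrow(current), kept = current,
                 disposition = data.frame(read_id = names(disposition),
                                          stage = unname(disposition),
                                          stringsAsFactors = FALSE)),
            class = "qc_report")
}

#' Replay a preprocessing table from printed stage counts
#'
#' Adapter clipping is performed upstream of this package, so published
#' preprocessing tables start from a raw count and list per-stage removal
#' counts (clipping included as an externally supplied removal). This
#' replays such a table under strict sequential accounting: stage k's
#' percentage is its removals over the reads entering stage k, to two
#' decimals, and the final count is the raw count minus all removals.
#'
#' @param raw_count reads before any processing.
#' @param removals named integer vector of per-stage removal counts, in
#'   cascade order.
#' @return data.frame with stage, entering, removed, removed_pct rows plus
#'   a `final_count` attribute.
#' @export
qc_replay <- function(raw_count, removals) {
  stopifnot(raw_count >= 0, all(removals >= 0))
  entering <- raw_count
  rows <- list()
  for (i in seq_along(removals)) {
    rem <- removals[[i]]
    if (rem > entering) stop("stage removes more reads than enter it")
    rows[[i]] <- data.frame(
      stage = if (is.null(names(removals))) as.character(i) else
        names(removals)[i],
      entering = entering, removed = rem,
      removed_pct = round(100 * rem / entering, 2), stringsAsFactors = FALSE)
    entering <- entering - rem
  }
  out <- do.call(rbind, rows)
  attr(out, "final_count") <- entering
  out
}
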