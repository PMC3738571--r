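# Assembly statistics and the two reliability diagnostics used for de novo
# transcriptome assemblies without a reference genome: the correlation of
# contig length with the number of constituent reads (a sound OLC assembly
# builds longer contigs from more reads), and the degree of redundancy
# revealed by aligning a contig set against itself.

#' N50 of a length multiset
#'
#' The smallest length L such that sequences of length >= L together span
#' at least half of the assembly's nucleotides; equivalently the length of
#' the contig that spans the median nucleotide of the assembly. Ties (when
#' several candidate lengths qualify) resolve to the largest qualifying
#' contig length by construction of the scan.
#'
#' @param lengths non-empty numeric vector of sequence lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50: empty length set")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(l)
  l[which(cum >= sum(l) / 2)[1L]]
}

#' Summary statistics of an assembly
#'
#' @param contigs a `seq_set`.
#' @return list with n_sequences, n50, longest, total_nt.
#' @export
assembly_stats <- function(contigs) {
  lens <- nchar(contigs$seq)
  list(n_sequences = nrow(contigs), n50 = n50(lens),
       longest = max(lens), total_nt = sum(lens))
}

#' Contig length versus read count correlation
#'
#' Correlates log contig length against log constituent-read count, the
#' standard sanity check that an assembly's contig sizes are driven by
#' data rather than artifacts.
#'
#' @param contigs a `seq_set`.
#' @param read_counts named vector mapping contig id to the number of
#'   reads that built it (all >= 1).
#' @return list with pearson_r_loglog, spearman_rho and n.
#' @export
length_vs_reads <- function(contigs, read_counts) {
  counts <- unname(read_counts[contigs$id])
  if (any(is.na(counts))) stop("read_counts missing for some contigs")
  if (any(counts < 1)) stop("read counts must be >= 1")
  n <- nrow(contigs)
  if (n < 3L) stop("length_vs_reads needs at least 3 contigs")
  ll <- log(nchar(contigs$seq)); lr <- log(as.numeric(counts))
  list(pearson_r_loglog = stats::cor(ll, lr, method = "pearson"),
       spearman_rho = stats::cor(ll, lr, method = "spearman"),
       n = n)
}

#' Self-alignment redundancy of a contig set
#'
#' Aligns the set against itself, discards self pairs, counts each
#' unordered pair once, and reports the proportion of contigs that
#' participate in at least one significant non-self pair. "Significant"
#' defaults to e-value <= 1e-10 with at least half the query aligned,
#' matching the significance level used for reciprocal-best-hit detection;
#' both knobs are exposed because published practice rarely states them.
#'
#' @param contigs a `seq_set` with >= 2 members.
#' @param aligner_params [align_params()].
#' @param max_evalue significance ceiling for a redundant pair.
#' @param min_query_cov minimum percent of the query aligned.
#' @return list with n_significant_nonself_pairs, n_sequences_in_pairs,
#'   proportion (percent of contigs in >= 1 pair) and the pair table.
#' @export
self_redundancy <- function(contigs, aligner_params = align_params(),
                            max_evalue = 1e-10, min_query_cov = 50) {
  stopifnot(nrow(contigs) >= 2L)
  p <- aligner_params
  p$max_evalue <- max(p$max_evalue, max_evalue)
  hits <- all_vs_all(contigs, contigs, p)
  hits <- hits[hits$query_id != hits$subject_id &
                 hits$evalue <= max_evalue &
                 hits$q_cov >= min_query_cov, , drop = FALSE]
  if (nrow(hits)) {
    a <- pmin(hits$query_id, hits$subject_id)
    b <- pmax(hits$query_id, hits$subject_id)
    pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  } else {
    pairs <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
  }
  in_pairs <- unique(c(pairs$a, pairs$b))
  list(n_significant_nonself_pairs = nrow(pairs),
       n_sequences_in_pairs = length(in_pairs),
       proportion = 100 * length(in_pairs) / nrow(contigs),
       pairs = pairs)
}
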