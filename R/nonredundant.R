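# Greedy identity-threshold clustering (CD-HIT-EST style): sequences are
# visited longest-first and each joins the first existing cluster whose
# representative it matches at >= identity over >= min_short_cov percent of
# the shorter sequence, else founds a new cluster. Representatives are the
# longest members, which is what makes the representative set a
# non-redundant extraction of the pooled assemblies.

similar_to_rep <- function(qseq, kq, rep_prof, identity_threshold,
                           min_short_cov, params) {
  aln <- align_core(qseq, kq, rep_prof, params)
  if (is.null(aln)) return(FALSE)
  res <- aln$res
  shorter <- min(nchar(qseq), nchar(rep_prof$seq))
  100 * res$matches / res$aln_len >= identity_threshold &&
    100 * res$aln_len / shorter >= min_short_cov
}

#' Greedy identity clustering
#'
#' Identity is measured over the best local alignment (both strands) and
#' coverage over the shorter sequence, with an 80 percent floor by default
#' so short fragments are only absorbed by sequences they substantially
#' overlap. The input order is irrelevant: sequences are canonically
#' sorted by decreasing length (ties by id) before the greedy pass, so the
#' clustering is deterministic.
#'
#' @param seqs a non-empty `seq_set`.
#' @param identity_threshold percent identity for cluster membership
#'   (default 90, the conventional default for EST collapsing).
#' @param min_short_cov minimum percent of the shorter sequence covered by
#'   the alignment.
#' @param aligner_params [align_params()]; the e-value ceiling is not used
#'   as a gate here (similarity is decided by identity and coverage), so a
#'   permissive ceiling is substituted.
#' @return list of clusters, each a list with `representative_id`,
#'   `member_ids` (representative included) and `threshold_used`. Clusters
#'   partition the input.
#' @export
cluster_greedy <- function(seqs, identity_threshold = 90,
                           min_short_cov = 80,
                           aligner_params = align_params()) {
  stopifnot(nrow(seqs) > 0L, identity_threshold > 0,
            identity_threshold <= 100)
  p <- aligner_params
  p$max_evalue <- 1e6   # gate on identity and coverage, not e-value
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  reps <- list()          # founding-order list of representative profiles
  members <- list()
  for (i in seq_len(nrow(seqs))) {
    qseq <- seqs$seq[i]
    kq <- seq_kmers(qseq, p$kmer)
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (similar_to_rep(qseq, kq, reps[[ci]], identity_threshold,
                         min_short_cov, p)) {
        members[[ci]] <- c(members[[ci]], seqs$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- subject_profile(seqs$id[i], qseq, p$kmer)
      members[[length(members) + 1L]] <- seqs$id[i]
    }
  }
  lapply(seq_along(reps), function(ci) {
    list(representative_id = reps[[ci]]$id, member_ids = members[[ci]],
         threshold_used = identity_threshold)
  })
}

#' Extract cluster representatives
#'
#' One record per cluster: its longest member, which by construction of
#' [cluster_greedy()] is the founding representative.
#'
#' @param clusters output of [cluster_greedy()].
#' @param seqs the `seq_set` that was clustered.
#' @return a `seq_set` of representatives, one per cluster.
#' @export
representatives <- function(clusters, seqs) {
  rep_ids <- vapply(clusters, `[[`, character(1), "representative_id")
  out <- seqs[match(rep_ids, seqs$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Cluster-count sweep over identity thresholds
#'
#' Clusters the same set at each threshold and tabulates the cluster
#' counts; the count is non-increasing as the threshold decreases (a
#' looser threshold can only merge).
#'
#' @param seqs a `seq_set`.
#' @param thresholds identity thresholds in percent.
#' @param min_short_cov,aligner_params as in [cluster_greedy()].
#' @return data.frame threshold, n_clusters, sorted by threshold.
#' @export
threshold_sweep <- function(seqs, thresholds = c(70, 80, 90, 95, 98),
                            min_short_cov = 80,
                            aligner_params = align_params()) {
  stopifnot(all(thresholds > 0 & thresholds <= 100))
  thresholds <- sort(thresholds)
  n <- vapply(thresholds, function(t) {
    length(cluster_greedy(seqs, t, min_short_cov, aligner_params))
  }, integer(1))
  data.frame(threshold = thresholds, n_clusters = n)
}
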