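#' Alignment parameters for the built-in similarity engine
#'
#' The engine is a k-mer-seeded local aligner (Smith-Waterman with affine
#' gaps) over both strands. It exists so the whole pipeline runs without an
#' external search tool; e-values use a simple Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with fixed ungapped-DNA defaults, and
#' are a configurable ranking device rather than a calibrated statistic --
#' every pipeline threshold that gates on them (1e-6, 1e-10, ...) is a
#' parameter.
#'
#' @param kmer seed length in nucleotides (>= 8); a pair of sequences is only
#'   aligned if they share at least one exact k-mer on some strand.
#' @param match,mismatch,gap_open,gap_extend scoring: a gap of length g
#'   scores `gap_open + (g - 1) * gap_extend` (the opening penalty includes
#'   the first gap position).
#' @param max_evalue hits with larger e-value are suppressed.
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters.
#' @param band optional half-width of a banded alignment around the seed
#'   diagonal; `NULL` (default) runs the full dynamic program. Banding is
#'   intended for read-to-reference placement where indels are not modelled.
#' @return a list of class `align_params`.
#' @export
align_params <- function(kmer = 12L, match = 1L, mismatch = -2L,
                         gap_open = -5L, gap_extend = -2L,
                         max_evalue = 10, karlin_lambda = 1.33,
                         karlin_k = 0.621, band = NULL) {
  stopifnot(kmer >= 8L, match > 0L, mismatch < 0L, gap_open < 0L,
            gap_extend < 0L, max_evalue > 0)
  structure(list(kmer = as.integer(kmer), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_evalue = max_evalue, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k, band = band),
            class = "align_params")
}

revcomp <- function(x) {
  vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

# precomputed per-subject search state: both strands' sequences and k-mer
# sets, plus (lazily, for banded mode) positional k-mer tables
subject_profile <- function(id, seq, k, positional = FALSE) {
  rc <- revcomp_cpp(seq)
  kf <- seq_kmers(seq, k)
  kr <- seq_kmers(rc, k)
  p <- list(id = id, seq = seq, rc = rc, kf = kf, kr = kr)
  if (positional) {
    p$pf <- split(seq_along(kf), kf)
    p$pr <- split(seq_along(kr), kr)
  }
  p
}

# candidate diagonals (j - i) from positional k-mer tables
seed_diagonals_pos <- function(kq, spos) {
  hit <- which(kq %in% names(spos))
  if (!length(hit)) return(integer())
  sort(unique(unlist(lapply(hit, function(i) spos[[kq[i]]] - i),
                     use.names = FALSE)))
}

# group nearby diagonals so one banded pass covers each cluster; returns
# cluster centres, largest clusters first, capped for bounded work
cluster_diagonals <- function(diags, band, max_groups = 6L) {
  if (!length(diags)) return(integer())
  grp <- cumsum(c(1L, diff(diags) > band))
  sp <- split(diags, grp)
  centres <- vapply(sp, function(d) as.integer(round(mean(d))), integer(1))
  ord <- order(-lengths(sp), centres)
  unname(centres[ord][seq_len(min(max_groups, length(centres)))])
}

# best local alignment of a query against one strand of a profile
sw_one_strand <- function(qseq, kq, sseq, ks, spos, p) {
  if (is.null(p$band)) {
    if (!any(kq %in% ks)) return(NULL)
    res <- sw_full_cpp(qseq, sseq, p$match, p$mismatch, p$gap_open,
                      p$gap_extend)
    if (res$score <= 0) return(NULL)
    return(res)
  }
  diags <- seed_diagonals_pos(kq, spos)
  if (!length(diags)) return(NULL)
  best <- NULL
  for (d in cluster_diagonals(diags, p$band)) {
    res <- sw_banded_cpp(qseq, sseq, p$match, p$mismatch, p$gap_open,
                         p$gap_extend, d, p$band)
    if (res$score > 0 && (is.null(best) || res$score > best$score)) best <- res
  }
  best
}

# best alignment of a query against both strands of a subject profile;
# forward wins score ties for determinism
align_core <- function(qseq, kq, prof, p) {
  fwd <- sw_one_strand(qseq, kq, prof$seq, prof$kf, prof$pf, p)
  rev <- sw_one_strand(qseq, kq, prof$rc, prof$kr, prof$pr, p)
  if (!is.null(fwd) && (is.null(rev) || fwd$score >= rev$score)) {
    list(res = fwd, strand = "+")
  } else if (!is.null(rev)) {
    list(res = rev, strand = "-")
  } else {
    NULL
  }
}

karlin_evalue <- function(score, m, n, params) {
  params$karlin_k * m * n * exp(-params$karlin_lambda * score)
}

# assemble the standard hit row from an align_core result
hit_row <- function(qid, qlen, prof, aln, ev, params, keep_path = FALSE) {
  res <- aln$res
  slen <- nchar(prof$seq)
  if (aln$strand == "+") {
    s_start <- res$s_start; s_end <- res$s_end
  } else {
    # map reverse-strand coordinates back to the forward subject strand;
    # s_start > s_end marks the minus strand
    s_start <- slen - res$s_start + 1L
    s_end <- slen - res$s_end + 1L
  }
  hit <- data.frame(
    query_id = qid, subject_id = prof$id,
    pct_identity = 100 * res$matches / res$aln_len,
    aln_len = res$aln_len, mismatches = res$mismatches,
    gap_opens = res$gap_opens,
    q_start = res$q_start, q_end = res$q_end,
    s_start = s_start, s_end = s_end,
    evalue = ev,
    bitscore = (params$karlin_lambda * res$score - log(params$karlin_k)) /
      log(2),
    q_cov = 100 * (res$q_end - res$q_start + 1) / qlen,
    stringsAsFactors = FALSE)
  hit$score <- res$score
  if (keep_path) {
    attr(hit, "path") <- list(q_cols = res$q_cols, s_cols = res$s_cols,
                              strand = aln$strand)
  }
  hit
}

as_seqrec <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id, seq = x$seq)
  } else {
    stopifnot(is.list(x), !is.null(x$id), !is.null(x$seq))
    x
  }
}

#' Align one query against one subject
#'
#' Searches both strands for the best local alignment, seeded by a shared
#' k-mer, and reports it as one tabular hit if its e-value passes
#' `params$max_evalue`. Hits on the reverse strand report
#' `s_start > s_end` (coordinates on the forward subject strand). When the
#' two strands score equally the forward strand is reported, for
#' determinism.
#'
#' @param query,subject single sequence records: one-row `seq_set`s or lists
#'   with `id` and `seq` elements.
#' @param params an [align_params()] object.
#' @param search_space_nt the subject search-space size used in the e-value;
#'   defaults to the subject length, but for database searches pass the
#'   total database size so e-values are comparable across subjects.
#' @param keep_path if `TRUE`, attach the aligned column index pairs and
#'   strand as the `"path"` attribute (used for pileup construction).
#' @return a one-row hit data.frame, or `NULL` when no seed is found or the
#'   e-value fails the ceiling.
#' @export
align_pair <- function(query, subject, params = align_params(),
                       search_space_nt = NULL, keep_path = FALSE) {
  q <- as_seqrec(query)
  s <- as_seqrec(subject)
  stopifnot(nchar(q$seq) > 0L, nchar(s$seq) > 0L)
  if (is.null(search_space_nt)) search_space_nt <- nchar(s$seq)
  prof <- subject_profile(s$id, s$seq, params$kmer,
                          positional = !is.null(params$band))
  kq <- seq_kmers(q$seq, params$kmer)
  aln <- align_core(q$seq, kq, prof, params)
  if (is.null(aln)) return(NULL)
  ev <- karlin_evalue(aln$res$score, nchar(q$seq), search_space_nt, params)
  if (ev > params$max_evalue) return(NULL)
  hit_row(q$id, nchar(q$seq), prof, aln, ev, params, keep_path)
}

# k-mer -> subject index over both strands of every subject, built from the
# profiles in one pass
build_kmer_index_profiles <- function(profiles) {
  kms <- lapply(profiles, function(p) unique(c(p$kf, p$kr)))
  idx <- rep.int(seq_along(profiles), lengths(kms))
  list2env(split(idx, unlist(kms, use.names = FALSE)),
           envir = new.env(hash = TRUE, parent = emptyenv()))
}

build_kmer_index <- function(subjects, k) {
  profiles <- lapply(seq_len(nrow(subjects)), function(i) {
    subject_profile(subjects$id[i], subjects$seq[i], k)
  })
  build_kmer_index_profiles(profiles)
}

candidate_subjects <- function(qseq, index, k) {
  km <- unique(seq_kmers(qseq, k))
  found <- unlist(mget(km, envir = index, ifnotfound = list(NULL)),
                  use.names = FALSE)
  sort(unique(found))
}

#' All-versus-all similarity search
#'
#' For every query, every subject sharing a seed k-mer on either strand is
#' aligned and the best hit per (query, subject) pair that passes the
#' e-value ceiling is reported. The e-value search space is the total
#' subject-set size, so e-values are comparable across subjects. Rows are
#' ordered by query (input order), then ascending e-value, then subject id.
#'
#' @param queries,subjects `seq_set`s.
#' @param params an [align_params()] object.
#' @return a hit data.frame (zero rows if nothing passes).
#' @export
all_vs_all <- function(queries, subjects, params = align_params()) {
  stopifnot(nrow(queries) > 0L, nrow(subjects) > 0L)
  profiles <- lapply(seq_len(nrow(subjects)), function(i) {
    subject_profile(subjects$id[i], subjects$seq[i], params$kmer,
                    positional = !is.null(params$band))
  })
  index <- build_kmer_index_profiles(profiles)
  space <- sum(nchar(subjects$seq))
  out <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$seq[qi]
    kq <- seq_kmers(qseq, params$kmer)
    cand <- unlist(mget(unique(kq), envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    cand <- sort(unique(cand))
    hits <- list()
    for (si in cand) {
      aln <- align_core(qseq, kq, profiles[[si]], params)
      if (is.null(aln)) next
      ev <- karlin_evalue(aln$res$score, nchar(qseq), space, params)
      if (ev > params$max_evalue) next
      hits[[length(hits) + 1L]] <- hit_row(queries$id[qi], nchar(qseq),
                                           profiles[[si]], aln, ev, params)
    }
    if (length(hits)) {
      hq <- do.call(rbind, hits)
      hq <- hq[order(hq$evalue, hq$subject_id), , drop = FALSE]
      out[[qi]] <- hq
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
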