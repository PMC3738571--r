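# Two-accession SNP detection from read pileups over a pseudo-reference.
# Reads are placed at their best local alignment; per-column base counts
# are kept per accession; genotypes are scored with a symmetric-error
# diploid likelihood; and a site is reported as an inter-accession SNP
# when the two accessions' most probable genotypes carry different allele
# sets, the joint posterior of that difference is high, and every reported
# allele has the minimum read support (2 reads per allele, in its own
# accession) -- the decision rules of a conservative two-organism caller,
# on a transparent likelihood core.

BASES <- c("A", "C", "G", "T")
GENOTYPES <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")

genotype_alleles <- function(g) unique(strsplit(g, "")[[1]])

#' Caller model parameters
#'
#' @param error_rate per-base sequencing error rate epsilon, in (0, 0.5)
#'   (0 is accepted as an exact-limit device in tests).
#' @param het_prior prior probability theta that a site is heterozygous
#'   within an accession; the six heterozygous genotypes share theta, the
#'   four homozygous ones share 1 - theta.
#' @param min_posterior minimum joint posterior that the two accessions'
#'   allele sets differ.
#' @param min_allele_reads minimum supporting reads for each reported
#'   allele, in the accession it is reported for.
#' @return list of class `caller_model`.
#' @export
caller_model <- function(error_rate = 0.01, het_prior = 0.001,
                         min_posterior = 0.9, min_allele_reads = 2L) {
  stopifnot(error_rate >= 0, error_rate < 0.5, het_prior > 0, het_prior < 1,
            min_posterior >= 0, min_posterior <= 1, min_allele_reads >= 0)
  structure(list(error_rate = error_rate, het_prior = het_prior,
                 min_posterior = min_posterior,
                 min_allele_reads = as.integer(min_allele_reads)),
            class = "caller_model")
}

# x * log(p) with the 0 * log(0) = 0 convention, so error_rate = 0 is an
# exact zero-error model rather than NaN
xlogy <- function(x, p) ifelse(x > 0, x * log(p), 0)

#' Genotype posteriors for one pileup column of one accession
#'
#' Likelihood: a homozygote XX emits X with probability 1 - eps and each
#' other base with eps/3; a heterozygote XY emits X (or Y) with
#' 0.5 (1 - eps) + eps/6 and each other base with eps/3. Priors follow
#' [caller_model()]. Reads with N at the column are excluded upstream.
#'
#' @param counts integer vector of A/C/G/T read counts (named or in that
#'   order) with depth >= 1.
#' @param model a [caller_model()].
#' @return named posterior vector over the 10 genotypes, summing to 1.
#' @export
genotype_posteriors <- function(counts, model = caller_model()) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 4L)
  depth <- sum(counts)
  if (depth < 1) stop("genotype_posteriors: zero-depth column")
  eps <- model$error_rate
  p_err <- eps / 3
  p_hom <- 1 - eps
  p_het <- 0.5 * (1 - eps) + eps / 6
  names(counts) <- BASES
  ll <- vapply(GENOTYPES, function(g) {
    al <- genotype_alleles(g)
    on <- sum(counts[al])
    if (length(al) == 1L) {
      xlogy(on, p_hom) + xlogy(depth - on, p_err)
    } else {
      xlogy(on, p_het) + xlogy(depth - on, p_err)
    }
  }, numeric(1))
  lp <- ifelse(nchar(GENOTYPES) == 2 & substr(GENOTYPES, 1, 1) ==
                 substr(GENOTYPES, 2, 2),
               log((1 - model$het_prior) / 4), log(model$het_prior / 6))
  lpost <- ll + lp
  if (!any(is.finite(lpost))) {
    # zero-error model faced with data impossible under every genotype
    return(stats::setNames(rep(1 / length(GENOTYPES), length(GENOTYPES)),
                           GENOTYPES))
  }
  lpost <- lpost - max(lpost[is.finite(lpost)])
  post <- exp(lpost)
  post[!is.finite(post)] <- 0
  post / sum(post)
}

#' Build a pileup of reads over a reference set
#'
#' Each read is placed at its best-scoring alignment (banded around the
#' seed diagonal by default: placement assumes no indels, which holds for
#' the substitution-only generator); reads with no passing alignment are
#' dropped and counted, as are reads tied between two best locations.
#' N bases contribute to a separate per-column N track, never to the
#' A/C/G/T counts.
#'
#' @param reads a `seq_set`.
#' @param reference a `seq_set` of pseudo-reference sequences.
#' @param aligner_params mapping parameters; defaults to a banded aligner
#'   with a 1e-6 e-value ceiling.
#' @return list of class `pileup`: per reference id a list with `counts`
#'   (4 x L matrix, rows A/C/G/T), `n` (per-column N counts) and `ref_seq`;
#'   plus counters `n_unaligned`, `n_ambiguous`, `n_placed`.
#' @export
build_pileup <- function(reads, reference,
                         aligner_params = align_params(band = 16L,
                                                       max_evalue = 1e-6)) {
  stopifnot(nrow(reference) > 0L)
  p <- aligner_params
  profiles <- lapply(seq_len(nrow(reference)), function(i) {
    subject_profile(reference$id[i], reference$seq[i], p$kmer,
                    positional = !is.null(p$band))
  })
  index <- build_kmer_index_profiles(profiles)
  space <- sum(nchar(reference$seq))
  pl <- lapply(seq_len(nrow(reference)), function(i) {
    L <- nchar(reference$seq[i])
    list(counts = matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES)),
         n = integer(L), ref_seq = reference$seq[i])
  })
  names(pl) <- reference$id
  n_unaligned <- 0L; n_ambiguous <- 0L; n_placed <- 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (ri in seq_len(nrow(reads))) {
    qseq <- reads$seq[ri]
    kq <- seq_kmers(qseq, p$kmer)
    cand <- unlist(mget(unique(kq), envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    cand <- sort(unique(cand))
    best <- NULL; best_sid <- NULL; best_tie <- FALSE
    for (si in cand) {
      aln <- align_core(qseq, kq, profiles[[si]], p)
      if (is.null(aln)) next
      ev <- karlin_evalue(aln$res$score, nchar(qseq), space, p)
      if (ev > p$max_evalue) next
      if (is.null(best) || aln$res$score > best$res$score) {
        best <- aln; best_sid <- profiles[[si]]$id; best_tie <- FALSE
      } else if (aln$res$score == best$res$score &&
                 profiles[[si]]$id != best_sid) {
        best_tie <- TRUE
      }
    }
    if (is.null(best)) { n_unaligned <- n_unaligned + 1L; next }
    if (best_tie) { n_ambiguous <- n_ambiguous + 1L; next }
    n_placed <- n_placed + 1L
    sid <- best_sid
    L <- nchar(pl[[sid]]$ref_seq)
    rb <- strsplit(qseq, "")[[1]][best$res$q_cols]
    if (best$strand == "+") {
      pos <- best$res$s_cols
    } else {
      pos <- L - best$res$s_cols + 1L
      rb <- comp[rb]
    }
    is_n <- rb == "N"
    if (any(is_n)) {
      pl[[sid]]$n[pos[is_n]] <- pl[[sid]]$n[pos[is_n]] + 1L
    }
    if (any(!is_n)) {
      bi <- match(rb[!is_n], BASES)
      idx <- cbind(bi, pos[!is_n])
      pl[[sid]]$counts[idx] <- pl[[sid]]$counts[idx] + 1L
    }
  }
  structure(list(columns = pl, n_unaligned = n_unaligned,
                 n_ambiguous = n_ambiguous, n_placed = n_placed),
            class = "pileup")
}

#' Build pileups for both accessions
#'
#' @param reads_by_acc named list `acc1`/`acc2` of read `seq_set`s.
#' @param reference pseudo-reference `seq_set`.
#' @param aligner_params as in [build_pileup()].
#' @return named list of two `pileup` objects.
#' @export
build_pileups <- function(reads_by_acc, reference,
                          aligner_params = align_params(band = 16L,
                                                        max_evalue = 1e-6)) {
  stopifnot(all(c("acc1", "acc2") %in% names(reads_by_acc)))
  lapply(reads_by_acc, build_pileup, reference = reference,
         aligner_params = aligner_params)
}

empty_calls <- function() {
  data.frame(seq_id = character(), pos = integer(),
             allele_acc1 = character(), allele_acc2 = character(),
             posterior = numeric(), depth_acc1 = integer(),
             depth_acc2 = integer(), count_acc1 = integer(),
             count_acc2 = integer(), stringsAsFactors = FALSE)
}

# pick the reported allele for one accession: prefer its private alleles
# (not in the other accession's genotype), majority read count, ties
# lexicographic
pick_allele <- function(own, other, counts) {
  cand <- setdiff(own, other)
  if (!length(cand)) cand <- own
  cand[order(-counts[cand], cand)][1L]
}

#' Call inter-accession SNPs from two pileups
#'
#' A site is reported when (i) the reference base is not N, (ii) at most
#' two alleles have minimum read support across both accessions pooled
#' (multi-allelic sites are skipped and counted), (iii) the two
#' accessions' maximum-posterior genotypes carry different allele sets,
#' (iv) the joint posterior that the allele sets differ is at least
#' `model$min_posterior`, and (v) each reported allele has at least
#' `model$min_allele_reads` reads in its own accession. The rule is
#' symmetric: swapping the accessions swaps the allele columns and
#' changes nothing else.
#'
#' @param pileup_acc1,pileup_acc2 `pileup` objects over the same reference.
#' @param model a [caller_model()].
#' @return SNP-call data.frame (seq_id, pos, allele_acc1, allele_acc2,
#'   posterior, depths and supporting counts) with a `skipped` attribute
#'   counting multi-allelic and reference-N sites.
#' @export
call_snps <- function(pileup_acc1, pileup_acc2, model = caller_model()) {
  stopifnot(identical(names(pileup_acc1$columns), names(pileup_acc2$columns)))
  min_reads <- model$min_allele_reads
  rows <- list()
  n_multi <- 0L; n_refn <- 0L
  for (sid in names(pileup_acc1$columns)) {
    p1 <- pileup_acc1$columns[[sid]]; p2 <- pileup_acc2$columns[[sid]]
    m1 <- p1$counts; m2 <- p2$counts
    d1 <- colSums(m1); d2 <- colSums(m2)
    L <- ncol(m1)
    ref_is_n <- strsplit(p1$ref_seq, "")[[1]] == "N"
    # cheap prefilter: need support in both accessions and either a
    # second allele with min support (pooled) or differing consensus
    pooled <- m1 + m2
    top <- apply(pooled, 2, function(x) sort(x, decreasing = TRUE)[2])
    c1 <- max.col(t(m1), ties.method = "first")
    c2 <- max.col(t(m2), ties.method = "first")
    cand <- which(d1 >= pmax(1L, min_reads) & d2 >= pmax(1L, min_reads) &
                    (top >= pmax(1L, min_reads) | c1 != c2))
    n_refn <- n_refn + sum(ref_is_n[cand])
    cand <- cand[!ref_is_n[cand]]
    for (j in cand) {
      obs <- BASES[pooled[, j] >= pmax(1L, min_reads)]
      if (length(obs) > 2L) { n_multi <- n_multi + 1L; next }
      post1 <- genotype_posteriors(m1[, j], model)
      post2 <- genotype_posteriors(m2[, j], model)
      g1 <- GENOTYPES[which.max(post1)]
      g2 <- GENOTYPES[which.max(post2)]
      a1 <- genotype_alleles(g1); a2 <- genotype_alleles(g2)
      if (setequal(a1, a2)) next
      # allele sets are in bijection with genotypes, so the posterior
      # that the sets differ is 1 - P(same genotype in both)
      p_diff <- 1 - sum(post1 * post2)
      if (p_diff < model$min_posterior) next
      cnt1 <- stats::setNames(m1[, j], BASES)
      cnt2 <- stats::setNames(m2[, j], BASES)
      al1 <- pick_allele(a1, a2, cnt1)
      al2 <- pick_allele(a2, a1, cnt2)
      if (cnt1[al1] < min_reads || cnt2[al2] < min_reads) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, pos = j, allele_acc1 = al1, allele_acc2 = al2,
        posterior = p_diff,
        depth_acc1 = unname(d1[j]), depth_acc2 = unname(d2[j]),
        count_acc1 = unname(cnt1[al1]), count_acc2 = unname(cnt2[al2]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  out <- out[order(out$seq_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(multiallelic = n_multi, ref_n = n_refn)
  out
}

#' Compare SNP calls with planted truth
#'
#' @param calls a [call_snps()] table over a synthetic pseudo-reference.
#' @param truth the `truth_set` the reads came from.
#' @return list with sensitivity (planted inter-accession sites called),
#'   false_call_rate (calls at unplanted sites over all calls), n_calls
#'   and n_planted.
#' @export
snp_recovery <- function(calls, truth) {
  planted <- paste(truth$snp_sites$gene, truth$snp_sites$pos)
  called <- paste(calls$seq_id, calls$pos)
  tp <- sum(planted %in% called)
  fp <- sum(!(called %in% planted))
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       false_call_rate = if (length(called)) fp / length(called) else 0,
       n_calls = length(called), n_planted = length(planted))
}
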