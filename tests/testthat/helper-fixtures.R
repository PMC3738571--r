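# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: alignment scores come from
# Biostrings::pairwiseAlignment, reciprocal-best enumeration and N50 are
# naive double loops.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# plant exactly n substitutions at distinct positions; `margin` keeps them
# away from the ends (a local alignment legitimately trims a mismatch
# sitting within 2 bp of a sequence end)
plant_subs <- function(seq, n_sub, margin = 0L) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq.int(1L + margin, length(ch) - margin), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# independent local-alignment score oracle (same scoring scheme: match 1,
# mismatch -2, gap of length g costs 5 + 2(g-1))
.sw_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
oracle_local_score <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = .sw_mat,
                                      gapOpening = 3, gapExtension = 2)
  max(0, Biostrings::score(pa))
}

oracle_best_strand_score <- function(a, b) {
  max(oracle_local_score(a, b), oracle_local_score(a, rc_str(b)))
}

# exhaustive mutually-best enumeration over full hit tables; ties broken
# like the contract says (e-value, then bitscore, then subject id), written
# as plain loops
oracle_best <- function(hits, qid, max_evalue) {
  h <- hits[hits$query_id == qid & hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  best <- h[1L, ]
  if (nrow(h) > 1L) {
    for (i in 2:nrow(h)) {
      r <- h[i, ]
      better <- r$evalue < best$evalue ||
        (r$evalue == best$evalue && r$bitscore > best$bitscore) ||
        (r$evalue == best$evalue && r$bitscore == best$bitscore &&
           r$subject_id < best$subject_id)
      if (better) best <- r
    }
  }
  best$subject_id
}

oracle_brbh <- function(forward, reciprocal, max_evalue) {
  pairs <- character()
  for (q in unique(forward$query_id)) {
    s <- oracle_best(forward, q, max_evalue)
    if (is.na(s)) next
    back <- oracle_best(reciprocal, s, max_evalue)
    if (!is.na(back) && back == q) {
      pairs <- c(pairs, paste(q, s, sep = "\t"))
    }
  }
  sort(pairs)
}

# brute-force N50: smallest L among observed lengths whose >=L mass covers
# half the total
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths))
  keep <- vapply(cands, function(L) sum(lengths[lengths >= L]) >= total / 2,
                 logical(1))
  max(cands[keep])
}

# random hit tables with deliberate e-value ties, for reciprocal-best
# logic checks
random_hit_tables <- function(n_q, n_s, density = 0.15) {
  mk <- function(qs, ss) {
    n <- length(qs) * length(ss)
    sel <- which(stats::runif(n) < density)
    if (!length(sel)) sel <- sample(n, 1)
    qi <- ((sel - 1) %% length(qs)) + 1
    si <- ((sel - 1) %/% length(qs)) + 1
    ev <- 10^(-sample(5:40, length(sel), TRUE))   # discrete -> frequent ties
    data.frame(query_id = qs[qi], subject_id = ss[si],
               pct_identity = 90, aln_len = 100L, mismatches = 5L,
               gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
               s_end = 100L, evalue = ev,
               bitscore = round(-log10(ev)) + sample(0:3, length(sel), TRUE),
               q_cov = 100, stringsAsFactors = FALSE)
  }
  qs <- sprintf("q%03d", seq_len(n_q))
  ss <- sprintf("s%03d", seq_len(n_s))
  list(forward = mk(qs, ss), reciprocal = mk(ss, qs))
}

# planted family: full-length parents plus two diverged/truncated children
make_triplets <- function(n_fam, parent_len = 300L, child_div = 0.05) {
  ids <- character(0); seqs <- character(0); parent_of <- character(0)
  for (f in seq_len(n_fam)) {
    parent <- rnd_dna(parent_len)
    pid <- sprintf("fam%02d_parent", f)
    kids <- vapply(1:2, function(k) {
      trunc <- substr(parent, 1, parent_len - 20 * k)
      plant_subs(trunc, round(child_div * nchar(trunc)))
    }, character(1))
    ids <- c(ids, pid, sprintf("fam%02d_child%d", f, 1:2))
    seqs <- c(seqs, parent, kids)
    parent_of <- c(parent_of, rep(pid, 3))
  }
  list(seqs = seq_set(ids, seqs), parent_of = stats::setNames(parent_of, ids))
}

empty_calls_fixture <- function() {
  data.frame(seq_id = character(), pos = integer(),
             allele_acc1 = character(), allele_acc2 = character(),
             posterior = numeric(), depth_acc1 = integer(),
             depth_acc2 = integer(), count_acc1 = integer(),
             count_acc2 = integer(), stringsAsFactors = FALSE)
}

# a hand-built pileup object over one or more reference sequences;
# `site_counts` is a list mapping "seqid:pos" to a named A/C/G/T count
# vector, all other columns zero
make_pileup <- function(refs, site_counts = list()) {
  cols <- lapply(seq_len(nrow(refs)), function(i) {
    L <- nchar(refs$seq[i])
    list(counts = matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"))),
         n = integer(L), ref_seq = refs$seq[i])
  })
  names(cols) <- refs$id
  for (key in names(site_counts)) {
    parts <- strsplit(key, ":")[[1]]
    sid <- parts[1]; pos <- as.integer(parts[2])
    v <- site_counts[[key]]
    cols[[sid]]$counts[names(v), pos] <- as.integer(v)
  }
  structure(list(columns = cols, n_unaligned = 0L, n_ambiguous = 0L,
                 n_placed = NA_integer_), class = "pileup")
}
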