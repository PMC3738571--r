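# Synthetic transcript universes with planted ground truth.
#
# The generator emulates a normalised-cDNA long-read survey of a selfing
# wild grass: a focal transcript set (with paralog families and embedded
# resistance-gene motifs), ortholog stand-ins for several reference
# species, two accessions separated by a configurable SNP density with
# configurable within-accession heterozygosity, long reads (default
# 300-800 nt) with substitution errors and 3'-biased Ns, and contaminant
# pools (repeat / organelle / human-like). Every planted feature is
# recorded so downstream recovery tests read only the truth, never
# re-derive it.

# fixed degenerate motif stand-ins for the NB-ARC domain and an
# intracellular LRR repeat, used by the toy domain scanner
NBARC_MOTIF <- paste0("GGTGGGCTTGGAAAGACAACTCTTGCTCGTAAAGTCTAC",
                      "GATGATCCTAGAGTTCAACA")
LRR_MOTIF <- paste0("CTTGACCTTTCTAACAACAAGCTTACTGGTGAAATTCCT")

#' Configuration for the synthetic transcript universe
#'
#' Defaults describe the emulated study design: two nearly-homozygous
#' accessions of a selfing wild grass sequenced with normalised-cDNA long
#' reads, plus four reference proteome stand-ins. Rates are per site or
#' per read as indicated.
#'
#' @param n_genes number of focal base transcripts.
#' @param n_species total species count including the focal one; species
#'   2..n become reference ortholog sets.
#' @param gene_len_range transcript length range in nt.
#' @param paralog_family_rate probability a base transcript founds a
#'   within-species paralog family (one extra diverged copy).
#' @param paralog_divergence per-site divergence of a paralog from its
#'   family founder.
#' @param ortholog_divergence per-site substitution rate between the focal
#'   species and each reference species.
#' @param snp_rate per-site rate of fixed differences between the two
#'   accessions.
#' @param het_fraction_acc1,het_fraction_acc2 fraction of SNP-bearing
#'   transcripts that are heterozygous within each accession (a
#'   heterozygous transcript carries the other accession's alleles on its
#'   second haplotype, i.e. residual cross-lineage heterozygosity).
#' @param read_len_range read length range in nt (within 46..828).
#' @param short_read_rate probability a read is drawn from a 20-45 nt
#'   short tail instead, to exercise the length filter.
#' @param coverage target mean per-accession fold coverage; per-transcript
#'   read counts are Poisson around `coverage * len / mean_read_len`
#'   scaled by a lognormal expression factor.
#' @param reads_per_gene_mean if non-NULL, overrides `coverage` with a
#'   flat expected read count per transcript.
#' @param expr_sdlog sdlog of the lognormal expression factor shared
#'   between accessions.
#' @param error_rate per-base substitution error rate of the simulated
#'   sequencer.
#' @param n_rate_3prime probability a read receives an ambiguous base (N)
#'   in its 3' half, emulating the strong 3' skew of ambiguous calls in
#'   long-read pyrosequencing.
#' @param n_rate_uniform small per-base background N rate (both halves).
#' @param strand_flip_prob probability a read is reported on the minus
#'   strand.
#' @param contaminant_fractions named fractions (of the transcript read
#'   count) for the `repeat`, `organelle` and `human` contaminant pools.
#' @param rgene_fraction fraction of base transcripts carrying a planted
#'   NB-ARC motif; `lrr_within_rate` of those also carry an LRR motif
#'   downstream.
#' @param lrr_within_rate see `rgene_fraction`.
#' @param motif_divergence per-site divergence applied to each planted
#'   motif copy.
#' @param seed integer seed; every generator draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 40L, n_species = 5L,
                       gene_len_range = c(600L, 1500L),
                       paralog_family_rate = 0.05,
                       paralog_divergence = 0.10,
                       ortholog_divergence = 0.05,
                       snp_rate = 0.002,
                       het_fraction_acc1 = 0.016,
                       het_fraction_acc2 = 0.30,
                       read_len_range = c(300L, 800L),
                       short_read_rate = 0.02,
                       coverage = 20,
                       reads_per_gene_mean = NULL,
                       expr_sdlog = 0.3,
                       error_rate = 0.005,
                       n_rate_3prime = 0.05,
                       n_rate_uniform = 0.001,
                       strand_flip_prob = 0.5,
                       contaminant_fractions = c("repeat" = 0.008,
                                                 organelle = 0.010,
                                                 human = 0.0003),
                       rgene_fraction = 0.10,
                       lrr_within_rate = 0.5,
                       motif_divergence = 0.05,
                       seed) {
  if (missing(seed)) stop("sim_config(): an explicit integer seed is required")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  rates <- c(paralog_family_rate, paralog_divergence, ortholog_divergence,
             snp_rate, het_fraction_acc1, het_fraction_acc2, short_read_rate,
             error_rate, n_rate_3prime, n_rate_uniform, strand_flip_prob,
             contaminant_fractions, rgene_fraction, lrr_within_rate,
             motif_divergence)
  stopifnot(all(rates >= 0 & rates <= 1))
  stopifnot(read_len_range[1] > 45L, read_len_range[2] <= 828L,
            n_genes >= 1L, n_species >= 2L,
            all(c("repeat", "organelle", "human") %in%
                  names(contaminant_fractions)))
  structure(cfg, class = "sim_config")
}

# derive stream-specific seeds from the master seed, kept within 32-bit range
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483587 + 1)
}

# uniform integers in [lo, hi], safe against R's scalar-sample pitfall
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site independently at `rate`; returns the mutated string
# and the 1-based positions with original/new alleles
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(list(seq = seq, pos = integer(),
                                from = character(), to = character()))
  ch <- strsplit(seq, "")[[1]]
  from <- ch[pos]
  to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
               character(1), USE.NAMES = FALSE)
  ch[pos] <- to
  list(seq = paste(ch, collapse = ""), pos = pos, from = from, to = to)
}

substitute_at <- function(seq, pos, alleles) {
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- alleles
  paste(ch, collapse = "")
}

plant_motif <- function(seq, motif, at, divergence) {
  m <- mutate_seq(motif, divergence)$seq
  paste0(substr(seq, 1, at - 1), m, substr(seq, at + nchar(m), nchar(seq)))
}

#' Generate a synthetic transcript universe with planted truth
#'
#' Builds the focal transcript set (base genes, paralog copies, embedded
#' NB-ARC/LRR motifs), reference-species ortholog sets, the two
#' accessions' consensus sequences and haplotypes, a genetic map over one
#' reference set, contaminant libraries, an annotation-term table, and
#' per-transcript expression factors. Fully deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `truth_set`; see the package vignette for the
#'   component layout.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  ng <- config$n_genes

  lens <- sample_range(config$gene_len_range[1], config$gene_len_range[2], ng)
  ids <- sprintf("g%03d", seq_len(ng))
  seqs <- vapply(lens, random_dna, character(1))

  # resistance-gene motifs are embedded before any divergence is applied,
  # so orthologs and accessions inherit (diverged copies of) them
  n_rg <- round(config$rgene_fraction * ng)
  rg_idx <- if (n_rg > 0) sort(sample(ng, n_rg)) else integer()
  lrr_idx <- if (length(rg_idx))
    sort(rg_idx[sample.int(length(rg_idx),
                           round(config$lrr_within_rate * length(rg_idx)))])
  else integer()
  for (i in rg_idx) {
    at <- sample(seq(30L, max(31L, lens[i] %/% 2)), 1)
    seqs[i] <- plant_motif(seqs[i], NBARC_MOTIF, at, config$motif_divergence)
  }
  for (i in lrr_idx) {
    at <- sample(seq(lens[i] %/% 2 + 60L, lens[i] - nchar(LRR_MOTIF) - 10L), 1)
    seqs[i] <- plant_motif(seqs[i], LRR_MOTIF, at, config$motif_divergence)
  }

  # within-species paralog families (focal species only)
  par_of <- which(stats::runif(ng) < config$paralog_family_rate)
  par_ids <- sprintf("%s_p1", ids[par_of])
  par_seqs <- vapply(seqs[par_of],
                     function(s) mutate_seq(s, config$paralog_divergence)$seq,
                     character(1), USE.NAMES = FALSE)
  focal_ids <- c(ids, par_ids)
  focal_seqs <- c(seqs, par_seqs)

  # reference species derived from the focal base genes
  ref_sets <- list()
  for (k in seq(2L, config$n_species)) {
    rs <- vapply(seqs, function(s) mutate_seq(s, config$ortholog_divergence)$seq,
                 character(1), USE.NAMES = FALSE)
    nm <- sprintf("sp%d", k)
    ref_sets[[nm]] <- seq_set(sprintf("%s_%s", nm, ids), rs,
                              source = "reference")
  }
  ortholog_map <- do.call(rbind, lapply(names(ref_sets), function(nm) {
    data.frame(focal_id = ids, ref_set = nm,
               ref_id = sprintf("%s_%s", nm, ids), stringsAsFactors = FALSE)
  }))

  # two-accession divergence over every focal transcript
  snp_rows <- list()
  acc2_seqs <- character(length(focal_seqs))
  for (i in seq_along(focal_seqs)) {
    mut <- mutate_seq(focal_seqs[i], config$snp_rate)
    acc2_seqs[i] <- mut$seq
    if (length(mut$pos)) {
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        gene = focal_ids[i], pos = mut$pos, allele_acc1 = mut$from,
        allele_acc2 = mut$to, stringsAsFactors = FALSE)
    }
  }
  snp_sites <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(gene = character(), pos = integer(),
               allele_acc1 = character(), allele_acc2 = character(),
               stringsAsFactors = FALSE)

  # residual heterozygosity: a heterozygous transcript's second haplotype
  # carries the other accession's alleles at that transcript's SNP sites,
  # so only SNP-bearing transcripts can be heterozygous
  snp_bearing <- unique(snp_sites$gene)
  het_acc1 <- snp_bearing[stats::runif(length(snp_bearing)) <
                            config$het_fraction_acc1]
  het_acc2 <- snp_bearing[stats::runif(length(snp_bearing)) <
                            config$het_fraction_acc2]

  hap_for <- function(i, acc) {
    gid <- focal_ids[i]
    own <- if (acc == "acc1") focal_seqs[i] else acc2_seqs[i]
    other <- if (acc == "acc1") acc2_seqs[i] else focal_seqs[i]
    het <- if (acc == "acc1") gid %in% het_acc1 else gid %in% het_acc2
    c(own, if (het) other else own)
  }
  haplotypes <- list(
    acc1 = lapply(seq_along(focal_ids), hap_for, acc = "acc1"),
    acc2 = lapply(seq_along(focal_ids), hap_for, acc = "acc2"))
  names(haplotypes$acc1) <- focal_ids
  names(haplotypes$acc2) <- focal_ids

  # genetic map over the first reference set's genes
  map_ref <- names(ref_sets)[1]
  genetic_map <- data.frame(
    gene_id = ref_sets[[map_ref]]$id,
    chromosome = sample(sprintf("%dH", 1:7), ng, replace = TRUE),
    cM = round(stats::runif(ng, 0, 150), 2), stringsAsFactors = FALSE)

  # contaminant pools: high-copy repeats, long organelle fragments,
  # human-like repeats, all unrelated to the transcript space
  contaminants <- list(
    "repeat" = seq_set(sprintf("rep%02d", 1:5),
                       vapply(rep(600L, 5), random_dna, character(1)),
                       source = "contaminant"),
    organelle = seq_set(sprintf("org%02d", 1:3),
                        vapply(rep(2000L, 3), random_dna, character(1)),
                        source = "contaminant"),
    human = seq_set(sprintf("hum%02d", 1:3),
                    vapply(rep(800L, 3), random_dna, character(1)),
                    source = "contaminant"))

  # annotation terms: most resistance transcripts get an NB-LRR term,
  # plus generic terms and LRR-kinase decoys elsewhere
  generic <- c("ATP binding", "protein kinase activity", "DNA binding",
               "structural constituent of ribosome", "oxidoreductase activity")
  annotations <- stats::setNames(vector("list", length(focal_ids)), focal_ids)
  for (i in seq_along(focal_ids)) {
    terms <- sample(generic, sample(1:2, 1))
    annotations[[i]] <- terms
  }
  lex_ids <- ids[rg_idx][stats::runif(length(rg_idx)) < 0.8]
  for (g in lex_ids) {
    annotations[[g]] <- c(annotations[[g]], "NB-LRR disease resistance protein")
  }
  decoys <- setdiff(ids, ids[rg_idx])
  decoys <- decoys[stats::runif(length(decoys)) < 0.05]
  for (g in decoys) {
    annotations[[g]] <- c(annotations[[g]],
                          "leucine-rich repeat receptor kinase")
  }

  expr <- stats::setNames(stats::rlnorm(length(focal_ids), 0,
                                        config$expr_sdlog), focal_ids)

  structure(list(
    config = config,
    genes = seq_set(focal_ids, focal_seqs, source = "contig"),
    acc2_consensus = stats::setNames(acc2_seqs, focal_ids),
    ref_sets = ref_sets,
    ortholog_map = ortholog_map,
    snp_sites = snp_sites,
    het_genes = list(acc1 = het_acc1, acc2 = het_acc2),
    haplotypes = haplotypes,
    rgene_ids = list(nbarc = ids[rg_idx], nblrr = ids[lrr_idx]),
    annotations = annotations,
    lexical_ids = lex_ids,
    genetic_map = genetic_map,
    map_ref = map_ref,
    contaminants = contaminants,
    expr = expr), class = "truth_set")
}

#' The pseudo-assembly of a synthetic universe
#'
#' Returns the focal transcript consensus sequences as a contig set. The
#' pipeline consumes contig FASTA from any assembler; for synthetic runs
#' the assembly step itself is out of scope and the consensus stands in.
#'
#' @param truth a `truth_set`.
#' @return a `seq_set` with source `"contig"`.
#' @export
pseudo_assembly <- function(truth) {
  truth$genes
}

#' Simulate reads for one accession
#'
#' Read lengths are uniform over `read_len_range` with a short-read tail;
#' start positions are uniform including partial overhangs at transcript
#' ends (clipped to the transcript), giving near-uniform coverage;
#' heterozygous transcripts contribute both haplotypes at a 1:1 ratio;
#' substitution errors, 3'-half-biased Ns and random strand are applied.
#'
#' @param truth a `truth_set`.
#' @param accession `"acc1"` or `"acc2"`.
#' @return list with `reads` (a `seq_set`) and `provenance` (data.frame
#'   read_id, gene, hap, start, end, strand).
#' @export
simulate_reads <- function(truth, accession = c("acc1", "acc2")) {
  accession <- match.arg(accession)
  config <- truth$config
  set.seed(derive_seed(config$seed, if (accession == "acc1") 2L else 3L))
  mean_len <- mean(config$read_len_range)
  ids <- truth$genes$id
  out_seq <- character(0); out_id <- character(0)
  prov <- list()
  for (gid in ids) {
    haps <- truth$haplotypes[[accession]][[gid]]
    L <- nchar(haps[1])
    # start positions include clipped overhangs at the transcript ends, so
    # a read's expected covered length is l * L / (L + l - 1); scaling the
    # read count by (L + l - 1) / l makes `coverage` the actual expected
    # interior fold coverage rather than a nominal one
    lambda <- if (!is.null(config$reads_per_gene_mean))
      config$reads_per_gene_mean
    else config$coverage * (L + mean_len - 1) / mean_len * truth$expr[[gid]]
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    for (r in seq_len(n)) {
      l <- if (stats::runif(1) < config$short_read_rate)
        sample_range(20L, 45L)
      else sample_range(config$read_len_range[1], config$read_len_range[2])
      hap_i <- if (stats::runif(1) < 0.5) 1L else 2L
      s <- sample(seq(2L - l, L), 1)
      a <- max(1L, s); b <- min(L, s + l - 1L)
      rd <- substr(haps[hap_i], a, b)
      rd <- mutate_seq(rd, config$error_rate)$seq
      w <- nchar(rd)
      ch <- strsplit(rd, "")[[1]]
      if (stats::runif(1) < config$n_rate_3prime) {
        p <- sample(seq(w %/% 2 + 1L, w), 1)
        ch[p] <- "N"
      }
      bg <- which(stats::runif(w) < config$n_rate_uniform)
      if (length(bg)) ch[bg] <- "N"
      rd <- paste(ch, collapse = "")
      strand <- if (stats::runif(1) < config$strand_flip_prob) "-" else "+"
      if (strand == "-") rd <- revcomp(rd)
      rid <- sprintf("%s_%s_r%d", accession, gid, r)
      out_id <- c(out_id, rid); out_seq <- c(out_seq, rd)
      prov[[length(prov) + 1L]] <- data.frame(
        read_id = rid, gene = gid, hap = hap_i, start = a, end = b,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  list(reads = seq_set(out_id, out_seq, source = "read"),
       provenance = do.call(rbind, prov))
}

#' Spike contaminant reads into a read set
#'
#' Draws a binomial number of contaminant reads for each pool at the
#' configured fraction of the transcript read count and appends them;
#' labels record the disposition of every read. Fractions summing above
#' 0.5 are rejected as unrealistic.
#'
#' @param reads a `seq_set` of transcript reads.
#' @param truth a `truth_set` (supplies the contaminant libraries).
#' @param config the [sim_config()] used to build `truth`.
#' @return list with `reads` (augmented `seq_set`) and `labels`
#'   (data.frame read_id, label), where labels partition the read set.
#' @export
spike_contaminants <- function(reads, truth, config = truth$config) {
  fr <- config$contaminant_fractions
  if (sum(fr) > 0.5) stop("contaminant fractions sum above 0.5: unrealistic")
  set.seed(derive_seed(config$seed, 4L))
  n0 <- nrow(reads)
  add_id <- character(0); add_seq <- character(0); add_lab <- character(0)
  for (lab in names(fr)) {
    lib <- truth$contaminants[[lab]]
    n_add <- stats::rbinom(1, n0, fr[[lab]])
    if (n_add == 0) next
    for (r in seq_len(n_add)) {
      src <- sample(nrow(lib), 1)
      L <- nchar(lib$seq[src])
      l <- min(L, sample_range(config$read_len_range[1],
                               config$read_len_range[2]))
      a <- sample(seq_len(L - l + 1L), 1)
      rd <- mutate_seq(substr(lib$seq[src], a, a + l - 1L),
                       config$error_rate)$seq
      add_id <- c(add_id, sprintf("%s_c%d", lab, r))
      add_seq <- c(add_seq, rd)
      add_lab <- c(add_lab, lab)
    }
  }
  combined <- rbind(reads,
                    seq_set(add_id, add_seq, source = "contaminant"))
  class(combined) <- c("seq_set", "data.frame")
  labels <- data.frame(
    read_id = combined$id,
    label = c(rep("transcript", n0), add_lab), stringsAsFactors = FALSE)
  list(reads = combined, labels = labels)
}
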