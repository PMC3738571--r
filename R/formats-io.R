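#' Construct a sequence set
#'
#' A sequence set is the package's in-memory container for identified DNA
#' sequences (reads, contigs, isotigs, reference genes, contaminants): a
#' data.frame with columns `id`, `seq`, `desc` and `source`. Sequences are
#' uppercase DNA over the alphabet A, C, G, T, N; ids must be unique and
#' non-empty. All coordinates handled by the package are 1-based inclusive.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of DNA sequences (coerced to uppercase).
#' @param desc free-text descriptions (recycled).
#' @param source provenance label, one of `"read"`, `"contig"`, `"isotig"`,
#'   `"reference"`, `"contaminant"` (recycled).
#' @return a data.frame of class `seq_set`.
#' @export
seq_set <- function(id, seq, desc = "", source = "contig") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  stopifnot(length(id) == length(seq))
  src_levels <- c("read", "contig", "isotig", "reference", "contaminant")
  source <- as.character(source)
  if (!all(source %in% src_levels)) {
    stop("source labels must be one of: ", paste(src_levels, collapse = ", "))
  }
  x <- data.frame(id = id, seq = seq,
                  desc = rep_len(as.character(desc), length(id)),
                  source = rep_len(source, length(id)),
                  stringsAsFactors = FALSE)
  validate_seq_set(x)
  class(x) <- c("seq_set", "data.frame")
  x
}

validate_seq_set <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$id))) stop("sequence ids must be non-empty")
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  if (any(nchar(x$seq) < 1L)) stop("zero-length sequence for id: ",
                                   x$id[nchar(x$seq) < 1L][[1L]])
  bad <- grepl("[^ACGTN]", x$seq)
  if (any(bad)) stop("non-IUPAC (non-ACGTN) characters in sequence: ",
                     x$id[bad][[1L]])
  invisible(x)
}

#' Read a FASTA file into a sequence set
#'
#' Record order is preserved and the id is the first whitespace-delimited
#' token of the header; the remainder of the header becomes the description.
#' Duplicated ids are a hard error; an empty file yields an empty set with a
#' warning.
#'
#' @param path path to a FASTA file.
#' @param source provenance label to stamp on every record.
#' @return a `seq_set`.
#' @export
read_fasta <- function(path, source = "contig") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_set(character(), character(), source = source))
  }
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seq_set(ids, as.character(dss), desc = desc, source = source)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a `seq_set`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  nm <- ifelse(nzchar(seqs$desc), paste(seqs$id, seqs$desc), seqs$id)
  dss <- Biostrings::DNAStringSet(seqs$seq)
  names(dss) <- nm
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file into a sequence set
#'
#' Base qualities are discarded: downstream screening only uses sequence
#' content (including Ns), never per-base quality.
#'
#' @inheritParams read_fasta
#' @return a `seq_set`.
#' @export
read_fastq <- function(path, source = "read") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTQ file: ", path)
    return(seq_set(character(), character(), source = source))
  }
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seq_set(ids, as.character(dss), desc = desc, source = source)
}

hit_columns <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

empty_hits <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_len = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  q_cov = numeric(), stringsAsFactors = FALSE)
  h
}

#' Read a 12-column tabular similarity-hit file
#'
#' The classic tabular pairwise-hit dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score, whitespace- or tab-separated.
#' Query coverage is always recomputed internally from `query_lengths`
#' (never read from file), so hit tables produced by any aligner are
#' interchangeable.
#'
#' @param path path to the hit table.
#' @param query_lengths optional named integer vector mapping query id to
#'   query length in nucleotides; used to derive `q_cov`. Queries without a
#'   known length get `q_cov = NA`.
#' @return a data.frame of hits with a derived `q_cov` column (percent of
#'   the query covered by the alignment).
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, comment.char = "#")
  if (length(nf) == 0L) return(empty_hits())
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop("malformed hit-table row (expected 12 columns) at line ", bad[[1L]],
         " of ", path)
  }
  h <- utils::read.table(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = hit_columns,
                         colClasses = c("character", "character", "numeric",
                                        "integer", "integer", "integer",
                                        "integer", "integer", "integer",
                                        "integer", "numeric", "numeric"))
  h$q_cov <- hit_q_cov(h, query_lengths)
  h
}

hit_q_cov <- function(h, query_lengths = NULL) {
  if (is.null(query_lengths)) return(rep(NA_real_, nrow(h)))
  len <- unname(query_lengths[h$query_id])
  100 * (h$q_end - h$q_start + 1) / as.numeric(len)
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits a hit data.frame (the derived `q_cov` column is dropped).
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_columns, drop = FALSE], file = path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write SNP calls as GFF3
#'
#' One feature of type `SNP` per call, 1-based inclusive single-nucleotide
#' coordinates, the call posterior in the score column, and the two
#' accessions' alleles and depths as attributes. Output is sorted by
#' (sequence id, position) so files are byte-deterministic.
#'
#' @param calls a SNP-call data.frame as produced by [call_snps()].
#' @param path output path.
#' @export
write_snp_gff <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  calls <- calls[order(calls$seq_id, calls$pos), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = calls$seq_id,
    ranges = IRanges::IRanges(start = calls$pos, end = calls$pos))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "sharest", type = "SNP", score = calls$posterior,
    allele_acc1 = calls$allele_acc1, allele_acc2 = calls$allele_acc2,
    depth_acc1 = calls$depth_acc1, depth_acc2 = calls$depth_acc2)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a genetic map
#'
#' Expects a tab-separated file with header columns `gene_id`,
#' `chromosome`, `cM`. Duplicated gene ids and negative or non-finite map
#' positions are rejected.
#'
#' @param path path to the TSV map.
#' @return data.frame with columns gene_id, chromosome, cM.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "cM")
  if (!all(need %in% names(m))) {
    stop("genetic map must have header columns: ", paste(need, collapse = ", "))
  }
  m <- m[, need]
  m$cM <- as.numeric(m$cM)
  dup <- m$gene_id[duplicated(m$gene_id)]
  if (length(dup)) stop("duplicate gene_id in genetic map: ", dup[[1L]])
  if (any(!is.finite(m$cM))) stop("non-finite cM position in genetic map")
  if (any(m$cM < 0)) stop("negative cM position in genetic map")
  m
}

#' Write a genetic map
#' @param map data.frame with gene_id, chromosome, cM.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map[, c("gene_id", "chromosome", "cM")], file = path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
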