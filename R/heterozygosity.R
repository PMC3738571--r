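# Allelic-ratio heterozygosity. At every called inter-accession SNP site,
# each accession's reads are tallied for the two call alleles; at adequate
# depth (>= 20 by convention) a most/least-frequent allele ratio near 1
# indicates the accession carries both alleles (heterozygous site), while
# a homozygous accession shows the ratio diverging to infinity. A sequence
# is classified heterozygous in an accession when at least one of its
# depth-eligible sites is heterozygous, and the per-accession rate is the
# percentage of classified sequences among SNP-bearing sequences with at
# least one eligible site in that accession.

#' Per-site allelic ratios at called SNPs
#'
#' For each SNP call and each accession, counts the reads supporting the
#' two call alleles in that accession's pileup; depth is the sum of those
#' two counts only (error bases are excluded), and a record is emitted
#' only when depth passes the gate. The ratio is most/least frequent of
#' the two alleles, `Inf` when the minor allele is absent.
#'
#' @param snp_calls a [call_snps()] table.
#' @param pileups named list `acc1`/`acc2` of `pileup` objects.
#' @param min_depth minimum two-allele depth for a usable record.
#' @return data.frame seq_id, pos, accession, n_major, n_minor, ratio,
#'   depth.
#' @export
allelic_ratios <- function(snp_calls, pileups, min_depth = 20L) {
  stopifnot(all(c("acc1", "acc2") %in% names(pileups)))
  rows <- list()
  for (acc in c("acc1", "acc2")) {
    cols <- pileups[[acc]]$columns
    for (i in seq_len(nrow(snp_calls))) {
      call <- snp_calls[i, ]
      m <- cols[[call$seq_id]]$counts
      n1 <- m[call$allele_acc1, call$pos]
      n2 <- m[call$allele_acc2, call$pos]
      depth <- n1 + n2
      if (depth < min_depth) next
      n_major <- max(n1, n2); n_minor <- min(n1, n2)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = call$seq_id, pos = call$pos, accession = acc,
        n_major = n_major, n_minor = n_minor,
        ratio = if (n_minor == 0) Inf else n_major / n_minor,
        depth = depth, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), pos = integer(),
                      accession = character(), n_major = integer(),
                      n_minor = integer(), ratio = numeric(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify sequences as heterozygous per accession
#'
#' A site is heterozygous when its allelic ratio is at most `max_ratio`
#' (the conventional cutoff 3.0 spans mixtures from 1:1 to 3:1). Under the
#' default `"any"` rule a sequence is heterozygous in an accession when at
#' least one of its eligible sites is; `"majority"` requires more than
#' half. Sequences with no eligible site in an accession do not appear for
#' that accession (they are outside the denominator).
#'
#' @param records an [allelic_ratios()] table.
#' @param max_ratio site-level heterozygosity cutoff.
#' @param rule `"any"` or `"majority"`.
#' @return data.frame seq_id, accession, n_eligible_sites, n_het_sites,
#'   is_het.
#' @export
classify_heterozygous <- function(records, max_ratio = 3.0,
                                  rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (nrow(records) == 0L) {
    return(data.frame(seq_id = character(), accession = character(),
                      n_eligible_sites = integer(), n_het_sites = integer(),
                      is_het = logical(), stringsAsFactors = FALSE))
  }
  key <- interaction(records$seq_id, records$accession, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    n_het <- sum(g$ratio <= max_ratio)
    data.frame(seq_id = g$seq_id[1], accession = g$accession[1],
               n_eligible_sites = nrow(g), n_het_sites = n_het,
               is_het = if (rule == "any") n_het >= 1L else
                 n_het > nrow(g) / 2,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$accession, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heterozygosity rate of one accession
#'
#' The percentage of heterozygous sequences among sequences with at least
#' one eligible site, reported to one decimal, e.g. 7 heterozygous of 444
#' eligible SNP-bearing sequences is 1.6.
#'
#' @param het_calls the [classify_heterozygous()] rows of one accession.
#' @return percent, rounded to 1 decimal.
#' @export
het_rate <- function(het_calls) {
  if (nrow(het_calls) == 0L) stop("het_rate: no classified sequences")
  if (length(unique(het_calls$accession)) > 1L) {
    stop("het_rate expects the calls of a single accession")
  }
  round(100 * sum(het_calls$is_het) / nrow(het_calls), 1)
}

#' Histogram of allelic ratios
#'
#' Finite ratios are counted in `[edge_i, edge_{i+1})` bins; everything at
#' or above the last edge, including infinite ratios (absent minor
#' allele), falls in the overflow bin. Counts always sum to the record
#' count.
#'
#' @param records an [allelic_ratios()] table (one accession or pooled).
#' @param bin_edges increasing numeric vector of bin edges.
#' @return named integer vector of counts, one per bin plus the overflow.
#' @export
ratio_histogram <- function(records, bin_edges = c(1, 1.5, 2, 2.5, 3, 4, 5)) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1L
  labs <- c(sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1]),
            sprintf(">=%g", bin_edges[length(bin_edges)]))
  counts <- stats::setNames(integer(nb + 1L), labs)
  if (nrow(records) == 0L) return(counts)
  r <- records$ratio
  over <- !is.finite(r) | r >= bin_edges[length(bin_edges)]
  counts[nb + 1L] <- sum(over)
  if (any(!over)) {
    bin <- findInterval(r[!over], bin_edges, rightmost.closed = FALSE)
    bin[bin < 1L] <- 1L   # ratios below the first edge cannot occur (>= 1)
    tab <- table(factor(bin, levels = seq_len(nb)))
    counts[seq_len(nb)] <- counts[seq_len(nb)] + as.integer(tab)
  }
  counts
}

#' Heterozygous-sequence counts per genetic-map bin
#'
#' @param het_calls a [classify_heterozygous()] table.
#' @param placements a [place_on_map()] table for the same sequences.
#' @param bin_width_cM bin width; bins are recomputed as
#'   `floor(cM / bin_width_cM)`.
#' @return list with `bins` (data.frame accession, chromosome, bin_index,
#'   n_het) and `n_unplaced` (named per accession: heterozygous sequences
#'   with no map placement).
#' @export
bin_het_on_map <- function(het_calls, placements, bin_width_cM = 5) {
  stopifnot(bin_width_cM > 0)
  het <- het_calls[het_calls$is_het, , drop = FALSE]
  idx <- match(het$seq_id, placements$query_id)
  placed <- !is.na(idx)
  n_unplaced <- tapply(!placed, het$accession, sum)
  if (!any(placed)) {
    return(list(bins = data.frame(accession = character(),
                                  chromosome = character(),
                                  bin_index = integer(), n_het = integer(),
                                  stringsAsFactors = FALSE),
                n_unplaced = n_unplaced))
  }
  h <- het[placed, , drop = FALSE]
  h$chromosome <- placements$chromosome[idx[placed]]
  h$bin_index <- as.integer(floor(placements$position_cM[idx[placed]] /
                                    bin_width_cM))
  agg <- stats::aggregate(list(n_het = rep(1L, nrow(h))),
                          by = h[, c("accession", "chromosome", "bin_index")],
                          FUN = sum)
  agg <- agg[order(agg$accession, agg$chromosome, agg$bin_index), ,
             drop = FALSE]
  rownames(agg) <- NULL
  list(bins = agg, n_unplaced = n_unplaced)
}

#' Marker conversion rate
#'
#' Bookkeeping for assay-validation summaries: the percentage of tested
#' SNPs successfully converted into co-dominant markers, e.g. 35 of 59
#' tested is 59.3.
#'
#' @param n_converted,n_tested counts with `n_converted <= n_tested`.
#' @return percent, rounded to 1 decimal.
#' @export
conversion_rate <- function(n_converted, n_tested) {
  stopifnot(n_tested > 0, n_converted >= 0, n_converted <= n_tested)
  round(100 * n_converted / n_tested, 1)
}
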