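mk_call <- function(seq_id, pos, a1 = "A", a2 = "G") {
  data.frame(seq_id = seq_id, pos = pos, allele_acc1 = a1, allele_acc2 = a2,
             posterior = 0.99, depth_acc1 = 25L, depth_acc2 = 25L,
             count_acc1 = 25L, count_acc2 = 25L, stringsAsFactors = FALSE)
}

test_that("allelic ratios gate on two-allele depth and handle absent minors", {
  refs <- seq_set("ctg1", rnd_dna(100))
  calls <- rbind(mk_call("ctg1", 10), mk_call("ctg1", 40),
                 mk_call("ctg1", 70))
  pls <- list(
    acc1 = make_pileup(refs, list("ctg1:10" = c(A = 15, G = 10),
                                  "ctg1:40" = c(A = 12, G = 7),
                                  "ctg1:70" = c(A = 20))),
    acc2 = make_pileup(refs, list("ctg1:10" = c(G = 25),
                                  "ctg1:40" = c(G = 21),
                                  "ctg1:70" = c(G = 30))))
  rec <- allelic_ratios(calls, pls, min_depth = 20)
  r1 <- rec[rec$accession == "acc1", ]
  expect_equal(r1$pos, c(10L, 70L))          # depth 19 at pos 40 suppressed
  expect_equal(r1$ratio[r1$pos == 10], 1.5)  # 15/10
  expect_equal(r1$depth[r1$pos == 10], 25L)
  expect_true(is.infinite(r1$ratio[r1$pos == 70]))
  expect_true(all(rec$n_major >= rec$n_minor))
  expect_true(all(rec$ratio >= 1))
  expect_true(all(rec$depth >= 20))
})

test_that("site and sequence classification follow the 3.0 cutoff", {
  base <- data.frame(seq_id = "s1", pos = 1L, accession = "acc2",
                     stringsAsFactors = FALSE)
  one <- function(ratio) transform(base, n_major = 30L, n_minor = 10L,
                                   ratio = ratio, depth = 40L)
  expect_true(classify_heterozygous(one(3.0))$is_het)     # <= 3.0 is het
  expect_false(classify_heterozygous(one(3.5))$is_het)

  two <- rbind(transform(base, n_major = 20L, n_minor = 0L, ratio = Inf,
                         depth = 20L),
               transform(base, pos = 2L, n_major = 20L, n_minor = 10L,
                         ratio = 2.0, depth = 30L))
  any_rule <- classify_heterozygous(two)
  expect_true(any_rule$is_het)               # one het site suffices
  expect_equal(any_rule$n_eligible_sites, 2L)
  expect_equal(any_rule$n_het_sites, 1L)
  maj_rule <- classify_heterozygous(two, rule = "majority")
  expect_false(maj_rule$is_het)              # 1 of 2 is not a majority
})

test_that("the heterozygosity rate reproduces the 7-of-444 worked example", {
  calls <- data.frame(seq_id = sprintf("iso%03d", 1:444), accession = "acc1",
                      n_eligible_sites = 1L,
                      n_het_sites = c(rep(1L, 7), rep(0L, 437)),
                      is_het = c(rep(TRUE, 7), rep(FALSE, 437)),
                      stringsAsFactors = FALSE)
  expect_equal(het_rate(calls), 1.6)
  calls$is_het <- FALSE
  expect_equal(het_rate(calls), 0.0)
  expect_error(het_rate(calls[0, ]), "no classified")
  expect_error(het_rate(transform(calls, accession = rep(c("acc1", "acc2"),
                                                         222))),
               "single accession")
})

test_that("raising the ratio cutoff never lowers a rate", {
  set.seed(151)
  rec <- data.frame(seq_id = sprintf("s%02d", sample(20, 60, TRUE)),
                    pos = 1:60, accession = "acc2",
                    n_major = 30L, n_minor = 10L,
                    ratio = c(sample(c(1.2, 2.5, 3.4, 6, Inf), 60, TRUE)),
                    depth = 40L, stringsAsFactors = FALSE)
  prev <- -1
  for (cutoff in c(1.5, 2, 3, 5, 10)) {
    cls <- classify_heterozygous(rec, max_ratio = cutoff)
    rate <- het_rate(cls)
    expect_gte(rate, prev)
    prev <- rate
  }
})

test_that("ratio histograms bin finite ratios and overflow the rest", {
  rec <- data.frame(ratio = c(1, 1, 1.4, 2.2, 3.5, 10, Inf))
  h <- ratio_histogram(rec, bin_edges = c(1, 1.5, 2, 2.5, 3, 4, 5))
  expect_equal(sum(h), nrow(rec))
  expect_equal(unname(h[1]), 3L)             # [1,1.5)
  expect_equal(unname(h[length(h)]), 2L)     # 10 and Inf overflow

  all_ones <- data.frame(ratio = rep(1, 9))
  h1 <- ratio_histogram(all_ones, bin_edges = 1:4)
  expect_equal(unname(h1[1]), 9L)
  expect_equal(sum(ratio_histogram(rec[0, , drop = FALSE], 1:4)), 0L)
})

test_that("map binning counts heterozygous sequences and the unplaced", {
  cls <- data.frame(seq_id = c("a", "b", "c", "d"), accession = "acc2",
                    n_eligible_sites = 1L, n_het_sites = 1L,
                    is_het = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  pl <- data.frame(query_id = c("a", "b"), gene_id = c("g1", "g2"),
                   chromosome = c("1H", "1H"), position_cM = c(10.5, 12),
                   bin_index = 0L, stringsAsFactors = FALSE)
  r <- bin_het_on_map(cls, pl, bin_width_cM = 5)
  expect_equal(sum(r$bins$n_het), 2L)
  expect_equal(unique(r$bins$chromosome), "1H")
  expect_equal(r$bins$bin_index, 2L)         # both in floor(cM/5) = 2
  expect_equal(unname(r$n_unplaced["acc2"]), 1L)   # c is het but unplaced

  empty <- bin_het_on_map(cls[cls$is_het == FALSE, , drop = FALSE], pl, 5)
  expect_equal(nrow(empty$bins), 0L)
})

test_that("clustered heterozygous genes concentrate on their planted chromosome", {
  set.seed(153)
  n <- 40
  cls <- data.frame(seq_id = sprintf("g%02d", 1:n), accession = "acc2",
                    n_eligible_sites = 1L, n_het_sites = 1L, is_het = TRUE,
                    stringsAsFactors = FALSE)
  chr <- c(rep("2H", 37), "5H", "6H", "7H")   # planted clustering on 2H
  pl <- data.frame(query_id = cls$seq_id, gene_id = sprintf("m%02d", 1:n),
                   chromosome = chr, position_cM = runif(n, 0, 150),
                   bin_index = 0L, stringsAsFactors = FALSE)
  r <- bin_het_on_map(cls, pl, 5)
  on_2h <- sum(r$bins$n_het[r$bins$chromosome == "2H"])
  expect_gte(on_2h / sum(r$bins$n_het), 0.9)
})

test_that("the marker conversion bookkeeping reproduces 35 of 59", {
  expect_equal(conversion_rate(35, 59), 59.3)
  expect_equal(round(conversion_rate(35, 59)), 59)
  expect_equal(conversion_rate(0, 10), 0)
  expect_error(conversion_rate(5, 0))
  expect_error(conversion_rate(11, 10))
})

test_that("planted heterozygosity is recovered through the full statistic", {
  set.seed(155)
  cfg <- sim_config(n_genes = 25L, n_species = 2L,
                    gene_len_range = c(600L, 800L), coverage = 25,
                    snp_rate = 0.004, het_fraction_acc1 = 0,
                    het_fraction_acc2 = 0.3, error_rate = 0.005,
                    paralog_family_rate = 0, seed = 157)
  t <- generate_universe(cfg)
  pls <- build_pileups(list(acc1 = simulate_reads(t, "acc1")$reads,
                            acc2 = simulate_reads(t, "acc2")$reads),
                       pseudo_assembly(t))
  calls <- call_snps(pls$acc1, pls$acc2, caller_model(error_rate = 0.005))
  rec <- allelic_ratios(calls, pls, min_depth = 20)
  cls <- classify_heterozygous(rec)
  cls2 <- cls[cls$accession == "acc2", ]
  cls1 <- cls[cls$accession == "acc1", ]
  # every classified-het sequence in acc2 is a planted het gene and the
  # planted het genes that reach the denominator are all found
  expect_true(all(cls2$seq_id[cls2$is_het] %in% t$het_genes$acc2))
  planted_in_denominator <- intersect(cls2$seq_id, t$het_genes$acc2)
  expect_equal(sort(cls2$seq_id[cls2$is_het]), sort(planted_in_denominator))
  # accession 1 carries no planted heterozygosity
  if (nrow(cls1) > 0) expect_equal(het_rate(cls1), 0.0)
})
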