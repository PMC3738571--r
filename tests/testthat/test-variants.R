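# closed-form likelihood oracle, written independently of the package code
oracle_posteriors <- function(counts, eps, theta) {
  gts <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")
  names(counts) <- c("A", "C", "G", "T")
  lik <- vapply(gts, function(g) {
    al <- unique(strsplit(g, "")[[1]])
    p <- rep(eps / 3, 4); names(p) <- names(counts)
    if (length(al) == 1) p[al] <- 1 - eps
    else p[al] <- 0.5 * (1 - eps) + eps / 6
    prod(p^counts)
  }, numeric(1))
  prior <- ifelse(nchar(gts) == 2 &
                    substr(gts, 1, 1) == substr(gts, 2, 2),
                  (1 - theta) / 4, theta / 6)
  post <- lik * prior
  post / sum(post)
}

test_that("genotype posteriors match the closed-form likelihood", {
  m <- caller_model(error_rate = 0.01, het_prior = 0.001)
  p <- genotype_posteriors(c(30, 0, 0, 0), m)
  expect_equal(names(which.max(p)), "AA")
  expect_gt(p[["AA"]], 0.999)
  expect_equal(unname(p), unname(oracle_posteriors(c(30, 0, 0, 0), 0.01, 0.001)),
               tolerance = 1e-12)

  p2 <- genotype_posteriors(c(15, 0, 15, 0), m)
  expect_equal(names(which.max(p2)), "AG")
  expect_equal(unname(p2), unname(oracle_posteriors(c(15, 0, 15, 0), 0.01, 0.001)),
               tolerance = 1e-12)

  set.seed(131)
  for (i in 1:20) {
    cnt <- stats::rmultinom(1, sample(5:60, 1), c(0.5, 0.3, 0.15, 0.05))[, 1]
    expect_equal(unname(genotype_posteriors(cnt, m)),
                 unname(oracle_posteriors(cnt, 0.01, 0.001)),
                 tolerance = 1e-10)
  }
})

test_that("the zero-error single-read limit is dominated by the homozygote", {
  p <- genotype_posteriors(c(1, 0, 0, 0), caller_model(error_rate = 0))
  expect_equal(names(which.max(p)), "AA")
  expect_error(genotype_posteriors(c(0, 0, 0, 0), caller_model()), "depth")
})

test_that("error-free reads give unanimous pileup columns", {
  set.seed(133)
  cfg <- sim_config(n_genes = 4L, n_species = 2L,
                    gene_len_range = c(400L, 500L), coverage = 10,
                    error_rate = 0, n_rate_3prime = 0, n_rate_uniform = 0,
                    short_read_rate = 0, snp_rate = 0,
                    het_fraction_acc1 = 0, het_fraction_acc2 = 0,
                    paralog_family_rate = 0, seed = 135)
  t <- generate_universe(cfg)
  reads <- simulate_reads(t, "acc1")$reads
  pl <- build_pileup(reads, pseudo_assembly(t))
  expect_equal(pl$n_unaligned + pl$n_ambiguous + pl$n_placed, nrow(reads))
  for (gid in names(pl$columns)) {
    m <- pl$columns[[gid]]$counts
    ref <- strsplit(pl$columns[[gid]]$ref_seq, "")[[1]]
    covered <- colSums(m) > 0
    consensus <- rownames(m)[apply(m[, covered, drop = FALSE], 2, which.max)]
    expect_equal(consensus, ref[covered])
    # unanimity: the consensus base carries the full depth
    expect_true(all(apply(m[, covered, drop = FALSE], 2, max) ==
                      colSums(m[, covered, drop = FALSE])))
  }
})

test_that("reads tied between duplicated references are dropped and counted", {
  set.seed(137)
  s <- rnd_dna(400)
  ref <- seq_set(c("dupA", "dupB", "other"), c(s, s, rnd_dna(400)))
  rd <- seq_set("r1", substr(s, 50, 249), source = "read")
  pl <- build_pileup(rd, ref)
  expect_equal(pl$n_ambiguous, 1L)
  expect_equal(pl$n_placed, 0L)
  expect_true(all(pl$columns$dupA$counts == 0L))
})

test_that("a clean fixed difference is called and a 1-read allele is not", {
  refs <- seq_set("ctg1", paste0(strrep("A", 50), rnd_dna(150)))
  m <- caller_model(error_rate = 0.01)
  p1 <- make_pileup(refs, list("ctg1:25" = c(A = 20)))
  p2 <- make_pileup(refs, list("ctg1:25" = c(G = 20)))
  calls <- call_snps(p1, p2, m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 25L)
  expect_equal(calls$allele_acc1, "A")
  expect_equal(calls$allele_acc2, "G")
  expect_gt(calls$posterior, 0.9)

  p2b <- make_pileup(refs, list("ctg1:25" = c(A = 19, G = 1)))
  expect_equal(nrow(call_snps(p1, p2b, m)), 0L)   # G below 2-read support
})

test_that("heterozygous-versus-homozygous sites are called with the private allele", {
  refs <- seq_set("ctg1", rnd_dna(100))
  m <- caller_model()
  p1 <- make_pileup(refs, list("ctg1:10" = c(A = 22)))
  p2 <- make_pileup(refs, list("ctg1:10" = c(A = 12, G = 11)))
  calls <- call_snps(p1, p2, m)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$allele_acc1, "A")
  expect_equal(calls$allele_acc2, "G")
})

test_that("calls are symmetric under swapping the accessions", {
  set.seed(139)
  refs <- seq_set("ctg1", rnd_dna(300))
  sites <- list("ctg1:30" = c(A = 18), "ctg1:90" = c(C = 25),
                "ctg1:150" = c(G = 12, T = 11), "ctg1:210" = c(T = 30))
  sites2 <- list("ctg1:30" = c(G = 21), "ctg1:90" = c(C = 24),
                 "ctg1:150" = c(G = 22), "ctg1:210" = c(T = 28, A = 1))
  pA <- make_pileup(refs, sites); pB <- make_pileup(refs, sites2)
  ab <- call_snps(pA, pB)
  ba <- call_snps(pB, pA)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$pos, ba$pos)
  expect_equal(ab$allele_acc1, ba$allele_acc2)
  expect_equal(ab$allele_acc2, ba$allele_acc1)
  expect_equal(ab$posterior, ba$posterior)
})

test_that("raising the posterior floor never adds calls", {
  set.seed(141)
  refs <- seq_set("ctg1", rnd_dna(200))
  p1 <- make_pileup(refs, list("ctg1:20" = c(A = 3), "ctg1:80" = c(C = 30)))
  p2 <- make_pileup(refs, list("ctg1:20" = c(G = 3), "ctg1:80" = c(T = 30)))
  lax <- call_snps(p1, p2, caller_model(min_posterior = 0.5))
  strict <- call_snps(p1, p2, caller_model(min_posterior = 0.99))
  expect_true(all(paste(strict$seq_id, strict$pos) %in%
                    paste(lax$seq_id, lax$pos)))
  expect_lte(nrow(strict), nrow(lax))
})

test_that("sites over reference Ns and multi-allelic sites are skipped", {
  refs <- seq_set("ctg1", paste0(strrep("A", 10), "N", strrep("A", 89)))
  p1 <- make_pileup(refs, list("ctg1:11" = c(A = 20),
                               "ctg1:40" = c(A = 10, C = 10)))
  p2 <- make_pileup(refs, list("ctg1:11" = c(G = 20),
                               "ctg1:40" = c(G = 10, T = 10)))
  calls <- call_snps(p1, p2)
  expect_false(11L %in% calls$pos)            # ref N
  expect_false(40L %in% calls$pos)            # 4 observed alleles
  skipped <- attr(calls, "skipped")
  expect_equal(unname(skipped["ref_n"]), 1L)
  expect_equal(unname(skipped["multiallelic"]), 1L)
})

test_that("the zero-error high-coverage limit recovers exactly the planted differences", {
  set.seed(143)
  cfg <- sim_config(n_genes = 8L, n_species = 2L,
                    gene_len_range = c(500L, 700L), coverage = 50,
                    error_rate = 0, n_rate_3prime = 0, n_rate_uniform = 0,
                    short_read_rate = 0, snp_rate = 0.005,
                    het_fraction_acc1 = 0, het_fraction_acc2 = 0,
                    paralog_family_rate = 0, seed = 145)
  t <- generate_universe(cfg)
  pls <- build_pileups(list(acc1 = simulate_reads(t, "acc1")$reads,
                            acc2 = simulate_reads(t, "acc2")$reads),
                       pseudo_assembly(t))
  calls <- call_snps(pls$acc1, pls$acc2, caller_model(error_rate = 0))
  rec <- snp_recovery(calls, t)
  expect_equal(rec$sensitivity, 1.0)
  expect_equal(rec$false_call_rate, 0.0)
  # alleles match the planted ones
  key <- paste(t$snp_sites$gene, t$snp_sites$pos)
  idx <- match(paste(calls$seq_id, calls$pos), key)
  expect_equal(calls$allele_acc1, t$snp_sites$allele_acc1[idx])
  expect_equal(calls$allele_acc2, t$snp_sites$allele_acc2[idx])
})
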