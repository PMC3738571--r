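test_that("the length filter removes reads of 45 nt and below, exactly", {
  reads <- seq_set(c("a", "b"), c(rnd_dna(45), rnd_dna(46)), source = "read")
  res <- length_filter(reads)
  expect_equal(res$removed$id, "a")
  expect_equal(res$kept$id, "b")

  all_long <- seq_set(sprintf("r%d", 1:20),
                      vapply(rep(300, 20), rnd_dna, character(1)),
                      source = "read")
  expect_equal(nrow(length_filter(all_long)$removed), 0L)

  set.seed(61)
  n_short <- 50
  lens <- c(rep(300, 950), sample(20:45, n_short, TRUE))
  mixed <- seq_set(sprintf("m%04d", seq_along(lens)),
                   vapply(lens, rnd_dna, character(1)), source = "read")
  res <- length_filter(mixed)
  expect_equal(nrow(res$removed), n_short)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(mixed))
})

test_that("library screening removes matching reads and spares diverged ones", {
  set.seed(63)
  lib <- seq_set("rep1", rnd_dna(400), source = "contaminant")
  exact <- substr(lib$seq, 50, 249)          # perfect 200 nt copy
  diverged <- plant_subs(exact, 40)          # 80% identity
  reads <- seq_set(c("hit", "miss"), c(exact, diverged), source = "read")
  rule <- screen_rule("triticeae_repeats", lib, 1e-6, 85, 85)
  res <- screen_by_library(reads, rule)
  expect_equal(res$removed$id, "hit")
  expect_equal(res$kept$id, "miss")          # 80% identity < 85% threshold
})

test_that("planted organelle reads are screened with no false removals", {
  set.seed(65)
  cfg <- sim_config(n_genes = 15L, n_species = 2L,
                    gene_len_range = c(400L, 700L), coverage = 8,
                    error_rate = 0, n_rate_3prime = 0, n_rate_uniform = 0,
                    short_read_rate = 0, seed = 67)
  t <- generate_universe(cfg)
  transcripts <- simulate_reads(t, "acc1")$reads
  org <- t$contaminants$organelle
  n_planted <- 100
  planted <- vapply(seq_len(n_planted), function(i) {
    src <- org$seq[sample(nrow(org), 1)]
    a <- sample(nchar(src) - 299, 1)
    substr(src, a, a + 299)
  }, character(1))
  reads <- rbind(transcripts,
                 seq_set(sprintf("org_read%03d", seq_len(n_planted)), planted,
                         source = "read"))
  class(reads) <- c("seq_set", "data.frame")
  rule <- screen_rule("organelle", org, 1e-6, 90, 90)
  res <- screen_by_library(reads, rule)
  removed_org <- sum(grepl("^org_read", res$removed$id))
  expect_gte(removed_org, 99)
  expect_equal(sum(!grepl("^org_read", res$removed$id)), 0L)
})

test_that("the cascade accounts sequentially and conserves reads", {
  set.seed(69)
  cfg <- sim_config(n_genes = 10L, n_species = 2L,
                    gene_len_range = c(300L, 500L), coverage = 6,
                    short_read_rate = 0.1, seed = 71)
  t <- generate_universe(cfg)
  sp <- spike_contaminants(simulate_reads(t, "acc1")$reads, t,
                           utils::modifyList(cfg, list(
                             contaminant_fractions = c("repeat" = 0.05,
                                                       organelle = 0.05,
                                                       human = 0.02))))
  rules <- list(
    screen_rule("short_reads", min_len = 46L),
    screen_rule("triticeae_repeats", t$contaminants[["repeat"]], 1e-6, 85, 85),
    screen_rule("organelle", t$contaminants$organelle, 1e-6, 90, 90),
    screen_rule("human_repeats", t$contaminants$human, 1e-6, 90, 90))
  rep <- run_cascade(sp$reads, rules)
  st <- rep$stages
  # stage k+1 sees exactly the survivors of stage k
  for (k in seq_len(nrow(st) - 1)) {
    expect_equal(st$input_count[k + 1], st$input_count[k] - st$removed_count[k])
  }
  expect_equal(rep$final_count, rep$input_count - sum(st$removed_count))
  expect_equal(sum(rep$disposition$stage == "kept"), rep$final_count)
  # contaminant reads end up removed by their own stages
  disp <- merge(rep$disposition, sp$labels, by = "read_id")
  expect_true(all(disp$stage[disp$label == "organelle"] %in%
                    c("organelle", "short_reads", "triticeae_repeats")))
})

test_that("permuting library screens changes stage counts, never the survivors", {
  set.seed(72)
  cfg <- sim_config(n_genes = 8L, n_species = 2L,
                    gene_len_range = c(300L, 500L), coverage = 6,
                    seed = 173)
  t <- generate_universe(cfg)
  sp <- spike_contaminants(simulate_reads(t, "acc1")$reads, t,
                           utils::modifyList(cfg, list(
                             contaminant_fractions = c("repeat" = 0.05,
                                                       organelle = 0.05,
                                                       human = 0.02))))
  r_rep <- screen_rule("triticeae_repeats", t$contaminants[["repeat"]],
                       1e-6, 85, 85)
  r_org <- screen_rule("organelle", t$contaminants$organelle, 1e-6, 90, 90)
  a <- run_cascade(sp$reads, list(r_rep, r_org))
  b <- run_cascade(sp$reads, list(r_org, r_rep))
  # removal is a pure per-read predicate, so the survivor set is invariant
  expect_setequal(a$kept$id, b$kept$id)
})

test_that("an empty rule list passes everything through", {
  reads <- seq_set(c("a", "b"), c(rnd_dna(60), rnd_dna(70)), source = "read")
  rep <- run_cascade(reads, list())
  expect_equal(rep$final_count, 2L)
  expect_equal(nrow(rep$stages), 0L)
})

test_that("replaying a printed preprocessing table uses the sequential denominator", {
  out <- qc_replay(1000L, c(a = 100L, b = 90L, c = 81L))
  expect_equal(out$entering, c(1000L, 900L, 810L))
  expect_equal(out$removed_pct, c(10, 10, 10))
  expect_equal(attr(out, "final_count"), 729L)
  expect_error(qc_replay(10L, c(a = 20L)), "more reads")
})
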