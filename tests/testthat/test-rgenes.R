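mk_domain <- function(id, class, ev) {
  data.frame(seq_id = id, profile_name = paste0(class, "_prof"),
             profile_class = class, domain_evalue = ev, start = 0L,
             end = 60L, stringsAsFactors = FALSE)
}

test_that("domain selection honours the strict 0.1 threshold", {
  hits <- rbind(mk_domain("a", "NB_ARC", 0.05),
                mk_domain("b", "NB_ARC", 0.5),
                mk_domain("c", "NB_ARC", 0.02),
                mk_domain("c", "NB_ARC", 0.001))
  sel <- select_domain_hits(hits, "NB_ARC")
  expect_setequal(sel, c("a", "c"))          # b fails, c counted once
  expect_true(all(!duplicated(sel)))
})

test_that("the cascade restricts the LRR search to NB-ARC positives", {
  hits <- rbind(mk_domain("both", "NB_ARC", 0.01),
                mk_domain("both", "LRR_clan", 0.01),
                mk_domain("lrr_only", "LRR_clan", 0.001),
                mk_domain("arc_only", "NB_ARC", 0.05))
  r <- nblrr_cascade(hits)
  expect_setequal(r$nbarc_ids, c("arc_only", "both"))
  expect_equal(r$nblrr_ids, "both")
  expect_false("lrr_only" %in% c(r$nbarc_ids, r$nblrr_ids))
})

test_that("a planted 40/10 domain structure is reported exactly", {
  set.seed(121)
  rows <- list()
  for (i in 1:40) {
    rows[[length(rows) + 1]] <- mk_domain(sprintf("nb%02d", i), "NB_ARC",
                                          runif(1, 1e-8, 0.09))
  }
  for (i in 1:10) {
    rows[[length(rows) + 1]] <- mk_domain(sprintf("nb%02d", i), "LRR_clan",
                                          runif(1, 1e-8, 0.09))
  }
  for (i in 1:5) {   # LRR-only decoys must not enter either set
    rows[[length(rows) + 1]] <- mk_domain(sprintf("decoy%d", i), "LRR_clan",
                                          1e-6)
  }
  r <- nblrr_cascade(do.call(rbind, rows))
  expect_length(r$nbarc_ids, 40L)
  expect_length(r$nblrr_ids, 10L)
  expect_true(all(r$nblrr_ids %in% r$nbarc_ids))
})

test_that("raising the domain e-value ceiling never shrinks the sets", {
  set.seed(123)
  hits <- do.call(rbind, lapply(1:50, function(i) {
    mk_domain(sprintf("s%02d", sample(30, 1)),
              sample(c("NB_ARC", "LRR_clan"), 1), 10^runif(1, -8, 1))
  }))
  prev <- nblrr_cascade(hits, 1e-6)
  for (ev in c(1e-4, 1e-2, 0.1, 1)) {
    cur <- nblrr_cascade(hits, ev)
    expect_true(all(prev$nbarc_ids %in% cur$nbarc_ids))
    expect_true(all(prev$nblrr_ids %in% cur$nblrr_ids))
    prev <- cur
  }
})

test_that("lexical search is a case-insensitive substring match", {
  ann <- list(a = c("NB-LRR disease resistance"),
              b = c("leucine-rich repeat kinase"),
              c = c("putative NBLRR protein"),
              d = c("ATP binding", "nb-lrr class resistance"))
  expect_setequal(lexical_search(ann), c("a", "c", "d"))

  set.seed(125)
  planted <- sprintf("hit%02d", 1:37)
  ann2 <- c(stats::setNames(rep(list("NB-LRR resistance"), 37), planted),
            stats::setNames(rep(list("kinase activity"), 63),
                            sprintf("bg%02d", 1:63)))
  expect_setequal(lexical_search(ann2), planted)
})

test_that("prediction overlap reproduces the 4-versus-37 worked example", {
  cascade <- c("a", "b", "c", "d")
  lexical <- c("a", sprintf("x%02d", 1:36))
  ov <- compare_predictions(cascade, lexical)
  expect_equal(ov$both, 1L)
  expect_equal(ov$only_cascade, 3L)
  expect_equal(ov$only_lexical, 36L)
  expect_equal(ov$both + ov$only_cascade + ov$only_lexical,
               length(union(cascade, lexical)))

  same <- compare_predictions(cascade, cascade)
  expect_equal(same$only_cascade + same$only_lexical, 0L)
  expect_equal(compare_predictions(cascade, c("x", "y"))$both, 0L)
})

test_that("the toy scanner recovers planted motifs through the full cascade", {
  set.seed(127)
  toy <- default_rgene_motifs()
  n_arc <- 20; n_lrr <- 8; n_bg <- 30
  ids <- c(sprintf("arc%02d", 1:n_arc), sprintf("bg%02d", 1:n_bg))
  seqs <- character(0)
  for (i in 1:n_arc) {
    s <- rnd_dna(500)
    s <- paste0(substr(s, 1, 99),
                plant_subs(toy$motifs$NB_ARC_toy, 3),
                substr(s, 100 + nchar(toy$motifs$NB_ARC_toy), 500))
    if (i <= n_lrr) {
      s <- paste0(substr(s, 1, 349), plant_subs(toy$motifs$LRR_toy, 2),
                  substr(s, 350 + nchar(toy$motifs$LRR_toy), 500))
    }
    seqs <- c(seqs, s)
  }
  seqs <- c(seqs, vapply(rep(500, n_bg), rnd_dna, character(1)))
  x <- seq_set(ids, seqs)
  hits <- scan_domains(x, toy$motifs, toy$classes)
  r <- nblrr_cascade(hits, 0.1)
  # sensitivity >= 0.9 on both stages, no false NB-LRR calls
  expect_gte(length(intersect(r$nbarc_ids, sprintf("arc%02d", 1:n_arc))),
             0.9 * n_arc)
  expect_gte(length(intersect(r$nblrr_ids, sprintf("arc%02d", 1:n_lrr))),
             0.9 * n_lrr)
  expect_length(setdiff(r$nblrr_ids, sprintf("arc%02d", 1:n_lrr)), 0L)
  expect_length(setdiff(r$nbarc_ids, sprintf("arc%02d", 1:n_arc)), 0L)
  expect_true(all(r$nblrr_ids %in% r$nbarc_ids))
})

test_that("domain and annotation tables round-trip through their readers", {
  hits <- rbind(mk_domain("a", "NB_ARC", 0.01), mk_domain("b", "LRR_clan", 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_domain_table(path), hits)

  ann <- data.frame(seq_id = c("a", "a", "b"),
                    term = c("ATP binding", "NB-LRR resistance", "kinase"),
                    stringsAsFactors = FALSE)
  apath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, apath, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_annotations(apath)
  expect_equal(got$a, c("ATP binding", "NB-LRR resistance"))
  expect_equal(lexical_search(got), "a")
})
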