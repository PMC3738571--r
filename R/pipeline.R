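# End-to-end orchestration: simulate -> qc -> asmqc -> orthology -> nr ->
# rgenes -> snps -> het, with every stage's report written as JSON into a
# run directory plus a MANIFEST recording versions, seed and config hash.
# All numeric thresholds of every stage live in one flat config whose
# defaults are the conventional values used throughout the package
# (screen rules 1e-6 with 85/85 and 90/90, reciprocal-best e-value 1e-10,
# clustering identity 90, domain e-value 0.1, depth gate 20, allelic-ratio
# cutoff 3.0, 2 reads per allele).

#' Pipeline configuration
#'
#' @param seed integer master seed for the synthetic universe.
#' @param sim a [sim_config()]; defaults to a compact universe sized for
#'   an end-to-end run in seconds.
#' @param min_len length-filter threshold (reads shorter are removed).
#' @param repeat_rule,organelle_rule,human_rule numeric vectors
#'   `c(max_evalue, min_query_cov, min_identity)` for the three screens.
#' @param brbh_evalue e-value ceiling for reciprocal-best-hit detection.
#' @param cluster_identity,cluster_min_short_cov greedy-clustering
#'   thresholds in percent.
#' @param domain_evalue per-domain e-value for the NB-ARC/LRR cascade.
#' @param caller a [caller_model()].
#' @param het_min_depth,het_max_ratio allelic-ratio gates.
#' @param bin_width_cM genetic-map bin width.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = NULL,
                            min_len = 46L,
                            repeat_rule = c(1e-6, 85, 85),
                            organelle_rule = c(1e-6, 90, 90),
                            human_rule = c(1e-6, 90, 90),
                            brbh_evalue = 1e-10,
                            cluster_identity = 90,
                            cluster_min_short_cov = 80,
                            domain_evalue = 0.1,
                            caller = caller_model(),
                            het_min_depth = 20L,
                            het_max_ratio = 3.0,
                            bin_width_cM = 5) {
  if (missing(seed)) stop("pipeline_config(): seed is required")
  if (is.null(sim)) {
    sim <- sim_config(n_genes = 12L, n_species = 5L,
                      gene_len_range = c(600L, 900L), coverage = 25,
                      seed = seed)
  }
  structure(list(seed = as.integer(seed), sim = sim, min_len = min_len,
                 repeat_rule = repeat_rule, organelle_rule = organelle_rule,
                 human_rule = human_rule, brbh_evalue = brbh_evalue,
                 cluster_identity = cluster_identity,
                 cluster_min_short_cov = cluster_min_short_cov,
                 domain_evalue = domain_evalue, caller = caller,
                 het_min_depth = het_min_depth, het_max_ratio = het_max_ratio,
                 bin_width_cM = bin_width_cM),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @name pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$contaminant_fractions <- as.list(x$sim$contaminant_fractions)
  x$caller <- unclass(x$caller)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$contaminant_fractions <- unlist(x$sim$contaminant_fractions)
  sim <- do.call(sim_config, x$sim)
  caller <- do.call(caller_model, x$caller)
  x$sim <- NULL; x$caller <- NULL
  do.call(pipeline_config, c(x, list(sim = sim, caller = caller)))
}

# polynomial rolling hash (mod a Mersenne prime); enough to fingerprint a
# config in the manifest
config_fingerprint <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_report <- function(x, dir, name) {
  jsonlite::write_json(x, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline on a synthetic universe
#'
#' Executes every stage in order on data generated from `config$sim`,
#' writing one JSON report per stage plus a MANIFEST into `out_dir`.
#' Fully deterministic under the seed. A stage failure aborts with the
#' stage name; reports of earlier stages are left intact.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a named list of all stage reports.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    write_report(res$report, out_dir, name)
    reports[[name]] <<- res$report
    res$value
  }

  sim <- stage("simulate", function() {
    truth <- generate_universe(config$sim)
    reads <- list(acc1 = simulate_reads(truth, "acc1"),
                  acc2 = simulate_reads(truth, "acc2"))
    spiked <- list(acc1 = spike_contaminants(reads$acc1$reads, truth),
                   acc2 = spike_contaminants(reads$acc2$reads, truth))
    list(value = list(truth = truth, reads = reads, spiked = spiked),
         report = list(
           n_genes = nrow(truth$genes),
           n_planted_snps = nrow(truth$snp_sites),
           n_het_genes = lapply(truth$het_genes, length),
           n_reads = lapply(spiked, function(s) nrow(s$reads)),
           seed = config$sim$seed))
  })

  qc <- stage("qc", function() {
    rules <- list(
      screen_rule("short_reads", min_len = config$min_len),
      screen_rule("triticeae_repeats", sim$truth$contaminants[["repeat"]],
                  config$repeat_rule[1], config$repeat_rule[2],
                  config$repeat_rule[3]),
      screen_rule("organelle", sim$truth$contaminants$organelle,
                  config$organelle_rule[1], config$organelle_rule[2],
                  config$organelle_rule[3]),
      screen_rule("human_repeats", sim$truth$contaminants$human,
                  config$human_rule[1], config$human_rule[2],
                  config$human_rule[3]))
    res <- lapply(sim$spiked, function(s) run_cascade(s$reads, rules))
    list(value = res,
         report = lapply(res, function(r) {
           list(stages = r$stages, input_count = r$input_count,
                final_count = r$final_count)
         }))
  })

  contigs <- pseudo_assembly(sim$truth)

  stage("asmqc", function() {
    prov <- rbind(sim$reads$acc1$provenance, sim$reads$acc2$provenance)
    counts <- table(factor(prov$gene, levels = contigs$id))
    counts <- stats::setNames(pmax(1L, as.integer(counts)), contigs$id)
    corr <- length_vs_reads(contigs, counts)
    red <- self_redundancy(contigs)
    list(value = NULL,
         report = list(stats = assembly_stats(contigs),
                       length_vs_reads = corr,
                       redundancy = red[c("n_significant_nonself_pairs",
                                          "n_sequences_in_pairs",
                                          "proportion")]))
  })

  orth <- stage("orthology", function() {
    params <- align_params(max_evalue = 10)
    brbh_sets <- lapply(sim$truth$ref_sets, function(ref) {
      fwd <- all_vs_all(contigs, ref, params)
      rev <- all_vs_all(ref, contigs, params)
      brbh(fwd, rev, config$brbh_evalue)
    })
    names(brbh_sets) <- names(sim$truth$ref_sets)
    un <- unique_hit_union(brbh_sets)
    core <- core_intersection(brbh_sets[1:4])
    placements <- place_on_map(brbh_sets[[sim$truth$map_ref]],
                               sim$truth$genetic_map, config$bin_width_cM)
    list(value = list(brbh_sets = brbh_sets, placements = placements),
         report = list(per_set_counts = lapply(brbh_sets, nrow),
                       union_count = un$count,
                       core = list(core_count = core$core_count,
                                   union_count = core$union_count,
                                   core_pct = core$core_pct),
                       n_placed = nrow(placements),
                       n_unplaced = attr(placements, "n_unplaced")))
  })

  stage("nr", function() {
    cl <- cluster_greedy(contigs, config$cluster_identity,
                         config$cluster_min_short_cov)
    reps <- representatives(cl, contigs)
    list(value = reps,
         report = list(n_input = nrow(contigs), n_clusters = length(cl),
                       n_representatives = nrow(reps)))
  })

  stage("rgenes", function() {
    toy <- default_rgene_motifs()
    hits <- scan_domains(contigs, toy$motifs, toy$classes)
    casc <- nblrr_cascade(hits, config$domain_evalue)
    lex <- lexical_search(sim$truth$annotations)
    ovl <- compare_predictions(casc$nblrr_ids, lex)
    list(value = casc,
         report = list(n_nbarc = length(casc$nbarc_ids),
                       n_nblrr = length(casc$nblrr_ids),
                       n_lexical = length(lex),
                       overlap = ovl[c("both", "only_cascade",
                                       "only_lexical")]))
  })

  snps <- stage("snps", function() {
    pls <- build_pileups(list(acc1 = qc$acc1$kept, acc2 = qc$acc2$kept),
                         contigs)
    calls <- call_snps(pls$acc1, pls$acc2, config$caller)
    gff <- file.path(out_dir, "snps.gff3")
    write_snp_gff(calls, gff)
    rec <- snp_recovery(calls, sim$truth)
    list(value = list(pileups = pls, calls = calls),
         report = list(n_calls = nrow(calls),
                       skipped = as.list(attr(calls, "skipped")),
                       recovery = rec, gff = basename(gff)))
  })

  stage("het", function() {
    ratios <- allelic_ratios(snps$calls, snps$pileups, config$het_min_depth)
    cls <- classify_heterozygous(ratios, config$het_max_ratio)
    rates <- lapply(c(acc1 = "acc1", acc2 = "acc2"), function(a) {
      sub <- cls[cls$accession == a, , drop = FALSE]
      if (nrow(sub) == 0L) NA_real_ else het_rate(sub)
    })
    hist <- ratio_histogram(ratios)
    mapbins <- bin_het_on_map(cls, orth$placements, config$bin_width_cM)
    list(value = NULL,
         report = list(n_ratio_records = nrow(ratios),
                       het_rate_acc1 = rates$acc1,
                       het_rate_acc2 = rates$acc2,
                       histogram = as.list(hist),
                       map_bins = mapbins$bins,
                       n_unplaced = as.list(mapbins$n_unplaced)))
  })

  cfg_yaml <- tempfile(); on.exit(unlink(cfg_yaml), add = TRUE)
  write_pipeline_config(config, cfg_yaml)
  manifest <- list(
    package = "sharest",
    version = as.character(utils::packageVersion("sharest")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_fingerprint(paste(readLines(cfg_yaml),
                                           collapse = "\n")),
    stages = c("simulate", "qc", "asmqc", "orthology", "nr", "rgenes",
               "snps", "het"))
  write_report(manifest, out_dir, "MANIFEST")
  invisible(reports)
}
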