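#' Pipeline configuration
#'
#' Bundles the thresholds and chain parameters of the full analysis. Defaults
#' follow the standard toolchain settings: five-animal herd threshold,
#' q-bar >= 0.7 assignment, HWE chain of 100 batches x 5000 iterations with
#' dememorization 10000, K scanned over 1-10 with 10 runs each, and 1e5
#' Mantel permutations. Chain lengths default to the scaled-down 1e4/1e4;
#' raise them for production runs.
#'
#' @param min_animals herd-size threshold for herd-level analyses.
#' @param q_threshold genetic-group assignment threshold on q-bar.
#' @param null_r_threshold null-allele suspicion threshold.
#' @param K_range,n_runs,burnin,iters admixture scan settings.
#' @param K cluster count used for grouping; `NULL` = Evanno argmax delta-K.
#' @param hwe_batches,hwe_iters,hwe_dememorization HWE chain settings.
#' @param n_perm Mantel permutations.
#' @param seed global seed, fanned out to stages by a fixed counter scheme
#'   (simulation/stage i uses seed + 100*i).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_animals = 5L, q_threshold = 0.7,
                            null_r_threshold = 0.05,
                            K_range = 1:10, n_runs = 10L,
                            burnin = 10000L, iters = 10000L, K = NULL,
                            hwe_batches = 100L, hwe_iters = 5000L,
                            hwe_dememorization = 10000L,
                            n_perm = 100000L, seed = 1L) {
  cfg <- list(min_animals = as.integer(min_animals),
              q_threshold = q_threshold,
              null_r_threshold = null_r_threshold,
              K_range = as.integer(K_range), n_runs = as.integer(n_runs),
              burnin = as.integer(burnin), iters = as.integer(iters),
              K = if (is.null(K)) NULL else as.integer(K),
              hwe_batches = as.integer(hwe_batches),
              hwe_iters = as.integer(hwe_iters),
              hwe_dememorization = as.integer(hwe_dememorization),
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full diversity-and-network analysis pipeline
#'
#' Executes validation, diversity statistics, differentiation, Bayesian
#' clustering with group assignment, network metrics, the Mantel correlation
#' and (when pedigree and candidates are supplied) donor ranking, writing
#' each stage's tables under `out_dir` together with a run manifest naming
#' the seed and parameters. A stage failure stops with an error naming the
#' stage; artifacts of completed stages are retained.
#'
#' @param gt a [genotype_table()] or path to a Genepop file.
#' @param exchanges an [exchange_records()] data.frame or path to an
#'   exchange table.
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param pedigree optional [pedigree_records()] or path.
#' @param candidates optional character vector of donor candidate ids.
#' @param natal_herd optional named vector for non-genotyped candidates.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(gt, exchanges, cfg = pipeline_config(),
                         out_dir = ".", pedigree = NULL, candidates = NULL,
                         natal_herd = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] seed=%d %s", stage, cfg$seed,
                    paste(..., collapse = " ")))
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(config = cfg)

  # genio --------------------------------------------------------------
  res$gt <- in_stage("genio", {
    if (is.character(gt)) gt <- read_genepop(gt)
    stopifnot(inherits(gt, "genotype_table"))
    gt
  })
  res$exchanges <- in_stage("genio", {
    if (is.character(exchanges)) exchanges <- read_exchange_table(exchanges)
    exchanges
  })
  if (is.character(pedigree)) pedigree <- read_pedigree_table(pedigree)
  res$validation <- in_stage("genio",
    validate_dataset(res$gt, res$exchanges, cfg$min_animals))
  log_stage("genio", sprintf("%d animals, %d loci, %d exchange records",
                             length(res$gt$individuals),
                             length(res$gt$loci), nrow(res$exchanges)))

  # diversity ----------------------------------------------------------
  res$diversity <- in_stage("diversity", {
    st <- per_locus_stats(res$gt, "breed")
    write.table(st, file.path(out_dir, "per_locus_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rich <- allelic_richness(res$gt, "breed")
    write.table(rich, file.path(out_dir, "allelic_richness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    set.seed(cfg$seed + 100L)
    hwe <- hwe_scan(res$gt, "breed", batches = cfg$hwe_batches,
                    iters_per_batch = cfg$hwe_iters,
                    dememorization = cfg$hwe_dememorization)
    write.table(hwe, file.path(out_dir, "hwe_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    nulls <- null_allele_estimate(res$gt, "breed", cfg$null_r_threshold)
    write.table(nulls, file.path(out_dir, "null_alleles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(per_locus = st, summary = unit_diversity_summary(st),
         richness = rich, hwe = hwe, nulls = nulls)
  })
  log_stage("diversity", sprintf("%d loci", length(res$gt$loci)))

  # differentiation ----------------------------------------------------
  res$fst <- in_stage("differentiation", {
    fst <- fst_jackknife(res$gt, "herd")
    dr <- reynolds_matrix(res$gt, min_animals = cfg$min_animals)
    write_herd_matrix(dr, file.path(out_dir, "reynolds_square.tsv"),
                      file.path(out_dir, "reynolds_long.tsv"))
    list(fst = fst, reynolds = dr)
  })
  log_stage("differentiation",
            sprintf("Fst=%.4f sd=%.4f", res$fst$fst$theta,
                    res$fst$fst$sd_jackknife))

  # clustering ----------------------------------------------------------
  res$clustering <- in_stage("clustering", {
    runs <- admixture_scan(res$gt, cfg$K_range, cfg$n_runs,
                           burnin = cfg$burnin, iters = cfg$iters,
                           seed = cfg$seed + 200L)
    ev <- evanno_delta_k(runs)
    write.table(ev, file.path(out_dir, "evanno_delta_k.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summ <- data.frame(K = vapply(runs, `[[`, 0L, "K"),
                       seed = vapply(runs, `[[`, 0L, "seed"),
                       lnP = vapply(runs, `[[`, 0, "lnP"))
    write.table(summ, file.path(out_dir, "run_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    K_use <- if (is.null(cfg$K)) attr(ev, "best_k") else cfg$K
    al <- align_runs(Filter(function(r) r$K == K_use, runs))
    write_q_matrix(al$q, res$gt$herd, file.path(out_dir, "q_matrix.tsv"))
    qb <- herd_membership(al$q, res$gt$herd)
    asg <- assign_groups(qb, cfg$q_threshold)
    write.table(cbind(asg, round(qb[asg$herd, , drop = FALSE], 4)),
                file.path(out_dir, "group_assignment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(runs = runs, evanno = ev, K = K_use, q = al$q,
         q_bars = qb, assignments = asg)
  })
  log_stage("clustering", sprintf("K=%d", res$clustering$K))

  # network -------------------------------------------------------------
  res$network <- in_stage("network", {
    g <- build_graph(res$exchanges)
    write_graph_tables(g, file.path(out_dir, "network_edges.tsv"),
                       file.path(out_dir, "network_adjacency.tsv"))
    list(graph = g, ad = average_degree(g))
  })
  log_stage("network", sprintf("AD=%.2f", res$network$ad))

  # correlate -----------------------------------------------------------
  res$mantel <- in_stage("correlate", {
    sel <- select_analysis_herds(res$gt, res$network$graph, cfg$min_animals)
    sub <- build_graph(res$exchanges, restrict_to = sel$herds)
    spl <- shortest_path_lengths(sub)
    cnt <- geodesic_counts(sub)
    dr <- reynolds_matrix(res$gt, herds = sel$herds,
                          min_animals = cfg$min_animals)
    al <- align_matrices(dr, spl, sel$herds)
    strat <- spl_stratified_metrics(sub, al$spl, cnt[al$spl$herds,
                                                    al$spl$herds],
                                    gen = al$gen)
    write.table(strat, file.path(out_dir, "spl_stratified_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mt <- mantel_test(al$gen, al$spl, n_perm = cfg$n_perm,
                      seed = cfg$seed + 300L)
    write.table(pair_scatter(al$gen, al$spl),
                file.path(out_dir, "pair_scatter.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(r = mt$r, p = mt$p, n_perm = mt$n_perm, n_herds = mt$n_herds,
           tail = mt$tail, seed = cfg$seed + 300L),
      file.path(out_dir, "mantel.json"), auto_unbox = TRUE, digits = NA)
    list(selection = sel, spl = al$spl, reynolds = al$gen,
         stratified = strat, mantel = mt)
  })
  log_stage("correlate", sprintf("r=%.3f p=%.4g",
                                 res$mantel$mantel$r, res$mantel$mantel$p))

  # donors --------------------------------------------------------------
  if (!is.null(candidates)) {
    res$donors <- in_stage("donors", {
      rk <- rank_donors(candidates, res$gt, res$clustering$assignments,
                        res$clustering$q, pedigree, res$network$graph,
                        natal_herd = natal_herd,
                        q_threshold = cfg$q_threshold)
      write.table(rk, file.path(out_dir, "donor_ranking.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summ <- donor_summary(rk)
      jsonlite::write_json(
        list(n_candidates = summ$n_candidates,
             n_characterized = summ$n_characterized,
             per_tier = as.list(setNames(as.integer(summ$per_tier),
                                         names(summ$per_tier))),
             per_group = as.list(setNames(as.integer(summ$per_group),
                                          names(summ$per_group)))),
        file.path(out_dir, "donor_summary.json"), auto_unbox = TRUE,
        digits = NA)
      list(ranking = rk, summary = summ)
    })
    log_stage("donors", sprintf("%d candidates", length(candidates)))
  }

  manifest <- list(seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "K_range")],
                   K_range = range(cfg$K_range),
                   n_individuals = length(res$gt$individuals),
                   n_loci = length(res$gt$loci),
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
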