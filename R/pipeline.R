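#' Run the full cross-ploidy analysis from one configuration
#'
#' Orchestrates the stages in the order of the study design -- simulate
#' (or load), karyotype/consistency QC, subgenome-mismatch correction and
#' TE redistribution, split normalization and NB differential expression,
#' the midparent-value TE test, triad bias analysis, and DEG-overlap
#' statistics -- writing one TSV per result plus a run manifest. QC runs
#' before DE; aneuploidy-flagged samples are kept with a warning by
#' default and excluded when the `qc$exclude_flagged` flag is set.
#'
#' The configuration is a YAML file (or equivalent list) with blocks:
#' `out_dir`; `seed`; exactly one of `simulation` (arguments of
#' [sim_config()]) or `data` (paths `counts`, `annotation`, `samples`,
#' `triads`); optional `pipeline` (arguments of [pipeline_config()]) and
#' `qc` (`exclude_flagged`).
#'
#' @param config path to a YAML file or a list.
#' @param out_dir overrides the configured output directory.
#' @param seed overrides the configured seed.
#' @return the run manifest data.frame (stage, output, rows), invisibly;
#'   `config_hash`, `seed` and `version` are attached as attributes and
#'   written to `manifest.tsv`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "simulation", "data", "pipeline", "qc")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    .config_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$simulation) && !is.null(config$data))
    .config_error("ambiguous input: both 'simulation' and 'data' given")
  if (is.null(config$simulation) && is.null(config$data))
    .config_error("no input: provide a 'simulation' or 'data' block")
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) .config_error("no out_dir configured")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  pcfg <- do.call(pipeline_config, as.list(config$pipeline))
  exclude_flagged <- isTRUE(config$qc$exclude_flagged)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  note <- function(stage, name, obj) {
    path <- file.path(out_dir, name)
    write_table(obj, path)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, output = name,
      rows = if (is.matrix(obj)) nrow(obj) else nrow(obj),
      stringsAsFactors = FALSE)
  }

  # --- stage 1: input -------------------------------------------------
  te_tab <- NULL
  if (!is.null(config$simulation)) {
    .log_stage("simulate", "generating synthetic experiment")
    sim_args <- config$simulation
    sim_args$rng_seed <- as.integer(seed)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_experiment(scfg)
    tab <- sim$counts
    triads <- sim$triads
    te_tab <- simulate_te_families(scfg)$counts
    note("simulate", "sim_truth_de.tsv", sim$truth$de_truth)
    note("simulate", "sim_truth_bias.tsv", sim$truth$bias_truth)
  } else {
    d <- config$data
    for (key in c("counts", "annotation", "samples", "triads"))
      if (is.null(d[[key]]))
        .config_error("data block lacks '", key, "'")
    .log_stage("load", "reading ", d$counts)
    tab <- load_dataset(d$counts, d$annotation, d$samples)
    triads <- read_triad_table(d$triads, tab$features)
    if (any(tab$features$feature_class == "te_family"))
      te_tab <- subset_count_table(
        tab, features = tab$features$feature_class == "te_family")
  }
  roles <- tab$samples$role
  genes <- subset_count_table(tab, features = .is_gene(tab$features))
  dip <- subset_count_table(genes, samples = roles == "diploid_parent")
  tet <- subset_count_table(genes, samples = roles == "tetraploid_parent")
  syn <- subset_count_table(genes,
                            samples = roles %in% c("synthetic",
                                                   "natural_hexaploid"))

  # --- stage 2: QC ----------------------------------------------------
  .log_stage("qc", "in-silico karyotype and consistency checks")
  tpm <- normalize_expression(genes, "tpm")
  rpm <- normalize_expression(genes, "rpm")
  poly_ids <- syn$samples$sample_id
  kwin <- list(); kflag <- list()
  for (sid in poly_ids) {
    w <- karyotype_ratios(tpm, sid, config = pcfg)
    f <- flag_aneuploidy(w, pcfg)
    w$sample_id <- sid; f$sample_id <- sid
    kwin[[sid]] <- w; kflag[[sid]] <- f
  }
  kwin <- do.call(rbind, kwin); kflag <- do.call(rbind, kflag)
  note("qc", "karyotype_windows.tsv", kwin)
  note("qc", "karyotype_flags.tsv", kflag)
  cc <- sample_correlation(rpm)
  note("qc", "sample_correlation.tsv", cc$correlation)
  pca <- pca_overview(rpm)
  note("qc", "pca_scores.tsv", pca$scores)
  flagged <- unique(kflag$sample_id[kflag$flag != "euploid"])
  if (length(flagged)) {
    if (exclude_flagged) {
      warning("excluding aneuploidy-flagged sample(s): ",
              paste(flagged, collapse = ", "))
      syn <- subset_count_table(
        syn, samples = !syn$samples$sample_id %in% flagged)
    } else {
      warning("aneuploidy-flagged sample(s) retained: ",
              paste(flagged, collapse = ", "))
    }
  }

  # --- stage 3: preprocess -------------------------------------------
  .log_stage("preprocess", "subgenome-mismatch correction")
  corrected <- correct_subgenome_mismatch(dip, tet, pcfg)

  # --- stage 4: split normalization + DE ------------------------------
  .log_stage("de", "split-by-subgenome normalization and NB testing")
  groups <- build_normalization_groups(syn, corrected$diploid,
                                       corrected$tetraploid, pcfg)
  genotypes <- unique(syn$samples$genotype_id)
  de_all <- list(); de_sum <- list()
  for (g in genotypes) {
    for (grp in groups) {
      if (!g %in% grp$samples$genotype_id) next
      de <- de_test(grp, synthetic_genotype = g, config = pcfg)
      de$genotype <- g
      de$partition <- grp$partition
      de_all[[paste(g, grp$partition)]] <- de
      s <- classify_degs(de)
      s$genotype <- g; s$partition <- grp$partition
      de_sum[[paste(g, grp$partition)]] <- s
    }
  }
  de_all <- do.call(rbind, de_all)
  note("de", "de_genes.tsv", de_all)
  note("de", "de_summary.tsv", do.call(rbind, de_sum))

  # --- stage 5: TE midparent-value test -------------------------------
  if (!is.null(te_tab)) {
    .log_stage("te", "midparent-value TE-family test")
    te_roles <- te_tab$samples$role
    dip_te <- redistribute_parent_te_counts(
      subset_count_table(te_tab, samples = te_roles == "diploid_parent"))
    tet_te <- redistribute_parent_te_counts(
      subset_count_table(te_tab, samples = te_roles == "tetraploid_parent"))
    syn_te <- subset_count_table(
      te_tab, samples = te_roles %in% c("synthetic", "natural_hexaploid"))
    mpv <- build_mpv_libraries(te_family_rpm(dip_te), te_family_rpm(tet_te))
    syn_rpm <- te_family_rpm(syn_te)
    te_de <- list()
    for (g in unique(syn_te$samples$genotype_id)) {
      cols <- syn_te$samples$genotype_id == g
      r <- te_mpv_de(syn_rpm[, cols, drop = FALSE], mpv, pcfg)
      r$genotype <- g
      te_de[[g]] <- r
    }
    note("te", "de_te_families.tsv", do.call(rbind, te_de))
  }

  # --- stage 6: triad bias --------------------------------------------
  .log_stage("triads", "homoeolog bias classification and movement")
  dip_rpm <- normalize_expression(dip, "rpm")
  tet_rpm <- normalize_expression(tet, "rpm")
  insilico <- combine_parents_in_silico(dip_rpm, tet_rpm, pcfg)
  par_states <- classify_triads(
    triad_contributions(insilico, triads, config = pcfg))
  par_states$genotype <- "in_silico_parent"
  syn_rpm_tab <- normalize_expression(syn, "rpm")
  states_all <- list(par = par_states)
  moves <- list(); stats <- list()
  for (g in genotypes) {
    st <- classify_triads(triad_contributions(
      syn_rpm_tab, triads,
      samples = syn_rpm_tab$samples$sample_id[
        syn_rpm_tab$samples$genotype_id == g],
      config = pcfg))
    st$genotype <- g
    states_all[[g]] <- st
    mv <- triad_movement(par_states, st, pcfg)
    mv$genotype <- g
    tr_counts <- attr(mv, "transitions")
    bc <- bias_correlation(par_states, st)
    assoc <- bias_de_association(st, triads,
                                 de_all[de_all$genotype == g, ], pcfg)
    moves[[g]] <- mv
    stats[[g]] <- data.frame(
      genotype = g,
      bias_correlation_vs_parents = bc$r,
      n_shared_triads = bc$n_triads,
      unbalanced_to_balanced = tr_counts[["unbalanced_to_balanced"]],
      balanced_to_unbalanced = tr_counts[["balanced_to_unbalanced"]],
      t_statistic = if (is.null(assoc$t_test)) NA_real_
      else assoc$t_test$statistic,
      t_p = if (is.null(assoc$t_test)) NA_real_ else assoc$t_test$p,
      chisq_statistic = assoc$chisq$statistic,
      chisq_p = assoc$chisq$p,
      stringsAsFactors = FALSE)
  }
  note("triads", "triad_states.tsv", do.call(rbind, states_all))
  note("triads", "triad_movement.tsv", do.call(rbind, moves))
  note("triads", "bias_stats.tsv", do.call(rbind, stats))

  # --- stage 7: DEG overlaps ------------------------------------------
  .log_stage("overlap", "DEG-set overlap statistics")
  ov <- list()
  if (length(genotypes) >= 2) {
    for (i in seq_len(length(genotypes) - 1)) {
      for (j in seq(i + 1, length(genotypes))) {
        d1 <- de_all[de_all$genotype == genotypes[i], ]
        d2 <- de_all[de_all$genotype == genotypes[j], ]
        bg <- intersect(d1$feature_id, d2$feature_id)
        s1 <- d1$feature_id[d1$significant & d1$feature_id %in% bg]
        s2 <- d2$feature_id[d2$significant & d2$feature_id %in% bg]
        r <- overlap_test(s1, s2, bg,
                          dir1 = setNames(d1$direction, d1$feature_id),
                          dir2 = setNames(d2$direction, d2$feature_id))
        ov[[paste(i, j)]] <- data.frame(
          genotype_1 = genotypes[i], genotype_2 = genotypes[j],
          n1 = r$n1, n2 = r$n2, N = r$N, k = r$k,
          expected = r$expected,
          representation_factor = r$representation_factor,
          p_exact = r$p_exact, p_normal = r$p_normal,
          same_direction = r$same_direction,
          opposite_direction = r$opposite_direction,
          direction_binomial_p = r$direction_binomial_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  ov <- if (length(ov)) do.call(rbind, ov) else
    data.frame(genotype_1 = character(), genotype_2 = character(),
               n1 = integer(), n2 = integer(), N = integer(),
               k = integer(), expected = numeric(),
               representation_factor = numeric(), p_exact = numeric(),
               p_normal = numeric(), same_direction = integer(),
               opposite_direction = integer(),
               direction_binomial_p = numeric())
  note("overlap", "deg_overlaps.tsv", ov)

  manifest <- do.call(rbind, manifest)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  attr(manifest, "config_hash") <- hash
  attr(manifest, "seed") <- as.integer(seed)
  attr(manifest, "version") <-
    as.character(utils::packageVersion("crossploidy"))
  out <- manifest
  out$config_hash <- hash
  out$seed <- as.integer(seed)
  out$version <- attr(manifest, "version")
  write_table(out, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

.config_error <- function(...) {
  stop(structure(class = c("crossploidy_config_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
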