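#' Configuration of the synthetic-experiment generator
#'
#' Describes a simulated allopolyploidization experiment: a diploid (DD)
#' parent, a tetraploid (AABB) parent and synthetic hexaploid (AABBDD)
#' replicates, all sequenced to a common library depth. Gene-level counts
#' are negative binomial (variance = mu + phi * mu^2) around means set by
#' a per-gene expression weight, the sample's native subgenomes, triad
#' bias vectors, differential-expression effects, and chromosome copy
#' ratios; the weights of each library are renormalized to its depth, so
#' parents concentrate their reads on fewer genes than the hexaploid --
#' the compositional structure that makes naive cross-ploidy comparisons
#' fail.
#'
#' @param n_triads number of homoeolog triads (one gene per subgenome).
#' @param n_singletons_per_subgenome singleton genes per subgenome; each
#'   gets a zero-expressed decoy homoeolog on another subgenome that
#'   receives its cross-mapped reads.
#' @param n_chromosomes_per_subgenome chromosomes per subgenome (wheat: 7).
#' @param replicates named integer vector with entries `diploid_parent`,
#'   `tetraploid_parent` and `synthetic` (replicates per synthetic
#'   genotype).
#' @param n_synthetic_genotypes number of synthetic genotypes sharing the
#'   two parents.
#' @param baseline_mean expected counts per gene in a hexaploid library at
#'   the nominal depth. Parental per-gene means are correspondingly higher
#'   at the same depth because their transcriptomes are smaller.
#' @param gene_spread_log2_sd SD of a per-gene log2-normal spread around
#'   `baseline_mean` (0 = all genes at the baseline).
#' @param dispersion genome-wide NB dispersion phi.
#' @param library_size expected total counts per library; default
#'   `3 * n_genes_per_subgenome * baseline_mean` so a hexaploid gene
#'   averages `baseline_mean` counts.
#' @param de_spec `NULL` or data.frame(`feature_id`, `log2fc`): true
#'   expression effects applied in the synthetics relative to the parents.
#' @param bias_spec `NULL` or an `n_triads` x 3 matrix of parental
#'   contribution vectors (rows on the simplex). `NULL` draws them from a
#'   symmetric Dirichlet with concentration `bias_alpha`.
#' @param bias_alpha Dirichlet concentration used when `bias_spec` is
#'   `NULL`; 15 gives mostly balanced triads with a realistic spread.
#' @param synthetic_bias_shrink fraction in `[0, 1]` by which the
#'   synthetic samples' triad contributions are pulled from the parental
#'   bias toward the balanced point (1/3, 1/3, 1/3); 0 means the
#'   synthetics inherit the parental bias unchanged (pure parental
#'   legacy).
#' @param mismatch_rate fraction of each gene's reads cross-assigned to
#'   its homoeolog partners (binomial thinning, reads conserved).
#' @param aneuploidy_spec `NULL` or data.frame(`sample_id`, `chromosome`,
#'   `copy_ratio`) with copy_ratio 0.5 (monosomy) or 1.5 (trisomy).
#' @param te_spec `NULL` or data.frame(`family`, `rpm_diploid`,
#'   `rpm_tetraploid`, `log2_effect`) for the TE-family generator; `NULL`
#'   draws `n_te_families` families with log-normal parental RPM levels
#'   and zero synthetic effect.
#' @param n_te_families,te_dispersion defaults for the TE generator.
#' @param te_library_size expected total mapped reads per library used to
#'   scale TE RPM levels into counts.
#' @param tissue tissue label for all samples.
#' @param rng_seed integer seed; identical config + seed reproduces the
#'   experiment exactly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_triads = 2000,
                       n_singletons_per_subgenome = 0,
                       n_chromosomes_per_subgenome = 7,
                       replicates = c(diploid_parent = 3,
                                      tetraploid_parent = 3,
                                      synthetic = 3),
                       n_synthetic_genotypes = 1,
                       baseline_mean = 100,
                       gene_spread_log2_sd = 0,
                       dispersion = 0.1,
                       library_size = NULL,
                       de_spec = NULL,
                       bias_spec = NULL,
                       bias_alpha = 15,
                       synthetic_bias_shrink = 0,
                       mismatch_rate = 0.02,
                       aneuploidy_spec = NULL,
                       te_spec = NULL,
                       n_te_families = 40,
                       te_dispersion = 0.1,
                       te_library_size = 1e6,
                       tissue = "leaf",
                       rng_seed = 1L) {
  stopifnot(n_triads >= 1, n_singletons_per_subgenome >= 0,
            n_chromosomes_per_subgenome >= 1,
            baseline_mean > 0, dispersion >= 0,
            mismatch_rate >= 0, mismatch_rate < 1,
            synthetic_bias_shrink >= 0, synthetic_bias_shrink <= 1,
            n_synthetic_genotypes >= 1,
            te_library_size > 0)
  req <- c("diploid_parent", "tetraploid_parent", "synthetic")
  if (!all(req %in% names(replicates)))
    stop("replicates must name: ", paste(req, collapse = ", "))
  if (any(replicates[req] < 1))
    stop("each role needs at least one replicate")
  if (!is.null(bias_spec)) {
    bias_spec <- as.matrix(bias_spec)
    if (nrow(bias_spec) != n_triads || ncol(bias_spec) != 3)
      stop("bias_spec must be an n_triads x 3 matrix")
    if (any(bias_spec < 0) || any(abs(rowSums(bias_spec) - 1) > 1e-8))
      stop("bias_spec rows must be non-negative and sum to 1")
  }
  if (!is.null(aneuploidy_spec) &&
      !all(aneuploidy_spec$copy_ratio %in% c(0.5, 1.5)))
    stop("copy_ratio must be 0.5 or 1.5")
  cfg <- list(n_triads = n_triads,
              n_singletons_per_subgenome = n_singletons_per_subgenome,
              n_chromosomes_per_subgenome = n_chromosomes_per_subgenome,
              replicates = replicates,
              n_synthetic_genotypes = n_synthetic_genotypes,
              baseline_mean = baseline_mean,
              gene_spread_log2_sd = gene_spread_log2_sd,
              dispersion = dispersion,
              library_size = library_size,
              de_spec = de_spec,
              bias_spec = bias_spec,
              bias_alpha = bias_alpha,
              synthetic_bias_shrink = synthetic_bias_shrink,
              mismatch_rate = mismatch_rate,
              aneuploidy_spec = aneuploidy_spec,
              te_spec = te_spec,
              n_te_families = n_te_families,
              te_dispersion = te_dispersion,
              te_library_size = te_library_size,
              tissue = tissue,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

# Cross-assignment of one library: thin each gene's count binomially at
# `rate` and move the thinned reads to its partner features (split evenly
# when two partners exist). Reads are moved, never created or lost.
.inject_mismatch <- function(y, p1, p2, rate) {
  n <- length(y)
  moved <- stats::rbinom(n, y, rate)
  y <- y - moved
  has2 <- !is.na(p1) & !is.na(p2)
  only1 <- !is.na(p1) & is.na(p2)
  to1 <- integer(n)
  to1[has2] <- stats::rbinom(sum(has2), moved[has2], 0.5)
  to1[only1] <- moved[only1]
  to2 <- integer(n)
  to2[has2] <- moved[has2] - to1[has2]
  stay <- moved - to1 - to2  # partnerless features keep their reads
  y <- y + stay
  src1 <- !is.na(p1)
  add1 <- tapply(to1[src1], p1[src1], sum)
  y[as.integer(names(add1))] <- y[as.integer(names(add1))] + add1
  if (any(has2)) {
    add2 <- tapply(to2[has2], p2[has2], sum)
    y[as.integer(names(add2))] <- y[as.integer(names(add2))] + add2
  }
  y
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

.sim_features <- function(config) {
  nt <- config$n_triads
  ns <- config$n_singletons_per_subgenome
  k <- config$n_chromosomes_per_subgenome
  per_chr <- ceiling(nt / k)
  mk <- function(sg, ids, class = "hc_gene") {
    n <- length(ids)
    chr_rank <- seq_len(n) - 1L
    data.frame(
      feature_id = ids,
      feature_class = class,
      subgenome = sg,
      chromosome = paste0(pmin((chr_rank %/% per_chr) + 1L, k), sg),
      order_index = chr_rank %% per_chr,
      stringsAsFactors = FALSE)
  }
  tri_ids <- sprintf("tr%05d", seq_len(nt))
  fe <- do.call(rbind, lapply(c("A", "B", "D"), function(sg)
    mk(sg, paste0("g", sprintf("%05d", seq_len(nt)), "_", sg))))
  triads <- data.frame(triad_id = tri_ids,
                       gene_A = paste0("g", sprintf("%05d", seq_len(nt)), "_A"),
                       gene_B = paste0("g", sprintf("%05d", seq_len(nt)), "_B"),
                       gene_D = paste0("g", sprintf("%05d", seq_len(nt)), "_D"),
                       stringsAsFactors = FALSE)
  if (ns > 0) {
    rot <- c(A = "B", B = "D", D = "A")
    for (sg in c("A", "B", "D")) {
      sing <- mk(sg, sprintf("s%04d_%s", seq_len(ns), sg))
      sing$order_index <- per_chr + seq_len(ns) - 1L  # appended after triad genes
      sing$chromosome <- paste0("1", sg)
      dec <- sing
      dec$feature_id <- sub(paste0("_", sg, "$"),
                            paste0("_", sg, "dec"), sing$feature_id)
      dec$subgenome <- rot[[sg]]
      dec$chromosome <- paste0("1", rot[[sg]])
      dec$order_index <- per_chr + ns + seq_len(ns) - 1L
      fe <- rbind(fe, sing, dec)
    }
  }
  fe$length_bp <- round(stats::rlnorm(nrow(fe), log(1500), 0.35))
  list(features = fe, triads = triads)
}

.sim_samples <- function(config) {
  reps <- config$replicates
  rows <- list()
  add <- function(genotype, role, n, dip = NA, tet = NA) {
    data.frame(sample_id = paste0(genotype, "_r", seq_len(n)),
               genotype_id = genotype, tissue = config$tissue,
               generation = if (role == "synthetic") "C2" else "P",
               role = role, replicate_of = genotype,
               diploid_parent = dip, tetraploid_parent = tet,
               stringsAsFactors = FALSE)
  }
  rows[["dip"]] <- add("tauschii1", "diploid_parent", reps[["diploid_parent"]])
  rows[["tet"]] <- add("durum1", "tetraploid_parent",
                       reps[["tetraploid_parent"]])
  for (g in seq_len(config$n_synthetic_genotypes))
    rows[[paste0("syn", g)]] <- add(paste0("synthetic", g), "synthetic",
                                    reps[["synthetic"]],
                                    dip = "tauschii1", tet = "durum1")
  do.call(rbind, rows)
}

#' Simulate a cross-ploidy RNA-seq experiment
#'
#' Generates NB-distributed gene counts for the parents and synthetic
#' hexaploids described by `config`, injects homoeologous cross-mapping by
#' binomial thinning (reads moved, never created), and returns the raw
#' count table, the triad table and a ground-truth record.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_table()]), `triads`
#'   (triad table) and `truth` (list of `de_truth`, `bias_truth`,
#'   `mismatch_truth`, `aneuploidy_truth`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  fs <- .sim_features(config)
  fe <- fs$features
  triads <- fs$triads
  samples <- .sim_samples(config)
  nt <- config$n_triads
  n_fe <- nrow(fe)

  # Per-triad total expression weight and contribution vectors.
  spread <- if (config$gene_spread_log2_sd > 0)
    2^stats::rnorm(nt, 0, config$gene_spread_log2_sd) else rep(1, nt)
  triad_total <- 3 * config$baseline_mean * spread
  bias <- config$bias_spec
  if (is.null(bias)) bias <- .rdirichlet(nt, rep(config$bias_alpha, 3))
  colnames(bias) <- c("A", "B", "D")

  sing <- grepl("^s", fe$feature_id) & !grepl("dec$", fe$feature_id)
  gene_weights <- function(b) {
    w <- numeric(n_fe)
    names(w) <- fe$feature_id
    w[triads$gene_A] <- triad_total * b[, "A"]
    w[triads$gene_B] <- triad_total * b[, "B"]
    w[triads$gene_D] <- triad_total * b[, "D"]
    w[sing] <- config$baseline_mean
    w
  }
  w <- gene_weights(bias)
  s_shr <- config$synthetic_bias_shrink
  bias_syn <- bias + s_shr * (matrix(1 / 3, nt, 3) - bias)
  w_syn <- if (s_shr > 0) gene_weights(bias_syn) else w

  de <- config$de_spec
  if (!is.null(de)) {
    if (!all(de$feature_id %in% fe$feature_id))
      stop("de_spec references unknown feature(s): ",
           de$feature_id[!de$feature_id %in% fe$feature_id][1])
    if (anyDuplicated(de$feature_id))
      stop("de_spec lists a feature twice")
  }
  lib_size <- config$library_size
  if (is.null(lib_size)) lib_size <- round(sum(w))

  # Partner map for cross-assignment: triad members move reads to the two
  # other members; singletons move to their decoy (and back).
  p1 <- p2 <- rep(NA_integer_, n_fe)
  names(p1) <- names(p2) <- fe$feature_id
  idx <- function(ids) match(ids, fe$feature_id)
  p1[triads$gene_A] <- idx(triads$gene_B); p2[triads$gene_A] <- idx(triads$gene_D)
  p1[triads$gene_B] <- idx(triads$gene_A); p2[triads$gene_B] <- idx(triads$gene_D)
  p1[triads$gene_D] <- idx(triads$gene_A); p2[triads$gene_D] <- idx(triads$gene_B)
  if (config$n_singletons_per_subgenome > 0) {
    sids <- fe$feature_id[sing]
    decs <- sub("_([ABD])$", "_\\1dec", sids)
    p1[sids] <- idx(decs)
    p1[decs] <- idx(sids)
  }

  native_sets <- list(diploid_parent = "D",
                      tetraploid_parent = c("A", "B"),
                      synthetic = c("A", "B", "D"),
                      natural_hexaploid = c("A", "B", "D"))
  counts <- matrix(0, n_fe, nrow(samples),
                   dimnames = list(fe$feature_id, samples$sample_id))
  an <- config$aneuploidy_spec
  for (j in seq_len(nrow(samples))) {
    role <- samples$role[j]
    ws <- if (role %in% c("synthetic", "natural_hexaploid")) w_syn else w
    ws[!fe$subgenome %in% native_sets[[role]]] <- 0
    if (role == "synthetic" && !is.null(de)) {
      m <- match(de$feature_id, fe$feature_id)
      ws[m] <- ws[m] * 2^de$log2fc
    }
    if (!is.null(an)) {
      hit <- an[an$sample_id == samples$sample_id[j], , drop = FALSE]
      for (r in seq_len(nrow(hit))) {
        on_chr <- fe$chromosome == hit$chromosome[r]
        ws[on_chr] <- ws[on_chr] * hit$copy_ratio[r]
      }
    }
    mu <- lib_size * ws / sum(ws)
    y <- if (config$dispersion > 0)
      stats::rnbinom(n_fe, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(n_fe, mu)
    if (config$mismatch_rate > 0)
      y <- .inject_mismatch(y, p1, p2, config$mismatch_rate)
    counts[, j] <- y
  }
  samples$lib_size <- colSums(counts)

  truth <- list(
    de_truth = if (is.null(de))
      data.frame(feature_id = character(), log2fc = numeric()) else de,
    bias_truth = data.frame(triad_id = triads$triad_id, bias,
                            stringsAsFactors = FALSE),
    bias_truth_synthetic = data.frame(triad_id = triads$triad_id, bias_syn,
                                      stringsAsFactors = FALSE),
    mismatch_truth = data.frame(feature_id = fe$feature_id,
                                rate = ifelse(is.na(p1), 0,
                                              config$mismatch_rate)),
    aneuploidy_truth = if (is.null(an))
      data.frame(sample_id = character(), chromosome = character(),
                 copy_ratio = numeric()) else an)
  list(counts = count_table(counts, fe, samples, unit = "counts"),
       triads = triads, truth = truth)
}

#' Simulate TE-family count tables with multimapper smearing
#'
#' Each family's library-level total is NB around its role-specific
#' expected RPM (diploid level, tetraploid level, or midparent value times
#' `2^log2_effect` for synthetics) scaled by the library depth; the total
#' is then smeared multinomially across per-subgenome buckets A/B/D/un
#' with equal weights, emulating random placement of multimapping reads.
#'
#' @param config a [sim_config()]; `te_spec` describes the families.
#' @param smear_weights length-4 non-negative weights for the A/B/D/un
#'   buckets.
#' @return list with `counts` (a [count_table()] of `te_family` features
#'   carrying a `te_family` column) and `truth` (the realized `te_spec`).
#' @export
simulate_te_families <- function(config,
                                 smear_weights = c(1, 1, 1, 1) / 4) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(length(smear_weights) == 4, all(smear_weights >= 0),
            sum(smear_weights) > 0)
  set.seed(config$rng_seed + 1L)
  spec <- config$te_spec
  if (is.null(spec)) {
    nf <- config$n_te_families
    spec <- data.frame(
      family = sprintf("TEfam%03d", seq_len(nf)),
      rpm_diploid = stats::rlnorm(nf, log(200), 1),
      rpm_tetraploid = stats::rlnorm(nf, log(200), 1),
      log2_effect = 0,
      stringsAsFactors = FALSE)
  }
  if (any(spec$rpm_diploid < 0) || any(spec$rpm_tetraploid < 0))
    stop("negative RPM level in te_spec")
  if (nrow(spec) == 0) stop("te_spec is empty")
  samples <- .sim_samples(config)
  lib <- config$te_library_size
  samples$lib_size <- lib
  mpv <- spec$rpm_diploid / 3 + 2 * spec$rpm_tetraploid / 3
  level <- cbind(diploid_parent = spec$rpm_diploid,
                 tetraploid_parent = spec$rpm_tetraploid,
                 synthetic = mpv * 2^spec$log2_effect,
                 natural_hexaploid = mpv)
  buckets <- c("A", "B", "D", "un")
  fe <- data.frame(
    feature_id = paste0(rep(spec$family, each = 4), "|",
                        rep(buckets, nrow(spec))),
    feature_class = "te_family",
    subgenome = rep(buckets, nrow(spec)),
    chromosome = "chrTE",
    order_index = seq_len(4 * nrow(spec)) - 1L,
    length_bp = NA_real_,
    te_family = rep(spec$family, each = 4),
    stringsAsFactors = FALSE)
  counts <- matrix(0, nrow(fe), nrow(samples),
                   dimnames = list(fe$feature_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- level[, samples$role[j]] * lib / 1e6
    tot <- if (config$te_dispersion > 0)
      stats::rnbinom(nrow(spec), mu = mu, size = 1 / config$te_dispersion)
    else stats::rpois(nrow(spec), mu)
    for (f in seq_len(nrow(spec))) {
      sm <- stats::rmultinom(1, tot[f], smear_weights)[, 1]
      counts[(f - 1) * 4 + 1:4, j] <- sm
    }
  }
  list(counts = count_table(counts, fe, samples, unit = "counts"),
       truth = list(te_truth = spec))
}
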