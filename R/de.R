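#' Build genotype-consistent split-normalization groups
#'
#' Cross-ploidy comparisons are only meaningful within a subgenome set the
#' two sides share, so the hexaploid transcriptomes are split into their
#' AB and D parts and each part is normalized together with the matching
#' parent: one group per (diploid parent genotype) holding the D parts of
#' its synthetics plus the diploid parent's libraries, and one group per
#' (tetraploid parent genotype) holding the AB parts plus the tetraploid
#' parent. Library sizes are the partition column totals; TMM factors are
#' computed within each group and features with zero counts across all
#' group members are then removed.
#'
#' @param synthetic a [count_table()] of synthetic (or natural hexaploid)
#'   samples over the full gene set; its sample sheet must carry
#'   `diploid_parent` and `tetraploid_parent` genotype columns.
#' @param diploid,tetraploid parental [count_table()]s (normally the
#'   output of [correct_subgenome_mismatch()]).
#' @param config a [pipeline_config()].
#' @return list of `norm_group` objects with elements `partition` ("AB" or
#'   "D"), `parent_genotype`, `counts`, `features`, `samples`, `lib_size`,
#'   `tmm` and `eff_lib_size`.
#' @export
build_normalization_groups <- function(synthetic, diploid, tetraploid,
                                       config = pipeline_config()) {
  stopifnot(inherits(synthetic, "count_table"))
  sa <- synthetic$samples
  if (is.null(sa$diploid_parent) || is.null(sa$tetraploid_parent) ||
      anyNA(sa$diploid_parent) || anyNA(sa$tetraploid_parent))
    stop("synthetic sample sheet must name diploid_parent and ",
         "tetraploid_parent genotypes")
  parts <- split_by_subgenome(synthetic)
  dip_parts <- split_by_subgenome(diploid)
  tet_parts <- split_by_subgenome(tetraploid)

  build <- function(partition, parent_part, parent_col, parent_genotype) {
    syn_part <- parts[[partition]]
    keep_syn <- syn_part$samples[[parent_col]] == parent_genotype
    if (!any(keep_syn)) return(NULL)
    keep_par <- parent_part$samples$genotype_id == parent_genotype
    if (!any(keep_par))
      stop("parent genotype '", parent_genotype,
           "' absent from the parental table")
    stopifnot(identical(parent_part$features$feature_id,
                        syn_part$features$feature_id))
    counts <- cbind(parent_part$counts[, keep_par, drop = FALSE],
                    syn_part$counts[, keep_syn, drop = FALSE])
    samples <- rbind(
      parent_part$samples[keep_par,
                          c("sample_id", "genotype_id", "tissue",
                            "generation", "role", "replicate_of")],
      syn_part$samples[keep_syn,
                       c("sample_id", "genotype_id", "tissue",
                         "generation", "role", "replicate_of")])
    lib_size <- colSums(counts)
    tmm <- tmm_factors(counts, lib_size = lib_size)
    keep_fe <- rowSums(counts) > 0
    g <- list(partition = partition,
              parent_genotype = parent_genotype,
              counts = counts[keep_fe, , drop = FALSE],
              features = parent_part$features[keep_fe, , drop = FALSE],
              samples = samples,
              lib_size = lib_size,
              tmm = tmm,
              eff_lib_size = lib_size * tmm)
    class(g) <- "norm_group"
    g
  }

  groups <- list()
  for (pg in unique(sa$diploid_parent)) {
    g <- build("D", dip_parts$D, "diploid_parent", pg)
    if (!is.null(g)) groups[[paste0("D.", pg)]] <- g
  }
  for (pg in unique(sa$tetraploid_parent)) {
    g <- build("AB", tet_parts$AB, "tetraploid_parent", pg)
    if (!is.null(g)) groups[[paste0("AB.", pg)]] <- g
  }
  groups
}

#' @export
print.norm_group <- function(x, ...) {
  cat(sprintf("norm_group %s / parent %s: %d features, %d libraries\n",
              x$partition, x$parent_genotype, nrow(x$counts),
              ncol(x$counts)))
  invisible(x)
}

#' NB likelihood-ratio test of synthetic vs parent within a group
#'
#' Fits per-feature NB means for the parent and synthetic libraries with
#' offsets equal to the log effective library sizes, tests equality of
#' means by likelihood ratio against a chi-square with one degree of
#' freedom, adjusts p-values by Benjamini-Hochberg over all tested
#' features in the group, and applies the significance rule
#' FDR < `fdr_max` and |log2 FC| > `min_abs_log2fc`.
#'
#' @param group a `norm_group` from [build_normalization_groups()].
#' @param synthetic_genotype restrict the synthetic side to one genotype
#'   (`NULL` uses all synthetic libraries in the group).
#' @param dispersion per-feature dispersions; estimated via
#'   [estimate_dispersion()] when `NULL`.
#' @param config a [pipeline_config()].
#' @return data.frame with `feature_id`, `subgenome`, `log2fc`
#'   (synthetic minus parent), `pvalue`, `fdr`, `significant`,
#'   `direction`.
#' @export
de_test <- function(group, synthetic_genotype = NULL, dispersion = NULL,
                    config = pipeline_config()) {
  stopifnot(inherits(group, "norm_group"))
  is_par <- group$samples$role %in% c("diploid_parent", "tetraploid_parent")
  is_syn <- !is_par
  if (!is.null(synthetic_genotype))
    is_syn <- is_syn & group$samples$genotype_id == synthetic_genotype
  if (!any(is_par) || !any(is_syn))
    stop("contrast needs at least one library on each side")
  keep <- is_par | is_syn
  y <- group$counts[, keep, drop = FALSE]
  off <- log(group$eff_lib_size[keep])
  cond <- ifelse(is_par[keep], "parent", "synthetic")
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(y, cond, group$eff_lib_size[keep],
                                      prior_df = config$dispersion_prior_df)
  res <- .nb_lrt(y, which(cond == "parent"), which(cond == "synthetic"),
                 off, dispersion)
  out <- data.frame(feature_id = group$features$feature_id,
                    subgenome = group$features$subgenome,
                    log2fc = res$log2fc,
                    pvalue = res$pvalue,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr < config$fdr_max &
    abs(out$log2fc) > config$min_abs_log2fc
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}

#' Tally significant DEGs by subgenome and direction
#'
#' @param de a DE result data.frame from [de_test()].
#' @return data.frame with per-subgenome counts of up- and down-regulated
#'   significant genes.
#' @export
classify_degs <- function(de) {
  sg <- sort(unique(de$subgenome))
  data.frame(
    subgenome = sg,
    n_up = vapply(sg, function(s)
      sum(de$subgenome == s & de$direction == "up"), integer(1)),
    n_down = vapply(sg, function(s)
      sum(de$subgenome == s & de$direction == "down"), integer(1)),
    n_tested = vapply(sg, function(s) sum(de$subgenome == s), integer(1)),
    row.names = NULL)
}

#' Whole-library cross-ploidy DE (the comparison the split design avoids)
#'
#' Benchmarks the naive inter-ploidy analysis: parent and hexaploid
#' libraries normalized jointly by their full library depths, with no
#' regard for the different transcriptome sizes, then tested feature by
#' feature with the same NB machinery. Because a given gene is a larger
#' fraction of the smaller parental transcriptome, this comparison
#' manufactures fold changes around the ploidy ratio for every shared
#' gene; it exists to quantify that artefact against the split
#' normalization.
#'
#' @param parent,synthetic [count_table()]s (full libraries).
#' @param config a [pipeline_config()].
#' @return a DE result data.frame as from [de_test()], restricted to gene
#'   features detected (non-zero in at least one library) on both sides.
#' @export
de_whole_library <- function(parent, synthetic,
                             config = pipeline_config()) {
  stopifnot(identical(parent$features$feature_id,
                      synthetic$features$feature_id))
  gene <- .is_gene(parent$features)
  expressed <- rowSums(parent$counts) > 0 & rowSums(synthetic$counts) > 0
  keep <- gene & expressed
  y <- cbind(parent$counts[keep, , drop = FALSE],
             synthetic$counts[keep, , drop = FALSE])
  lib <- c(colSums(parent$counts), colSums(synthetic$counts))
  cond <- c(rep("parent", ncol(parent$counts)),
            rep("synthetic", ncol(synthetic$counts)))
  phi <- estimate_dispersion(y, cond, lib,
                             prior_df = config$dispersion_prior_df)
  res <- .nb_lrt(y, which(cond == "parent"), which(cond == "synthetic"),
                 log(lib), phi)
  out <- data.frame(feature_id = parent$features$feature_id[keep],
                    subgenome = parent$features$subgenome[keep],
                    log2fc = res$log2fc,
                    pvalue = res$pvalue,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr < config$fdr_max &
    abs(out$log2fc) > config$min_abs_log2fc
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}

#' Per-family TE RPM totals
#'
#' Sums a family's A/B/D/unassigned bucket counts per library and converts
#' to RPM against the library's total mapped reads.
#'
#' @param x a [count_table()] of `te_family` features (with a `te_family`
#'   annotation column).
#' @param lib_size total mapped reads per library; defaults to
#'   `samples$lib_size`, falling back to column totals.
#' @return family x library matrix of RPM totals.
#' @export
te_family_rpm <- function(x, lib_size = NULL) {
  stopifnot(inherits(x, "count_table"))
  te <- x$features$feature_class == "te_family"
  if (!any(te)) stop("no te_family features in the table")
  if (is.null(x$features$te_family))
    stop("te_family column missing from the feature annotation")
  if (is.null(lib_size)) lib_size <- x$samples$lib_size
  if (is.null(lib_size)) lib_size <- colSums(x$counts)
  fam <- x$features$te_family[te]
  totals <- rowsum(x$counts[te, , drop = FALSE], fam)
  sweep(totals, 2, lib_size / 1e6, "/")
}

#' Midparent-value pseudo-libraries for TE families
#'
#' One pseudo-library per (diploid replicate, tetraploid replicate) pair:
#' MPV = 1/3 RPM(diploid) + 2/3 RPM(tetraploid) per family, the expected
#' transcription level under purely additive inheritance.
#'
#' @param diploid_rpm,tetraploid_rpm family x replicate RPM matrices (from
#'   [te_family_rpm()] after [redistribute_parent_te_counts()] or raw
#'   bucket sums; families must match).
#' @return family x pair matrix of MPV RPMs; the replicate pairing is
#'   recorded in `attr(, "provenance")`.
#' @export
build_mpv_libraries <- function(diploid_rpm, tetraploid_rpm) {
  diploid_rpm <- as.matrix(diploid_rpm)
  tetraploid_rpm <- as.matrix(tetraploid_rpm)
  if (!ncol(diploid_rpm) || !ncol(tetraploid_rpm))
    stop("each parent needs at least one replicate")
  if (!identical(rownames(diploid_rpm), rownames(tetraploid_rpm)))
    stop("family sets of the two parents differ")
  pairs <- expand.grid(d = seq_len(ncol(diploid_rpm)),
                       t = seq_len(ncol(tetraploid_rpm)))
  mpv <- vapply(seq_len(nrow(pairs)), function(i)
    diploid_rpm[, pairs$d[i]] / 3 + 2 * tetraploid_rpm[, pairs$t[i]] / 3,
    numeric(nrow(diploid_rpm)))
  mpv <- matrix(mpv, nrow = nrow(diploid_rpm),
                dimnames = list(rownames(diploid_rpm),
                                paste0("MPV_",
                                       colnames(diploid_rpm)[pairs$d], "_",
                                       colnames(tetraploid_rpm)[pairs$t])))
  attr(mpv, "provenance") <- data.frame(
    diploid_replicate = colnames(diploid_rpm)[pairs$d],
    tetraploid_replicate = colnames(tetraploid_rpm)[pairs$t])
  mpv
}

#' Test TE families for departure from the midparent value
#'
#' Applies the NB testing machinery to the synthetic per-family RPM totals
#' against the MPV pseudo-libraries: values are rounded half-to-even and
#' treated as counts at equal depth (offset zero), dispersions estimated
#' from the two sides, LRT p-values BH-adjusted over families, and the
#' FDR/fold-change thresholds applied.
#'
#' @param synthetic_rpm family x replicate matrix of synthetic RPM totals.
#' @param mpv MPV matrix from [build_mpv_libraries()].
#' @param config a [pipeline_config()].
#' @return DE result data.frame (one row per family; `log2fc` is
#'   synthetic minus MPV).
#' @export
te_mpv_de <- function(synthetic_rpm, mpv, config = pipeline_config()) {
  synthetic_rpm <- as.matrix(synthetic_rpm)
  mpv <- as.matrix(mpv)
  if (ncol(mpv) < 2 || ncol(synthetic_rpm) < 2)
    stop("need at least two MPV pseudo-libraries and two synthetic ",
         "replicates")
  shared <- intersect(rownames(synthetic_rpm), rownames(mpv))
  missing <- setdiff(union(rownames(synthetic_rpm), rownames(mpv)), shared)
  if (length(missing))
    warning("excluding ", length(missing),
            " family(ies) absent on one side")
  y <- cbind(round(mpv[shared, , drop = FALSE]),
             round(synthetic_rpm[shared, , drop = FALSE]))
  cond <- c(rep("mpv", ncol(mpv)), rep("synthetic", ncol(synthetic_rpm)))
  off <- rep(0, ncol(y))
  phi <- estimate_dispersion(y, cond, rep(1, ncol(y)),
                             prior_df = config$dispersion_prior_df)
  res <- .nb_lrt(y, which(cond == "mpv"), which(cond == "synthetic"),
                 off, phi)
  out <- data.frame(feature_id = shared,
                    subgenome = "un",
                    log2fc = res$log2fc,
                    pvalue = res$pvalue,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr < config$fdr_max &
    abs(out$log2fc) > config$min_abs_log2fc
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}
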