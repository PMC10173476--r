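#' Convert raw counts to RPM or TPM
#'
#' RPM divides each column by its total and scales to one million; TPM
#' first divides by feature length in kb, then scales each column to sum
#' to one million.
#'
#' @param x a [count_table()] with `unit = "counts"`.
#' @param kind `"rpm"` or `"tpm"`; TPM requires `length_bp` for every
#'   included feature.
#' @return a [count_table()] in the requested unit. The original library
#'   depths are kept in `samples$lib_size`.
#' @export
normalize_expression <- function(x, kind = c("rpm", "tpm")) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "count_table"))
  if (x$unit != "counts")
    stop("normalize_expression expects unit = 'counts', got '", x$unit, "'")
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop("zero column total for sample '",
         x$samples$sample_id[which(tot == 0)[1]], "'")
  samples <- x$samples
  if (is.null(samples$lib_size)) samples$lib_size <- tot
  if (kind == "rpm") {
    vals <- sweep(x$counts, 2, tot / 1e6, "/")
  } else {
    if (anyNA(x$features$length_bp))
      stop("length_bp missing for feature '",
           x$features$feature_id[which(is.na(x$features$length_bp))[1]],
           "'; required for TPM")
    rate <- x$counts / (x$features$length_bp / 1000)
    vals <- sweep(rate, 2, colSums(rate) / 1e6, "/")
  }
  count_table(vals, x$features, samples, unit = kind,
              corrected = x$corrected)
}

.is_gene <- function(features) features$feature_class %in% c("hc_gene", "lc_gene")

#' Correct subgenome mismatches between the parental count tables
#'
#' Reads of one parent that map to homoeologous features on the other
#' parent's subgenomes ("subgenome mismatches") inflate apparent
#' expression differences against the synthetic hexaploid, whose libraries
#' contain such cross-mapped reads from all three subgenomes. The
#' correction converts each parent's mismatch counts to RPM, scales them
#' by the subgenome share of the hexaploid transcriptome (1/3 for the
#' diploid, 2/3 for the tetraploid), averages across that parent's
#' replicates, and adds the averages -- converted to each recipient
#' library's own count scale -- to every library of the other parent.
#' Native counts are untouched; outputs may be fractional and carry
#' `corrected = TRUE`, which blocks re-application.
#'
#' @param diploid,tetraploid [count_table()]s of the two parents (all
#'   samples `diploid_parent` / `tetraploid_parent` respectively), mapped
#'   against the same full feature set.
#' @param config a [pipeline_config()] supplying `diploid_scale` and
#'   `tetraploid_scale`.
#' @return list with corrected `diploid` and `tetraploid` tables.
#' @export
correct_subgenome_mismatch <- function(diploid, tetraploid,
                                       config = pipeline_config()) {
  stopifnot(inherits(diploid, "count_table"),
            inherits(tetraploid, "count_table"))
  if (diploid$corrected || tetraploid$corrected)
    stop("subgenome-mismatch correction has already been applied")
  if (diploid$unit != "counts" || tetraploid$unit != "counts")
    stop("correction operates on raw counts")
  if (!all(diploid$samples$role == "diploid_parent"))
    stop("all samples of 'diploid' must have role diploid_parent")
  if (!all(tetraploid$samples$role == "tetraploid_parent"))
    stop("all samples of 'tetraploid' must have role tetraploid_parent")
  if (ncol(diploid$counts) < 1 || ncol(tetraploid$counts) < 1)
    stop("each parent needs at least one replicate")
  if (!identical(diploid$features$feature_id, tetraploid$features$feature_id))
    stop("the two parent tables must share the same feature set")

  fe <- diploid$features
  mism_in_dip <- .is_gene(fe) & fe$subgenome %in% c("A", "B")
  mism_in_tet <- .is_gene(fe) & fe$subgenome == "D"

  transfer <- function(src, mism, scale) {
    tot <- colSums(src$counts)
    rpm <- sweep(src$counts[mism, , drop = FALSE], 2, tot / 1e6, "/")
    rowMeans(rpm * scale)
  }
  from_dip <- transfer(diploid, mism_in_dip, config$diploid_scale)
  from_tet <- transfer(tetraploid, mism_in_tet, config$tetraploid_scale)

  dip_counts <- diploid$counts
  tet_counts <- tetraploid$counts
  tet_tot <- colSums(tet_counts)
  for (j in seq_along(tet_tot))
    tet_counts[mism_in_dip, j] <- tet_counts[mism_in_dip, j] +
      from_dip * tet_tot[j] / 1e6
  dip_tot <- colSums(dip_counts)
  for (j in seq_along(dip_tot))
    dip_counts[mism_in_tet, j] <- dip_counts[mism_in_tet, j] +
      from_tet * dip_tot[j] / 1e6

  list(diploid = count_table(dip_counts, diploid$features, diploid$samples,
                             unit = "counts", corrected = TRUE),
       tetraploid = count_table(tet_counts, tetraploid$features,
                                tetraploid$samples,
                                unit = "counts", corrected = TRUE))
}

#' Redistribute parental TE counts to the native subgenome buckets
#'
#' TE-family reads are multimappers smeared across per-subgenome buckets
#' regardless of origin. In a parent, all of a family's reads necessarily
#' originate from its native subgenome(s), so the buckets are collapsed:
#' for the diploid, A-, B- and unassigned counts are added to the D
#' bucket; for the tetraploid, the D and unassigned counts are split
#' equally between A and B. Family totals are conserved per library.
#'
#' @param x a [count_table()] whose samples are all `diploid_parent` or
#'   all `tetraploid_parent`, containing `te_family` features with a
#'   `te_family` column.
#' @return the table with redistributed TE counts.
#' @export
redistribute_parent_te_counts <- function(x) {
  stopifnot(inherits(x, "count_table"))
  role <- unique(x$samples$role)
  if (length(role) != 1 ||
      !role %in% c("diploid_parent", "tetraploid_parent"))
    stop("TE redistribution applies to parental samples only")
  te <- which(x$features$feature_class == "te_family")
  if (!length(te)) return(x)
  if (is.null(x$features$te_family))
    stop("te_family column missing from the feature annotation")
  counts <- x$counts
  fam <- x$features$te_family[te]
  sg <- x$features$subgenome[te]
  for (f in unique(fam)) {
    rows <- te[fam == f]
    rsg <- sg[fam == f]
    pick <- function(s) rows[rsg == s]
    a <- pick("A"); b <- pick("B"); d <- pick("D"); un <- pick("un")
    if (role == "diploid_parent") {
      if (!length(d))
        stop("family '", f, "' lacks a D bucket")
      counts[d, ] <- counts[d, ] + colSums(counts[c(a, b, un), , drop = FALSE])
      counts[c(a, b, un), ] <- 0
    } else {
      if (!length(a) || !length(b))
        stop("family '", f, "' lacks an A or B bucket")
      half <- colSums(counts[c(d, un), , drop = FALSE]) / 2
      counts[a, ] <- counts[a, ] + matrix(half, length(a), ncol(counts),
                                          byrow = TRUE) / length(a)
      counts[b, ] <- counts[b, ] + matrix(half, length(b), ncol(counts),
                                          byrow = TRUE) / length(b)
      counts[c(d, un), ] <- 0
    }
  }
  count_table(counts, x$features, x$samples, unit = x$unit,
              corrected = x$corrected)
}

#' Split a table into its AB and D subgenome parts
#'
#' Partitions the gene features (high- and low-confidence) into an AB
#' table and a D table; unassigned-subgenome genes and TE features are
#' excluded. The partition column totals recorded in `samples$lib_size`
#' become the library sizes used by the split normalization.
#'
#' @param x a [count_table()].
#' @return list with [count_table()]s `AB` and `D`.
#' @export
split_by_subgenome <- function(x) {
  stopifnot(inherits(x, "count_table"))
  gene <- .is_gene(x$features)
  dropped <- sum(gene & x$features$subgenome == "un") +
    sum(!gene)
  if (dropped > 0)
    .log_stage("split", dropped,
               " feature(s) excluded from the subgenome partitions",
               " (unassigned or TE)")
  part <- function(sgs) {
    keep <- gene & x$features$subgenome %in% sgs
    sa <- x$samples
    sa$lib_size <- colSums(x$counts[keep, , drop = FALSE])
    count_table(x$counts[keep, , drop = FALSE],
                x$features[keep, , drop = FALSE], sa,
                unit = x$unit, corrected = x$corrected)
  }
  list(AB = part(c("A", "B")), D = part("D"))
}

#' Combine the parental transcriptomes in silico
#'
#' Builds the expected hexaploid expression under pure parental legacy:
#' per feature, 0.33 times the replicate-averaged diploid RPM plus 0.67
#' times the replicate-averaged tetraploid RPM, as one pseudo-sample.
#'
#' @param diploid_rpm,tetraploid_rpm [count_table()]s with `unit = "rpm"`
#'   over the same feature universe.
#' @param config a [pipeline_config()] supplying the weights.
#' @return a one-sample [count_table()] (`role = "in_silico_parent"`).
#' @export
combine_parents_in_silico <- function(diploid_rpm, tetraploid_rpm,
                                      config = pipeline_config()) {
  stopifnot(inherits(diploid_rpm, "count_table"),
            inherits(tetraploid_rpm, "count_table"))
  if (diploid_rpm$unit != "rpm" || tetraploid_rpm$unit != "rpm")
    stop("combine_parents_in_silico expects RPM tables")
  if (!identical(diploid_rpm$features$feature_id,
                 tetraploid_rpm$features$feature_id))
    stop("the two parent tables must share the same feature set")
  comb <- config$insilico_diploid_weight * rowMeans(diploid_rpm$counts) +
    config$insilico_tetraploid_weight * rowMeans(tetraploid_rpm$counts)
  samples <- data.frame(
    sample_id = "in_silico_parent",
    genotype_id = paste0(diploid_rpm$samples$genotype_id[1], "x",
                         tetraploid_rpm$samples$genotype_id[1]),
    tissue = diploid_rpm$samples$tissue[1],
    generation = "P",
    role = "in_silico_parent",
    replicate_of = "in_silico_parent",
    stringsAsFactors = FALSE)
  count_table(matrix(comb, ncol = 1,
                     dimnames = list(diploid_rpm$features$feature_id,
                                     "in_silico_parent")),
              diploid_rpm$features, samples, unit = "rpm")
}
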