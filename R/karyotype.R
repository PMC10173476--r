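#' Replicate-averaged parental reference TPM for karyotyping
#'
#' Builds the euploid reference expression profile: for D genes the mean
#' TPM across diploid-parent replicates, for A and B genes the mean across
#' tetraploid-parent replicates.
#'
#' @param tpm a [count_table()] with `unit = "tpm"` containing parental
#'   samples.
#' @return named numeric vector over the gene features.
#' @export
parental_reference_tpm <- function(tpm) {
  stopifnot(inherits(tpm, "count_table"), tpm$unit == "tpm")
  dip <- tpm$samples$role == "diploid_parent"
  tet <- tpm$samples$role == "tetraploid_parent"
  if (!any(dip) || !any(tet))
    stop("reference needs both parental roles in the table")
  ref <- numeric(nrow(tpm$counts))
  names(ref) <- tpm$features$feature_id
  is_d <- tpm$features$subgenome == "D"
  is_ab <- tpm$features$subgenome %in% c("A", "B")
  ref[is_d] <- rowMeans(tpm$counts[is_d, dip, drop = FALSE])
  ref[is_ab] <- rowMeans(tpm$counts[is_ab, tet, drop = FALSE])
  ref
}

#' Windowed expression ratios along the chromosomes
#'
#' The in-silico karyotype: genes passing the expression filter
#' (TPM > `tpm_floor` in at least `min_samples_expressed` samples of the
#' analysis set) are sorted by chromosome and position rank and cut into
#' consecutive non-overlapping windows of `window_size` genes (a final
#' partial window is kept when it holds at least half a window). Per
#' window, the ratio of the sample's median TPM to the reference median is
#' computed; raw ratios are then rescaled by the median raw ratio within
#' the sample's subgenome partition (AB or D) so that the typical euploid
#' window sits at one, restoring the ~1 / ~0.5 / ~1.5
#' euploid/monosomy/trisomy expectations despite the different
#' transcriptome sizes of the ploidies.
#'
#' @param tpm a [count_table()] with `unit = "tpm"` holding the analysis
#'   set (the sample of interest plus the samples used for the filter and
#'   reference).
#' @param sample_id the sample to profile.
#' @param reference named reference TPM vector; defaults to
#'   [parental_reference_tpm()].
#' @param config a [pipeline_config()].
#' @return data.frame with `chromosome`, `window_index`, `n_genes`,
#'   `subgenome`, `raw_ratio`, `ratio`.
#' @export
karyotype_ratios <- function(tpm, sample_id, reference = NULL,
                             config = pipeline_config()) {
  stopifnot(inherits(tpm, "count_table"), tpm$unit == "tpm")
  if (!sample_id %in% tpm$samples$sample_id)
    stop("unknown sample '", sample_id, "'")
  if (is.null(reference)) reference <- parental_reference_tpm(tpm)
  gene <- .is_gene(tpm$features) & tpm$features$subgenome %in% c("A", "B", "D")
  expressed <- rowSums(tpm$counts > config$tpm_floor) >=
    config$min_samples_expressed
  keep <- which(gene & expressed)
  fe <- tpm$features[keep, , drop = FALSE]
  sval <- tpm$counts[keep, sample_id]
  rval <- reference[fe$feature_id]
  ord <- order(fe$chromosome, fe$order_index)
  fe <- fe[ord, ]; sval <- sval[ord]; rval <- rval[ord]

  ws <- config$window_size
  rows <- list()
  for (chr in unique(fe$chromosome)) {
    on <- which(fe$chromosome == chr)
    n <- length(on)
    n_full <- n %/% ws
    rem <- n - n_full * ws
    nw <- n_full + (rem >= ws / 2)
    if (nw == 0) next
    for (wdx in seq_len(nw)) {
      lo <- (wdx - 1) * ws + 1
      hi <- min(wdx * ws, n)
      idx <- on[lo:hi]
      r_med <- median(rval[idx])
      if (r_med == 0) {
        warning("reference median is zero in window ", wdx,
                " of chromosome ", chr, "; window dropped")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = chr, window_index = wdx, n_genes = length(idx),
        subgenome = fe$subgenome[idx[1]],
        raw_ratio = median(sval[idx]) / r_med,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no windows could be formed")
  part <- ifelse(out$subgenome == "D", "D", "AB")
  scale <- tapply(out$raw_ratio, part, median)
  out$ratio <- out$raw_ratio / scale[part]
  rownames(out) <- NULL
  out
}

#' Flag aneuploidy candidates from windowed ratios
#'
#' A chromosome is a monosomy candidate when its median rescaled window
#' ratio falls in `mono_band`, a trisomy candidate in `tri_band`, and
#' euploid otherwise.
#'
#' @param windows output of [karyotype_ratios()].
#' @param config a [pipeline_config()].
#' @return data.frame with `chromosome`, `median_ratio`, `flag`.
#' @export
flag_aneuploidy <- function(windows, config = pipeline_config()) {
  chr <- unique(windows$chromosome)
  med <- vapply(chr, function(c)
    median(windows$ratio[windows$chromosome == c]), numeric(1))
  flag <- rep("euploid", length(chr))
  flag[med >= config$mono_band[1] & med <= config$mono_band[2]] <-
    "monosomy_candidate"
  flag[med >= config$tri_band[1] & med <= config$tri_band[2]] <-
    "trisomy_candidate"
  data.frame(chromosome = chr, median_ratio = unname(med), flag = flag,
             stringsAsFactors = FALSE)
}

#' Pairwise sample correlation with UPGMA ordering
#'
#' Pearson correlation of log(RPM + 0.001) between all sample pairs,
#' clustered with UPGMA (average linkage on 1 - r distances).
#'
#' @param rpm a [count_table()] with `unit = "rpm"` and at least two
#'   samples.
#' @param pseudo pseudo-count added before the log transform.
#' @return list with `correlation` (matrix), `tree` (hclust) and `order`
#'   (leaf order of sample ids).
#' @export
sample_correlation <- function(rpm, pseudo = 0.001) {
  stopifnot(inherits(rpm, "count_table"))
  if (ncol(rpm$counts) < 2) stop("need at least two samples")
  lt <- log(rpm$counts + pseudo)
  sds <- apply(lt, 2, sd)
  if (any(sds == 0))
    stop("sample '", colnames(lt)[which(sds == 0)[1]],
         "' is constant after the log transform")
  cc <- cor(lt)
  tree <- hclust(as.dist(1 - cc), method = "average")
  list(correlation = cc, tree = tree,
       order = colnames(cc)[tree$order])
}

#' PCA overview of the samples
#'
#' Centered principal component analysis of the samples in expression
#' space, components ordered by explained variance, with the sign of each
#' component fixed so its largest-magnitude loading is positive.
#'
#' @param rpm a [count_table()] with at least three samples.
#' @param n_components number of components to return scores for.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (proportions, full vector) and `loadings`.
#' @export
pca_overview <- function(rpm, n_components = 2) {
  stopifnot(inherits(rpm, "count_table"))
  if (ncol(rpm$counts) < 3) stop("PCA needs at least three samples")
  p <- prcomp(t(rpm$counts), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  for (i in seq_len(k)) {
    j <- which.max(abs(p$rotation[, i]))
    if (p$rotation[j, i] < 0) {
      p$rotation[, i] <- -p$rotation[, i]
      p$x[, i] <- -p$x[, i]
    }
  }
  ev <- p$sdev^2
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained_variance = if (sum(ev) > 0) ev / sum(ev) else ev,
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}
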