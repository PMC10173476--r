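#' Analysis parameters with the study defaults
#'
#' Central parameter object for the whole pipeline. Defaults follow the
#' wheat cross-ploidy study design: parental RPM scaling by transcriptome
#' share (1/3 diploid, 2/3 tetraploid), DEG thresholds FDR < 0.01 and
#' fold change > 3 (|log2 FC| > 1.585), the 5 RPM triad filter with
#' biased-homoeolog cut-offs 1/6 and 2/3 and the 0.3 eigen-distance
#' movement cut-off, and karyotype windows of 200 position-ordered genes
#' with the TPM > 0.01 in >= 2 samples expression filter.
#'
#' @param diploid_scale,tetraploid_scale scaling applied to parental
#'   mismatch RPMs before transfer (transcriptome share of the subgenomes).
#' @param insilico_diploid_weight,insilico_tetraploid_weight weights of the
#'   in-silico parental combination of replicate-averaged RPMs.
#' @param fdr_max BH-adjusted FDR threshold for significance.
#' @param min_fold_change fold-change threshold (kept for reporting).
#' @param min_abs_log2fc log2 fold-change threshold actually applied.
#' @param min_triad_rpm triads with replicate-mean total RPM below this are
#'   removed.
#' @param biased_low,biased_high contribution cut-offs defining suppressed
#'   (< 1/6) and dominant (> 2/3) homoeologs.
#' @param movement_cutoff eigen-distance above which a category-changing
#'   triad movement is reported.
#' @param window_size number of position-ordered genes per karyotype
#'   window.
#' @param tpm_floor,min_samples_expressed expression filter: genes with
#'   TPM > `tpm_floor` in fewer than `min_samples_expressed` samples are
#'   removed before windowing.
#' @param mono_band,tri_band numeric length-2 ranges of median window
#'   ratios flagged as monosomy/trisomy candidates.
#' @param dispersion_prior_df prior degrees of freedom for shrinking
#'   per-feature dispersions toward the common dispersion.
#' @param rng_seed optional integer seed recorded with results.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(diploid_scale = 1 / 3,
                            tetraploid_scale = 2 / 3,
                            insilico_diploid_weight = 0.33,
                            insilico_tetraploid_weight = 0.67,
                            fdr_max = 0.01,
                            min_fold_change = 3,
                            min_abs_log2fc = 1.585,
                            min_triad_rpm = 5,
                            biased_low = 1 / 6,
                            biased_high = 2 / 3,
                            movement_cutoff = 0.3,
                            window_size = 200,
                            tpm_floor = 0.01,
                            min_samples_expressed = 2,
                            mono_band = c(0.35, 0.65),
                            tri_band = c(1.35, 1.65),
                            dispersion_prior_df = 10,
                            rng_seed = NULL) {
  cfg <- list(diploid_scale = diploid_scale,
              tetraploid_scale = tetraploid_scale,
              insilico_diploid_weight = insilico_diploid_weight,
              insilico_tetraploid_weight = insilico_tetraploid_weight,
              fdr_max = fdr_max,
              min_fold_change = min_fold_change,
              min_abs_log2fc = min_abs_log2fc,
              min_triad_rpm = min_triad_rpm,
              biased_low = biased_low,
              biased_high = biased_high,
              movement_cutoff = movement_cutoff,
              window_size = window_size,
              tpm_floor = tpm_floor,
              min_samples_expressed = min_samples_expressed,
              mono_band = mono_band,
              tri_band = tri_band,
              dispersion_prior_df = dispersion_prior_df,
              rng_seed = rng_seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config` to validate.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$biased_low > 0, cfg$biased_low < cfg$biased_high,
    cfg$biased_high < 1,
    cfg$window_size >= 1,
    cfg$diploid_scale > 0, cfg$diploid_scale <= 1,
    cfg$tetraploid_scale > 0, cfg$tetraploid_scale <= 1,
    cfg$insilico_diploid_weight > 0, cfg$insilico_diploid_weight <= 1,
    cfg$insilico_tetraploid_weight > 0, cfg$insilico_tetraploid_weight <= 1,
    cfg$fdr_max > 0, cfg$fdr_max <= 1,
    cfg$min_triad_rpm >= 0,
    length(cfg$mono_band) == 2, length(cfg$tri_band) == 2,
    cfg$dispersion_prior_df >= 0)
  invisible(cfg)
}

#' Read a pipeline_config from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys raise a
#' configuration error.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
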