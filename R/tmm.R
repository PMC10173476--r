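#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-library TMM normalization factors against a reference
#' library, following the published recipe: per-gene log2 ratios (M) and
#' average log2 intensities (A) between each library and the reference,
#' double trimming (30% of the M distribution, 5% of the A distribution on
#' each side), inverse-asymptotic-variance weighting of the surviving M
#' values, and rescaling so the factors have geometric mean one. The
#' reference is the library whose 75th expression percentile is closest to
#' the mean 75th percentile.
#'
#' @param x a [count_table()] or a numeric matrix of counts.
#' @param lib_size library sizes (defaults to column totals).
#' @param logratio_trim,sum_trim trim fractions for M and A.
#' @param do_weighting use precision weights (default) or a plain trimmed
#'   mean.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(x, lib_size = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05, do_weighting = TRUE) {
  counts <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2)
    stop("TMM needs at least two libraries")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0))
    stop("non-positive library size for sample '",
         colnames(counts)[which(lib_size <= 0)[1]], "'")
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j] / lib_size[j], 0.75), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
              logratio_trim, sum_trim, do_weighting,
              sample_id = colnames(counts)[j]),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                      do_weighting, sample_id = "?") {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  if (!any(fin))
    stop("library '", sample_id,
         "' shares no co-expressed features with the reference")
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- if (do_weighting)
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  else mean(logR[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}
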