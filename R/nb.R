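# Negative-binomial likelihood machinery shared by the DE tests.
# Counts may be non-negative reals (mismatch-corrected tables are
# fractional), so the log-likelihood is evaluated through lgamma rather
# than dnbinom.

.MIN_MU <- 1e-10
.MIN_BETA <- log(1e-8)

# Row-wise NB log-likelihood: y, mu matrices (features x libraries), phi
# per-feature vector. Returns the per-feature sum.
.nb_ll <- function(y, mu, phi) {
  mu <- pmax(mu, .MIN_MU)
  r <- 1 / pmax(phi, 1e-8)
  ll <- lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
    r * log(r / (r + mu)) + y * log(mu / (r + mu))
  ll[y == 0 & mu <= .MIN_MU] <- 0
  rowSums(ll)
}

# MLE of a common log-mean beta per feature, with per-library offsets
# (log effective library sizes): mu_ij = exp(beta_i + o_j). Vectorized
# Newton iteration on the NB score equation.
.fit_nb_mean <- function(y, offsets, phi, iter = 40) {
  stopifnot(ncol(y) == length(offsets))
  e_off <- matrix(exp(offsets), nrow(y), ncol(y), byrow = TRUE)
  beta <- log(pmax(rowSums(y), 1e-8) / sum(exp(offsets)))
  beta <- pmax(beta, .MIN_BETA)
  phi <- pmax(phi, 1e-8)
  for (it in seq_len(iter)) {
    mu <- exp(beta) * e_off
    score <- rowSums((y - mu) / (1 + phi * mu))
    info <- rowSums(mu / (1 + phi * mu))
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    beta <- pmax(beta + step, .MIN_BETA)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

# Two-group NB likelihood-ratio test with fixed per-feature dispersion.
# Returns log2 fold change (group2 - group1), LRT statistic and p-value.
.nb_lrt <- function(y, group1, group2, offsets, phi) {
  y1 <- y[, group1, drop = FALSE]
  y2 <- y[, group2, drop = FALSE]
  b1 <- .fit_nb_mean(y1, offsets[group1], phi)
  b2 <- .fit_nb_mean(y2, offsets[group2], phi)
  b0 <- .fit_nb_mean(y, offsets, phi)
  mu1 <- exp(b1) %o% exp(offsets[group1])
  mu2 <- exp(b2) %o% exp(offsets[group2])
  mu0 <- exp(b0) %o% exp(offsets)
  ll_full <- .nb_ll(y1, mu1, phi) + .nb_ll(y2, mu2, phi)
  ll_null <- .nb_ll(y, mu0, phi)
  stat <- pmax(2 * (ll_full - ll_null), 0)
  data.frame(log2fc = (b2 - b1) / log(2),
             stat = stat,
             pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Estimate per-feature NB dispersions
#'
#' Method-of-moments estimator on counts scaled to a common effective
#' depth, pooled across the two conditions, shrunk toward the trimmed
#' common dispersion with an empirical-Bayes prior weight, and floored at
#' 1e-6. With single replicates in both conditions the estimator falls
#' back to a common dispersion computed across all libraries, with a
#' warning.
#'
#' @param counts feature x library matrix (non-negative reals).
#' @param condition factor/character of length `ncol(counts)` with two
#'   levels.
#' @param eff_lib_size effective library sizes (depth x TMM factor).
#' @param prior_df prior degrees of freedom of the shrinkage (default 10).
#' @param trim trim fraction of the common-dispersion mean.
#' @return numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, condition, eff_lib_size,
                                prior_df = 10, trim = 0.1) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stopifnot(ncol(counts) == length(condition),
            ncol(counts) == length(eff_lib_size))
  sf <- eff_lib_size / exp(mean(log(eff_lib_size)))
  z <- sweep(counts, 2, sf, "/")
  lv <- levels(condition)
  n_by <- table(condition)
  if (all(n_by < 2)) {
    warning("no condition has replicates; using a common dispersion ",
            "across all libraries")
    groups <- list(seq_len(ncol(z)))
  } else {
    groups <- lapply(lv[n_by >= 2], function(l) which(condition == l))
  }
  num <- den <- df <- 0
  for (idx in groups) {
    m <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1, var)
    w <- length(idx) - 1
    num <- num + (v - m) * w
    den <- den + m^2 * w
    df <- df + w
  }
  phi_raw <- num / pmax(den, 1e-12)
  phi_raw[!is.finite(phi_raw) | phi_raw < 0] <- 0
  expressed <- rowMeans(z) > 1
  common <- if (any(expressed))
    mean(phi_raw[expressed], trim = trim) else 0.1
  phi <- (df * phi_raw + prior_df * common) / (df + prior_df)
  pmax(phi, 1e-6)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] kept as the single place the
#' multiple-testing correction is applied.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
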