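#' Over-representation of an overlap between two DEG sets
#'
#' Tests whether two gene sets drawn from a common background (the genes
#' expressed in both analyses) share more members than expected by
#' chance: exact upper-tail hypergeometric probability P(X >= k) by
#' summation of the pmf, a normal approximation with continuity
#' correction, and the representation factor k / (n1 n2 / N). When
#' direction labels are supplied, the shared genes are split into
#' concordant and discordant pairs and the discordant count is tested
#' against a fair coin ([direction_concordance()]).
#'
#' @param set1,set2 character vectors of gene ids (subsets of
#'   `background`).
#' @param background character vector of gene ids expressed in both
#'   analyses.
#' @param dir1,dir2 optional named character vectors (`"up"`/`"down"`)
#'   giving each gene's direction in the two analyses.
#' @return list of class `overlap_result`: `n1`, `n2`, `N`, `k`,
#'   `expected`, `representation_factor`, `p_exact`, `p_normal`,
#'   `same_direction`, `opposite_direction`, `direction_binomial_p`.
#' @export
overlap_test <- function(set1, set2, background, dir1 = NULL,
                         dir2 = NULL) {
  set1 <- unique(set1); set2 <- unique(set2)
  background <- unique(background)
  N <- length(background)
  if (N == 0) stop("empty background")
  if (!all(set1 %in% background) || !all(set2 %in% background))
    stop("sets must be contained in the background")
  n1 <- length(set1); n2 <- length(set2)
  shared <- intersect(set1, set2)
  k <- length(shared)
  N <- as.numeric(N)  # guard against integer overflow in the moments
  expected <- n1 * n2 / N
  kmax <- min(n1, n2)
  p_exact <- sum(dhyper(k:kmax, n1, N - n1, n2))
  mu <- expected
  s2 <- as.numeric(n1) * n2 * (N - n1) * (N - n2) / (N^2 * max(N - 1, 1))
  p_normal <- if (s2 > 0)
    min(1, pnorm(k - 0.5, mean = mu, sd = sqrt(s2), lower.tail = FALSE))
  else as.numeric(k >= mu)
  res <- list(n1 = n1, n2 = n2, N = N, k = k, expected = expected,
              representation_factor = if (expected > 0) k / expected
              else NA_real_,
              p_exact = p_exact, p_normal = p_normal,
              same_direction = NA_integer_,
              opposite_direction = NA_integer_,
              direction_binomial_p = NA_real_)
  if (!is.null(dir1) && !is.null(dir2)) {
    conc <- direction_concordance(dir1[shared], dir2[shared])
    res$same_direction <- conc$same
    res$opposite_direction <- conc$opposite
    res$direction_binomial_p <- conc$p
  }
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of (%d, %d) on background %d; expected %.2f (RF %.2f)\n",
    x$k, x$n1, x$n2, x$N, x$expected, x$representation_factor))
  cat(sprintf("P(X >= k) exact = %.4g, normal approx = %.4g\n",
              x$p_exact, x$p_normal))
  if (!is.na(x$same_direction))
    cat(sprintf("direction: %d same / %d opposite (binomial p = %.4g)\n",
                x$same_direction, x$opposite_direction,
                x$direction_binomial_p))
  invisible(x)
}

#' Direction concordance of shared DEGs
#'
#' Counts shared genes whose expression change points the same way in two
#' analyses versus opposite ways, and tests the discordant count against
#' a fair coin with a two-sided exact binomial test.
#'
#' @param dir1,dir2 character vectors of equal length with `"up"`/`"down"`
#'   labels of the shared genes in each analysis.
#' @return list with `same`, `opposite` and two-sided `p` (`NA` for an
#'   empty shared set).
#' @export
direction_concordance <- function(dir1, dir2) {
  stopifnot(length(dir1) == length(dir2))
  n <- length(dir1)
  if (n == 0)
    return(list(same = 0L, opposite = 0L, p = NA_real_))
  opposite <- sum(dir1 != dir2)
  list(same = n - opposite, opposite = opposite,
       p = binom.test(opposite, n, 0.5)$p.value)
}
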