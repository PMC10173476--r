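# Homoeolog expression bias on the 2-simplex: per-triad A/B/D
# contributions, nearest-centroid classification, movement between
# samples, and bias-DE association tests.

#' The seven bias-category centroids on the expression simplex
#'
#' Vertices (dominance of one homoeolog), edge midpoints (suppression of
#' one homoeolog) and the centre (balance). Row order is the deterministic
#' tie-break order of the classifier.
#'
#' @return 7 x 3 numeric matrix with rownames the category labels and
#'   columns A, B, D.
#' @export
triad_centroids <- function() {
  m <- rbind(
    "Balanced" = c(1, 1, 1) / 3,
    "Dominant A" = c(1, 0, 0),
    "Dominant B" = c(0, 1, 0),
    "Dominant D" = c(0, 0, 1),
    "Suppressed A" = c(0, 0.5, 0.5),
    "Suppressed B" = c(0.5, 0, 0.5),
    "Suppressed D" = c(0.5, 0.5, 0))
  colnames(m) <- c("A", "B", "D")
  m
}

#' Euclidean (eigen) distance between points on the simplex
#'
#' @param p,q numeric length-3 vectors or n x 3 matrices of contribution
#'   vectors.
#' @return numeric vector of distances.
#' @export
eigen_distance <- function(p, q) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  d <- sqrt(rowSums((p - q)^2))
  names(d) <- NULL
  d
}

#' Per-triad homoeolog contributions
#'
#' Averages RPM across the selected replicate libraries, removes triads
#' whose A+B+D total is below `min_triad_rpm` (a total of exactly the
#' threshold is kept), and expresses each member as its fraction of the
#' triad total.
#'
#' @param rpm a [count_table()] with `unit = "rpm"`.
#' @param triads triad table (`triad_id`, `gene_A`, `gene_B`, `gene_D`).
#' @param samples sample ids (or indices) to average over; `NULL` uses all
#'   columns.
#' @param config a [pipeline_config()].
#' @return data.frame with `triad_id`, `A`, `B`, `D` (contributions
#'   summing to one) and `total_rpm`.
#' @export
triad_contributions <- function(rpm, triads, samples = NULL,
                                config = pipeline_config()) {
  stopifnot(inherits(rpm, "count_table"))
  if (rpm$unit != "rpm")
    stop("triad contributions are computed from RPM values")
  validate_triad_table(triads, rpm$features)
  si <- .resolve_index(samples, rpm$samples$sample_id, "sample")
  mean_rpm <- rowMeans(rpm$counts[, si, drop = FALSE])
  a <- mean_rpm[triads$gene_A]
  b <- mean_rpm[triads$gene_B]
  d <- mean_rpm[triads$gene_D]
  total <- a + b + d
  keep <- total >= config$min_triad_rpm
  data.frame(triad_id = triads$triad_id[keep],
             A = (a / total)[keep],
             B = (b / total)[keep],
             D = (d / total)[keep],
             total_rpm = total[keep],
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classify triads by nearest bias centroid
#'
#' Computes the eigen distance from each triad's contribution vector to
#' the seven centroids and assigns the category of the smallest distance
#' (ties broken by the fixed centroid order of [triad_centroids()]).
#'
#' @param states data.frame from [triad_contributions()].
#' @return `states` with added `category` and the seven distance columns.
#' @export
classify_triads <- function(states) {
  cen <- triad_centroids()
  pts <- as.matrix(states[, c("A", "B", "D")])
  d <- vapply(seq_len(nrow(cen)), function(i)
    sqrt(rowSums(sweep(pts, 2, cen[i, ])^2)), numeric(nrow(pts)))
  d <- matrix(d, nrow = nrow(pts))
  colnames(d) <- paste0("dist_", gsub(" ", "_", tolower(rownames(cen))))
  states$category <- rownames(cen)[max.col(-d, ties.method = "first")]
  cbind(states, as.data.frame(d))
}

#' Cross-sample correlation of homoeolog bias
#'
#' Pearson correlation over the concatenated A/B/D contributions of the
#' triads retained (by the RPM filter) in both samples.
#'
#' @param states_x,states_y classified or unclassified state tables from
#'   [triad_contributions()].
#' @return list with `r`, `n_triads` and `points` (paired contributions
#'   for scatter plotting).
#' @export
bias_correlation <- function(states_x, states_y) {
  shared <- intersect(states_x$triad_id, states_y$triad_id)
  if (length(shared) < 2)
    stop("fewer than two triads retained in both samples")
  x <- states_x[match(shared, states_x$triad_id), ]
  y <- states_y[match(shared, states_y$triad_id), ]
  px <- c(x$A, x$B, x$D)
  py <- c(y$A, y$B, y$D)
  list(r = cor(px, py),
       n_triads = length(shared),
       points = data.frame(
         triad_id = rep(shared, 3),
         homoeolog = rep(c("A", "B", "D"), each = length(shared)),
         contribution_x = px, contribution_y = py,
         stringsAsFactors = FALSE))
}

#' Triad movement between two samples
#'
#' For each triad retained in both samples (triads expressed in only one
#' are excluded), the eigen distance between its two contribution vectors.
#' A movement is `reported` when the bias category changed and the
#' distance exceeds `movement_cutoff`. Counts of unbalanced-to-balanced
#' and balanced-to-unbalanced reported transitions are attached as
#' `attr(, "transitions")`.
#'
#' @param states_from,states_to classified state tables (e.g. in-silico
#'   parents and a synthetic).
#' @param config a [pipeline_config()].
#' @return data.frame with `triad_id`, `category_from`, `category_to`,
#'   `distance`, `reported`.
#' @export
triad_movement <- function(states_from, states_to,
                           config = pipeline_config()) {
  if (is.null(states_from$category) || is.null(states_to$category))
    stop("states must be classified (see classify_triads)")
  shared <- intersect(states_from$triad_id, states_to$triad_id)
  f <- states_from[match(shared, states_from$triad_id), ]
  t <- states_to[match(shared, states_to$triad_id), ]
  dist <- eigen_distance(as.matrix(f[, c("A", "B", "D")]),
                         as.matrix(t[, c("A", "B", "D")]))
  out <- data.frame(triad_id = shared,
                    category_from = f$category,
                    category_to = t$category,
                    distance = dist,
                    stringsAsFactors = FALSE)
  out$reported <- out$distance > config$movement_cutoff &
    out$category_from != out$category_to
  rep_ <- out[out$reported, ]
  attr(out, "transitions") <- c(
    unbalanced_to_balanced = sum(rep_$category_from != "Balanced" &
                                   rep_$category_to == "Balanced"),
    balanced_to_unbalanced = sum(rep_$category_from == "Balanced" &
                                   rep_$category_to != "Balanced"))
  out
}

#' Association between homoeolog bias and differential expression
#'
#' Two tests relating triad bias to DE in the same genotype/tissue:
#' (i) a Welch two-sample t-test comparing the log2 fold changes of
#' dominant homoeologs (contribution > `biased_high`) with those of
#' suppressed homoeologs (contribution < `biased_low`); (ii) a 2x2
#' chi-square test of independence between "triad contains a significant
#' DEG" and "triad is unbalanced".
#'
#' @param states classified triad states of the synthetic sample.
#' @param triads the triad table linking genes to triads.
#' @param de DE results ([de_test()]) covering the triad genes.
#' @param config a [pipeline_config()].
#' @return list with components `t_test` (statistic, p, class sizes and
#'   means; `NULL` with a warning when a class has < 2 members) and
#'   `chisq` (statistic, p, the 2x2 table).
#' @export
bias_de_association <- function(states, triads, de,
                                config = pipeline_config()) {
  tr <- triads[match(states$triad_id, triads$triad_id), ]
  long <- data.frame(
    triad_id = rep(states$triad_id, 3),
    feature_id = c(tr$gene_A, tr$gene_B, tr$gene_D),
    contribution = c(states$A, states$B, states$D),
    stringsAsFactors = FALSE)
  long$log2fc <- de$log2fc[match(long$feature_id, de$feature_id)]
  long <- long[!is.na(long$log2fc), ]
  dom <- long$log2fc[long$contribution > config$biased_high]
  sup <- long$log2fc[long$contribution < config$biased_low]

  t_res <- NULL
  if (length(dom) >= 2 && length(sup) >= 2) {
    tt <- tryCatch(t.test(dom, sup), error = function(e) NULL)
    if (is.null(tt)) {
      # degenerate (zero-variance) classes: equal means => no evidence
      tt <- list(statistic = c(t = if (mean(dom) == mean(sup)) 0 else Inf),
                 p.value = if (mean(dom) == mean(sup)) 1 else 0)
    }
    t_res <- list(statistic = unname(tt$statistic), p = tt$p.value,
                  n_dominant = length(dom), n_suppressed = length(sup),
                  mean_dominant = mean(dom), mean_suppressed = mean(sup))
  } else {
    warning("dominant/suppressed class with fewer than two members; ",
            "t-test skipped")
  }

  has_deg <- tapply(de$significant[match(long$feature_id, de$feature_id)],
                    long$triad_id, any)
  unbalanced <- states$category != "Balanced"
  names(unbalanced) <- states$triad_id
  ids <- intersect(names(has_deg), names(unbalanced))
  tab <- table(factor(has_deg[ids], levels = c(FALSE, TRUE)),
               factor(unbalanced[ids], levels = c(FALSE, TRUE)),
               dnn = c("has_deg", "unbalanced"))
  chi_res <- NULL
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi_res <- list(statistic = unname(ct$statistic), p = ct$p.value,
                    table = tab)
  } else {
    warning("degenerate 2x2 table; chi-square test skipped")
    chi_res <- list(statistic = NA_real_, p = NA_real_, table = tab)
  }
  list(t_test = t_res, chisq = chi_res)
}
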