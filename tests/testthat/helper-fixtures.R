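# Shared fixture builders for the test suite. Everything is generated in
# code; no files are read from disk except those the tests write.

# A minimal literal two-gene, two-sample dataset.
tiny_table <- function() {
  counts <- matrix(c(10, 20, 30, 40), nrow = 2,
                   dimnames = list(c("gA1", "gD1"), c("s1", "s2")))
  features <- data.frame(
    feature_id = c("gA1", "gD1"),
    feature_class = "hc_gene",
    subgenome = c("A", "D"),
    chromosome = c("1A", "1D"),
    order_index = 0L,
    length_bp = c(1000, 2000),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("s1", "s2"),
    genotype_id = "geno1",
    tissue = "leaf",
    generation = "P",
    role = "diploid_parent",
    replicate_of = "geno1",
    stringsAsFactors = FALSE)
  count_table(counts, features, samples)
}

# A hand-built count_table with arbitrary content.
make_table <- function(counts, subgenome, role = "synthetic",
                       feature_class = "hc_gene", genotype = "geno1",
                       chromosome = NULL, length_bp = 1000,
                       unit = "counts", diploid_parent = NA,
                       tetraploid_parent = NA, corrected = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(genotype, "_r", seq_len(ncol(counts)))
  if (is.null(chromosome)) chromosome <- paste0("1", subgenome)
  features <- data.frame(
    feature_id = rownames(counts),
    feature_class = rep_len(feature_class, n),
    subgenome = rep_len(subgenome, n),
    chromosome = rep_len(chromosome, n),
    order_index = stats::ave(seq_len(n), rep_len(chromosome, n),
                             FUN = seq_along) - 1L,
    length_bp = rep_len(length_bp, n),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = colnames(counts),
    genotype_id = rep_len(genotype, ncol(counts)),
    tissue = "leaf",
    generation = "P",
    role = rep_len(role, ncol(counts)),
    replicate_of = rep_len(genotype, ncol(counts)),
    diploid_parent = diploid_parent,
    tetraploid_parent = tetraploid_parent,
    stringsAsFactors = FALSE)
  count_table(counts, features, samples, unit = unit, corrected = corrected)
}

# Split a simulated experiment's table into the three role tables.
split_roles <- function(tab) {
  roles <- tab$samples$role
  list(dip = subset_count_table(tab, samples = roles == "diploid_parent"),
       tet = subset_count_table(tab, samples = roles == "tetraploid_parent"),
       syn = subset_count_table(tab, samples = roles %in%
                                  c("synthetic", "natural_hexaploid")))
}

# Run the split-normalized parent-vs-synthetic DE for one simulated
# experiment; correct = FALSE skips the mismatch correction.
run_split_de <- function(sim, correct = TRUE, config = pipeline_config()) {
  r <- split_roles(sim$counts)
  if (correct) {
    corr <- correct_subgenome_mismatch(r$dip, r$tet, config)
    r$dip <- corr$diploid
    r$tet <- corr$tetraploid
  }
  groups <- build_normalization_groups(r$syn, r$dip, r$tet, config)
  lapply(groups, de_test, config = config)
}

# Step-by-step reference computation of the TMM factor of one library
# against a reference library: literal implementation of the published
# recipe with explicit trimming, independent of the package internals.
tmm_oracle_pair <- function(obs, ref, n_obs, n_ref) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

# Independent nearest-of-seven-centroids oracle: explicit loops, fixed
# tie order matching the package's documented convention.
oracle_classify <- function(p) {
  cen <- list(Balanced = c(1, 1, 1) / 3,
              `Dominant A` = c(1, 0, 0),
              `Dominant B` = c(0, 1, 0),
              `Dominant D` = c(0, 0, 1),
              `Suppressed A` = c(0, 0.5, 0.5),
              `Suppressed B` = c(0.5, 0, 0.5),
              `Suppressed D` = c(0.5, 0.5, 0))
  d <- vapply(cen, function(cc) sqrt(sum((p - cc)^2)), numeric(1))
  names(cen)[which.min(d)]
}

# Minimum gap between the two nearest centroid distances (to exclude
# ties from exact-agreement checks).
oracle_tie_gap <- function(p) {
  cen <- triad_centroids()
  d <- sort(apply(cen, 1, function(cc) sqrt(sum((p - cc)^2))))
  d[2] - d[1]
}

# Random points on the 2-simplex.
random_simplex <- function(n) {
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  g / rowSums(g)
}
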