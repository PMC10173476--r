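test_that("TMM factors are symmetric and depth-invariant", {
  set.seed(2)
  a <- rpois(200, 100)
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("f", 1:200)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(s1 = a, s2 = 3 * a)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM factors match a step-by-step reference on a toy table", {
  # 5 genes, one 50-fold outlier in library 2
  m <- cbind(s1 = c(100, 200, 300, 400, 500),
             s2 = c(110, 190, 310, 390, 25000))
  rownames(m) <- paste0("g", 1:5)
  lib <- colSums(m)
  f_raw <- c(1, tmm_oracle_pair(m[, 2], m[, 1], lib[2], lib[1]))
  expected <- f_raw / exp(mean(log(f_raw)))
  got <- tmm_factors(m)  # library 1 is the reference (f75 closer to mean)
  expect_equal(unname(got), unname(expected), tolerance = 1e-9)
})

test_that("TMM factors agree with edgeR::calcNormFactors", {
  set.seed(3)
  for (i in 1:3) {
    m <- matrix(rnbinom(500 * 6, mu = rexp(500, 1 / 80), size = 5),
                nrow = 500, ncol = 6)
    m <- m[rowSums(m) > 0, ]
    colnames(m) <- paste0("s", 1:6)
    expect_equal(unname(tmm_factors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-9)
  }
})

test_that("rescaling a library leaves normalized expression unchanged", {
  # exact invariance is a property of the unweighted trimmed mean; the
  # precision weights of the default recipe depend on absolute counts,
  # so the weighted factors drift slightly (~1%) under rescaling
  set.seed(4)
  m <- matrix(rnbinom(400 * 4, mu = 80, size = 5), nrow = 400,
              dimnames = list(paste0("f", 1:400), paste0("s", 1:4)))
  f1 <- tmm_factors(m, do_weighting = FALSE)
  norm1 <- sweep(m, 2, colSums(m) * f1, "/")
  m2 <- m
  m2[, 3] <- m2[, 3] * 7
  f2 <- tmm_factors(m2, do_weighting = FALSE)
  norm2 <- sweep(m2, 2, colSums(m2) * f2, "/")
  expect_equal(norm1, norm2, tolerance = 1e-9)
  expect_equal(unname(tmm_factors(m)), unname(tmm_factors(m2)),
               tolerance = 0.05)
})

test_that("normalization groups follow the genotype-sharing rule", {
  set.seed(5)
  mk_counts <- function(k) matrix(rpois(6 * k, 100), nrow = 6)
  sub6 <- c("A", "B", "A", "D", "D", "D")
  chr6 <- c("1A", "1B", "2A", "1D", "2D", "3D")
  parent <- function(genotype, role) {
    tab <- make_table(mk_counts(2), subgenome = sub6, chromosome = chr6,
                      role = role, genotype = genotype)
    tab
  }
  syn_tab <- function(genotype, dip, tet) {
    make_table(mk_counts(2), subgenome = sub6, chromosome = chr6,
               role = "synthetic", genotype = genotype,
               diploid_parent = dip, tetraploid_parent = tet)
  }
  cat2 <- function(a, b) {
    count_table(cbind(a$counts, b$counts), a$features,
                rbind(a$samples, b$samples))
  }
  dip1 <- parent("tauschii1", "diploid_parent")
  dip2 <- parent("tauschii2", "diploid_parent")
  tet1 <- parent("durum1", "tetraploid_parent")

  # two synthetics sharing both parents -> 2 groups (AB, D)
  syn_shared <- cat2(syn_tab("synA", "tauschii1", "durum1"),
                     syn_tab("synB", "tauschii1", "durum1"))
  g <- suppressMessages(
    build_normalization_groups(syn_shared, dip1, tet1))
  expect_length(g, 2)
  expect_setequal(vapply(g, `[[`, "", "partition"), c("AB", "D"))

  # different D parents, same AB parent -> 3 groups
  syn_mixed <- cat2(syn_tab("synA", "tauschii1", "durum1"),
                    syn_tab("synB", "tauschii2", "durum1"))
  dip_both <- cat2(dip1, dip2)
  g3 <- suppressMessages(
    build_normalization_groups(syn_mixed, dip_both, tet1))
  expect_length(g3, 3)

  # factors of every group have geometric mean one
  for (grp in g3)
    expect_equal(exp(mean(log(grp$tmm))), 1, tolerance = 1e-6)

  # a synthetic whose parent genotype is absent is an error
  expect_error(suppressMessages(
    build_normalization_groups(syn_mixed, dip1, tet1)), "absent")
})

test_that("dispersion estimation recovers the generating parameters", {
  set.seed(6)
  # Poisson data: median estimated dispersion near the floor
  y <- matrix(rpois(2000 * 10, 100), nrow = 2000)
  cond <- rep(c("a", "b"), each = 5)
  phi <- estimate_dispersion(y, cond, rep(1e6, 10))
  expect_lte(median(phi), 0.05)
  # NB at phi = 0.2: common dispersion within [0.1, 0.3]
  y2 <- matrix(rnbinom(2000 * 5, mu = 100, size = 5), nrow = 2000)
  phi2 <- estimate_dispersion(y2, rep(c("a", "b"), c(3, 2)), rep(1e6, 5))
  expect_gt(median(phi2), 0.1)
  expect_lt(median(phi2), 0.3)
  # constant feature: zero moment estimate, floored (no shrinkage)
  y3 <- rbind(matrix(rnbinom(50 * 6, mu = 100, size = 10), nrow = 50),
              rep(100, 6))
  phi3 <- estimate_dispersion(y3, rep(c("a", "b"), each = 3), rep(1, 6),
                              prior_df = 0)
  expect_equal(phi3[51], 1e-6)
  # no replicates anywhere: falls back with a warning
  expect_warning(estimate_dispersion(y3[, 1:2], c("a", "b"), c(1, 1)),
                 "common dispersion")
})

test_that("the LRT matches an independent likelihood optimization", {
  # group means 10 vs 160 (16-fold), phi = 0.05, n = 3 vs 3
  counts <- rbind(g1 = c(8, 10, 12, 150, 160, 170))
  grp <- make_table(counts, subgenome = "D", role = "synthetic")
  y <- counts
  off <- rep(log(1e6), 6)
  phi <- 0.05
  res <- crossploidy:::.nb_lrt(y, 1:3, 4:6, off, phi)

  nll <- function(beta, yy, oo) {
    mu <- exp(beta + oo)
    r <- 1 / phi
    -sum(lgamma(yy + r) - lgamma(r) - lgamma(yy + 1) +
           r * log(r / (r + mu)) + yy * log(mu / (r + mu)))
  }
  o1 <- optimize(nll, c(-30, 10), yy = y[1, 1:3], oo = off[1:3])
  o2 <- optimize(nll, c(-30, 10), yy = y[1, 4:6], oo = off[4:6])
  o0 <- optimize(nll, c(-30, 10), yy = y[1, ], oo = off)
  stat_oracle <- 2 * (o0$objective - o1$objective - o2$objective)
  expect_equal(res$stat, stat_oracle, tolerance = 1e-6)
  expect_gt(res$stat, qchisq(0.999, 1))
  expect_equal(res$log2fc, log2(160 / 10), tolerance = 1e-3)
})

test_that("identical replicate columns yield a null DE result", {
  set.seed(7)
  base <- rpois(50, 120)
  counts <- matrix(rep(base, 6), ncol = 6,
                   dimnames = list(paste0("f", 1:50),
                                   c(paste0("p", 1:3), paste0("s", 1:3))))
  fe <- data.frame(feature_id = paste0("f", 1:50),
                   feature_class = "hc_gene", subgenome = "D",
                   chromosome = "1D", order_index = 0:49, length_bp = 1000)
  sa <- data.frame(sample_id = colnames(counts),
                   genotype_id = rep(c("tauschii1", "syn1"), each = 3),
                   tissue = "leaf", generation = "P",
                   role = rep(c("diploid_parent", "synthetic"), each = 3),
                   replicate_of = rep(c("tauschii1", "syn1"), each = 3))
  grp <- structure(list(partition = "D", parent_genotype = "tauschii1",
                        counts = counts, features = fe, samples = sa,
                        lib_size = colSums(counts),
                        tmm = rep(1, 6),
                        eff_lib_size = colSums(counts)),
                   class = "norm_group")
  de <- de_test(grp)
  expect_true(all(de$log2fc == 0))
  expect_true(all(!de$significant))
  expect_true(all(de$direction == "none"))
})

test_that("significance requires both the FDR and fold-change thresholds", {
  set.seed(8)
  # f1: ~16-fold with tiny p -> significant up; f2: exactly 2-fold with
  # large counts (tiny p but |log2fc| ~ 1) -> not significant; the FDR
  # column is monotone in p.
  counts <- rbind(f1 = c(10, 11, 9, 161, 158, 160),
                  f2 = c(5000, 5050, 4950, 10000, 10100, 9900),
                  matrix(rpois(40 * 6, 100), nrow = 40,
                         dimnames = list(paste0("x", 1:40), NULL)))
  colnames(counts) <- c(paste0("p", 1:3), paste0("s", 1:3))
  fe <- data.frame(feature_id = rownames(counts),
                   feature_class = "hc_gene", subgenome = "D",
                   chromosome = "1D", order_index = seq_len(42) - 1,
                   length_bp = 1000)
  sa <- data.frame(sample_id = colnames(counts),
                   genotype_id = rep(c("tauschii1", "syn1"), each = 3),
                   tissue = "leaf", generation = "P",
                   role = rep(c("diploid_parent", "synthetic"), each = 3),
                   replicate_of = rep(c("tauschii1", "syn1"), each = 3))
  grp <- structure(list(partition = "D", parent_genotype = "tauschii1",
                        counts = counts, features = fe, samples = sa,
                        lib_size = rep(1e6, 6), tmm = rep(1, 6),
                        eff_lib_size = rep(1e6, 6)),
                   class = "norm_group")
  de <- de_test(grp, dispersion = rep(0.01, 42))
  expect_true(de$significant[de$feature_id == "f1"])
  expect_identical(de$direction[de$feature_id == "f1"], "up")
  expect_false(de$significant[de$feature_id == "f2"])
  expect_lt(de$fdr[de$feature_id == "f2"], 0.01)  # fails only on FC
  ord <- order(de$pvalue)
  expect_true(all(diff(de$fdr[ord]) >= -1e-12))
  expect_true(all(de$fdr <= 1))
  # summary bookkeeping
  s <- classify_degs(de)
  expect_equal(s$n_up[s$subgenome == "D"], 1L)
})

test_that("MPV pseudo-libraries cover all parental replicate pairs", {
  dip <- matrix(c(300, 0), nrow = 1,
                dimnames = list("fam1", c("d1", "d2")))
  tet <- matrix(c(600, 0, 300), nrow = 1,
                dimnames = list("fam1", c("t1", "t2", "t3")))
  mpv <- build_mpv_libraries(dip, tet)
  expect_equal(ncol(mpv), 6)
  expect_equal(mpv["fam1", "MPV_d1_t1"], 300 / 3 + 2 * 600 / 3)  # 500
  expect_equal(mpv["fam1", "MPV_d2_t2"], 0)
  expect_equal(nrow(attr(mpv, "provenance")), 6)
})

test_that("the MPV test flags planted effects and spares null families", {
  spec <- data.frame(family = sprintf("f%02d", 1:40),
                     rpm_diploid = 500, rpm_tetraploid = 500,
                     log2_effect = rep(c(0, 3), c(35, 5)))
  cfg <- sim_config(te_spec = spec, rng_seed = 13)
  te <- simulate_te_families(cfg)
  r <- split_roles(te$counts)
  mpv <- build_mpv_libraries(
    te_family_rpm(redistribute_parent_te_counts(r$dip)),
    te_family_rpm(redistribute_parent_te_counts(r$tet)))
  de <- te_mpv_de(te_family_rpm(r$syn), mpv)
  flagged <- de$feature_id[de$significant]
  expect_setequal(flagged, spec$family[spec$log2_effect == 3])
  expect_true(all(de$direction[de$feature_id %in% flagged] == "up"))
  # identical synthetic and MPV values -> nothing significant
  de0 <- te_mpv_de(mpv[, 1:3], mpv)
  expect_equal(sum(de0$significant), 0)
})
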