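triad_fixture <- function(mean_rpm) {
  # mean_rpm: matrix n x 3 of replicate-mean RPMs for A, B, D members
  n <- nrow(mean_rpm)
  ids <- sprintf("t%03d", seq_len(n))
  fe <- data.frame(
    feature_id = c(paste0(ids, "_A"), paste0(ids, "_B"),
                   paste0(ids, "_D")),
    feature_class = "hc_gene",
    subgenome = rep(c("A", "B", "D"), each = n),
    chromosome = rep(c("1A", "1B", "1D"), each = n),
    order_index = rep(seq_len(n) - 1L, 3),
    length_bp = 1000)
  counts <- matrix(c(mean_rpm[, 1], mean_rpm[, 2], mean_rpm[, 3]),
                   ncol = 1, dimnames = list(fe$feature_id, "s1"))
  sa <- data.frame(sample_id = "s1", genotype_id = "g1", tissue = "leaf",
                   generation = "C2", role = "synthetic",
                   replicate_of = "g1")
  list(tab = count_table(counts, fe, sa, unit = "rpm"),
       triads = data.frame(triad_id = ids, gene_A = paste0(ids, "_A"),
                           gene_B = paste0(ids, "_B"),
                           gene_D = paste0(ids, "_D")))
}

test_that("triad contributions apply the 5 RPM filter inclusively", {
  fx <- triad_fixture(rbind(c(2, 2, 1),      # total 5: kept (not below 5)
                            c(2, 2, 0.9),    # total 4.9: removed
                            c(0, 0, 8)))     # degenerate simplex point
  st <- triad_contributions(fx$tab, fx$triads)
  expect_setequal(st$triad_id, c("t001", "t003"))
  expect_equal(unlist(st[st$triad_id == "t001", c("A", "B", "D")]),
               c(A = 0.4, B = 0.4, D = 0.2))
  expect_equal(unlist(st[st$triad_id == "t003", c("A", "B", "D")]),
               c(A = 0, B = 0, D = 1))
  expect_true(all(abs(rowSums(st[, c("A", "B", "D")]) - 1) < 1e-9))
})

test_that("eigen distances evaluate the closed forms", {
  expect_equal(eigen_distance(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(eigen_distance(c(1, 1, 1) / 3, c(1, 1, 1) / 3), 0)
  expect_equal(eigen_distance(c(1, 1, 1) / 3, c(1, 0, 0)), sqrt(6) / 3,
               tolerance = 1e-12)
  expect_equal(eigen_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2),
               tolerance = 1e-12)
  expect_equal(eigen_distance(c(0.40, 0.30, 0.30), c(0.34, 0.33, 0.33)),
               sqrt(0.06^2 + 0.03^2 + 0.03^2), tolerance = 1e-12)
})

test_that("eigen distance is a metric on random state triples", {
  set.seed(30)
  p <- random_simplex(200); q <- random_simplex(200); r <- random_simplex(200)
  dpq <- eigen_distance(p, q)
  expect_equal(dpq, eigen_distance(q, p))
  expect_true(all(dpq <= eigen_distance(p, r) + eigen_distance(r, q) + 1e-12))
  expect_true(all(dpq >= 0 & dpq <= sqrt(2) + 1e-12))
})

test_that("classification picks the nearest of the seven centroids", {
  st <- data.frame(triad_id = c("a", "b", "c"),
                   A = c(0.34, 0.90, 0.05),
                   B = c(0.33, 0.05, 0.475),
                   D = c(0.33, 0.05, 0.475),
                   total_rpm = 100)
  got <- classify_triads(st)
  expect_identical(got$category,
                   c("Balanced", "Dominant A", "Suppressed A"))
  # exact agreement with the brute-force oracle on random points
  set.seed(31)
  pts <- random_simplex(2000)
  states <- data.frame(triad_id = as.character(seq_len(nrow(pts))),
                       A = pts[, 1], B = pts[, 2], D = pts[, 3],
                       total_rpm = 10)
  cats <- classify_triads(states)$category
  keep <- apply(pts, 1, oracle_tie_gap) > 1e-9
  oracle <- apply(pts, 1, oracle_classify)
  expect_identical(cats[keep], oracle[keep])
})

test_that("bias correlation reflects shared and broken structure", {
  set.seed(32)
  pts <- random_simplex(100)
  st <- data.frame(triad_id = as.character(1:100), A = pts[, 1],
                   B = pts[, 2], D = pts[, 3], total_rpm = 50)
  expect_equal(bias_correlation(st, st)$r, 1)
  swapped <- st
  swapped$A <- st$D
  swapped$D <- st$A
  expect_lt(bias_correlation(st, swapped)$r, 1)
  expect_error(bias_correlation(st[1, ], st[2, ]), "fewer than two")
})

test_that("synthetics inherit the parental bias (legacy correlation)", {
  set.seed(33)
  nt <- 800
  g <- matrix(rgamma(nt * 3, 2), ncol = 3)  # strong parental bias
  bias <- g / rowSums(g)
  # low biological dispersion: genetically identical inbred replicates
  cfg <- sim_config(n_triads = nt, bias_spec = bias, mismatch_rate = 0.01,
                    dispersion = 0.02, rng_seed = 34)
  sim <- simulate_experiment(cfg)
  r <- split_roles(sim$counts)
  insilico <- combine_parents_in_silico(
    normalize_expression(r$dip, "rpm"), normalize_expression(r$tet, "rpm"))
  par_st <- triad_contributions(insilico, sim$triads)
  syn_st <- triad_contributions(normalize_expression(r$syn, "rpm"),
                                sim$triads)
  expect_gte(bias_correlation(par_st, syn_st)$r, 0.95)
})

test_that("movement reporting needs a category change above the cut-off", {
  st1 <- classify_triads(data.frame(
    triad_id = c("t1", "t2", "t3"),
    A = c(1, 0.40, 1 / 3), B = c(0, 0.30, 1 / 3), D = c(0, 0.30, 1 / 3),
    total_rpm = 50))
  st2 <- classify_triads(data.frame(
    triad_id = c("t1", "t2", "t4"),
    A = c(0, 0.34, 0.2), B = c(1, 0.33, 0.4), D = c(0, 0.33, 0.4),
    total_rpm = 50))
  mv <- triad_movement(st1, st2)
  expect_setequal(mv$triad_id, c("t1", "t2"))  # t3/t4 not shared
  expect_equal(mv$distance[mv$triad_id == "t1"], sqrt(2))
  expect_true(mv$reported[mv$triad_id == "t1"])
  expect_equal(mv$distance[mv$triad_id == "t2"], 0.07348469,
               tolerance = 1e-6)
  expect_false(mv$reported[mv$triad_id == "t2"])
  mv0 <- triad_movement(st1, st1)
  expect_true(all(mv0$distance == 0) && !any(mv0$reported))
})

test_that("balance-ward drift shows up as asymmetric transitions", {
  set.seed(35)
  nt <- 600
  g <- matrix(rgamma(nt * 3, 1.2), ncol = 3)  # strongly biased parents
  bias <- g / rowSums(g)
  cfg <- sim_config(n_triads = nt, bias_spec = bias,
                    synthetic_bias_shrink = 0.5, mismatch_rate = 0,
                    rng_seed = 36)
  sim <- simulate_experiment(cfg)
  r <- split_roles(sim$counts)
  insilico <- combine_parents_in_silico(
    normalize_expression(r$dip, "rpm"), normalize_expression(r$tet, "rpm"))
  par_st <- classify_triads(triad_contributions(insilico, sim$triads))
  syn_st <- classify_triads(triad_contributions(
    normalize_expression(r$syn, "rpm"), sim$triads))
  tr <- attr(triad_movement(par_st, syn_st), "transitions")
  expect_gt(tr[["unbalanced_to_balanced"]], tr[["balanced_to_unbalanced"]])
})

test_that("near-centre bias classifies almost entirely as balanced", {
  set.seed(37)
  nt <- 500
  jitter <- matrix(runif(nt * 3, -0.1, 0.1), ncol = 3)
  bias <- 1 / 3 + jitter
  bias <- bias / rowSums(bias)
  stopifnot(max(bias) <= 0.5)
  cfg <- sim_config(n_triads = nt, bias_spec = bias, mismatch_rate = 0.01,
                    rng_seed = 38)
  sim <- simulate_experiment(cfg)
  syn_st <- classify_triads(triad_contributions(
    normalize_expression(split_roles(sim$counts)$syn, "rpm"), sim$triads))
  expect_gte(mean(syn_st$category == "Balanced"), 0.95)
})

test_that("bias-DE association detects coupling and respects nulls", {
  # identical log2fc distributions in both classes: t = 0, p = 1
  n <- 60
  st <- data.frame(triad_id = sprintf("t%03d", 1:n),
                   A = 0.8, B = 0.1, D = 0.1, total_rpm = 100)
  ids <- st$triad_id
  triads <- data.frame(triad_id = ids, gene_A = paste0(ids, "_A"),
                       gene_B = paste0(ids, "_B"),
                       gene_D = paste0(ids, "_D"))
  fcs <- rep(c(-1, 0, 1), length.out = n)
  de <- data.frame(feature_id = c(paste0(ids, "_A"), paste0(ids, "_B"),
                                  paste0(ids, "_D")),
                   log2fc = c(fcs, fcs, fcs),
                   significant = FALSE)
  st_cl <- classify_triads(st)
  res <- suppressWarnings(bias_de_association(st_cl, triads, de))
  expect_equal(res$t_test$statistic, 0)
  expect_equal(res$t_test$p, 1)

  # planted +1 shift on dominant homoeologs: strongly significant
  set.seed(39)
  n2 <- 250
  st2 <- data.frame(triad_id = sprintf("u%03d", 1:n2),
                    A = 0.8, B = 0.1, D = 0.1, total_rpm = 100)
  ids2 <- st2$triad_id
  triads2 <- data.frame(triad_id = ids2, gene_A = paste0(ids2, "_A"),
                        gene_B = paste0(ids2, "_B"),
                        gene_D = paste0(ids2, "_D"))
  de2 <- data.frame(
    feature_id = c(paste0(ids2, "_A"), paste0(ids2, "_B"),
                   paste0(ids2, "_D")),
    log2fc = c(rnorm(n2, 1), rnorm(n2, 0), rnorm(n2, 0)),
    significant = FALSE)
  res2 <- suppressWarnings(bias_de_association(classify_triads(st2),
                                               triads2, de2))
  expect_lt(res2$t_test$p, 0.01)
  expect_gt(res2$t_test$mean_dominant, res2$t_test$mean_suppressed)
})

test_that("a proportional DEG-by-bias table gives a zero chi-square", {
  # margins built to exact independence: 30 balanced (10 without DEG,
  # 20 with), 90 unbalanced (30 without, 60 with)
  n <- 120
  ids <- sprintf("v%03d", 1:n)
  balanced <- rep(c(TRUE, FALSE), c(30, 90))
  has_deg <- c(rep(c(FALSE, TRUE), c(10, 20)),
               rep(c(FALSE, TRUE), c(30, 60)))
  st <- data.frame(triad_id = ids,
                   A = ifelse(balanced, 1 / 3, 0.8),
                   B = ifelse(balanced, 1 / 3, 0.1),
                   D = ifelse(balanced, 1 / 3, 0.1),
                   total_rpm = 100)
  triads <- data.frame(triad_id = ids, gene_A = paste0(ids, "_A"),
                       gene_B = paste0(ids, "_B"),
                       gene_D = paste0(ids, "_D"))
  de <- data.frame(
    feature_id = c(paste0(ids, "_A"), paste0(ids, "_B"),
                   paste0(ids, "_D")),
    log2fc = rep(c(0.5, 1.5), 3 * 60),
    significant = c(has_deg, rep(FALSE, 2 * n)))
  res <- suppressWarnings(bias_de_association(classify_triads(st), triads,
                                              de))
  expect_equal(res$chisq$statistic, 0, tolerance = 1e-12)
  expect_equal(unname(as.vector(res$chisq$table)), c(10, 20, 30, 60))
})
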