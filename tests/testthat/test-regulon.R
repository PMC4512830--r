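test_that("KSG estimator matches the Gaussian closed form and the null", {
  # I = -0.5 * ln(1 - rho^2) = 0.830 nats at rho = 0.9
  mis <- vapply(1:3, function(s) {
    withr::with_seed(s, {
      x <- rnorm(2000)
      y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(2000)
      ksg_mi(x, y, k = 3)
    })
  }, numeric(1))
  expect_lt(abs(mean(mis) - 0.830), 0.05)
  null_mis <- vapply(4:6, function(s) {
    withr::with_seed(s, ksg_mi(rnorm(1000), rnorm(1000), k = 3))
  }, numeric(1))
  expect_lt(abs(mean(null_mis)), 0.05)
})

test_that("KSG estimator is symmetric and rank-invariant", {
  withr::with_seed(11, {
    x <- rnorm(400)
    y <- 0.7 * x + rnorm(400)
  })
  expect_equal(ksg_mi(x, y), ksg_mi(y, x), tolerance = 1e-6)
  # strictly monotone marginal transforms leave the estimate nearly unchanged
  expect_lt(abs(ksg_mi(exp(x), y) - ksg_mi(x, y)), 0.07)
  expect_lt(abs(ksg_mi(x, y^3) - ksg_mi(x, y)), 0.07)
})

test_that("KSG estimator guards its inputs", {
  expect_error(ksg_mi(1:3, 1:3, k = 3), "more than")
  expect_error(ksg_mi(1:5, 1:4), "equal length")
  expect_warning(mi <- ksg_mi(rep(1, 20), rnorm(20)), "constant")
  expect_equal(mi, 0)
})

test_that("mi_matrix agrees with per-pair calls on continuous data", {
  withr::with_seed(21, {
    A <- matrix(rnorm(3 * 60), 3, dimnames = list(paste0("m", 1:3),
                                                  paste0("s", 1:60)))
    B <- matrix(rnorm(2 * 60), 2, dimnames = list(paste0("g", 1:2),
                                                  paste0("s", 1:60)))
  })
  mm <- mi_matrix(A, B, k = 3)
  expect_equal(dim(mm), c(3L, 2L))
  for (i in 1:3) for (j in 1:2) {
    expect_equal(mm[i, j], ksg_mi(A[i, ], B[j, ], k = 3), tolerance = 1e-5)
  }
})

test_that("regulon rules behave at their extremes", {
  withr::with_seed(22, {
    A <- matrix(rnorm(2 * 40), 2, dimnames = list(c("m1", "m2"),
                                                  paste0("s", 1:40)))
    B <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("g", 1:5),
                                                  paste0("s", 1:40)))
  })
  expect_equal(nrow(build_regulon(A, B, rule = "top_k", top_k = 0)), 0L)
  r2 <- build_regulon(A, B, rule = "top_k", top_k = 2)
  expect_equal(nrow(r2), 4L)
  expect_equal(unname(table(r2$mirna)), as.integer(c(2, 2)),
               ignore_attr = TRUE)
  # independent data under the permutation rule: regulons are near-empty
  r0 <- build_regulon(A, B, rule = "permutation_fdr", n_perm = 30, seed = 2)
  expect_lte(nrow(r0), 1L)
})

test_that("planted regulons are recovered with high precision and recall", {
  # dependence-only configuration (no planted fold change), so mutual
  # information reflects the copula coupling rather than the class signal;
  # settings calibrated in a pilot run: strength 0.95, dispersion 0.02,
  # 60 + 60 samples, 40 permutations, alpha 0.01
  stats <- vapply(1:2, function(s) {
    cfg <- sim_config(n_tumor = 60, n_normal = 60, n_genes = 400,
                      n_mirnas = 40, n_pathways = 8,
                      pathway_size_range = c(15, 25), n_de_genes = 80,
                      planted_logfc = 0, nb_dispersion = 0.02,
                      n_crosstalk_pairs = 2, regulon_size = 12,
                      regulon_strength = 0.95, seed = s)
    st <- simulate_crosstalk_study(cfg)
    regs <- names(st$truth$regulons)
    mir_e <- log2(mirxtalk:::.normalize_counts(st$mirna) + 1)[regs, ,
                                                              drop = FALSE]
    gene_e <- log2(mirxtalk:::.normalize_counts(st$mrna) + 1)
    reg <- build_regulon(mir_e, gene_e, seed = 5, alpha = 0.01, n_perm = 40)
    rowMeans(vapply(regs, function(r) {
      tg <- reg$target[reg$mirna == r]
      c(if (length(tg)) mean(tg %in% st$truth$regulons[[r]]) else 0,
        mean(st$truth$regulons[[r]] %in% tg))
    }, numeric(2)))
  }, numeric(2))
  expect_true(all(stats[1, ] > 0.8)) # precision
  expect_true(all(stats[2, ] > 0.8)) # recall
})

test_that("mra_pair flags dual enrichment and matches the hypergeometric oracle", {
  u <- paste0("g", 1:60)
  coll <- list(A = u[1:8], B = u[9:16])
  # mirX targets every gene of both pathways; mirY targets none of them
  reg <- tibble::tibble(mirna = c(rep("mirX", 16), rep("mirY", 3)),
                        target = c(u[1:16], u[30:32]),
                        mi = 1)
  res <- mra_pair(reg, c("A", "B"), coll, u, de_mirnas = c("mirX", "mirY"))
  expect_equal(res$targets_in_a[res$mirna == "mirX"], 8L)
  expect_equal(res$targets_in_b[res$mirna == "mirX"], 8L)
  # oracle equality for the Fisher p-values in the table
  expect_equal(res$p_a[res$mirna == "mirX"],
               hyper_tail_oracle(8, 8, 60, 16), tolerance = 1e-12)
  expect_equal(res$p_b[res$mirna == "mirY"],
               hyper_tail_oracle(0, 8, 60, 3), tolerance = 1e-12)
  # mirX hits both pathways, mirY neither
  expect_true(res$is_mr[res$mirna == "mirX"])
  expect_false(res$is_mr[res$mirna == "mirY"])
  # BH is applied across miRNAs within each pathway
  expect_equal(res$fdr_a, bh_oracle(res$p_a))
  # a non-DE miRNA can never be a master regulator
  res2 <- mra_pair(reg, c("A", "B"), coll, u, de_mirnas = character(0))
  expect_false(any(res2$is_mr))
})

test_that("mra_pair handles maximal and empty enrichment", {
  u <- paste0("g", 1:12)
  coll <- list(A = u[1:6], B = u[1:6])
  reg <- tibble::tibble(mirna = "mirZ", target = u[1:6], mi = 1)
  res <- mra_pair(reg, c("A", "B"), coll, u, de_mirnas = "mirZ")
  expect_equal(res$p_a, 1 / choose(12, 6), tolerance = 1e-12)
  expect_true(res$is_mr)
  empty <- mra_pair(reg[0, ], c("A", "B"), coll, u, de_mirnas = "mirZ")
  expect_equal(nrow(empty), 0L)
})

test_that("delta index reproduces the published worked rows", {
  # self-consistent printed rows, inputs rounded to two decimals
  expect_equal(delta_index(48.07, 19.65, 1.134), 32.24, tolerance = 0.005)
  expect_equal(delta_index(23.47, 8.02, 1.432), 22.14, tolerance = 0.005)
  expect_equal(delta_index(4.75, 0.78, 2.608), 10.36, tolerance = 0.005)
  expect_equal(delta_index(3.99, 0.701, 2.312), 7.61, tolerance = 0.005)
  expect_equal(delta_index(5, 5, 2.3), 0)
  # sign agreement between expression change and fold change
  expect_gt(delta_index(10, 2, 1.5), 0)
  expect_gt(delta_index(2, 10, -1.5), 0)
  expect_lt(delta_index(2, 10, 1.5), 0)
  expect_error(delta_index(Inf, 1, 1), "finite")
})

test_that("delta_table summarizes DE miRNAs from a DEA result", {
  lab <- make_labels(3, 3)
  cnt <- make_balanced_counts(
    list(c(900, 910, 905, 30, 35, 40), c(50, 40, 45, 800, 790, 810),
         c(300, 300, 300, 300, 300, 295)), lab)
  res <- nb_exact_test(cnt, lab, dispersion = 0.01)
  dt <- delta_table(res)
  expect_setequal(dt$mirna, c("g01", "g02"))
  expect_equal(dt$delta,
               delta_index(dt$ex_bc, dt$ex_ns, dt$logFC))
  expect_true(all(dt$delta > 0))
  expect_equal(dt$delta, sort(dt$delta, decreasing = TRUE))
})
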