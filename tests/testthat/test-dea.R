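test_that("quantile_filter keeps features strictly above the mean quantile", {
  m <- matrix(1:4, 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  # type-7 quantile of {1,2,3,4} at 0.25 is 1.75
  expect_setequal(rownames(quantile_filter(m, 0.25)), c("g2", "g3", "g4"))
  # equal means: the quantile equals every mean, strict ">" removes all
  m2 <- matrix(5, 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_equal(nrow(quantile_filter(m2, 0.25)), 0L)
  # q -> 0 with distinct means: everything above the minimum survives; the
  # minimum itself sits exactly at the limiting quantile, and the strict
  # ">" rule (see the equal-means case above) excludes it
  expect_setequal(rownames(quantile_filter(m, 1e-9)), c("g2", "g3", "g4"))
  expect_error(quantile_filter(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(quantile_filter(m, q = 1), "in \\(0, 1\\)")
})

test_that("bh_adjust matches the step-up oracle and handles edge cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("exact NB test: identical groups give p = 1", {
  lab <- make_labels(2, 2)
  cnt <- make_balanced_counts(list(c(10, 10, 10, 10), c(3, 3, 3, 3)), lab)
  res <- nb_exact_test(cnt, lab, dispersion = 0)
  expect_equal(res$pvalue, c(1, 1))
  expect_equal(res$logFC, c(0, 0))
})

test_that("exact NB test reduces to the binomial exact test in the Poisson limit", {
  lab <- make_labels(2, 2)
  # equal library sizes (25 per sample) so normalization is the identity
  cnt <- make_balanced_counts(list(c(0, 0, 20, 20), c(25, 25, 5, 5)), lab)
  res <- nb_exact_test(cnt, lab, dispersion = 0)
  # conditional on the total 40 split between two equal groups, the null is
  # Binomial(40, 1/2); the two-sided minimum-likelihood rule matches
  expect_equal(res$pvalue[1], binom.test(0, 40, 0.5)$p.value, tolerance = 1e-10)
  expect_equal(res$pvalue[2], binom.test(50, 60, 0.5)$p.value, tolerance = 1e-10)
})

test_that("exact NB test is symmetric under group-label swap", {
  set.seed(7)
  lab <- make_labels(4, 3)
  cnt <- matrix(rnbinom(7 * 30, size = 8, mu = 60), 30,
                dimnames = list(sprintf("g%02d", 1:30), lab$sample))
  swapped <- lab
  swapped$class <- ifelse(lab$class == "tumor", "normal", "tumor")
  a <- nb_exact_test(cnt, lab, dispersion = 0.1)
  b <- nb_exact_test(cnt, swapped, dispersion = 0.1)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
})

test_that("exact NB test rejects bad input with informative errors", {
  lab <- make_labels(2, 2)
  cnt <- make_balanced_counts(list(c(1.5, 2, 2, 2), c(2, 2, 2, 2)), lab)
  expect_error(nb_exact_test(cnt, lab, 0.1), "non-integer.*g01")
  cnt0 <- make_balanced_counts(list(c(0, 0, 3, 3)), lab)
  expect_error(nb_exact_test(cnt0, lab, 0.1), "zero total count")
  lab1 <- make_labels(1, 3)
  cnt1 <- matrix(5, 2, 4, dimnames = list(c("a", "b"), lab1$sample))
  expect_error(nb_exact_test(cnt1, lab1, 0.1), "at least 2 samples")
})

test_that("type-I error of the exact test is calibrated on a simulated null", {
  set.seed(101)
  n_feat <- 2000
  lab <- make_labels(8, 8)
  phi <- 0.1
  mu <- exp(runif(n_feat, log(20), log(500)))
  cnt <- matrix(rnbinom(n_feat * 16, size = 1 / phi, mu = rep(mu, 16)),
                nrow = n_feat, dimnames = list(sprintf("f%04d", 1:n_feat),
                                               lab$sample))
  res <- nb_exact_test(cnt, lab, dispersion = phi)
  rate <- mean(res$pvalue <= 0.05)
  ci <- binom.test(round(0.05 * n_feat), n_feat)$conf.int
  # exact discrete tests are conservative; the rejection rate must not
  # exceed the nominal level and should stay near it
  expect_lt(rate, ci[2] + 0.01)
  expect_gt(rate, 0.01)
})

test_that("common dispersion estimate recovers the generating value", {
  st <- simulate_crosstalk_study(
    sim_config(n_tumor = 20, n_normal = 20, n_genes = 500, n_mirnas = 20,
               n_pathways = 4, pathway_size_range = c(5, 10),
               n_de_genes = 20, nb_dispersion = 0.1, n_crosstalk_pairs = 0,
               seed = 5))
  phi <- estimate_common_dispersion(st$mrna, st$labels)
  expect_gt(phi, 0.06)
  expect_lt(phi, 0.16)
})

test_that("exact test p-values track edgeR's exact test on common-dispersion data", {
  set.seed(33)
  lab <- make_labels(6, 6)
  n_feat <- 300
  mu <- exp(runif(n_feat, log(30), log(400)))
  lfc <- sample(c(0, 0, 0, 1.5, -1.5), n_feat, replace = TRUE)
  mu_mat <- outer(mu, rep(1, 12))
  mu_mat[, 1:6] <- mu_mat[, 1:6] * 2^lfc
  cnt <- matrix(rnbinom(n_feat * 12, size = 10, mu = mu_mat), nrow = n_feat,
                dimnames = list(sprintf("f%03d", 1:n_feat), lab$sample))
  res <- nb_exact_test(cnt, lab, dispersion = 0.1)
  dge <- edgeR::DGEList(counts = cnt,
                        group = factor(lab$class, c("normal", "tumor")))
  dge <- edgeR::calcNormFactors(dge, method = "none")
  et <- edgeR::exactTest(edgeR::estimateCommonDisp(dge))
  rho <- cor(log10(res$pvalue + 1e-300),
             log10(et$table$PValue + 1e-300), method = "spearman")
  expect_gt(rho, 0.95)
  # and the DE calls agree closely at the standard cut
  ours <- res$feature[res$is_de]
  theirs <- rownames(et$table)[p.adjust(et$table$PValue, "BH") < 0.01 &
                                 abs(et$table$logFC) > 1]
  expect_gt(length(intersect(ours, theirs)) /
              max(1, length(union(ours, theirs))), 0.85)
})

test_that("call_de applies strict thresholds on |logFC| and FDR", {
  res <- tibble::tibble(
    feature = c("a", "b", "c", "d"),
    logFC = c(1.0, -2, 3, 0.5),
    fdr = c(0.001, 0.001, 0.2, 0.001)
  )
  # logFC exactly 1 is excluded; negative logFC counts by absolute value
  expect_setequal(call_de(res), "b")
  expect_equal(call_de(res[0, ]), character(0))
})

test_that("stronger planted effects never weaken the planted genes' evidence", {
  med_logp <- vapply(c(1, 2, 3), function(lfc) {
    st <- simulate_crosstalk_study(
      sim_config(n_tumor = 15, n_normal = 15, n_genes = 300, n_mirnas = 20,
                 n_pathways = 4, pathway_size_range = c(5, 10),
                 n_de_genes = 30, planted_logfc = lfc, nb_dispersion = 0.1,
                 n_crosstalk_pairs = 0, seed = 77))
    res <- nb_exact_test(st$mrna, st$labels, dispersion = 0.1)
    stats::median(-log10(res$pvalue[res$feature %in% st$truth$de_genes]))
  }, numeric(1))
  expect_true(all(diff(med_logp) >= 0))
})
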