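test_that("pathway activity reduces to the two-point mean and sample SD", {
  expr <- matrix(c(3, 5, 2, 2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  act <- pathway_activity(expr, list(P = c("g1", "g2")), transform = FALSE)
  expect_equal(act$M["s1", "P"], 4)
  expect_equal(act$S["s1", "P"], sqrt(2))
  expect_equal(act$S["s2", "P"], 0) # constant member genes
  # member order is irrelevant
  act2 <- pathway_activity(expr, list(P = c("g2", "g1")), transform = FALSE)
  expect_equal(act$M, act2$M)
  expect_equal(act$S, act2$S)
})

test_that("pathway activity warns about absent genes and drops thin pathways", {
  expr <- matrix(1:6, 3, 2,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_warning(
    act <- pathway_activity(expr, list(A = c("g1", "g2", "ghost")),
                            transform = FALSE),
    "absent")
  expect_warning(
    expect_warning(
      pathway_activity(expr, list(A = c("g1", "g2"), B = c("g3", "ghost")),
                       transform = FALSE),
      "absent"),
    "dropped")
  expect_error(
    suppressWarnings(pathway_activity(expr, list(B = c("g3", "ghost")),
                                      transform = FALSE)),
    ">= 2 genes")
})

test_that("ds_score follows the signed signal-to-noise definition", {
  expect_equal(ds_score(2, 0.5, 1, 0.5), 1)
  expect_equal(ds_score(3, 1, 3, 4), 0)
  # antisymmetry
  expect_equal(ds_score(2.2, 0.3, 1.1, 0.9), -ds_score(1.1, 0.9, 2.2, 0.3))
  # zero spread: equal means give 0, unequal means are clipped
  expect_equal(ds_score(1, 0, 1, 0), 0)
  expect_equal(suppressMessages(ds_score(2, 0, 1, 0)), 1e6)
  expect_equal(suppressMessages(ds_score(1, 0, 2, 0, cap = 10)), -10)
  expect_error(ds_score(NA, 1, 1, 1), "NA")
})

test_that("ds_matrix enumerates canonical pairs: C(P,2) columns", {
  mkact <- function(P, n = 3) {
    M <- matrix(rnorm(n * P), n, P,
                dimnames = list(paste0("s", 1:n), sprintf("PW%02d", 1:P)))
    S <- matrix(abs(rnorm(n * P)) + 0.1, n, P, dimnames = dimnames(M))
    make_activity(M, S)
  }
  set.seed(2)
  expect_equal(ncol(ds_matrix(mkact(2))) - 1L, 1L)
  d48 <- ds_matrix(mkact(48))
  expect_equal(ncol(d48) - 1L, choose(48, 2))
  expect_equal(ncol(d48) - 1L, 1128L)
  # canonical lexicographic order, "A|B" with A < B
  pairs <- attr(d48, "pairs")
  expect_true(all(pairs$pathway_a < pairs$pathway_b))
  expect_equal(pairs$pair, sort(pairs$pair))
})

test_that("identical pathways score zero and affine shifts leave DS unchanged", {
  set.seed(5)
  expr <- matrix(rnorm(40, 8, 2), 8, 5,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  coll <- list(A = paste0("g", 1:4), B = paste0("g", 1:4),
               C = paste0("g", 5:8))
  act <- pathway_activity(expr, coll, transform = FALSE)
  dsm <- ds_matrix(act)
  expect_equal(dsm[["A|B"]], rep(0, 5))
  # x -> x + c: means shift together, spreads unchanged
  act2 <- pathway_activity(expr + 3.7, coll, transform = FALSE)
  expect_equal(ds_matrix(act2)[["A|C"]], dsm[["A|C"]], tolerance = 1e-12)
})

test_that("shuffling samples permutes DS rows without changing values", {
  set.seed(6)
  expr <- matrix(rpois(60, 50), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  coll <- list(A = paste0("g", 1:5), B = paste0("g", 6:10))
  d1 <- ds_matrix(pathway_activity(expr, coll))
  perm <- c(4, 1, 6, 2, 5, 3)
  d2 <- ds_matrix(pathway_activity(expr[, perm], coll))
  expect_equal(d2[match(d1$sample, d2$sample), ], d1, ignore_attr = TRUE)
})

test_that("euclidean comparator is |Mx - My| and relates to DS algebraically", {
  set.seed(9)
  M <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  S <- matrix(abs(rnorm(12)) + 0.2, 4, 3, dimnames = dimnames(M))
  act <- make_activity(M, S)
  eu <- euclidean_crosstalk(act)
  ds <- ds_matrix(act)
  expect_equal(eu[["A|B"]], abs(M[, "A"] - M[, "B"]), ignore_attr = TRUE)
  # |M_A - M_B| = |DS| * (S_A + S_B)
  expect_equal(eu[["A|B"]], abs(ds[["A|B"]]) * (S[, "A"] + S[, "B"]),
               ignore_attr = TRUE)
})

test_that("planted pairs separate classes more than background pairs", {
  hits <- vapply(1:3, function(s) {
    st <- simulate_crosstalk_study(
      sim_config(n_tumor = 25, n_normal = 25, n_genes = 500, n_mirnas = 20,
                 n_pathways = 10, pathway_size_range = c(12, 25),
                 n_de_genes = 70, planted_logfc = 2.5, nb_dispersion = 0.08,
                 n_crosstalk_pairs = 1, seed = s))
    act <- pathway_activity(st$mrna, st$pathways)
    dsm <- ds_matrix(act)
    tum <- st$labels$class[match(dsm$sample, st$labels$sample)] == "tumor"
    sep <- vapply(setdiff(names(dsm), "sample"), function(p) {
      x <- dsm[[p]]
      abs(mean(x[tum]) - mean(x[!tum])) /
        sqrt(stats::var(x[tum]) / sum(tum) + stats::var(x[!tum]) / sum(!tum))
    }, numeric(1))
    planted <- st$truth$crosstalk_pairs$pair
    mean(sep[planted] >= stats::quantile(sep[setdiff(names(sep), planted)],
                                         0.9))
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
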