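#' Stratified Monte Carlo cross-validation split
#'
#' One random train/test partition preserving the tumor/normal proportions:
#' `round(n_class * train_frac)` samples of each class go to training, the
#' rest to testing.
#'
#' @param labels data frame with columns `sample`, `class`.
#' @param train_frac training fraction in (0, 1), default 0.6.
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with character vectors `train` and `test` (sample ids).
#' @export
mccv_split <- function(labels, train_frac = 0.6, seed = 1) {
  .assert_labels(labels)
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must be in (0, 1): both partitions must be non-empty.")
  }
  cls <- split(labels$sample, labels$class)
  if (any(lengths(cls) < 2L)) abort("each class needs at least 2 samples.")
  picks <- withr::with_seed(seed, {
    lapply(cls, function(s) sample(s, round(length(s) * train_frac)))
  })
  if (any(lengths(picks) == 0L) ||
      any(lengths(cls) - lengths(picks) == 0L)) {
    abort("`train_frac` leaves a class empty in train or test.")
  }
  train <- unlist(picks, use.names = FALSE)
  list(train = train, test = setdiff(labels$sample, train))
}

# stratified fold assignment: within each class, shuffle then deal round-robin
.stratified_folds <- function(class, k, seed) {
  fold <- integer(length(class))
  withr::with_seed(seed, {
    for (cl in unique(class)) {
      idx <- sample(which(class == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

.rf_prob <- function(x_train, y_train, x_test, ntree, seed) {
  fit <- ranger::ranger(
    y = factor(y_train, levels = c("normal", "tumor")),
    x = data.frame(x = x_train),
    num.trees = ntree, mtry = 1, probability = TRUE,
    seed = seed, num.threads = 1, verbose = FALSE
  )
  stats::predict(fit, data.frame(x = x_test),
                 num.threads = 1, verbose = FALSE)$predictions[, "tumor"]
}

#' Cross-validated random-forest AUC of a single feature
#'
#' Fits a random forest (500 trees by default, `mtry = sqrt(p) = 1` for the
#' single feature) in a stratified k-fold cross-validation and returns the
#' mean out-of-fold AUC for discriminating tumor from normal. This is the
#' per-pathway-pair ranking statistic of the selection stage.
#'
#' @param x numeric feature vector, aligned with `labels` rows.
#' @param labels data frame with columns `sample`, `class`.
#' @param k folds (default 10); reduced with a warning when a class has
#'   fewer than `k` samples.
#' @param ntree trees per forest (default 500).
#' @param seed integer seed controlling folds and forests.
#' @return mean out-of-fold AUC in \[0, 1\]. A constant feature returns 0.5
#'   with a warning.
#' @export
pair_auc <- function(x, labels, k = 10, ntree = 500, seed = 1) {
  .assert_labels(labels)
  if (length(x) != nrow(labels)) abort("`x` and `labels` lengths differ.")
  if (anyNA(x)) abort("`x` contains NA.")
  if (sd(x) == 0) {
    warn("constant feature: AUC is 0.5 by convention.")
    return(0.5)
  }
  min_class <- min(table(labels$class))
  if (min_class < k) {
    warn(paste0("k reduced from ", k, " to ", min_class,
                " (smallest class size)."))
    k <- min_class
  }
  fold <- .stratified_folds(labels$class, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    te <- fold == f
    p <- .rf_prob(x[!te], labels$class[!te], x[te], ntree, seed + f)
    .auc(p, labels$class[te])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# train-AUC ranking of every feature column on the training samples,
# then held-out AUC of the selected top features
.bootstrap_rank <- function(features, labels, split, top_n, k, ntree, seed) {
  tr <- match(split$train, features$sample)
  te <- match(split$test, features$sample)
  lab_tr <- labels[match(split$train, labels$sample), ]
  lab_te <- labels[match(split$test, labels$sample), ]
  feat_names <- setdiff(names(features), "sample")
  if (length(feat_names) == 0L) return(NULL)
  train_auc <- vapply(feat_names, function(nm) {
    suppressWarnings(pair_auc(features[[nm]][tr], lab_tr, k, ntree, seed))
  }, numeric(1))
  ord <- order(-train_auc, feat_names)
  top <- head(ord, top_n)
  test_auc <- vapply(feat_names[top], function(nm) {
    p <- .rf_prob(features[[nm]][tr], lab_tr$class, features[[nm]][te],
                  ntree, seed)
    .auc(p, lab_te$class)
  }, numeric(1))
  tibble(pair = feat_names[top], rank = seq_along(top),
         train_auc = unname(train_auc[top]), test_auc = unname(test_auc))
}

# one full-pipeline pass on the training samples: DEA -> PEA -> DS features
# for all samples, using only training information to pick genes and pathways
.refit_features <- function(refit, labels, split) {
  lab_tr <- labels[match(split$train, labels$sample), ]
  kept <- quantile_filter(refit$counts[, split$train, drop = FALSE], refit$q)
  der <- nb_exact_test(kept, lab_tr, dispersion = refit$dispersion,
                       logfc_cut = refit$logfc_cut, fdr_cut = refit$fdr_cut)
  deg <- call_de(der, refit$logfc_cut, refit$fdr_cut)
  coll <- suppressMessages(
    restrict_collection(refit$collection, rownames(kept), refit$min_size)
  )
  enr <- enrich_all(deg, coll, alpha = refit$alpha)
  sig <- enr$pathway[enr$significant]
  if (length(sig) < 2L) return(NULL)
  act <- suppressWarnings(
    pathway_activity(refit$counts[, labels$sample, drop = FALSE], coll[sig])
  )
  ds_matrix(act)
}

#' Monte Carlo cross-validated pathway-pair selection
#'
#' Repeats `n_bootstraps` stratified 60/40 train/test splits. In each
#' bootstrap every feature (pathway-pair Discriminating Score column) is
#' ranked by its stratified k-fold cross-validated random-forest AUC on the
#' training samples; the `top_n` features are kept (ties broken by name) and
#' validated on the held-out samples. The per-bootstrap top lists are then
#' aggregated into a frequency ranking: a pair that discriminates robustly is
#' selected in many bootstraps.
#'
#' In full-pipeline mode (`refit` supplied) the differential expression,
#' pathway enrichment and Discriminating Score stages are recomputed from the
#' training samples of every bootstrap, so feature selection never sees the
#' test samples. In fixed-feature mode the supplied `features` table is used
#' as-is for every bootstrap.
#'
#' @param features tibble with a `sample` column and one numeric column per
#'   feature (e.g. from [ds_matrix()]); ignored when `refit` is given.
#' @param labels data frame with columns `sample`, `class`.
#' @param n_bootstraps number of random splits (default 50).
#' @param train_frac training fraction (default 0.6).
#' @param top_n size of each per-bootstrap top list (default 10).
#' @param k,ntree cross-validation folds and forest size; see [pair_auc()].
#' @param seed master seed; per-bootstrap seeds are drawn from it once, so
#'   results do not depend on evaluation order.
#' @param refit optional list for full-pipeline mode: `counts` (gene x sample
#'   matrix covering all samples), `collection` (full pathway list), and
#'   stage parameters `q`, `dispersion`, `logfc_cut`, `fdr_cut`, `alpha`,
#'   `min_size` (defaults 0.25, "auto", 1, 0.01, 0.01, 5).
#' @return an `mccv_result`: list with `selections` (one row per bootstrap x
#'   selected pair: rank, train and test AUC), `ranking` (pair, frequency,
#'   mean train/test AUC, sorted by decreasing frequency), and `splits`.
#' @export
run_mccv <- function(features = NULL, labels, n_bootstraps = 50,
                     train_frac = 0.6, top_n = 10, k = 10, ntree = 500,
                     seed = 1, refit = NULL) {
  .assert_labels(labels)
  if (is.null(refit)) {
    if (is.null(features) || !"sample" %in% names(features)) {
      abort("`features` must have a `sample` column (or supply `refit`).")
    }
    if (!setequal(features$sample, labels$sample)) {
      abort("`features` and `labels` sample sets differ.")
    }
  } else {
    defaults <- list(q = 0.25, dispersion = "auto", logfc_cut = 1,
                     fdr_cut = 0.01, alpha = 0.01, min_size = 5)
    refit <- utils::modifyList(defaults, refit)
    if (is.null(refit$counts) || is.null(refit$collection)) {
      abort("`refit` needs `counts` and `collection`.")
    }
  }
  if (n_bootstraps < 1L) {
    warn("n_bootstraps = 0: nothing to run.")
    return(structure(list(selections = tibble(), ranking = tibble(),
                          splits = tibble(), n_bootstraps = 0L,
                          top_n = top_n),
                     class = "mccv_result"))
  }
  boot_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_bootstraps)
  })
  sel <- vector("list", n_bootstraps)
  spl <- vector("list", n_bootstraps)
  for (b in seq_len(n_bootstraps)) {
    split <- mccv_split(labels, train_frac, boot_seeds[b])
    spl[[b]] <- tibble(bootstrap = b,
                       sample = c(split$train, split$test),
                       role = rep(c("train", "test"),
                                  c(length(split$train), length(split$test))))
    feats <- if (is.null(refit)) features else {
      .refit_features(refit, labels, split)
    }
    if (is.null(feats)) {
      warn(paste0("bootstrap ", b, ": fewer than 2 enriched pathways; ",
                  "no pairs selected."))
      next
    }
    res <- .bootstrap_rank(feats, labels, split, top_n, k, ntree,
                           boot_seeds[b])
    if (!is.null(res)) sel[[b]] <- dplyr::mutate(res, bootstrap = b,
                                                 .before = 1)
  }
  selections <- dplyr::bind_rows(sel)
  ranking <- if (nrow(selections)) {
    selections |>
      dplyr::group_by(.data$pair) |>
      dplyr::summarise(frequency = dplyr::n(),
                       mean_train_auc = mean(.data$train_auc),
                       mean_test_auc = mean(.data$test_auc),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$frequency),
                     dplyr::desc(.data$mean_train_auc), .data$pair)
  } else tibble()
  structure(list(selections = selections, ranking = ranking,
                 splits = dplyr::bind_rows(spl),
                 n_bootstraps = n_bootstraps, top_n = top_n, seed = seed),
            class = "mccv_result")
}

#' Baseline classification on raw expression features
#'
#' The comparison arm of the selection stage: instead of pathway-pair scores,
#' individual features' expression levels (e.g. transcription factors among
#' the DEGs, or differentially expressed miRNAs) enter the same Monte Carlo
#' cross-validated random-forest protocol, giving a per-feature top-list
#' frequency ranking directly comparable to the pathway-pair ranking.
#'
#' @param counts raw count matrix (features x samples).
#' @param labels data frame with columns `sample`, `class`.
#' @param features character vector of feature ids to use (must be
#'   non-empty and present in `counts`).
#' @param ... passed to [run_mccv()] (`n_bootstraps`, `seed`, ...).
#' @return an `mccv_result` over single-feature "pairs".
#' @export
baseline_classifier <- function(counts, labels, features, ...) {
  features <- intersect(features, rownames(counts))
  if (length(features) == 0L) abort("`features` is empty or absent from `counts`.")
  expr <- log2(.normalize_counts(counts[, labels$sample, drop = FALSE]) + 1)
  tab <- tibble(sample = labels$sample)
  for (f in features) tab[[f]] <- expr[f, ]
  run_mccv(tab, labels, ...)
}

#' @export
print.mccv_result <- function(x, ...) {
  cat("<mccv_result> ", x$n_bootstraps, " bootstraps, top-", x$top_n,
      " lists\n", sep = "")
  if (nrow(x$ranking)) print(head(x$ranking, 10))
  invisible(x)
}

#' @export
tidy.mccv_result <- function(x, ...) x$ranking

#' @export
glance.mccv_result <- function(x, ...) {
  tibble(
    n_bootstraps = x$n_bootstraps,
    n_pairs_selected = nrow(x$ranking),
    top_frequency = if (nrow(x$ranking)) max(x$ranking$frequency) else NA_integer_,
    mean_test_auc = if (nrow(x$selections)) mean(x$selections$test_auc) else NA_real_
  )
}

#' Selection-frequency plot of an MCCV ranking
#'
#' @param object an `mccv_result`.
#' @param top number of pairs shown (default 15).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.mccv_result <- function(object, top = 15, ...) {
  d <- head(object$ranking, top)
  ggplot2::ggplot(d, ggplot2::aes(.data$frequency,
                                  stats::reorder(.data$pair, .data$frequency),
                                  fill = .data$mean_test_auc)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("bootstraps in top-", object$top_n, " (of ",
                             object$n_bootstraps, ")"),
                  y = NULL, fill = "mean test AUC") +
    ggplot2::theme_minimal()
}
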