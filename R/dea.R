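#' Filter features by mean expression quantile
#'
#' Keeps the features whose mean expression across all samples is strictly
#' greater than the `q` quantile of all per-feature means. This reproduces the
#' usual pre-filter applied before differential expression testing so that
#' barely-expressed features do not dilute the multiple-testing correction.
#'
#' @param counts numeric matrix, features in rows, samples in columns.
#' @param q quantile in (0, 1); the default drops roughly the bottom quarter.
#'   The quantile of the per-feature means is computed by linear interpolation
#'   (type 7), and the comparison is strict, so when all means are identical
#'   no feature survives.
#' @return the row-subset of `counts` (sample set unchanged).
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
#' rownames(quantile_filter(m, 0.25)) # g2, g3, g4
#' @export
quantile_filter <- function(counts, q = 0.25) {
  if (!is.matrix(counts) || ncol(counts) < 1L || nrow(counts) < 1L) {
    abort("`counts` must be a non-empty features x samples matrix.")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    abort("`q` must be a single number in (0, 1).")
  }
  mu <- rowMeans(counts)
  counts[mu > quantile(mu, q, type = 7), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validating wrapper around
#' [stats::p.adjust()] so every stage of the pipeline shares one code path.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA`/`NaN` are rejected.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p)) abort("`p` contains NA/NaN values.")
  if (any(p < 0 | p > 1)) abort("`p` values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

# conditional log-likelihood of a common dispersion phi, given per-gene group
# totals, on library-equalized integer pseudo-counts (qCML-style)
.common_disp_cll <- function(phi, groups) {
  r <- 1 / phi
  ll <- 0
  for (Y in groups) {
    n <- ncol(Y)
    z <- rowSums(Y)
    ll <- ll + sum(rowSums(lgamma(Y + r)) - n * lgamma(r) +
                     lgamma(n * r) - lgamma(z + n * r))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of a single dispersion shared by
#' all features, computed on library-equalized pseudo-counts given the
#' per-group totals. This is the common-dispersion regime of the
#' quantile-adjusted conditional maximum likelihood estimator, with the
#' quantile adjustment simplified to mean-scaling of libraries to their
#' geometric mean.
#'
#' @param counts integer count matrix (features x samples).
#' @param labels data frame with columns `sample`, `class` ("tumor"/"normal").
#' @return the estimated dispersion (variance = mu + phi * mu^2).
#' @export
estimate_common_dispersion <- function(counts, labels) {
  .assert_labels(labels)
  pseudo <- round(.normalize_counts(counts[, labels$sample, drop = FALSE]))
  groups <- lapply(c("tumor", "normal"), function(cl) {
    pseudo[, labels$class == cl, drop = FALSE]
  })
  opt <- optimize(function(lphi) .common_disp_cll(exp(lphi), groups),
                  interval = c(log(1e-6), log(20)), maximum = TRUE, tol = 1e-4)
  phi <- exp(opt$maximum)
  # boundary: likelihood still rising toward phi -> 0 means Poisson-like data
  if (phi < 2e-6) phi <- 0
  phi
}

# exact two-sided NB test p-values, vectorized over features: condition on
# the total of the two group sums; two-sided by summing all outcomes no more
# likely than the observed one (the same rule binom.test uses)
.nb_exact_p <- function(s1, s2, n1, n2, phi) {
  t_all <- s1 + s2
  p_out <- rep(1, length(t_all))
  todo <- which(t_all > 0)
  if (!length(todo)) return(p_out)
  # support window: the summation runs over 15 conditional standard
  # deviations around the conditional mode and the observed split, clamped
  # to [0, t]; the neglected tail mass is < 1e-12 and always belongs to the
  # rejection sum, so p-values are exact to far below reporting precision
  mu_all <- t_all / (n1 + n2)
  v1 <- n1 * mu_all * (1 + mu_all * max(phi, 0))
  v2 <- n2 * mu_all * (1 + mu_all * max(phi, 0))
  w <- ceiling(15 * sqrt(v1 * v2 / pmax(v1 + v2, 1e-12))) + 16
  ctr <- t_all * n1 / (n1 + n2)
  lo_all <- pmax(0, floor(pmin(ctr, s1) - w))
  hi_all <- pmin(t_all, ceiling(pmax(ctr, s1) + w))
  # chunk so the expanded grids stay within ~2e6 cells at a time
  chunks <- split(todo, ceiling(cumsum(hi_all[todo] - lo_all[todo] + 1) / 2e6))
  for (idx in chunks) {
    t_vec <- t_all[idx]
    reps <- hi_all[idx] - lo_all[idx] + 1
    g <- rep(seq_along(idx), reps)
    a <- lo_all[idx][g] + sequence(reps) - 1
    mu <- mu_all[idx]
    if (phi <= 0) {
      lp <- dpois(a, (n1 * mu)[g], log = TRUE) +
        dpois(t_vec[g] - a, (n2 * mu)[g], log = TRUE)
    } else {
      r <- 1 / phi
      lp <- dnbinom(a, size = n1 * r, mu = (n1 * mu)[g], log = TRUE) +
        dnbinom(t_vec[g] - a, size = n2 * r, mu = (n2 * mu)[g], log = TRUE)
    }
    # lp is bounded below by the mode of a discrete conditional law, so
    # direct exponentiation cannot underflow to an all-zero feature
    pr <- exp(lp)
    tot <- rowsum(pr, g)[, 1]
    obs <- pr[cumsum(reps) - reps + (s1[idx] - lo_all[idx]) + 1] # a == s1
    keep <- pr <= (obs * (1 + 1e-8))[g]
    p_out[idx] <- pmin(1, rowsum(pr * keep, g)[, 1] / tot)
  }
  p_out
}

#' Exact negative-binomial differential expression test
#'
#' Two-sided exact test for a difference in mean expression between tumor and
#' normal samples, assuming negative-binomial counts with a common dispersion.
#' Library sizes are equalized by scaling every sample to the geometric-mean
#' library size (pseudo-counts rounded to integers for the exact test); the
#' test then conditions on the total pseudo-count of each feature, under which
#' the split between the two groups has a known distribution. Log fold changes
#' are computed from normalized group means with a pseudo-count of 0.5,
#' `log2((mean_tumor + 0.5) / (mean_normal + 0.5))`, so features absent from
#' one group stay finite.
#'
#' @param counts integer count matrix (features x samples).
#' @param labels data frame with columns `sample` and `class`
#'   ("tumor"/"normal"); both groups need at least 2 samples.
#' @param dispersion a nonnegative common dispersion, or `"auto"` to estimate
#'   it with [estimate_common_dispersion()]. Zero gives the Poisson limit.
#' @param logfc_cut,fdr_cut thresholds used for the `is_de` call; see
#'   [call_de()].
#' @return a `dea_result` tibble with columns `feature`, `logFC`, `pvalue`,
#'   `fdr`, `mean_tumor`, `mean_normal`, `is_de`, ordered as the input rows.
#' @seealso [quantile_filter()], [call_de()], [dea()]
#' @export
nb_exact_test <- function(counts, labels, dispersion = "auto",
                          logfc_cut = 1, fdr_cut = 0.01) {
  .assert_labels(labels)
  if (is.null(rownames(counts))) abort("`counts` must have feature rownames.")
  counts <- counts[, labels$sample, drop = FALSE]
  nonint <- rowSums(counts != round(counts)) > 0
  if (any(nonint)) {
    abort(paste0("non-integer counts for feature(s): ",
                 paste(head(rownames(counts)[nonint], 5), collapse = ", ")))
  }
  n1 <- sum(labels$class == "tumor")
  n2 <- sum(labels$class == "normal")
  if (n1 < 2L || n2 < 2L) abort("each class needs at least 2 samples.")
  for (cl in c("tumor", "normal")) {
    sub <- counts[, labels$class == cl, drop = FALSE]
    if (sum(sub) == 0) abort(paste0("group '", cl, "' has zero total count."))
  }
  if (identical(dispersion, "auto")) {
    dispersion <- estimate_common_dispersion(counts, labels)
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("`dispersion` must be a nonnegative number or \"auto\".")
  }

  norm <- .normalize_counts(counts)
  pseudo <- round(norm)
  tum <- labels$class == "tumor"
  s1 <- rowSums(pseudo[, tum, drop = FALSE])
  s2 <- rowSums(pseudo[, !tum, drop = FALSE])
  pval <- .nb_exact_p(s1, s2, n1, n2, dispersion)

  mean_t <- rowMeans(norm[, tum, drop = FALSE])
  mean_n <- rowMeans(norm[, !tum, drop = FALSE])
  res <- tibble(
    feature = rownames(counts),
    logFC = unname(log2((mean_t + 0.5) / (mean_n + 0.5))),
    pvalue = pval,
    fdr = bh_adjust(pval),
    mean_tumor = unname(mean_t),
    mean_normal = unname(mean_n)
  )
  res$is_de <- res$feature %in% call_de(res, logfc_cut, fdr_cut)
  structure(res, class = c("dea_result", class(res)),
            dispersion = dispersion,
            logfc_cut = logfc_cut, fdr_cut = fdr_cut)
}

#' Call differentially expressed features
#'
#' Applies the standard cut of absolute log2 fold change strictly above
#' `logfc_cut` and BH-adjusted p strictly below `fdr_cut`.
#'
#' @param results a data frame with columns `feature`, `logFC`, `fdr`.
#' @param logfc_cut,fdr_cut thresholds (defaults 1 and 0.01).
#' @return character vector of feature ids.
#' @export
call_de <- function(results, logfc_cut = 1, fdr_cut = 0.01) {
  if (nrow(results) == 0L) return(character(0))
  results$feature[abs(results$logFC) > logfc_cut & results$fdr < fdr_cut]
}

#' Differential expression analysis with quantile pre-filtering
#'
#' Convenience wrapper chaining [quantile_filter()] and [nb_exact_test()]:
#' the default workflow for one expression layer (mRNA or miRNA).
#'
#' @inheritParams nb_exact_test
#' @param q mean-expression quantile for the pre-filter.
#' @return a `dea_result` tibble (see [nb_exact_test()]); the filtered feature
#'   universe is attached as attribute `universe`.
#' @export
dea <- function(counts, labels, q = 0.25, dispersion = "auto",
                logfc_cut = 1, fdr_cut = 0.01) {
  kept <- quantile_filter(counts, q)
  res <- nb_exact_test(kept, labels, dispersion, logfc_cut, fdr_cut)
  attr(res, "universe") <- rownames(kept)
  res
}

#' @export
glance.dea_result <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_de = sum(x$is_de),
    dispersion = attr(x, "dispersion"),
    logfc_cut = attr(x, "logfc_cut"),
    fdr_cut = attr(x, "fdr_cut")
  )
}

#' Volcano plot of a differential expression result
#'
#' @param object a `dea_result` from [nb_exact_test()] or [dea()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.dea_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$logFC, -log10(.data$fdr),
                                       colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor vs normal)",
                  y = "-log10 FDR", colour = "DE") +
    ggplot2::theme_minimal()
}
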