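#' Kraskov k-nearest-neighbour mutual information
#'
#' Nonparametric mutual information estimate (in nats) between two sample
#' vectors, using entropy estimates from k-nearest-neighbour distances in the
#' max norm (the first Kraskov-Stoegbauer-Grassberger algorithm):
#' `psi(k) + psi(n) - mean(psi(nx+1) + psi(ny+1))`, where `nx` and `ny` count
#' the marginal neighbours strictly inside each point's distance to its k-th
#' joint neighbour. Count data produce tied distances that bias the neighbour
#' counts, so a deterministic uniform jitter of relative scale `jitter` is
#' added to both vectors before the neighbour search.
#'
#' @param x,y numeric vectors of equal length `n > k`.
#' @param k neighbour parameter (default 3).
#' @param jitter relative tie-breaking jitter scale (default 1e-10,
#'   multiplied by each vector's standard deviation).
#' @param jitter_seed seed for the jitter stream (default 0), so repeated
#'   calls are reproducible.
#' @return estimated mutual information in nats (can be slightly negative
#'   for independent data; the estimator is unbiased around 0).
#' @export
ksg_mi <- function(x, y, k = 3, jitter = 1e-10, jitter_seed = 0) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n <= k) abort("need more than `k` observations.")
  if (anyNA(x) || anyNA(y)) abort("NA values in input.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: MI is 0 by convention.")
    return(0)
  }
  withr::with_seed(jitter_seed, {
    x <- x + runif(n, -1, 1) * jitter * sd(x)
    y <- y + runif(n, -1, 1) * jitter * sd(y)
  })
  ksg_mi_cpp(x, y, as.integer(k))
}

#' Mutual information matrix between miRNAs and genes
#'
#' [ksg_mi()] for every miRNA x gene combination on matched samples; rows are
#' miRNAs, columns genes, values MI in nats.
#'
#' @param mirna,mrna numeric matrices (features x samples) sharing the same
#'   sample columns.
#' @param k neighbour parameter (default 3).
#' @param jitter,jitter_seed tie-breaking jitter; see [ksg_mi()].
#' @return an `mi_matrix`: numeric matrix with attribute `k`.
#' @export
mi_matrix <- function(mirna, mrna, k = 3, jitter = 1e-10, jitter_seed = 0) {
  if (ncol(mirna) != ncol(mrna)) abort("sample counts differ.")
  if (!is.null(colnames(mirna)) && !is.null(colnames(mrna))) {
    if (!identical(colnames(mirna), colnames(mrna))) {
      mrna <- mrna[, colnames(mirna), drop = FALSE]
    }
  }
  n <- ncol(mirna)
  if (n <= k) abort("need more than `k` samples.")
  jit <- function(m) {
    s <- apply(m, 1, sd)
    m + matrix(runif(length(m), -1, 1), nrow(m)) * jitter * pmax(s, 1e-300)
  }
  withr::with_seed(jitter_seed, {
    X <- t(jit(mirna))
    Y <- t(jit(mrna))
  })
  out <- mi_matrix_cpp(X, Y, as.integer(k))
  dimnames(out) <- list(rownames(mirna), rownames(mrna))
  structure(out, k = k, class = c("mi_matrix", "matrix", "array"))
}

#' Infer miRNA regulons from mutual information
#'
#' Turns the miRNA x gene MI matrix into per-miRNA target sets. Two rules are
#' available: `"permutation_fdr"` (default) builds a per-miRNA null by
#' recomputing MI after permuting the miRNA's sample order `n_perm` times
#' against all genes, converts each observed MI to a permutation p-value,
#' adjusts across genes with Benjamini-Hochberg and keeps genes below
#' `alpha`; `"top_k"` simply keeps each miRNA's `top_k` highest-MI genes.
#'
#' @param mirna,mrna expression matrices (features x samples) on matched
#'   samples.
#' @param rule `"permutation_fdr"` or `"top_k"`.
#' @param k KSG neighbour parameter (default 3).
#' @param alpha BH-adjusted significance cut for the permutation rule
#'   (default 0.05).
#' @param n_perm permutations per miRNA (default 20; the null pools across
#'   genes, so the effective null size is `n_perm * n_genes`).
#' @param top_k targets per miRNA for the `"top_k"` rule.
#' @param seed seed for the permutation draws.
#' @param mi optional precomputed [mi_matrix()] (skips recomputation).
#' @return a `regulon` tibble with columns `mirna`, `target`, `mi` and, for
#'   the permutation rule, `pvalue`, `fdr`; attributes record the rule and
#'   its settings.
#' @export
build_regulon <- function(mirna, mrna, rule = c("permutation_fdr", "top_k"),
                          k = 3, alpha = 0.05, n_perm = 20, top_k = 10,
                          seed = 1, mi = NULL) {
  rule <- match.arg(rule)
  if (is.null(mi)) mi <- mi_matrix(mirna, mrna, k = k)
  empty <- tibble(mirna = character(0), target = character(0),
                  mi = numeric(0))
  if (rule == "top_k") {
    out <- if (top_k < 1) empty else {
      purrr::map_dfr(rownames(mi), function(m) {
        ord <- order(-mi[m, ])[seq_len(min(top_k, ncol(mi)))]
        tibble(mirna = m, target = colnames(mi)[ord], mi = mi[m, ord])
      })
    }
  } else {
    perm_seeds <- withr::with_seed(seed, {
      sample.int(.Machine$integer.max - 1L, n_perm)
    })
    null_arr <- array(NA_real_, c(nrow(mi), ncol(mi), n_perm))
    for (p in seq_len(n_perm)) {
      shuf <- withr::with_seed(perm_seeds[p], {
        t(apply(mirna, 1, sample))
      })
      colnames(shuf) <- colnames(mirna)
      null_arr[, , p] <- mi_matrix(shuf, mrna, k = k,
                                   jitter_seed = perm_seeds[p])
    }
    # MI bias depends on each gene's tie structure, so standardize every
    # miRNA x gene cell against its own permutation null before pooling the
    # null across genes (pooling buys p-value resolution n_perm * n_genes)
    m_null <- apply(null_arr, c(1, 2), mean)
    s_null <- pmax(apply(null_arr, c(1, 2), sd), 1e-8)
    z_obs <- (unclass(mi) - m_null) / s_null
    z_null <- (null_arr - as.vector(m_null)) / as.vector(s_null)
    out <- purrr::map_dfr(seq_len(nrow(mi)), function(i) {
      nul <- as.vector(z_null[i, , ])
      pv <- (1 + vapply(z_obs[i, ], function(v) sum(nul >= v), numeric(1))) /
        (1 + length(nul))
      fdr <- bh_adjust(pv)
      keep <- fdr < alpha
      tibble(mirna = rownames(mi)[i], target = colnames(mi)[keep],
             mi = mi[i, keep], pvalue = pv[keep], fdr = fdr[keep])
    })
    if (nrow(out) == 0L) out <- dplyr::mutate(empty, pvalue = numeric(0),
                                              fdr = numeric(0))
  }
  structure(out, class = c("regulon", class(out)), rule = rule, k = k,
            alpha = alpha, n_perm = n_perm, top_k = top_k)
}

#' @export
glance.regulon <- function(x, ...) {
  tibble(
    n_mirnas = dplyr::n_distinct(x$mirna),
    n_edges = nrow(x),
    rule = attr(x, "rule"),
    k = attr(x, "k")
  )
}

#' Master regulator analysis of one pathway pair
#'
#' A miRNA is called a master regulator of a pathway pair when its inferred
#' targets are over-represented (one-sided Fisher test, BH-adjusted across
#' miRNAs within each pathway) in *both* pathways of the pair at adjusted
#' p below `alpha`, and the miRNA itself is differentially expressed.
#'
#' @param regulon a `regulon` tibble from [build_regulon()] (columns `mirna`,
#'   `target`).
#' @param pair character vector of two pathway names.
#' @param collection named list of gene sets containing both pathways,
#'   already restricted to `universe`.
#' @param universe character vector, the gene universe for the Fisher tests.
#' @param de_mirnas character vector of differentially expressed miRNA ids.
#' @param alpha adjusted-p threshold (default 0.01, applied to both
#'   pathways).
#' @return an `mra_result` tibble: `pathway_a`, `pathway_b`, `mirna`, `n_a`,
#'   `targets_in_a`, `n_b`, `targets_in_b`, `p_a`, `p_b`, `fdr_a`, `fdr_b`,
#'   `is_mr`; one row per miRNA with at least one inferred target.
#' @export
mra_pair <- function(regulon, pair, collection, universe, de_mirnas,
                     alpha = 0.01) {
  if (length(pair) != 2L || !all(pair %in% names(collection))) {
    abort("`pair` must name two pathways present in `collection`.")
  }
  ga <- intersect(collection[[pair[1]]], universe)
  gb <- intersect(collection[[pair[2]]], universe)
  mirnas <- unique(regulon$mirna)
  if (length(mirnas) == 0L) {
    return(structure(tibble(), class = c("mra_result", "tbl_df", "tbl",
                                         "data.frame")))
  }
  targets <- split(regulon$target, factor(regulon$mirna, levels = mirnas))
  res <- purrr::map_dfr(mirnas, function(m) {
    tg <- intersect(targets[[m]], universe)
    tibble(
      pathway_a = pair[1], pathway_b = pair[2], mirna = m,
      n_a = length(ga), targets_in_a = length(intersect(tg, ga)),
      n_b = length(gb), targets_in_b = length(intersect(tg, gb)),
      p_a = fisher_enrichment(tg, ga, universe),
      p_b = fisher_enrichment(tg, gb, universe)
    )
  })
  res$fdr_a <- bh_adjust(res$p_a)
  res$fdr_b <- bh_adjust(res$p_b)
  res$is_mr <- res$fdr_a < alpha & res$fdr_b < alpha &
    res$mirna %in% de_mirnas
  structure(res, class = c("mra_result", class(res)), alpha = alpha)
}

#' Master regulator analysis over several pathway pairs
#'
#' @param regulon a `regulon` tibble.
#' @param pairs data frame with columns `pathway_a`, `pathway_b` (e.g. the
#'   `pairs` attribute of [ds_matrix()], or the top pairs of an
#'   [run_mccv()] ranking split on `"|"`).
#' @inheritParams mra_pair
#' @return an `mra_result` tibble over all pairs.
#' @export
mra_all <- function(regulon, pairs, collection, universe, de_mirnas,
                    alpha = 0.01) {
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    mra_pair(regulon, c(pairs$pathway_a[i], pairs$pathway_b[i]),
             collection, universe, de_mirnas, alpha)
  })
  structure(out, class = c("mra_result", class(out)), alpha = alpha)
}

#' Delta expression index
#'
#' Magnitude-of-change summary for a differentially expressed miRNA: the
#' difference between mean tumor and mean normal expression multiplied by the
#' log2 fold change, `(ex_bc - ex_ns) * logfc`. Positive whenever the
#' direction of the expression difference agrees with the sign of the fold
#' change.
#'
#' @param ex_bc,ex_ns mean expression in tumor (breast cancer) and normal
#'   samples.
#' @param logfc log2 fold change (tumor vs normal).
#' @return the index, vectorized over its arguments.
#' @examples
#' delta_index(48.07, 19.65, 1.134)
#' @export
delta_index <- function(ex_bc, ex_ns, logfc) {
  if (!all(is.finite(ex_bc), is.finite(ex_ns), is.finite(logfc))) {
    abort("delta_index() inputs must be finite.")
  }
  (ex_bc - ex_ns) * logfc
}

#' Delta index table for differentially expressed miRNAs
#'
#' @param mirna_dea a `dea_result` from [nb_exact_test()] or [dea()] on the
#'   miRNA matrix.
#' @return tibble `mirna`, `logFC`, `ex_bc`, `ex_ns`, `delta` for the DE
#'   miRNAs, sorted by decreasing delta.
#' @export
delta_table <- function(mirna_dea) {
  de <- mirna_dea[mirna_dea$is_de, ]
  tibble(
    mirna = de$feature,
    logFC = de$logFC,
    ex_bc = de$mean_tumor,
    ex_ns = de$mean_normal,
    delta = delta_index(de$mean_tumor, de$mean_normal, de$logFC)
  ) |>
    dplyr::arrange(dplyr::desc(.data$delta))
}
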