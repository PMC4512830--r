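#' Per-sample pathway activity summaries
#'
#' For every pathway and sample, the mean `M` and sample standard deviation
#' `S` (denominator n-1) of the member genes' expression on the
#' `log2(normalized count + 1)` scale. These are the two summaries the
#' Discriminating Score is built from. Pathway genes absent from the
#' expression matrix are ignored with a warning; pathways left with fewer
#' than 2 measured genes are dropped.
#'
#' @param expr numeric matrix of raw counts (genes x samples); library-size
#'   normalization and the log2 transform are applied internally unless
#'   `transform = FALSE` (then `expr` is used as-is, assumed already on a
#'   log-like scale).
#' @param collection named list of gene sets (typically the enriched
#'   pathways).
#' @param transform apply normalization + `log2(x + 1)` (default TRUE).
#' @return a `pathway_activity` object: list with matrices `M` and `S`
#'   (samples x pathways) and the gene sets actually used.
#' @export
pathway_activity <- function(expr, collection, transform = TRUE) {
  if (is.null(rownames(expr))) abort("`expr` must have gene rownames.")
  if (transform) expr <- log2(.normalize_counts(expr) + 1)
  present <- lapply(collection, intersect, y = rownames(expr))
  missing_n <- sum(lengths(collection) - lengths(present))
  if (missing_n > 0) {
    warn(paste0(missing_n, " pathway gene occurrence(s) absent from the ",
                "expression matrix were ignored."))
  }
  keep <- lengths(present) >= 2L
  if (!any(keep)) abort("no pathway has >= 2 genes in the expression matrix.")
  if (any(!keep)) {
    warn(paste0("dropped pathway(s) with < 2 measured genes: ",
                paste(names(present)[!keep], collapse = ", ")))
  }
  present <- present[keep]
  M <- vapply(present, function(g) colMeans(expr[g, , drop = FALSE]),
              numeric(ncol(expr)))
  S <- vapply(present, function(g) apply(expr[g, , drop = FALSE], 2, sd),
              numeric(ncol(expr)))
  structure(list(M = M, S = S, pathways = present),
            class = "pathway_activity")
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat("<pathway_activity> ", nrow(x$M), " samples x ", ncol(x$M),
      " pathways\n", sep = "")
  invisible(x)
}

#' Tidy pathway activity into long form
#'
#' @param x a `pathway_activity` object.
#' @param ... ignored.
#' @return tibble with columns `sample`, `pathway`, `M`, `S`.
#' @export
tidy.pathway_activity <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$M), times = ncol(x$M)),
    pathway = rep(colnames(x$M), each = nrow(x$M)),
    M = as.vector(x$M),
    S = as.vector(x$S)
  )
}

#' Discriminating Score between two pathway activities
#'
#' `DS = (Mx - My) / (Sx + Sy)`: a signed, signal-to-noise-style contrast of
#' the mean activities of two pathways in one sample, large in magnitude when
#' the pathways differ in activity by more than their internal spread. When
#' both spreads are zero the score is 0 for equal means and is clipped to
#' `+/- cap` otherwise (with a message), so downstream classifiers always see
#' finite values.
#'
#' @param mx,sx mean and standard deviation of pathway x (vectorized).
#' @param my,sy mean and standard deviation of pathway y.
#' @param cap replacement magnitude for a zero denominator with unequal
#'   means (default 1e6).
#' @return numeric vector of scores.
#' @examples
#' ds_score(2, 0.5, 1, 0.5) # 1
#' @export
ds_score <- function(mx, sx, my, sy, cap = 1e6) {
  if (anyNA(c(mx, sx, my, sy))) abort("ds_score() inputs contain NA/NaN.")
  denom <- sx + sy
  num <- mx - my
  out <- num / denom
  zero <- denom == 0
  if (any(zero)) {
    out[zero] <- ifelse(num[zero] == 0, 0, sign(num[zero]) * cap)
    if (any(zero & num != 0)) {
      inform(paste0(sum(zero & num != 0),
                    " zero-spread score(s) clipped to +/-", cap, "."))
    }
  }
  out
}

# canonical unordered pairs, lexicographic within and across pairs
.canonical_pairs <- function(pathways) {
  p <- sort(pathways)
  if (length(p) < 2L) abort("need at least 2 pathways to form pairs.")
  idx <- combn(p, 2)
  tibble(pathway_a = idx[1, ], pathway_b = idx[2, ],
         pair = paste(idx[1, ], idx[2, ], sep = "|"))
}

#' Discriminating Score matrix over all pathway pairs
#'
#' Computes [ds_score()] for every unordered pair of pathways in every
#' sample. Pairs are laid out in a canonical order: pathway names sorted
#' lexicographically, pairs enumerated as all combinations, columns named
#' `"A|B"` with `A < B`. With `P` pathways this gives `choose(P, 2)` columns.
#'
#' @param activity a `pathway_activity` object.
#' @param cap passed to [ds_score()].
#' @return a tibble with column `sample` followed by one column per pair;
#'   attribute `pairs` holds the pair table.
#' @export
ds_matrix <- function(activity, cap = 1e6) {
  pairs <- .canonical_pairs(colnames(activity$M))
  cols <- purrr::map2(pairs$pathway_a, pairs$pathway_b, function(a, b) {
    unname(ds_score(activity$M[, a], activity$S[, a],
                    activity$M[, b], activity$S[, b], cap = cap))
  })
  out <- tibble(sample = rownames(activity$M))
  out[pairs$pair] <- cols
  structure(out, pairs = pairs)
}

#' Euclidean cross-talk comparator
#'
#' The simpler distance-based cross-talk measure used as a baseline for the
#' Discriminating Score: the per-sample absolute difference of the two
#' pathways' mean activities, `|Mx - My|` (the one-dimensional Euclidean
#' distance between the activity summaries). Identical layout to
#' [ds_matrix()].
#'
#' @inheritParams ds_matrix
#' @return a tibble with column `sample` followed by one column per pair.
#' @export
euclidean_crosstalk <- function(activity) {
  pairs <- .canonical_pairs(colnames(activity$M))
  cols <- purrr::map2(pairs$pathway_a, pairs$pathway_b, function(a, b) {
    unname(abs(activity$M[, a] - activity$M[, b]))
  })
  out <- tibble(sample = rownames(activity$M))
  out[pairs$pair] <- cols
  structure(out, pairs = pairs)
}
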