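#' Restrict a pathway collection to an expression universe
#'
#' Intersects every gene set with the (typically quantile-filtered) gene
#' universe and drops sets that fall below `min_size` genes, so enrichment is
#' always computed against the genes the experiment could actually have
#' detected.
#'
#' @param collection named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param universe character vector of gene ids.
#' @param min_size minimum surviving set size (default 5).
#' @return a named list of restricted gene sets with attribute `universe`.
#' @export
restrict_collection <- function(collection, universe, min_size = 5) {
  if (length(universe) == 0L) abort("`universe` is empty.")
  restricted <- lapply(collection, intersect, y = universe)
  keep <- lengths(restricted) >= min_size
  if (any(!keep)) {
    inform(paste0(sum(!keep), " pathway(s) dropped below min_size = ",
                  min_size, " after universe restriction."))
  }
  structure(restricted[keep], universe = unique(universe))
}

#' Fisher over-representation p-value for one gene set
#'
#' One-sided Fisher exact test of the 2x2 table formed by membership in the
#' differentially expressed set and membership in the pathway, both within
#' `universe`; equivalently the upper hypergeometric tail
#' `P(X >= |deg intersect pathway|)`.
#'
#' @param deg character vector of differentially expressed gene ids
#'   (a subset of `universe`).
#' @param pathway character vector of pathway gene ids (subset of `universe`).
#' @param universe character vector, the tested gene universe.
#' @return a single p-value.
#' @examples
#' # all 5 draws inside a 5-gene pathway of a 20-gene universe: 1/choose(20,5)
#' u <- paste0("g", 1:20)
#' fisher_enrichment(u[1:5], u[1:5], u)
#' @export
fisher_enrichment <- function(deg, pathway, universe) {
  if (length(universe) == 0L) abort("`universe` is empty.")
  universe <- unique(universe)
  deg <- intersect(unique(deg), universe)
  pathway <- intersect(unique(pathway), universe)
  k <- length(intersect(deg, pathway))
  phyper(k - 1, length(pathway), length(universe) - length(pathway),
         length(deg), lower.tail = FALSE)
}

#' Pathway enrichment analysis of a DEG set
#'
#' Runs [fisher_enrichment()] for every set in a universe-restricted
#' collection, adjusts across pathways with Benjamini-Hochberg, and flags
#' significance at adjusted p below `alpha`.
#'
#' @param deg character vector of differentially expressed gene ids.
#' @param collection restricted collection from [restrict_collection()]
#'   (must carry a `universe` attribute), or a named list plus `universe`.
#' @param universe gene universe; defaults to the collection's attribute.
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return an `enrichment_result` tibble with columns `pathway`, `n_pathway`,
#'   `n_common`, `pvalue`, `fdr`, `significant`, sorted by `fdr` then pathway
#'   name (so the order never depends on the order of sets in the input file).
#' @export
enrich_all <- function(deg, collection, universe = attr(collection, "universe"),
                       alpha = 0.01) {
  if (is.null(universe)) {
    abort("no `universe`: pass one or use restrict_collection() first.")
  }
  deg <- intersect(unique(deg), universe)
  res <- tibble(
    pathway = names(collection),
    n_pathway = unname(lengths(lapply(collection, intersect, y = universe))),
    n_common = vapply(unname(collection), function(g) {
      length(intersect(deg, intersect(g, universe)))
    }, integer(1)),
    pvalue = vapply(unname(collection), fisher_enrichment, numeric(1),
                    deg = deg, universe = universe)
  )
  res$fdr <- bh_adjust(res$pvalue)
  res$significant <- res$fdr < alpha
  res <- dplyr::arrange(res, .data$fdr, .data$pathway)
  structure(res, class = c("enrichment_result", class(res)),
            alpha = alpha, n_deg = length(deg), n_universe = length(universe))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_significant = sum(x$significant),
    n_deg = attr(x, "n_deg"),
    n_universe = attr(x, "n_universe"),
    alpha = attr(x, "alpha")
  )
}

#' Dot plot of pathway enrichment
#'
#' @param object an `enrichment_result` from [enrich_all()].
#' @param top number of pathways shown (default 20, by ascending FDR).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- head(object, top)
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$fdr),
                                  stats::reorder(.data$pathway, -.data$fdr),
                                  size = .data$n_common,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 FDR", y = NULL, size = "DEGs in set",
                  colour = paste0("FDR < ", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
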