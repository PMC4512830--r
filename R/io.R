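#' Read an expression matrix from TSV
#'
#' Expects feature ids in the first column and one column per sample.
#' Duplicate feature ids and non-numeric cells are rejected with the
#' offending id named.
#'
#' @param path TSV file path.
#' @return numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    abort(paste0("no features in ", path))
  }
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate feature id(s) in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  vals <- tab[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric column(s) in ", path, ": ",
                 paste(names(vals)[bad], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  tab <- tibble(feature = rownames(m))
  for (s in colnames(m)) tab[[s]] <- unname(m[, s])
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a pathway collection from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#' Windows line endings are tolerated; duplicate genes within a set are
#' dropped with a warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(paste0("GMT line ", short[1], " has fewer than 3 fields in ", path))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name(s) in ", path, ": ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(g) sum(duplicated(g)), integer(1)))
  if (ndup > 0) {
    warn(paste0(ndup, " duplicated gene entr(ies) within sets were dropped."))
  }
  setNames(lapply(sets, unique), nm)
}

#' Write a pathway collection to a GMT file
#'
#' @param collection named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled; default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], description, collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample labels from TSV
#'
#' Two columns, `sample` and `class` (values `tumor`/`normal`).
#'
#' @param path TSV file path.
#' @return tibble with columns `sample`, `class`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("sample", "class") %in% names(tab))) {
    abort(paste0(path, " must have columns `sample` and `class`."))
  }
  .assert_labels(tab[, c("sample", "class")])
}

#' Write sample labels to TSV
#'
#' @param labels tibble with columns `sample`, `class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("sample", "class")], path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter, validated up front so
#' a bad configuration fails before any computation. Parameter defaults are
#' the pipeline's canonical settings: expression quantile 0.25, |log2 FC|
#' cut 1, DE FDR 0.01, enrichment alpha 0.01, 50 bootstraps at a 0.6
#' training fraction with 10-fold cross-validation and 500 trees, and KSG
#' neighbour parameter 3.
#'
#' @param mrna,mirna,labels,gmt input file paths (see [read_expression()],
#'   [read_labels()], [read_gmt()]).
#' @param out output directory.
#' @param q,logfc_cut,fdr_cut differential expression settings.
#' @param alpha_pea enrichment significance threshold.
#' @param min_size minimum restricted pathway size.
#' @param dispersion common NB dispersion or `"auto"`.
#' @param n_bootstraps,train_frac,k_folds,ntree,top_n selection settings.
#' @param mccv_mode `"full"` (recompute DEA/PEA/DS per bootstrap) or
#'   `"fixed"`.
#' @param mi_k,regulon_rule,regulon_alpha,n_perm,top_k regulon settings.
#' @param mra_alpha master-regulator dual-enrichment threshold.
#' @param seed master seed for every randomized stage.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mrna, mirna, labels, gmt, out,
                            q = 0.25, logfc_cut = 1, fdr_cut = 0.01,
                            alpha_pea = 0.01, min_size = 5,
                            dispersion = "auto",
                            n_bootstraps = 50, train_frac = 0.6,
                            k_folds = 10, ntree = 500, top_n = 10,
                            mccv_mode = c("full", "fixed"),
                            mi_k = 3, regulon_rule = "permutation_fdr",
                            regulon_alpha = 0.05, n_perm = 20, top_k = 10,
                            mra_alpha = 0.01, seed = 1) {
  mccv_mode <- match.arg(mccv_mode)
  for (p in c(mrna, mirna, labels, gmt)) {
    if (!file.exists(p)) abort(paste0("pipeline_config: file not found: ", p))
  }
  chk <- function(ok, msg) if (!ok) abort(paste0("pipeline_config: ", msg))
  chk(q > 0 && q < 1, "`q` must be in (0, 1).")
  chk(train_frac > 0 && train_frac < 1, "`train_frac` must be in (0, 1).")
  chk(fdr_cut > 0 && fdr_cut <= 1, "`fdr_cut` must be in (0, 1].")
  chk(alpha_pea > 0 && alpha_pea <= 1, "`alpha_pea` must be in (0, 1].")
  chk(n_bootstraps >= 0, "`n_bootstraps` must be >= 0.")
  chk(k_folds >= 2, "`k_folds` must be >= 2.")
  chk(ntree >= 1, "`ntree` must be >= 1.")
  chk(mi_k >= 1, "`mi_k` must be >= 1.")
  chk(regulon_rule %in% c("permutation_fdr", "top_k"),
      "unknown `regulon_rule`.")
  structure(list(mrna = mrna, mirna = mirna, labels = labels, gmt = gmt,
                 out = out, q = q, logfc_cut = logfc_cut, fdr_cut = fdr_cut,
                 alpha_pea = alpha_pea, min_size = min_size,
                 dispersion = dispersion, n_bootstraps = n_bootstraps,
                 train_frac = train_frac, k_folds = k_folds, ntree = ntree,
                 top_n = top_n, mccv_mode = mccv_mode, mi_k = mi_k,
                 regulon_rule = regulon_rule, regulon_alpha = regulon_alpha,
                 n_perm = n_perm, top_k = top_k, mra_alpha = mra_alpha,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the
#'   YAML file's directory.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  vals <- yaml::read_yaml(path)
  base <- dirname(path)
  for (f in c("mrna", "mirna", "labels", "gmt")) {
    if (!is.null(vals[[f]]) && !file.exists(vals[[f]])) {
      vals[[f]] <- file.path(base, vals[[f]])
    }
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

.stage_log <- function(stage, msg) inform(paste0("[", stage, "] ", msg))

#' Run the full cross-talk pipeline
#'
#' Executes every stage in order, writing each intermediate artifact under
#' `config$out` together with a manifest that records parameters, seeds,
#' per-stage counts and the MD5 of every output file, so a rerun with the
#' same configuration and seed is verifiably identical:
#'
#' 1. differential expression of genes and miRNAs (quantile filter +
#'    NB exact test);
#' 2. Fisher pathway enrichment of the DEGs on the filtered universe;
#' 3. per-sample pathway activity and the Discriminating Score matrix over
#'    the enriched pathways;
#' 4. Monte Carlo cross-validated random-forest selection of pathway pairs;
#' 5. mutual-information regulons of the DE miRNAs over the genes of the
#'    selected pairs and the dual-Fisher master regulator analysis;
#' 6. the Delta expression index table of the DE miRNAs.
#'
#' @param config a [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return a `crosstalk_pipeline` list with every stage result and the
#'   manifest, invisibly; artifacts are on disk under `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a YAML path.")
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(tab, name) {
    p <- file.path(config$out, name)
    readr::write_tsv(as_tibble(tab), p, progress = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "input"
  res <- tryCatch({
    labels <- read_labels(config$labels)
    mrna <- read_expression(config$mrna)
    mirna <- read_expression(config$mirna)
    collection <- read_gmt(config$gmt)
    miss <- setdiff(labels$sample, colnames(mrna))
    if (length(miss)) abort(paste0("samples missing from mRNA matrix: ",
                                   paste(head(miss, 5), collapse = ", ")))
    mirna_samples <- intersect(labels$sample, colnames(mirna))

    stage <- "dea"
    dea_g <- dea(mrna[, labels$sample, drop = FALSE], labels, q = config$q,
                 dispersion = config$dispersion,
                 logfc_cut = config$logfc_cut, fdr_cut = config$fdr_cut)
    universe <- attr(dea_g, "universe")
    deg <- call_de(dea_g, config$logfc_cut, config$fdr_cut)
    .stage_log("dea", paste0(length(universe), " genes pass the quantile ",
                             "filter; ", length(deg), " DEGs."))
    emit(dea_g, "dea_mrna.tsv")
    lab_mir <- labels[labels$sample %in% mirna_samples, ]
    dea_m <- dea(mirna[, lab_mir$sample, drop = FALSE], lab_mir,
                 q = config$q, dispersion = config$dispersion,
                 logfc_cut = config$logfc_cut, fdr_cut = config$fdr_cut)
    de_mir <- call_de(dea_m, config$logfc_cut, config$fdr_cut)
    .stage_log("dea", paste0(length(de_mir), " DE miRNAs."))
    emit(dea_m, "dea_mirna.tsv")

    stage <- "pea"
    restricted <- restrict_collection(collection, universe, config$min_size)
    enr <- enrich_all(deg, restricted, alpha = config$alpha_pea)
    sig <- enr$pathway[enr$significant]
    .stage_log("pea", paste0(nrow(enr), " pathways tested; ", length(sig),
                             " enriched at FDR < ", config$alpha_pea, "."))
    emit(enr, "pea.tsv")
    if (length(sig) < 2L) {
      abort("fewer than 2 enriched pathways: no pairs to score.")
    }

    stage <- "crosstalk"
    act <- suppressWarnings(
      pathway_activity(mrna[, labels$sample, drop = FALSE], restricted[sig])
    )
    dsm <- ds_matrix(act)
    .stage_log("crosstalk", paste0(ncol(dsm) - 1L, " pathway-pair columns."))
    emit(dsm, "ds_matrix.tsv")

    stage <- "selection"
    mccv <- if (config$mccv_mode == "full") {
      run_mccv(labels = labels, n_bootstraps = config$n_bootstraps,
               train_frac = config$train_frac, top_n = config$top_n,
               k = config$k_folds, ntree = config$ntree, seed = config$seed,
               refit = list(counts = mrna[, labels$sample, drop = FALSE],
                            collection = collection, q = config$q,
                            dispersion = config$dispersion,
                            logfc_cut = config$logfc_cut,
                            fdr_cut = config$fdr_cut,
                            alpha = config$alpha_pea,
                            min_size = config$min_size))
    } else {
      run_mccv(dsm, labels, n_bootstraps = config$n_bootstraps,
               train_frac = config$train_frac, top_n = config$top_n,
               k = config$k_folds, ntree = config$ntree, seed = config$seed)
    }
    .stage_log("selection", paste0(nrow(mccv$ranking),
                                   " pairs ever selected."))
    if (nrow(mccv$ranking)) emit(mccv$ranking, "pair_ranking.tsv")
    if (nrow(mccv$selections)) emit(mccv$selections, "pair_selections.tsv")
    top_pairs <- head(mccv$ranking, config$top_n)
    membership <- if (nrow(mccv$selections)) {
      mccv$selections |>
        dplyr::mutate(selected = 1L) |>
        tidyr::pivot_wider(id_cols = "pair", names_from = "bootstrap",
                           values_from = "selected", values_fill = 0L,
                           names_prefix = "b")
    } else tibble()
    if (nrow(membership)) emit(membership, "pair_membership.tsv")

    stage <- "regulon"
    reg <- mra <- NULL
    mi <- NULL
    dtab <- delta_table(dea_m)
    emit(dtab, "delta_index.tsv")
    if (length(de_mir) && nrow(top_pairs)) {
      top_names <- do.call(rbind, strsplit(top_pairs$pair, "|", fixed = TRUE))
      pair_tab <- tibble(pathway_a = top_names[, 1],
                         pathway_b = top_names[, 2])
      pair_genes <- unique(unlist(
        restricted[unique(c(pair_tab$pathway_a, pair_tab$pathway_b))]
      ))
      mir_expr <- log2(.normalize_counts(
        mirna[, lab_mir$sample, drop = FALSE]) + 1)[de_mir, , drop = FALSE]
      gene_expr <- log2(.normalize_counts(
        mrna[, lab_mir$sample, drop = FALSE]) + 1)[pair_genes, , drop = FALSE]
      mi <- mi_matrix(mir_expr, gene_expr, k = config$mi_k)
      reg <- build_regulon(mir_expr, gene_expr, rule = config$regulon_rule,
                           k = config$mi_k, alpha = config$regulon_alpha,
                           n_perm = config$n_perm, top_k = config$top_k,
                           seed = config$seed, mi = mi)
      .stage_log("regulon", paste0(nrow(reg), " miRNA-target edges for ",
                                   dplyr::n_distinct(reg$mirna),
                                   " DE miRNAs."))
      mi_tab <- tibble(mirna = rownames(mi))
      for (g in colnames(mi)) mi_tab[[g]] <- unname(mi[, g])
      emit(mi_tab, "mi_matrix.tsv")
      p <- file.path(config$out, "regulon.json")
      jsonlite::write_json(
        split(reg$target, factor(reg$mirna, levels = unique(reg$mirna))),
        p, auto_unbox = FALSE, pretty = TRUE)
      written <- c(written, p)
      mra <- mra_all(reg, pair_tab, restricted, universe, de_mir,
                     alpha = config$mra_alpha)
      .stage_log("regulon", paste0(sum(mra$is_mr),
                                   " master-regulator calls."))
      emit(mra, "mra.tsv")
    } else {
      .stage_log("regulon", "skipped: no DE miRNAs or no selected pairs.")
    }

    list(dea_mrna = dea_g, dea_mirna = dea_m, enrichment = enr,
         ds = dsm, mccv = mccv, regulon = reg, mra = mra, delta = dtab)
  }, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirxtalk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = unclass(config),
    stage_counts = list(
      genes_filtered = length(attr(res$dea_mrna, "universe")),
      degs = sum(res$dea_mrna$is_de),
      de_mirnas = sum(res$dea_mirna$is_de),
      pathways_tested = nrow(res$enrichment),
      pathways_enriched = sum(res$enrichment$significant),
      ds_columns = ncol(res$ds) - 1L,
      pairs_selected = nrow(res$mccv$ranking),
      regulon_edges = if (is.null(res$regulon)) 0L else nrow(res$regulon),
      master_regulators = if (is.null(res$mra)) 0L else sum(res$mra$is_mr)
    ),
    files = as.list(setNames(unname(tools::md5sum(sort(written))),
                             basename(sort(written))))
  )
  mpath <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(structure(c(res, list(manifest = manifest, out = config$out)),
                      class = "crosstalk_pipeline"))
}

#' @export
print.crosstalk_pipeline <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("<crosstalk_pipeline> artifacts in ", x$out, "\n",
      "  genes filtered: ", sc$genes_filtered,
      ", DEGs: ", sc$degs,
      ", DE miRNAs: ", sc$de_mirnas, "\n",
      "  enriched pathways: ", sc$pathways_enriched,
      ", DS columns: ", sc$ds_columns,
      ", pairs selected: ", sc$pairs_selected, "\n",
      "  regulon edges: ", sc$regulon_edges,
      ", master regulators: ", sc$master_regulators, "\n", sep = "")
  invisible(x)
}
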