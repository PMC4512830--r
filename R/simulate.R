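#' Configuration for a synthetic cross-talk study
#'
#' Bundles and validates every knob of the generator: cohort sizes, feature
#' counts, the pathway collection geometry, the planted differential
#' expression signal, the negative-binomial noise level, the number of
#' pathway pairs with a planted class-separating activity shift, and the
#' planted miRNA regulons. Defaults describe a desk-scale two-arm RNA-seq
#' study with a clearly recoverable signal; see the package vignette for the
#' reasoning behind each value.
#'
#' @param n_tumor,n_normal samples per class (default 40 each).
#' @param n_genes,n_mirnas number of genes (1000) and miRNAs (150).
#' @param n_pathways gene sets in the collection (15).
#' @param pathway_size_range inclusive size range of each set (15-40 genes).
#' @param overlap_fraction fraction of the smaller pathway shared between the
#'   two members of each planted pair, in \[0, 1) (default 0.1).
#' @param n_de_genes total differentially expressed genes (100); must cover
#'   the genes consumed by the cross-talk planting.
#' @param planted_logfc log2 fold-change magnitude of planted DE features
#'   (default 2).
#' @param nb_dispersion common negative-binomial dispersion phi in
#'   `variance = mu + phi mu^2` (default 0.1; 0 gives Poisson counts).
#' @param n_crosstalk_pairs pathway pairs with a planted class-separating
#'   activity shift (default 2).
#' @param regulon_size target genes per planted regulator miRNA (15).
#' @param regulon_strength magnitude of the miRNA-target dependence in
#'   (0, 1) (default 0.8); the sign is negative (repression) by default.
#' @param regulon_sign `-1` (default, anti-correlated) or `1`.
#' @param seed RNG seed; identical configurations and seeds give
#'   byte-identical studies.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tumor = 40, n_normal = 40, n_genes = 1000,
                       n_mirnas = 150, n_pathways = 15,
                       pathway_size_range = c(15, 40),
                       overlap_fraction = 0.1, n_de_genes = 100,
                       planted_logfc = 2, nb_dispersion = 0.1,
                       n_crosstalk_pairs = 2, regulon_size = 15,
                       regulon_strength = 0.8, regulon_sign = -1, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_genes = n_genes,
              n_mirnas = n_mirnas, n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              overlap_fraction = overlap_fraction, n_de_genes = n_de_genes,
              planted_logfc = planted_logfc, nb_dispersion = nb_dispersion,
              n_crosstalk_pairs = n_crosstalk_pairs,
              regulon_size = regulon_size,
              regulon_strength = regulon_strength,
              regulon_sign = regulon_sign, seed = seed)
  stopifnot_cfg <- function(ok, msg) if (!ok) abort(paste0("sim_config: ", msg))
  stopifnot_cfg(n_tumor >= 2 && n_normal >= 2, "need >= 2 samples per class.")
  stopifnot_cfg(n_de_genes >= 0 && n_de_genes <= n_genes,
                "n_de_genes must lie in [0, n_genes].")
  stopifnot_cfg(length(pathway_size_range) == 2L &&
                  pathway_size_range[1] >= 2 &&
                  pathway_size_range[2] >= pathway_size_range[1],
                "pathway_size_range must be increasing and >= 2.")
  stopifnot_cfg(pathway_size_range[2] <= n_genes,
                "pathway sizes exceed the gene count.")
  stopifnot_cfg(overlap_fraction >= 0 && overlap_fraction < 1,
                "overlap_fraction must be in [0, 1).")
  stopifnot_cfg(regulon_strength > 0 && regulon_strength < 1,
                "regulon_strength must be in (0, 1).")
  stopifnot_cfg(regulon_sign %in% c(-1, 1), "regulon_sign must be -1 or 1.")
  stopifnot_cfg(nb_dispersion >= 0, "nb_dispersion must be >= 0.")
  stopifnot_cfg(2 * n_crosstalk_pairs <= n_pathways,
                "not enough pathways for the requested cross-talk pairs.")
  stopifnot_cfg(2 * n_crosstalk_pairs * pathway_size_range[2] <= n_genes,
                "planted pathways would exhaust the gene pool.")
  stopifnot_cfg(n_crosstalk_pairs <= n_mirnas,
                "need one miRNA per planted pair.")
  structure(cfg, class = "sim_config")
}

# NB quantile map for copula marginals; phi = 0 degenerates to Poisson
.q_counts <- function(u, mu, phi) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  if (phi <= 0) stats::qpois(u, lambda = mu) else {
    qnbinom(u, size = 1 / phi, mu = mu)
  }
}

.r_counts <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, lambda = mu) else {
    rnbinom(n, size = 1 / phi, mu = mu)
  }
}

#' Generate a synthetic cross-talk study with planted ground truth
#'
#' Simulates matched mRNA and miRNA count matrices, a pathway collection and
#' the ground truth needed to score every downstream stage:
#'
#' * counts are negative binomial with a common dispersion and log-normal
#'   baseline means (RNA-seq-like dynamic range), with mild log-normal
#'   library-size variation;
#' * `n_de_genes` genes differ between classes by `2^planted_logfc`;
#' * each of `n_crosstalk_pairs` pathway pairs shares `overlap_fraction` of
#'   its genes; the non-shared genes of the first member are shifted
#'   coherently upward in tumor samples (this separates the pair's
#'   Discriminating Score distributions), while the second member receives
#'   mixed-sign DE genes so both members are enriched without a large mean
#'   activity shift;
#' * one regulator miRNA per planted pair is differentially expressed and
#'   tied to `regulon_size` member genes of its pair through a Gaussian
#'   copula of strength `regulon_strength` (anti-correlated by default),
#'   giving a dependence the mutual-information stage can detect without
#'   dictating the count marginals.
#'
#' @param config a [sim_config()].
#' @return a `crosstalk_study` list: `mrna` and `mirna` count matrices
#'   (features x samples), `labels` tibble (`sample`, `class`), `pathways`
#'   named list, and `truth` (fields `de_genes`, `de_mirnas`,
#'   `enriched_pathways`, `crosstalk_pairs`, `regulons`).
#' @export
simulate_crosstalk_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  c2 <- config
  n <- c2$n_tumor + c2$n_normal
  samples <- c(sprintf("tumor%03d", seq_len(c2$n_tumor)),
               sprintf("normal%03d", seq_len(c2$n_normal)))
  labels <- tibble(sample = samples,
                   class = rep(c("tumor", "normal"),
                               c(c2$n_tumor, c2$n_normal)))
  genes <- sprintf("gene%04d", seq_len(c2$n_genes))
  mirnas <- sprintf("mir%04d", seq_len(c2$n_mirnas))
  pw_names <- sprintf("PW%02d", seq_len(c2$n_pathways))

  set.seed(c2$seed)
  mu_g <- rlnorm(c2$n_genes, meanlog = log(100), sdlog = 1.2)
  mu_m <- rlnorm(c2$n_mirnas, meanlog = log(100), sdlog = 1.2)
  libf <- rlnorm(n, 0, 0.15)

  size_choices <- seq(c2$pathway_size_range[1], c2$pathway_size_range[2])
  sizes <- if (length(size_choices) == 1L) {
    rep(size_choices, c2$n_pathways)
  } else {
    sample(size_choices, c2$n_pathways, replace = TRUE)
  }
  n_planted_pw <- 2 * c2$n_crosstalk_pairs
  planted_pw <- if (n_planted_pw > 0) sample(pw_names, n_planted_pw) else character(0)
  pathways <- setNames(vector("list", c2$n_pathways), pw_names)
  pool <- genes
  de_sign <- setNames(numeric(0), character(0)) # per-gene planted logFC sign
  shift_genes <- list()                         # coherent genes per pair
  pairs <- list()
  for (i in seq_len(c2$n_crosstalk_pairs)) {
    a <- planted_pw[2 * i - 1]
    b <- planted_pw[2 * i]
    sa <- sizes[match(a, pw_names)]
    sb <- sizes[match(b, pw_names)]
    n_sh <- floor(c2$overlap_fraction * min(sa, sb))
    shared <- sample(pool, n_sh); pool <- setdiff(pool, shared)
    a_spec <- sample(pool, sa - n_sh); pool <- setdiff(pool, a_spec)
    b_spec <- sample(pool, sb - n_sh); pool <- setdiff(pool, b_spec)
    pathways[[a]] <- c(shared, a_spec)
    pathways[[b]] <- c(shared, b_spec)
    # member-gene co-shift in tumor: all of A's specific genes move up
    de_sign[a_spec] <- 1
    shift_genes[[i]] <- a_spec
    # B gets mixed-sign DE members so it passes enrichment with little
    # net activity shift
    nb_de <- ceiling(0.6 * length(b_spec))
    b_de <- sample(b_spec, nb_de)
    de_sign[b_de] <- rep_len(c(1, -1), nb_de)
    ab <- sort(c(a, b))
    pairs[[i]] <- tibble(pathway_a = ab[1], pathway_b = ab[2],
                         pair = paste(ab[1], ab[2], sep = "|"))
  }
  for (p in setdiff(pw_names, planted_pw)) {
    pathways[[p]] <- sample(genes, sizes[match(p, pw_names)])
  }
  if (length(de_sign) > c2$n_de_genes) {
    abort(paste0("sim_config: n_de_genes = ", c2$n_de_genes, " is below the ",
                 length(de_sign), " genes consumed by cross-talk planting."))
  }
  n_extra <- c2$n_de_genes - length(de_sign)
  extra_pool <- setdiff(genes, c(unlist(pathways[planted_pw]),
                                 names(de_sign)))
  if (n_extra > 0) {
    extra <- sample(extra_pool, min(n_extra, length(extra_pool)))
    de_sign[extra] <- sample(c(1, -1), length(extra), replace = TRUE)
  }

  # regulator miRNAs: one per planted pair, DE (down by default), copula-tied
  # to regulon_size member genes of the pair
  regulators <- if (c2$n_crosstalk_pairs > 0) {
    sample(mirnas, c2$n_crosstalk_pairs)
  } else character(0)
  # a regulator must be expressed to be detectable: draw its baseline mean
  # from the upper half of the miRNA abundance distribution
  mu_m[match(regulators, mirnas)] <-
    stats::qlnorm(runif(length(regulators), 0.5, 1),
                  meanlog = log(100), sdlog = 1.2)
  regulons <- setNames(vector("list", length(regulators)), regulators)
  mirna_sign <- setNames(rep(c2$regulon_sign * 1, length(regulators)),
                         regulators)
  for (i in seq_along(regulators)) {
    pg <- unique(c(pathways[[planted_pw[2 * i - 1]]],
                   pathways[[planted_pw[2 * i]]]))
    regulons[[i]] <- sample(pg, min(c2$regulon_size, length(pg)))
  }
  n_extra_m <- max(0L, round(0.05 * c2$n_mirnas))
  extra_m <- sample(setdiff(mirnas, regulators), n_extra_m)
  mirna_sign[extra_m] <- sample(c(1, -1), n_extra_m, replace = TRUE)

  lfc_g <- setNames(rep(0, c2$n_genes), genes)
  lfc_g[names(de_sign)] <- de_sign * c2$planted_logfc
  lfc_m <- setNames(rep(0, c2$n_mirnas), mirnas)
  lfc_m[names(mirna_sign)] <- mirna_sign * c2$planted_logfc

  tum <- labels$class == "tumor"
  mean_for <- function(mu_base, lfc, ids) {
    m <- matrix(rep(mu_base, n), ncol = n, dimnames = list(ids, samples))
    m[, tum] <- m[, tum] * 2^lfc
    sweep(m, 2, libf, `*`)
  }
  mu_gene <- mean_for(mu_g, lfc_g, genes)   # genes x samples expected counts
  mu_mir <- mean_for(mu_m, lfc_m, mirnas)

  phi <- c2$nb_dispersion
  mrna <- matrix(.r_counts(length(mu_gene), as.vector(mu_gene), phi),
                 nrow = c2$n_genes, dimnames = list(genes, samples))
  mirna <- matrix(.r_counts(length(mu_mir), as.vector(mu_mir), phi),
                  nrow = c2$n_mirnas, dimnames = list(mirnas, samples))
  # overwrite copula-coupled features: shared latent factor per regulon
  a_load <- sqrt(c2$regulon_strength)
  for (i in seq_along(regulators)) {
    f <- rnorm(n)
    for (g in regulons[[i]]) {
      z <- a_load * f + sqrt(1 - c2$regulon_strength) * rnorm(n)
      mrna[g, ] <- .q_counts(pnorm(z), mu_gene[g, ], phi)
    }
    zr <- c2$regulon_sign * a_load * f +
      sqrt(1 - c2$regulon_strength) * rnorm(n)
    mirna[regulators[i], ] <- .q_counts(pnorm(zr),
                                        mu_mir[regulators[i], ], phi)
  }

  truth <- list(
    de_genes = sort(names(de_sign)),
    de_mirnas = sort(names(mirna_sign)),
    enriched_pathways = sort(planted_pw),
    crosstalk_pairs = if (length(pairs)) dplyr::bind_rows(pairs) else {
      tibble(pathway_a = character(0), pathway_b = character(0),
             pair = character(0))
    },
    regulons = lapply(regulons, sort)
  )
  structure(list(mrna = mrna, mirna = mirna, labels = labels,
                 pathways = lapply(pathways, sort), truth = truth,
                 config = c2),
            class = "crosstalk_study")
}

#' @export
print.crosstalk_study <- function(x, ...) {
  cat("<crosstalk_study> ", nrow(x$mrna), " genes, ", nrow(x$mirna),
      " miRNAs, ", nrow(x$labels), " samples (",
      sum(x$labels$class == "tumor"), " tumor), ",
      length(x$pathways), " pathways, ",
      nrow(x$truth$crosstalk_pairs), " planted pair(s)\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Serializes a [simulate_crosstalk_study()] result as the plain-text formats
#' the pipeline readers consume: TSV count matrices, a GMT pathway file, a
#' labels TSV and a ground-truth JSON. Reading the files back reproduces the
#' in-memory objects exactly.
#'
#' @param study a `crosstalk_study`.
#' @param outdir output directory (created if missing).
#' @return named character vector of the written paths (`mrna`, `mirna`,
#'   `labels`, `gmt`, `truth`).
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mrna = file.path(outdir, "mrna_counts.tsv"),
             mirna = file.path(outdir, "mirna_counts.tsv"),
             labels = file.path(outdir, "labels.tsv"),
             gmt = file.path(outdir, "pathways.gmt"),
             truth = file.path(outdir, "ground_truth.json"))
  write_expression(study$mrna, paths["mrna"])
  write_expression(study$mirna, paths["mirna"])
  write_labels(study$labels, paths["labels"])
  write_gmt(study$pathways, paths["gmt"])
  truth <- study$truth
  truth$crosstalk_pairs <- as.data.frame(truth$crosstalk_pairs)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE,
                       pretty = TRUE)
  paths
}
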