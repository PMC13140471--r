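#' Configuration for the synthetic bulk RNA-seq generator
#'
#' Counts follow the standard bulk RNA-seq model: gene baselines are
#' log-normal, per-sample library-size factors are log-normal, and counts are
#' negative binomial with mean
#' `lib_s * baseline_g * 2^(effect_{g, group(s)})` and a common dispersion.
#' Effects are planted per (gene, stage, region) with `NA` acting as a
#' wildcard, so a single row can shift a gene in every region of one stage,
#' or in one region of every stage. A planted gene-set shift adds the same
#' log2 effect to every member of the set in the target group, emulating a
#' coordinated pathway-level enrichment.
#'
#' @param n_genes number of genes in the universe.
#' @param groups data.frame with columns `stage`, `region`, `n` giving the
#'   number of samples per (stage x region) cell. The default is a balanced
#'   design over the three stages and three regions.
#' @param n_per_group convenience scalar used to build the default `groups`.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means (defaults give a median baseline of ~100 counts).
#' @param libsize_sdlog log-normal sd of per-sample library-size factors
#'   (meanlog 0, i.e. factors centred at 1).
#' @param dispersion negative-binomial dispersion (NB `size = 1/dispersion`);
#'   0.15 is a moderate bulk value.
#' @param de `NULL` or data.frame `gene_id, stage, region, log2fc`
#'   (`NA` stage/region = all).
#' @param set_shift `NULL` or a list of lists
#'   `list(name, genes, stage, region, log2_shift)`.
#' @param seed integer seed; per-group substreams derive from it so adding a
#'   group does not perturb the others.
#' @return an `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000,
                            groups = NULL,
                            n_per_group = 8,
                            baseline_meanlog = log(100),
                            baseline_sdlog = 1.2,
                            libsize_sdlog = 0.2,
                            dispersion = 0.15,
                            de = NULL,
                            set_shift = NULL,
                            seed = 1L) {
  if (is.null(groups)) {
    groups <- expand.grid(stage = c("benign", "borderline", "malignant"),
                          region = REGIONS, stringsAsFactors = FALSE)
    groups$n <- n_per_group
  }
  stopifnot(is.data.frame(groups),
            all(c("stage", "region", "n") %in% names(groups)),
            all(groups$n >= 1), n_genes >= 1, dispersion > 0)
  if (!is.null(de)) {
    stopifnot(is.data.frame(de),
              all(c("gene_id", "log2fc") %in% names(de)),
              all(is.finite(de$log2fc)))
    if (is.null(de$stage)) de$stage <- NA_character_
    if (is.null(de$region)) de$region <- NA_character_
    gene_universe <- sprintf("g%04d", seq_len(n_genes))
    outside <- setdiff(de$gene_id, gene_universe)
    if (length(outside) > 0) {
      stop("planted DE gene(s) outside the gene universe: ",
           paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(set_shift)) {
    for (sh in set_shift) {
      stopifnot(!is.null(sh$name), !is.null(sh$genes),
                is.finite(sh$log2_shift))
    }
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 libsize_sdlog = libsize_sdlog, dispersion = dispersion,
                 de = de, set_shift = set_shift, seed = as.integer(seed)),
            class = "expr_sim_config")
}

## log2 effect for each gene in one (stage, region) group: planted DE rows
## plus gene-set shifts, with NA stage/region as wildcard. Effects add.
.group_effects <- function(cfg, gene_ids, stage, region) {
  eff <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  if (!is.null(cfg$de)) {
    sel <- (is.na(cfg$de$stage) | cfg$de$stage == stage) &
      (is.na(cfg$de$region) | cfg$de$region == region)
    for (i in which(sel)) {
      eff[cfg$de$gene_id[i]] <- eff[cfg$de$gene_id[i]] + cfg$de$log2fc[i]
    }
  }
  for (sh in cfg$set_shift) {
    hit <- (is.null(sh$stage) || is.na(sh$stage) || sh$stage == stage) &&
      (is.null(sh$region) || is.na(sh$region) || sh$region == region)
    if (hit) {
      g <- intersect(sh$genes, gene_ids)
      eff[g] <- eff[g] + sh$log2_shift
    }
  }
  eff
}

#' Simulate a bulk RNA-seq count matrix with planted structure
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `expr` (an [expression_matrix()]) and `truth` (gene
#'   baselines, library factors, the planted effect matrix restricted to
#'   nonzero rows, planted DE table and set shifts, seed).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))

  set.seed(cfg$seed)
  baseline <- exp(stats::rnorm(cfg$n_genes, cfg$baseline_meanlog,
                               cfg$baseline_sdlog))
  names(baseline) <- gene_ids

  counts_cols <- list()
  meta_rows <- list()
  lib_all <- numeric(0)
  for (gi in seq_len(nrow(cfg$groups))) {
    stage <- cfg$groups$stage[gi]
    region <- cfg$groups$region[gi]
    n <- cfg$groups$n[gi]
    eff <- .group_effects(cfg, gene_ids, stage, region)
    mu_gene <- baseline * 2^eff
    set.seed(as.integer(cfg$seed + 131L * gi + 7L))
    lib <- exp(stats::rnorm(n, 0, cfg$libsize_sdlog))
    m <- matrix(0, nrow = cfg$n_genes, ncol = n)
    for (s in seq_len(n)) {
      m[, s] <- stats::rnbinom(cfg$n_genes, mu = mu_gene * lib[s],
                               size = 1 / cfg$dispersion)
    }
    ids <- sprintf("%s_%s_s%02d", stage, region, seq_len(n))
    colnames(m) <- ids
    counts_cols[[gi]] <- m
    lib_all <- c(lib_all, stats::setNames(lib, ids))
    meta_rows[[gi]] <- data.frame(
      sample_id = ids,
      patient_id = sprintf("%s_p%02d", stage, seq_len(n)),
      stage = stage, region = region, stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- gene_ids
  meta <- do.call(rbind, meta_rows)
  expr <- expression_matrix(counts, meta)

  truth <- list(de = cfg$de, set_shift = cfg$set_shift,
                baseline = baseline, library_factors = lib_all,
                dispersion = cfg$dispersion, seed = cfg$seed)
  list(expr = expr, truth = truth)
}
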