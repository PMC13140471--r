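#' Median-total-count normalization to log2 scale
#'
#' Each sample's counts are rescaled so that its total equals the median
#' total count across samples, then log2-transformed with a pseudocount:
#' `log2(count_gs * median(totals) / total_s + pseudocount)`. The correction
#' factor `median/total` absorbs per-sample sequencing depth exactly:
#' rescaling one sample's counts leaves its output unchanged provided the
#' median total is not displaced. A global rescaling of every sample by `c`
#' is, by the same algebra, carried through to the scaled counts (they all
#' become `c` times larger) — the scheme equalises samples at the cohort's
#' median depth rather than at a fixed reference.
#'
#' @param m an [expression_matrix()].
#' @param pseudocount added before the log; default 1.
#' @return a `normalized_matrix`: list with `logexpr` (genes x samples, log2
#'   scale), `median_total`, `pseudocount`, `samples` (metadata carried
#'   through).
#' @export
normalize_counts <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"), pseudocount >= 0)
  totals <- colSums(m$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  med <- stats::median(totals)
  scaled <- sweep(m$counts, 2, med / totals, `*`)
  structure(list(logexpr = log2(scaled + pseudocount),
                 median_total = med, pseudocount = pseudocount,
                 samples = m$samples),
            class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (median total %.0f, pseudocount %g)\n",
              nrow(x$logexpr), ncol(x$logexpr), x$median_total, x$pseudocount))
  invisible(x)
}

## gene universe after filtering; modes:
##  expressed - mean normalized value above min_mean (default)
##  all       - every gene
##  variable  - top n_var genes by variance of the normalized values
.filter_genes <- function(nm, gene_filter = list()) {
  mode <- gene_filter$mode %||% "expressed"
  le <- nm$logexpr
  genes <- switch(mode,
    all = rownames(le),
    expressed = rownames(le)[rowMeans(le) > (gene_filter$min_mean %||% 1)],
    variable = {
      n_var <- gene_filter$n_var %||% 500
      v <- apply(le, 1, stats::var)
      rownames(le)[order(v, decreasing = TRUE)[seq_len(min(n_var, nrow(le)))]]
    },
    stop("unknown gene_filter mode '", mode, "'", call. = FALSE))
  if (length(genes) == 0) {
    stop("gene universe empty after filtering (mode '", mode, "')",
         call. = FALSE)
  }
  genes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise transcriptome Euclidean distances between two sample groups
#'
#' For every cross-group sample pair (a, b), the Euclidean distance
#' `sqrt(sum_g (x_ga - x_gb)^2)` over the filtered gene universe of the
#' normalised matrix. All pairs are reported as a distribution plus summary
#' statistics, since group divergence is read off the distribution, not a
#' single number. With `matched_only = TRUE` only pairs sharing a
#' `patient_id` are kept (patient-matched contrasts, e.g. the two
#' peritumoural sites of one patient).
#'
#' @param nm a [normalize_counts()] result.
#' @param groupA,groupB disjoint non-empty character vectors of sample ids.
#' @param gene_filter list(`mode` = "expressed"/"all"/"variable",
#'   `min_mean`, `n_var`); see Details.
#' @param label contrast label carried into the result.
#' @param matched_only restrict to patient-matched pairs.
#' @return a `distance_result`: list with `pairs` (sample_a, sample_b,
#'   distance), `summary` (mean, median, n), `label`, `n_genes`.
#' @export
transcriptome_distance <- function(nm, groupA, groupB,
                                   gene_filter = list(mode = "expressed",
                                                      min_mean = 1),
                                   label = "A_vs_B",
                                   matched_only = FALSE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (length(groupA) == 0 || length(groupB) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups must be disjoint; shared sample(s): ",
         paste(intersect(groupA, groupB), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(groupA, groupB), colnames(nm$logexpr))
  if (length(missing) > 0) {
    stop("sample(s) not in the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes <- .filter_genes(nm, gene_filter)
  x <- nm$logexpr[genes, , drop = FALSE]
  pairs <- expand.grid(sample_a = groupA, sample_b = groupB,
                       stringsAsFactors = FALSE)
  if (matched_only) {
    pa <- nm$samples[pairs$sample_a, "patient_id"]
    pb <- nm$samples[pairs$sample_b, "patient_id"]
    pairs <- pairs[pa == pb, , drop = FALSE]
    if (nrow(pairs) == 0) {
      stop("no patient-matched cross-group pairs", call. = FALSE)
    }
  }
  pairs$distance <- sqrt(colSums(
    (x[, pairs$sample_a, drop = FALSE] - x[, pairs$sample_b, drop = FALSE])^2))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 summary = c(mean = mean(pairs$distance),
                             median = stats::median(pairs$distance),
                             n = nrow(pairs)),
                 label = label, n_genes = length(genes)),
            class = "distance_result")
}

#' @exportS3Method base::print
print.distance_result <- function(x, ...) {
  cat(sprintf("distance_result '%s': %d pairs over %d genes, mean %.2f, median %.2f\n",
              x$label, nrow(x$pairs), x$n_genes, x$summary["mean"],
              x$summary["median"]))
  invisible(x)
}

#' Differential expression with a normality-gated test battery
#'
#' Per gene: Shapiro-Wilk on each group at `alpha_normality` selects an
#' unpaired Student's t-test (both groups normal) or the Wilcoxon rank-sum
#' test. `log2fc` is the difference of group means on the normalised log2
#' scale (A minus B). P-values are Benjamini-Hochberg adjusted across the
#' tested genes only. Genes with zero variance in both groups are skipped
#' (p recorded as 1, flagged, excluded from the BH universe). Two
#' significance profiles are flagged: the standard call
#' (`|log2fc| > 0.5` and adjusted p < 0.05) and the strict volcano-plot
#' profile (`|log2fc| > 1.5` and FDR < 0.05).
#'
#' @param nm a [normalize_counts()] result.
#' @param groupA,groupB disjoint sample-id vectors, each of size >= 2.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param genes optional gene subset to test (default all genes).
#' @return a `deg_table` data.frame: `gene_id`, `log2fc`, `p_value`,
#'   `p_adj`, `method`, `skipped`, `sig_standard`, `sig_strict`.
#' @export
differential_expression <- function(nm, groupA, groupB,
                                    alpha_normality = 0.05, genes = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  x <- nm$logexpr[, groupA, drop = FALSE]
  y <- nm$logexpr[, groupB, drop = FALSE]
  if (is.null(genes)) genes <- rownames(nm$logexpr)
  ng <- length(genes)
  lfc <- rowMeans(x[genes, , drop = FALSE]) - rowMeans(y[genes, , drop = FALSE])
  p <- rep(NA_real_, ng)
  method <- rep(NA_character_, ng)
  skipped <- logical(ng)
  normal_ok <- function(v) {
    if (length(v) < 3 || diff(range(v)) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  for (i in seq_len(ng)) {
    gx <- x[genes[i], ]; gy <- y[genes[i], ]
    if (diff(range(c(gx, gy))) == 0) {
      skipped[i] <- TRUE
      p[i] <- 1
      method[i] <- "skipped"
      next
    }
    if (normal_ok(gx) && normal_ok(gy)) {
      p[i] <- stats::t.test(gx, gy, var.equal = TRUE)$p.value
      method[i] <- "t"
    } else {
      p[i] <- suppressWarnings(stats::wilcox.test(gx, gy, exact = FALSE,
                                                  correct = TRUE)$p.value)
      method[i] <- "wilcoxon"
    }
  }
  p_adj <- rep(NA_real_, ng)
  tested <- !skipped
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  p_adj[skipped] <- 1
  res <- data.frame(gene_id = genes, log2fc = unname(lfc), p_value = p,
                    p_adj = p_adj, method = method, skipped = skipped,
                    sig_standard = !skipped & abs(lfc) > 0.5 & p_adj < 0.05,
                    sig_strict = !skipped & abs(lfc) > 1.5 & p_adj < 0.05,
                    stringsAsFactors = FALSE)
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Per-sample gene-set enrichment scores (ssGSEA-style running sum)
#'
#' For each sample, genes are ranked by expression (descending; ties get
#' average ranks). A set's enrichment score is the sum over the ranked list
#' of the difference between the weighted in-set empirical CDF (weights
#' `rank^alpha`) and the unweighted out-of-set empirical CDF — the
#' rank-based running-sum integral of single-sample GSEA. Set members absent
#' from the matrix are dropped (counts recorded in attribute
#' `n_dropped_members`); sets with fewer than `min_size` present members
#' score `NA`. Optional range normalisation divides all scores by the
#' overall max-minus-min across the matrix.
#'
#' @param nm a [normalize_counts()] result (any `normalized_matrix`, or a
#'   plain genes x samples matrix).
#' @param sets a `gene_set_collection` (or named list of gene-id vectors).
#' @param alpha rank-weight exponent; 0.75 is the published default.
#' @param normalization `"none"` or `"range"`.
#' @param min_size minimum present members for a set to be scored.
#' @return a `signature_scores` matrix, sets x samples.
#' @export
score_signatures <- function(nm, sets, alpha = 0.75,
                             normalization = c("none", "range"),
                             min_size = 2) {
  normalization <- match.arg(normalization)
  le <- if (inherits(nm, "normalized_matrix")) nm$logexpr else as.matrix(nm)
  stopifnot(alpha >= 0, min_size >= 1)
  set_names <- names(sets)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(le),
                   dimnames = list(set_names, colnames(le)))
  dropped <- stats::setNames(integer(length(sets)), set_names)
  n <- nrow(le)
  membership <- lapply(sets, function(members) {
    members <- unique(members)
    present <- intersect(members, rownames(le))
    list(idx = match(present, rownames(le)),
         n_dropped = length(members) - length(present))
  })
  dropped[] <- vapply(membership, `[[`, integer(1), "n_dropped")
  for (s in seq_len(ncol(le))) {
    expr <- le[, s]
    # ranks by expression, descending, average for ties
    r <- rank(expr, ties.method = "average")          # ascending ranks
    ord <- order(expr, decreasing = TRUE, method = "radix")
    for (k in seq_along(sets)) {
      idx <- membership[[k]]$idx
      m <- length(idx)
      if (m < min_size || m >= n) next
      in_set <- logical(n)
      in_set[idx] <- TRUE
      in_ord <- in_set[ord]
      w <- r[ord]^alpha                                # rank weights, descending order walk
      num <- cumsum(ifelse(in_ord, w, 0))
      den <- sum(w[in_ord])
      p_in <- num / den
      p_out <- cumsum(!in_ord) / (n - m)
      scores[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalization == "range") {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  structure(scores, n_dropped_members = dropped,
            config = list(alpha = alpha, normalization = normalization,
                          min_size = min_size),
            class = c("signature_scores", "matrix", "array"))
}

#' Marker-set mean abundance score
#'
#' A simple stand-in for published immune deconvolution tools: the mean
#' normalised expression of a marker set per sample. Useful for relative
#' abundance contrasts between regions; not an absolute cell fraction.
#'
#' @param nm a [normalize_counts()] result.
#' @param markers named list of marker gene-id vectors (one per population).
#' @return matrix populations x samples of mean marker expression.
#' @export
marker_abundance <- function(nm, markers) {
  stopifnot(inherits(nm, "normalized_matrix"))
  t(vapply(markers, function(g) {
    g <- intersect(g, rownames(nm$logexpr))
    if (length(g) == 0) {
      return(stats::setNames(rep(NA_real_, ncol(nm$logexpr)),
                             colnames(nm$logexpr)))
    }
    colMeans(nm$logexpr[g, , drop = FALSE])
  }, numeric(ncol(nm$logexpr))))
}

#' Sample ids matching stage and/or region
#'
#' Convenience selector over the metadata of an [expression_matrix()] or
#' `normalized_matrix`.
#' @param x object carrying `$samples` metadata.
#' @param stage,region optional filters.
#' @return character vector of sample ids.
#' @export
samples_where <- function(x, stage = NULL, region = NULL) {
  meta <- x$samples
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(stage)) keep <- keep & meta$stage %in% stage
  if (!is.null(region)) keep <- keep & meta$region %in% region
  meta$sample_id[keep]
}
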