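#' Region-level cell-type abundance
#'
#' Counts, fractions (over the closed type vocabulary within the region) and
#' densities (cells/mm^2, when region areas are available) per
#' (region x cell type). Empty regions yield count 0 with `NA` fraction.
#'
#' @param cells a region-assigned [cell_table()].
#' @param regions optional list of `region_annotation`s supplying areas.
#' @param areas_um2 optional named numeric vector of region areas in um^2
#'   (overrides `regions`); densities are `NA` if neither source is given.
#' @return data.frame of abundance records: `patient_id`, `region`,
#'   `cell_type`, `count`, `fraction`, `density_mm2`.
#' @export
region_abundance <- function(cells, regions = NULL, areas_um2 = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  if (all(is.na(cells$region))) {
    stop("cells carry no region assignments; run assign_regions() first",
         call. = FALSE)
  }
  if (is.null(areas_um2) && !is.null(regions)) {
    areas_um2 <- stats::setNames(
      vapply(regions, region_area, numeric(1)),
      vapply(regions, `[[`, character(1), "region_label"))
  }
  tab <- table(factor(cells$region, levels = REGIONS),
               factor(cells$cell_type, levels = CELL_TYPES))
  totals <- rowSums(tab)
  out <- expand.grid(region = REGIONS, cell_type = CELL_TYPES,
                     stringsAsFactors = FALSE)
  out$count <- as.integer(tab[cbind(out$region, out$cell_type)])
  out$fraction <- ifelse(totals[out$region] > 0,
                         out$count / totals[out$region], NA_real_)
  out$density_mm2 <- if (!is.null(areas_um2)) {
    out$count / (areas_um2[out$region] / 1e6)
  } else {
    NA_real_
  }
  # denominators carried along so pooled bases can be recomputed exactly
  out$region_total <- as.integer(totals[out$region])
  out$area_um2 <- if (!is.null(areas_um2)) unname(areas_um2[out$region]) else
    NA_real_
  out <- data.frame(patient_id = attr(cells, "patient_id"), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tumour-infiltrating lymphocyte (TIL) proportion of a region
#'
#' The proportion of mononuclear inflammatory cells (lymphocytes +
#' macrophages; neutrophils are polymorphonuclear and excluded) occupying
#' the stromal compartment:
#' `(lymphocytes + macrophages) / (lymphocytes + macrophages + stromal)`.
#'
#' @param cells a region-assigned [cell_table()].
#' @param region region label to score.
#' @return proportion in [0, 1]; `NA` with a warning if the stromal
#'   compartment is empty.
#' @export
til_proportion <- function(cells, region) {
  stopifnot(inherits(cells, "cell_table"))
  region <- match.arg(region, REGIONS)
  sub <- cells[!is.na(cells$region) & cells$region == region, , drop = FALSE]
  n_mono <- sum(sub$cell_type %in% MONONUCLEAR_TYPES)
  n_strom <- sum(sub$cell_type == "stromal")
  if (n_mono + n_strom == 0) {
    warning("region '", region, "' has an empty stromal compartment",
            call. = FALSE)
    return(NA_real_)
  }
  n_mono / (n_mono + n_strom)
}

#' Peritumoural-minus-core lymphocyte difference per patient
#'
#' The spatial immune-segregation statistic: for each patient, lymphocyte
#' abundance in the selected peritumoural region minus abundance in the
#' tumour core, on a stated basis (fraction of all cells, density, or TIL
#' proportion). A positive difference marks peritumoural enrichment relative
#' to the core (lymphocytes accumulating at the boundary rather than
#' infiltrating), i.e. the immune-excluded phenotype. Patients missing
#' either measurement are excluded and listed in attribute `excluded`.
#'
#' @param abundance data.frame from [region_abundance()] (rows from several
#'   patients may be concatenated); for basis `"til"` supply instead a
#'   data.frame `patient_id, region, til` (e.g. built with
#'   [til_proportion()]).
#' @param basis `"fraction"`, `"density"` or `"til"`.
#' @param peri_region `"peri_1cm"` (default), `"peri_3cm"`, or `"pooled"`
#'   (count-weighted pooling of the two bands for fraction/density bases).
#' @param outcomes optional data.frame `patient_id, recurrence` (logical or
#'   0/1) merged into the result.
#' @return data.frame of gradient results: `patient_id`, `peri`, `core`,
#'   `difference`, `basis`, and `recurrence` when provided.
#' @export
peritumoural_core_difference <- function(abundance,
                                         basis = c("fraction", "density", "til"),
                                         peri_region = c("peri_1cm", "peri_3cm",
                                                         "pooled"),
                                         outcomes = NULL) {
  basis <- match.arg(basis)
  peri_region <- match.arg(peri_region)
  if (basis == "til") {
    stopifnot(all(c("patient_id", "region", "til") %in% names(abundance)))
    val <- abundance[, c("patient_id", "region")]
    val$value <- abundance$til
  } else {
    col <- if (basis == "fraction") "fraction" else "density_mm2"
    ab <- abundance[abundance$cell_type == "lymphocyte", , drop = FALSE]
    val <- ab[, c("patient_id", "region")]
    val$value <- ab[[col]]
    val$count <- ab$count
    # exact pooling denominators: all cells (fraction) or area (density)
    val$denom <- if (basis == "fraction") {
      if (!is.null(ab$region_total)) ab$region_total else NA_real_
    } else {
      if (!is.null(ab$area_um2)) ab$area_um2 / 1e6 else NA_real_
    }
  }
  per_patient <- function(pid) {
    v <- val[val$patient_id == pid, , drop = FALSE]
    core <- v$value[v$region == "core"]
    peri <- if (peri_region == "pooled") {
      rows <- v[v$region %in% c("peri_1cm", "peri_3cm") & !is.na(v$value), ,
                drop = FALSE]
      if (nrow(rows) == 0) numeric(0)
      else if (basis == "til" || any(is.na(rows$denom))) mean(rows$value)
      else sum(rows$count) / sum(rows$denom)  # exact pooled fraction/density
    } else {
      v$value[v$region == peri_region]
    }
    c(core = if (length(core) == 1 && !is.na(core)) core else NA_real_,
      peri = if (length(peri) == 1 && !is.na(peri)) peri else NA_real_)
  }
  pids <- unique(val$patient_id)
  mat <- t(vapply(pids, per_patient, numeric(2)))
  ok <- !is.na(mat[, "core"]) & !is.na(mat[, "peri"])
  res <- data.frame(patient_id = pids[ok],
                    peri = mat[ok, "peri"], core = mat[ok, "core"],
                    difference = mat[ok, "peri"] - mat[ok, "core"],
                    basis = basis, peri_region = peri_region,
                    stringsAsFactors = FALSE)
  if (!is.null(outcomes)) {
    stopifnot(all(c("patient_id", "recurrence") %in% names(outcomes)))
    outcomes$recurrence <- as.logical(outcomes$recurrence)
    res <- merge(res, outcomes[, c("patient_id", "recurrence")],
                 by = "patient_id", all.x = TRUE, sort = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "excluded") <- pids[!ok]
  class(res) <- c("gradient_result", "data.frame")
  res
}

#' Compare the immune gradient between outcome groups
#'
#' Tests whether the peritumoural-minus-core lymphocyte difference separates
#' recurrent from non-recurrent patients, using the normality-gated
#' t/Wilcoxon battery ([gated_two_sample_test()]). The same comparison is
#' also run on raw peritumoural abundance — the null contrast that
#' distinguishes spatial organisation from bulk immune quantity: a cohort
#' can be matched on raw peritumoural abundance yet differ in the gradient.
#'
#' @param grs a `gradient_result` with a `recurrence` column (no `NA`s among
#'   tested patients).
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return list of two test reports (`difference` and `raw_peri`), each with
#'   `method`, `p_value`, group medians (`median_nonrecurrent`,
#'   `median_recurrent`), `direction` (`"non_recurrent_higher"`,
#'   `"recurrent_higher"` or `"none"`), and group sizes.
#' @export
compare_outcome_groups <- function(grs, alpha_normality = 0.05) {
  stopifnot(inherits(grs, "data.frame"), "recurrence" %in% names(grs))
  grs <- grs[!is.na(grs$recurrence), , drop = FALSE]
  n_rec <- sum(grs$recurrence)
  n_non <- sum(!grs$recurrence)
  if (n_rec < 2 || n_non < 2) {
    stop("each outcome group needs >= 2 patients (got ", n_non,
         " non-recurrent, ", n_rec, " recurrent)", call. = FALSE)
  }
  run <- function(values) {
    x <- values[!grs$recurrence]  # non-recurrent
    y <- values[grs$recurrence]   # recurrent
    tst <- gated_two_sample_test(x, y, alpha_normality)
    list(method = tst$method, p_value = tst$p_value,
         median_nonrecurrent = tst$estimate_x,
         median_recurrent = tst$estimate_y,
         direction = switch(tst$direction,
                            x_higher = "non_recurrent_higher",
                            y_higher = "recurrent_higher",
                            "none"),
         n_nonrecurrent = n_non, n_recurrent = n_rec)
  }
  list(difference = run(grs$difference), raw_peri = run(grs$peri))
}
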