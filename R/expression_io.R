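#' Construct an expression matrix with sample metadata
#'
#' The substrate of the transcriptomic stages: a genes x samples matrix of
#' raw read counts plus per-sample metadata (patient, histological stage,
#' sampled region, optional recurrence status). Modelled on the plain
#' list-of-matrix-and-frame containers of the bulk RNA-seq toolchain.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param sample_meta data.frame with one row per sample: `sample_id`,
#'   `patient_id`, `stage` (one of benign/borderline/malignant), `region`
#'   (one of [REGIONS]) and optionally `recurrence` (logical).
#' @return an `expression_matrix` object (list with `$counts`, `$samples`).
#' @export
expression_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "stage", "region")
  missing_cols <- setdiff(need, names(sample_meta))
  if (length(missing_cols) > 0) {
    stop("sample_meta missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(absent) > 0) {
    stop("sample(s) in counts absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  stages <- c("benign", "borderline", "malignant")
  if (any(!sample_meta$stage %in% stages)) {
    stop("stage must be one of: ", paste(stages, collapse = ", "), call. = FALSE)
  }
  if (any(!sample_meta$region %in% REGIONS)) {
    stop("region must be one of: ", paste(REGIONS, collapse = ", "),
         call. = FALSE)
  }
  rownames(sample_meta) <- sample_meta$sample_id
  sample_meta <- sample_meta[colnames(counts), , drop = FALSE]
  structure(list(counts = counts, samples = sample_meta),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  stages: ", paste(names(table(x$samples$stage)), collapse = ", "), "\n")
  cat("  regions:", paste(names(table(x$samples$region)), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::dim
dim.expression_matrix <- function(x) dim(x$counts)

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV: genes x samples with gene ids in the first column and sample ids in
#' the header. MTX: a MatrixMarket triplet file with `<path>.rows` (gene ids)
#' and `<path>.cols` (sample ids) sidecar files, one id per line. Metadata is
#' a TSV keyed by `sample_id`.
#'
#' @param counts_path counts file (`.tsv` or `.mtx`).
#' @param meta_path sample metadata TSV.
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(counts_path, meta_path,
                            format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) "mtx"
      else "tsv"
  }
  counts <- if (format == "tsv") {
    df <- utils::read.delim(counts_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
  } else {
    m <- as.matrix(Matrix::readMM(counts_path))
    rows <- readLines(paste0(counts_path, ".rows"), warn = FALSE)
    cols <- readLines(paste0(counts_path, ".cols"), warn = FALSE)
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop("MTX sidecar length mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but sidecars give ", length(rows), " rows / ", length(cols),
           " cols", call. = FALSE)
    }
    dimnames(m) <- list(rows, cols)
    m
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if ("recurrence" %in% names(meta)) meta$recurrence <- as.logical(meta$recurrence)
  expression_matrix(counts, meta)
}

#' Write an expression matrix to TSV or MatrixMarket files
#'
#' @param m an [expression_matrix()].
#' @param counts_path output counts path (`.tsv` or `.mtx`; MTX writes
#'   `.rows`/`.cols` sidecars).
#' @param meta_path output metadata TSV.
#' @export
write_expression <- function(m, counts_path, meta_path) {
  stopifnot(inherits(m, "expression_matrix"))
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), counts_path)
    writeLines(rownames(m$counts), paste0(counts_path, ".rows"))
    writeLines(colnames(m$counts), paste0(counts_path, ".cols"))
  } else {
    df <- data.frame(gene_id = rownames(m$counts), m$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  utils::write.table(m$samples, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(counts_path)
}

#' Write a tidy feature table to TSV
#'
#' One row per cell (node-level features) or per region aggregate, written
#' tab-separated with a header — the interchange format for downstream
#' plotting or statistics outside R.
#'
#' @param records a data.frame.
#' @param path output TSV path.
#' @export
write_feature_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
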