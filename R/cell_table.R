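#' Construct and validate a cell table
#'
#' A cell table is the spatial substrate of the pipeline: one row per
#' segmented nucleus with its centroid in micrometres and its class label.
#' Region labels (`core`, `peri_1cm`, `peri_3cm`) may be present already or
#' assigned later with [assign_regions()].
#'
#' @param cells data.frame with columns `cell_id` (unique character),
#'   `x_um`, `y_um` (finite, non-negative reals), `cell_type` (one of
#'   [CELL_TYPES]) and optionally `region` (one of [REGIONS] or `NA` for
#'   unassigned).
#' @param slide_id,patient_id identifiers stored as attributes.
#' @return A `cell_table`: a data.frame with attributes `slide_id` and
#'   `patient_id`.
#' @export
cell_table <- function(cells, slide_id = "slide1", patient_id = "patient1") {
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "x_um", "y_um", "cell_type")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    stop("duplicate cell_id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("x_um", "y_um")) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      stop("non-finite or negative ", col, " at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  cells$cell_type <- as.character(cells$cell_type)
  bad_type <- which(!cells$cell_type %in% CELL_TYPES)
  if (length(bad_type) > 0) {
    stop("cell_type outside the closed vocabulary at row(s): ",
         paste(utils::head(bad_type, 10), collapse = ", "),
         " (map unknown classes to 'other' via type_map)", call. = FALSE)
  }
  if (is.null(cells$region)) {
    cells$region <- NA_character_
  } else {
    cells$region <- as.character(cells$region)
    bad_reg <- which(!is.na(cells$region) & !cells$region %in% REGIONS)
    if (length(bad_reg) > 0) {
      stop("region label outside {", paste(REGIONS, collapse = ", "),
           "} at row(s): ", paste(utils::head(bad_reg, 10), collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(cells) <- NULL
  structure(cells[, c("cell_id", "x_um", "y_um", "cell_type", "region")],
            slide_id = as.character(slide_id),
            patient_id = as.character(patient_id),
            class = c("cell_table", "data.frame"))
}

#' @exportS3Method base::print
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells | slide %s | patient %s\n",
              nrow(x), attr(x, "slide_id"), attr(x, "patient_id")))
  tab <- table(factor(x$cell_type, levels = CELL_TYPES))
  cat("  types:  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  reg <- table(factor(x$region, levels = REGIONS), useNA = "ifany")
  cat("  regions:", paste(sprintf("%s=%d", ifelse(is.na(names(reg)), "unassigned",
                                                  names(reg)), reg),
                          collapse = " "), "\n")
  invisible(x)
}

#' Read a cell table from delimited text
#'
#' Parses a CSV/TSV export of a nuclear segmentation/classification pipeline.
#' Column names are mapped through `dialect` rather than read positionally,
#' since exports vary; class labels not in [CELL_TYPES] and not covered by
#' `type_map` are mapped to `other` with a warning (the count is stored in
#' attribute `n_unknown_type`).
#'
#' @param path path to a delimited text file with a header.
#' @param dialect named list mapping the canonical column roles
#'   (`cell_id`, `x`, `y`, `cell_type`, `region`, `slide_id`, `patient_id`)
#'   to column names in the file. `x`, `y` and `cell_type` are mandatory
#'   roles; a missing `cell_id` role autogenerates `cell_0001`-style ids.
#' @param type_map named character vector mapping foreign class labels to
#'   [CELL_TYPES] entries, e.g. `c(fibroblast = "stromal")`.
#' @param pixel_size_um multiplier applied to raw coordinates (exports in
#'   pixel units); default 1 means coordinates are already micrometres.
#' @param sep field separator; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path,
                            dialect = list(cell_id = "cell_id", x = "x_um",
                                           y = "y_um", cell_type = "cell_type",
                                           region = "region",
                                           slide_id = "slide_id",
                                           patient_id = "patient_id"),
                            type_map = character(),
                            pixel_size_um = 1,
                            sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (role in c("x", "y", "cell_type")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("format error: mandatory column for role '", role, "' (",
           if (is.null(col)) "unmapped" else col, ") not found in ", path,
           call. = FALSE)
    }
  }
  get_col <- function(role) {
    col <- dialect[[role]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  x <- suppressWarnings(as.numeric(get_col("x")))
  y <- suppressWarnings(as.numeric(get_col("y")))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    stop("non-numeric coordinate(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  ids <- get_col("cell_id")
  if (is.null(ids)) ids <- sprintf("cell_%04d", seq_len(nrow(raw)))
  types <- as.character(get_col("cell_type"))
  if (length(type_map) > 0) {
    mapped <- type_map[types]
    types[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  unknown <- !types %in% CELL_TYPES
  n_unknown <- sum(unknown)
  if (n_unknown > 0) {
    warning(n_unknown, " cell(s) with unmapped class label mapped to 'other' (",
            paste(utils::head(unique(types[unknown]), 5), collapse = ", "), ")",
            call. = FALSE)
    types[unknown] <- "other"
  }
  slide <- get_col("slide_id")
  pat <- get_col("patient_id")
  ct <- cell_table(
    data.frame(cell_id = as.character(ids),
               x_um = x * pixel_size_um,
               y_um = y * pixel_size_um,
               cell_type = types,
               region = if (is.null(get_col("region"))) NA_character_
                        else as.character(get_col("region")),
               stringsAsFactors = FALSE),
    slide_id = if (is.null(slide)) "slide1" else unique(slide)[1],
    patient_id = if (is.null(pat)) "patient1" else unique(pat)[1])
  attr(ct, "n_unknown_type") <- n_unknown
  ct
}

#' Read a cell table from a HoVer-Net-style JSON export
#'
#' Accepts the common nucleus-dictionary convention: a top-level `nuc` object
#' whose entries carry a `centroid` (x, y) and a `type` field. Numeric type
#' codes are translated through `type_codes`. This importer is a dialect
#' assumption: the exact export schema of deep segmentation pipelines varies.
#'
#' @param path JSON file.
#' @param type_codes named character vector mapping type codes (as character)
#'   to [CELL_TYPES]; the default follows the common 0/1/2/3/4/5 convention
#'   (none/neoplastic/inflammatory/connective/necrotic/epithelial) collapsed
#'   to this package's vocabulary.
#' @param pixel_size_um coordinate multiplier (exports are usually in pixels).
#' @inheritParams read_cell_table
#' @return a [cell_table()].
#' @export
read_cell_table_json <- function(path,
                                 type_codes = c("0" = "other",
                                                "1" = "tumour",
                                                "2" = "lymphocyte",
                                                "3" = "stromal",
                                                "4" = "other",
                                                "5" = "other"),
                                 pixel_size_um = 1) {
  obj <- jsonlite::read_json(path)
  nuc <- if (!is.null(obj$nuc)) obj$nuc else obj
  if (length(nuc) == 0) {
    return(cell_table(data.frame(cell_id = character(), x_um = numeric(),
                                 y_um = numeric(), cell_type = character(),
                                 stringsAsFactors = FALSE)))
  }
  ids <- names(nuc)
  if (is.null(ids)) ids <- sprintf("cell_%04d", seq_along(nuc))
  cent <- t(vapply(nuc, function(n) as.numeric(unlist(n$centroid)[1:2]),
                   numeric(2)))
  types_raw <- vapply(nuc, function(n) as.character(n$type), character(1))
  types <- type_codes[types_raw]
  n_unknown <- sum(is.na(types))
  if (n_unknown > 0) {
    warning(n_unknown, " nucleus type code(s) without mapping set to 'other'",
            call. = FALSE)
    types[is.na(types)] <- "other"
  }
  ct <- cell_table(data.frame(cell_id = ids,
                              x_um = cent[, 1] * pixel_size_um,
                              y_um = cent[, 2] * pixel_size_um,
                              cell_type = unname(types),
                              stringsAsFactors = FALSE))
  attr(ct, "n_unknown_type") <- n_unknown
  ct
}

#' Write a cell table to delimited text
#'
#' Writes a header-ed CSV (or TSV) containing the cell columns plus
#' `slide_id`/`patient_id`, so that `read_cell_table()` on the output
#' reconstructs the table field-by-field.
#'
#' @param cells a [cell_table()].
#' @param path output path; extension `.tsv` switches to tab separation.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(inherits(cells, "cell_table"))
  out <- as.data.frame(cells)
  out$slide_id <- attr(cells, "slide_id")
  out$patient_id <- attr(cells, "patient_id")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
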