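#' Read a gene-set collection in GMT format
#'
#' GMT is the MSigDB convention: one set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member ids
#' within a set are removed on load.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: a named list of character vectors of
#'   member gene ids, with per-set descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error in GMT line ", i,
           ": expected at least 3 tab-separated fields (name, description, ",
           "members...), got ", length(fields), call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop("duplicate gene-set name '", nm, "' at GMT line ", i, call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("gene set '", nm, "' at GMT line ", i, " has no members",
           call. = FALSE)
    }
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets a `gene_set_collection` or a named list of character vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10)) {
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}
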