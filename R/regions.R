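#' Region annotations
#'
#' A region annotation ties one of the three sampling sites (tumour core,
#' peritumoural 1 cm, peritumoural 3 cm) to a geometry in the slide's
#' micrometre frame: either a simple polygon or an annulus
#' (centre, inner radius, outer radius; `r_inner = 0` gives a disk).
#' Boundary points belong to the region (closed-set convention).
#'
#' @param region_label one of [REGIONS].
#' @param center numeric length-2 centre (x, y) in micrometres.
#' @param r_inner,r_outer annulus radii, `0 <= r_inner < r_outer`.
#' @return a `region_annotation` object.
#' @export
annulus_region <- function(region_label, center, r_inner, r_outer) {
  region_label <- match.arg(region_label, REGIONS)
  stopifnot(length(center) == 2, is.finite(center),
            is.finite(r_inner), is.finite(r_outer))
  if (!(r_inner >= 0 && r_inner < r_outer)) {
    stop("annulus requires 0 <= r_inner < r_outer", call. = FALSE)
  }
  structure(list(region_label = region_label, type = "annulus",
                 center = as.numeric(center),
                 r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer)),
            class = "region_annotation")
}

#' @rdname annulus_region
#' @param vertices n x 2 numeric matrix of polygon vertices (micrometres),
#'   in order; the polygon is closed implicitly and must be simple
#'   (non-self-intersecting).
#' @export
polygon_region <- function(region_label, vertices) {
  region_label <- match.arg(region_label, REGIONS)
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3, all(is.finite(vertices)))
  # drop explicit closing vertex if present
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (.polygon_self_intersects(vertices)) {
    stop("polygon for region '", region_label,
         "' is self-intersecting (must be simple)", call. = FALSE)
  }
  structure(list(region_label = region_label, type = "polygon",
                 vertices = unname(vertices)),
            class = "region_annotation")
}

#' @exportS3Method base::print
print.region_annotation <- function(x, ...) {
  if (x$type == "annulus") {
    cat(sprintf("region '%s': annulus centre (%.1f, %.1f), r %.1f-%.1f um\n",
                x$region_label, x$center[1], x$center[2], x$r_inner, x$r_outer))
  } else {
    cat(sprintf("region '%s': polygon with %d vertices, area %.0f um^2\n",
                x$region_label, nrow(x$vertices), region_area(x)))
  }
  invisible(x)
}

#' Area of a region geometry in square micrometres
#'
#' Annulus: `pi * (r_outer^2 - r_inner^2)`. Polygon: shoelace formula.
#' @param region a `region_annotation`.
#' @return area in um^2.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "region_annotation"))
  if (region$type == "annulus") {
    pi * (region$r_outer^2 - region$r_inner^2)
  } else {
    v <- region$vertices
    n <- nrow(v)
    j <- c(2:n, 1)
    abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  }
}

## segment intersection test on open interiors; shared endpoints of adjacent
## edges do not count. Used only to reject self-intersecting polygons.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

## Even-odd ray casting with an explicit on-boundary check so that boundary
## points count as inside (closed polygons). Vectorised over points.
.points_in_polygon <- function(x, y, vertices, eps = 1e-9) {
  v <- vertices
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (k in seq_len(n)) {
    x1 <- v[j[k], 1]; y1 <- v[j[k], 2]; x2 <- v[k, 1]; y2 <- v[k, 2]
    # boundary: point within eps of segment k
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    # even-odd crossing of the horizontal ray towards +x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

.points_in_region <- function(x, y, region) {
  if (region$type == "annulus") {
    r2 <- (x - region$center[1])^2 + (y - region$center[2])^2
    r2 >= region$r_inner^2 & r2 <= region$r_outer^2
  } else {
    .points_in_polygon(x, y, region$vertices)
  }
}

#' Validate that a set of regions is pairwise disjoint
#'
#' Concentric annuli are compared exactly on their radial intervals. For other
#' geometry pairs the check is approximate: each geometry's vertices (or, for
#' annuli, points sampled on both bounding circles) and its centroid are
#' tested for containment in the other geometry's interior. Geometries that
#' merely touch on their boundary are allowed (ties are resolved to the
#' first-listed region during assignment).
#'
#' @param regions list of `region_annotation`s.
#' @return invisibly `TRUE`; errors naming the overlapping pair otherwise.
#' @export
validate_regions <- function(regions) {
  stopifnot(is.list(regions),
            all(vapply(regions, inherits, logical(1), "region_annotation")))
  labs <- vapply(regions, `[[`, character(1), "region_label")
  if (anyDuplicated(labs)) {
    stop("duplicate region label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  probe_pts <- function(r) {
    if (r$type == "annulus") {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      mid <- (r$r_inner + r$r_outer) / 2
      rads <- unique(c(mid, pmax(r$r_inner, 1e-9), r$r_outer))
      do.call(rbind, lapply(rads, function(rr)
        cbind(r$center[1] + rr * cos(th), r$center[2] + rr * sin(th))))
    } else {
      rbind(r$vertices, colMeans(r$vertices))
    }
  }
  interior <- function(x, y, r) {
    if (r$type == "annulus") {
      d2 <- (x - r$center[1])^2 + (y - r$center[2])^2
      d2 > r$r_inner^2 & d2 < r$r_outer^2
    } else {
      # strict interior: inside by even-odd but not on the boundary
      .points_in_polygon(x, y, r$vertices) &
        !.on_polygon_boundary(x, y, r$vertices, eps = 1e-6)
    }
  }
  n <- length(regions)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- regions[[i]]; b <- regions[[j]]
      overlap <- FALSE
      if (a$type == "annulus" && b$type == "annulus" &&
          isTRUE(all.equal(a$center, b$center))) {
        overlap <- max(a$r_inner, b$r_inner) < min(a$r_outer, b$r_outer)
      } else {
        pa <- probe_pts(a); pb <- probe_pts(b)
        overlap <- any(interior(pa[, 1], pa[, 2], b)) ||
          any(interior(pb[, 1], pb[, 2], a))
      }
      if (overlap) {
        stop("regions '", a$region_label, "' and '", b$region_label,
             "' overlap; regions must be pairwise disjoint", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

.on_polygon_boundary <- function(x, y, vertices, eps = 1e-9) {
  v <- vertices
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  on_b <- logical(length(x))
  for (k in seq_len(n)) {
    x1 <- v[j[k], 1]; y1 <- v[j[k], 2]; x2 <- v[k, 1]; y2 <- v[k, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    on_b <- on_b | d2 <= eps^2
  }
  on_b
}

#' Assign region labels to cells by geometric containment
#'
#' Each cell falling inside exactly one region geometry receives that label;
#' cells outside all geometries remain unassigned (`NA`). Containment uses
#' the even-odd rule for polygons and radial comparison for annuli, with
#' boundary points counting as inside. If geometries touch, a cell on the
#' shared boundary is assigned to the first-listed region and the number of
#' such ties is recorded in attribute `n_boundary_ties`.
#'
#' @param cells a [cell_table()].
#' @param regions list of `region_annotation`s (validated for disjointness).
#' @return the cell table with its `region` column filled in.
#' @export
assign_regions <- function(cells, regions) {
  stopifnot(inherits(cells, "cell_table"))
  validate_regions(regions)
  hits <- vapply(regions,
                 function(r) .points_in_region(cells$x_um, cells$y_um, r),
                 logical(nrow(cells)))
  if (nrow(cells) == 0) {
    attr(cells, "n_boundary_ties") <- 0L
    return(cells)
  }
  hits <- matrix(hits, nrow = nrow(cells))
  n_hit <- rowSums(hits)
  first_hit <- apply(hits, 1, function(h) which(h)[1])
  lab <- vapply(regions, `[[`, character(1), "region_label")
  cells$region <- ifelse(n_hit >= 1, lab[first_hit], NA_character_)
  attr(cells, "n_boundary_ties") <- sum(n_hit > 1)
  cells
}

#' Read region annotations from GeoJSON or annulus CSV
#'
#' GeoJSON: a FeatureCollection of Polygon features, each with a
#' `region_label` property; coordinates are taken as micrometres. Annulus
#' CSV: five columns `region_label, center_x, center_y, r_inner, r_outer`.
#'
#' @param path input file; format guessed from the extension unless given.
#' @param format `"geojson"` or `"annulus_csv"`.
#' @return list of `region_annotation`s (validated pairwise disjoint).
#' @export
read_region_annotations <- function(path, format = c("auto", "geojson",
                                                     "annulus_csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "annulus_csv"
  }
  regions <- if (format == "geojson") {
    obj <- jsonlite::read_json(path)
    feats <- if (!is.null(obj$features)) obj$features else list(obj)
    lapply(feats, function(f) {
      lab <- f$properties$region_label
      if (is.null(lab)) stop("GeoJSON feature lacks a 'region_label' property",
                             call. = FALSE)
      if (!identical(f$geometry$type, "Polygon")) {
        stop("unsupported geometry type '", f$geometry$type,
             "' (only Polygon)", call. = FALSE)
      }
      ring <- f$geometry$coordinates[[1]]
      v <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p)[1:2])))
      polygon_region(lab, v)
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("region_label", "center_x", "center_y", "r_inner", "r_outer")
    if (!all(need %in% names(df))) {
      stop("annulus CSV needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i)
      annulus_region(df$region_label[i], c(df$center_x[i], df$center_y[i]),
                     df$r_inner[i], df$r_outer[i]))
  }
  validate_regions(regions)
  regions
}

#' Write annulus region annotations to CSV
#'
#' @param regions list of annulus `region_annotation`s.
#' @param path output CSV path.
#' @export
write_region_annotations <- function(regions, path) {
  stopifnot(all(vapply(regions, function(r) r$type == "annulus", logical(1))))
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(region_label = r$region_label, center_x = r$center[1],
               center_y = r$center[2], r_inner = r$r_inner,
               r_outer = r$r_outer)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
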