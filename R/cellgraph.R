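#' Cell-pair graph configuration
#'
#' Parameters of the pairwise cell-type graph: edges are proposed by a
#' k-nearest-neighbour search between the two types and every proposed edge
#' longer than `max_edge_um` is removed. The 25 um default is the
#' empirically established short-range interaction radius of cell-graph
#' computational pathology; it dominates the result, so `k` mainly bounds
#' the candidate set (no value is canonical in the literature; 5 is a common
#' choice).
#'
#' @param pair character vector of length 1 or 2 naming the cell types of
#'   the graph (A, B); A may equal B.
#' @param k nearest-neighbour count (>= 1).
#' @param max_edge_um edge-length ceiling in um (> 0); candidate edges
#'   longer than this are discarded.
#' @return a `graph_config` list.
#' @export
graph_config <- function(pair, k = 5, max_edge_um = 25) {
  pair <- as.character(pair)
  if (length(pair) == 1) pair <- c(pair, pair)
  stopifnot(length(pair) == 2)
  bad <- setdiff(pair, CELL_TYPES)
  if (length(bad) > 0) {
    stop("unknown cell type(s) in pair: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(max_edge_um) || max_edge_um <= 0) {
    stop("max_edge_um must be positive", call. = FALSE)
  }
  structure(list(pair = sort(pair), k = as.integer(k),
                 max_edge_um = as.numeric(max_edge_um)),
            class = "graph_config")
}

## k nearest target cells for each query cell, ties at equal distance broken
## by target cell_id lexicographic order (deterministic across platforms).
## Returns a data.frame of directed candidate pairs with distances.
.knn_candidates <- function(qx, qy, qid, tx, ty, tid, k) {
  if (length(qid) == 0 || length(tid) == 0) {
    return(data.frame(u = character(), v = character(),
                      length_um = numeric(), stringsAsFactors = FALSE))
  }
  ord_t <- order(tid, method = "radix")
  tx <- tx[ord_t]; ty <- ty[ord_t]; tid <- tid[ord_t]
  out_u <- vector("list", length(qid))
  out_v <- vector("list", length(qid))
  out_d <- vector("list", length(qid))
  for (i in seq_along(qid)) {
    d <- sqrt((tx - qx[i])^2 + (ty - qy[i])^2)
    self <- tid == qid[i]
    d[self] <- Inf  # a cell is never its own neighbour
    # targets are pre-sorted by id, so order(d) is distance-then-id
    kk <- min(k, sum(is.finite(d)))
    if (kk == 0) next
    sel <- order(d, method = "radix")[seq_len(kk)]
    out_u[[i]] <- rep.int(qid[i], kk)
    out_v[[i]] <- tid[sel]
    out_d[[i]] <- d[sel]
  }
  data.frame(u = unlist(out_u), v = unlist(out_v),
             length_um = unlist(out_d), stringsAsFactors = FALSE)
}

#' Build a pairwise cell-type graph
#'
#' For each cell of type A, its `k` nearest cells of type B are proposed as
#' edges (and symmetrically B to A when the types differ); the union is
#' symmetrised into an undirected simple graph and every edge longer than
#' `max_edge_um` is removed. Edge lengths are Euclidean distances in the
#' original um frame. If either type is absent an empty graph is returned.
#'
#' @param cells a [cell_table()].
#' @param cfg a [graph_config()].
#' @param region optional region label; when given, only cells assigned to
#'   that region enter the graph (the default, per-region construction
#'   matches region-level reporting; pass `NULL` for a whole-slide graph).
#' @return a `cell_pair_graph`: list with `nodes` (cell_id, cell_type, x_um,
#'   y_um), `edges` (u, v, length_um; u < v), `pair`, `config`, `slide_id`,
#'   `region`.
#' @export
build_pair_graph <- function(cells, cfg, region = NULL) {
  stopifnot(inherits(cells, "cell_table"), inherits(cfg, "graph_config"))
  if (!is.null(region)) {
    region <- match.arg(region, REGIONS)
    cells_sub <- cells[!is.na(cells$region) & cells$region == region, ,
                       drop = FALSE]
  } else {
    cells_sub <- cells
  }
  a <- cfg$pair[1]; b <- cfg$pair[2]
  ca <- cells_sub[cells_sub$cell_type == a, , drop = FALSE]
  cb <- cells_sub[cells_sub$cell_type == b, , drop = FALSE]
  nodes <- unique(rbind(ca, cb))[, c("cell_id", "cell_type", "x_um", "y_um")]
  nodes <- nodes[order(nodes$cell_id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL

  cand <- .knn_candidates(ca$x_um, ca$y_um, ca$cell_id,
                          cb$x_um, cb$y_um, cb$cell_id, cfg$k)
  if (a != b) {
    cand <- rbind(cand, .knn_candidates(cb$x_um, cb$y_um, cb$cell_id,
                                        ca$x_um, ca$y_um, ca$cell_id, cfg$k))
  }
  if (nrow(cand) > 0) {
    # canonical undirected form, dedupe, threshold filter
    u <- pmin(cand$u, cand$v)
    v <- pmax(cand$u, cand$v)
    keep <- !duplicated(paste(u, v, sep = "\r")) & cand$length_um <= cfg$max_edge_um
    edges <- data.frame(u = u[keep], v = v[keep],
                        length_um = cand$length_um[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(), v = character(),
                        length_um = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, pair = cfg$pair, config = cfg,
                 slide_id = attr(cells, "slide_id"),
                 region = if (is.null(region)) NA_character_ else region),
            class = "cell_pair_graph")
}

#' @exportS3Method base::print
print.cell_pair_graph <- function(x, ...) {
  cat(sprintf("cell_pair_graph %s-%s: %d nodes, %d edges (k=%d, <=%.1f um)%s\n",
              x$pair[1], x$pair[2], nrow(x$nodes), nrow(x$edges),
              x$config$k, x$config$max_edge_um,
              if (is.na(x$region)) "" else paste0(" [", x$region, "]")))
  invisible(x)
}

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges[, c("u", "v"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = g$nodes$cell_id, stringsAsFactors = FALSE))
}

#' Connected components of a cell-pair graph
#'
#' The "subgraph" a cell belongs to is its connected component; `Nsubgraph`
#' is that component's size.
#'
#' @param g a `cell_pair_graph`.
#' @return data.frame `cell_id, component, Nsubgraph` (component ids are
#'   arbitrary but stable integers).
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "cell_pair_graph"))
  if (nrow(g$nodes) == 0) {
    return(data.frame(cell_id = character(), component = integer(),
                      Nsubgraph = integer(), stringsAsFactors = FALSE))
  }
  comp <- igraph::components(.as_igraph(g))
  data.frame(cell_id = g$nodes$cell_id,
             component = as.integer(comp$membership),
             Nsubgraph = as.integer(comp$csize[comp$membership]),
             stringsAsFactors = FALSE)
}

#' Per-cell topological descriptors of a cell-pair graph
#'
#' Computes, for every node: `Degree` (incident edges), `Nsubgraph`
#' (connected-component size), `MinEdgeLength` / `MeanEdgeLength` (over
#' incident edges; `NA` for isolated cells), `ClusteringCoefficient` (local,
#' `2 T(v) / (deg (deg - 1))`, 0 when degree < 2) and betweenness centrality
#' over unweighted shortest paths, reported both raw (`BetweennessRaw`) and
#' normalised by `(n - 1)(n - 2) / 2` within the node's component
#' (`Betweenness`; 0 for components of fewer than 3 nodes), so values are
#' comparable across regions with different cell counts.
#'
#' @param g a `cell_pair_graph`.
#' @return data.frame of `NodeFeatureRecord`s, one row per node.
#' @export
node_features <- function(g) {
  stopifnot(inherits(g, "cell_pair_graph"))
  n <- nrow(g$nodes)
  if (n == 0) {
    return(data.frame(cell_id = character(), Degree = integer(),
                      Nsubgraph = integer(), MinEdgeLength = numeric(),
                      MeanEdgeLength = numeric(),
                      ClusteringCoefficient = numeric(),
                      Betweenness = numeric(), BetweennessRaw = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- g$nodes$cell_id
  ig <- .as_igraph(g)
  deg <- igraph::degree(ig)
  comp <- igraph::components(ig)
  nsub <- as.integer(comp$csize[comp$membership])

  # incident edge-length summaries
  min_len <- rep(NA_real_, n)
  mean_len <- rep(NA_real_, n)
  if (nrow(g$edges) > 0) {
    idx <- c(match(g$edges$u, ids), match(g$edges$v, ids))
    len <- rep(g$edges$length_um, 2)
    min_len_v <- tapply(len, idx, min)
    mean_len_v <- tapply(len, idx, mean)
    pos <- as.integer(names(min_len_v))
    min_len[pos] <- as.numeric(min_len_v)
    mean_len[pos] <- as.numeric(mean_len_v)
  }

  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[deg < 2] <- 0  # convention: undefined -> 0 so aggregates stay defined

  btw_raw <- igraph::betweenness(ig, directed = FALSE, weights = NA,
                                 normalized = FALSE)
  denom <- (nsub - 1) * (nsub - 2) / 2
  btw_norm <- ifelse(nsub > 2, btw_raw / denom, 0)

  data.frame(cell_id = ids, Degree = as.integer(deg), Nsubgraph = nsub,
             MinEdgeLength = min_len, MeanEdgeLength = mean_len,
             ClusteringCoefficient = as.numeric(cc),
             Betweenness = as.numeric(btw_norm),
             BetweennessRaw = as.numeric(btw_raw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate node features per region and cell type
#'
#' Joins node-level feature records back to the cell table and summarises
#' each feature per group (mean, median, count). Undefined (`NA`)
#' edge-length features are excluded from their aggregates, with the number
#' of excluded cells reported per group. Empty groups (requested via
#' factor levels in `cells`) yield rows with count 0 and `NA` statistics.
#'
#' @param records output of [node_features()] (rows from several graphs may
#'   be concatenated; add provenance columns beforehand if needed).
#' @param cells the [cell_table()] the graphs were built from.
#' @param group_by character vector of grouping columns, any of
#'   `"region"`, `"cell_type"`.
#' @return tidy data.frame: grouping columns, `feature`, `mean`, `median`,
#'   `n`, `n_excluded`.
#' @export
aggregate_features <- function(records, cells, group_by = c("region", "cell_type")) {
  stopifnot(is.data.frame(records), inherits(cells, "cell_table"))
  group_by <- match.arg(group_by, c("region", "cell_type"), several.ok = TRUE)
  joined <- merge(records, as.data.frame(cells)[, c("cell_id", "cell_type",
                                                    "region")],
                  by = "cell_id", all.x = TRUE)
  features <- c("Degree", "Nsubgraph", "MinEdgeLength", "MeanEdgeLength",
                "ClusteringCoefficient", "Betweenness")
  features <- intersect(features, names(joined))
  if ("region" %in% group_by) {
    joined$region <- factor(joined$region, levels = REGIONS)
  }
  if ("cell_type" %in% group_by) {
    joined$cell_type <- factor(joined$cell_type,
                               levels = intersect(CELL_TYPES,
                                                  unique(joined$cell_type)))
  }
  key <- interaction(joined[group_by], drop = FALSE, sep = "\r")
  out <- list()
  for (lev in levels(key)) {
    sub <- joined[key == lev & !is.na(key), , drop = FALSE]
    glabs <- strsplit(lev, "\r", fixed = TRUE)[[1]]
    for (f in features) {
      v <- sub[[f]]
      n_excl <- sum(is.na(v))
      v_ok <- v[!is.na(v)]
      row <- as.list(stats::setNames(glabs, group_by))
      row$feature <- f
      row$mean <- if (length(v_ok) > 0) mean(v_ok) else NA_real_
      row$median <- if (length(v_ok) > 0) stats::median(v_ok) else NA_real_
      row$n <- length(v_ok)
      row$n_excluded <- n_excl
      out[[length(out) + 1]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a cell-pair graph's edge list as TSV
#' @param g a `cell_pair_graph`.
#' @param path output TSV (columns u, v, length_um).
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "cell_pair_graph"))
  utils::write.table(g$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
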