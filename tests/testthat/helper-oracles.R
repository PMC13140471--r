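# Independent brute-force oracles. These deliberately share no code with the
# package: direct O(n^2)/O(n^3) enumeration, union-find, BFS path counting,
# and a literal transcription of the running-sum enrichment formula.

# O(n^2) kNN + threshold oracle for the pair-graph edge set.
# cells: data.frame(cell_id, x_um, y_um, cell_type). Returns sorted "u|v" keys.
bf_pair_edges <- function(cells, type_a, type_b, k, max_edge) {
  ia <- which(cells$cell_type == type_a)
  ib <- which(cells$cell_type == type_b)
  pick <- function(from, to) {
    keys <- character(0)
    for (i in from) {
      d <- numeric(0); ids <- character(0)
      for (j in to) {
        if (cells$cell_id[j] == cells$cell_id[i]) next
        dij <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                    (cells$y_um[i] - cells$y_um[j])^2)
        d <- c(d, dij); ids <- c(ids, cells$cell_id[j])
      }
      if (length(d) == 0) next
      ord <- order(d, ids)
      take <- ord[seq_len(min(k, length(ord)))]
      ok <- take[d[take] <= max_edge]
      for (j in ok) {
        a <- cells$cell_id[i]; b <- ids[j]
        keys <- c(keys, paste(min(a, b), max(a, b), sep = "|"))
      }
    }
    keys
  }
  keys <- pick(ia, ib)
  if (type_a != type_b) keys <- c(keys, pick(ib, ia))
  sort(unique(keys))
}

# union-find connected components; edges as data.frame(u, v), ids character
bf_components <- function(ids, edges) {
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(match(edges$u[e], ids))
    rj <- find(match(edges$v[e], ids))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  match(roots, unique(roots))
}

# all six node features by direct enumeration on a small graph
bf_node_features <- function(ids, edges) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  len <- matrix(NA_real_, n, n)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      i <- match(edges$u[e], ids); j <- match(edges$v[e], ids)
      adj[i, j] <- adj[j, i] <- TRUE
      len[i, j] <- len[j, i] <- edges$length_um[e]
    }
  }
  deg <- rowSums(adj)
  comp <- bf_components(ids, edges)
  nsub <- as.integer(table(comp)[comp])
  min_len <- mean_len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    li <- len[i, adj[i, ]]
    if (length(li) > 0) { min_len[i] <- min(li); mean_len[i] <- mean(li) }
  }
  # clustering coefficient by triple enumeration
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (length(nb) < 2) { cc[v] <- 0; next }
    tri <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]]) tri <- tri + 1
    }
    cc[v] <- 2 * tri / (deg[v] * (deg[v] - 1))
  }
  # betweenness: BFS shortest-path counts from every source
  dist <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in which(adj[u, ])) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- dist[s, u] + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == dist[s, u] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (is.infinite(dist[s, t])) next
      if (dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw_norm <- ifelse(nsub > 2, btw / ((nsub - 1) * (nsub - 2) / 2), 0)
  data.frame(cell_id = ids, Degree = as.integer(deg), Nsubgraph = nsub,
             MinEdgeLength = min_len, MeanEdgeLength = mean_len,
             ClusteringCoefficient = cc, Betweenness = btw_norm,
             BetweennessRaw = btw, stringsAsFactors = FALSE)
}

# naive single-sample running-sum enrichment score, transcribed literally:
# walk genes by decreasing expression; in-set steps weighted rank^alpha,
# out-set steps 1/(N - m); score is the sum of (P_in - P_out) over positions.
bf_ssgsea_score <- function(expr, set_genes, alpha = 0.75) {
  genes <- names(expr)
  N <- length(genes)
  rk <- unname(rank(expr, ties.method = "average"))
  ord <- order(expr, decreasing = TRUE, method = "radix")
  in_set <- genes %in% set_genes
  m <- sum(in_set)
  w_total <- sum(rk[in_set]^alpha)
  p_in <- 0; p_out <- 0; score <- 0
  for (pos in seq_len(N)) {
    g <- ord[pos]
    if (in_set[g]) p_in <- p_in + rk[g]^alpha / w_total
    else p_out <- p_out + 1 / (N - m)
    score <- score + (p_in - p_out)
  }
  score
}

# textbook Benjamini-Hochberg step-up
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# small random cell table on a square field
random_cell_table <- function(n, types = c("lymphocyte", "stromal"),
                              side = 150, seed = 1) {
  set.seed(seed)
  cell_table(data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    x_um = runif(n, 0, side), y_um = runif(n, 0, side),
    cell_type = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE))
}
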