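make_expr <- function(counts, stages = NULL, regions = NULL) {
  ns <- ncol(counts)
  expression_matrix(counts, data.frame(
    sample_id = colnames(counts),
    patient_id = sprintf("p%d", seq_len(ns)),
    stage = if (is.null(stages)) rep("benign", ns) else stages,
    region = if (is.null(regions)) rep("core", ns) else regions,
    stringsAsFactors = FALSE))
}

test_that("median-total-count normalization matches the hand computation", {
  # 1 gene, totals 100/200/400 with counts 10/20/40: the median total is 200,
  # every scaled count becomes 20, every output log2(21)
  counts <- rbind(g1 = c(10, 20, 40), filler = c(90, 180, 360))
  colnames(counts) <- c("s1", "s2", "s3")
  nm <- normalize_counts(make_expr(counts))
  expect_equal(unname(nm$logexpr["g1", ]), rep(log2(21), 3))
  expect_equal(nm$median_total, 200)

  # equal totals: scaling factor 1 for every sample
  counts2 <- rbind(g1 = c(10, 30), g2 = c(90, 70))
  colnames(counts2) <- c("s1", "s2")
  nm2 <- normalize_counts(make_expr(counts2))
  expect_equal(unname(nm2$logexpr["g1", ]), log2(c(10, 30) + 1))

  # depth invariance: rescaling one sample's counts leaves the output
  # unchanged as long as the median total is not displaced (the correction
  # factor median/total absorbs per-sample depth exactly)
  counts3 <- rbind(g1 = c(10, 20, 40), filler = c(90, 180, 360))
  colnames(counts3) <- c("s1", "s2", "s3")
  nm_a <- normalize_counts(make_expr(counts3))
  counts3b <- counts3
  counts3b[, "s3"] <- counts3[, "s3"] * 5  # total 400 -> 2000, median still 200
  nm_b <- normalize_counts(make_expr(counts3b))
  expect_equal(nm_b$logexpr, nm_a$logexpr)
  # a global factor instead propagates into the scaled counts by construction:
  # scaled' = c * scaled, so the pre-log matrices differ by exactly c
  nm_c <- normalize_counts(make_expr(counts3 * 2))
  expect_equal(2^nm_c$logexpr - 1, 2 * (2^nm_a$logexpr - 1), tolerance = 1e-12)

  # zero-total sample is rejected by name
  counts4 <- rbind(g1 = c(5, 0))
  colnames(counts4) <- c("ok", "empty")
  expect_error(normalize_counts(make_expr(counts4)), "empty")
})

test_that("transcriptome distances: closed forms and per-pair reporting", {
  counts <- cbind(a1 = c(10, 20), a2 = c(10, 20), b1 = c(80, 120))
  rownames(counts) <- c("g1", "g2")
  nm <- normalize_counts(make_expr(counts))
  # identical profiles (after equalised totals) are at distance 0
  d0 <- transcriptome_distance(nm, "a1", "a2", gene_filter = list(mode = "all"))
  expect_equal(unname(d0$pairs$distance), 0)

  # hand-built log-scale profiles: (1,2) vs (4,6) -> 3-4-5 triangle
  fake <- structure(list(
    logexpr = cbind(x = c(1, 2), y = c(4, 6)),
    samples = data.frame(sample_id = c("x", "y"), patient_id = c("p", "p"),
                         stage = "benign", region = "core",
                         row.names = c("x", "y"))),
    class = "normalized_matrix")
  rownames(fake$logexpr) <- c("g1", "g2")
  d <- transcriptome_distance(fake, "x", "y", gene_filter = list(mode = "all"))
  expect_equal(unname(d$pairs$distance), 5)
  expect_equal(unname(d$summary["n"]), 1)

  expect_error(transcriptome_distance(nm, c("a1"), c("a1", "b1")), "disjoint")
})

test_that("mean cross-group distance grows with planted divergence", {
  deltas <- c(0, 1, 2)
  means <- vapply(1:10, function(seed) {
    vapply(deltas, function(delta) {
      de <- if (delta > 0) data.frame(gene_id = sprintf("g%04d", 1:200),
                                      stage = "malignant", log2fc = delta)
            else NULL
      sim <- simulate_expression(expr_sim_config(
        n_genes = 400, de = de, seed = seed,
        groups = transform(expand.grid(stage = c("benign", "malignant"),
                                       region = "core",
                                       stringsAsFactors = FALSE),
                           n = 4)))
      nm <- normalize_counts(sim$expr)
      unname(transcriptome_distance(nm, samples_where(nm, "benign"),
                                    samples_where(nm, "malignant"),
                                    gene_filter = list(mode = "all"))$summary["mean"])
    }, numeric(1))
  }, numeric(3))
  # strictly increasing in delta for every seed
  expect_true(all(means[2, ] > means[1, ]))
  expect_true(all(means[3, ] > means[2, ]))
})

test_that("differential expression applies the gated battery and thresholds", {
  set.seed(5)
  n <- 8
  counts <- matrix(rnbinom(40 * 2 * n, mu = 200, size = 10), nrow = 40,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("s%02d", 1:(2 * n))))
  em <- make_expr(counts, stages = rep(c("benign", "malignant"), each = n))
  nm <- normalize_counts(em)
  A <- samples_where(nm, "malignant")
  B <- samples_where(nm, "benign")
  deg <- differential_expression(nm, A, B)
  expect_s3_class(deg, "deg_table")
  expect_true(all(deg$p_adj >= deg$p_value - 1e-12))
  expect_true(all(deg$method %in% c("t", "wilcoxon")))

  # identical groups: log2FC 0, p = 1 via the zero-range skip path
  same <- matrix(5, nrow = 3, ncol = 6,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:6)))
  nm2 <- normalize_counts(make_expr(same))
  deg2 <- differential_expression(nm2, c("s1", "s2", "s3"),
                                  c("s4", "s5", "s6"))
  expect_equal(deg2$log2fc, rep(0, 3))
  expect_true(all(deg2$skipped))
  expect_equal(deg2$p_value, rep(1, 3))
  expect_false(any(deg2$sig_standard))
})

test_that("significance profiles respect the fold-change boundaries", {
  # a gene with |log2FC| = 0.4 can never pass the standard profile, however
  # small its adjusted p; 1.0 passes standard but not the strict profile
  fake_lfc <- c(0.4, 1.0, 2.0)
  fake_padj <- c(0.001, 0.001, 0.001)
  std <- abs(fake_lfc) > 0.5 & fake_padj < 0.05
  strict <- abs(fake_lfc) > 1.5 & fake_padj < 0.05
  expect_equal(std, c(FALSE, TRUE, TRUE))
  expect_equal(strict, c(FALSE, FALSE, TRUE))

  # and the implementation agrees on constructed data: two clearly separated
  # groups with a shift of exactly 2^0.4 vs 2^2 on the normalized scale
  set.seed(11)
  base <- exp(rnorm(6, log(400), 0.02))
  counts <- rbind(small = round(c(base * 2^0.4, base)),
                  big = round(c(base * 2^3, base)),
                  stable = round(c(base, base)))
  colnames(counts) <- sprintf("s%d", 1:12)
  em <- make_expr(counts, stages = rep(c("malignant", "benign"), each = 6))
  # keep depth equal so normalization does not dilute the planted shift
  em$counts <- rbind(em$counts,
                     ballast = round(8000 - colSums(em$counts)))
  em2 <- expression_matrix(em$counts, em$samples)
  nm <- normalize_counts(em2)
  deg <- differential_expression(nm, samples_where(nm, "malignant"),
                                 samples_where(nm, "benign"))
  expect_false(deg[deg$gene_id == "small", "sig_standard"])
  expect_true(deg[deg$gene_id == "big", "sig_standard"])
  expect_true(deg[deg$gene_id == "big", "sig_strict"])
})

test_that("BH adjustment matches the textbook step-up oracle", {
  set.seed(3)
  p <- round(runif(20), 3)
  expect_equal(stats::p.adjust(p, method = "BH"), bf_bh(p), tolerance = 1e-12)
})

test_that("signature scores: ordering, symmetry and oracle equivalence", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:20)
  le <- matrix(rnorm(20 * 3, 8, 2), nrow = 20,
               dimnames = list(genes, c("s1", "s2", "s3")))
  le[, 2] <- le[, 1]  # two identical samples
  sets <- list()
  for (s in 1:3) {
    ord <- order(le[, s], decreasing = TRUE)
    sets[[sprintf("top_s%d", s)]] <- genes[ord[1:5]]
    sets[[sprintf("bottom_s%d", s)]] <- genes[ord[16:20]]
  }
  sc <- score_signatures(le, sets)
  for (s in 1:3) {
    expect_gt(sc[sprintf("top_s%d", s), s], sc[sprintf("bottom_s%d", s), s])
  }
  expect_equal(sc[, 1], sc[, 2])  # identical expression -> identical scores

  # independent naive running-sum oracle, 20-gene universe
  for (nm_set in names(sets)) {
    for (s in 1:3) {
      expect_equal(sc[nm_set, s], bf_ssgsea_score(le[, s], sets[[nm_set]]),
                   tolerance = 1e-9)
    }
  }

  # relabelling genes outside the set leaves scores unchanged
  le2 <- le
  out_genes <- setdiff(genes, sets$top_s1)
  rownames(le2)[match(out_genes, rownames(le2))] <- paste0("x_", out_genes)
  expect_equal(score_signatures(le2, sets["top_s1"])["top_s1", ],
               sc["top_s1", ])

  # sets with < 2 present members score NA
  sc_small <- score_signatures(le, list(tiny = c("g01", "nonexistent")))
  expect_true(all(is.na(sc_small)))
})

test_that("marker abundance is the mean normalized marker expression", {
  counts <- cbind(s1 = c(16, 64, 100), s2 = c(64, 16, 100))
  rownames(counts) <- c("CD3", "CD8", "other")
  nm <- normalize_counts(make_expr(counts))
  ab <- marker_abundance(nm, list(tcell = c("CD3", "CD8")))
  expect_equal(unname(ab["tcell", ]),
               unname(colMeans(nm$logexpr[c("CD3", "CD8"), ])))
})
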