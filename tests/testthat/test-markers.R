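test_that("wilcoxon exact p matches full enumeration for small samples", {
  # fully separated groups: U = 0, two-sided p = 2/choose(6,3) = 0.1
  r <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)

  # identical multisets: no separation
  expect_equal(wilcoxon_test(c(2, 2, 5), c(2, 2, 5))$p, 1)

  # random small cases, with ties, against the enumeration oracle
  set.seed(31)
  for (rep in 1:30) {
    nx <- sample(2:6, 1)
    ny <- sample(2:(12 - nx), 1)
    x <- sample.int(5, nx, replace = TRUE)
    y <- sample.int(5, ny, replace = TRUE)
    expect_equal(wilcoxon_test(x, y)$p, naive_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_test(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon agrees with stats::wilcox.test where both are defined", {
  set.seed(8)
  # exact, tie-free, small
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(wilcoxon_test(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # normal approximation with continuity correction, larger
  x <- rnorm(30); y <- rnorm(25)
  expect_equal(wilcoxon_test(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # ties in the large-sample path
  x <- sample.int(4, 30, replace = TRUE); y <- sample.int(4, 30, replace = TRUE)
  expect_equal(wilcoxon_test(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("wilcoxon p-values are near-uniform under the null", {
  set.seed(17)
  ps <- replicate(2000, wilcoxon_test(rnorm(50), rnorm(50))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("log fold change follows the pseudocounted expm1-mean formula", {
  expect_equal(log_fold_change(c(1, 1), c(1, 1)), 0)
  # mean(expm1) in = 3, out = 1 -> log2(4/2) = 1
  x_in <- log1p(c(3, 3)); x_out <- log1p(c(1, 1))
  expect_equal(log_fold_change(x_in, x_out), 1)
  expect_equal(log_fold_change(c(0, 0), c(0, 0)), 0)
})

test_that("planted markers are recovered and filters apply as stated", {
  set.seed(77)
  n_genes <- 500; n_tec <- 60; n_other <- 140
  base <- rexp(n_genes, 1 / 3)
  mu <- cbind(matrix(base, n_genes, n_tec), matrix(base, n_genes, n_other))
  planted <- 1:10
  mu[planted, seq_len(n_tec)] <- mu[planted, seq_len(n_tec)] * 4 # log2FC 2
  counts <- matrix(rpois(length(mu), mu), n_genes)
  m <- expression_matrix(counts, sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_tec + n_other)),
                         layer = "counts")
  keep <- colSums(counts) > 0
  m <- em_subset(m, obs = which(keep))
  ann <- cell_annotation(m$obs_ids,
                         ifelse(seq_len(n_tec + n_other)[keep] <= n_tec,
                                "TEC", "Tumor"))
  mk <- find_markers(lognormalize(m), ann)
  tec_mk <- mk$gene_id[mk$cell_type == "TEC"]
  expect_true(all(sprintf("g%03d", planted) %in% tec_mk))
  # false positives among the 490 null genes stay near the FDR level
  expect_lte(sum(!tec_mk %in% sprintf("g%03d", planted)), 5)
})

test_that("marker output is invariant to cell and gene ordering", {
  m <- toy_lognorm(n_genes = 40, n_cells = 30, seed = 4, max_count = 8)
  ann <- cell_annotation(m$obs_ids, rep(c("TEC", "Tumor", "CAF"), each = 10))
  mk1 <- find_markers(m, ann, max_fdr = 0.9, min_logfc = 0, min_pct = 0)
  set.seed(1)
  gp <- sample(length(m$gene_ids)); op <- sample(length(m$obs_ids))
  m2 <- em_subset(m, genes = gp, obs = op)
  mk2 <- find_markers(m2, ann, max_fdr = 0.9, min_logfc = 0, min_pct = 0)
  attr(mk1, "dataset_id") <- attr(mk2, "dataset_id") <- NULL
  expect_equal(mk1, mk2)
})

test_that("marker thresholds are strict as specified", {
  # construct a two-type matrix where one gene has log_fc exactly 0.25
  n <- 40
  ann_types <- rep(c("TEC", "Tumor"), each = n / 2)
  x <- matrix(1, 4, n)
  # gene g1: mean(expm1) ratio exactly (2^0.25 * 2 - 1 + 1)/2 -> log2 fc 0.25
  in_val <- log1p(2^0.25 * 2 - 1)  # mean(expm1)+1 = 2^0.25 * 2
  out_val <- log1p(1)              # mean(expm1)+1 = 2
  x[1, ] <- ifelse(ann_types == "TEC", in_val, out_val)
  x[2, ] <- ifelse(ann_types == "TEC", 3, 0)   # clear marker
  x[3, ] <- rep(c(0.5, 0.7), n / 2)
  x[4, ] <- rep(c(0.2, 0.9, 0.4, 0.8), n / 4)
  m <- expression_matrix(x, paste0("g", 1:4), sprintf("c%02d", 1:n),
                         layer = "lognorm")
  ann <- cell_annotation(m$obs_ids, ann_types)
  lfc1 <- log_fold_change(x[1, ann_types == "TEC"], x[1, ann_types != "TEC"])
  expect_equal(lfc1, 0.25)
  # threshold set to the gene's exact logFC: strict drops it, inclusive keeps
  mk <- suppressWarnings(find_markers(m, ann, min_logfc = lfc1))
  expect_false("g1" %in% mk$gene_id[mk$cell_type == "TEC"])
  mk_inc <- suppressWarnings(find_markers(m, ann, min_logfc = lfc1,
                                          logfc_inclusive = TRUE))
  expect_true("g1" %in% mk_inc$gene_id[mk_inc$cell_type == "TEC"])
  mk <- suppressWarnings(find_markers(m, ann))
  expect_true("g2" %in% mk$gene_id[mk$cell_type == "TEC"])

  # pct_in below 0.25 drops a gene regardless of fold change
  x2 <- x
  x2[2, ] <- 0
  x2[2, which(ann_types == "TEC")[1:4]] <- 5  # pct_in = 0.2
  m2 <- expression_matrix(x2, paste0("g", 1:4), m$obs_ids, layer = "lognorm")
  mk2 <- suppressWarnings(find_markers(m2, ann))
  expect_false("g2" %in% mk2$gene_id[mk2$cell_type == "TEC"])
})

test_that("gy projection keeps only the endothelial markers and errors when absent", {
  mk <- data.frame(gene_id = c("B", "A", "C"),
                   cell_type = c("TEC", "TEC", "Tumor"),
                   log_fc = c(1, 2, 1), pct_in = 1, pct_out = 0.1,
                   p_value = 1e-4, fdr = 1e-3)
  attr(mk, "dataset_id") <- "ds1"
  g <- gy_set(mk)
  expect_identical(g$name, "Gy:ds1")
  expect_identical(g$genes, c("A", "B"))
  expect_error(gy_set(mk, cell_type = "Endo"), "no retained markers")
})

test_that("small cell types are skipped with a warning", {
  m <- toy_lognorm(n_genes = 20, n_cells = 12, seed = 6)
  ann <- cell_annotation(m$obs_ids,
                         c(rep("TEC", 6), rep("Tumor", 4), rep("CAF", 2)))
  expect_warning(mk <- find_markers(m, ann, max_fdr = 1, min_logfc = -10,
                                    min_pct = 0),
                 "CAF")
  expect_false("CAF" %in% mk$cell_type)
})
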