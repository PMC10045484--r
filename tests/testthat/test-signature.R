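test_that("spearman matches the brute-force rank-Pearson oracle with ties", {
  set.seed(21)
  for (rep in 1:40) {
    n <- 15
    x <- sample.int(8, n, replace = TRUE)  # injected ties
    y <- x + rnorm(n, sd = 2)
    r <- spearman(x, y)
    expect_equal(r$rho, naive_spearman(x, y), tolerance = 1e-12)
    # rho agrees with the standard library implementation
    expect_equal(r$rho, suppressWarnings(
      cor.test(x, y, method = "spearman")$estimate[["rho"]]),
      tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, x)$p, 0)
  expect_equal(spearman(sort(x), rev(sort(x)))$rho, -1)
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman(1:3, 1:3), ">= 4")
})

test_that("spearman p follows the t approximation with df = n - 2", {
  set.seed(2)
  x <- rnorm(20); y <- x + rnorm(20, sd = 3)
  r <- spearman(x, y)
  tstat <- r$rho * sqrt(18 / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), df = 18))
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (rep in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_gx_fixture <- function(n_tec = 60, n_genes = 80, n_pos = 10, seed = 5) {
  set.seed(seed)
  s <- runif(n_tec)
  x <- matrix(rpois(n_genes * n_tec, 5), n_genes, n_tec)
  for (i in seq_len(n_pos))
    x[i, ] <- rpois(n_tec, 4 * exp(1.5 * s))
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  obs <- sprintf("tec%02d", seq_len(n_tec))
  m <- expression_matrix(x, gene_ids, obs, layer = "counts")
  list(m = lognormalize(m),
       ann = cell_annotation(obs, rep("TEC", n_tec)),
       scores = setNames(s, obs),
       pos = gene_ids[seq_len(n_pos)])
}

test_that("gx_set keeps positively correlated genes under FDR and applies the floor", {
  f <- make_gx_fixture()
  res <- gx_set(f$m, f$ann, f$scores)
  expect_true(all(f$pos %in% res$set$genes))
  corr <- res$correlations
  expect_true(all(corr$rho[match(res$set$genes, corr$gene_id)] > 0))
  expect_true(all(corr$fdr[match(res$set$genes, corr$gene_id)] < 0.05))
  # negative or non-significant genes excluded
  out_genes <- setdiff(corr$gene_id, res$set$genes)
  expect_true(all(corr$rho[match(out_genes, corr$gene_id)] <= 0 |
                  corr$fdr[match(out_genes, corr$gene_id)] >= 0.05))
})

test_that("gx_set excludes weakly expressed genes from testing and the BH denominator", {
  f <- make_gx_fixture()
  x <- em_values(f$m)
  x[15, ] <- 0
  x[15, 1:5] <- 3   # expressed in 5 < 10 cells
  m <- expression_matrix(x, f$m$gene_ids, f$m$obs_ids, layer = "lognorm")
  res <- gx_set(m, f$ann, f$scores)
  expect_false("g015" %in% res$correlations$gene_id)
  expect_error(gx_set(f$m, cell_annotation(f$m$obs_ids,
                                           rep("Tumor", 60)), f$scores),
               ">= 10 cells")
})

test_that("gx permutation null controls the fraction of selected genes", {
  f <- make_gx_fixture(n_pos = 0, seed = 11)
  set.seed(42)
  fracs <- replicate(60, {
    s_perm <- sample(f$scores)
    names(s_perm) <- names(f$scores)
    res <- suppressMessages(gx_set(f$m, f$ann, s_perm))
    n_sel <- if (is.null(res$set)) 0 else length(res$set$genes)
    n_sel / nrow(res$correlations)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("dataset candidates intersect Gx and Gy", {
  c1 <- dataset_candidates(gene_set("gx", c("A", "B", "C")),
                           gene_set("gy", c("B", "C", "D")), "d1")
  expect_identical(c1$gn, c("B", "C"))
  expect_message(c2 <- dataset_candidates(gene_set("gx", "A"),
                                          gene_set("gy", "B"), "d2"),
                 "empty Gn")
  expect_length(c2$gn, 0)
  c3 <- dataset_candidates(gene_set("gx", c("X", "Y")),
                           gene_set("gy", c("Y", "X")), "d3")
  expect_identical(c3$gn, c3$gx)
})

test_that("consensus takes the geometric mean over supporting datasets with a strict cutoff", {
  mk_corr <- function(gene, ds, rho)
    data.frame(gene_id = gene, dataset_id = ds, rho = rho,
               p_value = 0.001, fdr = 0.01)
  cands <- list(
    dataset_candidates(c("A", "B"), c("A", "B"), "d1"),
    dataset_candidates(c("A", "B"), c("A", "B"), "d2"),
    dataset_candidates("A", "A", "d3"))
  corr <- rbind(mk_corr("A", "d1", 0.25), mk_corr("B", "d1", 0.1),
                mk_corr("A", "d2", 0.25), mk_corr("B", "d2", 0.4),
                mk_corr("A", "d3", 0.25))
  sig <- consensus(cands, corr)
  a <- sig[sig$gene_id == "A", ]
  b <- sig[sig$gene_id == "B", ]
  expect_equal(a$geo_mean, 0.25)       # equal rhos
  expect_equal(a$n_support, 3L)
  expect_true(a$member)
  expect_equal(b$geo_mean, sqrt(0.04)) # = 0.2, NOT a member (strict >)
  expect_false(b$member)

  # min_support monotonicity: raising support never adds members
  sig3 <- consensus(cands, corr, min_support = 3)
  expect_true(all(sig3$gene_id[sig3$member] %in% sig$gene_id[sig$member]))
  expect_false(sig3$member[sig3$gene_id == "B"])
  # raising the threshold never adds members
  sig_hi <- consensus(cands, corr, threshold = 0.24)
  expect_true(all(sig_hi$gene_id[sig_hi$member] %in% sig$gene_id[sig$member]))

  # missing rho for a Gn gene is a pipeline inconsistency
  expect_error(consensus(cands, corr[corr$gene_id != "B", ]), "missing rho")
})

test_that("consensus geometric means lie in (0, 1] and ordering is deterministic", {
  set.seed(3)
  cands <- list()
  corr <- NULL
  for (d in 1:4) {
    genes <- sprintf("g%02d", sample(1:20, 12))
    rho <- runif(length(genes), 0.01, 0.99)
    cands[[d]] <- dataset_candidates(genes, genes, paste0("d", d))
    corr <- rbind(corr, data.frame(gene_id = genes,
                                   dataset_id = paste0("d", d),
                                   rho = rho, p_value = 0.01, fdr = 0.01))
  }
  sig <- consensus(cands, corr)
  expect_true(all(sig$geo_mean > 0 & sig$geo_mean <= 1))
  expect_identical(order(-sig$geo_mean, sig$gene_id), seq_len(nrow(sig)))
})
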