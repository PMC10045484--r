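# Shared fixture builders: everything is generated in code.

toy_counts <- function(n_genes = 6, n_cells = 4, seed = 42,
                       gene_ids = sprintf("g%02d", seq_len(n_genes)),
                       max_count = 20) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1, n_genes * n_cells, replace = TRUE) - 1L,
              n_genes, n_cells)
  expression_matrix(m, gene_ids, sprintf("c%02d", seq_len(n_cells)),
                    layer = "counts", dataset_id = "toy")
}

toy_lognorm <- function(...) lognormalize(toy_counts(...))

# Independent naive enrichment-score oracle: materializes the full walk with
# explicit loops, no shared code with score_gene_set().
naive_set_score <- function(x, gene_ids, set_genes, method, tau = 1) {
  p <- nrow(x)
  inset <- gene_ids %in% set_genes
  sapply(seq_len(ncol(x)), function(j) {
    z <- rank(x[, j] * 0, ties.method = "average") # placeholder
    # per-gene ecdf statistic across observations
    z <- sapply(seq_len(p), function(i)
      rank(x[i, ], ties.method = "average")[j] / ncol(x))
    ord <- order(-z, gene_ids)
    dev <- 0
    profile <- numeric(p)
    wsum <- 0
    for (r in seq_len(p)) if (inset[ord[r]]) wsum <- wsum + abs(p / 2 - r)^tau
    for (r in seq_len(p)) {
      if (inset[ord[r]]) {
        dev <- dev + if (wsum > 0) abs(p / 2 - r)^tau / wsum
                     else 1 / sum(inset)
      } else {
        dev <- dev - 1 / (p - sum(inset))
      }
      profile[r] <- dev
    }
    maxpos <- max(c(profile, 0))
    minneg <- min(c(profile, 0))
    if (method == "maxdev") {
      if (maxpos + minneg > 1e-12) maxpos else minneg
    } else {
      maxpos + minneg
    }
  })
}

# Brute-force BH step-up: adj_i = min_{j >= i} p_(j) * m / j, clipped at 1.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force Spearman: Pearson on mid-ranks computed from first principles.
naive_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact Wilcoxon two-sided p by full enumeration of group assignments.
naive_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Small survival fixture with a known group effect.
toy_survival <- function(n = 60, beta = 1, seed = 7) {
  set.seed(seed)
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, rate = 0.1 * exp(beta * x))
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = time, event = 1L, x = x)
}
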