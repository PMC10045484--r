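#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location difference between two groups. For pooled
#' sample sizes up to 12 the p-value is computed by exact enumeration of all
#' group assignments of the pooled values (valid under ties); above that, by
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (Mann-Whitney U for `x`) and `p`.
#' @export
wilcoxon_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  if (n <= 12) {
    # Exact enumeration over all choose(n, nx) assignments of pooled ranks.
    combos <- utils::combn(n, nx)
    Us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p_lo <- mean(Us <= U + 1e-9)
    p_hi <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- 2 * stats::pnorm(-z)
    }
  }
  list(U = U, p = min(1, p))
}

#' Log2 fold change between two groups of log-normalized values
#'
#' `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`: the groups'
#' values are mapped back to the normalized-count scale, averaged, and the
#' ratio of pseudocounted means is taken in log2.
#'
#' @param x_in,x_out log-normalized expression values for the two groups.
#' @return single numeric log2 fold change.
#' @export
log_fold_change <- function(x_in, x_out) {
  log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))
}

#' One-vs-rest marker detection per cell type
#'
#' For every annotated cell type, each gene is tested for up-regulation in
#' that type against all other cells with the Wilcoxon rank-sum test (normal
#' approximation with tie and continuity corrections; exact enumeration when
#' the pooled size is at most 12). Benjamini-Hochberg adjustment is applied
#' per cell type across all tested genes. A gene is retained as a marker of a
#' type when the fraction of that type's cells expressing it is at least
#' `min_pct`, its log2 fold change exceeds `min_logfc` (strictly by default;
#' set `logfc_inclusive = TRUE` for `>=`), and its FDR is below `max_fdr`.
#' Only positive (enriched) markers are reported.
#'
#' @param m `ExpressionMatrix` with layer `"lognorm"`.
#' @param ann [cell_annotation()] data.frame covering the matrix columns.
#' @param min_pct minimum in-type expressed fraction (default 0.25).
#' @param min_logfc log2 fold-change threshold (default 0.25).
#' @param max_fdr FDR cutoff (default 0.05, strict `<`).
#' @param logfc_inclusive if `TRUE`, retain `log_fc >= min_logfc`.
#' @return data.frame of retained markers with columns `gene_id`,
#'   `cell_type`, `log_fc`, `pct_in`, `pct_out`, `p_value`, `fdr`, sorted by
#'   cell type then descending `log_fc`; attribute `dataset_id` from `m`.
#'   Cell types with fewer than 3 cells are skipped with a warning.
#' @export
find_markers <- function(m, ann, min_pct = 0.25, min_logfc = 0.25,
                         max_fdr = 0.05, logfc_inclusive = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm")
    stop("find_markers requires the lognorm layer, got '", m$layer, "'")
  idx <- match(m$obs_ids, ann$obs_id)
  if (anyNA(idx))
    stop("annotation missing for ", sum(is.na(idx)), " cell(s)")
  types <- ann$cell_type[idx]
  tab <- table(types)
  small <- names(tab)[tab < 3]
  if (length(small))
    warning("cell type(s) skipped with < 3 cells: ",
            paste(small, collapse = ", "))
  use_types <- sort(names(tab)[tab >= 3])
  if (length(use_types) < 2)
    stop("need >= 2 cell types with >= 3 cells each")
  x <- em_values(m)
  # deterministic gene order for output regardless of input ordering
  gene_ord <- order(m$gene_ids)
  x <- x[gene_ord, , drop = FALSE]
  genes <- m$gene_ids[gene_ord]
  n <- ncol(x)
  # One-vs-rest Wilcoxon pools all cells, so a single global rank matrix and
  # per-gene tie term serve every cell type.
  R <- t(apply(x, 1, rank, ties.method = "average"))
  tie_term <- apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  expressed <- x > 0
  res <- vector("list", length(use_types))
  for (k in seq_along(use_types)) {
    ct <- use_types[k]
    ingrp <- types == ct
    nx <- sum(ingrp); ny <- n - nx
    if (n <= 12) {
      pr <- t(vapply(seq_len(nrow(x)), function(i) {
        w <- wilcoxon_test(x[i, ingrp], x[i, !ingrp])
        c(w$U, w$p)
      }, numeric(2)))
      p <- pr[, 2]
    } else {
      W <- rowSums(R[, ingrp, drop = FALSE])
      U <- W - nx * (nx + 1) / 2
      mu <- nx * ny / 2
      v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- pmax((abs(U - mu) - 0.5), 0) / sqrt(pmax(v, .Machine$double.eps))
      p <- ifelse(v <= 0, 1, 2 * stats::pnorm(-z))
      p <- pmin(p, 1)
    }
    fdr <- bh_adjust(p)
    pct_in <- rowMeans(expressed[, ingrp, drop = FALSE])
    pct_out <- rowMeans(expressed[, !ingrp, drop = FALSE])
    mean_in <- rowMeans(expm1(x[, ingrp, drop = FALSE]))
    mean_out <- rowMeans(expm1(x[, !ingrp, drop = FALSE]))
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    pass_lfc <- if (logfc_inclusive) lfc >= min_logfc else lfc > min_logfc
    keep <- pct_in >= min_pct & pass_lfc & fdr < max_fdr
    res[[k]] <- data.frame(
      gene_id = genes[keep], cell_type = rep(ct, sum(keep)),
      log_fc = lfc[keep],
      pct_in = pct_in[keep], pct_out = pct_out[keep],
      p_value = p[keep], fdr = fdr[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$cell_type, -out$log_fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_id") <- m$dataset_id
  out
}

#' Endothelial marker gene set (Gy)
#'
#' Projects the retained markers of the endothelial cell type out of a
#' [find_markers()] table into a gene set named `Gy:<dataset_id>`. This is
#' the per-dataset endothelial-identity evidence later intersected with the
#' senescence-correlation evidence (Gx).
#'
#' @param markers data.frame from [find_markers()].
#' @param cell_type endothelial label (default `"TEC"`).
#' @param dataset_id dataset label; defaults to the `dataset_id` attribute of
#'   `markers`.
#' @return a [gene_set()] of the retained endothelial markers.
#' @export
gy_set <- function(markers, cell_type = "TEC", dataset_id = NULL) {
  if (is.null(dataset_id)) dataset_id <- attr(markers, "dataset_id")
  if (is.null(dataset_id)) dataset_id <- "dataset"
  rows <- markers$cell_type == cell_type
  if (!any(rows))
    stop("no retained markers for endothelial type '", cell_type, "'")
  gene_set(paste0("Gy:", dataset_id), sort(markers$gene_id[rows]))
}
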