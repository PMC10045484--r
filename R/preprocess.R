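#' Cell quality-control thresholds
#'
#' Defaults follow the standard scRNA-seq filter: cells detecting fewer than
#' 300 or more than 6500 genes, or with mitochondrial counts above 10% of
#' their library, are excluded. The exclusion inequalities are strict, so the
#' retained range is inclusive at both detected-gene boundaries.
#'
#' @param min_genes,max_genes detected-gene bounds (inclusive retention).
#' @param max_mito_pct maximum mitochondrial percentage (inclusive retention).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes = 300L, max_genes = 6500L,
                          max_mito_pct = 10, mito_prefix = "MT-") {
  min_genes <- as.integer(min_genes); max_genes <- as.integer(max_genes)
  if (!(min_genes > 0 && min_genes < max_genes))
    stop("need 0 < min_genes < max_genes")
  if (max_mito_pct < 0 || max_mito_pct > 100)
    stop("max_mito_pct must be in [0, 100]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct, mito_prefix = mito_prefix),
            class = "QCThresholds")
}

#' Quality-control filter for cells
#'
#' Retains cells whose detected-gene count (genes with count > 0) lies in
#' `[min_genes, max_genes]` and whose mitochondrial percentage (counts on
#' genes whose symbol starts with `mito_prefix`, as a percentage of total
#' counts) is at most `max_mito_pct`. Cells with zero total counts are
#' excluded and flagged, never an arithmetic error.
#'
#' @param m `ExpressionMatrix` with layer `"counts"`.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `matrix` (the filtered `ExpressionMatrix`) and `report`
#'   (data.frame `criterion`, `n_excluded`; criteria `low_genes`,
#'   `high_genes`, `high_mito`, `zero_counts`, plus the total). A cell failing
#'   several criteria is counted under each.
#' @export
qc_filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(thresholds, "QCThresholds"))
  if (m$layer != "counts")
    stop("qc_filter_cells requires the counts layer, got '", m$layer, "'")
  v <- m$values
  detected <- if (methods::is(v, "sparseMatrix"))
    Matrix::colSums(v > 0) else colSums(v > 0)
  total <- if (methods::is(v, "sparseMatrix"))
    Matrix::colSums(v) else colSums(v)
  mito_genes <- startsWith(m$gene_ids, thresholds$mito_prefix)
  mito <- if (any(mito_genes)) {
    mt <- v[mito_genes, , drop = FALSE]
    if (methods::is(mt, "sparseMatrix")) Matrix::colSums(mt) else colSums(mt)
  } else rep(0, length(total))
  zero <- total == 0
  mito_pct <- rep(0, length(total))
  mito_pct[!zero] <- 100 * mito[!zero] / total[!zero]
  low <- detected < thresholds$min_genes
  high <- detected > thresholds$max_genes
  himito <- !zero & mito_pct > thresholds$max_mito_pct
  keep <- !(low | high | himito | zero)
  report <- data.frame(
    criterion = c("low_genes", "high_genes", "high_mito", "zero_counts",
                  "total_excluded"),
    n_excluded = c(sum(low), sum(high), sum(himito), sum(zero), sum(!keep)),
    stringsAsFactors = FALSE)
  list(matrix = em_subset(m, obs = which(keep)), report = report)
}

#' Log-normalize counts
#'
#' Library-size normalization to `scale` counts per cell followed by log1p:
#' `value' = ln(1 + count * scale / cell_total)`. This is the standard
#' log1p-CP10K transform; downstream statistics in this package (ECDF
#' enrichment ranks, Spearman correlation, Wilcoxon) are rank-based within
#' genes, so they depend only on the within-gene ordering this transform
#' induces.
#'
#' @param m `ExpressionMatrix` with layer `"counts"`; every cell must have
#'   positive total counts (run [qc_filter_cells()] first).
#' @param scale target library size (default 1e4).
#' @return `ExpressionMatrix` with layer `"lognorm"`.
#' @export
lognormalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts")
    stop("lognormalize requires the counts layer, got '", m$layer, "'")
  v <- m$values
  total <- if (methods::is(v, "sparseMatrix")) Matrix::colSums(v) else colSums(v)
  if (any(total == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(m$obs_ids[total == 0], 5), collapse = ", "),
         " -- run qc_filter_cells first")
  if (methods::is(v, "sparseMatrix")) {
    v <- methods::as(methods::as(v, "dMatrix"), "CsparseMatrix")
    v@x <- log1p(v@x * scale / rep.int(total, diff(v@p)))
  } else {
    v <- log1p(sweep(v, 2, scale / total, `*`))
  }
  expression_matrix(v, m$gene_ids, m$obs_ids, layer = "lognorm",
                    dataset_id = m$dataset_id)
}
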