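#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; the two-sided p-value uses the
#' t statistic `rho * sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4) stop("spearman needs length >= 4, got ", n)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("spearman undefined for a constant vector")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (delegates to [stats::p.adjust()] with
#' `method = "BH"` after validating the input range).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Senescence-correlated gene evidence (Gx)
#'
#' Within the endothelial cells of one dataset, each sufficiently expressed
#' gene is correlated (Spearman) with the per-cell senescence enrichment
#' score. Genes with positive correlation and BH FDR below `max_fdr` form the
#' dataset's Gx set. Genes expressed (value > 0) in fewer than
#' `min_cells_expr` endothelial cells, or constant across them, are excluded
#' from testing (and from the BH denominator).
#'
#' @param m `ExpressionMatrix` with layer `"lognorm"`.
#' @param ann [cell_annotation()] covering the matrix columns.
#' @param sen_scores `EnrichmentScores` (or named numeric) defined on the
#'   endothelial cells.
#' @param cell_type endothelial label (default `"TEC"`).
#' @param max_fdr FDR cutoff (default 0.05, strict `<`).
#' @param min_cells_expr expression floor (default 10 cells).
#' @return list with `set` (a [gene_set()] named `Gx:<dataset_id>`; may be
#'   empty, in which case `set` is `NULL` with a message) and `correlations`
#'   (data.frame `gene_id`, `dataset_id`, `rho`, `p_value`, `fdr` over all
#'   tested genes).
#' @export
gx_set <- function(m, ann, sen_scores, cell_type = "TEC", max_fdr = 0.05,
                   min_cells_expr = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm")
    stop("gx_set requires the lognorm layer, got '", m$layer, "'")
  s <- if (inherits(sen_scores, "EnrichmentScores")) sen_scores$scores
       else sen_scores
  cells <- ann$obs_id[ann$cell_type == cell_type]
  cells <- intersect(m$obs_ids, cells)
  if (length(cells) < 10)
    stop("need >= 10 cells of type '", cell_type, "', got ", length(cells))
  miss <- setdiff(cells, names(s))
  if (length(miss))
    stop("senescence scores missing for ", length(miss), " cell(s)")
  s <- s[cells]
  if (length(unique(s)) == 1)
    stop("senescence scores constant across ", cell_type, " cells")
  x <- em_values(em_subset(m, obs = cells))
  nexpr <- rowSums(x > 0)
  variable <- apply(x, 1, function(r) length(unique(r)) > 1)
  test <- nexpr >= min_cells_expr & variable
  if (!any(test))
    stop("no gene passes the expression floor of ", min_cells_expr, " cells")
  xt <- x[test, , drop = FALSE]
  genes <- m$gene_ids[test]
  n <- ncol(xt)
  # vectorized rank-Pearson of every gene against the score
  R <- t(apply(xt, 1, rank, ties.method = "average"))
  rs <- rank(s, ties.method = "average")
  Rc <- R - rowMeans(R)
  rsc <- rs - mean(rs)
  rho <- as.numeric(Rc %*% rsc) /
    (sqrt(rowSums(Rc^2)) * sqrt(sum(rsc^2)))
  rho <- pmin(1, pmax(-1, rho))
  p <- ifelse(abs(rho) >= 1, 0,
              2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))),
                            df = n - 2))
  fdr <- bh_adjust(p)
  corr <- data.frame(gene_id = genes, dataset_id = m$dataset_id,
                     rho = rho, p_value = p, fdr = fdr,
                     stringsAsFactors = FALSE)
  corr <- corr[order(corr$gene_id), , drop = FALSE]
  rownames(corr) <- NULL
  in_gx <- corr$rho > 0 & corr$fdr < max_fdr
  set <- if (any(in_gx)) {
    gene_set(paste0("Gx:", m$dataset_id), corr$gene_id[in_gx])
  } else {
    message("gx_set: no gene passes (rho > 0, FDR < ", max_fdr,
            ") in dataset ", m$dataset_id)
    NULL
  }
  list(set = set, correlations = corr)
}

#' Per-dataset candidate sets Gx, Gy, Gn
#'
#' Intersects the senescence-correlation evidence (Gx) with the endothelial
#' marker evidence (Gy) into the dataset's candidate set Gn.
#'
#' @param gx,gy [gene_set()] objects (or `NULL`/character vectors) from the
#'   same dataset.
#' @param dataset_id dataset label.
#' @return list of class `DatasetCandidates` with `dataset_id`, `gx`, `gy`,
#'   `gn` (sorted character vectors; `gn` may be empty, which is logged).
#' @export
dataset_candidates <- function(gx, gy, dataset_id) {
  as_genes <- function(g) {
    if (is.null(g)) character(0)
    else if (inherits(g, "GeneSet")) g$genes
    else as.character(g)
  }
  gx <- sort(unique(as_genes(gx)))
  gy <- sort(unique(as_genes(gy)))
  gn <- intersect(gx, gy)
  if (length(gn) == 0)
    message("dataset_candidates: empty Gn for dataset ", dataset_id)
  structure(list(dataset_id = as.character(dataset_id)[1],
                 gx = gx, gy = gy, gn = gn),
            class = "DatasetCandidates")
}

#' Cross-dataset consensus signature
#'
#' For each gene appearing in at least one dataset's Gn, the geometric mean
#' of its Spearman coefficients is taken over the datasets where it
#' qualifies. Genes whose geometric mean strictly exceeds `threshold` and
#' whose support reaches `min_support` datasets are signature members.
#'
#' @param candidates list of [dataset_candidates()] objects.
#' @param correlations data.frame of per-dataset correlation results
#'   (row-bound `correlations` elements from [gx_set()]); every Gn gene must
#'   have a `rho` recorded for its dataset.
#' @param threshold geometric-mean cutoff (default 0.2, strict `>`).
#' @param min_support minimum number of supporting datasets (default 1; set
#'   to `length(candidates)` for the strict all-datasets mode).
#' @return data.frame of class `ConsensusSignature`: `gene_id`, `n_support`,
#'   `geo_mean`, `member`, plus one `rho_<dataset_id>` column per dataset
#'   (NA where the gene is not in that dataset's Gn); sorted by descending
#'   `geo_mean`, ties by `gene_id`.
#' @export
consensus <- function(candidates, correlations, threshold = 0.2,
                      min_support = 1) {
  if (length(candidates) < 1) stop("need >= 1 dataset")
  ds_ids <- vapply(candidates, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ds_ids)) stop("duplicate dataset_id among candidates")
  all_genes <- sort(unique(unlist(lapply(candidates, `[[`, "gn"))))
  rho_mat <- matrix(NA_real_, length(all_genes), length(ds_ids),
                    dimnames = list(all_genes, ds_ids))
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    if (length(cand$gn) == 0) next
    sub <- correlations[correlations$dataset_id == cand$dataset_id, ]
    hit <- match(cand$gn, sub$gene_id)
    if (anyNA(hit))
      stop("missing rho for gene(s) ",
           paste(cand$gn[is.na(hit)], collapse = ", "),
           " in dataset ", cand$dataset_id)
    rho_mat[cand$gn, k] <- sub$rho[hit]
  }
  if (any(rho_mat[!is.na(rho_mat)] <= 0))
    stop("non-positive rho recorded for a Gn gene (Gx must be positive)")
  n_support <- rowSums(!is.na(rho_mat))
  geo_mean <- exp(rowMeans(log(rho_mat), na.rm = TRUE))
  if (length(all_genes) == 0) {
    out <- data.frame(gene_id = character(0), n_support = integer(0),
                      geo_mean = numeric(0), member = logical(0))
  } else {
    out <- data.frame(gene_id = all_genes,
                      n_support = as.integer(n_support),
                      geo_mean = geo_mean,
                      member = geo_mean > threshold & n_support >= min_support,
                      stringsAsFactors = FALSE)
    rho_df <- as.data.frame(rho_mat)
    colnames(rho_df) <- paste0("rho_", ds_ids)
    out <- cbind(out, rho_df)
    out <- out[order(-out$geo_mean, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- threshold
  attr(out, "min_support") <- min_support
  class(out) <- c("ConsensusSignature", "data.frame")
  out
}

#' Extract the member genes of a consensus signature
#' @param sig a `ConsensusSignature` data.frame.
#' @param name name for the resulting gene set.
#' @return a [gene_set()] of member genes (error if none).
#' @export
signature_genes <- function(sig, name = "EC.SENESCENCE.CONSENSUS") {
  g <- sig$gene_id[sig$member]
  if (length(g) == 0) stop("consensus signature has no member genes")
  gene_set(name, sort(g))
}
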