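#' Per-gene observation-level enrichment statistic
#'
#' First stage of the single-sample enrichment score: each gene's expression
#' values are converted to a within-gene statistic across observations.
#'
#' * `kernel = "ecdf"`: `z_ij` = rank of `x_ij` among the gene's values (mean
#'   rank for ties) divided by the number of observations, i.e. the empirical
#'   CDF evaluated with mid-ranks. Invariant under any strictly increasing
#'   per-gene transform.
#' * `kernel = "gaussian"`: `z_ij = mean_k Phi((x_ij - x_ik)/h_i)` with
#'   bandwidth `h_i = sd_i / 4`; genes with zero standard deviation fall back
#'   to the ecdf statistic.
#'
#' @param m `ExpressionMatrix` with at least 3 observations.
#' @param kernel `"ecdf"` or `"gaussian"`.
#' @return numeric matrix of `z` values, genes x observations.
#' @export
gene_stat <- function(m, kernel = c("ecdf", "gaussian")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  kernel <- match.arg(kernel)
  x <- em_values(m)
  n <- ncol(x)
  if (n < 3)
    stop("gene_stat needs >= 3 observations, got ", n)
  ecdf_rows <- function(xx)
    t(apply(xx, 1, function(r) rank(r, ties.method = "average"))) / n
  if (kernel == "ecdf") {
    z <- ecdf_rows(x)
  } else {
    sds <- apply(x, 1, stats::sd)
    z <- matrix(0, nrow(x), n)
    flat <- sds == 0
    if (any(!flat)) {
      for (i in which(!flat)) {
        h <- sds[i] / 4
        z[i, ] <- rowMeans(stats::pnorm(outer(x[i, ], x[i, ], "-") / h))
      }
    }
    if (any(flat)) z[flat, ] <- ecdf_rows(x[flat, , drop = FALSE])
  }
  dimnames(z) <- list(m$gene_ids, m$obs_ids)
  z
}

# Deviation profile of the enrichment random walk for one observation.
# ord: gene indices in walk order; inset: logical per gene; w: |p/2 - r|^tau.
walk_profile <- function(z_col, gene_ids, inset, tau) {
  p <- length(z_col)
  ord <- order(-z_col, gene_ids)
  r <- seq_len(p)
  w <- abs(p / 2 - r)^tau
  in_ord <- inset[ord]
  step <- numeric(p)
  wsum <- sum(w[in_ord])
  # degenerate corner: every in-set gene at the zero-weight mid rank; fall
  # back to equal in-set increments (the tau -> 0 limit)
  step[in_ord] <- if (wsum > 0) w[in_ord] / wsum else 1 / sum(in_ord)
  step[!in_ord] <- -1 / (p - sum(inset))
  cumsum(step)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based random-walk statistic. Per observation: (i) genes are ranked by
#' their [gene_stat()] value in decreasing order, ties broken lexically by
#' gene ID; (ii) each rank position `r` receives the symmetric weight
#' `|p/2 - r|^tau`; (iii) a walk over the ordered genes adds the normalized
#' weight for in-set genes and subtracts `1/(p - |G|)` for out-set genes;
#' (iv) the score summarizes the walk's deviation profile:
#' `method = "maxdev"` returns the signed deviation of maximal magnitude
#' (equal-magnitude ties resolve to the negative deviation),
#' `method = "maxdiff"` returns the largest positive deviation plus the
#' smallest negative deviation (each clamped through 0). Scores lie in
#' `[-1, 1]`.
#'
#' @param m `ExpressionMatrix` (>= 3 observations).
#' @param g a [gene_set()]; genes absent from the matrix are dropped with a
#'   warning; the intersection must be non-empty and smaller than the gene
#'   universe.
#' @param method `"maxdiff"` (default) or `"maxdev"`.
#' @param kernel passed to [gene_stat()].
#' @param tau weight exponent (default 1).
#' @return object of class `EnrichmentScores`: list with `set_name`,
#'   `obs_ids`, `scores` (named numeric), `method`, `kernel`, `tau`.
#' @export
score_gene_set <- function(m, g, method = c("maxdiff", "maxdev"),
                           kernel = c("ecdf", "gaussian"), tau = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(g, "GeneSet"))
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  present <- g$genes %in% m$gene_ids
  if (any(!present))
    warning("score_gene_set: ", sum(!present), " gene(s) of set '", g$name,
            "' absent from matrix and dropped")
  gs <- g$genes[present]
  p <- length(m$gene_ids)
  if (length(gs) == 0)
    stop("gene set '", g$name, "' has empty intersection with the matrix")
  if (length(gs) >= p)
    stop("gene set '", g$name, "' covers the whole gene universe")
  z <- gene_stat(m, kernel = kernel)
  inset <- m$gene_ids %in% gs
  scores <- vapply(seq_len(ncol(z)), function(j) {
    cum <- walk_profile(z[, j], m$gene_ids, inset, tau)
    maxpos <- max(c(cum, 0))
    minneg <- min(c(cum, 0))
    if (method == "maxdev") {
      # equal-magnitude ties resolve to the negative deviation
      if (maxpos + minneg > 1e-12) maxpos else minneg
    } else {
      maxpos + minneg
    }
  }, numeric(1))
  names(scores) <- m$obs_ids
  structure(list(set_name = g$name, obs_ids = m$obs_ids, scores = scores,
                 method = method, kernel = kernel, tau = tau),
            class = "EnrichmentScores")
}

#' @export
print.EnrichmentScores <- function(x, ...) {
  cat(sprintf("EnrichmentScores '%s' (%s/%s, tau=%g): %d observations\n",
              x$set_name, x$method, x$kernel, x$tau, length(x$scores)))
  invisible(x)
}

#' Median split into high/low groups
#'
#' Dichotomizes observations at the median score: label `HS` (high) iff
#' score > median, ties at the median go to `LS`. Used both for the
#' high-/low-senescence TEC split and, via [dichotomize()], for the
#' high-/low-risk patient split.
#'
#' @param scores an `EnrichmentScores` object or a named numeric vector.
#' @param obs_subset optional character vector restricting the split to a
#'   subset of observations.
#' @return data.frame (`obs_id`, `score`, `label`) with attribute
#'   `"threshold"` (the median).
#' @export
median_split <- function(scores, obs_subset = NULL) {
  s <- if (inherits(scores, "EnrichmentScores")) scores$scores else scores
  if (is.null(names(s))) stop("scores must be named by observation")
  if (!is.null(obs_subset)) {
    miss <- setdiff(obs_subset, names(s))
    if (length(miss))
      stop("observations without scores: ", paste(miss, collapse = ", "))
    s <- s[obs_subset]
  }
  if (length(s) < 2) stop("median_split needs >= 2 observations")
  if (length(unique(s)) == 1)
    stop("degenerate split: all scores identical (", s[1], ")")
  thr <- stats::median(s)
  out <- data.frame(obs_id = names(s), score = unname(s),
                    label = ifelse(s > thr, "HS", "LS"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' Write enrichment scores as TSV
#' @param scores an `EnrichmentScores` object.
#' @param path output TSV (`obs_id`, `set_name`, `score`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "EnrichmentScores"))
  tab <- data.frame(obs_id = scores$obs_ids, set_name = scores$set_name,
                    score = unname(scores$scores))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
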