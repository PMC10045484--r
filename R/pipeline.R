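#' Pipeline configuration
#'
#' Bundles every threshold of the two workflows (signature derivation and
#' prognostic evaluation) with their defaults: QC bounds 300/6500 detected
#' genes and 10% mitochondrial counts; marker filters min_pct 0.25,
#' min_logfc 0.25, FDR 0.05; Gx FDR 0.05 with a 10-cell expression floor;
#' consensus geometric-mean threshold 0.2; ecdf kernel, maxdiff method,
#' tau 1 for enrichment scoring.
#'
#' @param qc a [qc_thresholds()] object.
#' @param min_pct,min_logfc,max_fdr marker filters (see [find_markers()]).
#' @param logfc_inclusive use `>=` instead of `>` for the logFC filter.
#' @param consensus_threshold geometric-mean membership cutoff.
#' @param min_support minimum supporting datasets for membership.
#' @param kernel,method,tau enrichment-scoring options
#'   (see [score_gene_set()]).
#' @param min_cells_expr Gx expression floor (cells).
#' @param endothelial_type annotation label of the endothelial type.
#' @param zscore z-score bulk expression in [risk_score()].
#' @param seed global seed, fanned out per stage via [stage_seed()].
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), min_pct = 0.25,
                            min_logfc = 0.25, max_fdr = 0.05,
                            logfc_inclusive = FALSE,
                            consensus_threshold = 0.2, min_support = 1,
                            kernel = "ecdf", method = "maxdiff", tau = 1,
                            min_cells_expr = 10, endothelial_type = "TEC",
                            zscore = TRUE, seed = 1) {
  stopifnot(inherits(qc, "QCThresholds"),
            min_pct >= 0, min_pct <= 1,
            max_fdr > 0, max_fdr <= 1,
            consensus_threshold >= 0, consensus_threshold < 1,
            min_support >= 1,
            kernel %in% c("ecdf", "gaussian"),
            method %in% c("maxdiff", "maxdev"),
            tau >= 0, min_cells_expr >= 1)
  structure(as.list(environment()), class = "PipelineConfig")
}

# flat key=value serialization of a config; stable ordering for hashing
config_lines <- function(config) {
  flat <- list()
  for (nm in sort(names(config))) {
    v <- config[[nm]]
    if (inherits(v, "QCThresholds")) {
      for (qn in sort(names(v)))
        flat[[paste0("qc.", qn)]] <- v[[qn]]
    } else if (is.atomic(v)) {
      flat[[nm]] <- v
    }
  }
  vapply(names(flat), function(k)
    paste0(k, "\t", paste(format(flat[[k]], digits = 15), collapse = ",")),
    character(1))
}

#' Write a configuration copy with its hash
#' @param config a `PipelineConfig`.
#' @param out_dir output directory.
#' @return md5 hash of the serialized config, invisibly.
#' @export
write_config <- function(config, out_dir) {
  path <- file.path(out_dir, "config.tsv")
  writeLines(config_lines(config), path)
  invisible(unname(tools::md5sum(path)))
}

# run one dataset through QC -> lognorm -> scoring -> Gx/Gy/Gn
derive_one_dataset <- function(ds, senescence_set, config) {
  ds_id <- ds$matrix$dataset_id
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[", stage, " | dataset ", ds_id, "] ", conditionMessage(e),
           call. = FALSE))
  }
  qc <- with_stage("qc_filter_cells",
                   qc_filter_cells(ds$matrix, config$qc))
  ln <- with_stage("lognormalize", lognormalize(qc$matrix))
  scores <- with_stage("score_gene_set",
                       score_gene_set(ln, senescence_set,
                                      method = config$method,
                                      kernel = config$kernel,
                                      tau = config$tau))
  ann <- ds$annotation[ds$annotation$obs_id %in% ln$obs_ids, , drop = FALSE]
  gx <- with_stage("gx_set",
                   gx_set(ln, ann, scores,
                          cell_type = config$endothelial_type,
                          max_fdr = config$max_fdr,
                          min_cells_expr = config$min_cells_expr))
  markers <- with_stage("find_markers",
                        find_markers(ln, ann, min_pct = config$min_pct,
                                     min_logfc = config$min_logfc,
                                     max_fdr = config$max_fdr,
                                     logfc_inclusive = config$logfc_inclusive))
  gy <- with_stage("gy_set",
                   gy_set(markers, cell_type = config$endothelial_type,
                          dataset_id = ds_id))
  cand <- dataset_candidates(gx$set, gy, ds_id)
  list(dataset_id = ds_id, qc_report = qc$report, scores = scores,
       correlations = gx$correlations, markers = markers,
       candidates = cand)
}

#' Derive the consensus signature from a list of datasets (in memory)
#'
#' The core of the derivation workflow: per dataset runs QC, normalization,
#' senescence scoring, correlation evidence (Gx), marker evidence (Gy) and
#' their intersection (Gn), then the cross-dataset geometric-mean consensus.
#'
#' @param datasets list, one element per dataset, each a list with `matrix`
#'   (`ExpressionMatrix`, counts layer) and `annotation`
#'   ([cell_annotation()]).
#' @param senescence_set the senescence readout [gene_set()].
#' @param config a [pipeline_config()].
#' @return list with `signature` (a [consensus()] table), `per_dataset`
#'   (stage results incl. QC reports, correlations, markers, candidates).
#' @export
derive_signature <- function(datasets, senescence_set,
                             config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"), length(datasets) >= 1)
  per_ds <- lapply(datasets, derive_one_dataset,
                   senescence_set = senescence_set, config = config)
  correlations <- do.call(rbind, lapply(per_ds, `[[`, "correlations"))
  cands <- lapply(per_ds, `[[`, "candidates")
  sig <- consensus(cands, correlations,
                   threshold = config$consensus_threshold,
                   min_support = config$min_support)
  list(signature = sig, per_dataset = per_ds)
}

# read a manifest TSV (dataset_id, matrix, annotation [, format]) into the
# in-memory dataset list
read_manifest <- function(path) {
  man <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("dataset_id", "matrix", "annotation")
  miss <- setdiff(need, colnames(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(man)), function(i) {
    mp <- resolve(man$matrix[i])
    if (!file.exists(mp))
      stop("manifest dataset '", man$dataset_id[i],
           "': matrix path not found: ", man$matrix[i])
    fmt <- if ("format" %in% colnames(man)) man$format[i]
           else if (dir.exists(mp)) "mtx_dir" else "tsv"
    m <- read_expression(mp, format = fmt, layer = "counts",
                         dataset_id = man$dataset_id[i])
    ap <- resolve(man$annotation[i])
    if (!file.exists(ap))
      stop("manifest dataset '", man$dataset_id[i],
           "': annotation path not found: ", man$annotation[i])
    ann <- utils::read.table(ap, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    list(matrix = m,
         annotation = cell_annotation(ann$obs_id, ann$cell_type,
                                      dataset_id = man$dataset_id[i]))
  })
}

write_tsv_det <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 15,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the signature-derivation workflow and write its outputs
#'
#' @param datasets list of in-memory datasets (as for [derive_signature()])
#'   or the path of a manifest TSV with columns `dataset_id`, `matrix`,
#'   `annotation`.
#' @param senescence_set the senescence readout [gene_set()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); receives per-dataset
#'   `gx_<id>.tsv`, `gy_<id>.tsv`, `gn_<id>.tsv`, `qc_<id>.tsv`, plus
#'   `signature.tsv`, `config.tsv` and `run.log`.
#' @return the [derive_signature()] result, invisibly.
#' @export
run_derive <- function(datasets, senescence_set,
                       config = pipeline_config(), out_dir) {
  if (is.character(datasets) && length(datasets) == 1)
    datasets <- read_manifest(datasets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- derive_signature(datasets, senescence_set, config)
  cfg_hash <- write_config(config, out_dir)
  log_lines <- c(sprintf("config_hash\t%s", cfg_hash),
                 sprintf("seed\t%d", config$seed),
                 sprintf("n_datasets\t%d", length(datasets)))
  for (pd in res$per_dataset) {
    id <- pd$dataset_id
    write_tsv_det(pd$qc_report, file.path(out_dir, paste0("qc_", id, ".tsv")))
    write_tsv_det(data.frame(gene_id = pd$candidates$gx),
                  file.path(out_dir, paste0("gx_", id, ".tsv")))
    write_tsv_det(data.frame(gene_id = pd$candidates$gy),
                  file.path(out_dir, paste0("gy_", id, ".tsv")))
    write_tsv_det(data.frame(gene_id = pd$candidates$gn),
                  file.path(out_dir, paste0("gn_", id, ".tsv")))
    log_lines <- c(log_lines, sprintf(
      "dataset\t%s\tcells_kept=%d\tgx=%d\tgy=%d\tgn=%d", id,
      length(pd$scores$obs_ids), length(pd$candidates$gx),
      length(pd$candidates$gy), length(pd$candidates$gn)))
  }
  sig_tab <- as.data.frame(res$signature)
  write_tsv_det(sig_tab, file.path(out_dir, "signature.tsv"))
  log_lines <- c(log_lines,
                 sprintf("signature_members\t%d", sum(res$signature$member)))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}

#' Run the prognostic workflow and write its outputs
#'
#' Scores bulk samples on the signature genes, fits (or accepts) Cox
#' coefficients, computes the linear risk score, dichotomizes at the median,
#' and evaluates Kaplan-Meier curves, the log-rank test and the concordance
#' index.
#'
#' @param expr `ExpressionMatrix` of bulk samples (genes x samples).
#' @param clinical data.frame with `sample_id`, `time`, `event` covering the
#'   samples of `expr`.
#' @param signature a [gene_set()] (or `ConsensusSignature`) naming the
#'   signature genes.
#' @param coef optional named coefficient vector; when `NULL` a multivariate
#'   [cox_fit()] on the z-scored signature genes supplies it.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; receives `risk_scores.tsv`,
#'   `km_curves.tsv`, `logrank.tsv`, `config.tsv`, `run.log`.
#' @return list with `model` (`CoxModel` or `NULL` when `coef` supplied),
#'   `coef`, `scores`, `groups`, `km`, `logrank`, `c_index`.
#' @export
run_prognostic <- function(expr, clinical, signature, coef = NULL,
                           config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(config, "PipelineConfig"))
  if (inherits(signature, "ConsensusSignature"))
    signature <- signature_genes(signature)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  common <- intersect(expr$obs_ids, clinical$sample_id)
  if (length(common) < 2)
    stop("fewer than 2 samples shared between expression and clinical data")
  expr <- em_subset(expr, obs = common)
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  genes <- intersect(signature$genes, expr$gene_ids)
  if (length(genes) == 0)
    stop("no signature gene present in the expression matrix")
  x <- em_values(em_subset(expr, genes = genes))
  if (config$zscore) {
    sdv <- apply(x, 1, stats::sd)
    keep <- sdv > 0
    if (!all(keep)) {
      warning("dropping zero-variance signature gene(s): ",
              paste(genes[!keep], collapse = ", "))
      genes <- genes[keep]
      x <- x[keep, , drop = FALSE]
    }
    x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  }
  model <- NULL
  if (is.null(coef)) {
    rec <- cbind(clinical[, c("time", "event")], as.data.frame(t(x)))
    model <- cox_fit(rec, genes)
    coef <- model$coef
  } else {
    missing_genes <- setdiff(names(coef), expr$gene_ids)
    if (length(missing_genes))
      stop("coefficient gene(s) absent from matrix: ",
           paste(missing_genes, collapse = ", "))
    genes <- names(coef)
    x <- em_values(em_subset(expr, genes = genes))
    if (config$zscore)
      x <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  }
  scores <- data.frame(sample_id = common,
                       score = as.numeric(crossprod(x, coef[genes])),
                       stringsAsFactors = FALSE)
  groups <- tryCatch(dichotomize(scores), error = function(e)
    stop(conditionMessage(e),
         " -- risk scores are constant; check that the coefficients are ",
         "not all zero and the signature genes vary across samples",
         call. = FALSE))
  rec <- data.frame(sample_id = common, time = clinical$time,
                    event = clinical$event, stringsAsFactors = FALSE)
  km <- km_estimate(rec, groups$group)
  lr <- logrank_test(rec, groups$group)
  ci <- concordance_index(rec, scores$score)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_hash <- write_config(config, out_dir)
    write_tsv_det(cbind(scores, group = groups$group),
                  file.path(out_dir, "risk_scores.tsv"))
    write_tsv_det(km, file.path(out_dir, "km_curves.tsv"))
    write_tsv_det(data.frame(chi_square = lr$chi_square, p = lr$p,
                             c_index = ci),
                  file.path(out_dir, "logrank.tsv"))
    writeLines(c(sprintf("config_hash\t%s", cfg_hash),
                 sprintf("n_samples\t%d", length(common)),
                 sprintf("n_signature_genes\t%d", length(genes)),
                 sprintf("logrank_p\t%s", format(lr$p, digits = 15)),
                 sprintf("c_index\t%s", format(ci, digits = 15))),
               file.path(out_dir, "run.log"))
  }
  list(model = model, coef = coef[genes], scores = scores, groups = groups,
       km = km, logrank = lr, c_index = ci)
}
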