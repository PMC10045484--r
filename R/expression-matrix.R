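#' Expression matrix container
#'
#' The shared substrate of the pipeline: a genes x observations matrix of
#' non-negative expression values. Observations are cells (single-cell stage)
#' or bulk samples (prognostic stage). The `layer` flag records whether the
#' values are raw counts or log-normalized expression; every downstream
#' operation checks it.
#'
#' @param values numeric matrix or [Matrix::sparseMatrix], genes in rows,
#'   observations in columns; finite and non-negative.
#' @param gene_ids character vector of unique gene symbols, one per row.
#' @param obs_ids character vector of unique cell/sample identifiers, one per
#'   column.
#' @param layer `"counts"` or `"lognorm"`.
#' @param dataset_id single string naming the dataset of origin.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `gene_ids`, `obs_ids`, `values`, `layer`, `dataset_id`.
#' @export
expression_matrix <- function(values, gene_ids, obs_ids,
                              layer = c("counts", "lognorm"),
                              dataset_id = "dataset") {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a base matrix or a Matrix::Matrix")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != nrow(values) (",
         nrow(values), ")")
  if (length(obs_ids) != ncol(values))
    stop("obs_ids length (", length(obs_ids), ") != ncol(values) (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(obs_ids))
    stop("duplicate obs_ids: ",
         paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "))
  vals <- if (methods::is(values, "Matrix")) values@x else values
  if (length(vals) && (!all(is.finite(vals)) || any(vals < 0)))
    stop("expression values must be finite and >= 0")
  if (!is.character(gene_ids)) gene_ids <- as.character(gene_ids)
  if (!is.character(obs_ids)) obs_ids <- as.character(obs_ids)
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(list(gene_ids = gene_ids, obs_ids = obs_ids, values = values,
                 layer = layer, dataset_id = as.character(dataset_id)[1]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d observations [%s]\n",
              x$dataset_id, length(x$gene_ids), length(x$obs_ids), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Dense numeric values of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return base numeric matrix, genes x observations.
#' @export
em_values <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  as.matrix(m$values)
}

#' Subset an ExpressionMatrix by genes and/or observations
#'
#' @param m an `ExpressionMatrix`.
#' @param genes,obs character vectors of IDs (or integer/logical indices) to
#'   keep; `NULL` keeps all.
#' @return the subset `ExpressionMatrix` (same layer and dataset_id).
#' @export
em_subset <- function(m, genes = NULL, obs = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else {
    if (is.character(genes)) {
      idx <- match(genes, m$gene_ids)
      if (anyNA(idx))
        stop("genes not present: ", paste(genes[is.na(idx)], collapse = ", "))
      idx
    } else genes
  }
  oi <- if (is.null(obs)) seq_along(m$obs_ids) else {
    if (is.character(obs)) {
      idx <- match(obs, m$obs_ids)
      if (anyNA(idx))
        stop("observations not present: ",
             paste(obs[is.na(idx)], collapse = ", "))
      idx
    } else obs
  }
  expression_matrix(m$values[gi, oi, drop = FALSE],
                    m$gene_ids[gi], m$obs_ids[oi],
                    layer = m$layer, dataset_id = m$dataset_id)
}

# Deterministic disambiguation of duplicated feature symbols: second and later
# occurrences (in file order) get suffixes ".1", ".2", ...
disambiguate_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  out <- ids
  tab <- table(ids)
  for (sym in names(tab)[tab > 1]) {
    at <- which(ids == sym)
    out[at[-1]] <- paste0(sym, ".", seq_len(length(at) - 1))
  }
  out
}

#' Read an expression matrix from disk
#'
#' Supports a 10x-style MTX directory (`matrix.mtx` or `matrix.mtx.gz` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, optionally gzipped) and a
#' dense TSV with a header row of observation IDs and gene IDs in the first
#' column. Duplicated feature symbols are disambiguated deterministically with
#' suffixes `.1`, `.2`, ... in file order.
#'
#' @param path directory (format `"mtx_dir"`) or file (format `"tsv"`).
#' @param format `"mtx_dir"` or `"tsv"`.
#' @param layer layer flag to stamp on the result (`"counts"` default).
#' @param dataset_id dataset label for the result.
#' @return a validated [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "tsv"),
                            layer = c("counts", "lognorm"),
                            dataset_id = NULL) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "mtx_dir") {
    find1 <- function(cands) {
      for (f in cands) {
        p <- file.path(path, f)
        if (file.exists(p)) return(p)
      }
      stop("missing companion file in ", path, ": expected one of ",
           paste(cands, collapse = ", "))
    }
    mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
    feat <- find1(c("features.tsv", "features.tsv.gz",
                    "genes.tsv", "genes.tsv.gz"))
    bc <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
    values <- Matrix::readMM(mtx)
    if (length(values@x) && any(values@x < 0)) {
      tm <- methods::as(values, "TsparseMatrix")
      bad <- which(tm@x < 0)[1]
      stop(sprintf("negative value %g at matrix coordinate (%d,%d) in %s",
                   tm@x[bad], tm@i[bad] + 1L, tm@j[bad] + 1L, mtx))
    }
    ftab <- utils::read.table(feat, sep = "\t", header = FALSE,
                              colClasses = "character", quote = "")
    # 10x features.tsv: id, symbol, type; plain genes.tsv may have 1-2 cols.
    sym <- if (ncol(ftab) >= 2) ftab[[2]] else ftab[[1]]
    bcs <- utils::read.table(bc, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")[[1]]
    if (nrow(values) != length(sym))
      stop("feature file rows (", length(sym), ") != matrix rows (",
           nrow(values), ") in ", path)
    if (ncol(values) != length(bcs))
      stop("barcode file rows (", length(bcs), ") != matrix columns (",
           ncol(values), ") in ", path)
    expression_matrix(methods::as(values, "CsparseMatrix"), disambiguate_ids(sym), bcs,
                      layer = layer, dataset_id = dataset_id)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, quote = "",
                             colClasses = "character")
    if (ncol(tab) < 2) stop("TSV must have gene column plus >= 1 observation")
    genes <- disambiguate_ids(tab[[1]])
    num <- suppressWarnings(
      vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    num <- matrix(num, nrow = nrow(tab),
                  dimnames = list(NULL, colnames(tab)[-1]))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric entry at gene '%s', observation '%s' in %s",
                   genes[bad[1]], colnames(num)[bad[2]], path))
    }
    if (any(num < 0)) {
      bad <- which(num < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative value at gene '%s', observation '%s' in %s",
                   genes[bad[1]], colnames(num)[bad[2]], path))
    }
    expression_matrix(num, genes, colnames(num),
                      layer = layer, dataset_id = dataset_id)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: `"tsv"` writes the dense gene x observation
#' table; `"mtx_dir"` writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file (tsv) or directory (mtx_dir; created if absent).
#' @param format `"tsv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "mtx_dir")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene_id = m$gene_ids, em_values(m),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(m$values, "dMatrix"),
                                "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
    writeLines(m$obs_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Cell-type annotation table
#'
#' @param obs_id character vector of cell IDs (each appearing exactly once).
#' @param cell_type character vector of labels, same length.
#' @param dataset_id dataset label.
#' @param vocabulary optional character vector; if given, every label must be
#'   drawn from it.
#' @return data.frame with columns `obs_id`, `cell_type`, `dataset_id`.
#' @export
cell_annotation <- function(obs_id, cell_type, dataset_id = "dataset",
                            vocabulary = NULL) {
  if (length(obs_id) != length(cell_type))
    stop("obs_id and cell_type lengths differ")
  if (anyDuplicated(obs_id))
    stop("duplicate obs_id in annotation: ",
         paste(unique(obs_id[duplicated(obs_id)]), collapse = ", "))
  if (!is.null(vocabulary) && !all(cell_type %in% vocabulary))
    stop("cell_type labels outside vocabulary: ",
         paste(setdiff(unique(cell_type), vocabulary), collapse = ", "))
  data.frame(obs_id = as.character(obs_id),
             cell_type = as.character(cell_type),
             dataset_id = dataset_id, stringsAsFactors = FALSE)
}

#' Gene set constructor
#'
#' @param name set name.
#' @param genes character vector of gene symbols; duplicates removed keeping
#'   the first occurrence; must be non-empty after deduplication.
#' @return list of class `GeneSet` with elements `name`, `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name)[1], genes = genes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' MSigDB dialect: one set per line, tab-separated `name`, `description`,
#' then the genes. Within-line duplicate genes are dropped keeping the first
#' occurrence.
#'
#' @param path GMT file.
#' @return named list of [gene_set()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has ", length(f), " fields (need >= 3)")
    sets[[i]] <- gene_set(f[1], f[-(1:2)])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of `GeneSet` objects.
#' @param path output file.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table of survival records
#'
#' TSV with required columns `sample_id`, `time`, `event`; additional numeric
#' columns are carried along as covariates. Rows with missing time or event
#' are dropped and the drop count is reported via a message and the
#' `"n_dropped"` attribute.
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `time` (positive), `event`
#'   (0/1) and any extra covariate columns; attribute `n_dropped` holds the
#'   number of incomplete rows removed.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  keep <- !(is.na(tab$time) | is.na(tab$event))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_clinical: dropped ", n_dropped,
            " row(s) with missing time or event")
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in clinical table")
  if (any(tab$time <= 0))
    stop("non-positive survival time for sample(s): ",
         paste(tab$sample_id[tab$time <= 0], collapse = ", "))
  if (!all(tab$event %in% c(0, 1)))
    stop("event must be 0 or 1; offending sample(s): ",
         paste(tab$sample_id[!tab$event %in% c(0, 1)], collapse = ", "))
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write a clinical table
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
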