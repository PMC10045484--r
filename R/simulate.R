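#' Derive a stage-specific seed from a global seed
#'
#' Deterministic fan-out of one global seed to per-stage seeds: the stage
#' name is folded into an integer via its character codes and combined with
#' the global seed modulo 2^31 - 1, so stages can be re-run in isolation.
#'
#' @param seed global integer seed.
#' @param stage stage name (string).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

#' Configuration for the synthetic single-cell generator
#'
#' Defines the multi-dataset single-cell study conditions: per dataset, five
#' cell types with a latent per-cell senescence activity `s ~ Uniform(0,1)`
#' in endothelial cells (TEC) only. Counts are negative binomial with
#' per-cell lognormal library sizes. Three gene programs are planted on a
#' shared gene universe:
#'
#' * a stand-in senescence readout set (`n_senescence_set` genes) whose mean
#'   is multiplied by `exp(effect * u)` where `u` is a pan-lineage senescence
#'   latent equal to `s` in TECs and an independent Uniform(0,1) elsewhere —
#'   senescence is not endothelial-specific, so the readout genes correlate
#'   with the score inside TECs yet are not endothelial markers;
#' * `n_planted_ec` true endothelial-senescence genes responding to `s`
#'   (TECs only) plus an endothelial baseline shift (so they are TEC
#'   markers) — the recovery target; a fraction `overlap_fraction` of these
#'   also sit in the readout set;
#' * an equally sized decoy program with the same pan-lineage response as
#'   the readout set but outside it — these appear in the correlation
#'   evidence (Gx) yet must be excluded from Gn by the marker filter (Gy).
#'
#' Each non-TEC cell type additionally gets `n_markers_per_type` baseline
#' marker genes, and TECs get `n_markers_per_type` non-senescence markers, so
#' marker detection has realistic structure. `n_mito` genes carry the `MT-`
#' prefix at a low total abundance.
#'
#' @param n_datasets number of datasets (default 6).
#' @param cell_counts named integer vector of cells per type.
#' @param n_genes gene universe size (default 2000).
#' @param n_senescence_set size of the stand-in readout set (default 50).
#' @param n_planted_ec number of planted endothelial-senescence genes
#'   (default 40).
#' @param effect mean log-expression shift per unit latent senescence
#'   (default 1.0).
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`; default 0.2, typical of droplet UMI data).
#' @param libsize_meanlog,libsize_sdlog lognormal library-size parameters
#'   (defaults `log(1e4)`, 0.25).
#' @param overlap_fraction fraction of planted genes shared with the readout
#'   set (default 0.2).
#' @param n_mito mitochondrial genes (default 13).
#' @param mito_abundance total mitochondrial share of the library
#'   (default 0.03).
#' @param n_markers_per_type baseline marker genes per cell type
#'   (default 30).
#' @param marker_shift log-scale baseline shift of marker genes in their type
#'   (default 1.5).
#' @param role_boost log-scale expression boost of program genes, placing
#'   them in the moderately-expressed stratum (default 1.0).
#' @param seed global seed.
#' @return list of class `SCSimConfig`.
#' @export
sc_sim_config <- function(n_datasets = 6,
                          cell_counts = c(TEC = 300, Tumor = 800, CAF = 200,
                                          Tcell = 400, Myeloid = 300),
                          n_genes = 2000, n_senescence_set = 50,
                          n_planted_ec = 40, effect = 1.0,
                          nb_dispersion = 0.2,
                          libsize_meanlog = log(1e4), libsize_sdlog = 0.25,
                          overlap_fraction = 0.2, n_mito = 13,
                          mito_abundance = 0.03, n_markers_per_type = 30,
                          marker_shift = 1.5, role_boost = 1.0, seed = 1) {
  stopifnot(n_datasets >= 1, all(cell_counts > 0), n_genes > 0,
            n_senescence_set > 0, n_planted_ec > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            nb_dispersion > 0, n_mito >= 0,
            mito_abundance >= 0, mito_abundance < 1)
  need <- n_senescence_set + n_planted_ec * 2 +
    n_markers_per_type * length(cell_counts) + n_mito
  if (need > n_genes)
    stop("gene programs need ", need, " genes but n_genes = ", n_genes)
  structure(as.list(environment()), class = "SCSimConfig")
}

#' Simulate multi-dataset single-cell data with planted ground truth
#'
#' See [sc_sim_config()] for the generative model. Gene roles are drawn once
#' from the global seed and shared across datasets (a common gene universe);
#' per-dataset baseline expression, latent activities, library sizes and
#' counts are drawn from per-dataset derived seeds, so datasets differ the
#' way real cohorts do while carrying the same planted program.
#'
#' @param config an [sc_sim_config()].
#' @return list with:
#'   * `datasets`: per dataset, a list of `matrix` (`ExpressionMatrix`,
#'     counts), `annotation` (cell types), `truth` (data.frame `obs_id`,
#'     `cell_type`, `s` — latent senescence, nonzero only in TECs);
#'   * `senescence_set`: the stand-in readout [gene_set()];
#'   * `planted`: character vector of true endothelial-senescence genes;
#'   * `decoys`: character vector of pan-lineage decoy genes;
#'   * `markers_by_type`: list of baseline marker genes per cell type;
#'   * `config`.
#' @export
simulate_sc <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "SCSimConfig"))
  cc <- config$cell_counts
  types <- names(cc)
  if (!"TEC" %in% types) stop("cell_counts must include a TEC type")
  n_genes <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_genes))

  # gene roles: drawn once, shared across datasets
  set.seed(stage_seed(config$seed, "gene_roles"))
  if (config$n_mito > 0) {
    mito_idx <- seq_len(config$n_mito)
    gene_ids[mito_idx] <- sprintf("MT-%d", seq_len(config$n_mito))
  } else mito_idx <- integer(0)
  pool <- setdiff(seq_len(n_genes), mito_idx)
  take <- function(n) {
    got <- sample(pool, n)
    pool <<- setdiff(pool, got)
    got
  }
  planted_idx <- take(config$n_planted_ec)
  n_overlap <- round(config$overlap_fraction * config$n_planted_ec)
  n_overlap <- min(n_overlap, config$n_senescence_set)
  sen_only_idx <- take(config$n_senescence_set - n_overlap)
  sen_idx <- c(if (n_overlap > 0) sample(planted_idx, n_overlap), sen_only_idx)
  decoy_idx <- take(config$n_planted_ec)
  marker_idx <- lapply(types, function(tp) take(config$n_markers_per_type))
  names(marker_idx) <- types

  n_cells <- sum(cc)
  type_vec <- rep(types, times = cc)

  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    ds_id <- sprintf("sim%02d", d)
    set.seed(stage_seed(config$seed, paste0("dataset_", d)))
    # baseline relative abundance; program genes boosted into the
    # moderately-expressed stratum
    logbase <- stats::rnorm(n_genes, 0, 1)
    boost <- unique(c(planted_idx, sen_idx, decoy_idx))
    logbase[boost] <- abs(stats::rnorm(length(boost), 0, 0.5)) +
      config$role_boost
    base <- exp(logbase)
    if (length(mito_idx)) {
      base[mito_idx] <- stats::runif(length(mito_idx), 0.5, 1.5)
      base[mito_idx] <- base[mito_idx] / sum(base[mito_idx]) *
        config$mito_abundance / (1 - config$mito_abundance) *
        sum(base[-mito_idx])
    }

    s <- ifelse(type_vec == "TEC", stats::runif(n_cells), 0)
    # pan-lineage senescence latent: the TEC activity inside TECs, an
    # independent level elsewhere (non-TEC cells senesce too)
    u <- ifelse(type_vec == "TEC", s, stats::runif(n_cells))
    libsize <- stats::rlnorm(n_cells, config$libsize_meanlog,
                             config$libsize_sdlog)

    # per-cell mean profile: baseline x type-marker shift x program response
    logmu <- matrix(log(base), n_genes, n_cells)
    for (tp in types) {
      cols <- type_vec == tp
      logmu[marker_idx[[tp]], cols] <-
        logmu[marker_idx[[tp]], cols] + config$marker_shift
    }
    tec_cols <- type_vec == "TEC"
    logmu[planted_idx, tec_cols] <- logmu[planted_idx, tec_cols] +
      config$marker_shift +
      config$effect * rep(s[tec_cols], each = length(planted_idx))
    pan <- unique(c(setdiff(sen_idx, planted_idx), decoy_idx))
    logmu[pan, ] <- logmu[pan, ] +
      config$effect * rep(u, each = length(pan))

    mu <- exp(logmu)
    mu <- sweep(mu, 2, colSums(mu), `/`)          # per-cell composition
    mu <- sweep(mu, 2, libsize, `*`)
    counts <- matrix(
      stats::rnbinom(n_genes * n_cells, mu = mu,
                     size = 1 / config$nb_dispersion),
      n_genes, n_cells)
    obs_ids <- sprintf("%s_c%04d", ds_id, seq_len(n_cells))
    datasets[[d]] <- list(
      matrix = expression_matrix(counts, gene_ids, obs_ids,
                                 layer = "counts", dataset_id = ds_id),
      annotation = cell_annotation(obs_ids, type_vec, dataset_id = ds_id),
      truth = data.frame(obs_id = obs_ids, cell_type = type_vec, s = s,
                         stringsAsFactors = FALSE))
  }
  names(datasets) <- vapply(datasets, function(x) x$matrix$dataset_id,
                            character(1))
  list(datasets = datasets,
       senescence_set = gene_set("SENESCENCE.STANDIN",
                                 sort(gene_ids[sen_idx])),
       planted = sort(gene_ids[planted_idx]),
       decoys = sort(gene_ids[decoy_idx]),
       markers_by_type = lapply(marker_idx, function(i) sort(gene_ids[i])),
       config = config)
}

#' Configuration for the synthetic bulk-cohort generator
#'
#' Bulk samples carry a latent activity `a ~ N(0, 1)`; signature-gene
#' expression is `baseline_mean + loading * a + N(0, noise_sd^2)` (floored at
#' zero), other genes are pure noise around the baseline. Survival times are
#' exponential with hazard `baseline_hazard * exp(beta_true * a)`;
#' independent exponential censoring is calibrated so the expected censored
#' fraction equals `censor_rate`.
#'
#' @param n_samples number of samples (default 500).
#' @param n_genes total genes (default 200).
#' @param n_signature number of activity-loaded signature genes (default 20).
#' @param loading expression units per unit activity (default 1).
#' @param baseline_mean baseline expression level (default 8).
#' @param noise_sd residual expression noise (default 1).
#' @param beta_true log hazard ratio per unit activity (default 0.7).
#' @param baseline_hazard exponential baseline hazard (default 0.1).
#' @param censor_rate target censored fraction in `[0, 1)` (default 0.3).
#' @param seed global seed.
#' @return list of class `BulkSimConfig`.
#' @export
bulk_sim_config <- function(n_samples = 500, n_genes = 200,
                            n_signature = 20, loading = 1,
                            baseline_mean = 8, noise_sd = 1,
                            beta_true = 0.7, baseline_hazard = 0.1,
                            censor_rate = 0.3, seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= n_signature, n_signature >= 1,
            censor_rate >= 0, censor_rate < 1, baseline_hazard > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "BulkSimConfig")
}

#' Simulate a bulk cohort with survival driven by a latent activity
#'
#' See [bulk_sim_config()]. The censoring rate is calibrated analytically:
#' given the realized activities, the censoring hazard `lambda_c` solves
#' `mean(lambda_c / (lambda_c + h_i)) = censor_rate` where
#' `h_i = baseline_hazard * exp(beta_true * a_i)`.
#'
#' @param config a [bulk_sim_config()].
#' @return list with `matrix` (`ExpressionMatrix`, lognorm layer, genes
#'   `BG0001...`, signature genes first), `clinical` (data.frame `sample_id`,
#'   `time`, `event`), `truth` (data.frame `sample_id`, `activity`,
#'   `linear_predictor`), `signature` (the loaded [gene_set()]), `config`.
#' @export
simulate_bulk <- function(config = bulk_sim_config()) {
  stopifnot(inherits(config, "BulkSimConfig"))
  set.seed(stage_seed(config$seed, "bulk"))
  n <- config$n_samples
  p <- config$n_genes
  gene_ids <- sprintf("BG%04d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  sig_idx <- seq_len(config$n_signature)
  a <- stats::rnorm(n)
  x <- matrix(stats::rnorm(p * n, config$baseline_mean, config$noise_sd),
              p, n)
  x[sig_idx, ] <- x[sig_idx, ] + config$loading * rep(a, each = length(sig_idx))
  x <- pmax(x, 0)
  hz <- config$baseline_hazard * exp(config$beta_true * a)
  tt <- stats::rexp(n, rate = hz)
  if (config$censor_rate > 0) {
    f <- function(lc) mean(lc / (lc + hz)) - config$censor_rate
    lam_c <- stats::uniroot(f, lower = 1e-10, upper = 1e6,
                            tol = 1e-12)$root
    cens <- stats::rexp(n, rate = lam_c)
    event <- as.integer(tt <= cens)
    time <- pmin(tt, cens)
  } else {
    event <- rep(1L, n)
    time <- tt
  }
  list(matrix = expression_matrix(x, gene_ids, sample_ids,
                                  layer = "lognorm",
                                  dataset_id = "bulk_sim"),
       clinical = data.frame(sample_id = sample_ids, time = time,
                             event = event, stringsAsFactors = FALSE),
       truth = data.frame(sample_id = sample_ids, activity = a,
                          linear_predictor = config$beta_true * a,
                          stringsAsFactors = FALSE),
       signature = gene_set("BULK.SIGNATURE", gene_ids[sig_idx]),
       config = config)
}
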