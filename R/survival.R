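#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with the Breslow (default) or Efron
#' treatment of tied event times. Iteration stops when successive
#' log-likelihoods differ by less than `tol` (default 1e-9) or after
#' `max_iter` iterations; a divergence guard aborts when any coefficient
#' exceeds 50 in magnitude, which signals a monotone likelihood (perfect
#' separation).
#'
#' @param records data.frame with columns `time` (> 0), `event` (0/1) and the
#'   covariate columns named in `covariate_names`; at least 10 events.
#' @param covariate_names character vector of covariate columns to include.
#' @param ties `"breslow"` or `"efron"`.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `CoxModel`: `coef` (named), `loglik`, `loglik_null`,
#'   `converged`, `n`, `n_events`, `iter`, `ties`.
#' @export
cox_fit <- function(records, covariate_names, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 100) {
  ties <- match.arg(ties)
  miss <- setdiff(c("time", "event", covariate_names), colnames(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(records[, covariate_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing covariate values are not supported")
  time <- records$time
  event <- records$event
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 10)
    stop("need >= 10 events, got ", sum(event))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate(s): ",
         paste(covariate_names[sds == 0], collapse = ", "))
  n <- nrow(X); d <- ncol(X)
  ev_times <- sort(unique(time[event == 1]))
  # risk sets / tied-death blocks precomputed once
  risk_idx <- lapply(ev_times, function(t) which(time >= t))
  death_idx <- lapply(ev_times, function(t) which(time == t & event == 1))

  loglik_grad_hess <- function(beta, want_derivs = TRUE) {
    eta <- as.numeric(X %*% beta)
    w <- exp(eta)
    ll <- 0
    g <- numeric(d)
    H <- matrix(0, d, d)
    for (k in seq_along(ev_times)) {
      rs <- risk_idx[[k]]; ds <- death_idx[[k]]
      m <- length(ds)
      wr <- w[rs]; Xr <- X[rs, , drop = FALSE]
      S0 <- sum(wr)
      S1 <- colSums(Xr * wr)
      sum_eta_d <- sum(eta[ds])
      sum_x_d <- colSums(X[ds, , drop = FALSE])
      if (ties == "breslow") {
        ll <- ll + sum_eta_d - m * log(S0)
        if (want_derivs) {
          S2 <- crossprod(Xr, Xr * wr)
          mu <- S1 / S0
          g <- g + sum_x_d - m * mu
          H <- H + m * (S2 / S0 - tcrossprod(mu))
        }
      } else {
        wd <- w[ds]; Xd <- X[ds, , drop = FALSE]
        S0d <- sum(wd)
        S1d <- colSums(Xd * wd)
        if (want_derivs) {
          S2 <- crossprod(Xr, Xr * wr)
          S2d <- crossprod(Xd, Xd * wd)
        }
        ll <- ll + sum_eta_d
        g_add <- sum_x_d
        for (l in seq_len(m) - 1) {
          f <- l / m
          S0l <- S0 - f * S0d
          ll <- ll - log(S0l)
          if (want_derivs) {
            S1l <- S1 - f * S1d
            mu <- S1l / S0l
            g_add <- g_add - mu
            H <- H + (S2 - f * S2d) / S0l - tcrossprod(mu)
          }
        }
        if (want_derivs) g <- g + g_add
      }
    }
    list(ll = ll, g = g, H = H)
  }

  beta <- numeric(d)
  ll0 <- loglik_grad_hess(beta, want_derivs = FALSE)$ll
  cur <- loglik_grad_hess(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$H, cur$g), error = function(e)
      stop("singular information matrix at iteration ", iter))
    new_beta <- beta + step
    halvings <- 0
    nxt <- loglik_grad_hess(new_beta)
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- loglik_grad_hess(new_beta)
      halvings <- halvings + 1
    }
    if (any(abs(new_beta) > 50))
      stop("divergence guard: |beta| > 50 -- monotone likelihood ",
           "(perfect separation?)")
    delta <- abs(nxt$ll - cur$ll)
    beta <- new_beta
    cur <- nxt
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("cox_fit did not converge in ", max_iter, " iterations")
  # a separated fit flattens the likelihood while a coefficient runs off:
  # |beta| > 20 (hazard ratio beyond e^20) is never identifiable
  if (any(abs(beta) > 20))
    stop("monotone likelihood (perfect separation?): coefficient ",
         covariate_names[which.max(abs(beta))], " diverged to ",
         format(beta[which.max(abs(beta))], digits = 4))
  names(beta) <- covariate_names
  structure(list(coef = beta, loglik = cur$ll, loglik_null = ll0,
                 converged = converged, n = n,
                 n_events = as.integer(sum(event)), iter = iter,
                 ties = ties),
            class = "CoxModel")
}

#' @export
print.CoxModel <- function(x, ...) {
  cat(sprintf("CoxModel (%s ties): n=%d, events=%d, loglik=%.4f%s\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coef, 4))
  invisible(x)
}

#' Cox partial log-likelihood for a given coefficient vector
#'
#' Exposed so callers (and tests) can evaluate the exact objective that
#' [cox_fit()] maximizes.
#'
#' @inheritParams cox_fit
#' @param beta coefficient vector (same order as `covariate_names`).
#' @return single numeric log partial likelihood.
#' @export
cox_loglik <- function(records, covariate_names, beta,
                       ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(records[, covariate_names, drop = FALSE])
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  time <- records$time; event <- records$event
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    rs <- time >= t
    ds <- time == t & event == 1
    m <- sum(ds)
    ll <- ll + sum(eta[ds])
    if (ties == "breslow") {
      ll <- ll - m * log(sum(w[rs]))
    } else {
      S0 <- sum(w[rs]); S0d <- sum(w[ds])
      for (l in seq_len(m) - 1) ll <- ll - log(S0 - l / m * S0d)
    }
  }
  ll
}

#' Linear risk score from Cox coefficients
#'
#' `score_j = sum_g beta_g * z_gj` over the model's genes, where `z` is the
#' per-gene z-scored expression across the cohort (the default reading of
#' "normalized expression"; set `zscore = FALSE` to use the matrix values
#' directly).
#'
#' @param expr `ExpressionMatrix` of bulk samples (genes x samples).
#' @param model a `CoxModel` (or named coefficient vector) whose names are
#'   gene IDs present in `expr`.
#' @param zscore z-score each gene across the cohort first (default `TRUE`).
#' @return data.frame `sample_id`, `score`.
#' @export
risk_score <- function(expr, model, zscore = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  beta <- if (inherits(model, "CoxModel")) model$coef else model
  if (is.null(names(beta))) stop("coefficients must be named by gene")
  missing_genes <- setdiff(names(beta), expr$gene_ids)
  if (length(missing_genes))
    stop("model gene(s) absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  x <- em_values(em_subset(expr, genes = names(beta)))
  if (zscore) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    if (any(sdv == 0))
      stop("zero-variance gene(s) cannot be z-scored: ",
           paste(names(beta)[sdv == 0], collapse = ", "))
    x <- (x - mu) / sdv
  }
  data.frame(sample_id = expr$obs_ids,
             score = as.numeric(crossprod(x, beta)),
             stringsAsFactors = FALSE)
}

#' Median dichotomization of risk scores
#'
#' Splits samples at the median risk score: `high` iff score > median, ties
#' at the median go to `low`. Same contract as [median_split()].
#'
#' @param scores data.frame from [risk_score()] or a named numeric vector.
#' @return data.frame `sample_id`, `score`, `group` (`"high"`/`"low"`) with
#'   attribute `"threshold"`.
#' @export
dichotomize <- function(scores) {
  s <- if (is.data.frame(scores)) {
    stats::setNames(scores$score, scores$sample_id)
  } else scores
  sp <- median_split(s)
  out <- data.frame(sample_id = sp$obs_id, score = sp$score,
                    group = ifelse(sp$label == "HS", "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- attr(sp, "threshold")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Delegates to [survival::survfit()] (which applies the standard convention
#' that events precede censorings at tied times) and returns the curve as a
#' plain table.
#'
#' @param records data.frame with `time`, `event` (and `sample_id`).
#' @param group optional vector (or single column name in `records`) of group
#'   labels; one curve per group.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(records, group = NULL) {
  if (nrow(records) < 1) stop("need >= 1 record")
  if (is.character(group) && length(group) == 1 && group %in% colnames(records))
    group <- records[[group]]
  if (is.null(group)) group <- rep("all", nrow(records))
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ grp,
    data = data.frame(grp = group))
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(unique(group)[1], length(smry$time))
         else sub("^grp=", "", as.character(smry$strata))
  data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, n_censor = smry$n.censor,
             survival = smry$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(sum O1 - sum E1)^2 / sum V` with hypergeometric
#' variance at each distinct event time (delegates to
#' [survival::survdiff()]); p-value from chi-square with 1 degree of freedom.
#'
#' @param records data.frame with `time`, `event`.
#' @param groups vector of exactly two group labels, one per record; each
#'   group must be non-empty and contain at least one event.
#' @return list of class `LogRankResult`: `chi_square`, `p`, `table`
#'   (per-group n, observed, expected).
#' @export
logrank_test <- function(records, groups) {
  if (length(groups) != nrow(records))
    stop("groups length must match records")
  lv <- unique(groups)
  if (length(lv) != 2)
    stop("logrank_test needs exactly 2 groups, got ", length(lv))
  for (g in lv) {
    if (sum(groups == g) == 0) stop("group '", g, "' has no records")
    if (sum(records$event[groups == g]) == 0)
      stop("group '", g, "' has no events")
  }
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ grp,
    data = data.frame(grp = groups))
  tab <- data.frame(group = sub("^grp=", "", rownames(as.matrix(sd$n))),
                    n = as.numeric(sd$n),
                    observed = as.numeric(sd$obs),
                    expected = as.numeric(sd$exp),
                    stringsAsFactors = FALSE)
  structure(list(chi_square = as.numeric(sd$chisq),
                 p = stats::pchisq(as.numeric(sd$chisq), df = 1,
                                   lower.tail = FALSE),
                 table = tab),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4f, p = %.4g\n", x$chi_square, x$p))
  print(x$table)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the sample with the higher risk score
#' has the shorter survival; score ties count 0.5. A pair is usable when the
#' shorter time belongs to an event (and the times differ).
#'
#' @param records data.frame with `time`, `event`, rows aligned with `scores`.
#' @param scores numeric risk scores, one per record.
#' @return single numeric C-index in `[0, 1]`.
#' @export
concordance_index <- function(records, scores) {
  if (length(scores) != nrow(records))
    stop("scores length must match records")
  time <- records$time; event <- records$event
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    later <- which(time > time[i])
    if (!length(later)) next
    den <- den + length(later)
    num <- num + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
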