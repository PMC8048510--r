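#' Fit expression predictors for a probe across tissues
#'
#' Dispatcher over the four methods.  Single-task methods (`lasso`,
#' `ridge`, `elastic_net`, `rf`) fit one model per tissue; multi-task
#' methods (`joint_lasso`, `rf_mtl`) fit a single model serving every
#' tissue.  The returned set records how many models were fitted, which
#' matters for multiple-testing accounting downstream.
#'
#' @param expression Matrix, tissues x individuals (rownames = tissue
#'   labels).
#' @param geno A `genotype_matrix` for the same individuals.
#' @param spec A [model_spec()].
#' @return Object of class `mttwas_model_set`: list with `models` (list
#'   of `mttwas_fit`), `tissues`, `method`, `n_models`.
#' @export
fit_panel <- function(expression, geno, spec = model_spec("lasso")) {
  Y <- rbind(expression)
  tissues <- rownames(Y)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(nrow(Y)))
  rownames(Y) <- tissues
  models <- if (is_mtl_method(spec$method)) {
    fit <- if (spec$method == "joint_lasso") fit_joint_lasso(Y, geno, spec)
           else fit_rf_mtl(Y, geno, spec)
    list(fit)
  } else {
    lapply(seq_along(tissues), function(g) {
      if (spec$method == "rf") fit_rf(geno, Y[g, ], spec, tissue = tissues[g])
      else fit_linear_stl(geno, Y[g, ], spec, tissue = tissues[g])
    })
  }
  structure(list(models = models, tissues = tissues, method = spec$method,
                 n_models = length(models)),
            class = "mttwas_model_set")
}

model_for_tissue <- function(set, tissue) {
  for (m in set$models) if (tissue %in% m$tissues) return(m)
  stop("no model for tissue ", tissue)
}

#' Linear-regression TWAS association test
#'
#' Regresses a quantitative GWAS trait on predicted expression and
#' returns the two-sided slope t-test p-value.  A constant prediction
#' vector cannot be tested: it yields `p = 1` with `flagged = TRUE`.
#'
#' @param pred_expr Predicted expression in the GWAS samples.
#' @param trait Quantitative GWAS trait.
#' @return List with `p`, `slope`, `flagged`.
#' @export
twas_linear_test <- function(pred_expr, trait) {
  if (length(pred_expr) != length(trait)) stop("input error: length mismatch")
  n <- length(trait)
  if (n < 3L) stop("need at least 3 samples")
  if (stats::sd(pred_expr) == 0)
    return(list(p = 1, slope = 0, flagged = TRUE))
  fit <- stats::lm.fit(cbind(1, pred_expr), trait)
  rss <- sum(fit$residuals^2)
  sxx <- sum((pred_expr - mean(pred_expr))^2)
  slope <- unname(fit$coefficients[2L])
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(p = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE),
       slope = slope, flagged = FALSE)
}

#' Stratified Cochran-Armitage trend test with continuous scores
#'
#' Trend test of case/control status against an arbitrary score (here,
#' predicted expression), stratified a la Mantel: within each stratum
#' the score statistic is \eqn{U_s = \sum_{cases}(x_i - \bar x_s)} and
#' its permutation (randomization) variance
#' \eqn{V_s = n_{1s} n_{0s} \sum_i (x_i - \bar x_s)^2 / (n_s (n_s - 1))};
#' the strata are combined as \eqn{Z = \sum_s U_s / \sqrt{\sum_s V_s}}
#' and referred to a standard normal, two-sided.  With a single stratum
#' this is the usual trend test; the variance convention matches the
#' permutation null exactly (verified against a permutation oracle in
#' the package tests).
#'
#' @param score Numeric score vector (e.g. predicted expression).
#' @param status Binary case indicator (0/1 or logical).
#' @param stratum Stratum label per sample (default: one stratum).
#' @return List with `p`, `statistic` (Z), `effect` (difference in mean
#'   score, cases minus controls, pooled over strata), `n_strata_used`.
#' @export
cochran_armitage_mantel <- function(score, status,
                                    stratum = rep(1L, length(score))) {
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be binary 0/1")
  if (length(score) != length(status) || length(score) != length(stratum))
    stop("input error: length mismatch")
  U <- 0; V <- 0; used <- 0L
  for (s in unique(stratum)) {
    idx <- stratum == s
    x <- score[idx]; y <- status[idx]
    n <- length(x); n1 <- sum(y); n0 <- n - n1
    if (n1 == 0L || n0 == 0L) {
      warning("stratum ", s, " has no cases or no controls; dropped")
      next
    }
    xc <- x - mean(x)
    U <- U + sum(xc[y == 1L])
    V <- V + n1 * n0 * sum(xc^2) / (n * (n - 1))
    used <- used + 1L
  }
  if (used == 0L) stop("no usable strata")
  if (V == 0) return(list(p = 1, statistic = 0, effect = 0,
                          n_strata_used = used))
  z <- U / sqrt(V)
  eff <- mean(score[status == 1L]) - mean(score[status == 0L])
  list(p = 2 * stats::pnorm(abs(z), lower.tail = FALSE), statistic = z,
       effect = eff, n_strata_used = used)
}

#' Benjamini-Hochberg adjustment over a fixed total number of models
#'
#' Step-up FDR adjustment where the denominator ranks are computed as if
#' `m_total` tests had been performed.  Models that were fitted but not
#' tested (e.g. null lasso models with no nonzero coefficients) count
#' towards `m_total` even though they contribute no p-value, which keeps
#' sparse linear methods comparable with methods that always produce a
#' testable model.
#'
#' @param pvals Observed p-values.
#' @param m_total Total number of fitted models, at least `length(pvals)`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals, m_total = length(pvals)) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("input error: p-values outside [0, 1]")
  m <- length(pvals)
  if (m_total < m) stop("m_total must be >= length(pvals)")
  o <- order(pvals)
  ranked <- pvals[o] * m_total / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Run a two-stage TWAS over fitted models
#'
#' For each probe and tissue: predict expression into the GWAS samples
#' with the fitted model and test the association between predicted
#' expression and the GWAS trait — linear regression for a quantitative
#' trait, or the stratified trend test for binary status.  P-values are
#' BH-adjusted separately per tissue (and per method), with the total
#' number of fitted models (null models included) as the denominator.
#'
#' @param model_sets Named list (by probe) of `mttwas_model_set` objects
#'   fitted on the eQTL data, all with the same method.
#' @param geno_gwas `genotype_matrix` of the GWAS samples.
#' @param trait GWAS trait: numeric (quantitative) or binary 0/1.
#' @param stratum Optional stratum labels for the binary design.
#' @return Data frame of class `twas_result`: probe, tissue, method, p,
#'   effect, p_adj, null flag, n_total_models.
#' @export
run_twas <- function(model_sets, geno_gwas, trait,
                     stratum = NULL) {
  if (inherits(model_sets, "mttwas_model_set"))
    model_sets <- list(probe1 = model_sets)
  binary <- all(trait %in% c(0, 1)) && length(unique(trait)) == 2L
  rows <- list()
  for (probe in names(model_sets)) {
    set <- model_sets[[probe]]
    for (tissue in set$tissues) {
      model <- model_for_tissue(set, tissue)
      pred <- tryCatch(predict(model, geno_gwas, tissue = tissue),
                       error = function(e) NULL)
      if (is.null(pred)) next  # probe dropped, e.g. no shared SNPs
      is_null <- isTRUE(attr(pred, "null"))
      if (is_null) {
        p <- NA_real_; eff <- NA_real_
      } else if (binary) {
        tst <- cochran_armitage_mantel(
          pred, trait,
          if (is.null(stratum)) rep(1L, length(trait)) else stratum)
        p <- tst$p; eff <- tst$effect
      } else {
        tst <- twas_linear_test(pred, trait)
        p <- if (tst$flagged) NA_real_ else tst$p
        eff <- tst$slope
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe = probe, tissue = tissue, method = set$method,
        p = p, effect = eff, null = is_null || is.na(p),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(structure(data.frame(), class = c("twas_result",
                                                             "data.frame")))
  res$p_adj <- NA_real_
  res$n_total_models <- NA_integer_
  for (tissue in unique(res$tissue)) {
    sel <- res$tissue == tissue
    m_total <- sum(sel)  # every fitted model for this tissue, incl. null
    tested <- sel & !is.na(res$p)
    res$p_adj[tested] <- bh_adjust(res$p[tested], m_total = m_total)
    res$n_total_models[sel] <- m_total
  }
  structure(res, class = c("twas_result", "data.frame"))
}
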