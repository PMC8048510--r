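#' Out-of-sample R-squared
#'
#' `1 - sum((y - pred)^2) / sum((y - mean(y))^2)`: the improvement of a
#' predictor over the constant mean model.  Unbounded below — a model
#' worse than the mean yields a negative value.
#'
#' @param y Observed values (non-constant).
#' @param pred Predictions.
#' @return Numeric scalar (may be negative); `NA` with a warning when
#'   `y` is constant.
#' @export
r_squared <- function(y, pred) {
  if (length(y) != length(pred)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  ss <- sum((y - mean(y))^2)
  if (ss == 0) {
    warning("constant y: R-squared undefined")
    return(NA_real_)
  }
  1 - sum((y - pred)^2) / ss
}

#' Advantage of one method over another
#'
#' Method 1 has an advantage over method 2 on a regression if its
#' R-squared is positive and strictly larger; the advantage is
#' `r2_m1 - max(0, r2_m2)` and is undefined (`NA`) otherwise.
#'
#' @param r2_m1,r2_m2 R-squared values of the two methods on the same
#'   test data.
#' @return Numeric scalar, or `NA` when undefined.
#' @export
advantage <- function(r2_m1, r2_m2) {
  if (is.na(r2_m1) || is.na(r2_m2)) return(NA_real_)
  if (r2_m1 <= 0 || r2_m1 <= r2_m2) return(NA_real_)
  r2_m1 - max(0, r2_m2)
}

#' Mean advantage over a set of regression problems
#'
#' Averages the defined advantage values only, i.e. over the problems
#' where method 1 actually outperforms method 2.
#'
#' @param r2_m1,r2_m2 Vectors of R-squared values (paired).
#' @return List with `mean_advantage` (`NA` if no problem has a defined
#'   advantage), `n_defined`.
#' @export
mean_advantage <- function(r2_m1, r2_m2) {
  adv <- mapply(advantage, r2_m1, r2_m2)
  def <- !is.na(adv)
  list(mean_advantage = if (any(def)) mean(adv[def]) else NA_real_,
       n_defined = sum(def))
}

#' Train/test split grouped by individual
#'
#' Partitions individuals (not sample rows) into a training and a test
#' set so that all rows belonging to one individual fall on the same
#' side.
#'
#' @param ids Individual id per sample row.
#' @param train_fraction Fraction of individuals assigned to training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `test`.
#' @export
grouped_split <- function(ids, train_fraction = 0.7, seed = 1L) {
  if (!length(ids)) stop("ids must be non-empty")
  set.seed(as.integer(seed))
  uid <- unique(ids)
  n_train <- round(train_fraction * length(uid))
  train_ids <- sample(uid, n_train)
  list(train = which(ids %in% train_ids),
       test = which(!ids %in% train_ids))
}

#' Probe eligibility by univariate cis-signal strength
#'
#' A probe enters the analysis only if at least one tissue has a
#' cis-SNP with univariate p-value strictly below the threshold.
#'
#' @param pvals Matrix (tissues x SNPs) or vector of scan p-values.
#' @param threshold Eligibility threshold, default `1e-7`.
#' @return Logical.
#' @export
probe_eligibility <- function(pvals, threshold = 1e-7) {
  min(as.numeric(pvals), na.rm = TRUE) < threshold
}

#' Run the causal-scenario power grid
#'
#' For every scenario cell and replicate: simulate a retained eQTL +
#' GWAS data-set pair from the haplotype pool, fit each requested
#' prediction method on the eQTL expression panel, predict the test
#' tissue's expression into the GWAS samples, test the association by
#' linear regression, and (for TWAS-significant replicates at
#' `sig_threshold`) apply the proportionality filter.  All methods see
#' the same simulated data within a replicate, so between-method
#' comparisons are paired.
#'
#' @param pool A `haplotype_pool` (one region, reused across
#'   replicates).
#' @param cells Character vector of scenario ids (default all six).
#' @param methods Methods to run (default all four main ones).
#' @param n_reps Replicates per cell.
#' @param n_ind Individuals per simulated data set (default 400).
#' @param n_background Background expression traits (default 4).
#' @param sig_threshold TWAS p threshold (0.05).
#' @param pf_threshold Proportionality filter threshold (0.05).
#' @param max_retries Retention retry budget per replicate.
#' @param seed Integer master seed; every replicate derives its own.
#' @param specs Optional named list of [model_spec()] overrides per
#'   method.
#' @param progress Print one line per cell.
#' @return List with `records` (one row per cell x replicate x method:
#'   p, reject, p_f, filtered_reject, retries) and `power_table`
#'   (per cell x method: proportion rejecting, proportion surviving the
#'   filter, n).
#' @export
run_scenario_grid <- function(pool, cells = scenario_grid()$scenario_id,
                              methods = c("lasso", "joint_lasso", "rf",
                                          "rf_mtl"),
                              n_reps = 100L, n_ind = 400L,
                              n_background = 4L,
                              sig_threshold = 0.05, pf_threshold = 0.05,
                              max_retries = 400L, seed = 1L,
                              specs = NULL, progress = FALSE) {
  seed <- as.integer(seed)
  records <- list()
  for (cell in cells) {
    if (progress) message("cell ", cell)
    for (r in seq_len(n_reps)) {
      rep_seed <- (seed + 104729L * match(cell, scenario_grid()$scenario_id)
                   + 1299709L * r) %% 2147483587L
      sim <- simulate_dataset(pool, cell, n_ind = n_ind,
                              n_background = n_background,
                              max_retries = max_retries, seed = rep_seed)
      expr <- sim$traits$expression
      rownames(expr) <- c("test", paste0("bg", seq_len(n_background)))
      for (method in methods) {
        spec <- if (!is.null(specs[[method]])) specs[[method]]
                else model_spec(method)
        spec$seed <- rep_seed
        fit <- if (method == "joint_lasso") {
          fit_joint_lasso(expr, sim$geno_eqtl, spec)
        } else if (method == "rf_mtl") {
          fit_rf_mtl(expr, sim$geno_eqtl, spec)
        } else if (method == "rf") {
          fit_rf(sim$geno_eqtl, expr["test", ], spec, tissue = "test")
        } else {
          fit_linear_stl(sim$geno_eqtl, expr["test", ], spec,
                         tissue = "test")
        }
        pred <- predict(fit, sim$geno_gwas, tissue = "test")
        is_null <- isTRUE(attr(pred, "null"))
        tst <- if (is_null) list(p = NA_real_, flagged = TRUE)
               else twas_linear_test(pred, sim$traits$gwas_trait)
        reject <- !is.na(tst$p) && tst$p < sig_threshold
        p_f <- NA_real_; filtered_reject <- FALSE
        if (reject) {
          cr <- coloc_filter_one(sim$geno_eqtl, sim$geno_gwas,
                                 expr["test", ], sim$traits$gwas_trait,
                                 pass_threshold = pf_threshold)
          p_f <- cr$p_f
          filtered_reject <- isTRUE(cr$pass)  # still a hit after filtering
        }
        records[[length(records) + 1L]] <- data.frame(
          cell = cell, replicate = r, method = method,
          p = tst$p, reject = reject, p_f = p_f,
          filtered_reject = filtered_reject, null_model = is_null,
          retries = sim$retries, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  power_table <- stats::aggregate(
    cbind(reject, filtered_reject) ~ cell + method, data = records, FUN = mean)
  names(power_table)[3:4] <- c("prop_rejected", "prop_filtered_rejected")
  power_table$n <- n_reps
  grid <- scenario_grid()
  power_table <- merge(grid, power_table, by.x = "scenario_id",
                       by.y = "cell")
  list(records = records, power_table = power_table)
}
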