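#' Specify an expression prediction model
#'
#' Collects the method tag and tuning setup for the four predictor
#' families: single-task penalized regressions (`lasso`, `ridge`,
#' `elastic_net`), the multi-task L2-fusion joint lasso (`joint_lasso`),
#' and regression forests (`rf` single-task, `rf_mtl` multi-task over a
#' stacked design with a tissue identifier).
#'
#' @param method One of `"lasso"`, `"ridge"`, `"elastic_net"`,
#'   `"joint_lasso"`, `"rf"`, `"rf_mtl"`.
#' @param alpha Elastic-net mixing parameter; forced to 1 for lasso and
#'   0 for ridge, default 0.5 for `elastic_net`.
#' @param lambda Optional fixed penalty; `NULL` (default) tunes by
#'   internal cross-validation.
#' @param gamma_grid Fusion-parameter candidates for the joint lasso
#'   (external CV); default `{0} + 7` geometric points spanning
#'   `1e-3 .. 1e2`.
#' @param tau Optional fixed tissue-pair penalty matrix; default is
#'   estimated from expression correlations (see
#'   [tissue_penalty_matrix()]).
#' @param n_lambda,lambda_min_ratio Penalty path for the joint-lasso
#'   solver: geometric grid of `n_lambda` values from the smallest
#'   null-model penalty down to `lambda_min_ratio` times it.
#' @param n_trees Number of trees (default 500).
#' @param min_node_size Minimum terminal node size (default 5).
#' @param mtry_fraction Fraction of SNPs considered at each split
#'   (default 1/3); the tissue identifier in `rf_mtl` is always a
#'   candidate on top of these.
#' @param cv_folds_internal Folds of the internal lambda CV (default 10).
#' @param cv_folds_external Folds of the external gamma CV (default 5).
#' @param seed Integer seed used for fold assignment and forests.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("lasso", "ridge", "elastic_net",
                                  "joint_lasso", "rf", "rf_mtl"),
                       alpha = NULL, lambda = NULL,
                       gamma_grid = c(0, 10^seq(-3, 2, length.out = 7)),
                       tau = NULL,
                       n_lambda = 100L, lambda_min_ratio = 1e-3,
                       n_trees = 500L, min_node_size = 5L,
                       mtry_fraction = 1 / 3,
                       cv_folds_internal = 10L, cv_folds_external = 5L,
                       seed = 1L) {
  method <- match.arg(method)
  alpha <- switch(method,
                  lasso = 1, ridge = 0, joint_lasso = 1,
                  elastic_net = if (is.null(alpha)) 0.5 else alpha,
                  alpha)
  if (!is.null(alpha) && (alpha < 0 || alpha > 1))
    stop("alpha must lie in [0, 1]")
  if (any(gamma_grid < 0)) stop("gamma_grid must be non-negative")
  structure(list(method = method, alpha = alpha, lambda = lambda,
                 gamma_grid = sort(unique(gamma_grid)), tau = tau,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 mtry_fraction = mtry_fraction,
                 cv_folds_internal = as.integer(cv_folds_internal),
                 cv_folds_external = as.integer(cv_folds_external),
                 seed = as.integer(seed)),
            class = "model_spec")
}

is_mtl_method <- function(method) method %in% c("joint_lasso", "rf_mtl")

#' Standardize expression for single-task model fitting
#'
#' Each tissue's expression vector is scaled to mean 0 and (sample)
#' variance 1; the constants are returned so predictions can be mapped
#' back to the original scale.
#'
#' @param expression Matrix, tissues x samples (a single tissue may be
#'   given as a vector).
#' @return List with `values` (standardized matrix), `center`, `scale`.
#' @export
preprocess_stl <- function(expression) {
  x <- rbind(expression)
  if (ncol(x) < 2L) stop("need at least 2 samples per tissue")
  ctr <- rowMeans(x)
  scl <- apply(x, 1L, stats::sd)
  if (any(scl == 0)) stop("preprocessing error: zero-variance expression")
  list(values = (x - ctr) / scl, center = ctr, scale = scl)
}

#' Center expression for multi-task model fitting
#'
#' Each tissue's expression is centered to mean 0 but deliberately not
#' rescaled, so between-tissue differences in expression variance remain
#' visible to the multi-task learners.
#'
#' @inheritParams preprocess_stl
#' @return List with `values` (centered matrix), `center`, `scale`
#'   (all 1).
#' @export
preprocess_mtl <- function(expression) {
  x <- rbind(expression)
  if (ncol(x) < 2L) stop("need at least 2 samples per tissue")
  ctr <- rowMeans(x)
  list(values = x - ctr, center = ctr, scale = rep(1, nrow(x)))
}

#' Tissue-pair fusion penalty matrix from expression correlations
#'
#' Sets the pair penalty to the between-tissue expression correlation
#' divided by the largest off-diagonal correlation, so the most similar
#' pair always receives penalty 1.  Negative correlations are clipped to
#' zero (a negative fusion weight would reward divergence).  If no pair
#' has an estimable positive correlation the matrix falls back to uniform
#' penalties of 1, which has been a serviceable default for this model
#' family.
#'
#' @param expression Matrix, tissues x samples, over shared individuals
#'   (`NA`s allowed; pairs use complete observations).
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   maximum off-diagonal entry 1; attribute `fallback` marks pairs (or
#'   the whole matrix) set by the uniform fallback.
#' @export
tissue_penalty_matrix <- function(expression) {
  x <- rbind(expression)
  G <- nrow(x)
  if (G < 2L) stop("need at least 2 tissues")
  rho <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  n_pair <- tcrossprod(!is.na(x) * 1)
  bad <- n_pair < 2L | is.na(rho)
  diag(bad) <- FALSE
  rho[bad] <- NA
  off <- rho; diag(off) <- NA
  rho_pos <- pmax(off, 0)
  mx <- suppressWarnings(max(rho_pos, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    tau <- matrix(1, G, G)
    attr(tau, "fallback") <- matrix(TRUE, G, G)
  } else {
    tau <- rho_pos / mx
    fb <- is.na(tau)
    tau[fb] <- 1
    attr(tau, "fallback") <- fb
  }
  diag(tau) <- 0
  dimnames(tau) <- list(rownames(x), rownames(x))
  tau
}
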