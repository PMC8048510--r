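dosage_matrix <- function(geno) {
  if (inherits(geno, "genotype_matrix")) {
    m <- geno$dosages
    colnames(m) <- geno$snp_ids
    m
  } else as.matrix(geno)
}

#' Cross-validation fold ids grouped by individual
#'
#' Assigns every sample row of an individual to the same fold, so that no
#' individual straddles a train/validation boundary.
#'
#' @param ids Individual id per sample row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
grouped_folds <- function(ids, k, seed = 1L) {
  set.seed(as.integer(seed))
  uid <- unique(ids)
  if (k > length(uid)) stop("more folds than individuals")
  fold_of <- sample(rep_len(seq_len(k), length(uid)))
  names(fold_of) <- uid
  unname(fold_of[as.character(ids)])
}

new_mttwas_fit <- function(method, spec, tissues, snp_ids, snp_means,
                           center, scale, beta = NULL, intercept = NULL,
                           null = NULL, forest = NULL, lambda = NULL,
                           gamma = NULL, tau = NULL) {
  structure(list(method = method, spec = spec, tissues = tissues,
                 snp_ids = snp_ids, snp_means = snp_means,
                 center = center, scale = scale, beta = beta,
                 intercept = intercept, null = null, forest = forest,
                 lambda = lambda, gamma = gamma, tau = tau),
            class = "mttwas_fit")
}

#' @export
print.mttwas_fit <- function(x, ...) {
  cat(sprintf("<mttwas_fit> method=%s, tissues=%s, %d SNPs%s\n",
              x$method, paste(x$tissues, collapse = ","),
              length(x$snp_ids),
              if (!is.null(x$null) && all(x$null)) " [null model]" else ""))
  invisible(x)
}

#' Fit a single-tissue penalized linear predictor
#'
#' Elastic-net family fit via coordinate descent (`glmnet`), with the
#' penalty chosen by internal k-fold cross-validation on a
#' lambda path derived from a master fit on all the data
#' (minimum-CV-error rule).  Expression is standardized to mean 0,
#' variance 1 before fitting and mapped back at prediction time.  A model
#' whose selected penalty zeroes every coefficient is legal and flagged
#' as null.
#'
#' @param geno A `genotype_matrix` (or dosage matrix) for the training
#'   individuals.
#' @param y Expression vector for one tissue.
#' @param spec A [model_spec()] with method `lasso`, `ridge` or
#'   `elastic_net`.
#' @param tissue Tissue label stored with the model.
#' @return An object of class `mttwas_fit`.
#' @export
fit_linear_stl <- function(geno, y, spec = model_spec("lasso"),
                           tissue = "tissue1") {
  X <- dosage_matrix(geno)
  if (nrow(X) != length(y)) stop("genotype/expression size mismatch")
  prep <- preprocess_stl(y)
  ys <- as.vector(prep$values)
  set.seed(spec$seed)
  if (is.null(spec$lambda)) {
    ids <- if (inherits(geno, "genotype_matrix")) geno$individual_ids
           else seq_len(nrow(X))
    foldid <- grouped_folds(ids, spec$cv_folds_internal, seed = spec$seed)
    cvfit <- glmnet::cv.glmnet(X, ys, alpha = spec$alpha, foldid = foldid,
                               standardize = TRUE)
    lam <- cvfit$lambda.min
    co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  } else {
    # fixed penalty: fit a path down to it for warm-start stability
    fit <- glmnet::glmnet(X, ys, alpha = spec$alpha, standardize = TRUE,
                          lambda.min.ratio = 1e-4)
    lam <- spec$lambda
    co <- as.matrix(stats::coef(fit, s = lam, exact = TRUE, x = X, y = ys,
                                alpha = spec$alpha, standardize = TRUE))
  }
  beta <- matrix(co[-1L, 1L], ncol = 1L,
                 dimnames = list(colnames(X), tissue))
  new_mttwas_fit(spec$method, spec, tissues = tissue,
                 snp_ids = colnames(X), snp_means = colMeans(X),
                 center = prep$center, scale = prep$scale,
                 beta = beta, intercept = stats::setNames(co[1L, 1L], tissue),
                 null = stats::setNames(all(beta == 0), tissue),
                 lambda = lam)
}

standardize_columns <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colSums(sweep(X, 2L, ctr)^2) / n)  # 1/n variance, glmnet-style
  ok <- scl > 0
  Xs <- sweep(X, 2L, ctr)
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2L, scl[ok], "/")
  Xs[, !ok] <- 0
  list(X = Xs, center = ctr, scale = ifelse(ok, scl, 1), keep = ok)
}

#' Solve the L2-fusion joint lasso at fixed penalties
#'
#' Minimizes, over per-tissue coefficient vectors `b_g`,
#' \deqn{\sum_g \|y_g - X_g b_g\|^2 / (2 n_g) + \lambda \sum_g \|b_g\|_1
#'   + \gamma \sum_{g<g'} \tau_{gg'} \|b_g - b_{g'}\|_2^2,}
#' by cyclic coordinate descent with soft-thresholding (compiled).
#' `gamma = 0` decouples the problem into independent per-tissue lassos;
#' large `gamma` with uniform `tau` forces all tissues to a common
#' coefficient vector (the pooled lasso).
#'
#' @param X_list List of design matrices, one per tissue (responses are
#'   centered internally; an intercept is returned per tissue).
#' @param y_list List of response vectors.
#' @param lambda Non-negative L1 penalty, or a decreasing vector (path).
#' @param gamma Non-negative fusion penalty.
#' @param tau Symmetric tissue-pair weight matrix (defaults to uniform 1).
#' @param standardize Standardize columns internally (glmnet convention,
#'   1/n variance) and return coefficients on the original scale.  With
#'   `FALSE` the objective above is minimized on the data as given.
#' @param max_iter,tol Solver controls: sweep cap and coordinate-change
#'   tolerance.
#' @param trace_objective Record the objective after every sweep
#'   (diagnostics; single-lambda calls only).
#' @return List with `beta` (p x G matrix, or p x G x n_lambda array for
#'   a path), `intercept` (per tissue), `iterations`, `converged`, and
#'   optionally `objective_trace`.
#' @export
solve_l2_fused_lasso <- function(X_list, y_list, lambda, gamma = 0,
                                 tau = NULL, standardize = TRUE,
                                 max_iter = 10000L, tol = 1e-8,
                                 trace_objective = FALSE) {
  G <- length(X_list)
  stopifnot(G == length(y_list), lambda >= 0, gamma >= 0)
  p <- ncol(X_list[[1L]])
  if (is.null(tau)) tau <- matrix(1, G, G) - diag(G)
  if (!isTRUE(all.equal(tau, t(tau)))) stop("tau must be symmetric")
  grams <- vector("list", G)
  cvec <- matrix(0, p, G)
  yty2n <- numeric(G)
  ybar <- numeric(G)
  std <- vector("list", G)
  for (g in seq_len(G)) {
    X <- as.matrix(X_list[[g]])
    y <- y_list[[g]]
    if (ncol(X) != p) stop("all tissues must share the SNP panel")
    n <- nrow(X)
    ybar[g] <- mean(y)
    yc <- y - ybar[g]
    if (standardize) {
      s <- standardize_columns(X)
      std[[g]] <- s
      X <- s$X
    } else {
      std[[g]] <- list(center = rep(0, p), scale = rep(1, p),
                       keep = rep(TRUE, p))
    }
    grams[[g]] <- crossprod(X) / n
    cvec[, g] <- crossprod(X, yc) / n
    yty2n[g] <- sum(yc^2) / (2 * n)
  }
  lam <- sort(lambda, decreasing = TRUE)
  res <- .fused_lasso_path_cpp(grams, cvec, yty2n, lam, gamma, tau,
                               max_iter = max_iter, tol = tol,
                               trace_objective = trace_objective)
  if (!res$converged)
    stop("convergence error: fused-lasso solver hit the iteration cap (",
         max_iter, " sweeps); last lambda = ", min(lam))
  bcube <- res$beta  # p x G x L
  L <- dim(bcube)[3L]
  intercepts <- matrix(0, G, L)
  # back-transform to the original X scale
  for (g in seq_len(G)) {
    Bg <- matrix(bcube[, g, ], nrow = p) / std[[g]]$scale
    bcube[, g, ] <- Bg
    intercepts[g, ] <- ybar[g] - as.vector(crossprod(Bg, std[[g]]$center))
  }
  out <- list(lambda = lam,
              iterations = res$iterations, converged = res$converged)
  if (L == 1L) {
    out$beta <- matrix(bcube[, , 1L], p, G)
    out$intercept <- intercepts[, 1L]
  } else {
    out$beta <- bcube
    out$intercept <- intercepts
  }
  if (trace_objective) out$objective_trace <- res$objective_trace
  out
}

joint_lambda_path <- function(grams_c, n_lambda, lambda_min_ratio) {
  lam_max <- max(abs(grams_c))
  if (lam_max <= 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

# Shared-design joint-lasso machinery: all tissues observe the same
# individuals and genotype matrix, so each fold needs only one Gram.
jl_gram_context <- function(Xs, Y, rows) {
  n <- length(rows)
  Xr <- Xs[rows, , drop = FALSE]
  ctr <- colMeans(Xr)
  scl <- sqrt(colSums(sweep(Xr, 2L, ctr)^2) / n)
  ok <- scl > 0
  Xstd <- sweep(Xr, 2L, ctr)
  Xstd[, ok] <- sweep(Xstd[, ok, drop = FALSE], 2L, scl[ok], "/")
  Xstd[, !ok] <- 0
  G <- nrow(Y)
  p <- ncol(Xs)
  cvec <- matrix(0, p, G)
  yty2n <- numeric(G)
  ybar <- numeric(G)
  for (g in seq_len(G)) {
    y <- Y[g, rows]
    ybar[g] <- mean(y)
    yc <- y - ybar[g]
    cvec[, g] <- crossprod(Xstd, yc) / n
    yty2n[g] <- sum(yc^2) / (2 * n)
  }
  list(gram = crossprod(Xstd) / n, cvec = cvec, yty2n = yty2n,
       ybar = ybar, center = ctr, scale = ifelse(ok, scl, 1), rows = rows)
}

jl_solve <- function(ctx, lambda_path, gamma, tau, max_iter = 5000L,
                     tol = 1e-4) {
  G <- ncol(ctx$cvec)
  res <- .fused_lasso_path_cpp(rep(list(ctx$gram), G), ctx$cvec, ctx$yty2n,
                               lambda_path, gamma, tau,
                               max_iter = max_iter, tol = tol,
                               trace_objective = FALSE)
  res
}

# Mean squared prediction error on held-out rows for every lambda.
jl_cv_error <- function(ctx, res, Xs, Y, ho_rows) {
  L <- length(res$iterations)
  G <- ncol(ctx$cvec)
  Xho <- sweep(Xs[ho_rows, , drop = FALSE], 2L, ctx$center)
  Xho <- sweep(Xho, 2L, ctx$scale, "/")
  err <- matrix(0, G, L)
  for (g in seq_len(G)) {
    B <- matrix(res$beta[, g, ], ncol = L)
    pred <- Xho %*% B + ctx$ybar[g]
    err[g, ] <- colMeans((Y[g, ho_rows] - pred)^2)
  }
  colMeans(err)
}

#' Fit the multi-task joint lasso with nested cross-validation
#'
#' Tunes the fusion parameter gamma by external k-fold cross-validation
#' (default 5) and, inside each training split and at each gamma, the L1
#' penalty lambda by internal k-fold cross-validation (default 10) along
#' a geometric path from the null-model penalty.  All folds are grouped
#' by individual.  Expression is centered (not scaled) per tissue; the
#' tissue-pair fusion weights default to expression-correlation penalties
#' (see [tissue_penalty_matrix()]).
#'
#' @param expression Matrix, tissues x individuals (rownames = tissue
#'   labels), measured on the individuals of `geno`.
#' @param geno A `genotype_matrix` shared by all tissues.
#' @param spec A [model_spec()] with method `"joint_lasso"`.
#' @return An `mttwas_fit` carrying per-tissue coefficients, the selected
#'   `gamma` and `lambda`, and the fusion weight matrix used.
#' @export
fit_joint_lasso <- function(expression, geno,
                            spec = model_spec("joint_lasso")) {
  Y <- rbind(expression)
  G <- nrow(Y)
  tissues <- rownames(Y)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(G))
  rownames(Y) <- tissues
  X <- dosage_matrix(geno)
  n <- nrow(X)
  if (ncol(Y) != n) stop("expression/genotype individuals mismatch")
  if (G == 1L) {
    fit <- fit_linear_stl(geno, as.vector(Y), model_spec(
      "lasso", cv_folds_internal = spec$cv_folds_internal,
      seed = spec$seed), tissue = tissues)
    fit$method <- "joint_lasso"
    fit$gamma <- 0
    return(fit)
  }
  prep <- preprocess_mtl(Y)
  Yc <- prep$values
  tau <- if (is.null(spec$tau)) tissue_penalty_matrix(Y) else spec$tau
  diag(tau) <- 0
  ids <- if (inherits(geno, "genotype_matrix")) geno$individual_ids
         else seq_len(n)
  full_ctx <- jl_gram_context(X, Yc, seq_len(n))
  path <- joint_lambda_path(full_ctx$cvec, spec$n_lambda,
                            spec$lambda_min_ratio)
  gammas <- spec$gamma_grid
  outer_id <- grouped_folds(ids, spec$cv_folds_external, seed = spec$seed)

  pick_lambda <- function(rows, seed_offset) {
    # internal CV over the lambda path, at each gamma, on `rows`
    inner_id <- grouped_folds(ids[rows], spec$cv_folds_internal,
                              seed = spec$seed + seed_offset)
    ctxs <- lapply(seq_len(spec$cv_folds_internal), function(f)
      jl_gram_context(X, Yc, rows[inner_id != f]))
    vapply(gammas, function(gm) {
      errs <- vapply(seq_len(spec$cv_folds_internal), function(f) {
        res <- jl_solve(ctxs[[f]], path, gm, tau)
        jl_cv_error(ctxs[[f]], res, X, Yc, rows[inner_id == f])
      }, numeric(length(path)))
      path[which.min(rowMeans(errs))]
    }, numeric(1L))
  }

  if (length(gammas) > 1L) {
    outer_err <- matrix(NA_real_, spec$cv_folds_external, length(gammas))
    for (f in seq_len(spec$cv_folds_external)) {
      train <- which(outer_id != f)
      test <- which(outer_id == f)
      lam_f <- pick_lambda(train, seed_offset = f)
      ctx <- jl_gram_context(X, Yc, train)
      for (gi in seq_along(gammas)) {
        sub_path <- path[path >= lam_f[gi]]
        res <- jl_solve(ctx, sub_path, gammas[gi], tau)
        err <- jl_cv_error(ctx, res, X, Yc, test)
        outer_err[f, gi] <- err[length(sub_path)]
      }
    }
    gamma_hat <- gammas[which.min(colMeans(outer_err))]
  } else {
    outer_err <- NULL
    gamma_hat <- gammas
  }

  lam_full <- pick_lambda(seq_len(n), seed_offset = 0L)
  lambda_hat <- lam_full[match(gamma_hat, gammas)]
  sub_path <- path[path >= lambda_hat]
  res <- jl_solve(full_ctx, sub_path, gamma_hat, tau, tol = 1e-7)
  L <- length(sub_path)
  beta_std <- matrix(res$beta[, , L], ncol = G)
  beta <- beta_std / full_ctx$scale
  intercept <- full_ctx$ybar - as.vector(crossprod(beta, full_ctx$center))
  dimnames(beta) <- list(colnames(X), tissues)
  fit <- new_mttwas_fit("joint_lasso", spec, tissues = tissues,
                        snp_ids = colnames(X), snp_means = colMeans(X),
                        center = prep$center,
                        scale = stats::setNames(rep(1, G), tissues),
                        beta = beta,
                        intercept = stats::setNames(intercept, tissues),
                        null = stats::setNames(colSums(beta != 0) == 0,
                                               tissues),
                        lambda = lambda_hat, gamma = gamma_hat, tau = tau)
  fit$cv_gamma_error <- if (is.null(outer_err)) NULL else colMeans(outer_err)
  fit
}
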