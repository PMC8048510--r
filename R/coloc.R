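#' Select SNPs for colocalisation testing
#'
#' Seeds are the SNPs whose GWAS or eQTL univariate p-value falls below
#' `p_threshold` (strict); the set is then expanded once by the seeds'
#' LD pockets — every SNP with squared correlation above `r2_threshold`
#' with any seed (a single round, not a transitive closure).
#'
#' @param gwas_p,eqtl_p Per-SNP p-value vectors (aligned).
#' @param r2 Symmetric LD matrix of squared correlations (same SNPs).
#' @param p_threshold Seed threshold, default `1e-4`.
#' @param r2_threshold Pocket threshold, default `0.2`.
#' @return Integer vector of selected SNP indices (empty, with attribute
#'   `insufficient = TRUE`, when no seeds exist).
#' @export
select_snps <- function(gwas_p, eqtl_p, r2, p_threshold = 1e-4,
                        r2_threshold = 0.2) {
  if (length(gwas_p) != length(eqtl_p) || nrow(r2) != length(gwas_p))
    stop("gwas_p, eqtl_p and r2 must be aligned")
  seeds <- which(pmin(gwas_p, eqtl_p) < p_threshold)
  if (!length(seeds)) {
    out <- integer(0)
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  pocket <- which(apply(r2[, seeds, drop = FALSE] > r2_threshold, 1L, any,
                        na.rm = TRUE))
  out <- sort(union(seeds, pocket))
  attr(out, "insufficient") <- FALSE
  out
}

#' Reduce a genotype submatrix to its leading principal components
#'
#' Column-centers the dosages and keeps `k = min(k80, 6)` PCs, where
#' `k80` is the smallest number of components whose cumulative variance
#' fraction reaches at least 0.8.  If the matrix rank is below `k`, the
#' available rank is used and flagged.
#'
#' @param geno_sub Dosage matrix (individuals x selected SNPs), >= 2 SNPs.
#' @param var_target Cumulative variance fraction target (default 0.8).
#' @param max_pcs Hard cap on the number of PCs (default 6).
#' @return List with `scores` (individuals x k), `rotation`, `k`,
#'   `var_fraction` (per-PC variance fractions), `rank_deficient` flag.
#' @export
pc_reduce <- function(geno_sub, var_target = 0.8, max_pcs = 6L) {
  X <- as.matrix(geno_sub)
  if (ncol(X) < 2L) stop("need at least 2 SNPs for PC reduction")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-10
  ev <- ev[pos]
  frac <- ev / sum(ev)
  k80 <- which(cumsum(frac) >= var_target)[1L]
  k <- min(k80, max_pcs, length(ev))
  rank_deficient <- length(ev) < min(ncol(X), nrow(X) - 1L)
  list(scores = Xc %*% sv$v[, seq_len(k), drop = FALSE],
       rotation = sv$v[, seq_len(k), drop = FALSE],
       k = k, var_fraction = frac, rank_deficient = rank_deficient)
}

#' Test proportionality of two coefficient vectors
#'
#' Null hypothesis: the two traits' regression coefficients on a common
#' basis are proportional, `b2 = theta * b1` — i.e. both association
#' signals are driven by the same underlying variant(s)
#' (colocalisation).  The statistic profiles theta over the quadratic
#' form \deqn{Q(\theta) = (b_2 - \theta b_1)' V(\theta)^{-1}
#' (b_2 - \theta b_1), \qquad V(\theta) = \Sigma_2 + \theta^2 \Sigma_1,}
#' valid when the two traits are measured on independent samples (so the
#' joint covariance is block-diagonal).  The minimized value is referred
#' to a chi-square with `k - 1` degrees of freedom.  Small p rejects
#' proportionality, i.e. indicates distinct signals in LD.  Theta is
#' profiled through the angle `atan(theta)` so the infinite-slope limit
#' is handled continuously.
#'
#' @param coef1,coef2 Coefficient vectors of length `k >= 2`.
#' @param vcov1,vcov2 Their covariance matrices (positive definite).
#' @return List with `p_f`, `theta_hat`, `statistic`, `df`.
#' @export
proportionality_test <- function(coef1, coef2, vcov1, vcov2) {
  k <- length(coef1)
  if (k < 2L || length(coef2) != k)
    stop("test undefined: need coefficient vectors of equal length >= 2")
  qform <- function(phi) {
    th <- tan(phi)
    # scale-balanced form: multiply residual by cos(phi) to keep the
    # quadratic form finite as phi -> pi/2 (theta -> Inf)
    u <- cos(phi) * coef2 - sin(phi) * coef1
    V <- cos(phi)^2 * vcov2 + sin(phi)^2 * vcov1
    drop(crossprod(u, solve(V, u)))
  }
  opt <- stats::optimize(qform, interval = c(-pi / 2, pi / 2))
  stat <- opt$objective
  theta <- tan(opt$minimum)
  list(p_f = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       theta_hat = theta, statistic = stat, df = k - 1)
}

#' Proportionality-based colocalisation filter for one TWAS hit
#'
#' Runs the full filter for a locus: select SNPs by association strength
#' and LD pockets, reduce them to principal components (shared basis for
#' both data sets), regress each trait on its own samples' PC scores,
#' and test proportionality of the two coefficient vectors.
#'
#' @param geno_eqtl,geno_gwas `genotype_matrix` objects on a common SNP
#'   panel.
#' @param expr Expression trait vector (eQTL individuals).
#' @param trait GWAS trait vector (GWAS individuals).
#' @param p_threshold,r2_threshold,var_target,max_pcs See
#'   [select_snps()] and [pc_reduce()].
#' @param pass_threshold Proportionality significance level: the hit
#'   passes (is considered colocalised) when `p_f >= pass_threshold`.
#' @return Object of class `coloc_result`: list with `p_f`, `theta_hat`,
#'   `n_pcs`, `n_snps`, `pass`, `insufficient`.
#' @export
coloc_filter_one <- function(geno_eqtl, geno_gwas, expr, trait,
                             p_threshold = 1e-4, r2_threshold = 0.2,
                             var_target = 0.8, max_pcs = 6L,
                             pass_threshold = 0.05) {
  eqtl_p <- univariate_scan(geno_eqtl, expr)
  gwas_p <- univariate_scan(geno_gwas, trait)
  combined <- rbind(geno_eqtl$dosages, geno_gwas$dosages)
  r2 <- ld_r2_matrix(combined)
  sel <- select_snps(gwas_p, eqtl_p, r2, p_threshold, r2_threshold)
  empty <- structure(list(p_f = NA_real_, theta_hat = NA_real_,
                          n_pcs = 0L, n_snps = length(sel), pass = FALSE,
                          insufficient = TRUE), class = "coloc_result")
  if (isTRUE(attr(sel, "insufficient")) || length(sel) < 2L) return(empty)
  pc <- pc_reduce(combined[, sel, drop = FALSE],
                  var_target = var_target, max_pcs = max_pcs)
  if (pc$k < 2L) return(empty)
  n_eqtl <- nrow(geno_eqtl$dosages)
  s_eqtl <- pc$scores[seq_len(n_eqtl), , drop = FALSE]
  s_gwas <- pc$scores[-seq_len(n_eqtl), , drop = FALSE]
  reg <- function(scores, y) {
    Z <- cbind(1, scores)
    fit <- stats::lm.fit(Z, y)
    dfres <- length(y) - ncol(Z)
    sigma2 <- sum(fit$residuals^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(Z)))
    list(coef = fit$coefficients[-1L],
         vcov = sigma2 * XtXinv[-1L, -1L, drop = FALSE])
  }
  r1 <- reg(s_eqtl, expr)
  r2b <- reg(s_gwas, trait)
  pt <- proportionality_test(r1$coef, r2b$coef, r1$vcov, r2b$vcov)
  structure(list(p_f = pt$p_f, theta_hat = pt$theta_hat, n_pcs = pc$k,
                 n_snps = length(sel), pass = pt$p_f >= pass_threshold,
                 insufficient = FALSE), class = "coloc_result")
}

#' Filter TWAS-significant hits for colocalisation
#'
#' Applies the proportionality filter to every TWAS-significant hit
#' (adjusted p below `sig_threshold`) in a [run_twas()] result.  An
#' SP-hit ("significant and proportional") is a hit that is
#' TWAS-significant and passes the filter; hits with too few associated
#' SNPs are dropped with a flag.
#'
#' @param twas_results A `twas_result` data frame.
#' @param model_sets The fitted model sets used for the TWAS (named by
#'   probe).
#' @param geno_eqtl,geno_gwas Genotype matrices of the two data sets.
#' @param expression_list Named list (by probe) of expression matrices
#'   (tissues x eQTL individuals).
#' @param trait GWAS trait vector.
#' @param sig_threshold TWAS significance level on adjusted p (0.05).
#' @param ... Passed to [coloc_filter_one()].
#' @return Data frame: probe, tissue, method, p_adj, p_f, theta_hat,
#'   n_pcs, n_snps, insufficient, sp_hit.
#' @export
filter_hits <- function(twas_results, model_sets, geno_eqtl, geno_gwas,
                        expression_list, trait, sig_threshold = 0.05, ...) {
  sig <- twas_results[!is.na(twas_results$p_adj) &
                        twas_results$p_adj < sig_threshold, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(probe = character(0), tissue = character(0),
                      method = character(0), p_adj = numeric(0),
                      p_f = numeric(0), theta_hat = numeric(0),
                      n_pcs = integer(0), n_snps = integer(0),
                      insufficient = logical(0), sp_hit = logical(0)))
  }
  out <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    probe <- sig$probe[i]; tissue <- sig$tissue[i]
    expr <- expression_list[[probe]][tissue, ]
    cr <- coloc_filter_one(geno_eqtl, geno_gwas, expr, trait, ...)
    out[[i]] <- data.frame(
      probe = probe, tissue = tissue, method = sig$method[i],
      p_adj = sig$p_adj[i], p_f = cr$p_f, theta_hat = cr$theta_hat,
      n_pcs = cr$n_pcs, n_snps = cr$n_snps,
      insufficient = cr$insufficient, sp_hit = isTRUE(cr$pass),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
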