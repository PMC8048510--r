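# Shared fixtures, built in code.

small_pool <- function(n_hap = 400, n_snp = 40, ld = 0.7, seed = 5) {
  build_haplotype_pool(n_hap, n_snp, ld_decay = ld, seed = seed)
}

# A small retained eQTL/GWAS dataset pair for pipeline tests.
small_sim <- function(scenario = "shared_A", seed = 1234, n_ind = 400,
                      pool = small_pool()) {
  sim <- simulate_dataset(pool, scenario, n_ind = n_ind, seed = seed)
  rownames(sim$traits$expression) <-
    c("test", paste0("bg", seq_len(nrow(sim$traits$expression) - 1L)))
  sim
}

# Uniform fusion weights for G tissues.
uniform_tau <- function(G) matrix(1, G, G) - diag(G)

# Brute-force minimization of the fused-lasso objective by iteratively
# refined grid search over all p*G coefficients; independent of the
# compiled solver.  Assumes centered y (no intercept).
fused_objective_matrix <- function(combos, X_list, y_list, lambda, gamma,
                                   tau) {
  G <- length(X_list)
  p <- ncol(X_list[[1]])
  obj <- numeric(nrow(combos))
  for (g in seq_len(G)) {
    idx <- (g - 1) * p + seq_len(p)
    Bg <- t(combos[, idx, drop = FALSE])            # p x N
    pred <- X_list[[g]] %*% Bg                      # n x N
    obj <- obj + colSums((y_list[[g]] - pred)^2) / (2 * length(y_list[[g]]))
    obj <- obj + lambda * colSums(abs(Bg))
  }
  if (G > 1 && gamma > 0) {
    for (g in 1:(G - 1)) for (h in (g + 1):G) {
      ig <- (g - 1) * p + seq_len(p)
      ih <- (h - 1) * p + seq_len(p)
      d <- combos[, ig, drop = FALSE] - combos[, ih, drop = FALSE]
      obj <- obj + gamma * tau[g, h] * rowSums(d^2)
    }
  }
  obj
}

grid_search_fused <- function(X_list, y_list, lambda, gamma = 0,
                              tau = NULL, lim = 1, rounds = 6) {
  G <- length(X_list)
  p <- ncol(X_list[[1]])
  if (is.null(tau)) tau <- uniform_tau(G)
  centre <- rep(0, p * G)
  half <- lim
  n_pts <- if (p * G <= 4) 13L else 7L
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p * G), function(d)
      seq(centre[d] - half, centre[d] + half, length.out = n_pts))
    combos <- as.matrix(expand.grid(grids))
    obj <- fused_objective_matrix(combos, X_list, y_list, lambda, gamma, tau)
    centre <- combos[which.min(obj), ]
    half <- half * 2 / (n_pts - 1)  # next round spans +- one grid step
  }
  list(beta = matrix(centre, p, G), objective = min(obj))
}
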