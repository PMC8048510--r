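test_that("preprocessing standardizes (STL) or centers (MTL) per tissue", {
  x <- rbind(t1 = c(1, 2, 3), t2 = c(10, 20, 60))
  st <- preprocess_stl(x)
  expect_equal(unname(rowMeans(st$values)), c(0, 0))
  expect_equal(unname(apply(st$values, 1, sd)), c(1, 1))
  # round-trip
  expect_equal(st$values * st$scale + st$center, x)
  expect_error(preprocess_stl(rbind(c(2, 2, 2))), "zero-variance")
  mt <- preprocess_mtl(x)
  expect_equal(unname(mt$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(mt$values)), c(0, 0))
  expect_equal(mt$scale, c(1, 1))
  # already-centered input is unchanged
  xc <- x - rowMeans(x)
  expect_equal(preprocess_mtl(xc)$values, xc)
})

test_that("tissue penalty matrix normalizes by the strongest pair", {
  set.seed(2)
  # two tissues: always 1 off-diagonal
  two <- matrix(rnorm(40), 2, 20)
  tau2 <- tissue_penalty_matrix(two)
  expect_equal(tau2[1, 2], 1)
  # three tissues: direct formula rho_ij / max rho
  three <- matrix(rnorm(90), 3, 30)
  rho <- cor(t(three))
  off <- rho; diag(off) <- NA
  expected <- pmax(off, 0) / max(pmax(off, 0), na.rm = TRUE)
  tau3 <- tissue_penalty_matrix(three)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(tau3[i, j], expected[i, j], tolerance = 1e-12)
  expect_equal(max(tau3), 1)
  expect_equal(tau3, t(tau3))
  # identical expression: all pairs at 1
  same <- rbind(three[1, ], three[1, ], three[1, ])
  tau_s <- tissue_penalty_matrix(same)
  expect_true(all(tau_s[upper.tri(tau_s)] == 1))
})

test_that("single-task lasso flags null fits and matches OLS at lambda 0", {
  set.seed(5)
  pool <- small_pool(n_snp = 10)
  geno <- sample_genotypes(pool, 80, seed = 5)
  # a penalty at least lambda_max zeroes every coefficient: null model
  y_null <- rnorm(80)
  f0 <- fit_linear_stl(geno, y_null, model_spec("lasso", lambda = 10))
  expect_true(f0$null[[1]])
  pred0 <- predict(f0, geno)
  expect_true(attr(pred0, "null"))
  expect_equal(sd(pred0), 0)
  # lambda = 0 on full-rank tall X reproduces least squares
  y <- as.vector(geno$dosages %*% c(0.5, -0.3, rep(0, 8))) + rnorm(80, 0, 0.5)
  f_ols <- fit_linear_stl(geno, y, model_spec("lasso", lambda = 0))
  ys <- (y - mean(y)) / sd(y)
  ols <- coef(lm(ys ~ geno$dosages))
  expect_lt(max(abs(f_ols$beta[, 1] - ols[-1])), 2e-3)
})

test_that("fused-lasso solver matches the grid-search oracle on toys", {
  set.seed(7)
  # single tissue, p = 2
  X1 <- matrix(rnorm(40), 20, 2)
  y1 <- as.vector(X1 %*% c(0.6, -0.4)) + rnorm(20, 0, 0.3)
  y1 <- y1 - mean(y1)
  sol <- solve_l2_fused_lasso(list(X1), list(y1), lambda = 0.1,
                              standardize = FALSE, tol = 1e-10)
  oracle <- grid_search_fused(list(X1), list(y1), lambda = 0.1)
  expect_lt(abs(fused_objective_matrix(matrix(as.vector(sol$beta), 1),
                                       list(X1), list(y1), 0.1, 0, NULL) -
                  oracle$objective), 1e-3)
  expect_lt(max(abs(sol$beta - oracle$beta)), 0.02)
  # two tissues, p = 2, active fusion
  X2 <- matrix(rnorm(40), 20, 2)
  y2 <- as.vector(X2 %*% c(0.5, 0.1)) + rnorm(20, 0, 0.3)
  y2 <- y2 - mean(y2)
  tau <- uniform_tau(2)
  for (gm in c(0.05, 0.5, 5)) {
    sol2 <- solve_l2_fused_lasso(list(X1, X2), list(y1, y2), lambda = 0.08,
                                 gamma = gm, tau = tau, standardize = FALSE,
                                 tol = 1e-10)
    or2 <- grid_search_fused(list(X1, X2), list(y1, y2), lambda = 0.08,
                             gamma = gm, tau = tau)
    o_sol <- fused_objective_matrix(matrix(as.vector(sol2$beta), 1),
                                    list(X1, X2), list(y1, y2), 0.08, gm, tau)
    expect_lt(abs(o_sol - or2$objective), 1e-3)
    expect_lt(max(abs(sol2$beta - or2$beta)), 0.02)
  }
  # p = 3, one tissue
  X3 <- matrix(rnorm(90), 30, 3)
  y3 <- as.vector(X3 %*% c(0.4, 0, -0.3)) + rnorm(30, 0, 0.3)
  y3 <- y3 - mean(y3)
  sol3 <- solve_l2_fused_lasso(list(X3), list(y3), lambda = 0.1,
                               standardize = FALSE, tol = 1e-10)
  or3 <- grid_search_fused(list(X3), list(y3), lambda = 0.1)
  o3 <- fused_objective_matrix(matrix(as.vector(sol3$beta), 1),
                               list(X3), list(y3), 0.1, 0, NULL)
  expect_lt(abs(o3 - or3$objective), 1e-3)
})

test_that("fused lasso decouples at gamma 0 and pools at large gamma", {
  set.seed(8)
  n <- 60; p <- 8; G <- 3
  # a common design across tissues keeps the per-tissue standardization
  # identical, so the large-gamma limit is the pooled lasso exactly
  X0 <- matrix(rbinom(n * p, 2, 0.3), n, p)
  X <- rep(list(X0), G)
  y <- lapply(1:G, function(g)
    as.vector(X0 %*% c(0.5, -0.4, rep(0, p - 2))) + rnorm(n))
  tau <- uniform_tau(G)
  # gamma = 0: per-tissue glmnet solutions
  s0 <- solve_l2_fused_lasso(X, y, lambda = 0.1, gamma = 0, tau = tau,
                             tol = 1e-10)
  for (g in 1:G) {
    gm <- glmnet::glmnet(X[[g]], y[[g]], lambda = 0.1, standardize = TRUE,
                         thresh = 1e-12)
    expect_lt(max(abs(s0$beta[, g] - as.vector(coef(gm))[-1])), 1e-6)
  }
  # gamma -> infinity with uniform tau: pooled lasso, tissues identical
  sb <- solve_l2_fused_lasso(X, y, lambda = 0.1, gamma = 1e6, tau = tau,
                             tol = 1e-10)
  expect_lt(max(abs(sb$beta - rowMeans(sb$beta))), 1e-3)
  sp <- solve_l2_fused_lasso(list(do.call(rbind, X)), list(unlist(y)),
                             lambda = 0.1, gamma = 0, tol = 1e-10)
  expect_lt(max(abs(sb$beta[, 1] - sp$beta[, 1])), 1e-3)
})

test_that("fused-lasso objective decreases monotonically over sweeps", {
  set.seed(9)
  X <- lapply(1:2, function(g) matrix(rnorm(100), 20, 5))
  y <- lapply(1:2, function(g) rnorm(20))
  tr <- solve_l2_fused_lasso(X, y, lambda = 0.05, gamma = 0.5,
                             tau = uniform_tau(2), standardize = FALSE,
                             trace_objective = TRUE, tol = 1e-10)
  expect_true(all(diff(tr$objective_trace) <= 1e-12))
})

test_that("joint lasso handles degenerate tissue structures", {
  pool <- small_pool(n_snp = 15)
  geno <- sample_genotypes(pool, 120, seed = 21)
  set.seed(21)
  y <- as.vector(geno$dosages %*% c(0.6, rep(0, 14))) + rnorm(120)
  # single tissue: reduces to the single-task lasso
  f1 <- fit_joint_lasso(rbind(t1 = y), geno,
                        model_spec("joint_lasso", seed = 2))
  f2 <- fit_linear_stl(geno, y, model_spec("lasso", seed = 2), tissue = "t1")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$gamma, 0)
  # identical tissues: identical per-tissue predictions
  expr2 <- rbind(t1 = y, t2 = y)
  f3 <- fit_joint_lasso(expr2, geno,
                        model_spec("joint_lasso", seed = 2,
                                   tau = uniform_tau(2)))
  p1 <- predict(f3, geno, tissue = "t1")
  p2 <- predict(f3, geno, tissue = "t2")
  expect_equal(p1, p2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fusion improves held-out error when tissues share a signal", {
  pool <- small_pool(n_snp = 15)
  gains <- sapply(1:8, function(r) {
    geno <- sample_genotypes(pool, 150, seed = 300 + r)
    set.seed(400 + r)
    mu <- as.vector(geno$dosages %*% c(0.5, rep(0, 14)))
    expr <- rbind(t1 = mu + rnorm(150), t2 = mu + rnorm(150))
    test_geno <- sample_genotypes(pool, 150, seed = 500 + r)
    mu_test <- as.vector(test_geno$dosages %*% c(0.5, rep(0, 14)))
    y_test <- mu_test + rnorm(150)
    sp_cv <- model_spec("joint_lasso", seed = r, tau = uniform_tau(2))
    sp_0 <- model_spec("joint_lasso", seed = r, tau = uniform_tau(2),
                       gamma_grid = 0)
    f_cv <- fit_joint_lasso(expr, geno, sp_cv)
    f_0 <- fit_joint_lasso(expr, geno, sp_0)
    mse <- function(f) mean((y_test - predict(f, test_geno, tissue = "t1"))^2)
    mse(f_0) - mse(f_cv)
  })
  # tuned fusion at least matches the unfused fit on average
  expect_gt(mean(gains), -0.005)
  expect_gt(mean(gains > 0), 0.5)
})

test_that("random forest fits track strong signals and respect seeds", {
  pool <- small_pool(n_snp = 20)
  geno <- sample_genotypes(pool, 500, seed = 31)
  test_geno <- sample_genotypes(pool, 200, seed = 32)
  set.seed(31)
  y <- geno$dosages[, 3] + rnorm(500, 0, 0.2)
  f <- fit_rf(geno, y, model_spec("rf", seed = 4), tissue = "t1")
  pred <- predict(f, test_geno, tissue = "t1")
  y_test <- test_geno$dosages[, 3] + rnorm(200, 0, 0.2)
  expect_gt(r_squared(y_test, pred), 0.8)
  # seed determinism
  f2 <- fit_rf(geno, y, model_spec("rf", seed = 4), tissue = "t1")
  expect_identical(pred, predict(f2, test_geno, tissue = "t1"))
  # constant response: constant predictions
  fc <- fit_rf(geno, rep(2.5, 500), model_spec("rf", seed = 4), tissue = "t1")
  expect_equal(unname(predict(fc, test_geno, tissue = "t1")),
               rep(2.5, 200), ignore_attr = TRUE)
})

test_that("multi-task forest pools identical tissues and splits opposite ones", {
  pool <- small_pool(n_snp = 15)
  geno <- sample_genotypes(pool, 150, seed = 41)
  set.seed(41)
  mu <- as.vector(geno$dosages %*% c(0.8, rep(0, 14)))
  noise <- rnorm(150, 0, 0.3)
  same <- rbind(t1 = mu + noise, t2 = mu + noise)
  f_same <- fit_rf_mtl(same, geno, model_spec("rf_mtl", seed = 6))
  d_same <- mean(abs(predict(f_same, geno, "t1") - predict(f_same, geno, "t2")))
  # opposite-sign effect of the causal SNP in the second tissue
  opp <- rbind(t1 = mu + noise, t2 = -mu + rnorm(150, 0, 0.3))
  f_opp <- fit_rf_mtl(opp, geno, model_spec("rf_mtl", seed = 6))
  d_opp <- mean(abs(predict(f_opp, geno, "t1") - predict(f_opp, geno, "t2")))
  expect_lt(d_same, 0.25 * sd(mu))
  expect_gt(d_opp, 3 * d_same)
  expect_gt(tissue_split_fraction(f_opp), 0.9)
  expect_error(predict(f_opp, geno, tissue = "t9"), "unknown tissue")
})

test_that("predictions align SNPs by id and impute missing ones", {
  pool <- small_pool(n_snp = 6)
  geno <- sample_genotypes(pool, 100, seed = 51)
  set.seed(51)
  y <- as.vector(geno$dosages %*% c(0.7, -0.5, rep(0, 4))) + rnorm(100, 0, 0.3)
  f <- fit_linear_stl(geno, y, model_spec("lasso", seed = 1), tissue = "t1")
  # hand evaluation: dot product plus intercept, back-transformed
  newX <- geno$dosages[1:5, ]
  colnames(newX) <- geno$snp_ids
  pred <- predict(f, newX, tissue = "t1")
  hand <- (as.vector(newX %*% f$beta[, 1]) + f$intercept[[1]]) *
    f$scale[[1]] + f$center[[1]]
  expect_equal(unname(pred), hand, ignore_attr = TRUE)
  # missing SNPs imputed at training mean dosage, with a warning
  part <- newX[, c(1, 3, 4, 5, 6)]
  expect_warning(pred_part <- predict(f, part, tissue = "t1"), "imputed")
  imputed <- cbind(newX[, 1, drop = FALSE], snp2 = f$snp_means[2],
                   newX[, 3:6])
  colnames(imputed) <- geno$snp_ids
  hand2 <- (as.vector(imputed %*% f$beta[, 1]) + f$intercept[[1]]) *
    f$scale[[1]] + f$center[[1]]
  expect_equal(unname(pred_part), hand2, ignore_attr = TRUE)
  # no shared SNPs: prediction error
  bad <- newX; colnames(bad) <- paste0("other", 1:6)
  expect_error(predict(f, bad, tissue = "t1"), "no SNPs shared")
})
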