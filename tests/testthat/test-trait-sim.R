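test_that("effect sizes behave as the maximum of five Gaussians", {
  set.seed(42)
  draws <- sample_effect_size(2e5)
  # symmetry: P(max > 0) = 1 - 0.5^5
  p_pos <- mean(draws > 0)
  se <- sqrt(0.96875 * (1 - 0.96875) / 2e5)
  expect_lt(abs(p_pos - 0.96875), 4 * se)
  # Monte-Carlo oracle for E[max of five N(0, 0.04)]: brute-force draw
  set.seed(99)
  oracle <- mean(apply(matrix(rnorm(5 * 2e5, 0, 0.2), 5, 2e5), 2, max))
  se_diff <- sd(draws) * sqrt(2 / 2e5)
  expect_lt(abs(mean(draws) - oracle), 4 * se_diff)
  # deterministic given seed
  expect_identical(sample_effect_size(5, seed = 7), sample_effect_size(5, seed = 7))
})

test_that("scenario effect maps follow the sharing grid", {
  grid <- scenario_grid()
  expect_equal(nrow(grid), 6L)
  expect_setequal(grid$row, c("shared", "distinct"))
  expect_setequal(grid$background, c("none", "B", "A"))
  geno <- sample_genotypes(small_pool(), 100, seed = 1)
  # top-left: GWAS and test share one SNP, no background effects
  em <- build_scenario("shared_none", geno, seed = 2)
  expect_equal(nrow(em), 2L)
  expect_equal(length(unique(em$snp_index)), 1L)
  expect_equal(em$trait_index, c(0L, 1L))
  # traits sharing a variant share its effect size
  expect_equal(em$beta[1], em$beta[2])
  # bottom-right: GWAS on A, test on C, four backgrounds on A
  em2 <- build_scenario("distinct_A", geno, seed = 3)
  expect_equal(nrow(em2), 6L)
  snp_A <- em2$snp_index[em2$trait_index == 0]
  expect_equal(sum(em2$snp_index == snp_A), 5L)
  expect_false(em2$snp_index[em2$trait_index == 1] == snp_A)
  # distinct_B needs three distinct SNPs: impossible with a 2-SNP panel
  tiny <- list(dosages = cbind(c(0L,1L,2L,1L), c(2L,1L,0L,1L)),
               individual_ids = paste0("i", 1:4),
               snp_ids = c("s1", "s2"), positions = c(1L, 2L))
  class(tiny) <- "genotype_matrix"
  expect_error(build_scenario("distinct_B", tiny, seed = 1), "scenario error")
})

test_that("traits are unit-variance Gaussians around the genetic mean", {
  pool <- small_pool()
  ge <- sample_genotypes(pool, 4000, seed = 1)
  gg <- sample_genotypes(pool, 4000, seed = 2)
  # null effects: standard Gaussian noise
  em0 <- build_scenario("shared_none", ge, seed = 3)
  em0$beta <- c(0, 0)
  tp0 <- simulate_traits(ge, gg, em0, seed = 4)
  expect_lt(abs(mean(tp0$expression["test", ])), 4 / sqrt(4000))
  expect_lt(abs(sd(tp0$gwas_trait) - 1), 0.08)
  # single effect: variance decomposition var(y) ~ 1 + beta^2 var(G)
  em <- build_scenario("shared_none", ge, seed = 5)
  em$beta <- c(0.8, 0.8)
  tp <- simulate_traits(ge, gg, em, seed = 6)
  v_g <- var(ge$dosages[, em$snp_index[2]])
  expect_equal(var(tp$expression["test", ]), 1 + 0.8^2 * v_g,
               tolerance = 0.08)
  # zero-noise hook exposes the exact genetic mean
  tp_exact <- simulate_traits(ge, gg, em, seed = 7, noise_sd = 0)
  expect_equal(unname(tp_exact$expression["test", ]),
               as.vector(ge$dosages[, em$snp_index[2]] * 0.8))
  # location equivariance: shifting dosages shifts the mean by beta * shift
  ge_shift <- ge
  ge_shift$dosages[, em$snp_index[2]] <- ge$dosages[, em$snp_index[2]] + 3L
  tp_shift <- simulate_traits(ge_shift, gg, em, seed = 7, noise_sd = 0)
  expect_equal(unname(tp_shift$expression["test", ] - tp_exact$expression["test", ]),
               rep(0.8 * 3, 4000))
})

test_that("univariate scan agrees with lm and is calibrated under the null", {
  # 5-point hand-checkable regression against the lm oracle
  g <- cbind(snp = c(0, 1, 2, 1, 0))
  y <- c(0.3, 1.1, 2.2, 0.9, -0.2)
  p_scan <- univariate_scan(g, y)
  p_lm <- summary(lm(y ~ g[, 1]))$coefficients[2, 4]
  expect_equal(p_scan, p_lm, tolerance = 1e-12)
  # perfect proportionality: p at the machine floor
  expect_lt(univariate_scan(cbind(c(0, 1, 2, 1, 0, 2)), c(0, 1, 2, 1, 0, 2) * 0.5)[1],
            1e-12)
  # monomorphic SNP: p = 1
  expect_equal(univariate_scan(cbind(rep(1, 5), c(0, 1, 2, 0, 1)), rnorm(5))[1], 1)
  # null calibration: p-values approximately uniform (KS test)
  set.seed(33)
  G <- matrix(rbinom(300 * 1000, 2, 0.3), 300, 1000)
  pv <- univariate_scan(G, rnorm(300))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("retention keeps only datasets with a strong eQTL signal", {
  expect_true(retention_filter(c(0.5, 5e-8, 0.2)))
  expect_false(retention_filter(c(1e-7, 0.3)))  # strict inequality
  expect_false(retention_filter(matrix(runif(100, 0.2, 1), 5)))
  expect_error(retention_filter(c(0.5, 1.2)), "\\[0, 1\\]")
  # null-effect retention is vanishingly rare: analytic upper bound
  # 1 - (1 - 1e-7)^1000 ~ 1e-4; none expected in 200 null scans
  pool <- small_pool(n_snp = 20)
  ge <- sample_genotypes(pool, 100, seed = 8)
  set.seed(8)
  hits <- replicate(200, {
    retention_filter(univariate_scan(ge, rnorm(100)))
  })
  expect_false(any(hits))
})

test_that("the simulation driver retries and reports failures", {
  pool <- small_pool()
  sim <- simulate_dataset(pool, "shared_A", n_ind = 200, seed = 77)
  expect_true(retention_filter(sim$scan_pvals))
  expect_gte(sim$retries, 0)
  expect_equal(dim(sim$traits$expression), c(5L, 200L))
  # identical seeds give identical datasets
  sim2 <- simulate_dataset(pool, "shared_A", n_ind = 200, seed = 77)
  expect_identical(sim$traits$gwas_trait, sim2$traits$gwas_trait)
  expect_identical(sim$effects$beta, sim2$effects$beta)
  # unsatisfiable retention exhausts the retry budget
  expect_error(
    simulate_dataset(pool, "shared_A", n_ind = 50, seed = 1,
                     retention_threshold = 0, max_retries = 3),
    "retry budget")
})

test_that("retention probability increases with effect size", {
  pool <- small_pool()
  ge <- sample_genotypes(pool, 200, seed = 10)
  gg <- sample_genotypes(pool, 200, seed = 11)
  betas <- c(0.1, 0.4, 0.8)
  rates <- sapply(betas, function(b) {
    mean(sapply(1:40, function(r) {
      em <- build_scenario("shared_none", ge, seed = 1000 + r)
      em$beta <- c(b, b)
      tp <- simulate_traits(ge, gg, em, seed = 2000 + r)
      retention_filter(univariate_scan(ge, tp$expression["test", ]))
    }))
  })
  expect_true(all(diff(rates) >= 0))
})
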