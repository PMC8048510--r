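#' Draw one causal effect size
#'
#' Effect sizes are sampled as the maximum of five independent mean-zero
#' Gaussians with variance 0.04 (sd 0.2).  Taking the maximum skews the
#' distribution towards positive, non-negligible effects so that fewer
#' simulated data sets carry an undetectably weak signal.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed (draws from the current RNG stream
#'   when `NULL`).
#' @return Numeric vector of length `n`.
#' @export
sample_effect_size <- function(n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  apply(matrix(stats::rnorm(5L * n, 0, sqrt(0.04)), 5L, n), 2L, max)
}

#' Scenario grid for causal-variant sharing
#'
#' Six scenarios form a 2 x 3 grid.  Rows: the GWAS trait and the test
#' expression trait either share causal variant A (`shared`) or use
#' distinct variants (`distinct`, GWAS on A, test on its own variant C).
#' Columns: the four background expression traits have no causal variant
#' (`none`), share their own variant B (`B`), or share the GWAS variant A
#' (`A`).
#'
#' @return Data frame with columns `scenario_id`, `row`, `background`.
#' @export
scenario_grid <- function() {
  g <- expand.grid(background = c("none", "B", "A"),
                   row = c("shared", "distinct"),
                   stringsAsFactors = FALSE)[, c("row", "background")]
  g$scenario_id <- paste(g$row, g$background, sep = "_")
  g[, c("scenario_id", "row", "background")]
}

#' Build an effect map for one causal scenario
#'
#' Samples the distinct causal variants a scenario needs uniformly from the
#' eligible SNPs (by default those with sample MAF at least `min_maf`) and
#' assigns each involved trait one causal variant.  One effect size is
#' drawn per variant (see [sample_effect_size()]) and shared by every
#' trait assigned that variant, so traits sharing a causal variant share
#' its effect.  Trait index 0 is the GWAS trait and trait 1 the
#' test expression trait; traits 2..(1+n_background) are background
#' expression traits.
#'
#' @param scenario_id One of [scenario_grid()]'s ids, e.g. `"shared_none"`.
#' @param geno A `genotype_matrix` used to determine eligible SNPs.
#' @param n_background Number of background expression traits (default 4).
#' @param min_maf Minimum sample MAF for a SNP to be a causal candidate.
#' @param seed Optional integer seed.
#' @return Object of class `effect_map`: data frame with columns
#'   `snp_index`, `trait_index`, `beta`, plus attributes `n_background`
#'   and `scenario_id`.
#' @export
build_scenario <- function(scenario_id, geno, n_background = 4L,
                           min_maf = 0.05, seed = NULL) {
  grid <- scenario_grid()
  if (!scenario_id %in% grid$scenario_id)
    stop("unknown scenario_id: ", scenario_id)
  if (!is.null(seed)) set.seed(as.integer(seed))
  row_kind <- grid$row[grid$scenario_id == scenario_id]
  background <- grid$background[grid$scenario_id == scenario_id]
  freq <- colMeans(geno$dosages) / 2
  eligible <- which(pmin(freq, 1 - freq) >= min_maf)
  n_distinct <- 1L + (row_kind == "distinct") + (background == "B")
  if (length(eligible) < n_distinct)
    stop("scenario error: ", n_distinct, " distinct causal SNPs required but ",
         length(eligible), " eligible")
  picks <- sample(eligible, n_distinct)
  snp_A <- picks[1]
  snp_test <- if (row_kind == "shared") snp_A else picks[2]
  snp_bg <- switch(background,
                   none = NA_integer_,
                   A    = snp_A,
                   B    = picks[n_distinct])
  traits <- c(0L, 1L)
  snps <- c(snp_A, snp_test)
  if (background != "none" && n_background > 0L) {
    traits <- c(traits, seq_len(n_background) + 1L)
    snps <- c(snps, rep(snp_bg, n_background))
  }
  # one effect size per causal variant, shared by all traits assigned it
  usnp <- unique(snps)
  beta_of <- stats::setNames(sample_effect_size(length(usnp)), usnp)
  em <- data.frame(snp_index = snps, trait_index = traits,
                   beta = unname(beta_of[as.character(snps)]))
  structure(em, class = c("effect_map", "data.frame"),
            n_background = n_background, scenario_id = scenario_id)
}

#' Simulate multi-tissue expression and a GWAS trait under an effect map
#'
#' Each trait is a unit-variance Gaussian around its genetic mean
#' `sum_i beta_ij G_i`: expression traits are generated on the eQTL
#' individuals and the GWAS trait on the GWAS individuals.
#'
#' @param geno_eqtl,geno_gwas `genotype_matrix` objects for the two
#'   data sets (same SNP panel).
#' @param effects An `effect_map`.
#' @param seed Optional integer seed.
#' @param noise_sd Residual standard deviation (1 by convention; a test
#'   hook allows 0 to expose the genetic means).
#' @return Object of class `trait_panel`: list with `gwas_trait` (numeric,
#'   GWAS individuals) and `expression` (matrix, traits x eQTL
#'   individuals; row 1 is the test trait, the rest background).
#' @export
simulate_traits <- function(geno_eqtl, geno_gwas, effects, seed = NULL,
                            noise_sd = 1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_bg <- attr(effects, "n_background")
  if (is.null(n_bg)) n_bg <- max(0L, max(effects$trait_index) - 1L)
  p <- ncol(geno_eqtl$dosages)
  if (any(effects$snp_index < 1L | effects$snp_index > p))
    stop("effect SNP index out of range")
  genetic_mean <- function(dos, trait) {
    sel <- effects$trait_index == trait
    mu <- numeric(nrow(dos))
    if (any(sel))
      mu <- as.vector(dos[, effects$snp_index[sel], drop = FALSE] %*%
                        effects$beta[sel])
    mu
  }
  n_expr <- 1L + n_bg
  expr <- matrix(NA_real_, n_expr, nrow(geno_eqtl$dosages))
  for (j in seq_len(n_expr)) {
    mu <- genetic_mean(geno_eqtl$dosages, j)
    expr[j, ] <- mu + stats::rnorm(length(mu), 0, noise_sd)
  }
  rownames(expr) <- c("test", if (n_bg > 0) paste0("background", seq_len(n_bg)))
  colnames(expr) <- geno_eqtl$individual_ids
  mu_g <- genetic_mean(geno_gwas$dosages, 0L)
  gwas <- mu_g + stats::rnorm(length(mu_g), 0, noise_sd)
  names(gwas) <- geno_gwas$individual_ids
  structure(list(gwas_trait = gwas, expression = expr), class = "trait_panel")
}

#' Per-SNP association scan by simple linear regression
#'
#' Regresses a quantitative trait on each dosage column separately and
#' returns the two-sided p-value of the slope t-test.  Monomorphic SNPs
#' get `p = 1`.
#'
#' @param geno A `genotype_matrix` or plain dosage matrix.
#' @param trait Numeric trait vector (one value per individual).
#' @return Numeric vector of p-values, one per SNP.
#' @export
univariate_scan <- function(geno, trait) {
  dos <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  n <- nrow(dos)
  if (length(trait) != n) stop("trait length must match individuals")
  if (n < 3L) stop("need at least 3 individuals")
  sdx <- apply(dos, 2L, stats::sd)
  p <- rep(1, ncol(dos))
  poly <- sdx > 0
  if (stats::sd(trait) == 0) return(p)
  if (any(poly)) {
    r <- suppressWarnings(as.vector(stats::cor(trait, dos[, poly, drop = FALSE])))
    r2 <- pmin(r^2, 1)
    tval <- sqrt(pmax(0, (n - 2) * r2 / (1 - r2)))
    tval[r2 >= 1 - 1e-15] <- Inf
    p[poly] <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  }
  p
}

#' eQTL-signal retention rule for a simulated data set
#'
#' A simulated data set is retained only if the smallest univariate
#' p-value over all SNPs and all expression traits is below `threshold`
#' (strict inequality).
#'
#' @param expression_pvals Matrix of p-values (traits x SNPs) or vector.
#' @param threshold Retention threshold, default `1e-7`.
#' @return `TRUE` if retained.
#' @export
retention_filter <- function(expression_pvals, threshold = 1e-7) {
  pv <- as.numeric(expression_pvals)
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  min(pv, na.rm = TRUE) < threshold
}

#' Simulate one retained eQTL + GWAS data set for a scenario
#'
#' Driver that repeatedly samples genotypes, causal variants, effect sizes
#' and traits until the retention rule (minimum expression-scan p-value
#' below `retention_threshold`) is met, or the retry budget is exhausted.
#'
#' @param pool A `haplotype_pool`.
#' @param scenario_id Scenario id from [scenario_grid()].
#' @param n_ind Individuals per data set (default 400, both data sets).
#' @param n_background Background expression traits (default 4).
#' @param retention_threshold Retention p-value threshold (default `1e-7`).
#' @param max_retries Retry budget for rejection sampling (default 100).
#' @param min_maf Causal-variant MAF floor.
#' @param seed Integer seed; each retry advances deterministically.
#' @return List with `geno_eqtl`, `geno_gwas`, `effects`, `traits`,
#'   `scan_pvals` (expression traits x SNPs), `retries`.
#' @export
simulate_dataset <- function(pool, scenario_id, n_ind = 400L,
                             n_background = 4L, retention_threshold = 1e-7,
                             max_retries = 100L, min_maf = 0.05, seed = 1L) {
  seed <- as.integer(seed)
  for (try in seq_len(max_retries)) {
    s <- (seed + 7919L * (try - 1L)) %% .Machine$integer.max
    geno_eqtl <- sample_genotypes(pool, n_ind, seed = s)
    geno_gwas <- sample_genotypes(pool, n_ind, seed = s + 1L)
    effects <- build_scenario(scenario_id, geno_eqtl,
                              n_background = n_background,
                              min_maf = min_maf, seed = s + 2L)
    traits <- simulate_traits(geno_eqtl, geno_gwas, effects, seed = s + 3L)
    scan <- t(apply(traits$expression, 1L, function(y)
      univariate_scan(geno_eqtl, y)))
    if (retention_filter(scan, retention_threshold)) {
      return(list(geno_eqtl = geno_eqtl, geno_gwas = geno_gwas,
                  effects = effects, traits = traits, scan_pvals = scan,
                  retries = try - 1L))
    }
  }
  stop("simulation error: retention retry budget (", max_retries,
       ") exhausted for scenario ", scenario_id)
}
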