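#' Fit a single-tissue random forest expression predictor
#'
#' Regression forest (via `ranger`) with the defaults used throughout
#' this package: 500 trees, minimum terminal node size 5, and one third
#' of the SNPs considered at each split.  Expression is standardized per
#' tissue before fitting (constants stored for back-transformation).
#'
#' @inheritParams fit_linear_stl
#' @param spec A [model_spec()] with method `"rf"`.
#' @return An `mttwas_fit` carrying the forest.
#' @export
fit_rf <- function(geno, y, spec = model_spec("rf"), tissue = "tissue1") {
  X <- dosage_matrix(geno)
  if (nrow(X) != length(y)) stop("genotype/expression size mismatch")
  if (nrow(X) < spec$min_node_size) stop("fewer samples than min_node_size")
  prep <- if (stats::sd(y) == 0) {
    # constant response: the forest degenerates to the constant predictor
    list(values = rbind(y - mean(y)), center = mean(y), scale = 1)
  } else preprocess_stl(y)
  dat <- as.data.frame(X)
  dat$.y <- as.vector(prep$values)
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = spec$n_trees, min.node.size = spec$min_node_size,
    mtry = max(1L, floor(ncol(X) * spec$mtry_fraction)),
    num.threads = 1L, seed = spec$seed)
  new_mttwas_fit("rf", spec, tissues = tissue, snp_ids = colnames(X),
                 snp_means = colMeans(X), center = prep$center,
                 scale = prep$scale, forest = forest,
                 null = stats::setNames(FALSE, tissue))
}

#' Fit a multi-task random forest over the stacked tissue design
#'
#' Expression vectors of all tissues are concatenated into one long
#' response, genotype rows are stacked correspondingly (each individual
#' contributing one sample point per tissue, treated as independent), and
#' a categorical tissue identifier is added.  The identifier is always in
#' the candidate set at every split, on top of the `mtry` randomly
#' sampled SNP columns, so the forest can separate dissimilar tissues or
#' pool similar ones branch by branch.  Expression is centered (not
#' scaled) per tissue.
#'
#' @inheritParams fit_joint_lasso
#' @param spec A [model_spec()] with method `"rf_mtl"`.
#' @return An `mttwas_fit`; predictions require a tissue id.
#' @export
fit_rf_mtl <- function(expression, geno, spec = model_spec("rf_mtl")) {
  Y <- rbind(expression)
  G <- nrow(Y)
  tissues <- rownames(Y)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(G))
  X <- dosage_matrix(geno)
  if (ncol(Y) != nrow(X)) stop("expression/genotype individuals mismatch")
  if (G > 32L) stop("at most 32 tissue levels supported for partition splits")
  prep <- preprocess_mtl(Y)
  stacked <- as.data.frame(X[rep(seq_len(nrow(X)), G), , drop = FALSE])
  stacked$.tissue <- factor(rep(tissues, each = nrow(X)), levels = tissues)
  stacked$.y <- as.vector(t(prep$values))
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = stacked,
    num.trees = spec$n_trees, min.node.size = spec$min_node_size,
    mtry = max(1L, floor(ncol(X) * spec$mtry_fraction)),
    always.split.variables = ".tissue",
    respect.unordered.factors = "partition",
    num.threads = 1L, seed = spec$seed)
  new_mttwas_fit("rf_mtl", spec, tissues = tissues, snp_ids = colnames(X),
                 snp_means = colMeans(X), center = prep$center,
                 scale = stats::setNames(rep(1, G), tissues),
                 forest = forest,
                 null = stats::setNames(rep(FALSE, G), tissues))
}

#' Fraction of trees whose splits use the tissue identifier
#'
#' Diagnostic for multi-task forests: a tissue id that is rarely used
#' indicates the tissues are being pooled as homogeneous.
#'
#' @param model An `mttwas_fit` with method `"rf_mtl"`.
#' @return Fraction in `[0, 1]`.
#' @export
tissue_split_fraction <- function(model) {
  stopifnot(model$method == "rf_mtl")
  forest <- model$forest
  id_col <- which(forest$forest$independent.variable.names == ".tissue")
  # split.varIDs include terminal nodes (stored as 0); look at internal only
  used <- vapply(seq_len(forest$num.trees), function(t) {
    vids <- forest$forest$split.varIDs[[t]]
    term <- forest$forest$child.nodeIDs[[t]][[1L]] == 0 &
      forest$forest$child.nodeIDs[[t]][[2L]] == 0
    any(vids[!term] == id_col - 1L)
  }, logical(1L))
  mean(used)
}
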