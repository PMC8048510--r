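#' Predict expression from a fitted model
#'
#' Applies a fitted predictor to new genotype data for a given tissue and
#' returns predictions on the original (unpreprocessed) expression scale.
#' SNPs are matched by id: SNPs present at training but absent from
#' `geno` are imputed at their training-mean dosage (with a warning); if
#' no training SNP is shared, prediction fails.  Null linear models
#' return the constant training mean; the result carries a `null`
#' attribute.
#'
#' @param object An `mttwas_fit`.
#' @param geno A `genotype_matrix` (or dosage matrix with SNP column
#'   names) for the individuals to predict.
#' @param tissue Tissue label to predict for (must be one of the model's
#'   tissues; defaults to the first).
#' @param ... Unused.
#' @return Numeric vector of predicted expression, with attribute
#'   `null` (logical).
#' @export
predict.mttwas_fit <- function(object, geno, tissue = object$tissues[1L],
                               ...) {
  if (!tissue %in% object$tissues)
    stop("prediction error: unknown tissue id '", tissue, "'")
  X <- dosage_matrix(geno)
  if (is.null(colnames(X)) && ncol(X) == length(object$snp_ids))
    colnames(X) <- object$snp_ids
  shared <- intersect(object$snp_ids, colnames(X))
  if (!length(shared))
    stop("prediction error: no SNPs shared with the training panel")
  if (length(shared) < length(object$snp_ids))
    warning(length(object$snp_ids) - length(shared),
            " training SNPs missing from prediction data; ",
            "imputed at training-mean dosage")
  n <- nrow(X)
  Xa <- matrix(rep(object$snp_means, each = n), n,
               length(object$snp_ids),
               dimnames = list(NULL, object$snp_ids))
  Xa[, shared] <- X[, shared]
  ti <- match(tissue, object$tissues)
  is_null <- isTRUE(object$null[[ti]])
  if (object$method %in% c("rf", "rf_mtl")) {
    dat <- as.data.frame(Xa)
    if (object$method == "rf_mtl")
      dat$.tissue <- factor(rep(tissue, n), levels = object$tissues)
    pred_pre <- stats::predict(object$forest, data = dat,
                               num.threads = 1L)$predictions
  } else {
    pred_pre <- as.vector(Xa %*% object$beta[, ti]) +
      object$intercept[[ti]]
  }
  pred <- pred_pre * object$scale[[ti]] + object$center[[ti]]
  attr(pred, "null") <- is_null
  pred
}
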