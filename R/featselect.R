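#' Regularization and cross-validation settings for feature selection
#'
#' @param alpha_grid Elastic-net mixing values searched in `"en"` mode;
#'   default 0.05 to 0.95 in steps of 0.1. LASSO mode fixes `alpha = 1`.
#' @param n_folds Cross-validation folds (default 10).
#' @param lambda_path_length Number of penalty values per path (default 100,
#'   log-spaced from the smallest all-zero penalty `lambda_max` down to
#'   `0.001 lambda_max`).
#' @param lambda_min_ratio Ratio of the smallest to largest path penalty.
#' @param fold_seed Seed for the fold permutation; fixing it makes fold
#'   assignment and therefore the whole selection deterministic.
#' @param cv_tol Coordinate-descent tolerance used for the fold fits during
#'   cross-validation; the final refit always uses the strict `1e-7`
#'   tolerance. Validation errors are insensitive to the last decimals of
#'   the coefficients, so the fold fits may run looser.
#' @param standardize Standardize columns to unit variance before fitting
#'   (coefficients are reported back on the genotype scale).
#' @return A `regularization_config` list.
#' @export
regularization_config <- function(alpha_grid = seq(0.05, 0.95, by = 0.1),
                                  n_folds = 10L,
                                  lambda_path_length = 100L,
                                  lambda_min_ratio = 0.001,
                                  fold_seed = 1L,
                                  cv_tol = 1e-5,
                                  standardize = TRUE) {
  if (any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop_gsfs("alpha values must lie in (0, 1]", class = "gsfs_config_error")
  }
  if (n_folds < 2L) stop_gsfs("need at least 2 folds", class = "gsfs_config_error")
  structure(list(alpha_grid = alpha_grid, n_folds = as.integer(n_folds),
                 lambda_path_length = as.integer(lambda_path_length),
                 lambda_min_ratio = lambda_min_ratio,
                 fold_seed = as.integer(fold_seed),
                 cv_tol = cv_tol,
                 standardize = isTRUE(standardize)),
            class = "regularization_config")
}

# standardization bookkeeping shared by enet_fit and the CV driver.
# sds use the 1/n convention so that unit-variance columns have x'x/n = 1.
.enet_prep <- function(X, y, standardize) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, `-`)
  sds <- sqrt(colMeans(Xc^2))
  zero <- sds <= .Machine$double.eps^0.5
  if (standardize) {
    sc <- ifelse(zero, 1, sds)
    Xc <- sweep(Xc, 2L, sc, `/`)
    xsq <- ifelse(zero, 0, 1)
  } else {
    sc <- rep(1, ncol(X))
    xsq <- ifelse(zero, 0, sds^2)
  }
  ym <- mean(y)
  list(X = Xc, y = y - ym, xm = xm, ym = ym, sc = sc, xsq = xsq, n = n)
}

.lambda_max <- function(prep, alpha) {
  max(abs(crossprod(prep$X, prep$y)) / prep$n) / alpha
}

#' Elastic-net / LASSO fit at fixed penalty
#'
#' Minimizes `(1/(2n)) RSS + lambda ((1-alpha)/2 sum b^2 + alpha sum |b|)`
#' by cyclic coordinate descent with soft-thresholding (convergence when the
#' largest coefficient change in a sweep falls below `1e-7`). The intercept
#' is handled by centering; with `standardize = TRUE` columns are scaled to
#' unit variance internally and coefficients are returned on the original
#' genotype scale. `alpha = 1` is the LASSO.
#'
#' @param X Numeric predictor matrix (individuals x SNPs).
#' @param y Numeric response.
#' @param alpha Elastic-net mixing in (0, 1].
#' @param lambda Penalty level(s); a decreasing vector is fitted as a
#'   warm-started path.
#' @param standardize Standardize columns before fitting.
#' @param tol,max_iter Coordinate-descent convergence controls.
#' @return For scalar `lambda`, a list with `intercept` and `beta`; for a
#'   vector, a list with `intercept` (vector) and `beta` (matrix, one column
#'   per lambda).
#' @export
enet_fit <- function(X, y, alpha, lambda, standardize = TRUE,
                     tol = 1e-7, max_iter = 100000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_gsfs("non-finite values in input")
  if (nrow(X) != length(y)) stop_gsfs("X and y dimensions disagree")
  if (!(alpha > 0 && alpha <= 1)) stop_gsfs("alpha must lie in (0, 1]")
  if (any(lambda < 0)) stop_gsfs("lambda must be >= 0")
  prep <- .enet_prep(X, y, standardize)
  lam <- sort(as.numeric(lambda), decreasing = TRUE)
  B <- .enet_cd_path(prep$X, prep$y, prep$xsq, lam, alpha, tol, as.integer(max_iter))
  B <- B / prep$sc                       # back to original scale
  ord <- match(as.numeric(lambda), lam)  # restore caller's order
  B <- B[, ord, drop = FALSE]
  intercept <- prep$ym - drop(crossprod(B, prep$xm))
  if (length(lambda) == 1L) {
    list(intercept = intercept[1L], beta = drop(B[, 1L]))
  } else {
    list(intercept = intercept, beta = B, lambda = as.numeric(lambda))
  }
}

# descending lambda path for one alpha on the full data
.lambda_path <- function(prep, alpha, config) {
  lmax <- .lambda_max(prep, alpha)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  # tiny headroom so the top of the path is exactly the all-zero model even
  # after floating-point differences in the inner products
  lmax <- lmax * (1 + 1e-9)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$lambda_path_length))
}

#' Cross-validated LASSO / elastic-net SNP selection with the 1SE rule
#'
#' For each mixing value `alpha` (a single `alpha = 1` in `"lasso"` mode,
#' the grid in `"en"` mode), a descending penalty path is fitted with k-fold
#' cross-validation; per `(alpha, lambda)` the mean and standard error of
#' the validation mean-squared error over folds are recorded. Within each
#' `alpha` the one-standard-error rule picks the largest penalty whose mean
#' CV error does not exceed the minimum mean error plus one standard error;
#' across the grid the pair with the smallest 1SE-rule CV error wins. The
#' winning model is refitted on all data and its nonzero coefficients form
#' the feature set.
#'
#' @param X Predictor matrix with SNP column names.
#' @param y Response vector.
#' @param config A [regularization_config()].
#' @param mode `"lasso"` or `"en"`.
#' @return A `feature_selection` object; `tidy()` gives the selected SNPs
#'   with coefficients, `glance()` the chosen `(alpha, lambda)` and CV error,
#'   `autoplot()` the CV curves. The `cv` element holds the full CV surface.
#' @export
cv_select_1se <- function(X, y, config = regularization_config(),
                          mode = c("lasso", "en")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < config$n_folds) stop_gsfs("fewer observations than folds")
  if (is.null(colnames(X))) colnames(X) <- sprintf("snp_%d", seq_len(ncol(X)))
  alphas <- if (mode == "lasso") 1 else config$alpha_grid
  folds <- withr::with_seed(config$fold_seed, {
    sample(rep_len(seq_len(config$n_folds), n))
  })

  prep_full <- .enet_prep(X, y, config$standardize)
  cv_rows <- vector("list", length(alphas))
  best <- NULL
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    lam <- .lambda_path(prep_full, a, config)
    errs <- matrix(NA_real_, config$n_folds, length(lam))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- enet_fit(X[tr, , drop = FALSE], y[tr], alpha = a, lambda = lam,
                      standardize = config$standardize, tol = config$cv_tol)
      pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2L, fit$intercept, `+`)
      errs[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    mean_err <- colMeans(errs)
    se_err <- apply(errs, 2L, sd) / sqrt(config$n_folds)
    i_min <- which.min(mean_err)
    # largest lambda (path is descending, so smallest index) within 1 SE
    i_1se <- min(which(mean_err <= mean_err[i_min] + se_err[i_min]))
    cv_rows[[ai]] <- tibble(alpha = a, lambda = lam,
                            mean_cv_error = mean_err, se_cv_error = se_err,
                            chosen = seq_along(lam) == i_1se)
    if (is.null(best) || mean_err[i_1se] < best$cv_error) {
      best <- list(alpha = a, lambda = lam[i_1se], cv_error = mean_err[i_1se],
                   cv_se = se_err[i_1se])
    }
  }
  refit <- enet_fit(X, y, alpha = best$alpha, lambda = best$lambda,
                    standardize = config$standardize)
  nz <- which(refit$beta != 0)
  if (!length(nz)) warn("feature selection returned an empty set")
  strategy <- if (mode == "lasso") "LASSO" else "EN"
  features <- tibble(snp_id = colnames(X)[nz],
                     coefficient = unname(refit$beta[nz]),
                     strategy = strategy,
                     alpha = best$alpha, lambda = best$lambda)
  structure(
    list(features = features, strategy = strategy,
         alpha = best$alpha, lambda = best$lambda,
         cv_error = best$cv_error, cv_se = best$cv_se,
         intercept = refit$intercept, n_selected = length(nz),
         cv = dplyr::bind_rows(cv_rows), folds = folds),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection>", x$strategy, "selected", x$n_selected,
      "SNPs at alpha =", x$alpha, "lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' @export
tidy.feature_selection <- function(x, ...) x$features

#' @export
glance.feature_selection <- function(x, ...) {
  tibble(strategy = x$strategy, alpha = x$alpha, lambda = x$lambda,
         n_selected = x$n_selected, cv_error = x$cv_error, cv_se = x$cv_se)
}

#' @export
autoplot.feature_selection <- function(object, ...) {
  cv <- object$cv
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data$mean_cv_error,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(cv, .data$chosen), size = 2) +
    ggplot2::labs(x = expression(log(lambda)), y = "CV mean squared error",
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
}

#' Comparator strategy: top N SNPs by association p-value
#'
#' Selects the `n` SNPs with the smallest mixed-model scan p-values, the
#' strategy conventionally paired against regularized-regression selection
#' with `n` matched to the LASSO or elastic-net selection size. Ties on the
#' p-value are broken by larger absolute effect, then by map order, so the
#' output is deterministic.
#'
#' @param result A `gwas_result`.
#' @param n Number of SNPs to keep.
#' @param strategy Label recorded for provenance (`"LMM_LASSO"` when `n`
#'   matches a LASSO set, `"LMM_EN"` for an elastic-net pairing).
#' @return A feature tibble (`snp_id`, `coefficient` = scan effect,
#'   `strategy`, `p_value`).
#' @export
top_n_by_pvalue <- function(result, n, strategy = c("LMM_LASSO", "LMM_EN")) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(result))
  n <- as.integer(n)
  if (n <= 0L) stop_gsfs("`n` must be positive")
  ok <- which(!is.na(result$p_value))
  if (n > length(ok)) stop_gsfs("`n` exceeds the number of tested SNPs")
  ord <- ok[order(result$p_value[ok], -abs(result$beta[ok]), ok)]
  sel <- sort(ord[seq_len(n)])
  tibble(snp_id = as.character(result$snp_id[sel]),
         coefficient = result$beta[sel],
         strategy = strategy,
         p_value = result$p_value[sel])
}
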