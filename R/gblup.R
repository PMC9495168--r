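#' Heterogeneous residual weights from DRP reliabilities
#'
#' The de-regressed proof of an individual with reliability `r2` carries
#' residual variance proportional to `d = (1 - r2) / r2`; these weights form
#' the diagonal of the residual covariance `sigma2_e D` in GBLUP. Weights
#' are floored at a small positive constant so that fully reliable proofs
#' (`r2 = 1`) keep the system well posed; floored individuals are flagged.
#'
#' @param reliabilities Reliabilities in (0, 1].
#' @param floor Lower bound on the weights (default `1e-6`).
#' @return A `residual_weights` object: `d` (weights) and `near_noiseless`
#'   (logical flags for floored entries).
#' @export
#' @examples
#' residual_weights(c(0.5, 0.4, 1))$d   # 1, 1.5, 1e-6
residual_weights <- function(reliabilities, floor = 1e-6) {
  r2 <- as.numeric(reliabilities)
  if (any(!is.finite(r2)) || any(r2 <= 0) || any(r2 > 1)) {
    stop_gsfs("reliabilities must lie in (0, 1]")
  }
  d <- (1 - r2) / r2
  flagged <- d < floor
  structure(list(d = pmax(d, floor), near_noiseless = flagged),
            class = "residual_weights")
}

.as_grm_list <- function(grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (!is.list(grms) || !all(vapply(grms, inherits, TRUE, "grm"))) {
    stop_gsfs("`grms` must be a grm or a list of grm objects")
  }
  if (is.null(names(grms))) {
    names(grms) <- if (length(grms) == 1L) "genomic" else
      sprintf("g%d", seq_along(grms))
  }
  grms
}

# Solve the mixed model at fixed variance components.
# V = sum_k s2[k] G_k + s2e D ; mu = (1'V^-1 y)/(1'V^-1 1) ; u = V^-1 (y - mu)
# component BLUPs a_k = s2[k] G_k u. Returns everything predict needs.
.gblup_solve_fixed <- function(y, Gs, s2, s2e, d) {
  n <- length(y)
  V <- diag(s2e * d, n)
  for (k in seq_along(Gs)) V <- V + s2[k] * Gs[[k]]
  ch <- tryCatch(chol(V), error = function(e) {
    stop_gsfs("phenotypic covariance matrix is singular or not PD; condition of V too poor")
  })
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  u <- Vinv_y - mu * Vinv_1
  a <- lapply(seq_along(Gs), function(k) drop(s2[k] * (Gs[[k]] %*% u)))
  names(a) <- names(Gs)
  list(mu = mu, u = u, components_blup = a, chol = ch)
}

#' Solve GBLUP at fixed variance components
#'
#' Direct conditional-mean solution of `y = 1 mu + sum_k a_k + e` with
#' `a_k ~ N(0, G_k sigma2_k)` and `e ~ N(0, D sigma2_e)`:
#' `a_k = sigma2_k G_k V^-1 (y - 1 mu)` with
#' `V = sum_k sigma2_k G_k + sigma2_e D` and GLS `mu`. Used internally by
#' [aireml_fit()] after convergence, and directly when components are known.
#'
#' @param y Phenotype vector (named with individual ids if prediction for
#'   other individuals will follow).
#' @param grms A `grm` or list of `grm` objects (rows/columns matching `y`).
#' @param components Per-GRM additive variances (same length/order as
#'   `grms`).
#' @param sigma2_e Residual variance.
#' @param weights Optional [residual_weights()]; default homogeneous
#'   (`D = I`).
#' @return List with `mu`, `gebv` (total), `components_blup` (per-GRM
#'   vectors) and `u = V^-1 (y - 1 mu)`.
#' @export
gblup_solve <- function(y, grms, components, sigma2_e, weights = NULL) {
  grms <- .as_grm_list(grms)
  y <- as.numeric(y)
  n <- length(y)
  Gs <- lapply(grms, function(g) {
    if (!all(dim(g$matrix) == n)) stop_gsfs("GRM dimension does not match phenotypes")
    g$matrix
  })
  d <- if (is.null(weights)) rep(1, n) else weights$d
  if (length(d) != n) stop_gsfs("weights length does not match phenotypes")
  sol <- .gblup_solve_fixed(y, Gs, as.numeric(components), sigma2_e, d)
  gebv <- Reduce(`+`, sol$components_blup)
  if (!all(is.finite(gebv))) stop_gsfs("non-finite GEBV")
  list(mu = sol$mu, gebv = gebv, components_blup = sol$components_blup, u = sol$u)
}

#' GBLUP variance components by average-information REML
#'
#' Fits `y = 1 mu + sum_k a_k + e`, `a_k ~ N(0, G_k sigma2_k)`,
#' `e ~ N(0, D sigma2_e)` by REML. Updates use the average-information
#' algorithm; whenever an AI step proposes a variance below the floor the
#' update for that iteration falls back to expectation-maximization, which
#' cannot leave the parameter space and cannot decrease the restricted
#' likelihood. Convergence is declared when the parameter change norm falls
#' below `tol` (relative to the parameter scale); hitting `max_iter` sets
#' `converged = FALSE` without raising, and downstream accuracy reporting
#' refuses unconverged fits unless forced.
#'
#' @param y Phenotype vector, named with individual ids when prediction for
#'   unphenotyped individuals is intended.
#' @param grms A `grm` or list of `grm` objects (one for a single additive
#'   term, two for split marker sets).
#' @param weights Optional [residual_weights()] (default `D = I`).
#' @param max_iter Iteration cap (default 1000).
#' @param tol Convergence tolerance on the parameter-change norm.
#' @param method `"ai"` (average information with EM fallback) or `"em"`
#'   (pure EM, slower but monotone; used for diagnostics).
#' @param var_floor Lower bound for variance components.
#' @return A `gblup_fit`: `mu`, `gebv` tibble (per individual, with one
#'   column per component), `components` (named additive variances),
#'   `sigma2_e`, `loglik`, `converged`, `n_iter`, `residuals`.
#' @export
aireml_fit <- function(y, grms, weights = NULL, max_iter = 1000L,
                       tol = 1e-8, method = c("ai", "em"),
                       var_floor = 1e-10) {
  method <- match.arg(method)
  grms <- .as_grm_list(grms)
  ids <- names(y) %||% sprintf("ind_%d", seq_along(y))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop_gsfs("need at least 3 individuals")
  Gs <- lapply(grms, function(g) {
    if (!all(dim(g$matrix) == n)) stop_gsfs("GRM dimension does not match phenotypes")
    g$matrix
  })
  d <- if (is.null(weights)) rep(1, n) else weights$d
  K <- length(Gs)
  vlist <- c(Gs, list(diag(d, n)))            # dV/dtheta for each component
  vy <- var(y)
  theta <- rep(vy / (K + 1), K + 1)           # (sigma2_1..K, sigma2_e)

  reml_ll <- function(theta) {
    V <- diag(theta[K + 1] * d, n)
    for (k in seq_len(K)) V <- V + theta[k] * Gs[[k]]
    ch <- chol(V)
    Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    s11 <- sum(Vinv_1)
    mu <- sum(Vinv_y) / s11
    Py <- Vinv_y - mu * Vinv_1
    -0.5 * (2 * sum(log(diag(ch))) + log(s11) + sum(y * Py) + (n - 1) * log(2 * pi))
  }

  converged <- FALSE
  ll <- -Inf
  ll_trace <- numeric(0)
  it <- 0L
  for (it in seq_len(max_iter)) {
    V <- diag(theta[K + 1] * d, n)
    for (k in seq_len(K)) V <- V + theta[k] * Gs[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      stop_gsfs(sprintf(
        "covariance matrix not positive definite at iteration %d (components: %s)",
        it, paste(signif(theta, 3), collapse = ", ")))
    }
    Vinv <- chol2inv(ch)
    Vinv_1 <- drop(Vinv %*% rep(1, n))
    s11 <- sum(Vinv_1)
    P <- Vinv - tcrossprod(Vinv_1) / s11
    u <- drop(P %*% y)

    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(s11) + sum(y * u) + (n - 1) * log(2 * pi))
    ll_trace <- c(ll_trace, ll)

    # scores and AI matrix
    score <- numeric(K + 1)
    vu <- vector("list", K + 1)
    for (k in seq_len(K + 1)) {
      Gk_u <- if (k <= K) drop(Gs[[k]] %*% u) else d * u
      vu[[k]] <- Gk_u
      trPG <- sum(P * vlist[[k]])       # tr(P G_k) via symmetry
      score[k] <- -0.5 * (trPG - sum(u * Gk_u))
    }
    AI <- matrix(0, K + 1, K + 1)
    Pv <- lapply(vu, function(v) drop(P %*% v))
    for (k in seq_len(K + 1)) {
      for (l in k:(K + 1)) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(vu[[k]] * Pv[[l]])
      }
    }

    proposal <- NULL
    if (method == "ai") {
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        # step-halving keeps the AI update inside the parameter space;
        # full fallback to EM only when even a tiny AI step is infeasible
        s <- 1
        while (s > 1e-6) {
          cand <- theta + s * step
          if (all(cand >= var_floor)) {
            proposal <- cand
            break
          }
          s <- s / 2
        }
      }
    }
    if (is.null(proposal) || any(!is.finite(proposal)) || any(proposal < var_floor)) {
      # EM update: cannot leave the parameter space, monotone in the REML ll
      proposal <- theta
      for (k in seq_len(K + 1)) {
        trPG <- sum(P * vlist[[k]])
        proposal[k] <- theta[k] + theta[k]^2 * (sum(u * vu[[k]]) - trPG) / n
      }
      proposal <- pmax(proposal, var_floor)
    }
    delta <- sqrt(sum((proposal - theta)^2)) / max(1, sqrt(sum(theta^2)))
    theta <- proposal
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ll <- reml_ll(theta)
  if (!converged) {
    warn(sprintf("AI-REML did not converge within %d iterations", max_iter))
  }

  sol <- .gblup_solve_fixed(y, Gs, theta[seq_len(K)], theta[K + 1], d)
  gebv_total <- Reduce(`+`, sol$components_blup)
  gebv <- tibble(id = ids, gebv = gebv_total)
  for (k in seq_len(K)) gebv[[names(Gs)[k]]] <- sol$components_blup[[k]]
  structure(
    list(mu = sol$mu,
         gebv = gebv,
         components = setNames(theta[seq_len(K)], names(Gs)),
         sigma2_e = theta[K + 1],
         residuals = y - sol$mu - gebv_total,
         u = sol$u,
         ids = ids,
         grm_names = names(Gs),
         weights = d,
         loglik = ll,
         loglik_trace = ll_trace,
         converged = converged,
         n_iter = it,
         method = method),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit>", length(x$ids), "individuals;",
      length(x$components), "genomic component(s)\n")
  cat("  mu =", signif(x$mu, 5), "\n")
  for (k in seq_along(x$components)) {
    cat("  sigma2_", names(x$components)[k], " = ",
        signif(x$components[k], 5), "\n", sep = "")
  }
  cat("  sigma2_e =", signif(x$sigma2_e, 5),
      "| converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' @export
tidy.gblup_fit <- function(x, ...) x$gebv

#' @export
glance.gblup_fit <- function(x, ...) {
  out <- tibble(mu = x$mu, sigma2_e = x$sigma2_e, loglik = x$loglik,
                converged = x$converged, n_iter = x$n_iter,
                n = length(x$ids))
  for (k in seq_along(x$components)) {
    out[[paste0("sigma2_", names(x$components)[k])]] <- x$components[k]
  }
  out
}

#' Predict GEBVs for individuals outside the fitted set
#'
#' Conditional-mean projection: for new individuals the breeding-value
#' prediction is `sum_k sigma2_k G_k[new, ref] V_ref^-1 (y_ref - 1 mu)`,
#' reusing `u = V^-1 (y - 1 mu)` stored in the fit. The supplied GRMs must
#' cover both fitted and new individuals (they are subset by id).
#'
#' @param object A `gblup_fit`.
#' @param grms `grm` or list of `grm` objects over all individuals, in the
#'   same order as the fit's GRMs.
#' @param ids Ids of the individuals to predict.
#' @param ... Unused.
#' @return Tibble `id`, `gebv`, plus one column per genomic component.
#' @export
predict.gblup_fit <- function(object, grms, ids, ...) {
  grms <- .as_grm_list(grms)
  if (length(grms) != length(object$components)) {
    stop_gsfs("number of GRMs does not match the fitted components")
  }
  comp <- vector("list", length(grms))
  for (k in seq_along(grms)) {
    M <- grms[[k]]$matrix
    if (is.null(rownames(M))) stop_gsfs("GRMs must carry individual ids for prediction")
    miss <- setdiff(c(ids, object$ids), rownames(M))
    if (length(miss)) stop_gsfs("GRM is missing individuals: ", paste(head(miss), collapse = ", "))
    comp[[k]] <- drop(M[ids, object$ids, drop = FALSE] %*%
                        (object$components[k] * object$u))
  }
  out <- tibble(id = ids, gebv = Reduce(`+`, comp))
  for (k in seq_along(comp)) out[[object$grm_names[k]]] <- comp[[k]]
  if (!all(is.finite(out$gebv))) stop_gsfs("non-finite GEBV prediction")
  out
}

#' @export
autoplot.gblup_fit <- function(object, ...) {
  df <- object$gebv
  df$deviation <- df$gebv + object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gebv, y = .data$deviation)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "GEBV", y = "phenotypic deviation (y - mu)") +
    ggplot2::theme_minimal()
}
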