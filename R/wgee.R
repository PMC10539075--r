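#' Weighted GEE logistic regression (independence working correlation)
#'
#' Fits a binary-outcome marginal model by solving the weighted quasi-score
#' equations
#' \deqn{U(\theta) = \sum_i x_i w_i (y_i - \mu_i(\theta)) = 0, \qquad
#'       \mathrm{logit}\,\mu_i = x_i^\top \theta,}
#' i.e. a weighted generalized estimating equation with independent subjects,
#' identity working correlation and Bernoulli variance.  With unit weights this
#' is exactly ordinary logistic regression.  The weights are analysis weights
#' in \eqn{(0, 1]} — typically 1 for subjects with observed disease status and
#' the classification confidence \eqn{\max(p, 1-p)} for subjects whose status
#' was imputed from an affection probability \eqn{p} (see
#' [impute_and_weight()]).
#'
#' Estimation is iteratively reweighted Fisher scoring with step-halving on
#' decreases of the weighted quasi-log-likelihood
#' \eqn{\sum_i w_i [y_i \log \mu_i + (1-y_i)\log(1-\mu_i)]}.  Convergence is
#' declared when the max-norm of the quasi-score drops below `tol`.  Both the
#' model-based covariance (inverse weighted expected information) and the
#' robust sandwich covariance are computed; the sandwich is the default for
#' inference whenever non-unit weights are in play.
#'
#' @param formula model formula with a binary (0/1 or logical/factor) response.
#' @param data data frame in which to evaluate `formula`.
#' @param weights optional vector of analysis weights in (0, 1]; default all 1.
#'   Evaluated in `data` first, like other modelling functions.
#' @param tol convergence tolerance on the max-norm of the quasi-score.
#' @param max_iter maximum number of Fisher scoring iterations.
#' @param check_separation if `TRUE`, error (naming the column) when a single
#'   predictor perfectly separates the response.
#' @return an object of class `"wgee"`: a list with components `coefficients`,
#'   `vcov_model`, `vcov_robust`, `fitted.values`, `linear.predictors`,
#'   `residuals` (response scale), `prior.weights`, `y`, `converged`, `iter`,
#'   `score_norm`, `quasi_loglik`, `df.residual`, `call`, `terms`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
#' f <- wgee(y ~ x, d)
#' summary(f)
#' wald_test(f, "x")
#' @seealso [wald_test()], [score_test()], [impute_and_weight()]
#' @export
wgee <- function(formula, data, weights = NULL, tol = 1e-8, max_iter = 50L,
                 check_separation = TRUE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w <- eval(substitute(weights), data, parent.frame())
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) != length(y)) stop("weights length does not match data")
  if (check_separation) .check_separation(X, y)
  fit <- wgee_fit(X, y, w, tol = tol, max_iter = max_iter)
  fit$call <- cl
  fit$terms <- attr(mf, "terms")
  fit
}

# Matrix-interface fitting path.  Every analysis method in the package (LR on
# labeled subjects, IP with unit weights, WIP with probability-derived
# weights), the simulation harness and the genome scan go through this one
# function; the methods differ only in the (subset, weight) inputs.
#' Low-level weighted GEE logistic fit
#'
#' Matrix interface to the estimator behind [wgee()]; useful when the design
#' matrix is already assembled (e.g. per-variant fits in a genome scan).
#'
#' @param X design matrix (including an intercept column if wanted).
#' @param y binary response vector.
#' @param w analysis weights, strictly positive. Default all 1.
#' @param tol,max_iter convergence control as in [wgee()].
#' @param start optional starting coefficients.
#' @return an object of class `"wgee"` (without formula/terms components).
#' @export
wgee_fit <- function(X, y, w = rep(1, length(y)), tol = 1e-8, max_iter = 50L,
                     start = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (is.null(start)) start <- numeric(ncol(X))
  res <- wgee_irls_cpp(X, as.double(y), as.double(w), tol,
                       as.integer(max_iter), as.double(start))
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))
  beta <- drop(res$coefficients)
  names(beta) <- cn
  vm <- res$vcov_model; vr <- res$vcov_robust
  dimnames(vm) <- dimnames(vr) <- list(cn, cn)
  nm <- names(y) %||% rownames(X)
  fitted <- drop(res$fitted); eta <- drop(res$linear_predictors)
  names(fitted) <- names(eta) <- nm
  y <- unname(y)
  structure(list(
    coefficients = beta,
    vcov_model = vm,
    vcov_robust = vr,
    fitted.values = fitted,
    linear.predictors = eta,
    residuals = y - fitted,
    prior.weights = w,
    y = y,
    converged = isTRUE(res$converged) && !isTRUE(res$singular),
    iter = res$iter,
    score_norm = res$score_norm,
    quasi_loglik = res$quasi_loglik,
    df.residual = length(y) - ncol(X),
    n = length(y),
    x = X
  ), class = "wgee")
}

# Flags a column whose range perfectly splits the two response classes.
.check_separation <- function(X, y) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (length(unique(x)) < 2L) next
    x1 <- x[y == 1]; x0 <- x[y == 0]
    if (length(x1) == 0L || length(x0) == 0L) next
    if (max(x1) < min(x0) || max(x0) < min(x1)) {
      stop("perfect separation by column '",
           colnames(X)[j] %||% j, "'")
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wgee <- function(x, ...) {
  cat("Weighted GEE logistic fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("n =", x$n, " iterations =", x$iter,
      " max|U| =", format(x$score_norm, digits = 3), "\n")
  cat("\nCoefficients:\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.wgee <- function(object, ...) object$coefficients

#' Covariance of a wgee fit
#' @param object a `"wgee"` fit.
#' @param type `"robust"` for the sandwich estimator (default), `"model"` for
#'   the inverse weighted expected information.
#' @param ... unused.
#' @export
vcov.wgee <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$vcov_robust else object$vcov_model
}

#' @export
summary.wgee <- function(object, vcov_type = c("robust", "model"), ...) {
  vcov_type <- match.arg(vcov_type)
  V <- vcov(object, type = vcov_type)
  se <- sqrt(diag(V))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = p)
  structure(list(coefficients = tab, vcov_type = vcov_type,
                 converged = object$converged, iter = object$iter,
                 n = object$n, call = object$call),
            class = "summary.wgee")
}

#' @export
print.summary.wgee <- function(x, ...) {
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("n =", x$n, "; covariance:", x$vcov_type,
      if (!x$converged) "; NOT converged", "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.wgee <- function(object, newdata = NULL,
                         type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    if (is.null(object$terms))
      stop("predict with newdata requires a formula-interface fit")
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
fitted.wgee <- function(object, ...) object$fitted.values

#' @export
residuals.wgee <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") {
    mu <- object$fitted.values
    r <- r / sqrt(mu * (1 - mu))
  }
  r
}

#' @export
nobs.wgee <- function(object, ...) object$n

#' Parametric simulation from a fitted wgee model
#'
#' Draws new binary responses from the fitted Bernoulli probabilities, one
#' column per requested replicate.
#' @param object a `"wgee"` fit.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed (an integer), as in [stats::simulate()].
#' @param ... unused.
#' @export
simulate.wgee <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Wald test of coefficients from a wgee fit
#'
#' Computes \eqn{W = \hat\beta^\top \mathrm{cov}(\hat\beta)^{-1} \hat\beta}
#' for the selected coefficients and refers it to a chi-squared distribution
#' with as many degrees of freedom as coefficients tested.
#'
#' @param fit a converged `"wgee"` fit.
#' @param which coefficient names or indices to test; default all non-intercept
#'   coefficients.
#' @param vcov_type `"robust"` (sandwich, default) or `"model"`.
#' @return an object of class `"wgee_test"` with `statistic`, `df`, `p.value`,
#'   `test = "wald"` and the covariance flavour used.
#' @export
wald_test <- function(fit, which = NULL, vcov_type = c("robust", "model")) {
  vcov_type <- match.arg(vcov_type)
  if (!inherits(fit, "wgee")) stop("'fit' must be a wgee fit")
  if (!fit$converged) stop("fit did not converge; refusing to test")
  cf <- fit$coefficients
  if (is.null(which)) {
    which <- setdiff(names(cf), "(Intercept)")
    if (length(which) == 0L) which <- names(cf)
  }
  b <- cf[which]
  V <- vcov(fit, type = vcov_type)[which, which, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance for the tested coefficients"))
  stat <- unname(drop(t(b) %*% Vi %*% b))
  df <- length(b)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 test = "wald", vcov_type = vcov_type,
                 coefficients = b),
            class = "wgee_test")
}

#' Generalized score test for added covariates
#'
#' Tests \eqn{H_0: \beta = 0} for covariates `g` added to a weighted null
#' model, without fitting the alternative.  With the nuisance coefficients
#' \eqn{\hat\alpha_0} solving the weighted null score equations, the partial
#' quasi-score is \eqn{U_P = \sum_i g_i w_i (y_i - \mu_i(\hat\alpha_0))} and
#' \deqn{T = U_P^\top \widehat{\mathrm{var}}(U_P)^{-1} U_P \sim \chi^2_{d}.}
#'
#' Two variance estimators are available.  `"model"` uses the weighted expected
#' information with the nuisance block projected out,
#' \eqn{I_{gg} - I_{gz} I_{zz}^{-1} I_{zg}} (with unit weights this is exactly
#' the classical Rao score test).  `"robust"` (default) uses the empirical
#' outer product of the per-subject effective scores
#' \eqn{s_i = w_i (y_i - \mu_i)(g_i - \hat g_i)}, where \eqn{\hat g_i} is the
#' weighted-information projection of `g` onto the null design — appropriate
#' when the weights are classification confidences rather than sampling
#' frequencies.
#'
#' @param null_fit a converged `"wgee"` fit of the covariate-only null model.
#' @param g vector or matrix of added covariate(s), aligned with the rows used
#'   in `null_fit` (e.g. SNP dosages).
#' @param X_null optional null-model design matrix; taken from the fit if it
#'   was produced by [wgee_fit()] with `keep_x = TRUE` or re-derivable.
#' @param vcov_type `"robust"` (default) or `"model"`.
#' @return a `"wgee_test"` object with `test = "score"`.
#' @export
score_test <- function(null_fit, g, X_null = NULL,
                       vcov_type = c("robust", "model")) {
  vcov_type <- match.arg(vcov_type)
  if (!inherits(null_fit, "wgee")) stop("'null_fit' must be a wgee fit")
  if (!null_fit$converged) stop("null model did not converge")
  G <- as.matrix(g)
  y <- null_fit$y
  if (nrow(G) != length(y)) stop("'g' length does not match the null fit")
  Z <- X_null %||% .design_of(null_fit)
  w <- null_fit$prior.weights
  mu <- null_fit$fitted.values
  v <- mu * (1 - mu)
  wv <- w * v
  U <- drop(crossprod(G, w * (y - mu)))            # partial quasi-score
  Izz <- crossprod(Z * wv, Z)
  Izg <- crossprod(Z * wv, G)
  Ghat <- Z %*% solve(Izz, Izg)                    # information projection
  R <- G - Ghat
  if (vcov_type == "model") {
    V <- crossprod(G * wv, G) - crossprod(Izg, solve(Izz, Izg))
  } else {
    S <- R * (w * (y - mu))                        # effective scores
    V <- crossprod(S)
  }
  df <- ncol(G)
  scale <- max(abs(crossprod(G * wv, G)), 1)
  if (max(abs(U)) < 1e-8 * scale) {
    # g lies in the span of the null design (e.g. constant): the partial
    # score vanishes identically and there is no evidence against H0
    stat <- 0
  } else {
    if (max(abs(V)) < 1e-10 * scale)
      stop("singular variance of the partial score")
    Vi <- tryCatch(solve(V), error = function(e)
      stop("singular variance of the partial score"))
    stat <- unname(drop(t(U) %*% Vi %*% U))
  }
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 test = "score", vcov_type = vcov_type, score = U),
            class = "wgee_test")
}

# Recover the design matrix of a fit (formula fits keep terms; wgee_fit keeps
# nothing, so the caller must pass X_null).
.design_of <- function(fit) {
  if (!is.null(fit$x)) return(fit$x)
  stop("pass 'X_null' (the null design matrix) for fits without stored design")
}

#' @export
print.wgee_test <- function(x, ...) {
  cat(sprintf("%s test (%s covariance): statistic = %.4g, df = %d, p = %.4g\n",
              x$test, x$vcov_type, x$statistic, x$df, x$p.value))
  invisible(x)
}
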