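#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits a binary logistic regression by iteratively reweighted least squares.
#' This is the fitting engine behind every association test in the package;
#' it is deliberately self-contained so that the likelihood, score and
#' observed-information matrix used by the interaction tests are explicit.
#'
#' Convergence is declared when the maximum absolute score (gradient of the
#' log-likelihood) falls below `score_tol` or the relative change in
#' log-likelihood falls below `ll_tol`, whichever comes first, within
#' `max_iter` iterations. Complete separation is guarded by flagging any fit
#' with a coefficient exceeding `beta_max` in absolute value as
#' non-converged rather than reporting an unstable estimate.
#'
#' @param x numeric design matrix (one row per individual, including an
#'   intercept column if one is wanted). Must be full rank.
#' @param y binary response vector (0/1), same length as `nrow(x)`.
#' @param max_iter maximum IRLS iterations.
#' @param score_tol convergence tolerance on the maximum absolute score.
#' @param ll_tol convergence tolerance on the relative log-likelihood change.
#' @param beta_max separation guard: any |coefficient| above this marks the
#'   fit non-converged.
#' @return an object of class `logistic_fit`: a list with elements
#'   `coefficients`, `vcov` (inverse observed information), `loglik`,
#'   `converged`, `iterations`, `n`, `fitted`.
#' @examples
#' x <- cbind(1, rnorm(100))
#' y <- rbinom(100, 1, plogis(x[, 2]))
#' fit <- fit_logistic(x, y)
#' coef(fit)
#' @export
fit_logistic <- function(x, y, max_iter = 100L, score_tol = 1e-8,
                         ll_tol = 1e-10, beta_max = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: all responses are ", y[1],
         "; logistic fit refused")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[seq.int(qx$rank + 1L, ncol(x))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  n <- nrow(x)
  p <- ncol(x)
  beta <- numeric(p)
  eta <- drop(x %*% beta)
  ll <- .loglik_bernoulli(y, eta)
  converged <- FALSE
  info <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    info <- crossprod(x, x * w)
    beta_new <- tryCatch(drop(solve(info, crossprod(x, w * z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    eta <- drop(x %*% beta_new)
    ll_new <- .loglik_bernoulli(y, eta)
    score <- crossprod(x, y - stats::plogis(eta))
    beta <- beta_new
    if (max(abs(score)) < score_tol ||
        abs(ll_new - ll) < ll_tol * (abs(ll) + ll_tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * pmax(mu * (1 - mu), 1e-10))
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  })
  if (any(abs(beta) > beta_max) || anyNA(vcov)) converged <- FALSE
  names(beta) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(coefficients = beta, vcov = vcov, loglik = ll,
                 converged = converged, iterations = iter, n = n,
                 fitted = mu, y = y),
            class = "logistic_fit")
}

.loglik_bernoulli <- function(y, eta) {
  # numerically stable sum of y*eta - log(1 + exp(eta))
  sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
}

#' Likelihood-ratio test between two nested logistic fits
#'
#' @param full,reduced `logistic_fit` objects, `reduced` nested in `full`.
#' @param df degrees of freedom of the test (default: difference in the
#'   number of coefficients).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_logistic <- function(full, reduced, df = NULL) {
  if (is.null(df)) {
    df <- length(full$coefficients) - length(reduced$coefficients)
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression fit (IRLS), n =", x$n, "\n")
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$coefficients, se = se,
               z = x$coefficients / se,
               p = 2 * stats::pnorm(-abs(x$coefficients / se)))
  print(round(tab, 6))
  cat("log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
residuals.logistic_fit <- function(object, type = c("response", "pearson"),
                                   ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  }
  r
}

#' Nagelkerke pseudo-R-squared from two nested fits
#'
#' Cox-Snell R2 rescaled to a \[0, 1\] maximum, computed against an
#' intercept-only null fit.
#'
#' @param fit a `logistic_fit` for the model of interest.
#' @param null_fit a `logistic_fit` for the intercept-only model on the same
#'   data.
#' @return numeric pseudo-R2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  n <- fit$n
  r2_cs <- 1 - exp(-2 * (fit$loglik - null_fit$loglik) / n)
  r2_max <- 1 - exp(2 * null_fit$loglik / n)
  max(0, min(1, r2_cs / r2_max))
}

#' McFadden pseudo-R-squared
#' @inheritParams nagelkerke_r2
#' @return numeric pseudo-R2.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  max(0, 1 - fit$loglik / null_fit$loglik)
}
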