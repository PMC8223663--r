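#' Firth bias-reduced logistic regression
#'
#' Fits a logistic regression by maximizing the penalized log-likelihood
#' \deqn{l^*(\beta) = l(\beta) + \tfrac12 \log |I(\beta)|,}
#' where \eqn{I(\beta) = X^T W X} is the Fisher information and
#' \eqn{W = \mathrm{diag}\{\pi_i(1-\pi_i)\}}. The penalty removes the
#' leading-order bias of the maximum-likelihood estimate and guarantees
#' finite coefficients even under complete separation, which makes it the
#' standard engine for rare binary outcomes (a few hundred exposed
#' participants in a cohort of hundreds of thousands).
#'
#' The solver is Newton--Raphson on the modified score
#' \deqn{U^*_r = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\} x_{ir},}
#' with \eqn{h_i} the hat-matrix leverages, using step-halving whenever a
#' step fails to increase the penalized likelihood. The information solve
#' is preconditioned to correlation form so that covariates on very
#' different scales (age in years next to ancestry principal components)
#' do not degrade the Cholesky factorization; all results are reported on
#' the original covariate scale.
#'
#' @param X numeric design matrix (n rows, p columns) including an
#'   intercept column if one is wanted; must have column names.
#' @param y binary response vector of 0/1 values, length n.
#' @param max_iter maximum Newton iterations (default 100).
#' @param tol_score convergence tolerance on the maximum absolute modified
#'   score component (default 1e-6).
#' @param tol_beta convergence tolerance on the maximum absolute coefficient
#'   update (default 1e-8).
#' @param max_halvings maximum step-halvings per Newton step (default 5).
#'
#' @return an object of class `firth_fit`: a list with elements `beta`
#'   (named coefficient vector, log-odds scale), `se` (Wald standard
#'   errors), `loglik` (penalized log-likelihood at the maximum),
#'   `fitted` (per-observation probabilities), `hat` (leverages, summing
#'   to p), `vcov`, `converged`, `n_iter`, `n`, and the data (`X`, `y`)
#'   for downstream profiling.
#'
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 1, 0.3)
#' y <- rbinom(200, 1, plogis(-2 + x))
#' fit <- fit_firth(cbind(intercept = 1, exposure = x), y)
#' coef(fit)
#' @seealso [firth_confint()] for profile penalized-likelihood intervals,
#'   [firth_plrt()] for penalized likelihood-ratio tests.
#' @export
fit_firth <- function(X, y, max_iter = 100, tol_score = 1e-6,
                      tol_beta = 1e-8, max_halvings = 5) {
  fit <- firth_engine(X, y, max_iter = max_iter, tol_score = tol_score,
                      tol_beta = tol_beta, max_halvings = max_halvings)
  fit$X <- fit$Xfull
  fit$Xfull <- NULL
  class(fit) <- "firth_fit"
  fit
}

# Core constrained maximizer of the penalized likelihood.
#
# Maximizes l(beta) + 0.5 log|X'WX| over the coefficients in `free`
# (all, by default), holding the others fixed at `fixed_values`. The
# penalty always uses the FULL p x p information, so constrained calls
# yield the profile penalized likelihood used for CIs and LRTs.
firth_engine <- function(X, y, free = seq_len(ncol(X)), fixed_values = NULL,
                         max_iter = 100, tol_score = 1e-6, tol_beta = 1e-8,
                         max_halvings = 5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y; drop incomplete rows upstream")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (n <= p) stop("need more observations than parameters (n > p)")

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- numeric(p)
  names(beta) <- colnames(X)
  fixed <- setdiff(seq_len(p), free)
  if (length(fixed)) beta[fixed] <- fixed_values

  info_pieces <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    w <- pmax(pi * (1 - pi), .Machine$double.xmin)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    # precondition to correlation form for the solve / determinant
    d <- sqrt(diag(XtWX))
    R <- XtWX / tcrossprod(d)
    ch <- chol(R)
    logdet <- 2 * sum(log(diag(ch))) + 2 * sum(log(d))
    Rinv <- chol2inv(ch)
    Vinv <- Rinv / tcrossprod(d)          # (X'WX)^{-1}
    h <- rowSums((XW %*% Vinv) * XW)
    ll <- sum(y * eta - log1p(exp(eta))) + 0.5 * logdet
    list(eta = eta, pi = pi, h = h, Vinv = Vinv, ll = ll)
  }

  st <- info_pieces(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    resid <- y - st$pi + st$h * (0.5 - st$pi)
    U <- drop(crossprod(X, resid))
    if (length(fixed)) U[fixed] <- 0
    if (max(abs(U)) < tol_score && iter > 1L) { converged <- TRUE; break }
    if (iter > max_iter) break
    # Newton step restricted to the free coordinates
    Vf <- st$Vinv[free, free, drop = FALSE]
    # use the free-block information for the step direction
    eta <- st$eta
    w <- pmax(st$pi * (1 - st$pi), .Machine$double.xmin)
    Xf <- X[, free, drop = FALSE]
    If <- crossprod(Xf * sqrt(w))
    df <- sqrt(diag(If))
    step <- drop((solve(If / tcrossprod(df), U[free] / df)) / df)
    new_beta <- beta
    new_beta[free] <- beta[free] + step
    new_st <- info_pieces(new_beta)
    halve <- 0L
    while (!is.finite(new_st$ll) || new_st$ll < st$ll) {
      halve <- halve + 1L
      if (halve > max_halvings) break
      step <- step / 2
      new_beta[free] <- beta[free] + step
      new_st <- info_pieces(new_beta)
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    st <- new_st
    if (delta < tol_beta && max(abs(U)) < tol_score) { converged <- TRUE; break }
  }

  se <- sqrt(pmax(diag(st$Vinv), 0))
  names(se) <- colnames(X)
  list(beta = beta, se = se, loglik = st$ll, fitted = st$pi, hat = st$h,
       vcov = st$Vinv, converged = converged, n_iter = iter, n = n, p = p,
       free = free, Xfull = X, y = y)
}

#' @export
coef.firth_fit <- function(object, ...) object$beta

#' @export
logLik.firth_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, class = "logLik")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized-likelihood logistic fit\n")
  cat(sprintf("n = %d, p = %d, penalized logLik = %.4f, %s in %d iterations\n",
              x$n, x$p, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(data.frame(coef = x$beta, se = x$se, or = exp(x$beta)))
  invisible(x)
}

# Profile penalized log-likelihood at a fixed value of one coefficient.
profiled_loglik <- function(fit, index, value) {
  con <- firth_engine(fit$X, fit$y, free = setdiff(seq_len(fit$p), index),
                      fixed_values = value)
  con$loglik
}

#' Confidence intervals for a Firth fit
#'
#' Profile penalized-likelihood intervals (the default) invert the
#' penalized likelihood-ratio test: the bounds are the coefficient values
#' at which the penalized log-likelihood, maximized over all other
#' coefficients, drops by \eqn{\chi^2_1(level)/2} (1.9207 at 95%) from its
#' maximum. These intervals are asymmetric where the likelihood is, which
#' is typical for rare exposures. Wald intervals
#' (\eqn{\hat\beta \pm z \cdot SE}) are available via `type = "wald"`.
#'
#' @param fit a `firth_fit` object.
#' @param parm coefficient index or name (default: all coefficients).
#' @param level confidence level (default 0.95).
#' @param type `"profile"` or `"wald"`.
#' @param bound_limit absolute log-odds value beyond which a profile bound
#'   is reported as open (`-Inf`/`Inf`); default 20.
#' @return matrix with columns `low`, `high` (log-odds scale) and one row
#'   per requested coefficient; attribute `open` flags unbracketed bounds.
#' @export
firth_confint <- function(fit, parm = seq_len(fit$p), level = 0.95,
                          type = c("profile", "wald"), bound_limit = 20) {
  type <- match.arg(type)
  if (is.character(parm)) parm <- match(parm, names(fit$beta))
  if (anyNA(parm)) stop("unknown coefficient name in 'parm'")
  z <- qnorm(1 - (1 - level) / 2)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(names(fit$beta)[parm], c("low", "high")))
  open <- matrix(FALSE, length(parm), 2)
  if (type == "wald") {
    out[, 1] <- fit$beta[parm] - z * fit$se[parm]
    out[, 2] <- fit$beta[parm] + z * fit$se[parm]
  } else {
    target <- fit$loglik - qchisq(level, 1) / 2
    for (k in seq_along(parm)) {
      j <- parm[k]
      for (side in 1:2) {
        dir <- if (side == 1) -1 else 1
        step <- if (is.finite(fit$se[j]) && fit$se[j] > 0) fit$se[j] else 0.5
        b0 <- fit$beta[j]
        b1 <- b0 + dir * step
        g <- function(b) profiled_loglik(fit, j, b) - target
        while (g(b1) > 0 && abs(b1) < bound_limit) b1 <- b0 + 2 * (b1 - b0)
        if (abs(b1) >= bound_limit && g(b1) > 0) {
          out[k, side] <- dir * Inf
          open[k, side] <- TRUE
        } else {
          out[k, side] <- uniroot(g, sort(c(b0, b1)), tol = 1e-7)$root
        }
      }
    }
  }
  attr(out, "open") <- open
  attr(out, "level") <- level
  attr(out, "type") <- type
  out
}

#' Penalized likelihood-ratio test between nested Firth fits
#'
#' Compares two Firth fits of the same data where the null model fixes one
#' or more of the full model's coefficients at zero. To keep the test
#' consistent with the profile confidence intervals, the null penalized
#' likelihood is computed under the full model's information penalty
#' (i.e. the constrained maximum of the full penalized likelihood).
#'
#' @param fit_full `firth_fit` for the full model.
#' @param fit_null either a `firth_fit` whose columns are a strict subset
#'   of the full model's columns, or a character vector naming the full
#'   model's terms to constrain to zero.
#' @return a list with `statistic` (the penalized deviance), `df`, and `p`.
#' @export
firth_plrt <- function(fit_full, fit_null) {
  if (is.character(fit_null)) {
    drop_cols <- fit_null
  } else {
    if (!inherits(fit_null, "firth_fit")) stop("fit_null must be a firth_fit or term names")
    if (fit_null$n != fit_full$n) stop("models fitted to different numbers of rows; not nested")
    drop_cols <- setdiff(colnames(fit_full$X), colnames(fit_null$X))
    if (length(drop_cols) == 0 ||
        !all(colnames(fit_null$X) %in% colnames(fit_full$X)))
      stop("null model does not nest within the full model")
  }
  idx <- match(drop_cols, colnames(fit_full$X))
  if (anyNA(idx)) stop("unknown term(s): ", paste(drop_cols[is.na(idx)], collapse = ", "))
  con <- firth_engine(fit_full$X, fit_full$y,
                      free = setdiff(seq_len(fit_full$p), idx),
                      fixed_values = rep(0, length(idx)))
  stat <- max(0, 2 * (fit_full$loglik - con$loglik))
  df <- length(idx)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
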