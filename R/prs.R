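#' Residualize a polygenic score on ancestry principal components
#'
#' Regresses the polygenic risk score on the first principal components of
#' ancestry by least squares and returns the standardized residuals (mean
#' 0, SD 1), removing ancestry-correlated differences in score
#' calibration before association analysis.
#'
#' @param prs numeric score vector.
#' @param pcs matrix or data.frame of principal components (typically 10
#'   columns), no missing values among included rows.
#' @return standardized residual vector.
#' @export
residualize_prs <- function(prs, pcs) {
  pcs <- as.matrix(pcs)
  if (anyNA(prs) || anyNA(pcs)) stop("missing values in prs or pcs")
  X <- cbind(1, pcs)
  if (qr(X)$rank < ncol(X)) stop("collinear principal components")
  res <- lm.fit(X, prs)$residuals
  s <- sd(res)
  if (s < sqrt(.Machine$double.eps) * max(1, sd(prs)))
    stop("residuals have (near-)zero variance: the score is fully explained by the PCs")
  (res - mean(res)) / s
}

#' Polygenic-score SD-equivalent of a carrier odds ratio
#'
#' Expresses a rare-variant carrier effect on the scale of a polygenic
#' score: the number of standard deviations of PRS conferring the same
#' log-odds, \eqn{\ln(OR_{carrier}) / \ln(OR_{perSD})}, assuming log-linear
#' PRS risk.
#'
#' @param or_carrier carrier odds ratio (> 0).
#' @param or_per_sd odds ratio per SD of the score (> 0, != 1).
#' @return SD units (numeric scalar).
#' @examples
#' sd_equivalent(3.07, 1.26)  # 4.85 SD
#' @export
sd_equivalent <- function(or_carrier, or_per_sd) {
  if (or_carrier <= 0 || or_per_sd <= 0) stop("odds ratios must be positive")
  if (or_per_sd == 1) stop("or_per_sd = 1: SD-equivalence undefined (zero per-SD log-odds)")
  log(or_carrier) / log(or_per_sd)
}

#' Population upper-tail percentage for an SD shift
#'
#' One-sided normal tail: the percentage of the population whose score
#' exceeds `sd_units` standard deviations, \eqn{100\{1 - \Phi(z)\}}.
#'
#' @param sd_units numeric, finite.
#' @return percentage in `[0, 100]`.
#' @export
upper_tail_percent <- function(sd_units) {
  stopifnot(all(is.finite(sd_units)))
  100 * pnorm(sd_units, lower.tail = FALSE)
}

#' PRS risk-equivalence summary
#'
#' Combines the carrier and per-SD odds ratios (with the relevant CI
#' bounds) into three SD-equivalence statistics: `average` (point
#' estimates), `conservative` (lower carrier CI bound over the per-SD
#' point estimate) and `most_conservative` (lower carrier CI bound over
#' the upper per-SD CI bound), each with the corresponding one-sided
#' population upper-tail percentage.
#'
#' @param or_carrier,or_carrier_ci_low carrier odds ratio and its lower
#'   95% bound.
#' @param or_per_sd,or_per_sd_ci_high per-SD odds ratio and its upper 95%
#'   bound.
#' @return object of class `prs_equivalence`: a list of the inputs, the
#'   three SD equivalents and their upper-tail percentages.
#' @examples
#' prs_equivalence(3.07, 1.81, 1.26, 1.32)
#' @export
prs_equivalence <- function(or_carrier, or_carrier_ci_low,
                            or_per_sd, or_per_sd_ci_high) {
  sd_avg <- sd_equivalent(or_carrier, or_per_sd)
  sd_cons <- sd_equivalent(or_carrier_ci_low, or_per_sd)
  sd_most <- sd_equivalent(or_carrier_ci_low, or_per_sd_ci_high)
  out <- list(or_carrier = or_carrier, or_carrier_ci_low = or_carrier_ci_low,
              or_per_sd = or_per_sd, or_per_sd_ci_high = or_per_sd_ci_high,
              sd_equivalent_average = sd_avg,
              sd_equivalent_conservative = sd_cons,
              sd_equivalent_most_conservative = sd_most,
              population_upper_percent = c(
                average = upper_tail_percent(sd_avg),
                conservative = upper_tail_percent(sd_cons),
                most_conservative = upper_tail_percent(sd_most)))
  class(out) <- "prs_equivalence"
  out
}

#' @export
print.prs_equivalence <- function(x, ...) {
  cat(sprintf("Carrier OR %.2f (lower CI %.2f); PRS OR per SD %.2f (upper CI %.2f)\n",
              x$or_carrier, x$or_carrier_ci_low, x$or_per_sd, x$or_per_sd_ci_high))
  cat(sprintf("SD equivalents: average %.2f, conservative %.2f, most conservative %.2f\n",
              x$sd_equivalent_average, x$sd_equivalent_conservative,
              x$sd_equivalent_most_conservative))
  cat(sprintf("Upper-tail population percentages: %.2g%%, %.1f%%, %.1f%%\n",
              x$population_upper_percent[1], x$population_upper_percent[2],
              x$population_upper_percent[3]))
  invisible(x)
}

#' Carrier-by-PRS interaction test
#'
#' Tests whether the polygenic score modifies carrier penetrance, in two
#' forms: `continuous` fits a Firth model with carrier, PRS and their
#' product and tests the product term by penalized LRT (1 df);
#' `categorical` cuts the residualized PRS at its 20th and 80th sample
#' percentiles (linear-interpolation quantiles, left-closed intervals)
#' into low / intermediate / high groups and tests the carrier-by-group
#' interaction (2 df).
#'
#' @param cohort data.frame with the outcome, `carrier`, and `prs`
#'   (residualized) columns plus any adjustment covariates.
#' @param outcome binary outcome column name.
#' @param type `"continuous"` or `"categorical"`.
#' @param adjustment covariate column names.
#' @return list with `p`, `df`, `statistic`, `type`, and for the
#'   categorical form the group sizes and a per-group zero-carrier flag.
#' @export
interaction_test <- function(cohort, outcome, type = c("continuous", "categorical"),
                             adjustment = character()) {
  type <- match.arg(type)
  cols <- c(outcome, "carrier", "prs", adjustment)
  dat <- cohort[complete.cases(cohort[cols]), cols, drop = FALSE]
  y <- dat[[outcome]]
  base <- if (length(adjustment))
    model.matrix(as.formula(paste("~", paste(adjustment, collapse = "+"))), dat)
  else matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  colnames(base)[1] <- "intercept"
  car <- as.numeric(dat$carrier)
  flagged <- FALSE
  if (type == "continuous") {
    X <- cbind(base, carrier = car, prs = dat$prs, carrier_prs = car * dat$prs)
    fit <- fit_firth(X, y)
    t <- firth_plrt(fit, "carrier_prs")
    groups <- NULL
  } else {
    qs <- quantile(dat$prs, c(0.2, 0.8), type = 7)
    grp <- cut(dat$prs, c(-Inf, qs, Inf), labels = c("low", "intermediate", "high"),
               right = FALSE)
    groups <- table(grp)
    flagged <- any(tapply(car, grp, sum) == 0)
    g_int <- as.numeric(grp == "intermediate")
    g_high <- as.numeric(grp == "high")
    X <- cbind(base, carrier = car, g_int = g_int, g_high = g_high,
               carrier_int = car * g_int, carrier_high = car * g_high)
    fit <- fit_firth(X, y)
    t <- firth_plrt(fit, c("carrier_int", "carrier_high"))
  }
  list(p = t$p, df = t$df, statistic = t$statistic, type = type,
       group_sizes = groups, zero_carrier_group = flagged)
}
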