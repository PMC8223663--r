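#' Transform a phenotype vector
#'
#' Applies one of the transforms used for non-normal phenotypes before
#' linear modelling: natural log (strictly positive measures such as HDL,
#' triglycerides, CRP and WMH volume), rank-based inverse-normal with Blom
#' offsets (heavily skewed measures such as Lp(a) and regional WMH
#' scores), or square root (lesion counts). Missing values are preserved;
#' the inverse-normal transform ranks non-missing values only, using
#' average ranks for ties: \eqn{\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}}.
#'
#' @param values numeric vector.
#' @param kind one of `"none"`, `"natural-log"`, `"inverse-normal"`,
#'   `"square-root"`.
#' @return transformed vector, same length and missingness pattern.
#' @examples
#' apply_transform(c(5, 1, 9), "inverse-normal")
#' @export
apply_transform <- function(values, kind = c("none", "natural-log",
                                             "inverse-normal", "square-root")) {
  kind <- match.arg(kind)
  ok <- !is.na(values)
  if (kind == "none") return(values)
  if (kind == "natural-log") {
    bad <- which(ok & values <= 0)
    if (length(bad))
      stop("natural-log transform needs strictly positive values; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    return(log(values))
  }
  if (kind == "square-root") {
    bad <- which(ok & values < 0)
    if (length(bad))
      stop("square-root transform needs non-negative values; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    return(sqrt(values))
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up false-discovery-rate control at level `q`; a thin wrapper over
#' [stats::p.adjust()] returning logical flags that are monotone in p.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical rejection vector.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH") <= q
}

# Build a complete-case design matrix (intercept + exposure + covariates)
# from a cohort data.frame; factors expand to treatment dummies.
build_design <- function(cohort, outcome, exposure, adjustment) {
  cols <- c(outcome, exposure, adjustment)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  dat <- cohort[cols]
  keep <- complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  rhs <- paste(c(exposure, adjustment), collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), data = dat)
  colnames(X)[1] <- "intercept"
  list(X = X, y = dat[[outcome]], n_used = nrow(dat),
       n_dropped = sum(!keep), exposure_col = colnames(X)[2])
}

#' Association of carrier status with a binary outcome
#'
#' Fits a Firth penalized-likelihood logistic regression of the outcome on
#' carrier status plus the adjustment covariates, on complete cases for
#' that model. The default inference matches the CI method to the test:
#' profile penalized-likelihood intervals and a penalized likelihood-ratio
#' p-value for the carrier term; Wald versions are available for
#' simulation loops where speed matters.
#'
#' @param cohort data.frame with the outcome, exposure and covariates.
#' @param outcome name of a 0/1 outcome column.
#' @param adjustment character vector of covariate column names (possibly
#'   empty for a crude model).
#' @param exposure exposure column name (default `"carrier"`).
#' @param ci_type `"profile"` or `"wald"`.
#' @param p_type `"plrt"` or `"wald"`.
#' @param level confidence level.
#' @return one-row data.frame (an association result): `outcome`, `model`,
#'   `effect` (odds ratio), `ci_low`, `ci_high`, `p`, `n_used`,
#'   `transform`, `adjustment`, `degenerate`.
#' @export
fit_binary_outcome <- function(cohort, outcome, adjustment = character(),
                               exposure = "carrier",
                               ci_type = c("profile", "wald"),
                               p_type = c("plrt", "wald"), level = 0.95) {
  ci_type <- match.arg(ci_type)
  p_type <- match.arg(p_type)
  d <- build_design(cohort, outcome, exposure, adjustment)
  degenerate <- FALSE
  if (sum(d$X[, 2] != 0) == 0 || length(unique(d$y)) < 2) degenerate <- TRUE
  if (degenerate)
    return(data.frame(outcome = outcome, model = "firth-logistic",
                      effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, n_used = d$n_used, transform = "none",
                      adjustment = paste(adjustment, collapse = "+"),
                      degenerate = TRUE, stringsAsFactors = FALSE))
  fit <- fit_firth(d$X, d$y)
  j <- d$exposure_col
  ci <- firth_confint(fit, parm = j, level = level, type = ci_type)
  p <- if (p_type == "plrt") firth_plrt(fit, j)$p else
    2 * pnorm(-abs(fit$beta[j] / fit$se[j]))
  data.frame(outcome = outcome, model = "firth-logistic",
             effect = exp(unname(fit$beta[j])),
             ci_low = exp(ci[1, "low"]), ci_high = exp(ci[1, "high"]),
             p = unname(p), n_used = d$n_used, transform = "none",
             adjustment = paste(adjustment, collapse = "+"),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Association of carrier status with a continuous outcome
#'
#' Transforms the outcome, z-scores it on the complete-case analysis
#' sample, and fits an ordinary linear regression on carrier status plus
#' covariates, so the carrier coefficient is a standardized difference in
#' SD units with a normal-theory confidence interval.
#'
#' @inheritParams fit_binary_outcome
#' @param transform transform applied before z-scoring (see
#'   [apply_transform()]).
#' @return one-row association-result data.frame (`effect` is the
#'   standardized difference).
#' @export
fit_continuous_outcome <- function(cohort, outcome, transform = "none",
                                   adjustment = character(),
                                   exposure = "carrier", level = 0.95) {
  d0 <- cohort
  d0[[outcome]] <- apply_transform(cohort[[outcome]], transform)
  d <- build_design(d0, outcome, exposure, adjustment)
  z <- d$y
  if (sd(z) == 0) stop("outcome '", outcome, "' has zero variance after transform")
  z <- (z - mean(z)) / sd(z)
  df <- as.data.frame(d$X[, -1, drop = FALSE])
  fit <- lm(z ~ ., data = df)
  j <- d$exposure_col
  est <- coef(fit)[[j]]
  ci <- confint(fit, j, level = level)
  p <- summary(fit)$coefficients[j, 4]
  data.frame(outcome = outcome, model = "linear",
             effect = est, ci_low = ci[1], ci_high = ci[2], p = unname(p),
             n_used = d$n_used, transform = transform,
             adjustment = paste(adjustment, collapse = "+"),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Carrier versus non-carrier descriptive comparison
#'
#' Builds a demographic comparison table: for each variable, per-group
#' summaries and a p-value from Pearson's chi-square test (categorical,
#' without continuity correction) or the pooled-variance two-sample t-test
#' (continuous).
#'
#' @param cohort data.frame.
#' @param variables character vector of column names to compare.
#' @param group name of the two-level grouping column (default `"carrier"`).
#' @return data.frame with one row per variable: `variable`, `type`,
#'   `group1`, `group0` (formatted summaries), `p`.
#' @export
descriptive_table <- function(cohort, variables, group = "carrier") {
  g <- as.integer(cohort[[group]])
  if (length(unique(g[!is.na(g)])) != 2) stop("grouping column must have two levels")
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; gg <- g[ok]
    if (!length(x) || min(table(gg)) < 2) stop("empty or near-empty group for '", v, "'")
    if (is.numeric(x) && length(unique(x)) > 2) {
      tt <- t.test(x[gg == 1], x[gg == 0], var.equal = TRUE)
      data.frame(variable = v, type = "continuous",
                 group1 = sprintf("%.1f (%.1f)", mean(x[gg == 1]), sd(x[gg == 1])),
                 group0 = sprintf("%.1f (%.1f)", mean(x[gg == 0]), sd(x[gg == 0])),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(gg, levels = c(1, 0)), x)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      lvl <- colnames(tab)[ncol(tab)]  # summarize the last level (e.g. "1")
      data.frame(variable = v, type = "categorical",
                 group1 = sprintf("%d (%.0f)", tab["1", lvl],
                                  100 * tab["1", lvl] / sum(tab["1", ])),
                 group0 = sprintf("%d (%.0f)", tab["0", lvl],
                                  100 * tab["0", lvl] / sum(tab["0", ])),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Global cognitive composite
#'
#' Z-scores each cognitive test on the analysis sample, flips tests whose
#' polarity is reversed (e.g. reaction time, where larger is worse), and
#' averages the available z-scores per participant. Participants with no
#' non-missing test get `NA`.
#'
#' @param test_scores data.frame (or matrix) of per-test scores, one row
#'   per participant.
#' @param polarity named numeric vector of +1/-1 per test column; defaults
#'   to +1 for every column.
#' @return numeric composite vector, one value per row.
#' @export
cognitive_composite <- function(test_scores, polarity = NULL) {
  m <- as.matrix(test_scores)
  if (is.null(polarity)) polarity <- setNames(rep(1, ncol(m)), colnames(m))
  if (!all(colnames(m) %in% names(polarity)))
    stop("polarity map missing test(s): ",
         paste(setdiff(colnames(m), names(polarity)), collapse = ", "))
  z <- scale(m)
  z <- sweep(z, 2, polarity[colnames(m)], `*`)
  out <- rowMeans(z, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Restrict binary outcomes to incident events
#'
#' Recodes an outcome to 1 only when its event date falls strictly after
#' recruitment and on or before the follow-up cutoff; prevalent-at-baseline
#' cases are recoded 0 (excluded from the incident definition).
#'
#' @param cohort data.frame.
#' @param outcome binary outcome column name; its event dates are taken
#'   from `paste0(outcome, "_date")` unless `date_col` is given.
#' @param recruitment_col column of recruitment dates (default
#'   `"recruitment_date"`).
#' @param cutoff_date latest follow-up date (default `"2019-03-31"`).
#' @param date_col optional event-date column name.
#' @return the cohort with the outcome column recoded to incident status.
#' @export
incident_filter <- function(cohort, outcome, recruitment_col = "recruitment_date",
                            cutoff_date = as.Date("2019-03-31"), date_col = NULL) {
  if (is.null(date_col)) date_col <- paste0(outcome, "_date")
  ev <- as.Date(cohort[[date_col]])
  rec <- as.Date(cohort[[recruitment_col]])
  cutoff_date <- as.Date(cutoff_date)
  y <- cohort[[outcome]]
  if (any(y == 1 & is.na(ev), na.rm = TRUE))
    stop("event date missing for some cases of '", outcome, "'")
  if (any(ev > cutoff_date, na.rm = TRUE))
    stop("event date after the follow-up cutoff for '", outcome, "'")
  incident <- !is.na(y) & y == 1 & !is.na(ev) & ev > rec & ev <= cutoff_date
  cohort[[outcome]] <- ifelse(is.na(y), NA_integer_, as.integer(incident))
  cohort
}
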