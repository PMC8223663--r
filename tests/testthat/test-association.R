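test_that("transforms match hand-computed values and preserve missingness", {
  # Blom inverse-normal of [5, 1, 9]: ranks 2,1,3 -> (r-3/8)/(3+1/4)
  expect_equal(apply_transform(c(5, 1, 9), "inverse-normal"),
               c(0, -0.8694238, 0.8694238), tolerance = 1e-6)
  expect_equal(apply_transform(c(1, exp(1)), "natural-log"), c(0, 1))
  expect_equal(apply_transform(c(0, 4), "square-root"), c(0, 2))
  x <- c(3, NA, 1, 7)
  out <- apply_transform(x, "inverse-normal")
  expect_true(is.na(out[2]) && !anyNA(out[-2]))
  expect_error(apply_transform(c(1, -1, 2), "natural-log"), "row")
  expect_error(apply_transform(c(1, -1), "square-root"), "row")
  # ties get average ranks
  expect_equal(apply_transform(c(2, 2), "inverse-normal"), c(0, 0))
})

test_that("inverse-normal output is approximately standard normal for tie-free input", {
  set.seed(5)
  x <- rexp(200)
  z <- apply_transform(x, "inverse-normal")
  expect_lt(abs(mean(z)), 1e-10)        # Blom scores are symmetric
  expect_lt(abs(var(z) - 1), 0.05)
  expect_equal(order(z), order(x))      # rank-preserving
})

test_that("BH step-up flags match the hand computation and are monotone in p", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.1), 0.05),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10))))
  expect_true(all(bh_fdr(rep(0, 10))))
  set.seed(8)
  p <- c(runif(12), runif(5, 0, 1e-4))
  sorted_flags <- bh_fdr(p)[order(p)]
  expect_true(all(diff(sorted_flags) <= 0))  # rejections form a prefix of sorted p
})

test_that("binary association recovers a null and handles separation and zero carriers", {
  set.seed(14)
  n <- 30000
  cohort <- data.frame(carrier = rbinom(n, 1, 0.01),
                       y = rbinom(n, 1, 0.05))
  res <- fit_binary_outcome(cohort, "y", ci_type = "wald", p_type = "wald")
  expect_false(res$degenerate)
  se <- (log(res$ci_high) - log(res$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(res$effect)), 3 * se)
  # carrier identical to outcome on tiny data: separation, still finite
  tiny <- data.frame(carrier = c(1, 1, 1, 0, 0, 0), y = c(1, 1, 1, 0, 0, 0))
  res2 <- fit_binary_outcome(tiny, "y", ci_type = "wald", p_type = "wald")
  expect_true(is.finite(res2$effect) && res2$effect > 1)
  # zero carriers among complete cases: degenerate, not an error
  none <- data.frame(carrier = 0, y = rbinom(50, 1, 0.3))
  expect_true(fit_binary_outcome(none, "y")$degenerate)
})

test_that("standardized continuous effects are scale-invariant and null at zero effect", {
  set.seed(15)
  n <- 5000
  cohort <- data.frame(carrier = rbinom(n, 1, 0.05), wmh = exp(rnorm(n, 8, 1)))
  r1 <- fit_continuous_outcome(cohort, "wmh", "natural-log")
  cohort2 <- cohort
  cohort2$wmh <- cohort$wmh^2   # doubles log-scale values: z-scoring absorbs it
  r2 <- fit_continuous_outcome(cohort2, "wmh", "natural-log")
  expect_equal(r1$effect, r2$effect, tolerance = 1e-10)
  se <- (r1$ci_high - r1$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(r1$effect), 3 * se)
  expect_error(fit_continuous_outcome(data.frame(carrier = c(0, 1), wmh = c(2, 2)),
                                      "wmh"), "zero variance")
})

test_that("complete-case handling drops rows with missing covariates per model", {
  cohort <- data.frame(carrier = c(1, 1, 0, 0, 0, 0, 1, 0),
                       y = c(1, 0, 1, 0, 0, 1, 1, 0),
                       age = c(50, NA, 60, 55, 58, 61, 52, 57))
  res <- fit_binary_outcome(cohort, "y", adjustment = "age",
                            ci_type = "wald", p_type = "wald")
  expect_equal(res$n_used, 7)
})

test_that("descriptive comparisons reproduce the published male-sex contrast", {
  carrier <- c(rep(1, 443), rep(0, 200189))
  male <- c(rep(1, 223), rep(0, 443 - 223), rep(1, 89872), rep(0, 200189 - 89872))
  cohort <- data.frame(carrier = carrier, male = male)
  tab <- descriptive_table(cohort, "male")
  expect_equal(round(tab$p, 2), 0.02)
  expect_equal(tab$group1, "223 (50)")
  expect_equal(tab$type, "categorical")
  # identical groups: chi-square p = 1
  same <- data.frame(carrier = rep(c(1, 0), each = 100),
                     flag = rep(c(1, 0, 1, 0), each = 50))
  expect_equal(descriptive_table(same, "flag")$p, 1)
  # pooled t-test has power against a 1 SD shift
  set.seed(16)
  tt <- data.frame(carrier = rep(c(1, 0), each = 1000),
                   x = c(rnorm(1000, 1), rnorm(1000, 0)))
  expect_lt(descriptive_table(tt, "x")$p, 1e-10)
})

test_that("the cognitive composite averages available z-scores with polarity flips", {
  scores <- data.frame(fluid = c(10, 12, 14, NA),
                       reaction_time = c(500, 450, 400, NA),
                       memory = c(5, 6, 7, 6))
  comp <- cognitive_composite(scores, polarity = c(fluid = 1, reaction_time = -1,
                                                   memory = 1))
  expect_equal(comp[2], 0)              # participant at every test mean
  expect_true(comp[3] > 0 && comp[1] < 0)
  expect_equal(comp[4], unname((6 - mean(scores$memory, na.rm = TRUE)) /
                                 sd(scores$memory, na.rm = TRUE)))  # single test
  all_na <- cognitive_composite(data.frame(a = c(1, NA), b = c(2, NA)))
  expect_true(is.na(all_na[2]))
  # two tests at z = +1 and -1 average to zero
  two <- cognitive_composite(data.frame(a = c(-1, 1), b = c(1, -1)))
  expect_equal(two, c(0, 0))
})

test_that("incident filtering keeps post-recruitment events only", {
  cohort <- data.frame(
    id = 1:4,
    stroke = c(1, 1, 0, 1),
    recruitment_date = as.Date("2008-01-01"),
    stroke_date = as.Date(c("2008-01-02",   # day after recruitment: incident
                            "2007-12-31",   # before recruitment: prevalent
                            NA,             # no event
                            "2015-06-01")))
  out <- incident_filter(cohort, "stroke")
  expect_equal(out$stroke, c(1, 0, 0, 1))
  late <- cohort
  late$stroke_date[1] <- as.Date("2019-04-01")
  expect_error(incident_filter(late, "stroke"), "cutoff")
  nodate <- cohort
  nodate$stroke_date[4] <- NA
  expect_error(incident_filter(nodate, "stroke"), "missing")
})
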