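small_config <- function(...) {
  cohort_config(n_participants = 20000, carrier_frequency = 0.02,
                mri_fraction = 0.5, ...)
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 42)
  c2 <- generate_cohort(cfg, seed = 42)
  expect_identical(c1, c2)
  m1 <- generate_mri_profiles(c1, cfg, seed = 43)
  m2 <- generate_mri_profiles(c1, cfg, seed = 43)
  expect_identical(m1, m2)
  v1 <- generate_variant_table(c1, seed = 44)
  v2 <- generate_variant_table(c1, seed = 44)
  expect_identical(v1, v2)
  expect_false(identical(generate_cohort(cfg, seed = 1)$carrier,
                         generate_cohort(cfg, seed = 2)$carrier))
})

test_that("carrier draws follow the configured binomial frequency", {
  cfg <- cohort_config()   # study-scale defaults: 443/200632
  cohort <- generate_cohort(cfg, seed = 3)
  k <- sum(cohort$carrier)
  mu <- cfg$n_participants * cfg$carrier_frequency
  expect_lt(abs(k - mu), 3 * sqrt(mu))
  # domain-group split among carriers
  frac16 <- mean(cohort$domain_group[cohort$carrier == 1] == "EGFR_1_6")
  expect_lt(abs(frac16 - 11 / 443), 3 * sqrt((11 / 443) * (1 - 11 / 443) / k))
  expect_true(all(is.na(cohort$domain_group[cohort$carrier == 0])))
})

test_that("zero carrier frequency yields a clean degenerate cohort", {
  cfg <- small_config(carrier_frequency = 0)
  expect_warning(cohort <- generate_cohort(cfg, seed = 5), "unstable")
  expect_equal(sum(cohort$carrier), 0)
  expect_equal(nrow(generate_variant_table(cohort, seed = 6, decoy_rate = 0)), 0)
  res <- fit_binary_outcome(cohort, "stroke")
  expect_true(res$degenerate)
})

test_that("an OR of 1 gives equal prevalence in expectation", {
  cfg <- small_config(outcomes = list(stroke = list(p0 = 0.1, or = 1)),
                      include_prs = FALSE, include_dates = FALSE)
  cohort <- generate_cohort(cfg, seed = 7)
  p1 <- mean(cohort$stroke[cohort$carrier == 1])
  p0 <- mean(cohort$stroke[cohort$carrier == 0])
  n1 <- sum(cohort$carrier)
  expect_lt(abs(p1 - p0), 3 * sqrt(0.1 * 0.9 * (1 / n1 + 1 / (nrow(cohort) - n1))))
})

test_that("variant tables round-trip through classification to the generator's carriers", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg, seed = 8)
  vt <- generate_variant_table(cohort, seed = 9, decoy_rate = 0.02)
  cl <- classify_variants(vt)
  recovered <- unique(cl$sample_id[cl$carrier_defining])
  expect_setequal(recovered, cohort$id[cohort$carrier == 1])
  # decoys never classify as carrier-defining
  decoys <- cl[cl$sample_id %in% cohort$id[cohort$carrier == 0], ]
  expect_false(any(decoys$carrier_defining))
  # domain-group consistency: assigned variants match the cohort's group
  grp <- cl$domain_group[cl$carrier_defining]
  ids <- cl$sample_id[cl$carrier_defining]
  expect_identical(unname(grp),
                   cohort$domain_group[match(ids, cohort$id)])
  # EGFR 1-6 carriers get variants inside domains 1-6 of the fixture
  pos16 <- cl$position[cl$carrier_defining & cl$domain_group == "EGFR_1_6"]
  expect_true(all(map_to_egfr_domain(pos16) <= 6))
})

test_that("MRI generator controls the presence odds ratio and WMH shift", {
  cfg <- cohort_config(n_participants = 10000, carrier_frequency = 0.5,
                       mri_fraction = 1)
  cohort <- generate_cohort(cfg, seed = 10)
  prof <- generate_mri_profiles(cohort, cfg, seed = 11)
  carrier <- prof$carrier
  # anterior temporal presence OR near the configured 7.65
  prof_all <- prof
  prof_all$flair_available <- TRUE    # isolate the model from missingness
  prof_all$swi_available <- TRUE
  res <- region_presence_analysis(prof_all, carrier, ci_type = "wald", p_type = "wald")
  at <- res[res$region == "anterior_temporal", ]
  se <- (log(at$ci_high) - log(at$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(at$effect) - log(7.65)), 3 * se)
  # log-WMH standardized carrier difference near 0.52 (balanced groups here)
  r <- fit_continuous_outcome(prof, "wmh_volume", "natural-log")
  attn <- sqrt(1 + 0.52^2 * 0.25)     # z-scoring absorbs the group shift
  se_w <- (r$ci_high - r$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(r$effect - 0.52 / attn), 3 * se_w)
  # a zero configured difference recovers zero
  cfg0 <- cohort_config(n_participants = 5000, carrier_frequency = 0.5,
                        mri_fraction = 1, wmh_sd_diff = 0)
  prof0 <- generate_mri_profiles(generate_cohort(cfg0, seed = 12), cfg0, seed = 13)
  r0 <- fit_continuous_outcome(prof0, "wmh_volume", "natural-log")
  se0 <- (r0$ci_high - r0$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(r0$effect), 3 * se0)
})

test_that("config validation rejects unknown fields and missing seeds", {
  expect_error(cohort_config(nonsense = 1), "unknown config field")
  expect_error(generate_cohort(cohort_config()), "seed is mandatory")
  expect_error(generate_variant_table(data.frame(id = "a", carrier = 1,
                                                 domain_group = "EGFR_7_34")),
               "seed is mandatory")
})
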