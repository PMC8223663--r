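#' Population attributable fraction
#'
#' The fraction of cases in the population attributable to an exposure.
#' The default is Levin's formula,
#' \eqn{PAF = p(OR-1) / \{1 + p(OR-1)\}}, with the odds ratio standing in
#' for the relative risk (adequate for rare outcomes). Miettinen's
#' case-based form, \eqn{PAF = p_c (OR-1)/OR} with \eqn{p_c} the exposed
#' fraction among cases, is provided as an alternative.
#'
#' @param exposure_prevalence exposure prevalence in the population, in
#'   `(0, 1)` (Levin), or the exposed fraction among cases (Miettinen).
#' @param or odds ratio (> 0).
#' @param method `"levin"` or `"miettinen"`.
#' @return attributable fraction in `(-1, 1)`.
#' @examples
#' population_attributable_fraction(443 / 200632, 2.33)
#' @export
population_attributable_fraction <- function(exposure_prevalence, or,
                                             method = c("levin", "miettinen")) {
  method <- match.arg(method)
  stopifnot(exposure_prevalence > 0, exposure_prevalence < 1, or > 0)
  if (method == "levin") {
    x <- exposure_prevalence * (or - 1)
    x / (1 + x)
  } else {
    exposure_prevalence * (or - 1) / or
  }
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates an end-to-end run on generated data: cohort and variant
#' generation, variant classification and carrier summary, the binary
#' association battery (including the domain-group-stratified stroke
#' model), PRS residualization and risk-equivalence, control matching,
#' and the MRI analyses (continuous measures, regional presence and
#' severity, lesion counts). Carrier status used by the analyses comes
#' from classifying the generated variant table, not from the generator's
#' flags, so the run exercises the whole ascertainment path. Every random
#' step is seeded from `seed`; re-running with the same config and seed
#' reproduces every number.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer seed.
#' @param adjustment covariate set for the regressions; default
#'   `c("age", "sex")` keeps orchestration runs fast (the full set with
#'   batch and 10 PCs is available by passing it explicitly).
#' @param include_mri run the matched-MRI stage (default `TRUE`).
#' @param ci_type,p_type inference options passed to the model fits.
#' @return a `pipeline_report` list with elements `carrier_summary`,
#'   `associations` (Fig 2-style table), `stroke_stratified` (Fig 3-style
#'   table), `paf`, `prs` (equivalence + interaction), `matches`, `mri`
#'   (Table 2-style and Fig 5-style tables), and `seed`/`config`.
#' @export
run_full_analysis <- function(config = cohort_config(), seed,
                              adjustment = c("age", "sex"),
                              include_mri = TRUE,
                              ci_type = "wald", p_type = "wald") {
  if (missing(seed)) stop("seed is mandatory")
  cohort <- generate_cohort(config, seed = seed)
  variants <- generate_variant_table(cohort, seed = seed + 1)
  classified <- classify_variants(variants)
  carriers <- unique(classified$sample_id[classified$carrier_defining])
  cohort$carrier <- as.integer(cohort$id %in% carriers)
  grp <- tapply(classified$domain_group[classified$carrier_defining],
                classified$sample_id[classified$carrier_defining],
                function(g) g[1])
  cohort$domain_group <- unname(grp[match(cohort$id, names(grp))])

  summary <- summarize_carriers(classified, n_total = nrow(cohort))

  binary_outcomes <- intersect(names(config$outcomes), names(cohort))
  assoc <- do.call(rbind, lapply(binary_outcomes, function(oc)
    fit_binary_outcome(cohort, oc, adjustment,
                       ci_type = ci_type, p_type = p_type)))

  # domain-group-stratified stroke model: two carrier dummies vs non-carriers
  cohort$egfr_1_6 <- as.integer(!is.na(cohort$domain_group) &
                                  cohort$domain_group == "EGFR_1_6")
  cohort$egfr_7_34 <- as.integer(!is.na(cohort$domain_group) &
                                   cohort$domain_group == "EGFR_7_34")
  strat <- do.call(rbind, lapply(c("egfr_1_6", "egfr_7_34"), function(ex)
    fit_binary_outcome(cohort, "stroke", adjustment, exposure = ex,
                       ci_type = ci_type, p_type = p_type)))
  strat$domain_group <- c("EGFR_1_6", "EGFR_7_34")

  stroke_row <- assoc[assoc$outcome == "stroke", ]
  paf <- data.frame(
    outcome = "stroke",
    method = c("levin", "miettinen"),
    paf = c(population_attributable_fraction(mean(cohort$carrier),
                                             stroke_row$effect, "levin"),
            population_attributable_fraction(
              mean(cohort$carrier[cohort$stroke == 1]),
              stroke_row$effect, "miettinen")))

  prs_res <- NULL
  if (config$include_prs && config$include_covariates) {
    cohort$prs <- residualize_prs(cohort$prs,
                                  cohort[paste0("pc", seq_len(config$n_pcs))])
    isch <- fit_binary_outcome(cohort, "ischaemic_stroke", adjustment,
                               ci_type = ci_type, p_type = p_type)
    Xp <- cbind(intercept = 1, prs = cohort$prs)
    pfit <- fit_firth(Xp, cohort$ischaemic_stroke)
    pci <- firth_confint(pfit, "prs", type = ci_type)
    prs_res <- list(
      equivalence = prs_equivalence(isch$effect, isch$ci_low,
                                    exp(pfit$beta[["prs"]]), exp(pci[1, "high"])),
      interaction = interaction_test(cohort, "ischaemic_stroke", "continuous"))
  }

  mri <- NULL
  matches <- NULL
  if (include_mri) {
    profiles <- generate_mri_profiles(cohort, config, seed = seed + 2)
    adj_cols <- intersect(adjustment, names(cohort))
    for (col in adj_cols)
      profiles[[col]] <- cohort[[col]][match(profiles$id, cohort$id)]
    sub <- cohort[cohort$mri_available, ]
    cases <- sub[sub$carrier == 1, c("id", "age", "sex", "ethnicity", "fh_stroke")]
    pool <- sub[sub$carrier == 0, c("id", "age", "sex", "ethnicity", "fh_stroke")]
    matches <- match_controls(cases, pool, ratio = 3, seed = seed + 3,
                              relax_caliper = TRUE)
    rated_ids <- c(matches$case_id, matches$control_id)
    rated <- profiles[match(rated_ids, profiles$id), ]
    mri <- list(
      continuous = rbind(
        fit_continuous_outcome(profiles, "wmh_volume", "natural-log", adjustment),
        fit_continuous_outcome(profiles, "psmd", "none", adjustment),
        fit_continuous_outcome(profiles, "brain_volume", "none", adjustment)),
      region_presence = region_presence_analysis(rated, rated$carrier,
                                                 ci_type = "wald", p_type = "wald"),
      region_severity = region_severity_analysis(rated, rated$carrier),
      lesions = lesion_count_analysis(rated, rated$carrier,
                                      ci_type = "wald", p_type = "wald"))
  }

  out <- list(carrier_summary = summary, associations = assoc,
              stroke_stratified = strat, paf = paf, prs = prs_res,
              matches = matches, mri = mri, seed = seed, config = config)
  class(out) <- "pipeline_report"
  out
}

#' Write a pipeline report to disk
#'
#' Emits each tabular stage as TSV and the scalar summaries (carrier
#' summary, PAF, PRS equivalence, seed) as a single JSON document, all
#' under `dir`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$associations, "associations")
  wr(report$stroke_stratified, "stroke_stratified")
  wr(report$paf, "paf")
  if (!is.null(report$matches)) wr(report$matches, "matches")
  if (!is.null(report$mri)) {
    wr(report$mri$continuous, "mri_continuous")
    wr(report$mri$region_presence, "mri_region_presence")
    wr(report$mri$region_severity, "mri_region_severity")
    wr(report$mri$lesions, "mri_lesions")
  }
  js <- list(seed = report$seed,
             carrier_summary = unclass(report$carrier_summary))
  if (!is.null(report$prs)) js$prs_equivalence <- unclass(report$prs$equivalence)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, p))
}
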