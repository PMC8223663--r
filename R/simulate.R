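# Variant labels used by the synthetic variant table, keyed by domain group.
# Positions verified against the bundled domain table at load time in tests.
VARIANT_POOL <- list(
  EGFR_1_6 = c("p.Arg90Cys", "p.Arg110Cys", "p.Arg141Cys", "p.Cys144Arg"),
  EGFR_7_34 = c("p.Arg578Cys", "p.Cys579Tyr", "p.Gly861Cys",
                "p.Arg1231Cys", "p.Cys1250Arg"),
  decoy = c("p.Arg578His", "p.Ala1020Val", "p.Ala30Cys")
)

#' Configuration for the synthetic cohort generator
#'
#' Returns the generator settings with defaults set to the study
#' conditions the analyses assume: a cohort of 200,632 with carrier
#' frequency 443/200,632 (2.2 per 1000), 11/443 of carriers in EGFR
#' domains 1-6, binary outcomes drawn from logistic models with the
#' carrier odds ratios of the published association battery, a
#' standard-normal PRS entering ischaemic stroke at OR 1.26 per SD, and
#' MRI effect sizes (WMH standardized difference 0.52, PSMD 0.72,
#' regional presence ORs, lacune OR 5.97, microbleed OR 4.38). Baseline
#' outcome prevalences are assumptions (see the package vignette);
#' covariates are non-confounding by default so that recovery targets
#' isolate the carrier term.
#'
#' @param n_participants cohort size.
#' @param ... any named setting to override (see the returned list for
#'   names).
#' @return a `generator_config` list.
#' @export
cohort_config <- function(n_participants = 200632, ...) {
  cfg <- list(
    n_participants = n_participants,
    carrier_frequency = 443 / 200632,
    frac_egfr_1_6 = 11 / 443,
    outcomes = list(
      stroke            = list(p0 = 0.02,  or = 2.33),
      ischaemic_stroke  = list(p0 = 0.012, or = 3.07),
      vascular_dementia = list(p0 = 0.003, or = 5.00),
      all_cause_dementia = list(p0 = 0.006, or = 2.11),
      epilepsy          = list(p0 = 0.01,  or = 1.92),
      fh_stroke         = list(p0 = 0.25,  or = 1.41),
      migraine          = list(p0 = 0.03,  or = 1.41),
      depression        = list(p0 = 0.06,  or = 0.88)),
    stroke_stratified = FALSE,
    stroke_or_egfr_1_6 = 13.60,
    stroke_or_egfr_7_34 = 2.17,
    prs_or_per_sd = 1.26,
    mri_fraction = 19686 / 200632,
    wmh_sd_diff = 0.52,
    psmd_sd_diff = 0.72,
    brain_volume_sd_diff = 0,
    region_presence = list(
      periventricular = list(p0 = 0.73, or = 1.51),
      frontal = list(p0 = 0.80, or = 1.40),
      parietal = list(p0 = 0.53, or = 2.44),
      occipital = list(p0 = 0.30, or = 1.82),
      anterior_temporal = list(p0 = 0.09, or = 7.65),
      posterior_temporal = list(p0 = 0.30, or = 0.94),
      corpus_callosum = list(p0 = 0.05, or = 2.34),
      caudate = list(p0 = 0.01, or = 7.80),
      putamen = list(p0 = 0.11, or = 1.97),
      globus_pallidus = list(p0 = 0.03, or = 0.19),
      thalamus = list(p0 = 0.03, or = 3.90),
      internal_capsule = list(p0 = 0.02, or = 2.20),
      external_capsule = list(p0 = 0.06, or = 13.32),
      cerebellum = list(p0 = 0.03, or = 2.10),
      mesencephalon = list(p0 = 0.02, or = 3.84),
      pons = list(p0 = 0.17, or = 1.51),
      medulla = list(p0 = 0.01, or = 0.80)),
    lacune = list(p0 = 0.10, or = 5.97, lambda = 0.8),
    microbleed = list(p0 = 0.15, or = 4.38, lambda = 0.8),
    flair_missing = 0.03,
    swi_missing = 0.05,
    age_range = c(40, 70),
    p_male = 0.455,
    n_pcs = 10,
    ethnicity_probs = c(white = 0.937, asian = 0.03, black = 0.015,
                        chinese = 0.005, mixed = 0.006, other = 0.007),
    confounded = FALSE,
    include_covariates = TRUE,
    include_prs = TRUE,
    include_dates = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$carrier_frequency >= 0, cfg$carrier_frequency < 1)
  class(cfg) <- "generator_config"
  cfg
}

with_seed <- function(seed, expr) {
  force(seed)   # force before saving state: the seed may itself be a draw
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort
#'
#' Draws a participant table with the statistical structure the analysis
#' battery assumes: a rare Bernoulli carrier indicator split into EGFR
#' domain groups, binary outcomes from logistic models with configured
#' carrier odds ratios (stroke optionally stratified by domain group), a
#' standard-normal PRS entering ischaemic stroke log-linearly, neutral
#' covariates (age, sex, ethnicity, exome batch, 10 ancestry PCs), an MRI
#' availability flag, and event/recruitment dates for the incident-case
#' path. Fully reproducible given the seed.
#'
#' @param config a [cohort_config()] list.
#' @param seed integer seed (mandatory).
#' @return data.frame with one row per participant.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  n <- config$n_participants
  if (n * config$carrier_frequency < 5)
    warning("expected carrier count below 5; estimates will be unstable")
  with_seed(seed, {
    carrier <- rbinom(n, 1, config$carrier_frequency)
    domain_group <- rep(NA_character_, n)
    idx <- which(carrier == 1)
    domain_group[idx] <- ifelse(runif(length(idx)) < config$frac_egfr_1_6,
                                "EGFR_1_6", "EGFR_7_34")
    dat <- data.frame(id = sprintf("P%06d", seq_len(n)), carrier = carrier,
                      domain_group = domain_group, stringsAsFactors = FALSE)
    if (config$include_covariates) {
      dat$age <- runif(n, config$age_range[1], config$age_range[2])
      dat$sex <- rbinom(n, 1, config$p_male)
      dat$ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                              prob = config$ethnicity_probs)
      dat$exome_batch <- sample(c("batch1", "batch2"), n, replace = TRUE)
      for (k in seq_len(config$n_pcs)) dat[[paste0("pc", k)]] <- rnorm(n)
    }
    if (config$include_prs) dat$prs <- rnorm(n)
    for (nm in names(config$outcomes)) {
      oc <- config$outcomes[[nm]]
      eta <- qlogis(oc$p0)
      if (nm == "stroke" && config$stroke_stratified) {
        eta <- eta + ifelse(is.na(domain_group), 0,
                            ifelse(domain_group == "EGFR_1_6",
                                   log(config$stroke_or_egfr_1_6),
                                   log(config$stroke_or_egfr_7_34)))
      } else {
        eta <- eta + log(oc$or) * carrier
      }
      if (nm == "ischaemic_stroke" && config$include_prs)
        eta <- eta + log(config$prs_or_per_sd) * dat$prs
      if (config$confounded && config$include_covariates &&
          nm %in% c("stroke", "ischaemic_stroke"))
        eta <- eta + 0.05 * (dat$age - mean(config$age_range)) + 0.3 * dat$sex
      dat[[nm]] <- rbinom(n, 1, plogis(eta))
    }
    dat$mri_available <- rbinom(n, 1, config$mri_fraction) == 1
    if (config$include_dates) {
      dat$recruitment_date <- as.Date("2006-01-01") +
        sample.int(4 * 365, n, replace = TRUE)
      for (nm in c("stroke", "vascular_dementia")) {
        if (is.null(dat[[nm]])) next
        dcol <- paste0(nm, "_date")
        dat[[dcol]] <- as.Date(NA)
        cases <- which(dat[[nm]] == 1)
        # ~30% prevalent at baseline, the rest incident before the cutoff
        prevalent <- runif(length(cases)) < 0.3
        dat[[dcol]][cases[prevalent]] <-
          dat$recruitment_date[cases[prevalent]] - sample.int(3650, sum(prevalent), replace = TRUE)
        inc <- cases[!prevalent]
        span <- as.integer(as.Date("2019-03-31") - dat$recruitment_date[inc])
        dat[[dcol]][inc] <- dat$recruitment_date[inc] +
          floor(runif(length(inc), 1, span + 1))
      }
    }
    dat
  })
}

#' Generate synthetic MRI measures and visual-rating profiles
#'
#' For the MRI subset of a cohort (or a standalone subcohort), draws
#' continuous measures -- log-normal WMH volume and normal PSMD/brain
#' volume with carrier mean shifts equal to the configured standardized
#' differences -- and visual-rating profiles: per-region ordinal Scheltens
#' scores from a latent-logistic threshold model whose carrier
#' presence-OR equals the configured per-region OR, and lacune/microbleed
#' counts from a Bernoulli-gate-times-(1+Poisson) model so presence ORs
#' are directly controlled. Missing FLAIR/SWI sequences null their
#' dependent measures.
#'
#' @param cohort data.frame with at least `id` and `carrier`; rows with
#'   `mri_available == TRUE` are used when the flag is present.
#' @param config a [cohort_config()] list.
#' @param seed integer seed.
#' @return data.frame, one row per imaged participant: `id`, `carrier`,
#'   `wmh_volume` (mm^3), `psmd`, `brain_volume`, the 17 region scores,
#'   `lacune_count`, `microbleed_count`, and availability flags.
#' @export
generate_mri_profiles <- function(cohort, config = cohort_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  sub <- if (!is.null(cohort$mri_available)) cohort[cohort$mri_available, ] else cohort
  n <- nrow(sub)
  carrier <- as.integer(sub$carrier)
  with_seed(seed, {
    out <- data.frame(id = sub$id, carrier = carrier, stringsAsFactors = FALSE)
    # log WMH in log(mm^3): mean 8, SD 1 -> median volume ~3 mL
    out$wmh_volume <- exp(rnorm(n, 8, 1) + config$wmh_sd_diff * carrier)
    out$psmd <- 2.2e-4 + 4e-5 * (rnorm(n) + config$psmd_sd_diff * carrier)
    out$brain_volume <- 1.5e6 + 7e4 * (rnorm(n) + config$brain_volume_sd_diff * carrier)
    out$t1_available <- TRUE
    out$flair_available <- runif(n) >= config$flair_missing
    out$swi_available <- runif(n) >= config$swi_missing
    thresholds <- seq(0, 6, length.out = 6)   # latent cutpoints -> scores 0..6
    for (r in SCHELTENS_REGIONS) {
      pr <- config$region_presence[[r]]
      latent <- rlogis(n, location = qlogis(pr$p0) + log(pr$or) * carrier)
      out[[r]] <- findInterval(latent, thresholds)
    }
    for (lt in c("lacune", "microbleed")) {
      pr <- config[[lt]]
      gate <- rbinom(n, 1, plogis(qlogis(pr$p0) + log(pr$or) * carrier))
      out[[paste0(lt, "_count")]] <- gate * (1 + rpois(n, pr$lambda))
    }
    validate_profiles(out)
  })
}

#' Generate a protein-level variant table consistent with a cohort
#'
#' Assigns each carrier one cysteine-altering HGVS.p variant drawn from a
#' pool consistent with its domain group, and gives a small fraction of
#' non-carriers decoy variants (non-cysteine missense, or cysteine
#' changes outside the EGFR domains) that must never classify as
#' carrier-defining. Round-tripping the table through
#' [classify_variants()] reproduces the cohort's carrier flags exactly.
#'
#' @param cohort data.frame with `id`, `carrier`, `domain_group`.
#' @param seed integer seed.
#' @param decoy_rate fraction of non-carriers given a decoy variant
#'   (default 0.001).
#' @return data.frame with columns `sample_id`, `hgvs_p`, `genotype`.
#' @export
generate_variant_table <- function(cohort, seed, decoy_rate = 0.001) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    rows <- list()
    idx <- which(cohort$carrier == 1)
    if (length(idx)) {
      pool <- ifelse(cohort$domain_group[idx] == "EGFR_1_6", "EGFR_1_6", "EGFR_7_34")
      hg <- vapply(pool, function(g) sample(VARIANT_POOL[[g]], 1), "")
      rows$carriers <- data.frame(sample_id = cohort$id[idx], hgvs_p = hg,
                                  genotype = "het", stringsAsFactors = FALSE)
    }
    nidx <- which(cohort$carrier == 0)
    dec <- nidx[runif(length(nidx)) < decoy_rate]
    if (length(dec))
      rows$decoys <- data.frame(sample_id = cohort$id[dec],
                                hgvs_p = sample(VARIANT_POOL$decoy, length(dec),
                                                replace = TRUE),
                                genotype = "het", stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(sample_id = character(), hgvs_p = character(),
                        genotype = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
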