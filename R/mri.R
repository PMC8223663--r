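#' The 17 brain regions of the modified Scheltens rating
#'
#' Region names, in rostro-caudal order, over which regional white-matter
#' hyperintensity (WMH) scores are rated on FLAIR imaging.
#' @export
SCHELTENS_REGIONS <- c(
  "periventricular", "frontal", "parietal", "occipital",
  "anterior_temporal", "posterior_temporal", "corpus_callosum",
  "caudate", "putamen", "globus_pallidus", "thalamus",
  "internal_capsule", "external_capsule", "cerebellum",
  "mesencephalon", "pons", "medulla")

validate_profiles <- function(profiles) {
  miss <- setdiff(SCHELTENS_REGIONS, names(profiles))
  if (length(miss)) stop("profiles missing region column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("lacune_count", "microbleed_count"))
    if (!is.null(profiles[[col]]) &&
        any(profiles[[col]] < 0 | profiles[[col]] %% 1 != 0, na.rm = TRUE))
      stop(col, " must contain non-negative integers")
  # a missing sequence nulls its dependent measures
  if (!is.null(profiles$flair_available)) {
    off <- !profiles$flair_available
    profiles[off, SCHELTENS_REGIONS] <- NA
    if (!is.null(profiles$lacune_count)) profiles$lacune_count[off] <- NA
  }
  if (!is.null(profiles$swi_available) && !is.null(profiles$microbleed_count))
    profiles$microbleed_count[!profiles$swi_available] <- NA
  profiles
}

#' Per-region presence of any WMH: carrier odds ratios
#'
#' For each Scheltens region, dichotomizes the score as any-WMH
#' (score > 0) and fits a Firth logistic regression of presence on
#' carrier status (plus optional covariates). Regions where presence is
#' constant overall are returned with a degenerate flag rather than a fit.
#'
#' @param profiles data.frame with the 17 region columns (see
#'   [SCHELTENS_REGIONS]), availability flags, and any covariates.
#' @param carrier logical/0-1 vector aligned with `profiles`.
#' @param adjustment covariate column names in `profiles`.
#' @param ci_type,p_type passed to [fit_binary_outcome()].
#' @return data.frame, one row per region, in association-result form,
#'   plus per-group presence counts and percentages (the Table-2 layout).
#' @export
region_presence_analysis <- function(profiles, carrier, adjustment = character(),
                                     ci_type = "profile", p_type = "plrt") {
  profiles <- validate_profiles(profiles)
  rows <- lapply(SCHELTENS_REGIONS, function(r) {
    dat <- profiles
    dat$presence <- as.integer(dat[[r]] > 0)
    dat$carrier <- as.integer(carrier)
    ok <- !is.na(dat$presence)
    n1 <- sum(dat$presence[ok] == 1 & dat$carrier[ok] == 1)
    n0 <- sum(dat$presence[ok] == 1 & dat$carrier[ok] == 0)
    d1 <- sum(dat$carrier[ok] == 1)
    d0 <- sum(dat$carrier[ok] == 0)
    if (length(unique(dat$presence[ok])) < 2) {
      res <- data.frame(outcome = "presence", model = "firth-logistic",
                        effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, n_used = sum(ok), transform = "none",
                        adjustment = paste(adjustment, collapse = "+"),
                        degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      res <- fit_binary_outcome(dat, "presence", adjustment,
                                ci_type = ci_type, p_type = p_type)
    }
    res$region <- r
    res$carrier_n <- n1; res$carrier_pct <- round(100 * n1 / max(d1, 1))
    res$control_n <- n0; res$control_pct <- round(100 * n0 / max(d0, 1))
    res
  })
  do.call(rbind, rows)
}

#' Per-region WMH severity: standardized carrier differences
#'
#' Inverse-normal transforms each region's ordinal score (Blom offsets,
#' average ranks for ties), z-scores it, and regresses on carrier status;
#' the aggregate row does the same for the sum of all 17 regional scores.
#' Benjamini-Hochberg rejection flags at `q` are attached across the
#' regional rows. Regions with a constant score are skipped with a flag.
#'
#' @inheritParams region_presence_analysis
#' @param q FDR level for the per-region flags (default 0.05).
#' @return data.frame of association-result rows (one per analysable
#'   region, plus an `aggregate` row) with `fdr_significant` flags.
#' @export
region_severity_analysis <- function(profiles, carrier, adjustment = character(),
                                     q = 0.05) {
  profiles <- validate_profiles(profiles)
  profiles$carrier <- as.integer(carrier)
  analyse <- function(x, label) {
    dat <- profiles
    dat$score <- x
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2)
      return(data.frame(region = label, effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, n_used = sum(ok),
                        skipped = TRUE, stringsAsFactors = FALSE))
    res <- fit_continuous_outcome(dat, "score", transform = "inverse-normal",
                                  adjustment = adjustment)
    data.frame(region = label, effect = res$effect, ci_low = res$ci_low,
               ci_high = res$ci_high, p = res$p, n_used = res$n_used,
               skipped = FALSE, stringsAsFactors = FALSE)
  }
  rows <- lapply(SCHELTENS_REGIONS, function(r) analyse(profiles[[r]], r))
  out <- do.call(rbind, rows)
  agg <- rowSums(profiles[SCHELTENS_REGIONS])
  out <- rbind(out, analyse(agg, "aggregate"))
  out$fdr_significant <- FALSE
  reg <- out$region != "aggregate" & !out$skipped
  out$fdr_significant[reg] <- bh_fdr(out$p[reg], q)
  out
}

#' Lacune and microbleed analyses
#'
#' For each lesion type, fits a presence model (count > 0, Firth logistic)
#' and a burden model (square-root transformed count, z-scored, linear
#' regression) of carrier status. Burden is skipped when all counts are
#' zero.
#'
#' @inheritParams region_presence_analysis
#' @return data.frame with rows `lacune_presence`, `lacune_burden`,
#'   `microbleed_presence`, `microbleed_burden` in association-result form.
#' @export
lesion_count_analysis <- function(profiles, carrier, adjustment = character(),
                                  ci_type = "profile", p_type = "plrt") {
  profiles <- validate_profiles(profiles)
  profiles$carrier <- as.integer(carrier)
  one <- function(col, label) {
    x <- profiles[[col]]
    dat <- profiles
    dat$presence <- as.integer(x > 0)
    pres <- if (length(unique(na.omit(dat$presence))) < 2)
      data.frame(outcome = paste0(label, "_presence"), model = "firth-logistic",
                 effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, n_used = sum(!is.na(x)), transform = "none",
                 adjustment = paste(adjustment, collapse = "+"),
                 degenerate = TRUE, stringsAsFactors = FALSE)
    else {
      r <- fit_binary_outcome(dat, "presence", adjustment,
                              ci_type = ci_type, p_type = p_type)
      r$outcome <- paste0(label, "_presence"); r
    }
    burden <- if (all(na.omit(x) == 0))
      data.frame(outcome = paste0(label, "_burden"), model = "linear",
                 effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, n_used = sum(!is.na(x)), transform = "square-root",
                 adjustment = paste(adjustment, collapse = "+"),
                 degenerate = TRUE, stringsAsFactors = FALSE)
    else {
      r <- fit_continuous_outcome(dat, col, transform = "square-root",
                                  adjustment = adjustment)
      r$outcome <- paste0(label, "_burden"); r$degenerate <- FALSE; r
    }
    rbind(pres, burden)
  }
  rbind(one("lacune_count", "lacune"), one("microbleed_count", "microbleed"))
}
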