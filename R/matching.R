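#' Match controls to carrier cases
#'
#' Selects `ratio` controls per case without replacement, matching exactly
#' on sex, ethnicity and family history of stroke and taking the nearest
#' controls in age within a caliper. Processing order over cases and
#' age-tie breaking are randomized by `seed`, so the output is a
#' deterministic function of the inputs and the seed.
#'
#' @param cases data.frame of cases with columns `id`, `age`, `sex`,
#'   `ethnicity`, `fh_stroke`.
#' @param control_pool data.frame of candidate controls with the same
#'   columns; must be disjoint from the cases (and non-carrier, if a
#'   `carrier` column is present).
#' @param ratio controls per case (default 3).
#' @param age_caliper maximum |age difference| in years (default 5).
#' @param seed integer seed controlling processing order and tie-breaks.
#' @param relax_caliper if `TRUE`, a case with too few in-caliper controls
#'   takes the nearest available exact-key controls regardless of age
#'   difference instead of erroring.
#' @return data.frame with one row per selected control: `case_id`,
#'   `control_id`, `rank`, `age_diff`, and the exact-match key columns.
#' @export
match_controls <- function(cases, control_pool, ratio = 3, age_caliper = 5,
                           seed = 1, relax_caliper = FALSE) {
  keys <- c("sex", "ethnicity", "fh_stroke")
  need <- c("id", "age", keys)
  stopifnot(all(need %in% names(cases)), all(need %in% names(control_pool)))
  if (length(intersect(cases$id, control_pool$id)))
    stop("control pool overlaps the case set")
  if (!is.null(control_pool$carrier) && any(control_pool$carrier != 0))
    stop("control pool contains carriers")
  if (anyDuplicated(control_pool$id)) stop("duplicate control ids")

  force(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  case_order <- sample(nrow(cases))
  used <- rep(FALSE, nrow(control_pool))
  rows <- vector("list", nrow(cases))
  for (ci in case_order) {
    case <- cases[ci, ]
    elig <- !used
    for (k in keys) elig <- elig & control_pool[[k]] == case[[k]]
    diffs <- abs(control_pool$age - case$age)
    in_cal <- elig & diffs <= age_caliper
    pick_from <- if (sum(in_cal) >= ratio) which(in_cal) else {
      if (!relax_caliper)
        stop("fewer than ", ratio, " eligible controls within +/-", age_caliper,
             " years for stratum sex=", case$sex, ", ethnicity=", case$ethnicity,
             ", fh_stroke=", case$fh_stroke, " (case ", case$id, ")")
      if (sum(elig) < ratio)
        stop("fewer than ", ratio, " exact-key controls available for case ", case$id)
      which(elig)
    }
    # nearest in age; ties broken by a seeded random draw
    ord <- pick_from[order(diffs[pick_from], runif(length(pick_from)))]
    sel <- ord[seq_len(ratio)]
    used[sel] <- TRUE
    rows[[ci]] <- data.frame(case_id = case$id,
                             control_id = control_pool$id[sel],
                             rank = seq_len(ratio),
                             age_diff = control_pool$age[sel] - case$age,
                             sex = case$sex, ethnicity = case$ethnicity,
                             fh_stroke = case$fh_stroke,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
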