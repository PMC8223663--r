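AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Parse HGVS protein substitution notation
#'
#' Accepts `p.` strings in either three-letter (`p.Arg1231Cys`) or
#' one-letter (`p.R1231C`) form and returns the normalized one-letter
#' change. Only simple missense substitutions are accepted; frameshift,
#' termination, deletion and synonymous notations raise an error naming
#' the offending token, since the downstream cysteine rule is defined for
#' missense changes only.
#'
#' @param text character vector of HGVS protein strings.
#' @return data.frame with columns `ref_aa`, `position`, `alt_aa` (one row
#'   per input string).
#' @examples
#' parse_hgvs_p(c("p.Arg1231Cys", "p.C579Y"))
#' @export
parse_hgvs_p <- function(text) {
  text <- as.character(text)
  one <- function(s) {
    if (is.na(s) || !startsWith(s, "p.")) stop("malformed HGVS protein string: '", s, "'")
    body <- sub("^p\\.", "", s)
    body <- gsub("[()]", "", body)
    if (grepl("fs|del|dup|ins|Ter|\\*|=", body))
      stop("non-missense notation in '", s, "': only simple substitutions are supported")
    m3 <- regmatches(body, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", body))[[1]]
    m1 <- regmatches(body, regexec("^([A-Z])([0-9]+)([A-Z])$", body))[[1]]
    if (length(m3) == 4) {
      ref <- unname(AA3[m3[2]]); alt <- unname(AA3[m3[4]])
      if (is.na(ref)) stop("unknown amino acid code '", m3[2], "' in '", s, "'")
      if (is.na(alt)) stop("unknown amino acid code '", m3[4], "' in '", s, "'")
      pos <- as.integer(m3[3])
    } else if (length(m1) == 4) {
      ref <- m1[2]; alt <- m1[4]; pos <- as.integer(m1[3])
      if (!ref %in% AA1) stop("unknown amino acid code '", ref, "' in '", s, "'")
      if (!alt %in% AA1) stop("unknown amino acid code '", alt, "' in '", s, "'")
    } else {
      stop("malformed HGVS protein string: '", s, "'")
    }
    if (pos < 1) stop("protein position must be >= 1 in '", s, "'")
    if (ref == alt) stop("non-missense notation in '", s, "': reference and alternate residue are identical")
    list(ref, pos, alt)
  }
  parsed <- lapply(text, one)
  data.frame(ref_aa = vapply(parsed, `[[`, "", 1),
             position = vapply(parsed, `[[`, 1L, 2),
             alt_aa = vapply(parsed, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Classify a substitution as cysteine gain, loss, or neither
#'
#' The CADASIL-defining lesion is an odd number of cysteines in an
#' EGF-like repeat, produced by a missense change that creates or removes
#' a cysteine. `gain` means the alternate residue is cysteine and the
#' reference is not; `loss` the converse; anything else is `none`.
#'
#' @param ref_aa,alt_aa one-letter amino acid codes (vectorized).
#' @return character vector of `"gain"`, `"loss"`, `"none"`.
#' @export
classify_cysteine_change <- function(ref_aa, alt_aa) {
  ifelse(alt_aa == "C" & ref_aa != "C", "gain",
         ifelse(ref_aa == "C" & alt_aa != "C", "loss", "none"))
}

#' EGF-like repeat domain coordinates for NOTCH3
#'
#' Loads the bundled table of the 34 EGF-like repeat (EGFR) domains of the
#' NOTCH3 extracellular region (residues 40-1373 in the Q9UM47 protein
#' numbering, initiator Met = 1). The bundled table is a synthetic
#' reconstruction -- a uniform 34-repeat tiling of residues 40-1373 --
#' validated against published anchor residues (578 in domain 14, 1231 in
#' domain 31); see the package vignette. A user-supplied table with the
#' same columns can be passed anywhere a domain table is accepted.
#'
#' @param path optional path to a TSV with columns `domain_index`,
#'   `start_aa`, `end_aa`; default: the bundled fixture.
#' @return validated data.frame of 34 rows.
#' @export
egfr_domains <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "egfr_domains_q9um47_synthetic.tsv",
                        package = "notch3risk", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("domain_index", "start_aa", "end_aa") %in% names(tab)))
  if (nrow(tab) != 34) stop("domain table must have exactly 34 entries")
  if (any(diff(tab$domain_index) <= 0)) stop("domain_index must be strictly increasing")
  if (any(tab$start_aa > tab$end_aa)) stop("domain with start_aa > end_aa")
  if (min(tab$start_aa) < 40 || max(tab$end_aa) > 1373)
    stop("domains must lie within residues 40-1373")
  o <- order(tab$start_aa)
  if (any(tab$start_aa[o][-1] <= tab$end_aa[o][-34]))
    stop("domain intervals overlap")
  tab
}

#' Map a protein position onto an EGFR domain
#'
#' Returns the index (1-34) of the domain whose inclusive interval
#' contains the position, or `NA` for positions outside every domain
#' (N-terminal of residue 40, C-terminal of 1373, or in an inter-domain
#' linker). Vectorized over positions.
#'
#' @param position integer protein coordinate(s), 1-based.
#' @param domains domain table from [egfr_domains()].
#' @return integer vector of domain indices with `NA` for unmapped positions.
#' @export
map_to_egfr_domain <- function(position, domains = egfr_domains()) {
  vapply(as.integer(position), function(p) {
    hit <- domains$domain_index[domains$start_aa <= p & domains$end_aa >= p]
    if (length(hit) == 1L) as.integer(hit) else NA_integer_
  }, integer(1))
}

#' Classify a participant-variant table
#'
#' Applies the full ascertainment rule to a table of protein-level
#' variants: parse the HGVS string, classify the cysteine change, map the
#' residue onto the EGFR domains, and flag the variant as carrier-defining
#' when (and only when) it is a cysteine gain or loss inside one of the 34
#' domains. Domain group `EGFR_1_6` covers domains 1-6, `EGFR_7_34` the
#' rest; variants outside any domain get no group.
#'
#' @param tbl data.frame with columns `sample_id`, `hgvs_p`, and
#'   optionally `genotype` (`"het"`/`"hom"`; default `"het"`).
#' @param domains domain table from [egfr_domains()].
#' @return data.frame of classified variants: the input columns plus
#'   `ref_aa`, `position`, `alt_aa`, `cys_class`, `domain_index`,
#'   `domain_group`, `carrier_defining`.
#' @export
classify_variants <- function(tbl, domains = egfr_domains()) {
  stopifnot(all(c("sample_id", "hgvs_p") %in% names(tbl)))
  if (is.null(tbl$genotype)) tbl$genotype <- "het"
  if (!all(tbl$genotype %in% c("het", "hom")))
    stop("genotype must be 'het' or 'hom'")
  pc <- parse_hgvs_p(tbl$hgvs_p)
  cys <- classify_cysteine_change(pc$ref_aa, pc$alt_aa)
  dom <- map_to_egfr_domain(pc$position, domains)
  group <- ifelse(is.na(dom), NA_character_,
                  ifelse(dom <= 6, "EGFR_1_6", "EGFR_7_34"))
  out <- cbind(tbl[c("sample_id", "hgvs_p", "genotype")], pc)
  out$cys_class <- cys
  out$domain_index <- dom
  out$domain_group <- group
  out$carrier_defining <- cys %in% c("gain", "loss") & !is.na(dom)
  out
}

#' Summarize carriers of cysteine-altering EGFR-domain variants
#'
#' @param classified output of [classify_variants()].
#' @param n_total total number of sequenced participants in the cohort
#'   (carriers and non-carriers).
#' @return an object of class `carrier_summary`: carrier count, per-1000
#'   frequency (one decimal), population frequency as a truncated
#'   "1 in N", unique carrier-defining variant count, singleton count,
#'   zygosity tally, and per-domain-group carrier counts.
#' @examples
#' tbl <- data.frame(sample_id = "s1", hgvs_p = "p.Arg1231Cys")
#' summarize_carriers(classify_variants(tbl), n_total = 452)
#' @export
summarize_carriers <- function(classified, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  cd <- classified[classified$carrier_defining, , drop = FALSE]
  carriers <- unique(cd$sample_id)
  k <- length(carriers)
  per_var <- table(cd$hgvs_p)
  zyg_per_sample <- tapply(cd$genotype, cd$sample_id,
                           function(g) if ("hom" %in% g) "hom" else "het")
  zyg <- table(factor(unlist(zyg_per_sample), levels = c("het", "hom")))
  # carriers counted once per domain group they carry a variant in
  grp <- tapply(cd$domain_group, cd$sample_id, function(g) unique(g))
  grp_counts <- c(EGFR_1_6 = sum(vapply(grp, function(g) "EGFR_1_6" %in% g, TRUE)),
                  EGFR_7_34 = sum(vapply(grp, function(g) "EGFR_7_34" %in% g, TRUE)))
  if (k == 0) grp_counts <- c(EGFR_1_6 = 0L, EGFR_7_34 = 0L)
  out <- list(
    n_total = n_total,
    n_carriers = k,
    per_1000 = round(k / n_total * 1000, 1),
    one_in = if (k > 0) as.integer(n_total %/% k) else NA_integer_,
    n_unique_variants = length(per_var),
    n_singleton_variants = sum(per_var == 1),
    zygosity = c(het = unname(zyg["het"]), hom = unname(zyg["hom"])),
    domain_group_counts = grp_counts
  )
  class(out) <- "carrier_summary"
  out
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat(sprintf("Carriers: %d of %d participants (%.1f per 1000; 1 in %s)\n",
              x$n_carriers, x$n_total, x$per_1000,
              ifelse(is.na(x$one_in), "-", x$one_in)))
  cat(sprintf("Unique carrier-defining variants: %d (%d singletons)\n",
              x$n_unique_variants, x$n_singleton_variants))
  cat(sprintf("Zygosity: %d het / %d hom; domain groups: EGFR 1-6 %d, EGFR 7-34 %d\n",
              x$zygosity["het"], x$zygosity["hom"],
              x$domain_group_counts["EGFR_1_6"], x$domain_group_counts["EGFR_7_34"]))
  invisible(x)
}
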