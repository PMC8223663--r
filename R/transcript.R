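NOTCH3_REGION <- list(chrom = "chr19", start = 15159038L, end = 15200995L,
                      strand = "-")

#' Synthetic NOTCH3-like transcript model
#'
#' Builds a reverse-strand transcript fixture occupying the GRCh38 NOTCH3
#' gene region (chr19:15,159,038-15,200,995) with a generated coding
#' sequence, for exercising the genomic-to-protein consequence path. The
#' CDS is synthetic (deterministically generated from `seed`), not the
#' real NOTCH3 transcript: consequence calling only needs a consistent
#' exon structure and codon table, and every test checks it against a
#' brute-force translation oracle that is sequence-agnostic.
#'
#' @param n_aa protein length excluding the stop codon (default 2321, the
#'   length of NOTCH3).
#' @param n_exons number of coding exons (default 33).
#' @param seed deterministic generation seed.
#' @return an object of class `transcript_model`: gene region, strand,
#'   exon table in genomic coordinates with transcript-order exon numbers,
#'   the CDS (sense-strand character string, length divisible by 3), and
#'   the translated reference protein.
#' @export
synthetic_transcript <- function(n_aa = 2321, n_exons = 33, seed = 101) {
  stopifnot(n_aa >= 10, n_exons >= 1)
  force(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  codons_for <- lapply(AA1, function(a) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == a]
  })
  names(codons_for) <- AA1
  aa <- c("M", sample(AA1, n_aa - 1, replace = TRUE))
  cds <- vapply(aa, function(a) sample(codons_for[[a]], 1), "")
  cds <- paste0(paste(cds, collapse = ""), "TAA")
  cds_len <- nchar(cds)                       # 3 * (n_aa + 1)

  # split the CDS into exons, then place them in the gene region;
  # transcript order runs from the HIGH genomic coordinate end (reverse strand)
  cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
  sizes <- diff(c(0, cuts, cds_len))
  gaps <- rep((NOTCH3_REGION$end - NOTCH3_REGION$start + 1 - cds_len) %/%
                (n_exons + 1), n_exons + 1)
  ends <- NOTCH3_REGION$end - cumsum(gaps[seq_len(n_exons)]) -
    cumsum(c(0, sizes[-n_exons]))
  starts <- ends - sizes + 1
  exons <- data.frame(exon = seq_len(n_exons), start = starts, end = ends,
                      cds_offset = cumsum(c(0, sizes[-n_exons])))
  stopifnot(min(exons$start) >= NOTCH3_REGION$start)

  protein <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  model <- list(chrom = NOTCH3_REGION$chrom, start = NOTCH3_REGION$start,
                end = NOTCH3_REGION$end, strand = "-", exons = exons,
                cds = cds, protein = sub("\\*$", "", protein))
  class(model) <- "transcript_model"
  model
}

#' Map a genomic coordinate to a CDS position (reverse strand)
#' @keywords internal
genomic_to_cds_pos <- function(pos, model) {
  ex <- model$exons
  hit <- which(ex$start <= pos & ex$end >= pos)
  if (length(hit) != 1L) return(NA_integer_)
  as.integer(ex$cds_offset[hit] + (ex$end[hit] - pos + 1L))
}

#' Protein consequence of a genomic SNV
#'
#' Calls the amino-acid consequence of a single-nucleotide substitution
#' against a reverse-strand transcript model: the alleles are
#' reverse-complemented, the affected codon located, and reference and
#' alternate codons translated with the standard genetic code.
#'
#' @param chrom,pos,ref,alt the variant in VCF convention (1-based genomic
#'   position, alleles on the forward genomic strand).
#' @param model a `transcript_model`.
#' @return a list with `type` one of `"missense"`, `"synonymous"`,
#'   `"stop_gained"`, `"stop_lost"`, `"non_coding"`; for missense calls,
#'   also `ref_aa`, `position`, `alt_aa`.
#' @export
genomic_to_protein <- function(chrom, pos, ref, alt, model) {
  bases <- c("A", "C", "G", "T")
  if (!ref %in% bases || !alt %in% bases)
    stop("unsupported variant: only single-nucleotide substitutions are handled (ref='",
         ref, "', alt='", alt, "')")
  if (ref == alt) stop("ref and alt alleles are identical")
  if (chrom != model$chrom || pos < model$start || pos > model$end)
    stop("variant outside the gene region ", model$chrom, ":",
         model$start, "-", model$end)
  cds_pos <- genomic_to_cds_pos(pos, model)
  if (is.na(cds_pos)) return(list(type = "non_coding"))

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds_ref <- unname(comp[ref])   # reverse strand: CDS base is the complement
  cds_alt <- unname(comp[alt])
  if (substr(model$cds, cds_pos, cds_pos) != cds_ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (expected genomic '", comp[substr(model$cds, cds_pos, cds_pos)],
         "', got '", ref, "')")

  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  codon_start <- (codon_i - 1L) * 3L + 1L
  ref_codon <- substr(model$cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_start + 1L, cds_pos - codon_start + 1L) <- cds_alt
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  if (ref_aa == alt_aa) return(list(type = "synonymous", position = codon_i))
  if (alt_aa == "*") return(list(type = "stop_gained", position = codon_i))
  if (ref_aa == "*") return(list(type = "stop_lost", position = codon_i))
  list(type = "missense", ref_aa = ref_aa, position = codon_i, alt_aa = alt_aa)
}
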