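test_that("HGVS protein parsing handles both notations and rejects non-missense", {
  expect_equal(parse_hgvs_p("p.Arg1231Cys"),
               data.frame(ref_aa = "R", position = 1231L, alt_aa = "C",
                          stringsAsFactors = FALSE))
  expect_equal(parse_hgvs_p("p.C579Y"),
               data.frame(ref_aa = "C", position = 579L, alt_aa = "Y",
                          stringsAsFactors = FALSE))
  expect_equal(parse_hgvs_p(c("p.Gly861Cys", "p.R90C"))$position, c(861L, 90L))
  expect_error(parse_hgvs_p("p.Arg578fs"), "non-missense")
  expect_error(parse_hgvs_p("p.Arg578Ter"), "non-missense")
  expect_error(parse_hgvs_p("p.Arg578del"), "non-missense")
  expect_error(parse_hgvs_p("p.Xyz578Cys"), "unknown amino acid")
  expect_error(parse_hgvs_p("Arg578Cys"), "malformed")
  expect_error(parse_hgvs_p("p.Arg578Arg"), "identical")
})

test_that("cysteine classification matches direct character comparison exhaustively", {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  pairs <- expand.grid(ref = aa, alt = aa, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- classify_cysteine_change(pairs$ref, pairs$alt)
  want <- ifelse(pairs$alt == "C", "gain", ifelse(pairs$ref == "C", "loss", "none"))
  expect_identical(got, want)
  expect_equal(sum(got == "gain"), 19)
  expect_equal(sum(got == "loss"), 19)
})

test_that("domain mapping is a partition with the published anchor residues", {
  dom <- egfr_domains()
  expect_equal(nrow(dom), 34)
  expect_equal(map_to_egfr_domain(1231, dom), 31L)  # p.Arg1231Cys
  expect_equal(map_to_egfr_domain(578, dom), 14L)   # p.Arg578Cys
  expect_true(is.na(map_to_egfr_domain(39, dom)))
  expect_true(is.na(map_to_egfr_domain(1374, dom)))
  # every position hits at most one domain; positions inside a domain hit exactly one
  hits <- vapply(1:1400, function(p) sum(dom$start_aa <= p & dom$end_aa >= p), 0)
  expect_true(all(hits <= 1))
  inside <- unlist(mapply(seq, dom$start_aa, dom$end_aa, SIMPLIFY = FALSE))
  expect_true(all(hits[inside] == 1))
})

test_that("carrier-defining flag requires a cysteine change inside a domain", {
  tbl <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    hgvs_p = c("p.Arg578Cys",   # gain in domain 14
               "p.Cys579Tyr",   # loss in domain 14
               "p.Arg578His",   # no cysteine involved
               "p.Ala30Cys",    # gain, but N-terminal of the domains
               "p.Arg90Cys"),   # gain in domain 2
    stringsAsFactors = FALSE)
  cl <- classify_variants(tbl)
  expect_equal(cl$cys_class, c("gain", "loss", "none", "gain", "gain"))
  expect_equal(cl$carrier_defining, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(cl$domain_group, c("EGFR_7_34", "EGFR_7_34", "EGFR_7_34", NA, "EGFR_1_6"))
  # exhaustively: a cysteine gain is carrier-defining iff the position maps
  dom <- egfr_domains()
  pos <- 1:1373
  cd <- classify_variants(data.frame(sample_id = paste0("x", pos),
                                     hgvs_p = paste0("p.R", pos, "C")))
  expect_identical(cd$carrier_defining, !is.na(map_to_egfr_domain(pos, dom)))
})

test_that("carrier summary reproduces the cohort-level frequencies", {
  tbl <- data.frame(sample_id = sprintf("s%03d", 1:443),
                    hgvs_p = rep(c("p.Arg1231Cys", "p.Arg578Cys", "p.Cys579Tyr"),
                                 length.out = 443),
                    stringsAsFactors = FALSE)
  s <- summarize_carriers(classify_variants(tbl), n_total = 200632)
  expect_equal(s$n_carriers, 443)
  expect_equal(s$per_1000, 2.2)
  expect_equal(s$one_in, 452L)
  expect_equal(unname(s$zygosity["het"]), 443L)
  # zero carriers
  s0 <- summarize_carriers(classify_variants(
    data.frame(sample_id = "a", hgvs_p = "p.Arg578His")), n_total = 100)
  expect_equal(s0$n_carriers, 0)
  expect_equal(s0$per_1000, 0)
  expect_true(is.na(s0$one_in))
  expect_error(summarize_carriers(classify_variants(tbl), 0), "positive")
  # homozygotes are retained and tallied, never assumed absent
  th <- data.frame(sample_id = c("h1", "h2"), hgvs_p = "p.Arg578Cys",
                   genotype = c("hom", "het"), stringsAsFactors = FALSE)
  sh <- summarize_carriers(classify_variants(th), n_total = 10)
  expect_equal(unname(sh$zygosity), c(1L, 1L))
  # singleton and unique-variant counts
  tu <- data.frame(sample_id = c("a", "b", "c"),
                   hgvs_p = c("p.Arg578Cys", "p.Arg578Cys", "p.Arg1231Cys"))
  su <- summarize_carriers(classify_variants(tu), n_total = 10)
  expect_equal(su$n_unique_variants, 2)
  expect_equal(su$n_singleton_variants, 1)
})
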