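# Published screening figures (carrier counts over 180 controls / 179 cases
# and the two population-database allele frequencies) frozen as fixtures.

test_that("carrier frequencies reproduce the screening-table cells under truncation", {
  expect_equal(carrier_frequency(6, 180), 0.033)
  expect_equal(carrier_frequency(8, 179), 0.044)   # rounding would say 0.045
  expect_equal(carrier_frequency(9, 179), 0.050)
  expect_equal(carrier_frequency(10, 180), 0.055)
  expect_equal(carrier_frequency(0, 180), 0)
  expect_equal(carrier_frequency(8, 179, mode = "round"), 0.045)
  expect_error(carrier_frequency(1, 0), class = "famfunnel_data_error")
  expect_error(carrier_frequency(5, 4), class = "famfunnel_data_error")
})

test_that("carrier frequency is bounded and monotone in the carrier count", {
  for (n in c(7, 179, 180)) {
    f <- vapply(0:n, carrier_frequency, numeric(1), n = n)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("allele frequencies reproduce the database values under rounding", {
  expect_equal(allele_frequency(8, 140282, 6), 0.000057)
  expect_equal(allele_frequency(1, 13006, 5), 0.00008)
  expect_equal(allele_frequency(0, 9999, 4), 0)
  expect_error(allele_frequency(1, 0), class = "famfunnel_data_error")
})

test_that("the polymorphism rule is a strict 1% threshold on control carriers", {
  expect_true(classify_polymorphism(6, 180))    # 0.0333
  expect_false(classify_polymorphism(0, 180))
  expect_false(classify_polymorphism(1, 100))   # exactly 0.01: not greater
  expect_true(classify_polymorphism(2, 100))
  expect_false(classify_polymorphism(NA, 180))  # not determined
})

# the ten published candidates, with gene-level annotation flags
published_candidates <- function() {
  v <- mk_variants(10,
    pos = c(101L, 102L, 103L, 104L, 105L, 106L, 107L, 108L, 109L, 110L),
    gene = c("HSPG2", "ARHGEF10L", "CNKSR1", "PER3", "RERE", "CDK11B",
             "HSPG2", "DOCK5", "CCDC27", "OR8G5"),
    consequence = c("missense", "missense", "missense", "splice_region",
                    "splice_region", "missense", "missense",
                    "splice_region", "splice_region", "splice_region"),
    revel = c(0.478, 0.364, 0.337, NA, NA, 0.146, 0.448, NA, NA, NA),
    sift = c(0.171, 0.008, 0.0, NA, NA, 0.0, 0.03, NA, NA, NA),
    polyphen = c(0.997, 0.979, 0.998, NA, NA, 0.99, 0.999, NA, NA, NA))
  # genotypes irrelevant for ranking inputs here; use the affected pattern
  ped <- ubrs131_pedigree()
  vs <- variant_set(v, mk_geno(ped, 10))
  counts <- data.frame(
    chrom = "1", pos = v$pos, ref = v$ref, alt = v$alt,
    het_controls = c(0L, 0L, 1L, 0L, 1L, 5L, 6L, 10L, 7L, NA),
    het_cases = c(0L, 0L, 0L, 0L, 1L, 3L, 8L, 9L, 2L, NA),
    n_controls = 180L, n_cases = 179L, stringsAsFactors = FALSE)
  counts$key <- variant_key(counts$chrom, counts$pos, counts$ref, counts$alt)
  keys <- vs_keys(vs)
  lods <- stats::setNames(as.list(c(rep(1.50515, 9), 0)), keys)
  ann <- data.frame(
    gene = c("HSPG2", "ARHGEF10L", "CNKSR1", "PER3", "RERE", "CDK11B",
             "DOCK5", "CCDC27", "OR8G5"),
    kidney_expressed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE),
    prior_disease_association = c(TRUE, rep(FALSE, 8)),
    prior_score = c(29.6, 8.3, 8, 80, 17.4, 2.6, 7.3, 0, 1),
    stringsAsFactors = FALSE)
  list(vs = vs, counts = counts, keys = keys, lods = lods, ann = ann)
}

test_that("the composite ranking selects the index candidate first", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  ranking <- rank_candidates(px$vs, screens, px$lods, px$ann)
  top <- ranking[ranking$rank == 1, ]
  expect_equal(top$gene, "HSPG2")
  expect_equal(top$key, px$keys[1])  # p.Asp775Glu analogue, not p.Val3123Met
  expect_equal(sort(ranking$rank), 1:10)
  # single survivor is rank 1 regardless of weights
  solo <- rank_candidates(vs_subset(px$vs, 2), screens[2, , drop = FALSE],
                          px$lods[2], px$ann)
  expect_equal(solo$rank, 1L)
})

test_that("ranking is invariant to input order", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  base <- rank_candidates(px$vs, screens, px$lods, px$ann)
  ref <- stats::setNames(base$rank, base$key)
  set.seed(14)
  for (i in 1:20) {
    perm <- sample(10)
    r <- rank_candidates(vs_subset(px$vs, perm),
                         screens[perm, , drop = FALSE], px$lods[perm],
                         px$ann)
    expect_equal(stats::setNames(r$rank, r$key)[names(ref)], ref)
  }
})

test_that("a cohort polymorphism never outranks a rare segregating candidate", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  set.seed(15)
  for (i in 1:20) {
    keep <- sort(sample(10, sample(3:10, 1)))
    r <- rank_candidates(vs_subset(px$vs, keep),
                         screens[keep, , drop = FALSE], px$lods[keep],
                         px$ann)
    rare_seg <- !r$is_polymorphism & r$segregates == 1
    if (any(rare_seg) && any(r$is_polymorphism)) {
      expect_true(max(r$rank[rare_seg]) < min(r$rank[r$is_polymorphism]))
    }
  }
})

test_that("unknown weight keys and missing screens are configuration errors", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  expect_error(rank_candidates(px$vs, screens, px$lods, px$ann,
                               weights = c(bogus = 1)),
               class = "famfunnel_config_error")
  expect_error(rank_candidates(px$vs, screens[-1, ], px$lods, px$ann),
               class = "famfunnel_config_error")
})

test_that("a failed-validation override removes the variant before ranking", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  validated <- stats::setNames(FALSE, px$keys[10])  # the false positive
  r <- rank_candidates(px$vs, screens, px$lods, px$ann,
                       validated = validated)
  expect_equal(nrow(r), 9L)
  expect_false(px$keys[10] %in% r$key)
})

test_that("the summary table prints the published cells and round-trips counts", {
  px <- published_candidates()
  screens <- cohort_screen(px$keys, px$counts)
  tab <- build_summary_table(px$vs, screens, px$lods, px$ann)
  v3123m <- tab[tab$gene == "HSPG2" & grepl("107", tab$variant), ]
  expect_equal(v3123m$controls, "6 (0.033)")
  expect_equal(v3123m$cases, "8 (0.044)")
  expect_equal(tab$segregation[1], "Yes (1.50)")
  expect_equal(tab$segregation[10], "No (0.00)")
  expect_equal(tab$causative[1], "Yes")
  expect_equal(tab$causative[7], "No")   # polymorphism
  expect_equal(tab$controls[10], "ND")
  expect_equal(parse_cohort_cell(tab$controls), px$counts$het_controls)
  expect_equal(parse_cohort_cell(tab$cases), px$counts$het_cases)
  # empty survivor set gives a header-only table
  empty <- build_summary_table(vs_subset(px$vs, integer(0)),
                               screens[0, ], list(), px$ann)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene", "variant", "controls", "cases") %in%
                    names(empty)))
})

test_that("formatted cells round-trip on random cohort screens", {
  set.seed(16)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    h <- sample(0:n, 1)
    cell <- if (h == 0) "0" else sprintf("%d (%.3f)",
                                         h, carrier_frequency(h, n))
    expect_equal(parse_cohort_cell(cell), h)
  }
})
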