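vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="c">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
    '##INFO=<ID=SIFT,Number=A,Type=Float,Description="s">',
    '##INFO=<ID=POLYPHEN,Number=A,Type=Float,Description="p">',
    '##INFO=<ID=REVEL,Number=A,Type=Float,Description="r">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("an affected-only heterozygous record parses to the affected sample set", {
  ped <- ubrs131_pedigree()
  gts <- ifelse(ubrs131_genotypes() == 1, "0/1", "0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(names(gts)),
               paste(c("1", "2325", ".", "C", "G", ".", "PASS",
                       "GENE=HSPG2;CSQ=missense;SIFT=0.171;POLYPHEN=0.997;REVEL=0.478",
                       "GT", gts), collapse = "\t")), path)
  vs <- read_annotated_vcf(path)
  expect_equal(n_variants(vs), 1L)
  expect_equal(vs$variants$gene, "HSPG2")
  expect_equal(vs$variants$consequence, "missense")
  expect_true(is.na(vs$variants$pop_af))  # missing stays missing, no default
  het <- vs_samples(vs)[vs$geno[1, ] == 1]
  expect_setequal(het, ped$members$id[ped$members$affection == "affected"])
})

test_that("a VCF with no records yields an empty variant set", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_header(c("S1", "S2")), path)
  vs <- read_annotated_vcf(path)
  expect_equal(n_variants(vs), 0L)
})

test_that("multi-allelic sites split into per-ALT records preserving dosage totals", {
  samples <- c("S1", "S2", "S3", "S4")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples),
               paste(c("2", "500", ".", "A", "T,G", ".", "PASS",
                       "GENE=GX;CSQ=missense;AF=0.001,0.002",
                       "GT", "0/1", "1/2", "2/2", "0/0"), collapse = "\t")),
             path)
  vs <- read_annotated_vcf(path)
  expect_equal(n_variants(vs), 2L)
  expect_equal(vs$variants$alt, c("T", "G"))
  expect_equal(vs$variants$pop_af, c(0.001, 0.002))
  # hand-split dosages: T carried by S1 (1) and S2 (1); G by S2 (1), S3 (2)
  expect_equal(unname(vs$geno[1, ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(vs$geno[2, ]), c(0L, 1L, 2L, 0L))
  # splitting preserves the total count of non-reference allele calls
  expect_equal(sum(vs$geno), 1L + 2L + 2L)
})

test_that("phased separators and missing calls are handled", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(c("S1", "S2", "S3")),
               paste(c("1", "10", ".", "A", "C", ".", ".", ".",
                       "GT", "0|1", "./.", "1|1"), collapse = "\t")), path)
  vs <- read_annotated_vcf(path)
  expect_equal(unname(vs$geno[1, ]), c(1L, NA_integer_, 2L))
  expect_true(is.na(vs$variants$gene))
})

test_that("writing then re-reading a variant set is lossless", {
  ped <- ubrs131_pedigree()
  set.seed(11)
  vs <- mk_vs(ped, n = 6,
              pos = c(100L, 200L, 300L, 400L, 500L, 600L),
              consequence = c("missense", "synonymous", "splice_region",
                              "intronic", "stop_gain", "missense"),
              pop_af = c(NA, 0.25, 0.000057, NA, 0.5, 0.00008),
              sift = c(0.008, NA, 0.171, 1, 0, NA),
              polyphen = c(0.979, NA, 0.997, 0.5, 1, NA),
              revel = c(0.364, NA, 0.478, 0.999999, 0, NA))
  vs$geno[2, 3] <- NA_integer_
  vs$geno[3, 1] <- 2L
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(vs, path)
  back <- read_annotated_vcf(path)
  expect_equal(back$variants[names(vs$variants)], vs$variants)
  expect_equal(back$geno, vs$geno)
})

test_that("sample filtering drops and warns about unexpected columns", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(c("S1", "S2", "EXTRA")),
               paste(c("1", "10", ".", "A", "C", ".", ".", ".",
                       "GT", "0/1", "0/0", "0/1"), collapse = "\t")), path)
  expect_warning(vs <- read_annotated_vcf(path, samples = c("S1", "S2")),
                 "EXTRA")
  expect_equal(vs_samples(vs), c("S1", "S2"))
})

test_that("panel files parse with set semantics and symbol normalization", {
  gene_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("hspg2", "# comment", "", "SLC34A1"), gene_path)
  var_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "1\t100\tA\tT", "1\t100\tA\tT", "2\t200\tC\tG",
               "3\t300\tG\tA", "4\t400\tT\tC"), var_path)
  panel <- read_panel(gene_path, var_path)
  expect_setequal(panel$genes, c("HSPG2", "SLC34A1"))
  expect_equal(nrow(panel$known_variants), 4L)  # duplicate collapsed

  empty_g <- withr::local_tempfile(); file.create(empty_g)
  empty_v <- withr::local_tempfile(); file.create(empty_v)
  empty <- read_panel(empty_g, empty_v)
  expect_length(empty$genes, 0)
  expect_equal(nrow(empty$known_variants), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t100\tA\tT", "1\tnot_a_position\tA"), bad)
  expect_error(read_panel(NULL, bad), "line 2",
               class = "famfunnel_parse_error")
})

test_that("auxiliary tables validate their contents", {
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf", "1\t5\tA\tT\t0.02"), lf)
  freqs <- read_local_freq(lf)
  expect_equal(unname(freqs["1:5:A:T"]), 0.02)

  bad_lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf", "1\t5\tA\tT\t1.5"), bad_lf)
  expect_error(read_local_freq(bad_lf), class = "famfunnel_data_error")

  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tkidney_expressed\tprior_disease_association\tprior_score",
               "hspg2\tTRUE\tTRUE\t29.6"), ann)
  a <- read_gene_annotations(ann)
  expect_equal(a$gene, "HSPG2")
  expect_true(a$kidney_expressed)

  cc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "het_controls",
                     "het_cases", "n_controls", "n_cases", sep = "\t"),
               "1\t5\tA\tT\t200\t0\t180\t179"), cc)
  expect_error(read_cohort_counts(cc), class = "famfunnel_data_error")
})
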