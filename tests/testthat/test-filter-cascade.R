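ped8 <- ubrs131_pedigree()

test_that("known-variant exclusion drops exact matches and flags panel genes", {
  vs <- mk_vs(ped8, n = 3, pos = c(100L, 200L, 300L),
              gene = c("HSPG2", "GX", "GY"))
  panel <- read_panel_from_strings(
    genes = "HSPG2",
    variants = c("chrom\tpos\tref\talt", "1\t200\tA\tT"))
  out <- exclude_known(vs, panel)
  expect_equal(n_variants(out), 2L)
  expect_false("1:200:A:T" %in% vs_keys(out))
  # panel-gene variant not matching a known coordinate: retained + flagged
  expect_true(out$variants$panel_gene[out$variants$gene == "HSPG2"])
  expect_false(out$variants$panel_gene[out$variants$gene == "GY"])
  # no panel at all is the identity (modulo the flag column)
  expect_equal(n_variants(exclude_known(vs, NULL)), 3L)
})

test_that("dominant segregation keeps exactly the affected-only het pattern", {
  keep_gt <- mk_geno(ped8, 1)
  all_het <- matrix(1L, 1, 8, dimnames = list(NULL, ped8$members$id))
  vs <- variant_set(mk_variants(2, pos = c(1L, 2L)),
                    rbind(keep_gt, all_het))
  out <- ad_segregation_filter(vs, ped8)
  expect_equal(vs_keys(out), "1:1:A:T")
})

test_that("over all 256 hom-ref/het patterns exactly one segregates", {
  ids <- ped8$members$id
  patterns <- as.matrix(expand.grid(rep(list(0:1), 8)))
  colnames(patterns) <- ids
  vs <- variant_set(mk_variants(nrow(patterns),
                                pos = seq_len(nrow(patterns))),
                    patterns)
  out <- ad_segregation_filter(vs, ped8)
  expect_equal(n_variants(out), 1L)
  expect_equal(unname(out$geno[1, ids]),
               unname(ubrs131_genotypes()[ids]))
})

test_that("missing and homozygous-alternate calls are handled per policy", {
  g <- mk_geno(ped8, 4)
  g[1, "II:1"] <- NA_integer_  # missing in an affected -> excluded
  g[2, "II:2"] <- NA_integer_  # missing in an unaffected
  g[3, "I:1"] <- 2L            # hom-alt anywhere -> excluded
  vs <- variant_set(mk_variants(4, pos = 1:4), g)
  strict <- ad_segregation_filter(vs, ped8)
  expect_equal(vs_keys(strict), "1:4:A:T")
  lenient <- ad_segregation_filter(vs, ped8, lenient_unaffected = TRUE)
  expect_setequal(vs_keys(lenient), c("1:2:A:T", "1:4:A:T"))
})

test_that("segregation filter demands genotypes for every pedigree member", {
  vs <- variant_set(mk_variants(1),
                    matrix(0L, 1, 2, dimnames = list(NULL, c("I:1", "I:2"))))
  expect_error(ad_segregation_filter(vs, ped8), "II:1",
               class = "famfunnel_config_error")
})

test_that("consequence filter keeps the retained classes only", {
  vs <- mk_vs(ped8, n = 10, pos = 1:10,
              consequence = c("missense", "splice_region", "stop_gain",
                              "inframe_or_frameshift_indel", "synonymous",
                              "synonymous", "intronic", "other", "other",
                              NA))
  out <- consequence_filter(vs)
  expect_equal(n_variants(out), 4L)
  expect_true(all(out$variants$consequence %in%
                    funnel_config()$retained_consequences))
  # a splice-region record is retained under the default set
  expect_true("1:2:A:T" %in% vs_keys(out))
})

test_that("population frequency filter is strict and treats missing as rare", {
  vs <- mk_vs(ped8, n = 4, pos = 1:4,
              pop_af = c(0.00008, 0.5, 0.01, NA))
  out <- maf_filter(vs)
  expect_setequal(vs_keys(out), c("1:1:A:T", "1:4:A:T"))  # 0.01 excluded
})

test_that("local frequency filter drops listed common variants only", {
  vs <- mk_vs(ped8, n = 6, pos = 1:6)
  local <- c("1:2:A:T" = 0.02, "1:5:A:T" = 0.30, "1:6:A:T" = 0.001)
  out <- local_db_filter(vs, local)
  expect_equal(n_variants(out), 4L)
  expect_false(any(c("1:2:A:T", "1:5:A:T") %in% vs_keys(out)))
  expect_true("1:6:A:T" %in% vs_keys(out))  # below threshold stays
  expect_equal(n_variants(local_db_filter(vs, NULL)), 6L)
})

test_that("every filter is idempotent on its own output", {
  set.seed(21)
  sim <- generate_dataset(sim_config(seed = 21), withr::local_tempdir())
  vs <- sim$variants
  panel <- read_panel(sim$paths$panel_genes, sim$paths$panel_variants)
  local <- read_local_freq(sim$paths$local_af)
  filters <- list(
    function(v) exclude_known(v, panel),
    function(v) ad_segregation_filter(v, ped8),
    function(v) consequence_filter(v),
    function(v) maf_filter(v),
    function(v) local_db_filter(v, local),
    function(v) consensus_filter(v))
  for (f in filters) {
    once <- f(vs)
    twice <- f(once)
    expect_equal(vs_keys(twice), vs_keys(once))
  }
})

test_that("the funnel matches a per-record predicate oracle and is order-invariant", {
  for (seed in c(5, 6)) {
    sim <- generate_dataset(sim_config(seed = seed, n_decoys_per_class = 2),
                            withr::local_tempdir())
    vs <- sim$variants
    panel <- read_panel(sim$paths$panel_genes, sim$paths$panel_variants)
    local <- read_local_freq(sim$paths$local_af)
    res <- run_funnel(vs, ped8, panel, local)
    oracle_keep <- brute_funnel_keep(vs, ped8, panel_variant_keys(panel),
                                     local, funnel_config(), consensus_rule())
    expect_setequal(vs_keys(res$survivors), vs_keys(vs)[oracle_keep])

    set.seed(seed)
    perm <- sample(FUNNEL_STAGES)
    res2 <- run_funnel(vs, ped8, panel, local, stages = perm)
    expect_setequal(vs_keys(res2$survivors), vs_keys(res$survivors))
    expect_equal(res2$report$stage, perm)
  }
})

test_that("funnel reports chain counts and handle empty input", {
  sim <- generate_dataset(sim_config(seed = 31), withr::local_tempdir())
  panel <- read_panel(sim$paths$panel_genes, sim$paths$panel_variants)
  res <- run_funnel(sim$variants, ped8, panel)
  rep <- res$report
  expect_true(all(rep$n_out <= rep$n_in))
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])

  empty <- vs_subset(sim$variants, integer(0))
  res0 <- run_funnel(empty, ped8, panel)
  expect_equal(n_variants(res0$survivors), 0L)
  expect_true(all(res0$report$n_in == 0L) && all(res0$report$n_out == 0L))
})

test_that("dropping the consensus stage reproduces the five-stage survivor set", {
  sim <- generate_dataset(sim_config(seed = 41), withr::local_tempdir())
  panel <- read_panel(sim$paths$panel_genes, sim$paths$panel_variants)
  five <- run_funnel(sim$variants, ped8, panel,
                     stages = setdiff(FUNNEL_STAGES, "consensus"))
  manual <- local_db_filter(
    maf_filter(consequence_filter(ad_segregation_filter(
      exclude_known(sim$variants, panel), ped8))), NULL)
  expect_setequal(vs_keys(five$survivors), vs_keys(manual))
  # the benign-consensus decoys are exactly the extra survivors
  extra <- setdiff(vs_keys(five$survivors),
                   vs_keys(run_funnel(sim$variants, ped8, panel)$survivors))
  classes <- sim$truth$class[match(extra, sim$truth$key)]
  expect_true(all(classes == "benign_consensus"))
})
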