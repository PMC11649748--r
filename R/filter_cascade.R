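# The ordered variant-filtering funnel.
#
# Six conjunctive stages: known-variant exclusion, autosomal-dominant
# segregation, consequence class, population allele frequency, local
# population frequency, and the k-of-3 pathogenicity consensus.  Each stage
# is an idempotent predicate filter; because the predicates are conjunctive
# the final survivor set is invariant to stage order (per-stage counts, of
# course, are not).

#' Funnel configuration
#'
#' @param maf_threshold keep variants with population allele frequency
#'   strictly below this value (missing frequency = kept, since novel
#'   variants absent from databases are the discovery target).
#' @param retained_consequences consequence classes kept by the consequence
#'   stage; the default is the union of protein-altering and splice classes.
#' @param local_af_threshold drop variants at or above this frequency in the
#'   local population table (absent from the table = kept).
#' @return a `funnel_config` list.
#' @export
funnel_config <- function(maf_threshold = 0.01,
                          retained_consequences = c(
                            "missense", "stop_gain", "stop_loss",
                            "inframe_or_frameshift_indel",
                            "splice_region", "splice_site"),
                          local_af_threshold = 0.01) {
  for (th in c(maf_threshold, local_af_threshold)) {
    if (!is.numeric(th) || length(th) != 1 || th <= 0 || th > 1) {
      ff_config_error("funnel thresholds must lie in (0, 1]")
    }
  }
  bad <- setdiff(retained_consequences, CONSEQUENCE_CLASSES)
  if (length(bad)) {
    ff_config_error(paste0("unknown consequence class(es): ",
                           paste(bad, collapse = ", ")))
  }
  structure(list(maf_threshold = maf_threshold,
                 retained_consequences = retained_consequences,
                 local_af_threshold = local_af_threshold),
            class = "funnel_config")
}

#' Exclude catalogued known variants
#'
#' Removes variants whose exact (chrom, pos, ref, alt) coordinates appear in
#' the panel's known-variant list.  Variants merely lying in a panel gene
#' are retained and flagged `panel_gene = TRUE` -- gene membership is
#' evidence, not grounds for exclusion.
#'
#' @param vs a `variant_set`.
#' @param panel a `panel_set` from [read_panel()], or `NULL` for none.
#' @return the filtered `variant_set`, with a `panel_gene` column added.
#' @export
exclude_known <- function(vs, panel = NULL) {
  if (is.null(panel)) {
    vs$variants$panel_gene <- rep(FALSE, n_variants(vs))
    return(vs)
  }
  vs$variants$panel_gene <- !is.na(vs$variants$gene) &
    vs$variants$gene %in% panel$genes
  keep <- !(vs_keys(vs) %in% panel_variant_keys(panel))
  vs_subset(vs, keep)
}

#' Autosomal-dominant segregation filter
#'
#' Keeps exactly the variants heterozygous (dosage 1) in every affected
#' pedigree member and homozygous reference (dosage 0) in every unaffected
#' member.  A homozygous-alternate call anywhere excludes the variant, as
#' does a missing call in an affected member (a causal dominant allele must
#' be observable in every affected).  A missing call in an unaffected
#' member excludes by default; `lenient_unaffected = TRUE` tolerates it,
#' since "absent in unaffected" is unverifiable on a missing call.
#' Members of unknown affection status are ignored.
#'
#' @param vs a `variant_set` whose samples cover every pedigree member.
#' @param ped a `fam_pedigree`.
#' @param lenient_unaffected tolerate missing calls in unaffected members.
#' @return the filtered `variant_set`.
#' @export
ad_segregation_filter <- function(vs, ped, lenient_unaffected = FALSE) {
  missing_samples <- setdiff(ped$members$id, vs_samples(vs))
  if (length(missing_samples)) {
    ff_config_error(paste0(
      "pedigree member(s) without a genotype column in the VCF: ",
      paste(missing_samples, collapse = ", ")))
  }
  if (n_variants(vs) == 0L) return(vs)
  aff <- ped$members$id[ped$members$affection == "affected"]
  una <- ped$members$id[ped$members$affection == "unaffected"]
  g <- vs$geno[, ped$members$id, drop = FALSE]
  no_homalt <- apply(g, 1, function(r) all(is.na(r) | r != 2L))
  aff_ok <- apply(g[, aff, drop = FALSE], 1,
                  function(r) all(!is.na(r) & r == 1L))
  una_ok <- if (lenient_unaffected) {
    apply(g[, una, drop = FALSE], 1, function(r) all(is.na(r) | r == 0L))
  } else {
    apply(g[, una, drop = FALSE], 1, function(r) all(!is.na(r) & r == 0L))
  }
  vs_subset(vs, no_homalt & aff_ok & una_ok)
}

#' Consequence-class filter
#'
#' Keeps variants whose consequence class is in
#' `cfg$retained_consequences`; a missing consequence excludes.
#'
#' @param vs a `variant_set`.
#' @param cfg a [funnel_config()].
#' @return the filtered `variant_set`.
#' @export
consequence_filter <- function(vs, cfg = funnel_config()) {
  keep <- !is.na(vs$variants$consequence) &
    vs$variants$consequence %in% cfg$retained_consequences
  vs_subset(vs, keep)
}

#' Population allele-frequency filter
#'
#' Keeps variants with `pop_af` strictly below `cfg$maf_threshold`, or with
#' no recorded population frequency (novel variants are rare by
#' presumption).
#'
#' @inheritParams consequence_filter
#' @return the filtered `variant_set`.
#' @export
maf_filter <- function(vs, cfg = funnel_config()) {
  keep <- is.na(vs$variants$pop_af) | vs$variants$pop_af < cfg$maf_threshold
  vs_subset(vs, keep)
}

#' Local population frequency filter
#'
#' Removes variants whose frequency in the local population table is at or
#' above `cfg$local_af_threshold`; variants absent from the table are
#' retained.
#'
#' @inheritParams consequence_filter
#' @param local named frequency vector from [read_local_freq()], or `NULL`.
#' @return the filtered `variant_set`.
#' @export
local_db_filter <- function(vs, local = NULL, cfg = funnel_config()) {
  if (is.null(local) || n_variants(vs) == 0L) return(vs)
  af <- local[vs_keys(vs)]
  keep <- is.na(af) | af < cfg$local_af_threshold
  vs_subset(vs, keep)
}

#' Pathogenicity-consensus filter stage
#'
#' Applies [consensus_pass()] to each variant's score bundle.  Variants
#' with no evaluable score (all three predictors missing, as for
#' splice-region and intronic records) bypass the stage under the rule's
#' default bypass policy.
#'
#' @param vs a `variant_set`.
#' @param rule a [consensus_rule()].
#' @return the filtered `variant_set`.
#' @export
consensus_filter <- function(vs, rule = consensus_rule()) {
  if (n_variants(vs) == 0L) return(vs)
  cp <- consensus_pass(vs$variants$sift, vs$variants$polyphen,
                       vs$variants$revel, rule)
  vs_subset(vs, cp$pass)
}

#' The funnel stage names, in their default order
#'
#' @format character vector of stage names accepted by [run_funnel()].
#' @export
FUNNEL_STAGES <- c("known", "segregation", "consequence", "maf", "local",
                   "consensus")

#' Run the full filtering funnel
#'
#' Applies the stages in `stages` order (default: known-variant exclusion,
#' dominant segregation, consequence class, population frequency, local
#' frequency, pathogenicity consensus) and records per-stage in/out counts.
#' The survivor set is order-invariant because every stage is a conjunctive
#' predicate; the per-stage counts mirror whatever order was configured.
#'
#' @param vs a `variant_set`.
#' @param ped a `fam_pedigree`.
#' @param panel optional `panel_set`.
#' @param local optional named frequency vector ([read_local_freq()]).
#' @param cfg a [funnel_config()].
#' @param rule a [consensus_rule()].
#' @param stages character vector, a permutation of (a subset of)
#'   `c("known", "segregation", "consequence", "maf", "local", "consensus")`.
#' @param lenient_unaffected see [ad_segregation_filter()].
#' @return a `funnel_result`: list with `survivors` (a `variant_set`) and
#'   `report` (data.frame `stage`, `n_in`, `n_out`).
#' @export
run_funnel <- function(vs, ped, panel = NULL, local = NULL,
                       cfg = funnel_config(), rule = consensus_rule(),
                       stages = FUNNEL_STAGES,
                       lenient_unaffected = FALSE) {
  bad <- setdiff(stages, FUNNEL_STAGES)
  if (length(bad) || anyDuplicated(stages)) {
    ff_config_error(paste0("stages must be distinct names among: ",
                           paste(FUNNEL_STAGES, collapse = ", ")))
  }
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
  for (stage in stages) {
    n_in <- n_variants(vs)
    vs <- switch(stage,
      known = exclude_known(vs, panel),
      segregation = ad_segregation_filter(vs, ped, lenient_unaffected),
      consequence = consequence_filter(vs, cfg),
      maf = maf_filter(vs, cfg),
      local = local_db_filter(vs, local, cfg),
      consensus = consensus_filter(vs, rule))
    report <- rbind(report, data.frame(stage = stage, n_in = n_in,
                                       n_out = n_variants(vs),
                                       stringsAsFactors = FALSE))
  }
  structure(list(survivors = vs, report = report), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("<funnel_result>\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("%d survivor(s)\n", n_variants(x$survivors)))
  invisible(x)
}

#' Write a funnel report as TSV and/or JSON
#'
#' @param report the `report` data.frame of a [run_funnel()] result.
#' @param tsv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_funnel_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(report, json, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(report)
}
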