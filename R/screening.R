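# Case/control carrier screening and composite candidate ranking.
#
# Frequencies in the screening report are carrier (heterozygote)
# frequencies -- the fraction of individuals carrying one alternate allele
# -- not allele frequencies, and are truncated (not rounded) to three
# decimals in the table dialect: 8 heterozygotes among 179 cases prints as
# 0.044, never 0.045.

#' Carrier (heterozygote) frequency with report formatting
#'
#' @param het_count number of heterozygous carriers observed.
#' @param n cohort size (individuals, >= 1).
#' @param decimals decimal places kept in the formatted value.
#' @param mode `"truncate"` (default, the report dialect) or `"round"`.
#' @return `het_count / n` formatted to `decimals` places under `mode`.
#' @examples
#' carrier_frequency(6, 180)   # 0.033
#' carrier_frequency(8, 179)   # 0.044 (rounding would give 0.045)
#' @export
carrier_frequency <- function(het_count, n, decimals = 3,
                              mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (anyNA(n) || any(n < 1)) ff_data_error("cohort size n must be >= 1")
  if (anyNA(het_count) || any(het_count < 0 | het_count > n)) {
    ff_data_error("het_count must lie in [0, n]")
  }
  x <- het_count / n
  if (mode == "truncate") truncate_decimal(x, decimals)
  else round(x, decimals)
}

#' Allele frequency from allele counts
#'
#' Chromosome-level frequency `allele_count / allele_number`, rounded --
#' the convention of population databases, as opposed to the truncating
#' carrier-frequency dialect of the screening table.
#'
#' @param allele_count alternate allele count (>= 0).
#' @param allele_number total allele number (>= 1).
#' @param decimals decimal places (default 6).
#' @return the rounded allele frequency.
#' @examples
#' allele_frequency(8, 140282, 6)  # 0.000057
#' allele_frequency(1, 13006, 5)   # 0.00008
#' @export
allele_frequency <- function(allele_count, allele_number, decimals = 6) {
  if (any(allele_number < 1)) ff_data_error("allele_number must be >= 1")
  if (any(allele_count < 0 | allele_count > allele_number)) {
    ff_data_error("allele_count must lie in [0, allele_number]")
  }
  round(allele_count / allele_number, decimals)
}

#' Classify a variant as a common polymorphism
#'
#' A variant is a polymorphism when its unformatted control carrier
#' frequency strictly exceeds the threshold (default 1%).  Polymorphisms
#' are retained in the report but never promoted to causative candidates.
#'
#' @param het_controls heterozygote count in controls (`NA` = not
#'   determined, classified `FALSE`).
#' @param n_controls control cohort size.
#' @param threshold polymorphism frequency threshold (strict greater-than).
#' @return logical vector.
#' @export
classify_polymorphism <- function(het_controls, n_controls,
                                  threshold = 0.01) {
  !is.na(het_controls) & (het_controls / n_controls > threshold)
}

#' Build per-variant cohort screening records
#'
#' Joins a variant key vector against a cohort count table
#' ([read_cohort_counts()]) and computes formatted carrier frequencies and
#' the polymorphism call.  Keys without counts get `NA` counts ("not
#' determined").
#'
#' @param keys character vector of variant keys (`"chrom:pos:ref:alt"`).
#' @param counts data.frame from [read_cohort_counts()].
#' @param threshold polymorphism threshold, see [classify_polymorphism()].
#' @return data.frame: `key`, `het_controls`, `het_cases`, `n_controls`,
#'   `n_cases`, `freq_controls`, `freq_cases`, `is_polymorphism`.
#' @export
cohort_screen <- function(keys, counts, threshold = 0.01) {
  i <- match(keys, counts$key)
  nctl <- counts$n_controls[i]
  ncas <- counts$n_cases[i]
  hctl <- counts$het_controls[i]
  hcas <- counts$het_cases[i]
  data.frame(
    key = keys,
    het_controls = hctl,
    het_cases = hcas,
    n_controls = nctl,
    n_cases = ncas,
    freq_controls = ifelse(is.na(hctl), NA_real_,
                           carrier_frequency(ifelse(is.na(hctl), 0, hctl),
                                             ifelse(is.na(nctl), 1, nctl))),
    freq_cases = ifelse(is.na(hcas), NA_real_,
                        carrier_frequency(ifelse(is.na(hcas), 0, hcas),
                                          ifelse(is.na(ncas), 1, ncas))),
    is_polymorphism = classify_polymorphism(hctl, nctl, threshold),
    stringsAsFactors = FALSE
  )
}

#' Default ranking weights
#'
#' Powers of two ordering the binary evidence components lexicographically:
#' segregation dominates everything, then absence from both cohorts, then
#' prior disease association, then pathogenicity consensus, then kidney
#' expression; the scaled prior score (in \[0, 1\]) only breaks ties among
#' otherwise equal candidates.
#'
#' @return named numeric vector of weights.
#' @export
default_rank_weights <- function() {
  c(segregates = 32, zero_cohort_carriers = 16, prior_association = 8,
    consensus_pass = 4, kidney_expressed = 2, prior_score_scaled = 1)
}

#' Composite candidate ranking
#'
#' Scores every funnel survivor as a weighted sum of evidence components:
#' `segregates` (LOD > 0), `zero_cohort_carriers` (no carrier in either
#' cohort), `prior_association` and `kidney_expressed` (from the gene
#' annotation table; genes missing from it get all-false flags),
#' `consensus_pass` (k-of-3 pathogenicity consensus, unevaluable bundles
#' bypassing), and `prior_score_scaled` (prior score divided by the maximum
#' prior score among the candidates).  Variants classified as cohort
#' polymorphisms are demoted below every non-polymorphic candidate
#' regardless of score, so a common variant can never outrank a rare
#' segregating one.  Ties break deterministically on (chrom, pos, ref,
#' alt), so input order never affects ranks.
#'
#' @param vs `variant_set` of funnel survivors.
#' @param screens data.frame from [cohort_screen()], aligned by key.
#' @param lods named list of `lod_result` objects (or named numeric LOD
#'   vector), keyed by variant key.
#' @param annotations data.frame from [read_gene_annotations()].
#' @param weights named weights, see [default_rank_weights()].
#' @param rule a [consensus_rule()] for the consensus component.
#' @param validated optional named logical; variants explicitly marked
#'   `FALSE` (failed wet-lab validation, i.e. sequencing false positives)
#'   are removed before ranking.
#' @return data.frame with key, gene, the six components, `total`,
#'   `is_polymorphism` and `rank` (a permutation of 1..n).
#' @export
rank_candidates <- function(vs, screens, lods, annotations = NULL,
                            weights = default_rank_weights(),
                            rule = consensus_rule(), validated = NULL) {
  expected <- names(default_rank_weights())
  if (!setequal(names(weights), expected)) {
    ff_config_error(paste0("ranking weights must have exactly the keys: ",
                           paste(expected, collapse = ", ")))
  }
  keys <- vs_keys(vs)
  if (!is.null(validated)) {
    drop <- names(validated)[!is.na(validated) & !validated]
    keep <- !(keys %in% drop)
    vs <- vs_subset(vs, keep)
    keys <- vs_keys(vs)
  }
  if (n_variants(vs) == 0L) {
    return(data.frame(key = character(0), gene = character(0),
                      segregates = numeric(0), zero_cohort_carriers = numeric(0),
                      prior_association = numeric(0), consensus_pass = numeric(0),
                      kidney_expressed = numeric(0),
                      prior_score_scaled = numeric(0), total = numeric(0),
                      is_polymorphism = logical(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  si <- match(keys, screens$key)
  if (any(is.na(si))) {
    ff_config_error("every survivor needs a cohort screen record")
  }
  scr <- screens[si, , drop = FALSE]
  lod_of <- function(key) {
    x <- lods[[key]]
    if (is.null(x)) ff_config_error(
      paste0("every survivor needs a LOD result; missing: ", key))
    if (inherits(x, "lod_result")) x$lod else as.numeric(x)
  }
  lod_vals <- vapply(keys, lod_of, numeric(1))

  ann_match <- if (is.null(annotations)) rep(NA_integer_, length(keys))
               else match(vs$variants$gene, annotations$gene)
  kidney <- ifelse(is.na(ann_match), FALSE,
                   annotations$kidney_expressed[ann_match])
  assoc <- ifelse(is.na(ann_match), FALSE,
                  annotations$prior_disease_association[ann_match])
  prior <- ifelse(is.na(ann_match), 0, annotations$prior_score[ann_match])
  prior_scaled <- if (max(prior) > 0) prior / max(prior) else prior

  cp <- consensus_pass(vs$variants$sift, vs$variants$polyphen,
                       vs$variants$revel, rule)
  comp <- data.frame(
    segregates = as.numeric(lod_vals > 0),
    zero_cohort_carriers = as.numeric(
      !is.na(scr$het_controls) & scr$het_controls == 0 &
      !is.na(scr$het_cases) & scr$het_cases == 0),
    prior_association = as.numeric(assoc),
    consensus_pass = as.numeric(cp$pass),
    kidney_expressed = as.numeric(kidney),
    prior_score_scaled = prior_scaled
  )
  total <- as.numeric(as.matrix(comp) %*% weights[names(comp)])
  out <- cbind(data.frame(key = keys, gene = vs$variants$gene,
                          stringsAsFactors = FALSE),
               comp,
               data.frame(total = total,
                          is_polymorphism = scr$is_polymorphism %in% TRUE,
                          stringsAsFactors = FALSE))
  ord <- order(out$is_polymorphism, -out$total, vs$variants$chrom,
               vs$variants$pos, vs$variants$ref, vs$variants$alt)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}

# "6 (0.033)" / "0" / "ND" cells of the screening table
format_cohort_cell <- function(het, n) {
  out <- rep("ND", length(het))
  out[!is.na(het) & het == 0] <- "0"
  pos <- !is.na(het) & het > 0
  if (any(pos)) {
    out[pos] <- sprintf("%d (%.3f)", het[pos],
                        carrier_frequency(het[pos], n[pos]))
  }
  out
}

#' Parse a screening-table cohort cell back to its carrier count
#'
#' Inverse of the `"count (frequency)"` cell format of
#' [build_summary_table()]: `"6 (0.033)"` gives 6, `"0"` gives 0, `"ND"`
#' gives `NA`.
#'
#' @param cell character vector of cells.
#' @return integer vector of carrier counts.
#' @export
parse_cohort_cell <- function(cell) {
  out <- rep(NA_integer_, length(cell))
  out[cell == "0"] <- 0L
  m <- regmatches(cell, regexec("^([0-9]+) \\(([0-9.]+)\\)$", cell))
  has <- lengths(m) == 3
  out[has] <- as.integer(vapply(m[has], `[`, character(1), 2))
  out
}

#' Build the per-variant summary table
#'
#' One row per surviving variant: gene, variant label, segregation call
#' with the truncated LOD, the three predictor scores with their category
#' letters, the prior gene score, formatted control and case cohort cells,
#' and the final causative call (`"Yes"` for variants that segregate and
#' are not cohort polymorphisms).
#'
#' @inheritParams rank_candidates
#' @return data.frame, one row per variant.
#' @export
build_summary_table <- function(vs, screens, lods, annotations = NULL,
                                rule = consensus_rule()) {
  keys <- vs_keys(vs)
  if (!length(keys)) {
    return(data.frame(gene = character(0), variant = character(0),
                      consequence = character(0), segregation = character(0),
                      revel = numeric(0), revel_cat = character(0),
                      sift = numeric(0), sift_cat = character(0),
                      polyphen = numeric(0), polyphen_cat = character(0),
                      prior_score = numeric(0), controls = character(0),
                      cases = character(0), causative = character(0),
                      stringsAsFactors = FALSE))
  }
  si <- match(keys, screens$key)
  scr <- screens[si, , drop = FALSE]
  lod_vals <- vapply(keys, function(k) {
    x <- lods[[k]]
    if (inherits(x, "lod_result")) x$lod else as.numeric(x)
  }, numeric(1))
  cats <- categorize(vs$variants$sift, vs$variants$polyphen,
                     vs$variants$revel, rule)
  ann_match <- if (is.null(annotations)) rep(NA_integer_, length(keys))
               else match(vs$variants$gene, annotations$gene)
  prior <- ifelse(is.na(ann_match), NA_real_,
                  annotations$prior_score[ann_match])
  segregates <- lod_vals > 0
  poly <- scr$is_polymorphism %in% TRUE
  data.frame(
    gene = vs$variants$gene,
    variant = sprintf("%s:%d %s>%s", vs$variants$chrom, vs$variants$pos,
                      vs$variants$ref, vs$variants$alt),
    consequence = vs$variants$consequence,
    segregation = sprintf("%s (%s)", ifelse(segregates, "Yes", "No"),
                          format_lod(lod_vals)),
    revel = vs$variants$revel, revel_cat = cats$revel_cat,
    sift = vs$variants$sift, sift_cat = cats$sift_cat,
    polyphen = vs$variants$polyphen, polyphen_cat = cats$polyphen_cat,
    prior_score = prior,
    controls = format_cohort_cell(scr$het_controls, scr$n_controls),
    cases = format_cohort_cell(scr$het_cases, scr$n_cases),
    causative = ifelse(segregates & !poly, "Yes", "No"),
    stringsAsFactors = FALSE
  )
}

#' Write the summary table as TSV and/or Markdown
#'
#' @param summary data.frame from [build_summary_table()].
#' @param tsv,md optional output paths.
#' @return the summary, invisibly.
#' @export
write_summary_table <- function(summary, tsv = NULL, md = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(summary, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  if (!is.null(md)) {
    cells <- as.matrix(format(summary))
    lines <- c(
      paste0("| ", paste(colnames(cells), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|"),
      apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
    writeLines(lines, md)
  }
  invisible(summary)
}
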