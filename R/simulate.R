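# Synthetic pedigree exome data by gene dropping.
#
# The generator writes a complete, self-consistent analysis input set --
# multi-sample annotated VCF, PED, panel files, local frequency table, gene
# annotation table, cohort carrier counts, truth labels and a manifest --
# with one planted causal variant plus decoy variants engineered to fail
# exactly one designated funnel stage and no earlier one.  All randomness
# flows from a single integer seed; floating-point annotation values are
# quantized to six decimals before writing so identical seeds give
# byte-identical files.

DECOY_CLASSES <- c("non_segregating", "common_maf", "excluded_consequence",
                   "benign_consensus", "known_panel_variant",
                   "cohort_polymorphism", "pass_all_decoy")

#' Simulation configuration
#'
#' The defaults reproduce the structure of the index study: the eight-member
#' two-generation kindred ([ubrs131_pedigree()]) with four affected members,
#' screening cohorts of 180 controls and 179 cases, ten decoys per class,
#' and the five decoy classes that fail the five non-trivial funnel stages
#' (`non_segregating`, `common_maf`, `excluded_consequence`,
#' `benign_consensus`, `known_panel_variant`).  Two further classes are
#' available: `cohort_polymorphism` (passes the funnel, flagged as a common
#' polymorphism at screening) and `pass_all_decoy` (passes everything and is
#' separated from the planted variant only at ranking).
#'
#' @param pedigree a `fam_pedigree`; genotypes are simulated for every
#'   member.
#' @param n_decoys_per_class decoys per class (>= 1).
#' @param decoy_classes subset of the available classes.
#' @param n_controls,n_cases screening cohort sizes.
#' @param causal_profile `"damaging"` (default; planted scores pass the
#'   2-of-3 consensus) or `"index_candidate"` (the discordant profile of
#'   the index family's HSPG2 p.Asp775Glu candidate: REVEL 0.478 N, SIFT
#'   0.171 T, PolyPhen 0.997 PD -- damaging by one tool only, so it
#'   survives only when the consensus stage is relaxed or bypassed).
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pedigree = ubrs131_pedigree(),
                       n_decoys_per_class = 10L,
                       decoy_classes = c("non_segregating", "common_maf",
                                         "excluded_consequence",
                                         "benign_consensus",
                                         "known_panel_variant"),
                       n_controls = 180L,
                       n_cases = 179L,
                       causal_profile = c("damaging", "index_candidate"),
                       seed = 1L) {
  causal_profile <- match.arg(causal_profile)
  bad <- setdiff(decoy_classes, DECOY_CLASSES)
  if (length(bad) || !length(decoy_classes)) {
    ff_config_error(paste0("decoy_classes must be a non-empty subset of: ",
                           paste(DECOY_CLASSES, collapse = ", ")))
  }
  if (n_decoys_per_class < 1) {
    ff_config_error("n_decoys_per_class must be >= 1")
  }
  if (n_affected(pedigree) < 1) {
    ff_data_error("simulation pedigree needs at least one affected member")
  }
  structure(list(pedigree = pedigree,
                 n_decoys_per_class = as.integer(n_decoys_per_class),
                 decoy_classes = unique(decoy_classes),
                 n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 causal_profile = causal_profile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Gene dropping: simulate Mendelian transmission of a founder allele
#'
#' The carrier founder is made heterozygous, all other founders homozygous
#' reference, and every transmission down the pedigree draws one of the
#' parent's two alleles with probability 1/2 independently -- so each
#' offspring of the carrier is a carrier with probability 1/2.  Outputs are
#' Mendelian-consistent by construction.
#'
#' @param ped a `fam_pedigree`.
#' @param founder_carrier id of the carrier founder.
#' @param n number of independent drops (rows of the output when > 1).
#' @param seed optional integer seed (set locally when given).
#' @return for `n = 1` a named dosage vector over members; for `n > 1` an
#'   `n x n_members` dosage matrix with member ids as column names.
#' @export
gene_drop <- function(ped, founder_carrier, n = 1L, seed = NULL) {
  m <- ped$members
  if (!(founder_carrier %in% m$id)) {
    ff_data_error(paste0("unknown individual id: ", founder_carrier))
  }
  if (!(founder_carrier %in% founder_ids(ped))) {
    ff_data_error(paste0(founder_carrier,
                         " is not a founder; gene dropping starts at founders"))
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(ped)
  k <- length(ord)
  # allele pairs per member, vectorized across the n drops
  a1 <- matrix(0L, n, k, dimnames = list(NULL, ord))
  a2 <- matrix(0L, n, k, dimnames = list(NULL, ord))
  a1[, founder_carrier] <- 1L
  for (id in ord) {
    i <- match(id, m$id)
    if (is.na(m$father[i])) next
    pick_f <- stats::runif(n) < 0.5
    pick_m <- stats::runif(n) < 0.5
    a1[, id] <- ifelse(pick_f, a1[, m$father[i]], a2[, m$father[i]])
    a2[, id] <- ifelse(pick_m, a1[, m$mother[i]], a2[, m$mother[i]])
  }
  dose <- a1 + a2
  dose <- dose[, m$id, drop = FALSE]  # restore pedigree member order
  if (n == 1L) stats::setNames(as.integer(dose[1, ]), m$id) else dose
}

#' Check a dosage configuration for Mendelian consistency
#'
#' A child's dosage must be attainable from one allele of each parent:
#' e.g. two homozygous-reference parents cannot have a carrier child.
#' Missing dosages are treated as compatible.
#'
#' @param ped a `fam_pedigree`.
#' @param dosages named dosage vector (0/1/2/NA) over pedigree members.
#' @return `TRUE` if consistent, `FALSE` otherwise.
#' @export
mendelian_consistent <- function(ped, dosages) {
  m <- ped$members
  rng <- function(d) { # possible transmitted alleles given dosage
    if (is.na(d)) c(0L, 1L) else switch(d + 1L, 0L, c(0L, 1L), 1L)
  }
  for (i in seq_len(nrow(m))) {
    if (is.na(m$father[i])) next
    d <- dosages[m$id[i]]
    if (is.na(d)) next
    pf <- rng(dosages[m$father[i]])
    pm <- rng(dosages[m$mother[i]])
    possible <- unique(as.vector(outer(pf, pm, `+`)))
    if (!(d %in% possible)) return(FALSE)
  }
  TRUE
}

# affected-only heterozygous dosage pattern (the causal configuration)
causal_pattern <- function(ped) {
  stats::setNames(as.integer(ped$members$affection == "affected"),
                  ped$members$id)
}

#' Plant the causal variant
#'
#' Builds the single-variant `variant_set` that the funnel must retain:
#' heterozygous in exactly the affected members and homozygous reference
#' elsewhere, missense, absent from population databases, with a score
#' bundle given by the configured causal profile (see [sim_config()]).
#'
#' @param ped a `fam_pedigree`.
#' @param causal_profile `"damaging"` or `"index_candidate"`.
#' @return a one-variant `variant_set` (gene `HSPG2`, the index candidate's
#'   coding position as a label).
#' @export
plant_causal_variant <- function(ped,
                                 causal_profile = c("damaging",
                                                    "index_candidate")) {
  causal_profile <- match.arg(causal_profile)
  scores <- if (causal_profile == "damaging") {
    list(sift = 0.01, polyphen = 0.98, revel = 0.75, pop_af = NA_real_)
  } else {
    # the discordant published profile: damaging by PolyPhen only
    list(sift = 0.171, polyphen = 0.997, revel = 0.478, pop_af = 0.00008)
  }
  variant_set(
    data.frame(chrom = "1", pos = 2325L, ref = "C", alt = "G",
               gene = "HSPG2", consequence = "missense",
               pop_af = scores$pop_af, sift = scores$sift,
               polyphen = scores$polyphen, revel = scores$revel,
               stringsAsFactors = FALSE),
    matrix(causal_pattern(ped), nrow = 1,
           dimnames = list(NULL, ped$members$id))
  )
}

# draw uniformly on the safe side of a threshold, 0.005 guard band away
runif_below <- function(n, threshold, guard = 0.005) {
  stats::runif(n, 0, max(threshold - guard, threshold / 2))
}
runif_above <- function(n, threshold, guard = 0.005, upper = 1) {
  stats::runif(n, min(threshold + guard, (threshold + upper) / 2), upper)
}

# one decoy variant row + genotype vector for a given class
make_decoy <- function(class, ped, pos, idx, rule, cfg) {
  pattern <- causal_pattern(ped)
  geno <- pattern
  consequence <- "missense"
  pop_af <- round(runif_below(1, cfg$maf_threshold), 6)
  sift <- round(runif_below(1, rule$sift_deleterious_max), 6)
  polyphen <- round(runif_above(1, rule$polyphen_probably_min), 6)
  revel <- round(runif_above(1, rule$revel_damaging_min), 6)

  if (class == "non_segregating") {
    repeat {
      geno <- gene_drop(ped, founder_ids(ped)[1])
      if (!identical(unname(geno), unname(pattern))) break
    }
  } else if (class == "common_maf") {
    pop_af <- round(runif_above(1, cfg$maf_threshold, upper = 0.5), 6)
  } else if (class == "excluded_consequence") {
    consequence <- sample(c("synonymous", "intronic"), 1)
    sift <- polyphen <- revel <- NA_real_  # not scored by the predictors
  } else if (class == "benign_consensus") {
    sift <- round(runif_above(1, rule$sift_deleterious_max, upper = 0.9), 6)
    polyphen <- round(runif_below(1, rule$polyphen_damaging_min), 6)
    revel <- round(runif_below(1, rule$revel_damaging_min), 6)
  }
  # known_panel_variant, cohort_polymorphism and pass_all_decoy keep the
  # funnel-passing base profile; the first is listed in the panel and the
  # second gets polymorphism-level cohort counts downstream.
  ref_alt <- sample(c("A", "C", "G", "T"), 2)
  list(
    row = data.frame(chrom = "1", pos = pos,
                     ref = ref_alt[1], alt = ref_alt[2],
                     gene = sprintf("GENE%03d", idx),
                     consequence = consequence, pop_af = pop_af,
                     sift = sift, polyphen = polyphen, revel = revel,
                     stringsAsFactors = FALSE),
    geno = geno
  )
}

#' Generate a complete synthetic analysis dataset
#'
#' Writes, under `dir`: `dataset.vcf` (planted causal variant plus
#' `n_decoys_per_class` decoys per configured class), `family.ped`,
#' `panel_genes.txt`, `panel_variants.tsv`, `local_af.tsv`,
#' `gene_annotations.tsv`, `cohort_counts.tsv`, `truth.tsv` (class label
#' per variant) and `manifest.json` (configuration echo).  Every decoy is
#' verified by assertion to fail exactly its designated funnel stage when
#' stages are applied in isolation; the generator stops rather than emit an
#' unfaithful dataset.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param funnel a [funnel_config()] the decoys are calibrated against.
#' @param rule a [consensus_rule()] the decoys are calibrated against.
#' @return invisibly, a list with the file `paths`, the `variant_set`, the
#'   truth table and the pedigree.
#' @export
generate_dataset <- function(cfg = sim_config(), dir,
                             funnel = funnel_config(),
                             rule = consensus_rule()) {
  if ("benign_consensus" %in% cfg$decoy_classes && rule$min_damaging == 0L) {
    ff_config_error(
      "benign_consensus decoys are unsatisfiable when the consensus stage passes everything (min_damaging = 0)")
  }
  ped <- cfg$pedigree
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  planted <- plant_causal_variant(ped, cfg$causal_profile)
  rows <- list(planted$variants)
  genos <- list(planted$geno[1, ])
  truth <- data.frame(key = vs_keys(planted), class = "planted_causal",
                      stringsAsFactors = FALSE)

  pos <- 10000L
  idx <- 1L
  for (class in cfg$decoy_classes) {
    for (r in seq_len(cfg$n_decoys_per_class)) {
      d <- make_decoy(class, ped, pos, idx, rule, funnel)
      rows[[length(rows) + 1L]] <- d$row
      genos[[length(genos) + 1L]] <- d$geno
      truth <- rbind(truth, data.frame(
        key = with(d$row, variant_key(chrom, pos, ref, alt)), class = class,
        stringsAsFactors = FALSE))
      pos <- pos + 100L
      idx <- idx + 1L
    }
  }
  vs <- variant_set(do.call(rbind, rows),
                    do.call(rbind, genos))

  # panel: the known_panel_variant decoys plus one panel gene that none of
  # the emitted variants matches by coordinate (exercises flag-not-drop)
  known_keys <- truth$key[truth$class == "known_panel_variant"]
  panel_genes <- c("SLC34A1", vs$variants$gene[vs_keys(vs) %in% known_keys])
  kv <- vs$variants[vs_keys(vs) %in% known_keys,
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]

  # local frequency table: lists the common_maf decoys at their population
  # frequency (consistent local evidence; they already fail the MAF stage)
  lf <- vs$variants[truth$class == "common_maf",
                    c("chrom", "pos", "ref", "alt", "pop_af"), drop = FALSE]
  names(lf)[5] <- "af"

  # gene annotations: planted gene kidney-expressed with a prior disease
  # association; decoy genes get random expression flags and lower priors
  genes <- unique(vs$variants$gene)
  ann <- data.frame(
    gene = genes,
    kidney_expressed = ifelse(genes == "HSPG2", TRUE,
                              stats::runif(length(genes)) < 0.5),
    prior_disease_association = genes == "HSPG2",
    prior_score = ifelse(genes == "HSPG2", 29.6,
                         round(stats::runif(length(genes), 0, 20), 1)),
    stringsAsFactors = FALSE)

  # cohort counts: zero carriers everywhere except polymorphism decoys
  poly <- truth$class == "cohort_polymorphism"
  het_controls <- ifelse(poly, sample(4:18, nrow(truth), replace = TRUE), 0L)
  het_cases <- ifelse(poly, sample(0:18, nrow(truth), replace = TRUE), 0L)
  cohort <- cbind(vs$variants[, c("chrom", "pos", "ref", "alt")],
                  data.frame(het_controls = het_controls,
                             het_cases = het_cases,
                             n_controls = cfg$n_controls,
                             n_cases = cfg$n_cases))

  assert_class_faithfulness(vs, truth, ped,
                            read_panel_obj(panel_genes, kv), funnel, rule,
                            cfg$causal_profile)

  paths <- list(
    vcf = file.path(dir, "dataset.vcf"),
    ped = file.path(dir, "family.ped"),
    panel_genes = file.path(dir, "panel_genes.txt"),
    panel_variants = file.path(dir, "panel_variants.tsv"),
    local_af = file.path(dir, "local_af.tsv"),
    annotations = file.path(dir, "gene_annotations.tsv"),
    cohort = file.path(dir, "cohort_counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_variant_vcf(vs, paths$vcf)
  write_ped(ped, paths$ped)
  writeLines(panel_genes, paths$panel_genes)
  utils::write.table(kv, paths$panel_variants, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lf, paths$local_af, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort, paths$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    seed = cfg$seed,
    family_id = ped$family_id,
    n_members = n_members(ped),
    n_affected = n_affected(ped),
    n_decoys_per_class = cfg$n_decoys_per_class,
    decoy_classes = cfg$decoy_classes,
    n_controls = cfg$n_controls,
    n_cases = cfg$n_cases,
    causal_profile = cfg$causal_profile,
    n_variants = n_variants(vs)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = paths, variants = vs, truth = truth, ped = ped,
                 planted_key = truth$key[1]))
}

# construct a panel_set in memory (same shape read_panel() returns)
read_panel_obj <- function(genes, known_variants) {
  structure(list(genes = unique(toupper(genes)),
                 known_variants = unique(known_variants)),
            class = "panel_set")
}

# verify each decoy fails exactly its designated stage when stages are
# applied in isolation, and that every genotype column is Mendelian-
# consistent; called before anything is written to disk
assert_class_faithfulness <- function(vs, truth, ped, panel, funnel, rule,
                                      causal_profile) {
  keys <- vs_keys(vs)
  survives <- function(stage_fun) keys %in% vs_keys(stage_fun(vs))
  pass <- data.frame(
    known = survives(function(v) exclude_known(v, panel)),
    segregation = survives(function(v) ad_segregation_filter(v, ped)),
    consequence = survives(function(v) consequence_filter(v, funnel)),
    maf = survives(function(v) maf_filter(v, funnel)),
    consensus = survives(function(v) consensus_filter(v, rule))
  )
  fails_only <- function(i, stage) {
    all(unlist(pass[i, setdiff(names(pass), stage)])) && !pass[i, stage]
  }
  for (i in seq_along(keys)) {
    cls <- truth$class[i]
    ok <- switch(cls,
      planted_causal = if (causal_profile == "damaging") all(unlist(pass[i, ]))
                       else all(unlist(pass[i, names(pass) != "consensus"])),
      non_segregating = fails_only(i, "segregation"),
      common_maf = fails_only(i, "maf"),
      excluded_consequence = fails_only(i, "consequence"),
      benign_consensus = fails_only(i, "consensus"),
      known_panel_variant = fails_only(i, "known"),
      cohort_polymorphism = all(unlist(pass[i, ])),
      pass_all_decoy = all(unlist(pass[i, ])))
    if (!isTRUE(ok)) {
      ff_data_error(sprintf(
        "simulated variant %s does not behave as its class '%s' requires",
        keys[i], cls))
    }
  }
  for (i in seq_along(keys)) {
    if (!mendelian_consistent(ped, stats::setNames(vs$geno[i, ],
                                                   vs_samples(vs)))) {
      ff_data_error(paste0("Mendelian inconsistency in simulated variant ",
                           keys[i]))
    }
  }
  invisible(TRUE)
}
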