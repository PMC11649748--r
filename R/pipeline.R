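# End-to-end orchestration and the command-line interface.
#
# `run_pipeline()` is the programmatic "run everything" entry point;
# `cli_main()` is a thin argv-level wrapper around the package functions,
# intended to be invoked through the Rscript launcher installed under
# `inst/cli/famfunnel`.  Exit statuses: 0 success, 1 data/parse error,
# 2 configuration error.

#' Run the complete prioritization pipeline
#'
#' Reads every input, runs the filtering funnel, computes the two-point LOD
#' for each survivor, screens survivors against the case/control carrier
#' counts, ranks candidates and writes all reports to `out_dir`:
#' `funnel_report.tsv` / `funnel_report.json`, `survivors.tsv`,
#' `survivors.vcf`, `lod.tsv` / `lod.json`, `ranking.tsv`, `summary.tsv` /
#' `summary.md` and `run_manifest.json` (every effective configuration
#' value, for reproducibility).
#'
#' @param vcf path to the annotated multi-sample VCF.
#' @param ped path to the 6-column PED file.
#' @param out_dir output directory (created if needed).
#' @param panel_genes,panel_variants optional panel file paths
#'   ([read_panel()]).
#' @param local_af optional local frequency table path
#'   ([read_local_freq()]).
#' @param annotations optional gene annotation table path
#'   ([read_gene_annotations()]).
#' @param cohort optional cohort carrier-count table path
#'   ([read_cohort_counts()]); survivors absent from it count as "not
#'   determined".
#' @param cfg a [funnel_config()].
#' @param rule a [consensus_rule()].
#' @param model a [lod_model()].
#' @param weights ranking weights ([default_rank_weights()]).
#' @param field_map VCF INFO key mapping ([default_field_map()]).
#' @param lenient_unaffected see [ad_segregation_filter()].
#' @param stages funnel stage order (see [run_funnel()]).
#' @return invisibly, a list with `survivors`, `report`, `lods`, `screens`,
#'   `ranking`, `summary` and the output `paths`.
#' @export
run_pipeline <- function(vcf, ped, out_dir,
                         panel_genes = NULL, panel_variants = NULL,
                         local_af = NULL, annotations = NULL, cohort = NULL,
                         cfg = funnel_config(), rule = consensus_rule(),
                         model = lod_model(),
                         weights = default_rank_weights(),
                         field_map = default_field_map(),
                         lenient_unaffected = FALSE,
                         stages = FUNNEL_STAGES) {
  pedigree <- read_ped(ped)
  vs <- read_annotated_vcf(vcf, field_map = field_map)
  panel <- if (is.null(panel_genes) && is.null(panel_variants)) NULL
           else read_panel(panel_genes, panel_variants)
  local <- if (is.null(local_af)) NULL else read_local_freq(local_af)
  ann <- if (is.null(annotations)) NULL else read_gene_annotations(annotations)
  counts <- if (is.null(cohort)) NULL else read_cohort_counts(cohort)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fr <- run_funnel(vs, pedigree, panel = panel, local = local, cfg = cfg,
                   rule = rule, stages = stages,
                   lenient_unaffected = lenient_unaffected)
  surv <- fr$survivors
  keys <- vs_keys(surv)

  lods <- stats::setNames(lapply(seq_len(n_variants(surv)), function(i) {
    withCallingHandlers(
      compute_lod(pedigree, vs_genotypes(surv, i), model),
      warning = function(w) invokeRestart("muffleWarning"))
  }), keys)

  screens <- if (is.null(counts)) {
    cohort_screen(keys, data.frame(key = character(0),
                                   het_controls = integer(0),
                                   het_cases = integer(0),
                                   n_controls = integer(0),
                                   n_cases = integer(0),
                                   stringsAsFactors = FALSE))
  } else {
    cohort_screen(keys, counts)
  }
  ranking <- rank_candidates(surv, screens, lods, ann, weights, rule)
  summary <- build_summary_table(surv, screens, lods, ann, rule)

  paths <- list(
    funnel_tsv = file.path(out_dir, "funnel_report.tsv"),
    funnel_json = file.path(out_dir, "funnel_report.json"),
    survivors_tsv = file.path(out_dir, "survivors.tsv"),
    survivors_vcf = file.path(out_dir, "survivors.vcf"),
    lod_tsv = file.path(out_dir, "lod.tsv"),
    lod_json = file.path(out_dir, "lod.json"),
    ranking_tsv = file.path(out_dir, "ranking.tsv"),
    summary_tsv = file.path(out_dir, "summary.tsv"),
    summary_md = file.path(out_dir, "summary.md"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  write_funnel_report(fr$report, tsv = paths$funnel_tsv,
                      json = paths$funnel_json)
  utils::write.table(surv$variants, paths$survivors_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_variant_vcf(surv, paths$survivors_vcf, field_map)
  lod_df <- data.frame(
    key = keys,
    lod = vapply(lods, `[[`, numeric(1), "lod"),
    lod_display = vapply(lods, `[[`, character(1), "lod_display"),
    theta_eval = vapply(lods, `[[`, numeric(1), "theta_eval"),
    n_configs = vapply(lods, `[[`, integer(1), "n_configs"),
    stringsAsFactors = FALSE)
  utils::write.table(lod_df, paths$lod_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(lod_df, paths$lod_json, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(ranking, paths$ranking_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_summary_table(summary, tsv = paths$summary_tsv, md = paths$summary_md)
  manifest <- list(
    inputs = list(vcf = vcf, ped = ped, panel_genes = panel_genes,
                  panel_variants = panel_variants, local_af = local_af,
                  annotations = annotations, cohort = cohort),
    funnel_config = unclass(cfg),
    consensus_rule = unclass(rule),
    lod_model = unclass(model),
    weights = as.list(weights),
    stages = stages,
    lenient_unaffected = lenient_unaffected,
    n_input_variants = n_variants(vs),
    n_survivors = n_variants(surv)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(survivors = surv, report = fr$report, lods = lods,
                 screens = screens, ranking = ranking, summary = summary,
                 paths = paths))
}

# ---- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: famfunnel <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --out DIR [--seed N] [--n-decoys K] [--classes a,b,c]",
    "            [--causal-profile damaging|index_candidate]",
    "  filter    --vcf F --ped F --out DIR [--panel-genes F]",
    "            [--panel-variants F] [--local-af F] [--lenient-unaffected]",
    "  lod       --vcf F --ped F --variant chrom:pos:ref:alt --out DIR",
    "            [--theta X]",
    "  screen    --vcf F --cohort F --out DIR",
    "  rank      --vcf F --ped F --cohort F --annotations F --out DIR",
    "  run-all   --vcf F --ped F --out DIR [--panel-genes F]",
    "            [--panel-variants F] [--local-af F] [--annotations F]",
    "            [--cohort F] [--theta X] [--consensus-k K]",
    "            [--lenient-unaffected] [--seed N]",
    "",
    "exit status: 0 ok, 1 data error, 2 configuration error",
    sep = "\n")
}

# minimal --key value / --flag parser; returns a named list
parse_cli_options <- function(args, flags = character(0)) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      ff_config_error(paste0("unexpected argument: ", a))
    }
    key <- gsub("-", "_", substring(a, 3))
    if (key %in% flags) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) {
        ff_config_error(paste0("option ", a, " needs a value"))
      }
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_require <- function(opts, keys) {
  for (k in keys) {
    if (is.null(opts[[k]])) {
      ff_config_error(paste0("missing required option --",
                             gsub("_", "-", k)))
    }
  }
}

cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)
cli_int <- function(x, default) if (is.null(x)) default else as.integer(x)

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `lod`, `screen`,
#' `rank` and `run-all` onto the package functions.  Designed to be called
#' from the installed `famfunnel` launcher script with
#' `commandArgs(trailingOnly = TRUE)`; returns the process exit status
#' instead of quitting so it can be driven in-process from R.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 1 data error, 2 configuration
#'   error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  sub <- args[1]
  rest <- args[-1]
  if ("--help" %in% rest) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  status <- tryCatch({
    cli_dispatch(sub, rest)
    0L
  },
  famfunnel_config_error = function(e) {
    message("configuration error: ", conditionMessage(e))
    2L
  },
  famfunnel_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

cli_dispatch <- function(sub, rest) {
  flags <- "lenient_unaffected"
  opts <- parse_cli_options(rest, flags)
  switch(sub,
    simulate = {
      cli_require(opts, "out")
      classes <- if (is.null(opts$classes)) {
        c("non_segregating", "common_maf", "excluded_consequence",
          "benign_consensus", "known_panel_variant")
      } else strsplit(opts$classes, ",", fixed = TRUE)[[1]]
      cfg <- sim_config(
        n_decoys_per_class = cli_int(opts$n_decoys, 10L),
        decoy_classes = classes,
        causal_profile = if (is.null(opts$causal_profile)) "damaging"
                         else opts$causal_profile,
        seed = cli_int(opts$seed, 1L))
      res <- generate_dataset(cfg, opts$out)
      message("dataset written to ", opts$out, " (",
              n_variants(res$variants), " variants)")
    },
    filter = {
      cli_require(opts, c("vcf", "ped", "out"))
      run_pipeline(opts$vcf, opts$ped, opts$out,
                   panel_genes = opts$panel_genes,
                   panel_variants = opts$panel_variants,
                   local_af = opts$local_af,
                   lenient_unaffected = isTRUE(opts$lenient_unaffected),
                   stages = setdiff(FUNNEL_STAGES, "consensus"))
      message("funnel reports written to ", opts$out)
    },
    lod = {
      cli_require(opts, c("vcf", "ped", "variant", "out"))
      ped <- read_ped(opts$ped)
      vs <- read_annotated_vcf(opts$vcf)
      model <- lod_model(theta = cli_num(opts$theta, 0))
      res <- compute_lod(ped, vs_genotypes(vs, opts$variant), model)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(unclass(res),
                           file.path(opts$out, "lod.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      writeLines(sprintf("%s\t%s\t%g", opts$variant, res$lod_display,
                         res$theta_eval),
                 file.path(opts$out, "lod.tsv"))
      message("LOD ", res$lod_display, " at theta ", res$theta_eval)
    },
    screen = {
      cli_require(opts, c("vcf", "cohort", "out"))
      vs <- read_annotated_vcf(opts$vcf)
      counts <- read_cohort_counts(opts$cohort)
      screens <- cohort_screen(vs_keys(vs), counts)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(screens, file.path(opts$out, "screens.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message("screening table written to ", opts$out)
    },
    rank = ,
    `run-all` = {
      cli_require(opts, c("vcf", "ped", "out"))
      rule <- consensus_rule(min_damaging = cli_int(opts$consensus_k, 2L))
      res <- run_pipeline(opts$vcf, opts$ped, opts$out,
                          panel_genes = opts$panel_genes,
                          panel_variants = opts$panel_variants,
                          local_af = opts$local_af,
                          annotations = opts$annotations,
                          cohort = opts$cohort,
                          rule = rule,
                          model = lod_model(theta = cli_num(opts$theta, 0)),
                          lenient_unaffected =
                            isTRUE(opts$lenient_unaffected))
      top <- res$ranking[res$ranking$rank == 1, , drop = FALSE]
      if (nrow(top)) {
        message("top candidate: ", top$key, " (", top$gene, ")")
      } else {
        message("no survivors")
      }
    },
    ff_config_error(paste0("unknown subcommand: ", sub))
  )
  invisible(NULL)
}
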