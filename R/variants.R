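# Variant container and annotated-VCF / auxiliary-table IO.
#
# Variants flow through the funnel as a `variant_set`: a variant table
# (one row per bi-allelic record) plus an aligned genotype dosage matrix
# (rows = variants, columns = samples, values 0/1/2/NA).  All coordinates
# are 1-based VCF throughout the package; there are no 0-based conversions
# anywhere.

#' Consequence classes recognized by the funnel
#'
#' Annotation strings are normalized onto this fixed vocabulary; anything
#' unrecognized maps to `"other"`.
#'
#' @format character vector.
#' @export
CONSEQUENCE_CLASSES <- c(
  "missense", "stop_gain", "stop_loss", "inframe_or_frameshift_indel",
  "splice_region", "splice_site", "intronic", "synonymous", "other"
)

# common annotation synonyms (SnpEff/VEP dialects) -> canonical class
normalize_consequence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  map <- c(
    missense = "missense", missense_variant = "missense",
    stop_gain = "stop_gain", stop_gained = "stop_gain", nonsense = "stop_gain",
    stop_loss = "stop_loss", stop_lost = "stop_loss",
    inframe_or_frameshift_indel = "inframe_or_frameshift_indel",
    frameshift_variant = "inframe_or_frameshift_indel",
    inframe_insertion = "inframe_or_frameshift_indel",
    inframe_deletion = "inframe_or_frameshift_indel",
    disruptive_inframe_deletion = "inframe_or_frameshift_indel",
    splice_region = "splice_region",
    splice_region_variant = "splice_region",
    splice_site = "splice_site",
    splice_acceptor_variant = "splice_site",
    splice_donor_variant = "splice_site",
    intronic = "intronic", intron_variant = "intronic",
    synonymous = "synonymous", synonymous_variant = "synonymous",
    stop_retained_variant = "synonymous",
    other = "other"
  )
  out <- unname(map[x])
  out[is.na(out) & !is.na(x) & x != ""] <- "other"
  out
}

#' Construct a validated variant set
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, `consequence` (one of [CONSEQUENCE_CLASSES] or `NA`),
#'   `pop_af` (maximum population allele frequency, `NA` = not observed),
#'   `sift`, `polyphen`, `revel` (scores in \[0,1\], `NA` = not annotated).
#'   Extra columns are carried through untouched.
#' @param geno integer matrix of alt-allele dosages, `nrow(variants)` rows,
#'   one named column per sample; values 0, 1, 2 or `NA`.
#' @return a `variant_set` object.
#' @export
variant_set <- function(variants, geno) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "pop_af", "sift", "polyphen", "revel")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    ff_config_error(paste0("variant table lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants)) {
    if (any(is.na(variants$pos) | variants$pos < 1L)) {
      ff_data_error("variant positions must be integers >= 1 (1-based VCF)")
    }
    if (any(variants$ref == variants$alt)) {
      ff_data_error("ref and alt alleles must differ")
    }
    bad_csq <- !is.na(variants$consequence) &
      !(variants$consequence %in% CONSEQUENCE_CLASSES)
    if (any(bad_csq)) {
      ff_data_error(paste0("unrecognized consequence class: ",
        paste(unique(variants$consequence[bad_csq]), collapse = ", ")))
    }
    for (col in c("pop_af", "sift", "polyphen", "revel")) {
      v <- variants[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        ff_data_error(paste0(col, " values must lie in [0, 1]"))
      }
    }
  }
  geno <- as.matrix(geno)
  if (nrow(variants) == 0L && length(geno) == 0L) {
    geno <- matrix(integer(0), nrow = 0, ncol = ncol(geno),
                   dimnames = list(NULL, colnames(geno)))
  }
  if (nrow(geno) != nrow(variants)) {
    ff_config_error("genotype matrix rows must match the variant table")
  }
  if (ncol(geno) > 0 && is.null(colnames(geno))) {
    ff_config_error("genotype matrix must have sample column names")
  }
  storage.mode(geno) <- "integer"
  if (any(!is.na(geno) & !(geno %in% 0:2))) {
    ff_data_error("genotype dosages must be 0, 1, 2 or NA")
  }
  rownames(variants) <- NULL
  rownames(geno) <- NULL
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variant(s) x %d sample(s)\n",
              n_variants(x), length(vs_samples(x))))
  if (n_variants(x)) print(utils::head(x$variants, 10), row.names = FALSE)
  invisible(x)
}

#' Number of variants in a variant set
#' @param vs a `variant_set`.
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Sample names of a variant set
#' @param vs a `variant_set`.
#' @export
vs_samples <- function(vs) colnames(vs$geno)

#' Subset a variant set by row index
#' @param vs a `variant_set`.
#' @param idx logical or integer row index.
#' @export
vs_subset <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE],
              vs$geno[idx, , drop = FALSE])
}

#' Variant keys ("chrom:pos:ref:alt") of a variant set
#' @param vs a `variant_set`.
#' @export
vs_keys <- function(vs) {
  with(vs$variants, variant_key(chrom, pos, ref, alt))
}

#' Marker genotypes of one variant as a named dosage vector
#' @param vs a `variant_set`.
#' @param i variant row index (or key).
#' @export
vs_genotypes <- function(vs, i) {
  if (is.character(i)) i <- match(i, vs_keys(vs))
  if (is.na(i) || i < 1 || i > n_variants(vs)) {
    ff_data_error("variant not found in variant set")
  }
  stats::setNames(vs$geno[i, ], vs_samples(vs))
}

#' Default INFO field mapping for annotated VCFs
#'
#' Names the INFO keys carrying the gene symbol, consequence class, maximum
#' population allele frequency and the three pathogenicity scores.  Matches
#' the VCFs written by [generate_dataset()] and [write_variant_vcf()];
#' override entries for other annotation producers.
#'
#' @return named list of INFO keys.
#' @export
default_field_map <- function() {
  list(gene = "GENE", consequence = "CSQ", af = "AF",
       sift = "SIFT", polyphen = "POLYPHEN", revel = "REVEL")
}

# dosage of allele `j` from one GT string ("0/1", "1|2", "./.", ...)
gt_dosage <- function(gt, j) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(j))
}

# j-th comma-separated element of a per-allele INFO value (Number=A),
# falling back to the whole value for site-level annotations
info_element <- function(val, j) {
  if (is.na(val) || val == "." || val == "") return(NA_character_)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  out <- if (length(parts) >= j) parts[j] else parts[1]
  if (out == ".") NA_character_ else out
}

#' Read an annotated multi-sample VCF into a variant set
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns one record per
#' bi-allelic ALT allele: multi-allelic sites are split, with genotype
#' dosages re-expressed against each ALT and per-allele (Number=A) INFO
#' values taken positionally.  Missing annotations become `NA` fields,
#' never defaults.  Phased genotype separators are accepted and treated as
#' unphased (the analysis marginalizes phase in the LOD model).
#'
#' @param path path to the VCF.
#' @param field_map named list of INFO keys, see [default_field_map()].
#' @param samples optional character vector restricting the sample columns;
#'   VCF samples outside this set are dropped with a warning.
#' @return a [variant_set()].
#' @export
read_annotated_vcf <- function(path, field_map = default_field_map(),
                               samples = NULL) {
  if (!file.exists(path)) ff_config_error(paste0("VCF not found: ", path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) ff_parse_error(
                    paste0("failed to parse VCF ", path, ": ",
                           conditionMessage(e))))
  fix <- vcf@fix
  empty <- function(smp) variant_set(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene = character(0),
               consequence = character(0), pop_af = numeric(0),
               sift = numeric(0), polyphen = numeric(0), revel = numeric(0),
               stringsAsFactors = FALSE),
    matrix(integer(0), 0, length(smp), dimnames = list(NULL, smp)))
  smp <- setdiff(colnames(vcf@gt), "FORMAT")
  if (!is.null(samples)) {
    extra <- setdiff(smp, samples)
    if (length(extra)) {
      warning("VCF sample(s) outside the configured sample set dropped: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    smp <- intersect(smp, samples)
  }
  if (is.null(fix) || nrow(fix) == 0L) return(empty(smp))

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  colnames(gt_raw) <- setdiff(colnames(vcf@gt), "FORMAT")
  info_vals <- lapply(field_map, function(key)
    vcfR::extract.info(vcf, element = key))

  rows <- list()
  genos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      if (alts[j] == "." || alts[j] == "") next
      dose <- vapply(smp, function(s) gt_dosage(gt_raw[i, s], j), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[j],
        gene = {
          g <- info_element(info_vals$gene[i], j)
          if (is.na(g)) NA_character_ else toupper(g)
        },
        consequence = normalize_consequence(
          info_element(info_vals$consequence[i], j)),
        pop_af = suppressWarnings(as.numeric(info_element(info_vals$af[i], j))),
        sift = suppressWarnings(as.numeric(info_element(info_vals$sift[i], j))),
        polyphen = suppressWarnings(
          as.numeric(info_element(info_vals$polyphen[i], j))),
        revel = suppressWarnings(
          as.numeric(info_element(info_vals$revel[i], j))),
        stringsAsFactors = FALSE
      )
      genos[[length(genos) + 1L]] <- dose
    }
  }
  if (!length(rows)) return(empty(smp))
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- smp
  variant_set(variants, geno)
}

#' Write a variant set as a VCF 4.2 file
#'
#' Emits one bi-allelic record per variant, annotations in the INFO keys of
#' `field_map`, genotypes as unphased GT.  Records are written in
#' (chrom, pos) order.  Reading the file back with [read_annotated_vcf()]
#' reproduces the variant set exactly (annotation values are printed as
#' plain decimals with up to six decimal places).
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @param field_map named list of INFO keys, see [default_field_map()].
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vs, path, field_map = default_field_map()) {
  v <- vs$variants
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  v <- v[ord, , drop = FALSE]
  g <- vs$geno[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">',
            field_map$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Consequence class">',
            field_map$consequence),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Max population allele frequency">',
            field_map$af),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="SIFT score (low = deleterious)">',
            field_map$sift),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="PolyPhen-2 probability">',
            field_map$polyphen),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="REVEL score">',
            field_map$revel),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")
  )
  info_field <- function(i) {
    parts <- c(
      if (!is.na(v$gene[i])) paste0(field_map$gene, "=", v$gene[i]),
      if (!is.na(v$consequence[i]))
        paste0(field_map$consequence, "=", v$consequence[i]),
      if (!is.na(v$pop_af[i])) paste0(field_map$af, "=", ff_num(v$pop_af[i])),
      if (!is.na(v$sift[i])) paste0(field_map$sift, "=", ff_num(v$sift[i])),
      if (!is.na(v$polyphen[i]))
        paste0(field_map$polyphen, "=", ff_num(v$polyphen[i])),
      if (!is.na(v$revel[i])) paste0(field_map$revel, "=", ff_num(v$revel[i]))
    )
    if (length(parts)) paste(parts, collapse = ";") else "."
  }
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    gts <- ifelse(is.na(g[i, ]), "./.", gt_code[g[i, ] + 1L])
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            info_field(i), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the known-gene panel and known-variant list
#'
#' The panel stands in for a curated disease gene panel plus a catalogue of
#' known pathogenic variants: a plain-text gene list (one symbol per line,
#' `#` comments allowed) and a TSV of known variant coordinates
#' (`chrom  pos  ref  alt`, 1-based, optional header).
#'
#' @param gene_path path to the gene list (may be `NULL` for none).
#' @param variant_path path to the variant TSV (may be `NULL` for none).
#' @return a `panel_set`: list with `genes` (uppercased unique symbols) and
#'   `known_variants` (data.frame chrom/pos/ref/alt, duplicates removed).
#' @export
read_panel <- function(gene_path = NULL, variant_path = NULL) {
  genes <- character(0)
  if (!is.null(gene_path)) {
    if (!file.exists(gene_path)) {
      ff_config_error(paste0("panel gene file not found: ", gene_path))
    }
    genes <- readLines(gene_path)
    genes <- trimws(genes)
    genes <- genes[genes != "" & !grepl("^#", genes)]
    genes <- unique(toupper(genes))
  }
  kv <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(variant_path)) {
    if (!file.exists(variant_path)) {
      ff_config_error(paste0("panel variant file not found: ", variant_path))
    }
    lines <- readLines(variant_path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    lineno <- which(keep)
    if (length(lines) && grepl("^chrom\\b", lines[1], ignore.case = TRUE)) {
      lines <- lines[-1]
      lineno <- lineno[-1]
    }
    if (length(lines)) {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      for (k in seq_along(fields)) {
        f <- fields[[k]]
        if (length(f) < 4 || is.na(suppressWarnings(as.integer(f[2])))) {
          ff_parse_error(sprintf(
            "panel variant file line %d is malformed (need chrom<TAB>pos<TAB>ref<TAB>alt)",
            lineno[k]))
        }
      }
      kv <- data.frame(
        chrom = vapply(fields, `[`, character(1), 1),
        pos = as.integer(vapply(fields, `[`, character(1), 2)),
        ref = vapply(fields, `[`, character(1), 3),
        alt = vapply(fields, `[`, character(1), 4),
        stringsAsFactors = FALSE)
      kv <- unique(kv)
      rownames(kv) <- NULL
    }
  }
  structure(list(genes = genes, known_variants = kv), class = "panel_set")
}

#' Keys of the known variants in a panel
#' @param panel a `panel_set`.
#' @export
panel_variant_keys <- function(panel) {
  with(panel$known_variants, variant_key(chrom, pos, ref, alt))
}

#' Read a local population allele-frequency table
#'
#' TSV with header `chrom  pos  ref  alt  af`; stands in for an in-house /
#' national variant frequency database used to drop variants common in the
#' local population regardless of global databases.
#'
#' @param path path to the TSV.
#' @return named numeric vector of frequencies keyed by
#'   `"chrom:pos:ref:alt"`.
#' @export
read_local_freq <- function(path) {
  if (!file.exists(path)) {
    ff_config_error(paste0("local frequency table not found: ", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(df))) {
    ff_parse_error(paste0("local frequency table needs columns: ",
                          paste(need, collapse = ", ")))
  }
  if (any(is.na(df$af) | df$af < 0 | df$af > 1)) {
    ff_data_error("local frequencies must lie in [0, 1]")
  }
  stats::setNames(df$af, variant_key(df$chrom, df$pos, df$ref, df$alt))
}

#' Read a gene annotation table
#'
#' TSV with header `gene  kidney_expressed  prior_disease_association
#' prior_score`: per-gene flags for tissue expression and previously
#' reported disease association, plus an externally supplied
#' prioritization score (non-negative; consumed as-is, never recomputed).
#'
#' @param path path to the TSV.
#' @return data.frame with the four columns, gene symbols uppercased.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) {
    ff_config_error(paste0("gene annotation table not found: ", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "kidney_expressed", "prior_disease_association",
            "prior_score")
  if (!all(need %in% names(df))) {
    ff_parse_error(paste0("gene annotation table needs columns: ",
                          paste(need, collapse = ", ")))
  }
  df$gene <- toupper(df$gene)
  df$kidney_expressed <- as.logical(df$kidney_expressed)
  df$prior_disease_association <- as.logical(df$prior_disease_association)
  if (any(is.na(df$prior_score) | df$prior_score < 0)) {
    ff_data_error("prior_score must be non-negative")
  }
  df[, need]
}

#' Read case/control carrier counts
#'
#' TSV with header `chrom  pos  ref  alt  het_controls  het_cases
#' n_controls  n_cases`; `NA` counts mean "not determined".
#'
#' @param path path to the TSV.
#' @return data.frame with a `key` column plus the count columns.
#' @export
read_cohort_counts <- function(path) {
  if (!file.exists(path)) {
    ff_config_error(paste0("cohort count table not found: ", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "het_controls", "het_cases",
            "n_controls", "n_cases")
  if (!all(need %in% names(df))) {
    ff_parse_error(paste0("cohort count table needs columns: ",
                          paste(need, collapse = ", ")))
  }
  bad <- !is.na(df$het_controls) & df$het_controls > df$n_controls
  bad <- bad | (!is.na(df$het_cases) & df$het_cases > df$n_cases)
  if (any(bad)) ff_data_error("carrier counts exceed cohort sizes")
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}
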