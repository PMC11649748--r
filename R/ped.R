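#' Pedigrees for family-based variant prioritization
#'
#' A pedigree is the unit over which dominant segregation filtering,
#' co-segregation LOD scoring and gene-dropping simulation are computed.
#' It is stored as a `fam_pedigree` object: a family identifier plus an
#' ordered member table with columns `id`, `father`, `mother` (both `NA`
#' for founders), `sex` (`"male"`, `"female"`, `"unknown"`) and `affection`
#' (`"affected"`, `"unaffected"`, `"unknown"`).
#'
#' Validation enforces: unique member ids; parents either both present or
#' both absent; referenced parents present in the same family; no individual
#' its own ancestor.  Sex is carried but never used by the autosomal model,
#' so a parent of unexpected sex raises a warning, not an error.
#'
#' @param members data.frame with columns `id`, `father`, `mother`, `sex`,
#'   `affection` as described above.  `father`/`mother` may use `NA` or `"0"`
#'   for founders.
#' @param family_id single string naming the family.
#' @return a validated `fam_pedigree` object.
#' @seealso [read_ped()], [write_ped()], [informative_meioses()]
#' @export
pedigree <- function(members, family_id = "FAM1") {
  required <- c("id", "father", "mother", "sex", "affection")
  if (!is.data.frame(members) || !all(required %in% names(members))) {
    ff_config_error(paste0("pedigree members need columns: ",
                           paste(required, collapse = ", ")))
  }
  members <- as.data.frame(members[, required], stringsAsFactors = FALSE)
  for (col in required) members[[col]] <- as.character(members[[col]])
  members$father[members$father %in% c("0", "")] <- NA_character_
  members$mother[members$mother %in% c("0", "")] <- NA_character_

  if (nrow(members) == 0L) ff_data_error("pedigree has no members")
  if (anyDuplicated(members$id)) {
    ff_data_error(paste0("duplicate individual id(s): ",
      paste(unique(members$id[duplicated(members$id)]), collapse = ", ")))
  }
  if (any(is.na(members$id) | members$id == "")) {
    ff_data_error("empty individual id")
  }
  one_parent <- xor(is.na(members$father), is.na(members$mother))
  if (any(one_parent)) {
    ff_data_error(paste0("individual(s) with exactly one parent recorded: ",
      paste(members$id[one_parent], collapse = ", ")))
  }
  for (col in c("father", "mother")) {
    ref <- members[[col]]
    missing_ref <- !is.na(ref) & !(ref %in% members$id)
    if (any(missing_ref)) {
      ff_data_error(paste0("unknown ", col, " id(s): ",
        paste(unique(ref[missing_ref]), collapse = ", ")))
    }
  }
  if (!all(members$sex %in% c("male", "female", "unknown"))) {
    ff_data_error("sex must be one of male/female/unknown")
  }
  if (!all(members$affection %in% c("affected", "unaffected", "unknown"))) {
    ff_data_error("affection must be one of affected/unaffected/unknown")
  }

  # acyclicity: walking ancestor links from any member must never revisit it
  idx <- stats::setNames(seq_len(nrow(members)), members$id)
  for (start in members$id) {
    seen <- character(0)
    frontier <- start
    while (length(frontier)) {
      parents <- unlist(members[idx[frontier], c("father", "mother")],
                        use.names = FALSE)
      parents <- unique(parents[!is.na(parents)])
      if (start %in% parents) ff_data_error(
        paste0("pedigree cycle involving individual ", start))
      frontier <- setdiff(parents, seen)
      seen <- union(seen, frontier)
    }
  }

  # sex consistency is advisory only (autosomal model ignores sex)
  fathers <- unique(members$father[!is.na(members$father)])
  mothers <- unique(members$mother[!is.na(members$mother)])
  bad_sex <- c(
    fathers[members$sex[idx[fathers]] == "female"],
    mothers[members$sex[idx[mothers]] == "male"]
  )
  if (length(bad_sex)) {
    warning("parental sex inconsistent for: ",
            paste(unique(bad_sex), collapse = ", "), call. = FALSE)
  }

  rownames(members) <- NULL
  structure(list(family_id = as.character(family_id)[1], members = members),
            class = "fam_pedigree")
}

#' @export
print.fam_pedigree <- function(x, ...) {
  cat(sprintf("<fam_pedigree> family %s: %d members (%d affected, %d founders)\n",
              x$family_id, n_members(x), n_affected(x), n_founders(x)))
  print(x$members, row.names = FALSE)
  invisible(x)
}

#' Pedigree summary counts
#'
#' @param ped a `fam_pedigree`.
#' @return an integer count.
#' @name pedigree-counts
NULL

#' @rdname pedigree-counts
#' @export
n_members <- function(ped) nrow(ped$members)

#' @rdname pedigree-counts
#' @export
n_affected <- function(ped) sum(ped$members$affection == "affected")

#' @rdname pedigree-counts
#' @export
n_unaffected <- function(ped) sum(ped$members$affection == "unaffected")

#' @rdname pedigree-counts
#' @export
n_unknown_affection <- function(ped) sum(ped$members$affection == "unknown")

#' @rdname pedigree-counts
#' @export
n_founders <- function(ped) sum(is.na(ped$members$father))

# ids of members with no recorded parents
founder_ids <- function(ped) ped$members$id[is.na(ped$members$father)]

# ids of children of `id` (as father or mother)
children_of <- function(ped, id) {
  m <- ped$members
  m$id[(!is.na(m$father) & m$father == id) | (!is.na(m$mother) & m$mother == id)]
}

# member order with parents always before children
topological_order <- function(ped) {
  m <- ped$members
  placed <- character(0)
  remaining <- m$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(id) {
      i <- match(id, m$id)
      fa <- m$father[i]
      (is.na(fa)) || all(c(m$father[i], m$mother[i]) %in% placed)
    }, logical(1))
    if (!any(ready)) ff_data_error("pedigree ordering failed (cycle?)")
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Read a pedigree from a 6-column PED file
#'
#' Reads a PLINK-style whitespace-delimited PED file with mandatory columns
#' FID IID PAT MAT SEX PHENO.  Phenotype codes: 1 = unaffected, 2 = affected,
#' 0 or -9 = unknown.  Sex codes: 1 = male, 2 = female, anything else =
#' unknown.  Parent code "0" marks a founder.  Extra columns are ignored
#' with a warning; a second family id in the same file is an error (one
#' family per analysis).  Input row order is preserved.
#'
#' @param path path to the PED file (plain text or gzip).
#' @return a validated [pedigree()].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) ff_config_error(paste0("PED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) ff_parse_error(paste0("PED file is empty: ", path))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    ff_parse_error(sprintf("PED line %d has %d column(s); 6 required",
                           which(nf < 6L)[1], nf[which(nf < 6L)[1]]))
  }
  if (any(nf > 6L)) {
    warning("PED file has extra columns beyond the 6 mandatory ones; ignored",
            call. = FALSE)
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  fams <- unique(mat[, 1])
  if (length(fams) > 1L) {
    ff_data_error(paste0("multiple family ids in PED file: ",
                         paste(fams, collapse = ", ")))
  }
  pheno <- mat[, 6]
  ok <- pheno %in% c("1", "2", "0", "-9")
  if (!all(ok)) {
    ff_parse_error(sprintf("PED line %d has unrecognized phenotype code '%s'",
                           which(!ok)[1], pheno[which(!ok)[1]]))
  }
  members <- data.frame(
    id = mat[, 2],
    father = mat[, 3],
    mother = mat[, 4],
    sex = c("1" = "male", "2" = "female")[mat[, 5]],
    affection = c("1" = "unaffected", "2" = "affected",
                  "0" = "unknown", "-9" = "unknown")[pheno],
    stringsAsFactors = FALSE
  )
  members$sex[is.na(members$sex)] <- "unknown"
  pedigree(members, family_id = fams)
}

#' Write a pedigree to a 6-column PED file
#'
#' Inverse of [read_ped()] on the validated field set: writing and re-reading
#' reproduces the same pedigree.
#'
#' @param ped a `fam_pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  m <- ped$members
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
    ped$family_id, m$id,
    ifelse(is.na(m$father), "0", m$father),
    ifelse(is.na(m$mother), "0", m$mother),
    c(male = "1", female = "2", unknown = "0")[m$sex],
    c(affected = "2", unaffected = "1", unknown = "0")[m$affection])
  writeLines(lines, path)
  invisible(path)
}

#' Count informative meioses below a carrier parent
#'
#' The number of offspring of `carrier_parent` whose affection status is
#' recorded.  For a fully informative, fully penetrant dominant pedigree
#' with one doubly heterozygous carrier founder this is the `n` of the
#' phase-unknown closed-form LOD `(n - 1) * log10(2)`
#' (see [lod_closed_form_phase_unknown()]).
#'
#' @param ped a `fam_pedigree`.
#' @param carrier_parent member id of the carrier parent.
#' @return integer count of phenotyped offspring.
#' @export
informative_meioses <- function(ped, carrier_parent) {
  if (!(carrier_parent %in% ped$members$id)) {
    ff_data_error(paste0("unknown individual id: ", carrier_parent))
  }
  kids <- children_of(ped, carrier_parent)
  aff <- ped$members$affection[match(kids, ped$members$id)]
  sum(aff != "unknown")
}
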