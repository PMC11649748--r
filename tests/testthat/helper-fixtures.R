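# Fixture builders and independent oracles shared across test files.
# Oracles deliberately re-derive results through different code paths than
# the package (naive Cartesian enumeration, per-record predicates) so that
# agreement is evidence, not tautology.

# -- pedigree fixtures -------------------------------------------------------

nuclear_pedigree <- function(n_children,
                             child_affection = rep("unaffected", n_children),
                             father_affection = "affected") {
  ids <- c("F", "M", paste0("C", seq_len(n_children)))
  pedigree(data.frame(
    id = ids,
    father = c(NA, NA, rep("F", n_children)),
    mother = c(NA, NA, rep("M", n_children)),
    sex = c("male", "female", rep("unknown", n_children)),
    affection = c(father_affection, "unaffected", child_affection),
    stringsAsFactors = FALSE))
}

random_small_pedigree <- function() {
  n_children <- sample(2:5, 1)
  aff <- sample(c("affected", "unaffected"), n_children, replace = TRUE)
  ped <- nuclear_pedigree(n_children, child_affection = aff)
  gt <- gene_drop(ped, "F")
  list(ped = ped, gt = gt)
}

# -- variant-set fixtures ----------------------------------------------------

# variant table with sensible defaults, overridable per column
mk_variants <- function(n, ...) {
  df <- data.frame(
    chrom = rep("1", n),
    pos = 1000L + seq_len(n),
    ref = rep("A", n),
    alt = rep("T", n),
    gene = sprintf("G%03d", seq_len(n)),
    consequence = rep("missense", n),
    pop_af = rep(NA_real_, n),
    sift = rep(NA_real_, n),
    polyphen = rep(NA_real_, n),
    revel = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# genotype matrix where every variant shows the affected-only het pattern
mk_geno <- function(ped, n) {
  pat <- as.integer(ped$members$affection == "affected")
  matrix(rep(pat, each = n), nrow = n,
         dimnames = list(NULL, ped$members$id))
}

mk_vs <- function(ped, n = 1, geno = mk_geno(ped, n), ...) {
  variant_set(mk_variants(n, ...), geno)
}

# -- independent LOD oracle --------------------------------------------------

# Naive evaluation: generate the full Cartesian product of per-member phased
# two-locus states allowed by the observed marker dosages alone (no
# penetrance pruning), then score every configuration one by one.
brute_lod_likelihood <- function(ped, gt, theta,
                                 pd = 1e-4, pm = 1e-4, pen = c(0, 1, 1)) {
  hd <- c(0, 0, 1, 1)  # disease allele on haplotype 1..4
  hm <- c(0, 1, 0, 1)  # marker allele on haplotype 1..4
  hp_of <- rep(1:4, each = 4)
  hm_of <- rep(1:4, times = 4)
  mrk_dose <- hm[hp_of] + hm[hm_of]
  m <- ped$members
  allowed <- lapply(m$id, function(id) {
    d <- if (id %in% names(gt)) gt[[id]] else NA
    if (is.na(d)) 1:16 else which(mrk_dose == d)
  })
  names(allowed) <- m$id
  grid <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))

  hap_prior <- pd^hd * (1 - pd)^(1 - hd) * pm^hm * (1 - pm)^(1 - hm)
  trans_p <- function(par_state, child_hap) {
    a <- hp_of[par_state]; b <- hm_of[par_state]
    p <- 0
    if (child_hap == a) p <- p + (1 - theta) / 2
    if (child_hap == b) p <- p + (1 - theta) / 2
    if (child_hap == (2 * hd[a] + hm[b] + 1)) p <- p + theta / 2
    if (child_hap == (2 * hd[b] + hm[a] + 1)) p <- p + theta / 2
    p
  }
  total <- 0
  n_pos <- 0L
  for (r in seq_len(nrow(grid))) {
    prob <- 1
    for (i in seq_len(nrow(m))) {
      s <- grid[r, i]
      dc <- hd[hp_of[s]] + hd[hm_of[s]]
      prob <- prob * switch(m$affection[i],
                            affected = pen[dc + 1],
                            unaffected = 1 - pen[dc + 1],
                            unknown = 1)
      if (is.na(m$father[i])) {
        prob <- prob * hap_prior[hp_of[s]] * hap_prior[hm_of[s]]
      } else {
        fs <- grid[r, match(m$father[i], m$id)]
        ms <- grid[r, match(m$mother[i], m$id)]
        prob <- prob * trans_p(fs, hp_of[s]) * trans_p(ms, hm_of[s])
      }
      if (prob == 0) break
    }
    total <- total + prob
    if (prob > 0) n_pos <- n_pos + 1L
  }
  list(likelihood = total, n_configs = n_pos)
}

# -- independent funnel oracle -----------------------------------------------

# Per-record predicate evaluation, one boolean expression per stage.
brute_funnel_keep <- function(vs, ped, panel_keys, local, cfg, rule) {
  aff <- ped$members$id[ped$members$affection == "affected"]
  una <- ped$members$id[ped$members$affection == "unaffected"]
  vapply(seq_len(n_variants(vs)), function(i) {
    v <- vs$variants[i, ]
    key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    g <- vs$geno[i, ]
    seg <- all(!is.na(g[aff]) & g[aff] == 1) &&
      all(!is.na(g[una]) & g[una] == 0) &&
      all(is.na(g) | g != 2)
    csq <- !is.na(v$consequence) &&
      v$consequence %in% cfg$retained_consequences
    maf <- is.na(v$pop_af) || v$pop_af < cfg$maf_threshold
    loc <- is.na(local[key]) || local[key] < cfg$local_af_threshold
    scores <- c(v$sift, v$polyphen, v$revel)
    dmg <- sum(c(!is.na(v$sift) && v$sift < rule$sift_deleterious_max,
                 !is.na(v$polyphen) &&
                   v$polyphen >= rule$polyphen_damaging_min,
                 !is.na(v$revel) && v$revel >= rule$revel_damaging_min))
    cons <- if (sum(!is.na(scores)) >= rule$evaluable_min) {
      dmg >= rule$min_damaging
    } else {
      rule$bypass_unevaluable
    }
    !(key %in% panel_keys) && seg && csq && maf && loc && cons
  }, logical(1))
}

# -- the reference genotype pattern ------------------------------------------

ubrs131_genotypes <- function() {
  c("I:1" = 1L, "I:2" = 0L, "II:1" = 1L, "II:2" = 0L,
    "II:3" = 1L, "II:4" = 1L, "II:5" = 0L, "II:6" = 0L)
}

# build a panel_set from in-memory strings via temporary files
read_panel_from_strings <- function(genes = character(0),
                                    variants = character(0)) {
  gp <- tempfile(fileext = ".txt")
  writeLines(genes, gp)
  vp <- tempfile(fileext = ".tsv")
  writeLines(variants, vp)
  read_panel(gp, vp)
}
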