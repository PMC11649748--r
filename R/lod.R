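# Exact two-point parametric LOD scoring for small pedigrees.
#
# The likelihood is evaluated by full enumeration of phased two-locus
# genotype configurations (disease locus x marker locus), with constraint
# propagation from observed marker dosages and zero-penetrance pruning.
# For the pedigrees in scope (<= 12 members) this exhaustive sum is exact
# and auditable; no peeling approximation is used.
#
# Internal encoding: a haplotype is one of 4 integers combining a disease
# allele indicator d (0 = wild type, 1 = disease allele D) and a marker
# allele indicator m (0 = reference, 1 = alternate M).  A phased genotype
# ("state") is an ordered pair (paternal haplotype, maternal haplotype),
# one of 16.

HAP_D <- c(0L, 0L, 1L, 1L)   # disease indicator of haplotype 1..4
HAP_M <- c(0L, 1L, 0L, 1L)   # marker  indicator of haplotype 1..4
STATE_HP <- rep(1:4, each = 4)  # paternal haplotype of state 1..16
STATE_HM <- rep(1:4, times = 4) # maternal haplotype of state 1..16
STATE_DC <- HAP_D[STATE_HP] + HAP_D[STATE_HM]  # disease allele copies
STATE_MC <- HAP_M[STATE_HP] + HAP_M[STATE_HM]  # marker alt dosage

#' Two-point parametric linkage model
#'
#' Parameters of the disease/marker two-locus model under which the pedigree
#' likelihood is evaluated: the recombination fraction theta, the disease
#' and marker allele frequencies used for founder Hardy-Weinberg priors
#' (with linkage equilibrium between the loci), and the penetrance vector
#' `(f0, f1, f2)` giving the probability of being affected with 0, 1 or 2
#' copies of the disease allele.
#'
#' The defaults describe a fully penetrant autosomal-dominant disease with
#' no phenocopies (`penetrance = c(0, 1, 1)`) and rare disease and marker
#' alleles (`1e-4` each) -- the standard model under which perfect
#' co-segregation through one phase-unknown carrier founder with n
#' informative meioses yields a LOD of `(n - 1) * log10(2)`.
#'
#' @param theta recombination fraction in \[0, 0.5\] at which the numerator
#'   likelihood is evaluated (default 0).
#' @param disease_allele_freq founder frequency of the disease allele.
#' @param marker_allele_freq founder frequency of the marker alternate
#'   allele.
#' @param penetrance numeric triple `(f0, f1, f2)`, each in \[0, 1\].
#' @return a `lod_model` list.
#' @export
lod_model <- function(theta = 0,
                      disease_allele_freq = 1e-4,
                      marker_allele_freq = 1e-4,
                      penetrance = c(0, 1, 1)) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 0.5) {
    ff_config_error("theta must be a single value in [0, 0.5]")
  }
  for (p in c(disease_allele_freq, marker_allele_freq)) {
    if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
      ff_config_error("allele frequencies must lie strictly in (0, 1)")
    }
  }
  if (length(penetrance) != 3 || any(penetrance < 0) || any(penetrance > 1)) {
    ff_config_error("penetrance must be a triple of probabilities (f0, f1, f2)")
  }
  structure(list(theta = theta,
                 disease_allele_freq = disease_allele_freq,
                 marker_allele_freq = marker_allele_freq,
                 penetrance = as.numeric(penetrance)),
            class = "lod_model")
}

# 16 x 4 matrix of transmission probabilities: row = parental phased state,
# column = transmitted haplotype.  Each meiosis transmits one of the two
# parental haplotypes unchanged with probability (1 - theta)/2 each, or one
# of the two recombinant haplotypes with probability theta/2 each.
transmission_matrix <- function(theta) {
  tm <- matrix(0, 16, 4)
  for (s in 1:16) {
    ha <- STATE_HP[s]; hb <- STATE_HM[s]
    rec1 <- 2L * HAP_D[ha] + HAP_M[hb] + 1L  # d from ha, m from hb
    rec2 <- 2L * HAP_D[hb] + HAP_M[ha] + 1L
    tm[s, ha] <- tm[s, ha] + (1 - theta) / 2
    tm[s, hb] <- tm[s, hb] + (1 - theta) / 2
    tm[s, rec1] <- tm[s, rec1] + theta / 2
    tm[s, rec2] <- tm[s, rec2] + theta / 2
  }
  tm
}

# Allowed phased states per member given observed marker dosage (NA = any)
# and a strictly positive penetrance factor; returns list(states, weight)
# where weight carries the penetrance term (and is multiplied later by the
# founder prior or transmission probability).
member_states <- function(affection, dosage, penetrance) {
  pen <- switch(affection,
    affected   = penetrance[STATE_DC + 1L],
    unaffected = 1 - penetrance[STATE_DC + 1L],
    unknown    = rep(1, 16))
  ok <- pen > 0
  if (!is.na(dosage)) ok <- ok & (STATE_MC == dosage)
  list(states = which(ok), weight = pen[ok])
}

ped_likelihood_enum <- function(ped, marker_genotypes, model, theta) {
  m <- ped$members
  n <- nrow(m)
  if (n > 12L) {
    ff_config_error(sprintf(
      "pedigree has %d members; exact enumeration is limited to 12", n))
  }
  ord <- topological_order(ped)
  oi <- match(ord, m$id)

  dos <- rep(NA_integer_, n)
  names(dos) <- m$id
  known <- intersect(names(marker_genotypes), m$id)
  dos[known] <- as.integer(marker_genotypes[known])
  if (any(!is.na(dos) & !(dos %in% 0:2))) {
    ff_data_error("marker genotypes must be alt-allele dosages 0, 1 or 2")
  }
  untyped_aff <- m$id[m$affection == "affected" & is.na(dos[m$id])]
  if (length(untyped_aff)) {
    warning("untyped affected member(s) marginalized: ",
            paste(untyped_aff, collapse = ", "), call. = FALSE)
  }

  pd <- model$disease_allele_freq
  pm <- model$marker_allele_freq
  hap_prior <- (pd^HAP_D * (1 - pd)^(1 - HAP_D)) *
               (pm^HAP_M * (1 - pm)^(1 - HAP_M))
  state_prior <- hap_prior[STATE_HP] * hap_prior[STATE_HM]
  tm <- transmission_matrix(theta)

  allowed <- lapply(oi, function(i)
    member_states(m$affection[i], dos[m$id[i]], model$penetrance))
  is_founder <- is.na(m$father[oi])
  fa_pos <- match(m$father[oi], ord)  # position in `ord` of each parent
  mo_pos <- match(m$mother[oi], ord)

  lik <- 0
  n_configs <- 0L
  assigned <- integer(n)  # state chosen for ord[k]

  recurse <- function(k, acc) {
    if (k > n) {
      lik <<- lik + acc
      n_configs <<- n_configs + 1L
      return(invisible())
    }
    st <- allowed[[k]]$states
    wt <- allowed[[k]]$weight
    for (j in seq_along(st)) {
      s <- st[j]
      f <- if (is_founder[k]) {
        state_prior[s]
      } else {
        tm[assigned[fa_pos[k]], STATE_HP[s]] *
          tm[assigned[mo_pos[k]], STATE_HM[s]]
      }
      p <- acc * f * wt[j]
      if (p > 0) {
        assigned[k] <<- s
        recurse(k + 1L, p)
      }
    }
    invisible()
  }
  recurse(1L, 1)
  list(likelihood = lik, n_configs = n_configs)
}

#' Exact pedigree likelihood at a given recombination fraction
#'
#' Sums, over every phased two-locus genotype configuration consistent with
#' the observed marker dosages, the product of founder Hardy-Weinberg /
#' linkage-equilibrium haplotype priors, Mendelian transmission probabilities
#' with recombination `theta`, and penetrance terms.  Members missing from
#' `marker_genotypes` (or with `NA` dosage) are marginalized; an untyped
#' affected member triggers a warning since it weakens the linkage signal.
#'
#' @param ped a `fam_pedigree` with at most 12 members.
#' @param marker_genotypes named integer vector of alt-allele dosages
#'   (0/1/2, `NA` allowed), names matching member ids.
#' @param model a [lod_model()].
#' @param theta recombination fraction at which to evaluate.
#' @return the likelihood, a non-negative probability.
#' @export
pedigree_likelihood <- function(ped, marker_genotypes, model = lod_model(),
                                theta = model$theta) {
  ped_likelihood_enum(ped, marker_genotypes, model, theta)$likelihood
}

#' Two-point LOD score by exact enumeration
#'
#' Computes `lod = log10 L(theta) - log10 L(0.5)` where `L` is the exact
#' pedigree likelihood of [pedigree_likelihood()].  The numerator is
#' evaluated at `model$theta`; when that likelihood is exactly zero (an
#' obligate recombinant at `theta = 0`), the numerator is re-evaluated on
#' the grid `{0.01, 0.05, 0.1, 0.2, 0.3, 0.4}` and the maximum is returned,
#' with the chosen value recorded in `theta_eval`.
#'
#' The printed form (`lod_display`) truncates -- never rounds -- to two
#' decimals, so the fully informative six-meiosis value `log10(32) = 1.505`
#' reports as `"1.50"`.
#'
#' @inheritParams pedigree_likelihood
#' @return a `lod_result` list: `lod` (full precision), `theta_eval`,
#'   `n_configs` (configurations with positive likelihood contribution at
#'   `theta_eval`), and `lod_display`.
#' @examples
#' ped <- ubrs131_pedigree()
#' gt <- c("I:1" = 1, "I:2" = 0, "II:1" = 1, "II:2" = 0,
#'         "II:3" = 1, "II:4" = 1, "II:5" = 0, "II:6" = 0)
#' compute_lod(ped, gt)  # LOD 1.505, displayed 1.50
#' @export
compute_lod <- function(ped, marker_genotypes, model = lod_model()) {
  if (n_affected(ped) < 1L) {
    ff_data_error("pedigree has no affected member; LOD is undefined")
  }
  denom <- withCallingHandlers(
    ped_likelihood_enum(ped, marker_genotypes, model, 0.5),
    warning = function(w) invokeRestart("muffleWarning"))
  num <- ped_likelihood_enum(ped, marker_genotypes, model, model$theta)
  theta_eval <- model$theta
  if (num$likelihood == 0) {
    if (denom$likelihood == 0) {
      ff_data_error("phenotype/genotype pattern impossible under the model")
    }
    grid <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4)
    evals <- lapply(grid, function(th) withCallingHandlers(
      ped_likelihood_enum(ped, marker_genotypes, model, th),
      warning = function(w) invokeRestart("muffleWarning")))
    liks <- vapply(evals, `[[`, numeric(1), "likelihood")
    best <- which.max(liks)
    num <- evals[[best]]
    theta_eval <- grid[best]
  }
  lod <- log10(num$likelihood) - log10(denom$likelihood)
  structure(list(lod = lod,
                 theta_eval = theta_eval,
                 n_configs = num$n_configs,
                 lod_display = format_lod(lod)),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> LOD = %s (exact %.6f) at theta = %g; %d configurations\n",
              x$lod_display, x$lod, x$theta_eval, x$n_configs))
  invisible(x)
}

#' Format a LOD score for reports (truncate to two decimals)
#'
#' @param lod numeric LOD score.
#' @return character, the LOD truncated toward zero to two decimals.
#' @export
format_lod <- function(lod) {
  sprintf("%.2f", truncate_decimal(lod, 2))
}

#' Closed-form phase-unknown LOD for perfect dominant co-segregation
#'
#' For a single doubly heterozygous carrier parent of unknown phase with
#' `n` fully informative, non-recombinant meioses, the theta = 0 two-point
#' LOD is `(n - 1) * log10(2)`: marginalizing the two founder phases costs
#' exactly one meiosis of linkage information.  Serves as an independent
#' oracle for [compute_lod()] in the rare-allele limit.
#'
#' @param n_informative number of informative meioses (>= 1).
#' @return the LOD score `(n - 1) * log10(2)`.
#' @examples
#' lod_closed_form_phase_unknown(6)  # 1.5051; six meioses print as 1.50
#' @export
lod_closed_form_phase_unknown <- function(n_informative) {
  if (!is.numeric(n_informative) || length(n_informative) != 1 ||
      n_informative < 1 || n_informative != round(n_informative)) {
    ff_config_error("n_informative must be a single integer >= 1")
  }
  (n_informative - 1) * log10(2)
}

#' The eight-member two-generation index kindred
#'
#' The default simulation template: an affected father (I:1), unaffected
#' mother (I:2) and six offspring of whom three (II:1, II:3, II:4) are
#' affected -- four affected members in total across two generations,
#' consistent with autosomal-dominant transmission.  With the causal
#' variant heterozygous in exactly the affected members this pedigree
#' carries six informative meioses and a phase-unknown LOD of
#' `log10(32) = 1.505`, reported as 1.50.
#'
#' @return a `fam_pedigree` of 8 members (family id "UBRS131").
#' @export
ubrs131_pedigree <- function() {
  pedigree(data.frame(
    id        = c("I:1", "I:2", "II:1", "II:2", "II:3", "II:4", "II:5", "II:6"),
    father    = c(NA, NA, rep("I:1", 6)),
    mother    = c(NA, NA, rep("I:2", 6)),
    sex       = c("male", "female", "male", "male", "female", "female",
                  "male", "male"),
    affection = c("affected", "unaffected", "affected", "unaffected",
                  "affected", "affected", "unaffected", "unaffected"),
    stringsAsFactors = FALSE
  ), family_id = "UBRS131")
}
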