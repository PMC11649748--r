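# k-of-n pathogenicity consensus over SIFT / PolyPhen-2 / REVEL.
#
# Raw scores are kept in their native orientation (SIFT: low = deleterious;
# PolyPhen and REVEL: high = damaging) and mapped to categorical calls only
# here.  The funnel's consensus stage requires at least `min_damaging` of
# the three tools to call the variant damaging; variants with no evaluable
# score (e.g. splice-region and intronic records, which these missense
# predictors do not score) bypass the stage rather than failing it.

#' Consensus rule for the pathogenicity stage
#'
#' Thresholds follow each tool's published convention: SIFT calls a variant
#' deleterious ("D") below 0.05; PolyPhen-2 calls it possibly damaging ("P")
#' from 0.446 and probably damaging ("PD") from 0.908; REVEL calls it
#' damaging ("D") from 0.5.  The consensus passes a variant damaging by at
#' least `min_damaging` of the three tools (default 2 of 3).
#'
#' @param sift_deleterious_max SIFT score strictly below this is "D".
#' @param polyphen_damaging_min PolyPhen score at or above this is at least
#'   possibly damaging.
#' @param polyphen_probably_min PolyPhen score at or above this is probably
#'   damaging ("PD").
#' @param revel_damaging_min REVEL score at or above this is damaging.
#' @param min_damaging minimum number of damaging calls to pass (k of 3).
#' @param evaluable_min minimum number of non-missing scores for the rule
#'   to apply; below this the variant is handled by `bypass_unevaluable`.
#' @param polyphen_possibly_counts should "possibly damaging" count toward
#'   the consensus (default) or only "probably damaging"?
#' @param bypass_unevaluable pass (`TRUE`, default) or fail variants with
#'   fewer than `evaluable_min` scores.
#' @return a `consensus_rule` list.
#' @export
consensus_rule <- function(sift_deleterious_max = 0.05,
                           polyphen_damaging_min = 0.446,
                           polyphen_probably_min = 0.908,
                           revel_damaging_min = 0.5,
                           min_damaging = 2L,
                           evaluable_min = 1L,
                           polyphen_possibly_counts = TRUE,
                           bypass_unevaluable = TRUE) {
  for (th in c(sift_deleterious_max, polyphen_damaging_min,
               polyphen_probably_min, revel_damaging_min)) {
    if (!is.numeric(th) || length(th) != 1 || th < 0 || th > 1) {
      ff_config_error("consensus thresholds must lie in [0, 1]")
    }
  }
  if (polyphen_probably_min < polyphen_damaging_min) {
    ff_config_error(
      "polyphen_probably_min must be >= polyphen_damaging_min")
  }
  if (!(min_damaging %in% 0:3)) {
    ff_config_error("min_damaging must be an integer in 0..3")
  }
  if (!(evaluable_min %in% 0:3)) {
    ff_config_error("evaluable_min must be an integer in 0..3")
  }
  structure(list(sift_deleterious_max = sift_deleterious_max,
                 polyphen_damaging_min = polyphen_damaging_min,
                 polyphen_probably_min = polyphen_probably_min,
                 revel_damaging_min = revel_damaging_min,
                 min_damaging = as.integer(min_damaging),
                 evaluable_min = as.integer(evaluable_min),
                 polyphen_possibly_counts = isTRUE(polyphen_possibly_counts),
                 bypass_unevaluable = isTRUE(bypass_unevaluable)),
            class = "consensus_rule")
}

#' Map raw predictor scores to categorical calls
#'
#' Deterministic, vectorized mapping: SIFT to "D"/"T", PolyPhen-2 to
#' "PD"/"P"/"B", REVEL to "D"/"N"; missing scores map to `NA`.
#'
#' @param sift,polyphen,revel numeric score vectors (NA allowed).
#' @param rule a [consensus_rule()].
#' @return data.frame with columns `sift_cat`, `polyphen_cat`, `revel_cat`.
#' @examples
#' # the two missense profiles of the index family's candidate gene region:
#' categorize(sift = c(0.171, 0.008), polyphen = c(0.997, 0.979),
#'            revel = c(0.478, 0.364))
#' @export
categorize <- function(sift = NA_real_, polyphen = NA_real_,
                       revel = NA_real_, rule = consensus_rule()) {
  n <- max(length(sift), length(polyphen), length(revel))
  sift <- rep_len(as.numeric(sift), n)
  polyphen <- rep_len(as.numeric(polyphen), n)
  revel <- rep_len(as.numeric(revel), n)
  data.frame(
    sift_cat = ifelse(is.na(sift), NA_character_,
                      ifelse(sift < rule$sift_deleterious_max, "D", "T")),
    polyphen_cat = ifelse(is.na(polyphen), NA_character_,
                   ifelse(polyphen >= rule$polyphen_probably_min, "PD",
                   ifelse(polyphen >= rule$polyphen_damaging_min, "P", "B"))),
    revel_cat = ifelse(is.na(revel), NA_character_,
                       ifelse(revel >= rule$revel_damaging_min, "D", "N")),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the k-of-3 damaging consensus
#'
#' Counts the damaging calls among the evaluable (non-missing) scores and
#' applies the rule: pass when `damaging_count >= min_damaging`, provided
#' at least `evaluable_min` scores are present; otherwise the bypass policy
#' decides.  Monotone: raising any score toward its damaging direction can
#' never turn a pass into a fail.
#'
#' @inheritParams categorize
#' @return data.frame with columns `damaging_count`, `evaluable_count`,
#'   `pass`.
#' @export
consensus_pass <- function(sift = NA_real_, polyphen = NA_real_,
                           revel = NA_real_, rule = consensus_rule()) {
  cats <- categorize(sift, polyphen, revel, rule)
  pp_damaging <- if (rule$polyphen_possibly_counts) c("PD", "P") else "PD"
  dmg <- (!is.na(cats$sift_cat) & cats$sift_cat == "D") +
         (!is.na(cats$polyphen_cat) & cats$polyphen_cat %in% pp_damaging) +
         (!is.na(cats$revel_cat) & cats$revel_cat == "D")
  evaluable <- (!is.na(cats$sift_cat)) + (!is.na(cats$polyphen_cat)) +
               (!is.na(cats$revel_cat))
  pass <- ifelse(evaluable >= rule$evaluable_min,
                 dmg >= rule$min_damaging,
                 rule$bypass_unevaluable)
  data.frame(damaging_count = as.integer(dmg),
             evaluable_count = as.integer(evaluable),
             pass = pass)
}
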