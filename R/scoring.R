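# Debye-length scoring and mechanism classification.

#' Debye-length score of an intermolecular distance
#'
#' S_D = 1 for distances below the Debye length and
#' exp(-(Delta - lambda_D) / lambda_D) beyond it; continuous and
#' non-increasing in Delta, with S_D(2 lambda_D) = 1/e. Distances should be
#' surface-to-surface distances for the relaxed conformation.
#'
#' @param delta intermolecular (surface) distance in nm (>= 0); vectorized
#' @param lambda_d Debye length in nm; the default is the estimated in-cell
#'   maximum of 2.2 nm
#' @return score in \[0, 1\]
#' @export
sd_score <- function(delta, lambda_d = 2.2) {
  if (any(delta < 0, na.rm = TRUE)) stop_config("'delta' must be >= 0")
  if (lambda_d <= 0) stop_config("'lambda_d' must be positive")
  ifelse(delta < lambda_d, 1, exp(-(delta - lambda_d) / lambda_d))
}

#' Mechanism call from the three scenario scores
#'
#' An organelle is compatible with multicomponent phase separation
#' (PSCP/LLPS) if any of the three scenario scores reaches the cutoff
#' (comparison is `>=`, i.e. a score exactly at the cutoff passes); three
#' sub-cutoff scores favor demixing by interaction with clustered binding
#' sites (ICBS).
#'
#' @param scores numeric vector of S_D scores in \[0, 1\]; names label the
#'   scenarios
#' @param cutoff acceptance cutoff
#' @return list with `call` (`"PSCP_LLPS_compatible"` or `"ICBS_favored"`)
#'   and `passing` (names of scenarios at or above the cutoff)
#' @export
classify <- function(scores, cutoff = 0.5) {
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop_config("scores must lie in [0, 1]")
  if (is.null(names(scores)))
    names(scores) <- paste0("scenario_", seq_along(scores))
  passing <- names(scores)[scores >= cutoff]
  list(call = if (length(passing)) "PSCP_LLPS_compatible" else "ICBS_favored",
       passing = passing)
}

#' Nucleosome-to-protein ratio in an organelle
#'
#' The number of nucleosomes per candidate scaffold protein; an excess of
#' nucleosomes (> 1) marks organelles with abundant chromatin binding sites
#' for an ICBS scenario.
#'
#' @param census data frame with columns `class` and `copies`
#' @return dimensionless ratio
#' @export
nucleosome_protein_ratio <- function(census) {
  prot <- sum(census$copies[census$class == "protein"])
  if (prot <= 0) stop_config("organelle census contains no proteins")
  sum(census$copies[census$class == "nucleosome"]) / prot
}

#' Score one organelle across the three multicomponent scenarios
#'
#' Computes surface distances for proteins only, proteins + RNAs, and
#' proteins + RNAs + nucleosomes using the supplied (relaxed-conformation)
#' component diameters, maps them to S_D scores and classifies the
#' mechanism.
#'
#' @param components data frame as from [mixture_components()] with classes
#'   `protein`, `rna`, `nucleosome` and relaxed-conformation diameters
#' @param v_org organelle volume in um^3
#' @param organelle organelle name recorded in the scorecard
#' @param lambda_d Debye length in nm
#' @param cutoff classification cutoff
#' @return a [score_card()]
#' @export
score_organelle <- function(components, v_org, organelle = "organelle",
                            lambda_d = 2.2, cutoff = 0.5) {
  states <- lapply(names(scenario_classes), function(sc)
    scenario_distances(components, sc, v_org, conformation = "relaxed"))
  deltas <- vapply(states, `[[`, numeric(1), "surface_distance")
  scores <- setNames(sd_score(deltas, lambda_d), names(scenario_classes))
  score_card(organelle, scores,
             nucleosome_protein_ratio(components), cutoff = cutoff)
}
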