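# Molecular sizes under explicit conformational models. Proteins are built
# from ordered/disordered domains (predicted structure, random-walk "relaxed"
# arrangement, half-way-to-straight "expanded" arrangement); RNAs follow a
# folded scaling law and a worm-like chain; everything ends up as a sphere of
# diameter d with volume (4*pi/3)*(d/2)^3.

#' Segment a per-residue order/disorder annotation into domains
#'
#' Applies majority smoothing with a centered window (ties resolved to
#' ordered), then merges any remaining run shorter than the window into its
#' flanking context, and returns the contiguous runs as domains. The
#' operation is idempotent: segmenting the flags implied by its own output
#' reproduces it.
#'
#' @param flags character vector (or single string) of per-residue flags,
#'   `"O"` for ordered and `"D"` for disordered
#' @param window smoothing window length in residues
#' @return list of [domain_segment()] with `kind` and `n_residues` set and
#'   `rg` left unset
#' @examples
#' segment_domains("OOODOOOOOOOO") # one ordered domain of 12 residues
#' @export
segment_domains <- function(flags, window = 5L) {
  if (length(flags) == 1L && nchar(flags[1]) > 1L)
    flags <- strsplit(flags, "")[[1]]
  if (length(flags) == 0L) stop_config("empty order/disorder annotation")
  if (!all(flags %in% c("O", "D")))
    stop_config("flags must be 'O' or 'D'")
  n <- length(flags)
  half <- (window - 1L) %/% 2L
  smoothed <- vapply(seq_len(n), function(i) {
    w <- flags[max(1L, i - half):min(n, i + half)]
    n_o <- sum(w == "O")
    if (n_o >= length(w) - n_o) "O" else "D"  # tie -> ordered
  }, character(1))
  r <- rle(smoothed)
  # absorb short runs into their flanks (flanks always carry the other kind)
  while (length(r$lengths) > 1L && min(r$lengths) < window) {
    j <- which.min(r$lengths)
    r$values[j] <- if (r$values[j] == "O") "D" else "O"
    r <- rle(inverse.rle(r))
  }
  mapply(function(v, l) domain_segment(
    if (v == "O") "ordered" else "disordered", l),
    r$values, r$lengths, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Radius of gyration of a disordered chain
#'
#' @param n_residues chain length in residues
#' @param law a [scaling_law()]; defaults to the disordered-chain law
#' @return Rg in nm
#' @export
rg_disordered <- function(n_residues, law = default_scaling_laws()$disordered) {
  if (any(n_residues < 1)) stop_config("'n_residues' must be >= 1")
  law$prefactor * n_residues^law$exponent
}

resolve_domain_rg <- function(domains, laws = default_scaling_laws()) {
  lapply(domains, function(d) {
    if (is.na(d$rg)) {
      if (d$kind != "disordered")
        stop_config("ordered domain of %d residues has no radius of gyration",
                    d$n_residues)
      d$rg <- rg_disordered(d$n_residues, laws$disordered)
    }
    d
  })
}

domain_rgs <- function(domains) {
  rg <- vapply(domains, `[[`, numeric(1), "rg")
  if (any(is.na(rg)))
    stop_config("domain without radius of gyration; resolve '?' radii first")
  rg
}

#' Relaxed protein diameter (random-walk arrangement of domains)
#'
#' d = 2 * sqrt(sum Rg_i^2) over all ordered and disordered domains. If this
#' falls below the predicted-structure diameter, the predicted diameter is
#' used (the relaxed conformation can only be more extended than the
#' prediction).
#'
#' @param domains list of [domain_segment()] with radii of gyration set
#' @param predicted_diameter predicted-structure diameter in nm
#' @return diameter in nm
#' @export
diameter_relaxed <- function(domains, predicted_diameter) {
  if (length(domains) == 0L) return(predicted_diameter)
  rg <- domain_rgs(domains)
  max(2 * sqrt(sum(rg^2)), predicted_diameter)
}

#' Expanded protein diameter (midpoint between straight and relaxed)
#'
#' d = sum(Rg_i) + sqrt(sum Rg_i^2), the arithmetic mean of the straight-line
#' arrangement (2 * sum Rg_i) and the relaxed random walk. Values above the
#' fully denatured chain diameter are capped at the latter.
#'
#' @param domains list of [domain_segment()] with radii of gyration set
#' @param predicted_diameter predicted-structure diameter in nm
#' @param denatured_diameter diameter of the fully denatured chain in nm
#'   (from the denatured-chain scaling law on the total residue count)
#' @return diameter in nm
#' @export
diameter_expanded <- function(domains, predicted_diameter,
                              denatured_diameter = Inf) {
  if (length(domains) == 0L) return(predicted_diameter)
  rg <- domain_rgs(domains)
  min(sum(rg) + sqrt(sum(rg^2)), denatured_diameter)
}

#' All three conformational diameters of a protein species
#'
#' Computes predicted, relaxed and expanded diameters, resolving `?` radii
#' of gyration from the disordered-chain law and capping the expanded
#' diameter at the denatured chain. Direct overrides on the species (used
#' for large complexes) take precedence. The returned diameters are
#' monotone: predicted <= relaxed <= expanded.
#'
#' @param species a [protein_species()]
#' @param laws scaling laws as from [default_scaling_laws()]
#' @return named numeric vector with elements `predicted`, `relaxed`,
#'   `expanded` (nm)
#' @export
protein_diameters <- function(species, laws = default_scaling_laws()) {
  domains <- resolve_domain_rg(species$domains, laws)
  predicted <- species$predicted_diameter
  relaxed <- if (!is.na(species$relaxed_diameter)) species$relaxed_diameter
             else diameter_relaxed(domains, predicted)
  relaxed <- max(relaxed, predicted)
  expanded <- if (!is.na(species$expanded_diameter)) species$expanded_diameter
  else {
    n_res <- sum(vapply(domains, `[[`, integer(1), "n_residues"))
    denat <- if (n_res > 0) 2 * rg_disordered(n_res, laws$denatured) else Inf
    diameter_expanded(domains, predicted, denat)
  }
  expanded <- max(expanded, relaxed)
  c(predicted = predicted, relaxed = relaxed, expanded = expanded)
}

#' RNA diameter under a conformational model
#'
#' Folded RNA follows d = 2 * 0.55 * N^0.33 (nm); the expanded conformation
#' treats the RNA as a worm-like chain with persistence length
#' l_p = 0.15 * N^0.33 nm and contour length l_c = 0.696 nm * N, using the
#' exact worm-like-chain radius of gyration; relaxed is the mean of the two.
#'
#' @param n_nt RNA length in nucleotides
#' @param conformation `"folded"` (alias `"predicted"`), `"relaxed"`, or
#'   `"expanded"`
#' @return diameter in nm
#' @export
rna_diameter <- function(n_nt, conformation = c("folded", "relaxed",
                                                "expanded", "predicted")) {
  if (any(n_nt < 1)) stop_config("'n_nt' must be >= 1")
  conformation <- match.arg(conformation)
  folded <- 2 * 0.55 * n_nt^0.33
  if (conformation %in% c("folded", "predicted")) return(folded)
  lp <- 0.15 * n_nt^0.33
  lc <- 0.696 * n_nt
  rg2 <- lp * lc / 3 - lp^2 +
    2 * lp^3 / lc * (1 - lp / lc * (1 - exp(-lc / lp)))
  expanded <- 2 * sqrt(rg2)
  switch(conformation,
         expanded = expanded,
         relaxed = (folded + expanded) / 2)
}

#' Volume of a sphere of diameter d
#'
#' @param d diameter in nm
#' @return volume in nm^3
#' @export
molecule_volume <- function(d) {
  if (any(d <= 0)) stop_config("'d' must be positive")
  (4 * pi / 3) * (d / 2)^3
}
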