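# Absolute abundance census: iBAQ calibration, partition of copies into
# organelles, RNA and nucleosome pools, and class-wise mass densities.

#' Theoretical number of histone H4 molecules per cell
#'
#' Each nucleosome carries two H4 molecules, so the total is
#' ploidy * 2 * genome_size / NRL. With the default diploid 2.5 Gb genome and
#' a 186 bp repeat length this is about 54 million molecules, which anchors
#' the iBAQ calibration.
#'
#' @param nuc a [nucleus_model()]
#' @return H4 copies per cell
#' @export
theoretical_h4_total <- function(nuc) {
  stopifnot(inherits(nuc, "nucleus_model"))
  nuc$ploidy * 2 * nuc$genome_size_haploid / nuc$nucleosome_repeat_length
}

#' Fit the iBAQ-to-copies calibration
#'
#' Ordinary least squares through the origin of measured copies on iBAQ:
#' N = a * iBAQ. The through-origin form reflects that an undetected protein
#' has both zero iBAQ and (up to the detection limit) zero copies.
#'
#' @param refs list of [calibration_ref()] (at least one)
#' @return list of class `calibration_model` with `scale_a`, its standard
#'   error `se_a`, and the anchors used
#' @export
fit_calibration <- function(refs) {
  if (length(refs) == 0L) stop_config("at least one calibration anchor is required")
  stopifnot(all(vapply(refs, inherits, logical(1), "calibration_ref")))
  x <- vapply(refs, `[[`, numeric(1), "ibaq")
  y <- vapply(refs, `[[`, numeric(1), "measured_copies")
  if (any(x <= 0) || any(y <= 0))
    stop_config("calibration anchors must have positive iBAQ and copies")
  if (length(refs) == 1L) {
    a <- y / x
    se <- NA_real_
  } else {
    fit <- stats::lm(y ~ 0 + x)
    a <- unname(coef(fit)[1])
    # noise-free anchors give a perfect fit; the SE warning is expected then
    se <- unname(suppressWarnings(summary(fit))$coefficients[1, 2])
  }
  structure(list(scale_a = a, se_a = se, refs = refs),
            class = "calibration_model")
}

#' Total copies per cell for one species
#'
#' Directly measured copies take precedence; otherwise copies are
#' a * iBAQ; proteins undetected by mass spectrometry (iBAQ absent or zero)
#' are assigned the configured detection-limit copy number.
#'
#' @param species a [protein_species()]
#' @param calib a `calibration_model` from [fit_calibration()]
#' @param nuc a [nucleus_model()] (supplies the detection limit)
#' @return copies per cell
#' @export
total_copies <- function(species, calib, nuc) {
  stopifnot(inherits(species, "protein_species"))
  if (!is.null(species$total_copies)) return(species$total_copies)
  ibaq <- species$ibaq
  if (is.null(ibaq) || is.na(ibaq) || ibaq <= 0)
    return(nuc$detection_limit_copies)
  calib$scale_a * ibaq
}

#' Enrichment from background-subtracted image intensities
#'
#' alpha = (I_org - I_BG) / (I_np - I_BG), the ratio of average
#' concentrations inside the organelle and in the nucleoplasm.
#'
#' @param i_org mean intensity inside the organelle
#' @param i_np mean intensity in the nucleoplasm
#' @param i_bg background intensity
#' @return enrichment alpha (dimensionless)
#' @export
enrichment_from_intensities <- function(i_org, i_np, i_bg) {
  if (i_np <= i_bg)
    stop_config("nucleoplasm intensity must exceed background (i_np > i_bg)")
  (i_org - i_bg) / (i_np - i_bg)
}

#' Partition total copies into one organelle class
#'
#' Decomposes the nuclear pool into organelle and nucleoplasm compartments:
#' N_org = alpha * N_tot * V_org / ((alpha - 1) * n_org * V_org + V_nuc).
#' An infinite alpha (exclusive localization) returns the analytic limit
#' N_tot / n_org with an empty nucleoplasm pool.
#'
#' @param n_tot total copies per cell
#' @param alpha enrichment (>= 0, `Inf` allowed)
#' @param org an [organelle_model()]
#' @param nuc a [nucleus_model()]
#' @return list with `copies` (per single organelle), `concentration` (uM in
#'   the organelle), and `nucleoplasm_copies` (total copies outside all
#'   organelles of this class)
#' @export
organelle_copies <- function(n_tot, alpha, org, nuc) {
  if (is.na(alpha) || alpha < 0) stop_config("'alpha' must be >= 0")
  v_np <- nuc$nucleus_volume - org$count_per_nucleus * org$volume
  if (v_np <= 0)
    stop_config("organelles of class '%s' do not fit into the nucleus", org$name)
  if (is.infinite(alpha)) {
    n_org <- n_tot / org$count_per_nucleus
    c_np <- 0
  } else {
    denom <- (alpha - 1) * org$count_per_nucleus * org$volume +
      nuc$nucleus_volume
    if (denom <= 0)
      stop_config("partition denominator is non-positive (alpha = %g)", alpha)
    n_org <- alpha * n_tot * org$volume / denom
    c_np <- n_tot / denom  # copies per um^3 in the nucleoplasm
  }
  list(copies = n_org,
       concentration = conc_uM(n_org, org$volume),
       nucleoplasm_copies = c_np * v_np)
}

#' Nuclear RNA census
#'
#' Converts the nuclear RNA mass into ribonucleotides
#' (N_rn = M_tot * f_nuc / MW * N_A) and distributes them over the
#' organelles according to their RNA enrichments:
#' c_rn,np = N_rn,tot / (V_np + sum_i alpha_i * n_i * V_i) and
#' N_rn,org,i = c_rn,np * alpha_i * V_i per organelle. Molecule counts are
#' obtained by dividing by each organelle's characteristic RNA length and
#' may be fractional.
#'
#' @param nuc a [nucleus_model()]
#' @param organelles list of [organelle_model()]
#' @return list of class `rna_pool` with `total_ribonucleotides`,
#'   `nucleoplasm_concentration` (ribonucleotides per um^3),
#'   `nucleoplasm_ribonucleotides`, and named vectors
#'   `per_organelle_ribonucleotides` / `per_organelle_molecules`
#'   (per single organelle)
#' @export
rna_census <- function(nuc, organelles) {
  stopifnot(inherits(nuc, "nucleus_model"))
  n_rn_tot <- nuc$total_rna_mass * 1e-12 * nuc$nuclear_rna_fraction /
    nuc$ribonucleotide_mw * AVOGADRO
  nV <- vapply(organelles, function(o) o$count_per_nucleus * o$volume,
               numeric(1))
  alphas <- vapply(organelles, `[[`, numeric(1), "rna_enrichment")
  v_np <- nuc$nucleus_volume - sum(nV)
  if (v_np <= 0) stop_config("organelles leave no nucleoplasm volume")
  if (!all(is.finite(alphas)))
    stop_config("RNA enrichments must be finite")
  c_np <- n_rn_tot / (v_np + sum(alphas * nV))
  per_org <- c_np * alphas *
    vapply(organelles, `[[`, numeric(1), "volume")
  names(per_org) <- vapply(organelles, `[[`, character(1), "name")
  lens <- vapply(organelles, `[[`, numeric(1), "rna_length")
  molecules <- per_org / lens
  structure(list(
    total_ribonucleotides = n_rn_tot,
    nucleoplasm_concentration = c_np,
    nucleoplasm_ribonucleotides = c_np * v_np,
    per_organelle_ribonucleotides = per_org,
    per_organelle_molecules = molecules
  ), class = "rna_pool")
}

#' Nucleosome census for one organelle
#'
#' Each nucleosome carries two H4 molecules, so the nucleosome total is half
#' the H4 total. The total is then partitioned like a protein with
#' alpha = the supplied DAPI/chromatin enrichment; for organelles flagged as
#' containing AT-rich satellite repeats (preferentially stained by DAPI) the
#' enrichment is first divided by the satellite-staining bias.
#'
#' @param nuc a [nucleus_model()]
#' @param org an [organelle_model()]
#' @param h4_total H4 copies per cell (defaults to the theoretical value)
#' @return nucleosome copies in a single organelle
#' @export
nucleosome_census <- function(nuc, org, h4_total = theoretical_h4_total(nuc)) {
  if (h4_total <= 0) stop_config("'h4_total' must be positive")
  alpha <- org$nucleosome_enrichment
  if (org$dapi_bias_correction) alpha <- alpha / nuc$dapi_satellite_bias
  organelle_copies(h4_total / 2, alpha, org, nuc)$copies
}

#' DNA content represented by a nucleosome count
#'
#' @param nucleosomes number of nucleosomes
#' @param nuc a [nucleus_model()] supplying the nucleosome repeat length
#' @return DNA length in bp
#' @export
dna_content <- function(nucleosomes, nuc) {
  if (any(nucleosomes < 0)) stop_config("'nucleosomes' must be >= 0")
  nucleosomes * nuc$nucleosome_repeat_length
}

#' Nucleosome molecular weight (octamer plus linker DNA)
#'
#' @param nuc a [nucleus_model()]
#' @return molecular weight in g/mol
#' @export
nucleosome_mw <- function(nuc) {
  nuc$histone_octamer_mw + nuc$nucleosome_repeat_length * nuc$bp_mw
}

#' Class-wise mass densities in an organelle
#'
#' Sums N * MW / (N_A * V_org) over the entries of each molecular class and
#' converts to mg/mL.
#'
#' @param entries data frame with columns `class`, `copies` and `mw_da`
#' @param org an [organelle_model()]
#' @return named numeric vector of mass densities (mg/mL) per class
#' @export
mass_density <- function(entries, org) {
  if (any(is.na(entries$mw_da)))
    stop_config("missing molecular weight for species: %s",
                paste(entries$species[is.na(entries$mw_da)], collapse = ", "))
  cls <- unique(entries$class)
  out <- vapply(cls, function(k) {
    sel <- entries$class == k
    mass_density_mg_ml(sum(entries$copies[sel] * entries$mw_da[sel]),
                       1, org$volume)
  }, numeric(1))
  names(out) <- cls
  out
}
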