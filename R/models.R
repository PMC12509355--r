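# Domain types for the census. Plain S3 lists with strict validators, in the
# style of small structural-bioinformatics toolkits: constructors validate on
# creation and print methods summarize.

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config("field '%s' must be a single strictly positive number", name)
  invisible(x)
}

#' Global nuclear model
#'
#' Holds the cell-level constants that drive the census: nuclear volume,
#' genome size, nucleosome repeat length, total RNA mass and its nuclear
#' fraction, plus the scoring constants. Defaults are the mouse embryonic
#' stem cell values used throughout the package.
#'
#' @param nucleus_volume nuclear volume in um^3
#' @param genome_size_haploid haploid genome size in bp
#' @param ploidy integer ploidy (2 = diploid)
#' @param nucleosome_repeat_length average bp of DNA per nucleosome
#' @param total_rna_mass total cellular RNA mass in pg
#' @param nuclear_rna_fraction fraction of cellular RNA in the nucleus, in (0, 1]
#' @param ribonucleotide_mw molecular weight of a ribonucleotide monophosphate
#'   in g/mol
#' @param detection_limit_copies copy number assigned to proteins below the
#'   mass-spectrometry detection limit
#' @param dapi_satellite_bias factor by which DAPI overreports AT-rich
#'   satellite chromatin; applied to flagged organelles
#' @param debye_length_max maximum in-cell Debye length in nm
#' @param debye_length_physiological Debye length at physiological ionic
#'   strength in nm
#' @param nucleosome_diameter nucleosome disk diameter in nm (crystal
#'   structure)
#' @param histone_octamer_mw molecular weight of the histone octamer in g/mol
#' @param bp_mw molecular weight of one bp of double-stranded DNA in g/mol
#' @return an object of class `nucleus_model`
#' @examples
#' nuc <- nucleus_model()
#' theoretical_h4_total(nuc) # ~54 million H4 molecules
#' @export
nucleus_model <- function(nucleus_volume = 450,
                          genome_size_haploid = 2.5e9,
                          ploidy = 2L,
                          nucleosome_repeat_length = 186,
                          total_rna_mass = 20,
                          nuclear_rna_fraction = 0.15,
                          ribonucleotide_mw = 340,
                          detection_limit_copies = 407,
                          dapi_satellite_bias = 1.5,
                          debye_length_max = 2.2,
                          debye_length_physiological = 0.8,
                          nucleosome_diameter = 11,
                          histone_octamer_mw = 108000,
                          bp_mw = 650) {
  for (f in c("nucleus_volume", "genome_size_haploid",
              "nucleosome_repeat_length", "total_rna_mass",
              "ribonucleotide_mw", "detection_limit_copies",
              "dapi_satellite_bias", "debye_length_max",
              "debye_length_physiological", "nucleosome_diameter",
              "histone_octamer_mw", "bp_mw"))
    check_positive(get(f), f)
  if (!is.numeric(ploidy) || length(ploidy) != 1L || is.na(ploidy) ||
      ploidy < 1 || ploidy != round(ploidy))
    stop_config("field 'ploidy' must be an integer >= 1")
  if (!is.numeric(nuclear_rna_fraction) || length(nuclear_rna_fraction) != 1L ||
      is.na(nuclear_rna_fraction) ||
      nuclear_rna_fraction <= 0 || nuclear_rna_fraction > 1)
    stop_config("field 'nuclear_rna_fraction' must lie in (0, 1]")
  structure(list(
    nucleus_volume = nucleus_volume,
    genome_size_haploid = genome_size_haploid,
    ploidy = as.integer(ploidy),
    nucleosome_repeat_length = nucleosome_repeat_length,
    total_rna_mass = total_rna_mass,
    nuclear_rna_fraction = nuclear_rna_fraction,
    ribonucleotide_mw = ribonucleotide_mw,
    detection_limit_copies = detection_limit_copies,
    dapi_satellite_bias = dapi_satellite_bias,
    debye_length_max = debye_length_max,
    debye_length_physiological = debye_length_physiological,
    nucleosome_diameter = nucleosome_diameter,
    histone_octamer_mw = histone_octamer_mw,
    bp_mw = bp_mw
  ), class = "nucleus_model")
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat("<nucleus_model>\n")
  cat(sprintf("  V_nuc = %g um^3, genome %g bp x %d (ploidy), NRL %g bp\n",
              x$nucleus_volume, x$genome_size_haploid, x$ploidy,
              x$nucleosome_repeat_length))
  cat(sprintf("  RNA: %g pg total, nuclear fraction %g\n",
              x$total_rna_mass, x$nuclear_rna_fraction))
  invisible(x)
}

#' One membraneless organelle's geometry and enrichment parameters
#'
#' @param name organelle identifier
#' @param volume volume of a single organelle in um^3
#' @param count_per_nucleus number of such organelles per nucleus
#' @param rna_enrichment RNA enrichment alpha relative to nucleoplasm (>= 0)
#' @param nucleosome_enrichment chromatin (DAPI) enrichment alpha (>= 0)
#' @param rna_length RNA length in nucleotides used to convert ribonucleotides
#'   to molecules (14,000 nt for nucleolar compartments, 2790 nt otherwise)
#' @param dapi_bias_correction logical; divide the supplied DAPI enrichment by
#'   the satellite-staining bias before partitioning nucleosomes (used for
#'   AT-rich heterochromatin foci)
#' @return an object of class `organelle_model`
#' @export
organelle_model <- function(name, volume, count_per_nucleus = 1L,
                            rna_enrichment = 1, nucleosome_enrichment = 1,
                            rna_length = 2790, dapi_bias_correction = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("organelle 'name' must be a non-empty string")
  check_positive(volume, "volume")
  check_positive(rna_length, "rna_length")
  if (!is.numeric(count_per_nucleus) || count_per_nucleus < 1 ||
      count_per_nucleus != round(count_per_nucleus))
    stop_config("field 'count_per_nucleus' must be an integer >= 1")
  for (f in c("rna_enrichment", "nucleosome_enrichment")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_config("field '%s' must be >= 0", f)
  }
  structure(list(
    name = name, volume = volume,
    count_per_nucleus = as.integer(count_per_nucleus),
    rna_enrichment = rna_enrichment,
    nucleosome_enrichment = nucleosome_enrichment,
    rna_length = rna_length,
    dapi_bias_correction = isTRUE(dapi_bias_correction)
  ), class = "organelle_model")
}

#' @export
print.organelle_model <- function(x, ...) {
  cat(sprintf("<organelle_model> %s: V = %g um^3 x %d\n",
              x$name, x$volume, x$count_per_nucleus))
  invisible(x)
}

# total volume occupied by all organelle copies must fit in the nucleus
check_organelle_budget <- function(nucleus, organelles) {
  occupied <- sum(vapply(organelles, function(o)
    o$volume * o$count_per_nucleus, numeric(1)))
  if (occupied >= nucleus$nucleus_volume)
    stop_config(
      "organelles occupy %g um^3, which is not smaller than the nucleus (%g um^3)",
      occupied, nucleus$nucleus_volume)
  invisible(occupied)
}

#' Calibration anchor: a protein with both a measured copy number and an iBAQ
#'
#' @param protein protein identifier
#' @param measured_copies experimentally measured copies per cell
#' @param ibaq averaged iBAQ intensity (arbitrary linear units)
#' @return an object of class `calibration_ref`
#' @export
calibration_ref <- function(protein, measured_copies, ibaq) {
  check_positive(measured_copies, "measured_copies")
  check_positive(ibaq, "ibaq")
  structure(list(protein = protein, measured_copies = measured_copies,
                 ibaq = ibaq), class = "calibration_ref")
}

#' A contiguous ordered or disordered protein domain
#'
#' @param kind `"ordered"` or `"disordered"`
#' @param n_residues number of amino acids in the domain
#' @param rg radius of gyration in nm, or `NA` if it is to be filled in from
#'   the disordered-chain scaling law
#' @return an object of class `domain_segment`
#' @export
domain_segment <- function(kind = c("ordered", "disordered"), n_residues,
                           rg = NA_real_) {
  kind <- match.arg(kind)
  if (!is.numeric(n_residues) || n_residues < 1 ||
      n_residues != round(n_residues))
    stop_config("'n_residues' must be an integer >= 1")
  if (!is.na(rg)) check_positive(rg, "rg")
  structure(list(kind = kind, n_residues = as.integer(n_residues),
                 rg = as.numeric(rg)), class = "domain_segment")
}

#' A candidate scaffold protein species
#'
#' Exactly one of `ibaq` and `total_copies` must be supplied. An `ibaq` of
#' `NA` or 0 marks the protein as undetected by mass spectrometry; the census
#' then assigns the configured detection-limit copy number.
#'
#' @param name species identifier
#' @param ibaq averaged iBAQ intensity, or `NA`/0 for undetected proteins
#' @param total_copies directly measured copies per cell (overrides iBAQ)
#' @param enrichment organelle enrichment alpha (>= 0); `Inf` means the
#'   protein localizes exclusively to the organelle
#' @param mw molecular weight in g/mol
#' @param domains list of [domain_segment()] objects (may be empty)
#' @param predicted_diameter diameter 2*Rg of the predicted structure in nm
#' @param organelle optional organelle name this species belongs to; `NA`
#'   partitions the species into every configured organelle
#' @param relaxed_diameter,expanded_diameter optional direct diameter
#'   overrides in nm, used for large complexes whose conformations are
#'   supplied rather than derived from a domain decomposition
#' @return an object of class `protein_species`
#' @export
protein_species <- function(name, ibaq = NULL, total_copies = NULL,
                            enrichment = 1, mw, domains = list(),
                            predicted_diameter, organelle = NA_character_,
                            relaxed_diameter = NA_real_,
                            expanded_diameter = NA_real_) {
  if (is.null(ibaq) == is.null(total_copies))
    stop_config("species '%s': exactly one of 'ibaq' and 'total_copies' is required",
                name)
  if (!is.null(total_copies)) check_positive(total_copies, "total_copies")
  if (!(is.numeric(enrichment) && length(enrichment) == 1L &&
        !is.na(enrichment) && enrichment >= 0))
    stop_config("species '%s': 'enrichment' must be >= 0 (Inf allowed)", name)
  check_positive(mw, "mw")
  check_positive(predicted_diameter, "predicted_diameter")
  if (!all(vapply(domains, inherits, logical(1), "domain_segment")))
    stop_config("species '%s': 'domains' must be a list of domain_segment", name)
  structure(list(
    name = name, ibaq = if (is.null(ibaq)) NULL else as.numeric(ibaq),
    total_copies = total_copies, enrichment = enrichment, mw = mw,
    domains = domains, predicted_diameter = predicted_diameter,
    organelle = organelle,
    relaxed_diameter = as.numeric(relaxed_diameter),
    expanded_diameter = as.numeric(expanded_diameter)
  ), class = "protein_species")
}

#' A power-law relation between chain length and radius of gyration
#'
#' Used for disordered protein regions (Rg = prefactor * n^exponent with n in
#' residues) and for the fully denatured chain that caps the expanded
#' conformation. The coefficients are configurable; the defaults are typical
#' literature values for intrinsically disordered and chemically denatured
#' proteins and can be replaced by any preferred parameterization.
#'
#' @param prefactor prefactor in nm
#' @param exponent dimensionless Flory-type exponent in (0, 1)
#' @return an object of class `scaling_law`
#' @export
scaling_law <- function(prefactor, exponent) {
  check_positive(prefactor, "prefactor")
  if (!is.numeric(exponent) || exponent <= 0 || exponent >= 1)
    stop_config("'exponent' must lie in (0, 1)")
  structure(list(prefactor = prefactor, exponent = exponent),
            class = "scaling_law")
}

#' Default chain scaling laws
#'
#' @return list with elements `disordered` and `denatured`, each a
#'   [scaling_law()]
#' @export
default_scaling_laws <- function() {
  list(disordered = scaling_law(0.254, 0.522),
       denatured = scaling_law(0.19, 0.588))
}

#' Per-scenario packing state of an organelle
#'
#' @param scenario one of `"proteins_only"`, `"proteins_rna"`,
#'   `"proteins_rna_nucleosomes"`
#' @param conformation one of `"predicted"`, `"relaxed"`, `"expanded"`
#' @param effective_radius count-weighted effective radius in nm
#' @param volume_fraction packing fraction phi
#' @param center_distance mean center-to-center nearest-neighbor distance, nm
#' @param surface_distance mean surface-to-surface distance, nm
#' @param overlap_ratio concentration relative to the overlap concentration
#' @return an object of class `packing_state`
#' @export
packing_state <- function(scenario, conformation, effective_radius,
                          volume_fraction, center_distance, surface_distance,
                          overlap_ratio) {
  scenario <- match.arg(scenario, c("proteins_only", "proteins_rna",
                                    "proteins_rna_nucleosomes"))
  conformation <- match.arg(conformation,
                            c("predicted", "relaxed", "expanded"))
  if (volume_fraction < 0) stop_config("volume_fraction must be >= 0")
  structure(list(scenario = scenario, conformation = conformation,
                 effective_radius = effective_radius,
                 volume_fraction = volume_fraction,
                 center_distance = center_distance,
                 surface_distance = surface_distance,
                 overlap_ratio = overlap_ratio), class = "packing_state")
}

#' Scorecard for one organelle
#'
#' @param organelle organelle name
#' @param scores named numeric vector of three S_D scores in \[0, 1\], in the
#'   order proteins only / proteins + RNAs / proteins + RNAs + nucleosomes
#' @param nucleosome_to_protein_ratio nucleosomes per candidate scaffold
#'   protein in the organelle
#' @param cutoff score cutoff used for the mechanism call
#' @return an object of class `score_card` with fields `mechanism_call`
#'   (`"PSCP_LLPS_compatible"` or `"ICBS_favored"`) and `passing_scenarios`
#' @export
score_card <- function(organelle, scores, nucleosome_to_protein_ratio,
                       cutoff = 0.5) {
  if (length(scores) != 3L || any(is.na(scores)) ||
      any(scores < 0 | scores > 1))
    stop_config("'scores' must be three values in [0, 1]")
  if (is.null(names(scores)))
    names(scores) <- c("proteins_only", "proteins_rna",
                       "proteins_rna_nucleosomes")
  cls <- classify(scores, cutoff = cutoff)
  structure(list(organelle = organelle, scores = scores,
                 nucleosome_to_protein_ratio = nucleosome_to_protein_ratio,
                 mechanism_call = cls$call,
                 passing_scenarios = cls$passing,
                 cutoff = cutoff), class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s: %s\n", x$organelle, x$mechanism_call))
  cat(sprintf("  S_D = %.3f / %.3f / %.3f (proteins / +RNA / +nucleosomes)\n",
              x$scores[1], x$scores[2], x$scores[3]))
  cat(sprintf("  nucleosome:protein ratio = %.3g\n",
              x$nucleosome_to_protein_ratio))
  invisible(x)
}
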