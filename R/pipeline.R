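# End-to-end census pipeline: calibration -> copy numbers -> per-organelle
# censuses of proteins, RNAs and nucleosomes -> conformer sizes -> packing
# states -> scorecards.

rna_conformation <- function(conformation) {
  switch(conformation, predicted = "folded", conformation)
}

#' Run the full molecular census
#'
#' @param config configuration list as returned by [load_config()] (or an
#'   equivalently shaped list with `nucleus`, `organelles`,
#'   `calibration_refs` and `species`)
#' @param laws chain scaling laws, see [default_scaling_laws()]
#' @param conformations conformations to evaluate packing states for
#' @param lambda_d Debye length used for scoring; defaults to the nucleus
#'   model's maximum Debye length
#' @param cutoff classification cutoff
#' @return object of class `census_result`: a list with
#'   \describe{
#'     \item{census}{data frame, one row per species (and per RNA and
#'       nucleosome pool) per organelle: copies, concentration (uM),
#'       molecular weight, mass density (mg/mL)}
#'     \item{geometry}{data frame of per-species diameters for each
#'       conformation}
#'     \item{packing}{data frame of packing states per organelle x scenario
#'       x conformation}
#'     \item{scorecards}{list of [score_card()], one per organelle}
#'     \item{calibration}{the fitted `calibration_model` (or `NULL`)}
#'   }
#' @export
run_census <- function(config, laws = default_scaling_laws(),
                       conformations = c("predicted", "relaxed", "expanded"),
                       lambda_d = NULL, cutoff = 0.5) {
  nuc <- config$nucleus
  organelles <- config$organelles
  species <- config$species
  if (is.null(lambda_d)) lambda_d <- nuc$debye_length_max
  calib <- if (length(config$calibration_refs))
    fit_calibration(config$calibration_refs) else NULL
  needs_calib <- any(vapply(species, function(s)
    is.null(s$total_copies), logical(1)))
  if (needs_calib && is.null(calib))
    stop_config("species with iBAQ values require calibration anchors")
  h4 <- theoretical_h4_total(nuc)
  rna <- rna_census(nuc, organelles)

  census <- list()
  diam <- lapply(species, protein_diameters, laws = laws)
  names(diam) <- vapply(species, `[[`, character(1), "name")
  for (org in organelles) {
    mine <- Filter(function(s)
      is.na(s$organelle) || s$organelle == org$name, species)
    for (s in mine) {
      oc <- organelle_copies(total_copies(s, calib, nuc), s$enrichment,
                             org, nuc)
      census[[length(census) + 1L]] <- data.frame(
        organelle = org$name, species = s$name, class = "protein",
        copies = oc$copies, concentration_uM = oc$concentration,
        mw_da = s$mw,
        mass_density_mg_ml = mass_density_mg_ml(oc$copies, s$mw, org$volume),
        stringsAsFactors = FALSE)
    }
    rna_mol <- rna$per_organelle_molecules[[org$name]]
    rna_mw <- org$rna_length * nuc$ribonucleotide_mw
    census[[length(census) + 1L]] <- data.frame(
      organelle = org$name, species = "RNA", class = "rna",
      copies = rna_mol, concentration_uM = conc_uM(rna_mol, org$volume),
      mw_da = rna_mw,
      mass_density_mg_ml = mass_density_mg_ml(rna_mol, rna_mw, org$volume),
      stringsAsFactors = FALSE)
    nucl <- nucleosome_census(nuc, org, h4)
    census[[length(census) + 1L]] <- data.frame(
      organelle = org$name, species = "nucleosome", class = "nucleosome",
      copies = nucl, concentration_uM = conc_uM(nucl, org$volume),
      mw_da = nucleosome_mw(nuc),
      mass_density_mg_ml = mass_density_mg_ml(nucl, nucleosome_mw(nuc),
                                              org$volume),
      stringsAsFactors = FALSE)
  }
  census <- do.call(rbind, census)

  geometry <- do.call(rbind, lapply(names(diam), function(nm) data.frame(
    species = nm, conformation = names(diam[[nm]]),
    diameter = unname(diam[[nm]]), stringsAsFactors = FALSE)))

  components_of <- function(org, conformation) {
    rows <- census[census$organelle == org$name, , drop = FALSE]
    d <- vapply(seq_len(nrow(rows)), function(i) {
      switch(rows$class[i],
             protein = diam[[rows$species[i]]][[conformation]],
             rna = rna_diameter(org$rna_length,
                                rna_conformation(conformation)),
             nucleosome = nuc$nucleosome_diameter)
    }, numeric(1))
    cbind(mixture_components(rows$species, rows$copies, d, rows$class),
          concentration_uM = rows$concentration_uM)
  }

  packing <- list()
  scorecards <- list()
  for (org in organelles) {
    for (conformation in conformations) {
      comp <- components_of(org, conformation)
      for (sc in names(scenario_classes)) {
        st <- scenario_distances(comp, sc, org$volume, conformation)
        packing[[length(packing) + 1L]] <- data.frame(
          organelle = org$name, scenario = st$scenario,
          conformation = st$conformation,
          effective_radius = st$effective_radius,
          volume_fraction = st$volume_fraction,
          center_distance = st$center_distance,
          surface_distance = st$surface_distance,
          overlap_ratio = st$overlap_ratio, stringsAsFactors = FALSE)
      }
    }
    scorecards[[org$name]] <- score_organelle(
      components_of(org, "relaxed"), org$volume, organelle = org$name,
      lambda_d = lambda_d, cutoff = cutoff)
  }
  structure(list(census = census, geometry = geometry,
                 packing = do.call(rbind, packing),
                 scorecards = scorecards, calibration = calib,
                 nucleus = nuc, organelles = organelles,
                 components_of = components_of),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("<census_result> %d organelle class(es), %d census rows\n",
              length(x$organelles), nrow(x$census)))
  for (sc in x$scorecards) print(sc)
  invisible(x)
}

#' Extract the mixture components of one organelle
#'
#' @param result a `census_result` from [run_census()]
#' @param organelle organelle name
#' @param conformation conformation for the diameters
#' @return data frame with `species`, `class`, `copies`, `diameter` and
#'   `concentration_uM`
#' @export
census_components <- function(result, organelle,
                              conformation = c("relaxed", "predicted",
                                               "expanded")) {
  conformation <- match.arg(conformation)
  org <- Filter(function(o) o$name == organelle, result$organelles)
  if (!length(org)) stop_config("unknown organelle '%s'", organelle)
  result$components_of(org[[1]], conformation)
}
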