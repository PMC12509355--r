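# Crowding metrics and mean nearest-neighbor distances for randomly
# distributed (effectively hard-sphere) molecules in an organelle.

# unnormalized upper incomplete gamma Gamma(a, x)
upper_incomplete_gamma <- function(a, x) {
  gamma(a) * stats::pgamma(x, shape = a, lower.tail = FALSE)
}

# phi at and beyond random dense packing of rigid spheres: contact distance
PHI_DENSE_PACKING <- 0.65

#' Volume available per molecule
#'
#' @param v_org organelle volume in um^3
#' @param n_molecules number of molecules in the organelle
#' @return available volume per molecule in nm^3
#' @export
available_volume <- function(v_org, n_molecules) {
  if (n_molecules < 1) stop_config("'n_molecules' must be >= 1")
  v_org * NM3_PER_UM3 / n_molecules
}

#' Volume fraction of a sphere in its available volume
#'
#' @param r sphere radius in nm
#' @param v_available available volume per molecule in nm^3
#' @return volume fraction phi
#' @export
volume_fraction <- function(r, v_available) {
  if (any(r <= 0) || any(v_available <= 0))
    stop_config("radius and available volume must be positive")
  (4 * pi / 3) * r^3 / v_available
}

#' Mean center-to-center nearest-neighbor distance
#'
#' For randomly placed spheres of radius r at volume fraction phi,
#' Delta_center = 2r + exp(8 phi) * r / (3 phi^(1/3)) * Gamma(1/3, 8 phi),
#' with the unnormalized upper incomplete gamma function. In the dilute
#' limit this reduces to the Poisson nearest-neighbor mean
#' Gamma(4/3) * (4 pi n / 3)^(-1/3). At phi >= 0.65 (random dense packing)
#' neighbors are taken to be in contact, Delta_center = 2r.
#'
#' @param r sphere radius in nm
#' @param phi volume fraction (> 0); vectorized
#' @return mean center distance in nm
#' @export
nn_center_distance <- function(r, phi) {
  if (any(phi <= 0)) stop_config("'phi' must be positive")
  gap <- exp(8 * phi) * r / (3 * phi^(1 / 3)) *
    upper_incomplete_gamma(1 / 3, 8 * phi)
  ifelse(phi >= PHI_DENSE_PACKING, 2 * r, 2 * r + gap)
}

#' Mean surface-to-surface nearest-neighbor distance
#'
#' Delta_surface = Delta_center - 2r; zero at and beyond phi = 0.65. The
#' clamp is applied after the analytic evaluation.
#'
#' @inheritParams nn_center_distance
#' @return mean surface distance in nm
#' @export
nn_surface_distance <- function(r, phi) {
  pmax(nn_center_distance(r, phi) - 2 * r, 0)
}

#' Build a mixture component table
#'
#' @param species character vector of identifiers
#' @param copies copy numbers (>= 0)
#' @param diameter diameters in nm (> 0)
#' @param class optional molecular class (`"protein"`, `"rna"`,
#'   `"nucleosome"`)
#' @return data frame of mixture components
#' @export
mixture_components <- function(species, copies, diameter,
                               class = rep("protein", length(species))) {
  if (any(copies < 0)) stop_config("'copies' must be >= 0")
  if (any(diameter <= 0)) stop_config("'diameter' must be positive")
  data.frame(species = species, class = class, copies = copies,
             diameter = diameter, stringsAsFactors = FALSE)
}

#' Count-weighted effective radius of a mixture
#'
#' r_avg = (sum N_i (d_i/2)^3 / sum N_i)^(1/3): the radius whose sphere has
#' the mean per-molecule volume of the mixture.
#'
#' @param components data frame with columns `copies` and `diameter`
#' @return effective radius in nm
#' @export
effective_radius <- function(components) {
  n <- components$copies
  if (sum(n) <= 0) stop_config("mixture has no molecules")
  (sum(n * (components$diameter / 2)^3) / sum(n))^(1 / 3)
}

#' Concentration relative to the overlap concentration
#'
#' c / c_overlap = sum_i N_i V_i / V_org, where V_i is the pervaded sphere
#' volume of species i. At 1 the molecules' pervaded volumes tile the
#' organelle.
#'
#' @param components data frame with columns `copies` and `diameter`
#' @param v_org organelle volume in um^3
#' @return dimensionless overlap ratio
#' @export
overlap_ratio <- function(components, v_org) {
  if (v_org <= 0) stop_config("'v_org' must be positive")
  if (nrow(components) == 0L || sum(components$copies) == 0) return(0)
  sum(components$copies * molecule_volume(components$diameter)) /
    (v_org * NM3_PER_UM3)
}

scenario_classes <- list(
  proteins_only = "protein",
  proteins_rna = c("protein", "rna"),
  proteins_rna_nucleosomes = c("protein", "rna", "nucleosome"))

#' Packing state for a multicomponent scenario
#'
#' Pools the molecular classes required by the scenario, computes the
#' count-weighted effective radius, the volume fraction
#' phi = (4 pi / 3) r_avg^3 * N / V_org, and the nearest-neighbor center and
#' surface distances. If any class the scenario requires has zero total
#' copies, a degenerate state with phi = 0 and infinite distances is
#' returned with a warning.
#'
#' @param components data frame as from [mixture_components()] with a
#'   `class` column; diameters must correspond to the conformation in use
#' @param scenario `"proteins_only"`, `"proteins_rna"`, or
#'   `"proteins_rna_nucleosomes"`
#' @param v_org organelle volume in um^3
#' @param conformation conformation label recorded in the state
#' @return a [packing_state()]
#' @export
scenario_distances <- function(components, scenario, v_org,
                               conformation = "relaxed") {
  scenario <- match.arg(scenario, names(scenario_classes))
  need <- scenario_classes[[scenario]]
  sel <- components[components$class %in% need, , drop = FALSE]
  per_class <- vapply(need, function(k)
    sum(sel$copies[sel$class == k]), numeric(1))
  if (any(per_class == 0)) {
    warning(sprintf(
      "scenario '%s' requires class(es) with zero copies (%s); returning phi = 0",
      scenario, paste(need[per_class == 0], collapse = ", ")))
    return(packing_state(scenario, conformation, NA_real_, 0,
                         Inf, Inf, overlap_ratio(sel, v_org)))
  }
  r_avg <- effective_radius(sel)
  n_tot <- sum(sel$copies)
  phi <- volume_fraction(r_avg, available_volume(v_org, n_tot))
  packing_state(scenario, conformation,
                effective_radius = r_avg, volume_fraction = phi,
                center_distance = nn_center_distance(r_avg, phi),
                surface_distance = nn_surface_distance(r_avg, phi),
                overlap_ratio = overlap_ratio(sel, v_org))
}
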