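# Synthetic-data generation and Monte-Carlo oracles. The synthetic cell
# emulates the study conditions (a diploid mammalian stem-cell nucleus with
# RNA-rich and chromatin-rich organelle classes) with known ground truth, so
# that every census stage can be validated end to end without external data.

#' Generate a synthetic cell with known ground truth
#'
#' Creates a nucleus with two default organelle classes (ten chromatin-rich,
#' DAPI-biased foci of 3 um^3 and two RNA-rich nucleolus-like bodies of
#' 40 um^3 inside a 450 um^3 nucleus), a set of candidate scaffold species
#' with ground-truth copy numbers drawn log-uniformly between 1e3 and 1e7,
#' enrichments drawn log-normally, random ordered/disordered domain
#' decompositions, and iBAQ values generated as copies / a_true with
#' optional multiplicative log-normal noise. Configuration and species
#' tables are written through the package's own writers, so reading them
#' back exercises the public I/O surface. Byte-identical output for a given
#' seed.
#'
#' @param seed integer seed
#' @param n_species number of candidate scaffold species (>= 1)
#' @param organelle_specs optional list of argument lists for
#'   [organelle_model()], replacing the default two organelle classes
#' @param dir output directory (created; defaults to a fresh temporary
#'   directory)
#' @param a_true ground-truth calibration slope (copies per iBAQ unit)
#' @param ibaq_noise_sd standard deviation of the log-normal multiplicative
#'   iBAQ noise (0 = noise-free)
#' @param n_refs number of calibration anchor proteins
#' @return list with `dir`, `config_path`, `species_path`, the generated
#'   `nucleus`, `organelles`, `species` and `calibration_refs`, and `truth`
#'   (ground-truth `a`, per-species `copies`, `alpha`, `organelle`
#'   assignment and expected per-organelle copies `n_org`)
#' @export
make_synthetic_cell <- function(seed, n_species = 12L, organelle_specs = NULL,
                                dir = tempfile("syncell"), a_true = 120,
                                ibaq_noise_sd = 0, n_refs = 5L) {
  if (n_species < 1) stop_config("'n_species' must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nucleus <- nucleus_model()
  if (is.null(organelle_specs)) {
    organelle_specs <- list(
      list(name = "chromatin_focus", volume = 3, count_per_nucleus = 10L,
           rna_enrichment = 0.5, nucleosome_enrichment = 4.5,
           rna_length = 2790, dapi_bias_correction = TRUE),
      list(name = "rna_body", volume = 40, count_per_nucleus = 2L,
           rna_enrichment = 12, nucleosome_enrichment = 0.3,
           rna_length = 14000))
  }
  organelles <- lapply(organelle_specs, function(s) do.call(organelle_model, s))
  check_organelle_budget(nucleus, organelles)
  org_names <- vapply(organelles, `[[`, character(1), "name")

  out <- with_seed(seed, {
    copies <- 10^runif(n_species, 3, 7)
    alpha <- rlnorm(n_species, meanlog = log(4), sdlog = 0.8)
    assignment <- org_names[((seq_len(n_species) - 1L) %% length(org_names)) + 1L]
    mw <- runif(n_species, 2e4, 2e5)
    noise <- function(n) if (ibaq_noise_sd > 0)
      rlnorm(n, meanlog = 0, sdlog = ibaq_noise_sd) else rep(1, n)
    ibaq <- copies / a_true * noise(n_species)
    laws <- default_scaling_laws()
    species <- lapply(seq_len(n_species), function(i) {
      n_res <- max(20L, round(mw[i] / 110))
      k <- sample(1:4, 1)
      cuts <- sort(sample(seq_len(n_res - 1L), k - 1L))
      lens <- diff(c(0L, cuts, n_res))
      kinds <- rep(c("ordered", "disordered"),
                   length.out = k)[sample(seq_len(k))]
      domains <- mapply(function(kind, l) {
        rg <- if (kind == "ordered") 0.3 * l^0.35
              else rg_disordered(l, laws$disordered)
        domain_segment(kind, l, rg)
      }, kinds, lens, SIMPLIFY = FALSE, USE.NAMES = FALSE)
      predicted <- diameter_relaxed(domains, 0) * runif(1, 0.6, 0.95)
      protein_species(sprintf("SP%03d", i), ibaq = ibaq[i],
                      enrichment = alpha[i], mw = mw[i], domains = domains,
                      predicted_diameter = predicted,
                      organelle = assignment[i])
    })
    ref_copies <- 10^runif(n_refs, 4, 6.5)
    refs <- lapply(seq_len(n_refs), function(j)
      calibration_ref(sprintf("REF%02d", j), ref_copies[j],
                      ref_copies[j] / a_true * noise(1)))
    list(species = species, refs = refs, copies = copies, alpha = alpha,
         assignment = assignment)
  })

  # expected per-organelle copies from the partition model, written out as
  # ground truth (independent inline arithmetic, not the census code path)
  n_org_truth <- vapply(seq_len(n_species), function(i) {
    org <- organelles[[match(out$assignment[i], org_names)]]
    a <- out$alpha[i]
    a * out$copies[i] * org$volume /
      ((a - 1) * org$count_per_nucleus * org$volume + nucleus$nucleus_volume)
  }, numeric(1))

  species_path <- file.path(dir, "species.tsv")
  config_path <- file.path(dir, "config.yaml")
  write_species_tsv(out$species, species_path)
  write_config(nucleus, organelles, out$refs, config_path,
               species_file = "species.tsv")
  names(out$copies) <- names(out$alpha) <- names(n_org_truth) <-
    vapply(out$species, `[[`, character(1), "name")
  list(dir = dir, config_path = config_path, species_path = species_path,
       nucleus = nucleus, organelles = organelles, species = out$species,
       calibration_refs = out$refs,
       truth = list(a = a_true, copies = out$copies, alpha = out$alpha,
                    organelle = setNames(out$assignment, names(out$copies)),
                    n_org = n_org_truth))
}

#' Poisson nearest-neighbor oracle
#'
#' Samples uniform points in a periodic cube at the requested density and
#' returns the mean nearest-neighbor center distance. The expectation is
#' Gamma(4/3) * (4 pi density / 3)^(-1/3), about 0.55396 * density^(-1/3).
#'
#' @param density number density in points per nm^3
#' @param n_points number of points (>= 1e4 recommended)
#' @param seed integer seed
#' @return list with `mean` (nm), `se` (standard error of the mean) and
#'   `n_points`
#' @export
poisson_nn_oracle <- function(density, n_points = 1e5, seed = 1L) {
  if (density <= 0) stop_config("'density' must be positive")
  n_points <- as.integer(n_points)
  L <- (n_points / density)^(1 / 3)
  d <- with_seed(seed, {
    pts <- matrix(runif(3 * n_points) * L, ncol = 3)
    cpp_nn_distances_periodic(pts, L)
  })
  list(mean = mean(d), se = stats::sd(d) / sqrt(n_points),
       n_points = n_points)
}

#' Hard-sphere nearest-neighbor oracle (random sequential insertion)
#'
#' Places non-overlapping spheres of radius `r` at volume fraction `phi` in
#' a periodic cube by rejection sampling and returns the mean
#' nearest-neighbor center distance. Feasible up to roughly phi = 0.3;
#' insertion failure raises an error suggesting a lower volume fraction.
#'
#' @param r sphere radius in nm
#' @param phi volume fraction (0 < phi <= 0.35)
#' @param n_points number of spheres
#' @param seed integer seed
#' @param max_attempts total insertion attempt budget
#' @return list with `mean` (nm), `se` and `n_points`
#' @export
hard_sphere_nn_oracle <- function(r, phi, n_points = 4000, seed = 1L,
                                  max_attempts = 2e4 * n_points) {
  if (phi <= 0 || phi > 0.35)
    stop_config("'phi' must lie in (0, 0.35] for random sequential insertion")
  n_points <- as.integer(n_points)
  L <- (n_points * (4 * pi / 3) * r^3 / phi)^(1 / 3)
  d <- with_seed(seed, {
    pts <- cpp_rsa_insert(n_points, r, L, max_attempts)
    cpp_nn_distances_periodic(pts, L)
  })
  list(mean = mean(d), se = stats::sd(d) / sqrt(n_points),
       n_points = n_points)
}
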