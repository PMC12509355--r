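test_that("constructors enforce physical invariants", {
  expect_error(nucleus_model(nucleus_volume = -1), "nucleus_volume")
  expect_error(nucleus_model(ploidy = 0), "ploidy")
  expect_error(nucleus_model(nuclear_rna_fraction = 1.5), "nuclear_rna_fraction")
  expect_error(organelle_model("x", volume = 0), "volume")
  expect_error(organelle_model("x", 1, count_per_nucleus = 0), "count_per_nucleus")
  expect_error(organelle_model("x", 1, rna_enrichment = -0.1), "rna_enrichment")
  expect_error(domain_segment("ordered", 0), "n_residues")
  expect_error(calibration_ref("p", -5, 1), "measured_copies")
  expect_error(scaling_law(0.2, 1.2), "exponent")
  # exactly one abundance source per species
  expect_error(protein_species("p", ibaq = 1, total_copies = 10, mw = 1e4,
                               predicted_diameter = 3), "exactly one")
  expect_error(protein_species("p", mw = 1e4, predicted_diameter = 3),
               "exactly one")
})

test_that("organelles must fit inside the nucleus", {
  nuc <- nucleus_model(nucleus_volume = 10)
  orgs <- list(organelle_model("a", 3, 2L), organelle_model("b", 5, 1L))
  expect_error(nucleocensus:::check_organelle_budget(nuc, orgs), "nucleus")
  d <- tempfile()
  syn <- make_synthetic_cell(seed = 1, n_species = 2, dir = d,
                             organelle_specs = list(
                               list(name = "a", volume = 40,
                                    count_per_nucleus = 10L)))
  cfg <- yaml::read_yaml(syn$config_path)
  cfg$organelles[[1]]$volume <- 60  # 10 x 60 um^3 > 450 um^3 nucleus
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(load_config(bad), "nucleus")
})

test_that("missing configuration fields are reported by name", {
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(organelles = list(list(name = "a"))), bad)
  expect_error(load_config(bad), "volume")
  yaml::write_yaml(list(calibration = list(list(protein = "p", ibaq = 3))),
                   bad)
  expect_error(load_config(bad), "measured_copies")
})

test_that("config and species tables round-trip through the public readers", {
  syn <- make_synthetic_cell(seed = 42, n_species = 7)
  cfg <- load_config(syn$config_path)
  expect_equal(unclass(cfg$nucleus), unclass(syn$nucleus))
  expect_equal(lapply(cfg$organelles, unclass),
               lapply(syn$organelles, unclass))
  expect_equal(length(cfg$species), 7L)
  # write the parsed species back; byte-identical table
  second <- tempfile(fileext = ".tsv")
  write_species_tsv(cfg$species, second)
  expect_identical(readLines(second), readLines(syn$species_path))
  # enrichment Inf is encoded as the literal "inf"
  sp <- protein_species("excl", total_copies = 500, enrichment = Inf,
                        mw = 5e4, predicted_diameter = 4)
  p <- tempfile(fileext = ".tsv")
  write_species_tsv(list(sp), p)
  expect_match(readLines(p)[2], "\tinf\t")
  back <- read_species_tsv(p)
  expect_identical(back[[1]]$enrichment, Inf)
  expect_identical(back[[1]]$total_copies, 500)
})

test_that("domain encoding parses, resolves '?' and formats back", {
  doms <- parse_domains("O:120:2.1;D:80:?")
  expect_length(doms, 2L)
  expect_identical(doms[[1]]$kind, "ordered")
  expect_equal(doms[[2]]$rg, rg_disordered(80))
  expect_error(parse_domains("O:10:?"), "disordered")
  expect_error(parse_domains("X:10:1"), "unknown domain kind")
  rt <- parse_domains(format_domains(doms))
  expect_equal(rt, doms)
})

test_that("census reports round-trip and refuse invalid entries", {
  entries <- data.frame(
    organelle = "org", species = c("A", "B"), class = "protein",
    copies = c(12345, 67), concentration_uM = c(1.234567891e-3, 7.2),
    mw_da = c(5e4, 1.2e5), mass_density_mg_ml = c(0.1, 0.2),
    stringsAsFactors = FALSE)
  scores <- list(score_card("org", c(a = 0.1, b = 0.6, c = 0.2), 3))
  d <- tempfile()
  write_census_report(entries, scores, d)
  back <- read_census_report(d)
  expect_identical(back$entries$copies, entries$copies)
  expect_rel_equal(back$entries$concentration_uM, entries$concentration_uM,
                   1e-9)
  expect_identical(back$scores[[1]]$mechanism_call, "PSCP_LLPS_compatible")
  expect_equal(back$scores[[1]]$scores, scores[[1]]$scores)
  # empty scorecards: tables only, with a warning
  expect_warning(write_census_report(entries, list(), tempfile()),
                 "census tables only")
  entries$copies[1] <- -1
  expect_error(write_census_report(entries, scores, tempfile()), "negative")
})
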