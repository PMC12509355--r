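test_that("theoretical H4 totals follow ploidy, genome size and repeat length", {
  nuc <- nucleus_model()
  expect_equal(theoretical_h4_total(nuc), 4 * 2.5e9 / 186)
  expect_equal(theoretical_h4_total(nucleus_model(ploidy = 1)),
               theoretical_h4_total(nuc) / 2)
  expect_equal(theoretical_h4_total(
    nucleus_model(nucleosome_repeat_length = 200)), 5.0e7)
})

test_that("through-origin calibration recovers closed-form slopes", {
  one <- fit_calibration(list(calibration_ref("p", 1000, 10)))
  expect_equal(one$scale_a, 100)
  coll <- fit_calibration(list(calibration_ref("p", 100, 1),
                               calibration_ref("q", 200, 2)))
  expect_equal(coll$scale_a, 100)
  # through-origin OLS: sum(xy)/sum(x^2) = 700/5
  two <- fit_calibration(list(calibration_ref("p", 100, 1),
                              calibration_ref("q", 300, 2)))
  expect_equal(two$scale_a, 140)
  expect_error(fit_calibration(list()), "at least one")
  expect_error(fit_calibration(list(calibration_ref("p", 10, 1),
                                    structure(list(protein = "q",
                                                   measured_copies = -1,
                                                   ibaq = 1),
                                              class = "calibration_ref"))),
               "positive")
})

test_that("total copies: direct measurement, iBAQ path, detection limit", {
  nuc <- nucleus_model()
  calib <- fit_calibration(list(calibration_ref("p", 1000, 10)))
  sp_ibaq <- protein_species("a", ibaq = 10, mw = 1e4, predicted_diameter = 3)
  expect_equal(total_copies(sp_ibaq, calib, nuc), 1000)
  sp_direct <- protein_species("b", total_copies = 5e4, mw = 1e4,
                               predicted_diameter = 3)
  expect_equal(total_copies(sp_direct, calib, nuc), 5e4)
  sp_und <- protein_species("c", ibaq = NA, mw = 1e4, predicted_diameter = 3)
  expect_equal(total_copies(sp_und, calib, nuc), 407)
  expect_equal(total_copies(protein_species("d", ibaq = 0, mw = 1e4,
                                            predicted_diameter = 3),
                            calib, nuc), 407)
})

test_that("enrichment from intensities is background-subtracted", {
  expect_equal(enrichment_from_intensities(30, 12, 2), 2.8)
  expect_equal(enrichment_from_intensities(12, 12, 2), 1.0)
  expect_equal(enrichment_from_intensities(2, 12, 2), 0.0)
  expect_error(enrichment_from_intensities(30, 2, 2), "background")
})

test_that("organelle partition: uniform, exclusive, and worked case", {
  g <- simple_geometry(v_nuc = 100, v_org = 1, n_org = 10L)
  uni <- organelle_copies(1e6, 1, g$organelle, g$nucleus)
  expect_equal(uni$copies, 1e6 * 1 / 100)
  excl <- organelle_copies(1e6, Inf, g$organelle, g$nucleus)
  expect_equal(excl$copies, 1e5)
  expect_equal(excl$nucleoplasm_copies, 0)
  wk <- organelle_copies(1e6, 10, g$organelle, g$nucleus)
  expect_equal(wk$copies, 1e7 / 190)
  expect_equal(wk$concentration, conc_uM(1e7 / 190, 1))
  depl <- organelle_copies(1e6, 0, g$organelle, g$nucleus)
  expect_equal(depl$copies, 0)
})

test_that("protein partition conserves the total pool and is monotone in alpha", {
  set.seed(7)
  for (i in 1:100) {
    v_nuc <- runif(1, 50, 800)
    n_org <- sample(1:20, 1)
    v_org <- runif(1, 0.05, v_nuc / n_org * 0.8)
    g <- simple_geometry(v_nuc, v_org, n_org)
    n_tot <- 10^runif(1, 3, 8)
    alpha <- rlnorm(1, 0, 1.5)
    oc <- organelle_copies(n_tot, alpha, g$organelle, g$nucleus)
    expect_rel_equal(n_org * oc$copies + oc$nucleoplasm_copies, n_tot, 1e-9)
  }
  g <- simple_geometry()
  alphas <- c(0.1, 0.5, 1, 2, 5, 20, 1e3)
  copies <- vapply(alphas, function(a)
    organelle_copies(1e6, a, g$organelle, g$nucleus)$copies, numeric(1))
  expect_true(all(diff(copies) > 0))
  # alpha = Inf equals the numeric alpha -> 1e9 limit
  lim <- organelle_copies(1e6, 1e9, g$organelle, g$nucleus)$copies
  expect_rel_equal(organelle_copies(1e6, Inf, g$organelle, g$nucleus)$copies,
                   lim, 1e-6)
})

test_that("RNA census converts mass to ribonucleotides and conserves them", {
  nuc <- nucleus_model()
  orgs <- list(organelle_model("a", 3, 10L, rna_enrichment = 0.4),
               organelle_model("b", 40, 2L, rna_enrichment = 12,
                               rna_length = 14000))
  pool <- rna_census(nuc, orgs)
  expect_rel_equal(pool$total_ribonucleotides,
                   20e-12 * 0.15 / 340 * 6.02214076e23, 1e-12)
  n_inst <- vapply(orgs, `[[`, integer(1), "count_per_nucleus")
  expect_rel_equal(
    pool$nucleoplasm_ribonucleotides +
      sum(n_inst * pool$per_organelle_ribonucleotides),
    pool$total_ribonucleotides, 1e-9)
  expect_equal(pool$per_organelle_molecules[["b"]],
               pool$per_organelle_ribonucleotides[["b"]] / 14000)
  # uniform enrichment: organelle concentration equals nucleoplasm
  uni <- rna_census(nuc, list(organelle_model("u", 5, 4L)))
  expect_equal(uni$per_organelle_ribonucleotides[["u"]] / 5,
               uni$nucleoplasm_concentration)
  # full depletion: everything stays in the nucleoplasm
  dep <- rna_census(nuc, list(organelle_model("d", 5, 4L,
                                              rna_enrichment = 0)))
  expect_equal(dep$per_organelle_ribonucleotides[["d"]], 0)
  expect_rel_equal(dep$nucleoplasm_ribonucleotides,
                   dep$total_ribonucleotides, 1e-12)
})

test_that("nucleosome census halves H4 and applies the DAPI satellite bias", {
  nuc <- nucleus_model()
  h4 <- theoretical_h4_total(nuc)
  # alpha = 1 at 1% volume ratio puts 1% of all nucleosomes in the organelle
  org <- organelle_model("o", nuc$nucleus_volume / 100, 1L)
  expect_rel_equal(nucleosome_census(nuc, org, h4), h4 / 2 / 100, 1e-12)
  # flagged DAPI enrichment 3.0 behaves like unflagged enrichment 2.0
  biased <- organelle_model("b", 2, 5L, nucleosome_enrichment = 3,
                            dapi_bias_correction = TRUE)
  plain <- organelle_model("p", 2, 5L, nucleosome_enrichment = 2)
  expect_equal(nucleosome_census(nuc, biased, h4),
               nucleosome_census(nuc, plain, h4))
})

test_that("nucleosome counts convert to DNA lengths via the repeat length", {
  nuc <- nucleus_model()
  expect_equal(dna_content(180000, nuc), 33.48e6)
  expect_equal(dna_content(1400, nuc), 260.4e3)
  expect_equal(dna_content(0, nuc), 0)
})

test_that("mass densities aggregate per class and scale with volume", {
  org1 <- organelle_model("o", 1)
  entries <- data.frame(species = "A", class = "protein", copies = 1e6,
                        mw_da = 6e4, stringsAsFactors = FALSE)
  d1 <- mass_density(entries, org1)
  expect_rel_equal(d1[["protein"]], 99.63234, 1e-5)
  org2 <- organelle_model("o", 2)
  expect_equal(mass_density(entries, org2)[["protein"]], d1[["protein"]] / 2)
  two <- rbind(entries,
               data.frame(species = "R", class = "rna", copies = 1e5,
                          mw_da = 1e6, stringsAsFactors = FALSE))
  d2 <- mass_density(two, org1)
  expect_named(d2, c("protein", "rna"))
  expect_equal(d2[["protein"]], d1[["protein"]])
  entries$mw_da <- NA
  expect_error(mass_density(entries, org1), "A")
})
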