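test_that("available volume and volume fraction follow their definitions", {
  expect_equal(available_volume(1, 1e6), 1000)
  expect_equal(available_volume(1, 5e5), 2000)
  expect_equal(available_volume(0.1, 2.5e4), 4000)
  expect_error(available_volume(1, 0), "n_molecules")
  expect_equal(volume_fraction(1, 4 * pi / 3), 1)
  expect_equal(volume_fraction(1, 4188.790205), 0.001, tolerance = 1e-9)
  expect_equal(volume_fraction(2, 100), 8 * volume_fraction(1, 100))
})

test_that("nearest-neighbor distance has the correct dilute limit", {
  # phi -> 0: the gap term approaches (Gamma(1/3)/3) * r * phi^(-1/3)
  r <- 1
  phi <- 1e-12
  expect_rel_equal(nn_center_distance(r, phi) - 2 * r,
                   gamma(1 / 3) / 3 * r * phi^(-1 / 3), 1e-3)
  # which equals the Poisson nearest-neighbor mean at density n
  n_dens <- phi / (4 * pi / 3 * r^3)
  expect_rel_equal(nn_center_distance(r, phi),
                   gamma(4 / 3) * (4 * pi * n_dens / 3)^(-1 / 3), 1e-3)
})

test_that("surface distance decreases with crowding and clamps at 0.65", {
  r <- 1.7
  phis <- seq(0.001, 0.649, length.out = 200)
  d <- nn_surface_distance(r, phis)
  expect_true(all(diff(d) < 0))
  expect_equal(nn_surface_distance(r, 0.65), 0)
  expect_equal(nn_surface_distance(r, 0.9), 0)
  expect_equal(nn_center_distance(r, 0.66), 2 * r)
  # clamp is applied after the analytic evaluation, not folded into it
  expect_gt(nn_surface_distance(r, 0.6499), 0)
  expect_error(nn_center_distance(1, 0), "phi")
})

test_that("analytic distance stays within 15% of the hard-sphere oracle at phi = 0.3", {
  hs <- hard_sphere_nn_oracle(r = 1, phi = 0.3, n_points = 2000, seed = 12)
  expect_rel_equal(nn_center_distance(1, 0.3), hs$mean, 0.15)
})

test_that("effective radius is the count-weighted cubic mean", {
  single <- mixture_components("a", 10, 6)
  expect_equal(effective_radius(single), 3)
  two <- mixture_components(c("a", "b"), c(5, 5), c(2, 4))
  expect_equal(effective_radius(two), 4.5^(1 / 3))
  expect_equal(effective_radius(rbind(two, two)), effective_radius(two))
  expect_error(effective_radius(mixture_components("a", 0, 6)),
               "no molecules")
})

test_that("overlap ratio measures pervaded volume per organelle volume", {
  d <- 10
  fill <- mixture_components("a", 1e9 / molecule_volume(d), d)
  expect_equal(overlap_ratio(fill, 1), 1)
  expect_equal(overlap_ratio(mixture_components(character(0), numeric(0),
                                                numeric(0)), 1), 0)
  crowd <- mixture_components("a", 1e6, 10)
  expect_rel_equal(overlap_ratio(crowd, 1), 0.5235988, 1e-6)
})

test_that("scenario packing reduces to the one-component formulas", {
  comp <- mixture_components("a", 5e5, 8, class = "protein")
  st <- scenario_distances(comp, "proteins_only", 0.5)
  r <- effective_radius(comp)
  phi <- volume_fraction(r, available_volume(0.5, 5e5))
  expect_identical(st$effective_radius, r)
  expect_identical(st$volume_fraction, phi)
  expect_identical(st$center_distance, nn_center_distance(r, phi))
  expect_identical(st$surface_distance, nn_surface_distance(r, phi))
  expect_equal(r, 4)
})

test_that("scenario packing is symmetric and densifies with added RNA", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    comp <- mixture_components(
      paste0("s", 1:k), 10^runif(k, 2, 5), runif(k, 2, 20),
      class = sample(c("protein", "rna"), k, replace = TRUE))
    if (!all(c("protein", "rna") %in% comp$class)) next
    perm <- comp[sample(seq_len(k)), , drop = FALSE]
    a <- scenario_distances(comp, "proteins_rna", 5)
    b <- scenario_distances(perm, "proteins_rna", 5)
    expect_equal(unclass(a), unclass(b))
    prot <- scenario_distances(comp, "proteins_only", 5)
    expect_gt(a$volume_fraction, prot$volume_fraction)
    expect_lt(a$surface_distance, prot$surface_distance)
  }
})

test_that("a scenario missing a required class degenerates with a warning", {
  comp <- mixture_components("a", 100, 5, class = "protein")
  expect_warning(st <- scenario_distances(comp, "proteins_rna", 1), "zero")
  expect_equal(st$volume_fraction, 0)
  expect_equal(st$surface_distance, Inf)
})
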