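# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# a single-organelle nucleus with simple round geometry
simple_geometry <- function(v_nuc = 100, v_org = 1, n_org = 10L) {
  list(nucleus = nucleus_model(nucleus_volume = v_nuc),
       organelle = organelle_model("org", v_org, n_org))
}

# random ordered/disordered domain decomposition with radii of gyration
random_domains <- function(n_res) {
  k <- sample(1:5, 1)
  cuts <- if (k > 1) sort(sample(seq_len(n_res - 1L), k - 1L)) else integer(0)
  lens <- diff(c(0L, cuts, n_res))
  lapply(seq_len(k), function(j) {
    kind <- sample(c("ordered", "disordered"), 1)
    rg <- if (kind == "ordered") 0.3 * lens[j]^0.35
          else rg_disordered(lens[j])
    domain_segment(kind, lens[j], rg)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
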