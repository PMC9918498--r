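test_that("titration spec rejects invalid conditions naming the field", {
  expect_error(titration_sim_spec(true_kd = -1), "true_kd")
  expect_error(titration_sim_spec(enzyme_total = 0), "enzyme_total")
  expect_error(titration_sim_spec(inhibitor_grid = c(0, 100, 100)),
               "inhibitor_grid")
  expect_error(titration_sim_spec(inhibitor_grid = c(100, 200)),
               "inhibitor_grid")
  expect_error(titration_sim_spec(noise_cv = 0.9), "noise_cv")
  expect_error(titration_sim_spec(n_replicates = 0), "n_replicates")
})

test_that("noiseless titration equals the equilibrium forward model", {
  # stoichiometric limit
  spec <- titration_sim_spec(true_kd = 0, enzyme_total = 500,
                             inhibitor_grid = c(0, 250, 500, 750),
                             noise_cv = 0, n_replicates = 1)
  expect_equal(gen_titration(spec)$activity_fraction, c(1, 0.5, 0, 0))
  # finite affinity: matches the independent mass-balance root oracle
  spec2 <- titration_sim_spec(noise_cv = 0, n_replicates = 1)
  ts <- gen_titration(spec2)
  expect_equal(ts$activity_fraction,
               morrison_oracle(515, ts$inhibitor_total, 30.25),
               tolerance = 1e-9)
  expect_equal(round(morrison_activity(515, 515, 30.25), 4), 0.2148)
})

test_that("titration generator is deterministic and bounded", {
  spec <- titration_sim_spec(noise_cv = 0.1, n_replicates = 3, seed = 99)
  a <- gen_titration(spec)
  b <- gen_titration(spec)
  expect_identical(a, b)
  expect_true(all(a$activity_fraction >= 0 & a$activity_fraction <= 1.05))
  # a different seed gives different noise
  c_ <- gen_titration(titration_sim_spec(noise_cv = 0.1, n_replicates = 3,
                                         seed = 100))
  expect_false(identical(a$activity_fraction, c_$activity_fraction))
})

test_that("envelope generator implements the m/z relation", {
  env <- gen_envelope(envelope_sim_spec(10000, c(7, 8, 9)))
  expect_equal(env$mz, sort((10000 + c(7, 8, 9) * 1.007276) / c(7, 8, 9)))
  single <- gen_envelope(envelope_sim_spec(1000, 1))
  expect_equal(single$mz, 1001.007276)
  expect_error(envelope_sim_spec(1000, integer()), "charges")
  expect_error(envelope_sim_spec(-5, 1), "true_mass")
  expect_error(envelope_sim_spec(1000, c(3, 3)), "charges")
})

test_that("noiseless envelope round trip recovers the mass exactly", {
  env <- gen_envelope(envelope_sim_spec(10000, 7:9))
  dec <- deconvolve(env)
  expect_equal(dec$mass, 10000)
  expect_equal(dec$spread, 0)
  expect_equal(dec$assignment$charges, c(9, 8, 7))
})

test_that("framework generator builds the prescribed scaffold", {
  s <- gen_framework_sequence("ICK", rep(2, 7), seed = 1)
  fw <- extract_framework(s)
  expect_equal(fw$count, 6)
  expect_equal(fw$spacings, rep(2L, 5))
  # ten-cysteine colipase-like scaffold
  s10 <- gen_framework_sequence("MIT1-colipase", rep(3, 11), seed = 2)
  expect_equal(extract_framework(s10)$count, 10)
  # deterministic under seed
  expect_identical(gen_framework_sequence("ICK", rep(4, 7), seed = 5),
                   gen_framework_sequence("ICK", rep(4, 7), seed = 5))
  expect_error(gen_framework_sequence("nosuch", rep(2, 7)), "unknown")
  expect_error(gen_framework_sequence("ICK", rep(2, 6)), "spacer")
})

test_that("toy complex realises requested donor-acceptor distances", {
  m <- toy_pair_model(3.44)
  expect_equal(measure_distance(m, "A/1/NZ", "B/1/OG"), 3.44)
  expect_error(gen_toy_complex(data.frame(
    donor_resname = "LYS", donor_atom = "NZ",
    acceptor_resname = "SER", acceptor_atom = "OG", distance = -1)),
    "conflicting")
  # several pairs at once, all independent
  m2 <- gen_toy_complex(data.frame(
    donor_resname = c("LYS", "HIS"), donor_atom = c("NZ", "ND1"),
    acceptor_resname = c("SER", "GLU"), acceptor_atom = c("OG", "OE1"),
    distance = c(2.9, 10)))
  expect_equal(measure_distance(m2, "A/1/NZ", "B/1/OG"), 2.9)
  expect_equal(measure_distance(m2, "A/2/ND1", "B/2/OE1"), 10)
})
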