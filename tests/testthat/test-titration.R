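test_that("titration series validates its invariants", {
  expect_error(titration_series(c(0, 100), c(1, 0.5, 0.2)), "equal length")
  expect_error(titration_series(c(100, 0), c(0.5, 1)), "increasing")
  expect_error(titration_series(c(0, -5), c(1, 0.9)), ">= 0")
  # micromolar input converts to nM
  ts <- titration_series(c(0, 0.25, 0.5, 1), c(1, 0.6, 0.2, 0.05),
                         unit = "uM")
  expect_equal(ts$inhibitor_total, c(0, 250, 500, 1000))
})

test_that("equivalence extrapolation recovers the sharp-titration corner", {
  # K -> 0: the triangle's rectilinear limb hits zero exactly at E_t
  s <- morrison_series(enzyme_total = 500, kd = 0,
                       grid = seq(0, 2000, by = 100))
  eq <- titration_equivalence(s)
  expect_equal(eq$equivalence, 500, tolerance = 1e-6)
  expect_equal(eq$activity_at_equivalence, 0, tolerance = 1e-9)
})

test_that("equivalence requires a real titration", {
  expect_error(
    titration_equivalence(titration_series(c(0, 100, 200),
                                           c(1, 0.6, 0.2))),
    "at least 4")
  flat <- titration_series(seq(0, 400, 100), rep(1, 5))
  expect_error(titration_equivalence(flat), "decrease|slope")
})

test_that("stoichiometric estimator is exact on dense noiseless data", {
  s <- morrison_series(grid = seq(0, 4000, by = 10))
  est <- kd_stoichiometric(s)
  expect_lt(abs(est$kd - 30.25) / 30.25, 0.01)
  expect_lt(abs(est$equivalence_point - 515) / 515, 0.01)
})

test_that("stoichiometric estimator is exact on the dilution-series grid", {
  est <- kd_stoichiometric(morrison_series())
  expect_equal(est$kd, 30.25, tolerance = 1e-6)
  expect_equal(est$equivalence_point, 515, tolerance = 1e-6)
})

test_that("single-pass reading shows the documented K_D-order bias", {
  # the rectilinear intercept of a convex curve lands near E_t + K_D, so
  # the uncalibrated estimate must fall below truth
  est <- kd_stoichiometric(morrison_series(grid = seq(0, 4000, by = 10)),
                           refine = FALSE)
  expect_gt(est$diagnostics$intercept, 515)
  expect_lt(est$kd, 30.25)
})

test_that("kd = [E][I]/[EI] identity holds exactly on returned estimates", {
  for (seed in 1:5) {
    ts <- gen_titration(titration_sim_spec(seed = seed))
    est <- kd_stoichiometric(ts)
    expect_equal(est$free_enzyme * est$free_inhibitor / est$complex_conc,
                 est$kd, tolerance = 1e-12)
    expect_equal(est$free_enzyme, est$free_inhibitor)
    expect_equal(est$free_enzyme + est$complex_conc, est$equivalence_point,
                 tolerance = 1e-9)
  }
})

test_that("hand-checkable species bookkeeping at the equivalence point", {
  # a_eq = 0.5 at E_t = 100: E = I = 50, EI = 50, kd = 50
  prof <- data.frame(inhibitor_total = c(0, 50, 100, 150, 200),
                     activity_fraction = c(1, 0.75, 0.5, 0.25, 0.1))
  s <- titration_series(prof$inhibitor_total, prof$activity_fraction)
  eq <- titration_equivalence(s, rect_floor = 0.5)
  est <- kd_stoichiometric(s, refine = FALSE)
  a <- est$diagnostics$activity_at_equivalence
  E <- est$equivalence_point
  expect_equal(est$free_enzyme, a * E)
  expect_equal(est$complex_conc, (1 - a) * E)
  expect_equal(est$kd, (a * E)^2 / ((1 - a) * E))
})

test_that("Morrison fit recovers generator truth exactly without noise", {
  s <- morrison_series()
  fit_known <- fit_morrison(s, enzyme_total = 515)
  expect_equal(fit_known$kd, 30.25, tolerance = 1e-6)
  fit_free <- fit_morrison(s)
  expect_equal(fit_free$kd, 30.25, tolerance = 1e-4)
  expect_equal(fit_free$equivalence_point, 515, tolerance = 1e-4)
})

test_that("Morrison fit drives kd to zero on sharp-titration data", {
  s <- morrison_series(enzyme_total = 515, kd = 0)
  fit <- fit_morrison(s, enzyme_total = 515)
  expect_lt(fit$kd, 1) # below grid resolution
})

test_that("the two estimators agree on dense noiseless data", {
  s <- morrison_series(grid = seq(0, 4000, by = 25))
  k1 <- kd_stoichiometric(s)$kd
  k2 <- fit_morrison(s, enzyme_total = 515)$kd
  expect_lt(abs(k1 - k2) / k2, 0.1)
})

test_that("noisy parameter recovery stays within assay precision", {
  # spec'd study conditions: 2% multiplicative noise, triplicates
  kds <- vapply(1:60, function(i) {
    kd_stoichiometric(gen_titration(titration_sim_spec(seed = i)))$kd
  }, numeric(1L))
  expect_lt(median(abs(kds - 30.25)) / 30.25, 0.25)
})

test_that("bootstrap standard error is produced with replicates", {
  ts <- gen_titration(titration_sim_spec(seed = 42))
  est <- kd_stoichiometric(ts, n_boot = 25, seed = 7)
  expect_true(is.finite(est$se_kd))
  expect_gt(est$se_kd, 0)
  # reproducible given the seed
  est2 <- kd_stoichiometric(ts, n_boot = 25, seed = 7)
  expect_identical(est$se_kd, est2$se_kd)
})

test_that("relative potency is a plain ratio", {
  expect_equal(relative_potency(30.25, 7.34), 30.25 / 7.34)
  expect_error(relative_potency(1, 0), "positive")
})
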